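#' Pipeline configuration
#'
#' Collects every input and flag of the full comparative analysis. All
#' arguments have study defaults: the packaged species tables and regime
#' fixture, the four visual responses (interommatidial angle excluded from
#' OU fitting, since it is a deterministic transform of the ommatidium
#' count and would mirror it) and the four antennal responses, natural-log
#' transformation, and no observational error term.
#'
#' @param tree Path to a Newick tree, an [ape::phylo] object, or `NULL`
#'   for a contrasts-only run.
#' @param traits A [species_traits] table, path(s) to species-level trait
#'   CSVs, or `NULL` for the packaged tables.
#' @param regimes A [regime_assignment], a path, or `NULL` for the
#'   packaged assignment.
#' @param responses Traits to model with the OU machinery.
#' @param contrast_traits Traits to contrast between regimes (all shared
#'   traits by default).
#' @param predictor_trait Continuous body-size predictor.
#' @param log_transform,measurement_error Passed to [fit_ou_model()].
#' @param include_delta_gamma_ou Also fit OU models to the interommatidial
#'   angle (default `FALSE`).
#' @param correlate_log Use ln-transformed relative values in
#'   [relative_correlations()].
#' @param out_dir Output directory (`NULL`: nothing written).
#' @param seed Integer seed recorded in the run log (the fixture pipeline
#'   itself is deterministic).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(tree = NULL, traits = NULL, regimes = NULL,
                            responses = c("E_area", "OC_diameter",
                                          "OM_number", "OM_area",
                                          "A_length", "F_length",
                                          "P_length", "ANT_length"),
                            contrast_traits = NULL,
                            predictor_trait = "H_width",
                            log_transform = TRUE,
                            measurement_error = FALSE,
                            include_delta_gamma_ou = FALSE,
                            correlate_log = FALSE,
                            out_dir = NULL, seed = 1L) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full comparative pipeline
#'
#' Orchestrates the study replica: load the species traits and regimes
#' (packaged tables by default), compute the regime contrasts, the
#' interommatidial-angle regression on head width and the size-relative
#' eye-antenna correlations; then, if a tree is supplied, enumerate all
#' maximum-parsimony regime reconstructions and fit the four OU model
#' variants per response under each reconstruction, assembling one AICc
#' comparison block per response. Results are returned as a list and,
#' when `out_dir` is set, written as CSV/JSON files together with a
#' manifest recording the configuration, the package version and the
#' completed stages (a failed stage leaves a manifest flagged incomplete).
#'
#' @param config A [pipeline_config()], or a path to a YAML file whose
#'   keys are `pipeline_config()` arguments.
#' @return List with `traits`, `regimes`, `contrasts`, `angle_regression`,
#'   `correlations`, and (tree runs) `tree`, `paintings`, `ou` (per
#'   reconstruction, per response: the [fit_ou_models()] result).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) {
    args <- yaml::read_yaml(config)
    config <- do.call(pipeline_config, args)
  }
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  manifest <- list(
    package = "flyvis",
    version = as.character(utils::packageVersion("flyvis")),
    seed = config$seed,
    flags = list(log_transform = config$log_transform,
                 measurement_error = config$measurement_error,
                 include_delta_gamma_ou = config$include_delta_gamma_ou,
                 correlate_log = config$correlate_log),
    stages = character(0),
    complete = FALSE
  )
  out <- list(config = config)
  finish_stage <- function(name) {
    manifest$stages <<- c(manifest$stages, name)
    if (!is.null(config$out_dir)) write_manifest(manifest, config$out_dir)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      if (!is.null(config$out_dir)) write_manifest(manifest, config$out_dir)
      stop("stage ", name, ": ", conditionMessage(e), call. = FALSE)
    })
  }
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  }

  out$traits <- stage("load_traits", {
    tr <- config$traits
    if (is.null(tr)) {
      combine_trait_tables(builtin_fixture("table1"), builtin_fixture("table2"))
    } else if (is.character(tr)) {
      do.call(combine_trait_tables, lapply(tr, read_trait_table))
    } else {
      species_traits(tr)
    }
  })
  out$regimes <- stage("load_regimes", {
    rg <- config$regimes
    if (is.null(rg)) {
      builtin_fixture("regimes")
    } else if (is.character(rg)) {
      read_regimes(rg)
    } else {
      regime_assignment(rg)
    }
  })
  finish_stage("load_inputs")

  out$contrasts <- stage("contrasts", {
    trs <- config$contrast_traits
    if (is.null(trs)) trs <- unique(out$traits$trait)
    do.call(rbind, lapply(trs, function(tr) {
      group_summary(out$traits, out$regimes, tr)
    }))
  })
  out$angle_regression <- stage("angle_regression", {
    if (all(c("delta_gamma", "H_width") %in% out$traits$trait)) {
      hw <- trait_means(out$traits, "H_width")
      dg <- trait_means(out$traits, "delta_gamma", species = names(hw))
      ols_regression(hw, dg)
    }
  })
  out$correlations <- stage("correlations", {
    eyes <- intersect(c("OM_number", "E_area"), unique(out$traits$trait))
    ants <- intersect(c("ANT_length", "A_length", "F_length"),
                      unique(out$traits$trait))
    if (length(eyes) > 0 && length(ants) > 0) {
      relative_correlations(out$traits, eyes, ants, log = config$correlate_log)
    }
  })
  finish_stage("contrasts")

  if (!is.null(config$tree)) {
    out$tree <- stage("load_tree", {
      if (is.character(config$tree)) read_tree(config$tree) else {
        validate_tree(config$tree)
        rescale_tree_depth(config$tree)
      }
    })
    out$paintings <- stage("parsimony", {
      enumerate_mp_reconstructions(out$tree, out$regimes)
    })
    responses <- config$responses
    if (config$include_delta_gamma_ou) responses <- c(responses, "delta_gamma")
    responses <- intersect(responses, unique(out$traits$trait))
    out$ou <- stage("ou_models", {
      lapply(seq_along(out$paintings), function(pi) {
        blocks <- lapply(responses, function(resp) {
          fit_ou_models(out$tree, out$traits, out$paintings[[pi]], resp,
                        predictor_trait = config$predictor_trait,
                        log_transform = config$log_transform,
                        measurement_error = config$measurement_error)
        })
        names(blocks) <- responses
        blocks
      })
    })
    finish_stage("ou_models")
  }

  if (!is.null(config$out_dir)) {
    stage("write_outputs", write_pipeline_outputs(out, config$out_dir))
    manifest$complete <- TRUE
    finish_stage("write_outputs")
  } else {
    manifest$complete <- TRUE
  }
  out$manifest <- manifest
  invisible(out)
}

write_manifest <- function(manifest, out_dir) {
  jsonlite::write_json(manifest, file.path(out_dir, "MANIFEST.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

write_pipeline_outputs <- function(out, out_dir) {
  write_trait_table(out$traits, file.path(out_dir, "species_traits.csv"))
  utils::write.csv(out$contrasts, file.path(out_dir, "contrasts.csv"),
                   row.names = FALSE)
  if (!is.null(out$correlations)) {
    utils::write.csv(out$correlations, file.path(out_dir, "correlations.csv"),
                     row.names = FALSE)
  }
  if (!is.null(out$angle_regression)) {
    jsonlite::write_json(out$angle_regression,
                         file.path(out_dir, "angle_regression.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(out$ou)) {
    ape::write.tree(out$tree, file.path(out_dir, "tree.nwk"))
    paint_json <- lapply(out$paintings, function(p) {
      list(reconstruction_index = p$reconstruction_index,
           root_regime = p$root_regime, n_changes = p$n_changes,
           node_state = p$node_state)
    })
    jsonlite::write_json(paint_json, file.path(out_dir, "paintings.json"),
                         auto_unbox = TRUE, digits = NA)
    fits_json <- lapply(out$ou, function(per_painting) {
      lapply(per_painting, function(block) {
        tab <- block$comparison
        tab$optima <- I(lapply(block$fits, function(f) as.list(f$optima)))
        tab
      })
    })
    jsonlite::write_json(fits_json, file.path(out_dir, "ou_fits.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(out_dir)
}
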