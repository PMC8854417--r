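#' Species trait tables
#'
#' A species trait table is a long-format data frame with one row per
#' species x trait combination and columns `species_id`, `trait`, `mean`,
#' `se` and (optionally) `n`, carrying class `"species_traits"`. All trait
#' means must be finite and strictly positive; standard errors must be
#' non-negative when present. When the three antennal parts and the total
#' antennal length are all present for a species, the total must agree with
#' the sum of the parts to within 5% (means of sums and sums of means can
#' differ slightly when specimens have missing parts).
#'
#' @param x A data frame with columns `species_id`, `trait`, `mean`, `se`
#'   and optionally `n`.
#' @return `x` with class `"species_traits"` prepended, after validation.
#' @seealso [read_trait_table()], [trait_means()], [builtin_fixture()]
#' @export
species_traits <- function(x) {
  stopifnot(is.data.frame(x))
  needed <- c("species_id", "trait", "mean", "se")
  missing_cols <- setdiff(needed, names(x))
  if (length(missing_cols) > 0) {
    stop("trait table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(x) == 0) stop("no records in trait table")
  if (!("n" %in% names(x))) x$n <- NA_integer_
  x$species_id <- normalize_species_id(x$species_id)
  if (anyDuplicated(x[, c("species_id", "trait")])) {
    dup <- x[duplicated(x[, c("species_id", "trait")]), , drop = FALSE]
    stop("duplicated species/trait combination: ",
         dup$species_id[1], " / ", dup$trait[1])
  }
  if (any(!is.finite(x$mean)) || any(x$mean <= 0)) {
    bad <- which(!is.finite(x$mean) | x$mean <= 0)[1]
    stop("trait mean must be finite and positive (row ", bad, ": ",
         x$species_id[bad], " / ", x$trait[bad], ")")
  }
  if (any(!is.na(x$se) & x$se < 0)) stop("negative standard error")
  check_antenna_sum(x)
  class(x) <- unique(c("species_traits", class(x)))
  x
}

# |ANT - (F + P + A)| / ANT < 0.05 whenever all four are present.
# A warning, not an error: species means of per-specimen sums legitimately
# drift from sums of species means when specimens have missing parts, and
# published tables occasionally exceed the heuristic bound.
check_antenna_sum <- function(x) {
  parts <- c("F_length", "P_length", "A_length")
  for (sp in unique(x$species_id)) {
    rows <- x[x$species_id == sp, , drop = FALSE]
    if (all(c(parts, "ANT_length") %in% rows$trait)) {
      ant <- rows$mean[rows$trait == "ANT_length"]
      s <- sum(rows$mean[match(parts, rows$trait)])
      if (abs(ant - s) / ant >= 0.05) {
        warning("antennal length of ", sp, " (", ant,
                ") inconsistent with funiculus + pedicel + arista (", s, ")",
                call. = FALSE)
      }
    }
  }
  invisible(TRUE)
}

normalize_species_id <- function(id) {
  id <- trimws(as.character(id))
  gsub("[[:space:]]+", " ", id)
}

#' Extract a named vector of species means for one trait
#'
#' @param traits A [species_traits] table.
#' @param trait Trait name, e.g. `"E_area"`.
#' @param species Optional character vector giving the species order of the
#'   result; defaults to the order of first appearance in the table.
#' @return Named numeric vector of species means.
#' @export
trait_means <- function(traits, trait, species = NULL) {
  rows <- traits[traits$trait == trait, , drop = FALSE]
  if (nrow(rows) == 0) stop("trait not present in table: ", trait)
  out <- stats::setNames(rows$mean, rows$species_id)
  if (!is.null(species)) {
    miss <- setdiff(species, names(out))
    if (length(miss) > 0) {
      stop("trait ", trait, " missing for species: ", paste(miss, collapse = ", "))
    }
    out <- out[species]
  }
  out
}

#' @rdname trait_means
#' @export
trait_ses <- function(traits, trait, species = NULL) {
  rows <- traits[traits$trait == trait, , drop = FALSE]
  if (nrow(rows) == 0) stop("trait not present in table: ", trait)
  out <- stats::setNames(rows$se, rows$species_id)
  if (!is.null(species)) out <- out[species]
  out
}

#' Combine trait tables that cover different traits of the same species
#'
#' @param ... [species_traits] tables.
#' @return A single validated [species_traits] table.
#' @export
combine_trait_tables <- function(...) {
  tabs <- list(...)
  cols <- c("species_id", "trait", "mean", "se", "n")
  tabs <- lapply(tabs, function(t) {
    if (!("n" %in% names(t))) t$n <- NA_integer_
    as.data.frame(t)[, cols]
  })
  species_traits(do.call(rbind, tabs))
}
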