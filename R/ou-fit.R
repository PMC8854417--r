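#' Fit one Hansen-type OU adaptive-regression model
#'
#' Maximum-likelihood fit of an Ornstein-Uhlenbeck model for a species
#' trait on an ultrametric tree, parametrized by the phylogenetic half-life
#' `t_half = ln(2)/alpha` (in units of tree depth) and the stationary
#' variance `v_y = sigma2/(2 alpha)`. Four model variants cover the usual
#' comparative questions:
#'
#' * `"none"` — intercept only; the half-life measures the overall
#'   phylogenetic effect on the trait.
#' * `"bm"` — a Brownian-motion body-size predictor (head width by
#'   default); the GLS slope on the observed predictor is the
#'   *evolutionary* slope, and dividing it by [rho_ou()]`(alpha T)` gives
#'   the inertia-free *optimal* slope.
#' * `"regime"` — regime-dependent primary optima fixed by a branch
#'   painting of the binary host-finding character (the [regime_weights()]
#'   design).
#' * `"both"` — regime optima plus the body-size predictor.
#'
#' The likelihood is maximized over a grid of half-lives
#' (`{0} U logspace(-3, 1, 60) x depth U {Inf}`) with the scale parameter
#' profiled analytically at each grid point when no measurement error is
#' included (it is then a pure scale of the covariance), followed by local
#' refinement around the best grid cell. The `t_half = 0` (white-noise GLS)
#' and `t_half = Inf` (Brownian-motion GLS, free diffusion variance
#' `sigma2`) endpoints are handled as exact analytic limits, so both can be
#' reported as maximum-likelihood estimates. With
#' `measurement_error = TRUE` the squared trait standard errors are added
#' to the covariance diagonal and the surface is explored on a full
#' (t_half, v_y) grid with Nelder-Mead refinement. The reported support
#' region is the set of half-lives whose profile log-likelihood lies
#' within 2 units of the maximum.
#'
#' @param tree Ultrametric [ape::phylo] tree (depth conventionally 1).
#' @param traits A [species_traits] table covering all tips.
#' @param painting A `regime_painting` (required for the `"regime"` and
#'   `"both"` variants).
#' @param response Trait name of the response.
#' @param predictors One of `"none"`, `"bm"`, `"regime"`, `"both"`.
#' @param predictor_trait Trait used as the continuous body-size predictor.
#' @param log_transform Natural-log transform the response (and predictor)
#'   before fitting (default `TRUE`; comparative analyses of positive size
#'   traits are conventionally done on the log scale).
#' @param measurement_error Add squared standard errors of the species
#'   means to the covariance diagonal (delta-method transferred to the log
#'   scale when `log_transform` is on). Default `FALSE`.
#' @param t_half_grid Optional custom half-life grid (absolute units).
#' @param v_y_grid_length Number of `v_y` grid points per half-life in the
#'   measurement-error path.
#' @param refine Locally refine the best grid cell (default `TRUE`).
#' @return An object of class `ou_fit`: a list with the estimates
#'   (`t_half`, `support_region`, `v_y`, `alpha`, `sigma2`, `optima`,
#'   `optimal_slope`, `optimal_slope_se`, `evolutionary_slope`,
#'   `evolutionary_slope_se`), the fit summaries (`logL`, `k_params`,
#'   `AICc`, `R2_phylo`, `n`), the coefficient table, and the half-life
#'   profile (`profile`).
#' @export
fit_ou_model <- function(tree, traits, painting = NULL, response,
                         predictors = c("none", "bm", "regime", "both"),
                         predictor_trait = "H_width",
                         log_transform = TRUE,
                         measurement_error = FALSE,
                         t_half_grid = NULL,
                         v_y_grid_length = 25,
                         refine = TRUE) {
  predictors <- match.arg(predictors)
  validate_tree(tree)
  tips <- tree$tip.label
  n <- length(tips)
  y <- trait_means(traits, response, species = tips)
  se <- trait_ses(traits, response, species = tips)
  x <- NULL
  if (predictors %in% c("bm", "both")) {
    x <- trait_means(traits, predictor_trait, species = tips)
    if (log_transform) x <- log(x)
  }
  if (predictors %in% c("regime", "both") && is.null(painting)) {
    stop("a regime painting is required for the '", predictors, "' model")
  }
  me <- rep(0, n)
  if (measurement_error) {
    if (anyNA(se)) stop("measurement_error = TRUE requires standard errors for all species")
    me <- if (log_transform) (se / y)^2 else se^2
  }
  if (log_transform) y <- log(y)

  Tdepth <- max(ape::node.depth.edgelength(tree))
  S <- ape::vcv(tree)
  D <- outer(diag(S), diag(S), "+") - 2 * S
  k_grid <- if (is.null(t_half_grid)) {
    c(0, exp(seq(log(1e-3), log(10), length.out = 60)) * Tdepth, Inf)
  } else {
    sort(unique(t_half_grid))
  }

  design <- function(alpha) {
    X <- switch(predictors,
      none = matrix(1, n, 1, dimnames = list(tips, "theta")),
      bm = cbind(intercept = 1, x = x),
      regime = regime_weights(tree, painting, alpha),
      both = cbind(regime_weights(tree, painting, alpha), x = x)
    )
    keep <- colSums(abs(X)) > 1e-12   # alpha = 0 collapses non-root optima
    X[, keep, drop = FALSE]
  }
  shape <- function(alpha) {          # unit-scale covariance shape
    if (is.infinite(alpha)) return(diag(1, n))
    if (alpha * Tdepth < 1e-10) return(S)
    (1 - exp(-2 * alpha * S)) * exp(-alpha * D)
  }

  # profile logL at one half-life; returns the fit augmented with the scale
  eval_t_half <- function(t_half, v_y = NULL) {
    alpha <- if (t_half == 0) Inf else log(2) / t_half
    X <- design(alpha)
    V0 <- shape(alpha)
    if (!measurement_error) {
      fit <- tryCatch(gls_profile_scale(X, V0, y), error = function(e) NULL)
      if (is.null(fit)) return(NULL)
      fit$t_half <- t_half
      fit$scale <- fit$scale_hat
      return(fit)
    }
    # measurement-error path: grid over the scale parameter
    scales <- if (is.null(v_y)) me_scale_grid(X, V0, y, v_y_grid_length) else v_y
    best <- NULL
    for (s in scales) {
      fit <- tryCatch(gls_fit(X, s * V0 + diag(me, n), y),
                      error = function(e) NULL)
      if (!is.null(fit) && (is.null(best) || fit$logL > best$logL)) {
        best <- fit
        best$scale <- s
      }
    }
    if (!is.null(best)) best$t_half <- t_half
    best
  }

  fits <- lapply(k_grid, eval_t_half)
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok)) stop("likelihood could not be evaluated on the half-life grid")
  k_grid <- k_grid[ok]
  fits <- fits[ok]
  prof <- vapply(fits, `[[`, 0, "logL")
  best_i <- which.max(prof)
  best <- fits[[best_i]]

  if (refine && is.finite(k_grid[best_i]) && k_grid[best_i] > 0) {
    lo <- if (best_i > 1 && k_grid[best_i - 1] > 0) k_grid[best_i - 1] else k_grid[best_i] / 2
    hi <- if (best_i < length(k_grid) && is.finite(k_grid[best_i + 1])) {
      k_grid[best_i + 1]
    } else {
      k_grid[best_i] * 2
    }
    if (!measurement_error) {
      opt <- stats::optimize(function(lt) {
        f <- eval_t_half(exp(lt))
        if (is.null(f)) -Inf else f$logL
      }, interval = log(c(lo, hi)), maximum = TRUE, tol = 1e-6)
      cand <- eval_t_half(exp(opt$maximum))
    } else {
      start <- c(log(k_grid[best_i]), log(best$scale))
      nm <- stats::optim(start, function(p) {
        f <- eval_t_half(exp(p[1]), v_y = exp(p[2]))
        if (is.null(f)) Inf else -f$logL
      }, method = "Nelder-Mead")
      cand <- eval_t_half(exp(nm$par[1]), v_y = exp(nm$par[2]))
    }
    if (!is.null(cand) && cand$logL > best$logL) best <- cand
  }

  t_half <- best$t_half
  alpha <- if (t_half == 0) Inf else log(2) / t_half
  v_y <- if (is.infinite(t_half)) Inf else best$scale
  sigma2 <- if (is.infinite(t_half)) best$scale else 2 * alpha * best$scale

  support <- support_region(k_grid, prof, max(prof, best$logL))

  beta <- best$coefficients
  se_beta <- best$se
  regimes_present <- if (!is.null(painting)) {
    sort(unique(c(painting$edge_regime, painting$root_regime)))
  } else {
    character(0)
  }
  optima <- switch(predictors,
    none = stats::setNames(beta[1], "theta"),
    bm = NULL,
    regime = ,
    both = {
      th <- stats::setNames(rep(NA_real_, length(regimes_present)), regimes_present)
      hit <- intersect(names(beta), regimes_present)
      th[hit] <- beta[hit]
      th
    }
  )
  evo_slope <- if ("x" %in% names(beta)) unname(beta["x"]) else NA_real_
  evo_se <- if ("x" %in% names(se_beta)) unname(se_beta["x"]) else NA_real_
  r <- rho_ou(alpha * Tdepth)
  r <- if (is.infinite(alpha)) 1 else r
  opt_slope <- if (is.na(evo_slope)) NA_real_ else if (r > 0) evo_slope / r else Inf * sign(evo_slope)
  opt_se <- if (is.na(evo_se)) NA_real_ else if (r > 0) evo_se / r else Inf

  k_params <- 2 + length(beta)
  if (n - k_params - 1 <= 0) {
    stop("too few species (n = ", n, ") for k = ", k_params, " parameters")
  }
  if (!is.finite(best$logL)) stop("non-finite likelihood at the optimum")
  aicc <- -2 * best$logL + 2 * k_params + 2 * k_params * (k_params + 1) / (n - k_params - 1)

  structure(list(
    response = response,
    predictors = predictors,
    log_transform = log_transform,
    measurement_error = measurement_error,
    t_half = t_half,
    support_region = support,
    v_y = v_y,
    alpha = alpha,
    sigma2 = sigma2,
    optima = optima,
    optimal_slope = opt_slope,
    optimal_slope_se = opt_se,
    evolutionary_slope = evo_slope,
    evolutionary_slope_se = evo_se,
    coefficients = beta,
    coefficient_se = se_beta,
    logL = best$logL,
    k_params = k_params,
    n = n,
    AICc = aicc,
    R2_phylo = best$R2_phylo,
    tree_depth = Tdepth,
    profile = data.frame(t_half = k_grid, logL = prof)
  ), class = "ou_fit")
}

# starting v_y grid for the measurement-error path: logspace around the
# OLS residual variance
me_scale_grid <- function(X, V0, y, length_out) {
  r <- stats::lsfit(X, y, intercept = FALSE)$residuals
  s2 <- max(stats::var(r), 1e-10)
  exp(seq(log(s2 / 100), log(s2 * 100), length.out = length_out))
}

# half-lives whose profile logL is within 2 units of the maximum,
# with log-linear interpolation at the crossings
support_region <- function(t_half, logL, max_logL) {
  thr <- max_logL - 2
  inside <- logL >= thr
  if (!any(inside)) return(c(NA_real_, NA_real_))
  i <- range(which(inside))
  lo <- t_half[i[1]]
  hi <- t_half[i[2]]
  interp <- function(t1, l1, t2, l2) {
    # crossing between (t1,l1) outside and (t2,l2) inside
    f <- (thr - l1) / (l2 - l1)
    if (t1 == 0 || !is.finite(t2)) return(t1 + f * (t2 - t1))
    exp(log(t1) + f * (log(t2) - log(t1)))
  }
  if (i[1] > 1) lo <- interp(t_half[i[1] - 1], logL[i[1] - 1], lo, logL[i[1]])
  if (i[2] < length(t_half)) {
    hi <- interp(t_half[i[2] + 1], logL[i[2] + 1], hi, logL[i[2]])
  }
  c(lo, hi)
}

#' @export
print.ou_fit <- function(x, digits = 3, ...) {
  cat("Hansen OU fit: ", x$response, " ~ ", x$predictors,
      if (x$log_transform) " (log scale)", "\n", sep = "")
  cat("  t_half = ", format(x$t_half, digits = digits),
      "  support [", format(x$support_region[1], digits = digits), ", ",
      format(x$support_region[2], digits = digits), "]",
      "  v_y = ", format(x$v_y, digits = digits), "\n", sep = "")
  if (!is.na(x$evolutionary_slope)) {
    cat("  slopes: optimal ", format(x$optimal_slope, digits = digits),
        " +- ", format(x$optimal_slope_se, digits = digits),
        ", evolutionary ", format(x$evolutionary_slope, digits = digits),
        " +- ", format(x$evolutionary_slope_se, digits = digits), "\n", sep = "")
  }
  if (!is.null(x$optima)) {
    cat("  optima:", paste(names(x$optima),
        format(x$optima, digits = digits), sep = " = ", collapse = ", "), "\n")
  }
  cat("  logL = ", format(x$logL, digits = 6), ", k = ", x$k_params,
      ", AICc = ", format(x$AICc, digits = 5),
      ", R2_phylo = ", format(x$R2_phylo, digits = digits), "\n", sep = "")
  invisible(x)
}

#' Compare OU model variants by AICc
#'
#' Ranks fits of the same response by small-sample corrected AIC, computes
#' `delta = AICc - min(AICc)`, flags the single best model and all models
#' within `delta < 4` (conventionally treated as equally supported).
#'
#' @param fits A list of [fit_ou_model()] results for the same response
#'   (at least two).
#' @param delta_threshold Support threshold (default 4).
#' @return A data frame of class `ou_model_comparison` with one row per
#'   model, in input order, plus `delta`, `best` and `equally_supported`.
#' @examples
#' \dontrun{
#' compare_models(list(fit_none, fit_bm, fit_regime, fit_both))
#' }
#' @export
compare_models <- function(fits, delta_threshold = 4) {
  if (length(fits) < 2) stop("need at least two fits to compare")
  responses <- vapply(fits, `[[`, "", "response")
  if (length(unique(responses)) != 1) {
    stop("fits mix responses: ", paste(unique(responses), collapse = ", "))
  }
  aicc <- vapply(fits, `[[`, 0, "AICc")
  delta <- aicc - min(aicc)
  best <- seq_along(fits) == which.min(aicc)
  out <- data.frame(
    response = responses,
    predictors = vapply(fits, `[[`, "", "predictors"),
    t_half = vapply(fits, `[[`, 0, "t_half"),
    support_lo = vapply(fits, function(f) f$support_region[1], 0),
    support_hi = vapply(fits, function(f) f$support_region[2], 0),
    v_y = vapply(fits, `[[`, 0, "v_y"),
    optimal_slope = vapply(fits, `[[`, 0, "optimal_slope"),
    optimal_slope_se = vapply(fits, `[[`, 0, "optimal_slope_se"),
    evolutionary_slope = vapply(fits, `[[`, 0, "evolutionary_slope"),
    evolutionary_slope_se = vapply(fits, `[[`, 0, "evolutionary_slope_se"),
    R2_phylo = vapply(fits, `[[`, 0, "R2_phylo"),
    logL = vapply(fits, `[[`, 0, "logL"),
    AICc = aicc,
    delta = delta,
    best = best,
    equally_supported = delta < delta_threshold
  )
  class(out) <- c("ou_model_comparison", class(out))
  out
}

#' Fit all four OU model variants for one response
#'
#' Convenience wrapper running the intercept-only, body-size, regime and
#' regime + body-size models and assembling the AICc comparison.
#'
#' @inheritParams fit_ou_model
#' @return List with elements `fits` (named list of [fit_ou_model()]
#'   results) and `comparison` (the [compare_models()] table).
#' @export
fit_ou_models <- function(tree, traits, painting, response,
                          predictor_trait = "H_width",
                          log_transform = TRUE,
                          measurement_error = FALSE, ...) {
  variants <- c("none", "bm", "regime", "both")
  fits <- lapply(variants, function(p) {
    fit_ou_model(tree, traits, painting, response, predictors = p,
                 predictor_trait = predictor_trait,
                 log_transform = log_transform,
                 measurement_error = measurement_error, ...)
  })
  names(fits) <- variants
  list(fits = fits, comparison = compare_models(fits))
}
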