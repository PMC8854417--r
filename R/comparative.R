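#' Two-sample t-test on species means
#'
#' Equal-variance (pooled) Student t-test by default, with
#' `df = n1 + n2 - 2`; Welch's unequal-variance test is available behind
#' the `welch` flag.
#'
#' @param a,b Numeric vectors of species means (each of length `>= 2`).
#' @param welch Use the Welch test instead of pooling (default `FALSE`).
#' @return List with `t`, `df`, `p` (two-sided).
#' @export
pooled_t_test <- function(a, b, welch = FALSE) {
  if (length(a) < 2 || length(b) < 2) stop("each group needs n >= 2")
  tt <- stats::t.test(a, b, var.equal = !welch)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = unname(tt$p.value))
}

#' Group contrast of one trait between regimes
#'
#' Unweighted mean and standard error (sd / sqrt(n)) of the species means
#' per regime, the group ratio reported in the direction that makes it
#' `>= 1` (with a direction label), and the pooled two-sample t-test.
#'
#' @param traits A [species_traits] table.
#' @param regimes A [regime_assignment] covering the species.
#' @param trait Trait name.
#' @param welch Use Welch's t-test (default pooled).
#' @return A one-row data frame of class `group_contrast` with the group
#'   summaries, `ratio`, `ratio_direction` (`"SAT/NON_SAT"` or
#'   `"NON_SAT/SAT"`), `t`, `df`, `p`.
#' @examples
#' t1 <- builtin_fixture("table1")
#' rg <- builtin_fixture("regimes")
#' group_summary(t1, rg, "E_area")  # eye area ~1.74x greater in SAT
#' @export
group_summary <- function(traits, regimes, trait, welch = FALSE) {
  m <- trait_means(traits, trait)
  reg <- stats::setNames(regimes$regime, regimes$species_id)[names(m)]
  if (anyNA(reg)) {
    stop("species without regime: ",
         paste(names(m)[is.na(reg)], collapse = ", "))
  }
  a <- m[reg == "SAT"]
  b <- m[reg == "NON_SAT"]
  if (length(a) == 0 || length(b) == 0) stop("empty regime group for ", trait)
  se_of <- function(v) if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_
  ratio_raw <- mean(a) / mean(b)
  tt <- if (length(a) > 1 && length(b) > 1) {
    pooled_t_test(a, b, welch = welch)
  } else {
    list(t = NA_real_, df = NA_real_, p = NA_real_)
  }
  out <- data.frame(
    trait = trait,
    mean_SAT = mean(a), se_SAT = se_of(a), n_SAT = length(a),
    mean_NONSAT = mean(b), se_NONSAT = se_of(b), n_NONSAT = length(b),
    ratio = max(ratio_raw, 1 / ratio_raw),
    ratio_direction = if (ratio_raw >= 1) "SAT/NON_SAT" else "NON_SAT/SAT",
    t = tt$t, df = tt$df, p = tt$p
  )
  class(out) <- c("group_contrast", class(out))
  out
}

#' Simple least-squares regression
#'
#' Ordinary least squares of `y` on `x` with the usual coefficient of
#' determination. Thin wrapper over [stats::lm()] kept as a stable surface
#' for report code.
#'
#' @param x,y Numeric vectors (`n >= 3`, `x` not constant).
#' @return List with `slope`, `intercept`, `R2`.
#' @export
ols_regression <- function(x, y) {
  if (length(x) < 3) stop("need at least 3 points")
  if (stats::sd(x) == 0) stop("x is constant")
  fit <- stats::lm(y ~ x)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       R2 = summary(fit)$r.squared)
}

#' Size-relative Pearson correlations between eye and antennal traits
#'
#' Divides every trait by head width (x100, see [relative_trait()]) and
#' computes the Pearson correlation with a two-sided test for every
#' (eye trait, antennal trait) pair. Set `log = TRUE` to correlate the
#' natural logs of the relative values instead.
#'
#' @param traits A [species_traits] table containing `H_width`, the eye
#'   traits and the antennal traits.
#' @param eye_traits,antennal_traits Character vectors of trait names.
#' @param log Correlate ln-transformed relative values (default `FALSE`).
#' @return Data frame with one row per pair: `eye_trait`,
#'   `antennal_trait`, `r`, `p`, `n`.
#' @export
relative_correlations <- function(traits,
                                  eye_traits = c("OM_number", "E_area"),
                                  antennal_traits = c("ANT_length", "A_length", "F_length"),
                                  log = FALSE) {
  hw <- trait_means(traits, "H_width")
  rel <- function(tr) {
    v <- trait_means(traits, tr)
    sp <- intersect(names(v), names(hw))
    r <- relative_trait(v[sp], hw[sp])
    if (log) base::log(r) else r
  }
  out <- list()
  for (e in eye_traits) {
    for (a in antennal_traits) {
      re <- rel(e); ra <- rel(a)
      sp <- intersect(names(re), names(ra))
      if (length(sp) < 3) stop("fewer than 3 complete species for ", e, " vs ", a)
      ct <- stats::cor.test(re[sp], ra[sp])
      out[[length(out) + 1]] <- data.frame(
        eye_trait = e, antennal_trait = a,
        r = unname(ct$estimate), p = ct$p.value, n = length(sp)
      )
    }
  }
  do.call(rbind, out)
}
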