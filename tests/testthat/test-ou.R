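test_that("OU covariance has the right limits and shape", {
  tree <- simulate_tree(8, seed = 3)
  S <- ape::vcv(tree)
  # stationary independence at alpha -> Inf
  V <- ou_covariance(tree, Inf, v_y = 0.3)
  expect_equal(V, diag(0.3, 8), ignore_attr = TRUE)
  # Brownian limit: with sigma2 held fixed, small alpha converges to BM
  V_bm <- ou_covariance(tree, 0, v_y = 0, sigma2 = 2)
  expect_equal(V_bm, 2 * S)
  V_small <- ou_covariance(tree, 1e-8, v_y = 2 / (2 * 1e-8))
  expect_lt(max(abs(V_small - V_bm)) / max(V_bm), 1e-6)
  # symmetric positive semi-definite at a generic alpha
  V1 <- ou_covariance(tree, 1.7, v_y = 0.5)
  expect_equal(V1, t(V1))
  expect_true(all(eigen(V1, symmetric = TRUE, only.values = TRUE)$values > -1e-12))
  expect_error(ou_covariance(tree, -1, 1), "alpha")
})

test_that("OU covariance matches Monte-Carlo covariance of exact simulations", {
  tree <- simulate_tree(5, seed = 9)
  sim <- simulate_regimes(tree, "clade_paint", seed = 10)
  t_half <- log(2)          # alpha = 1
  v_y <- 0.25
  nrep <- 1e5
  tips <- simulate_ou_tips(tree, sim$painting, t_half, v_y,
                           c(NON_SAT = 0, SAT = 0), nrep = nrep, seed = 11)
  V_mc <- stats::cov(tips)
  V <- ou_covariance(tree, 1, v_y)
  se <- sqrt((outer(diag(V), diag(V)) + V^2) / nrep)
  expect_true(all(abs(V_mc - V) < 3.5 * se))
})

test_that("regime weights sum to one and hit both rate limits", {
  set.seed(5)
  for (i in 1:5) {
    tree <- simulate_tree(10, seed = 50 + i)
    sim <- simulate_regimes(tree, "markov", seed = 60 + i, rate = 2)
    W <- regime_weights(tree, sim$painting, alpha = 2)
    expect_equal(unname(rowSums(W)), rep(1, 10), tolerance = 1e-12)
    # alpha -> 0: everything collapses onto the root regime
    W0 <- regime_weights(tree, sim$painting, alpha = 1e-12)
    expect_equal(unname(W0[, sim$painting$root_regime]), rep(1, 10),
                 tolerance = 1e-9)
    # alpha -> Inf: indicator of the terminal branch's regime
    Winf <- regime_weights(tree, sim$painting, alpha = Inf)
    term <- match(seq_len(10), tree$edge[, 2])
    expect_equal(
      Winf[cbind(seq_len(10),
                 match(sim$painting$edge_regime[term], colnames(Winf)))],
      rep(1, 10), ignore_attr = TRUE
    )
  }
})

test_that("GLS reduces to OLS under identity covariance", {
  x <- c(1.2, 2.5, 3.1, 4.8, 5.0, 6.6)
  y <- c(2.0, 4.9, 6.4, 10.1, 9.8, 13.7)
  X <- cbind(1, x)
  fit <- gls_fit(X, diag(6), y)
  ols <- lm(y ~ x)
  expect_equal(unname(fit$coefficients), unname(coef(ols)), tolerance = 1e-10)
  # with V = I taken as known, SEs come from (X'X)^-1 without a scale factor
  expect_equal(unname(fit$se),
               unname(sqrt(diag(vcov(ols) / summary(ols)$sigma^2))),
               tolerance = 1e-10)
  # a perfectly linear response has R2 = 1 and zero residuals
  fit2 <- gls_fit(X, diag(6), 2 * x + 1)
  expect_equal(fit2$R2_phylo, 1)
  expect_equal(max(abs(fit2$residuals)), 0, tolerance = 1e-12)
})

test_that("GLS coefficients are invariant to covariance rescaling", {
  set.seed(12)
  n <- 12
  A <- matrix(rnorm(n * n), n)
  V <- crossprod(A) + diag(n)
  X <- cbind(1, rnorm(n))
  y <- rnorm(n)
  f1 <- gls_fit(X, V, y)
  f2 <- gls_fit(X, 7.3 * V, y)
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-10)
  expect_error(gls_fit(cbind(X, X[, 2]), V, y), "rank deficient")
})

test_that("the white-noise endpoint reproduces ordinary least squares exactly", {
  d <- ou_test_data()
  fit <- fit_ou_model(d$tree, d$traits, d$painting, "y", predictors = "bm",
                      predictor_trait = "x", t_half_grid = 0, refine = FALSE)
  yv <- log(trait_means(d$traits, "y", d$tree$tip.label))
  xv <- log(trait_means(d$traits, "x", d$tree$tip.label))
  ols <- lm(yv ~ xv)
  expect_equal(unname(fit$coefficients), unname(coef(ols)), tolerance = 1e-10)
  expect_equal(fit$logL, as.numeric(logLik(ols)), tolerance = 1e-10)
  expect_equal(fit$t_half, 0)
  expect_equal(fit$evolutionary_slope, fit$optimal_slope)  # rho(Inf) = 1
})

test_that("the Brownian endpoint matches an independent phylogenetic GLS", {
  skip_if_not_installed("nlme")
  d <- ou_test_data()
  fit <- fit_ou_model(d$tree, d$traits, d$painting, "y", predictors = "bm",
                      predictor_trait = "x", t_half_grid = Inf, refine = FALSE)
  df <- data.frame(
    yv = log(trait_means(d$traits, "y", d$tree$tip.label)),
    xv = log(trait_means(d$traits, "x", d$tree$tip.label)),
    sp = d$tree$tip.label
  )
  g <- nlme::gls(yv ~ xv, data = df, method = "ML",
                 correlation = ape::corBrownian(phy = d$tree, form = ~sp))
  expect_equal(fit$logL, as.numeric(logLik(g)), tolerance = 1e-4)
  expect_equal(unname(fit$coefficients), unname(coef(g)), tolerance = 1e-6)
  expect_true(is.infinite(fit$v_y))
})

test_that("maximized likelihood agrees with an independent generic optimizer", {
  d <- ou_test_data()
  fit <- fit_ou_model(d$tree, d$traits, d$painting, "y", predictors = "regime")
  # independent route: covariance and normal density built from scratch,
  # joint optimization over (log alpha, log v_y) with profiled-out betas
  S <- ape::vcv(d$tree)
  D <- outer(diag(S), diag(S), "+") - 2 * S
  yv <- log(trait_means(d$traits, "y", d$tree$tip.label))
  negll <- function(p) {
    a <- exp(p[1]); v <- exp(p[2])
    V <- v * (1 - exp(-2 * a * S)) * exp(-a * D)
    W <- regime_weights(d$tree, d$painting, a)
    b <- solve(t(W) %*% solve(V, W), t(W) %*% solve(V, yv))
    r <- yv - W %*% b
    0.5 * (length(yv) * log(2 * pi) +
             determinant(V)$modulus + t(r) %*% solve(V, r))[1]
  }
  opt <- optim(c(log(log(2) / fit$t_half), log(fit$v_y)), negll,
               method = "Nelder-Mead",
               control = list(reltol = 1e-12, maxit = 5000))
  expect_equal(fit$logL, -opt$value, tolerance = 1e-4)
})

test_that("rho links the optimal and evolutionary regressions", {
  x <- seq(0.01, 20, by = 0.01)
  r <- rho_ou(x)
  expect_true(all(diff(r) > 0))
  expect_true(all(r > 0 & r < 1))
  expect_equal(rho_ou(1e-9), 0, tolerance = 1e-8)
  expect_equal(rho_ou(1e4), 1, tolerance = 1e-3)
  d <- ou_test_data()
  fit <- fit_ou_model(d$tree, d$traits, d$painting, "y", predictors = "both",
                      predictor_trait = "x")
  expect_equal(fit$evolutionary_slope,
               fit$optimal_slope * rho_ou(fit$alpha * fit$tree_depth),
               tolerance = 1e-12)
  expect_lte(abs(fit$evolutionary_slope), abs(fit$optimal_slope))
})

test_that("AICc comparison flags the best and the equally supported models", {
  fits <- lapply(c(-4.38, 14.10, 8.66, 18.40), fake_fit)
  tab <- compare_models(fits)
  expect_equal(tab$AICc[tab$best], -4.38)
  expect_equal(sum(tab$equally_supported), 1)   # nothing else within 4
  expect_equal(tab$delta[tab$best], 0)
  # permuting the input order leaves the flags attached to the same models
  perm <- c(3, 1, 4, 2)
  tab2 <- compare_models(fits[perm])
  expect_equal(tab2$best, tab$best[perm])
  expect_equal(tab2$delta, tab$delta[perm])
  expect_error(compare_models(fits[1]), "at least two")
  bad <- fits
  bad[[2]]$response <- "OM_number"
  expect_error(compare_models(bad), "mix responses")
})

test_that("the half-life grid is fine enough for the likelihood surface", {
  d <- ou_test_data()
  Tdepth <- 1
  coarse <- fit_ou_model(d$tree, d$traits, d$painting, "y",
                         predictors = "regime")
  fine_grid <- c(0, exp(seq(log(1e-3), log(10), length.out = 240)) * Tdepth, Inf)
  fine <- fit_ou_model(d$tree, d$traits, d$painting, "y",
                       predictors = "regime", t_half_grid = fine_grid)
  expect_lt(abs(coarse$logL - fine$logL), 0.01)
})

test_that("measurement error enters as a covariance diagonal", {
  d <- ou_test_data()
  plain <- fit_ou_model(d$tree, d$traits, d$painting, "y", predictors = "regime")
  me <- fit_ou_model(d$tree, d$traits, d$painting, "y", predictors = "regime",
                     measurement_error = TRUE)
  # adding observation variance can only flatten the fit, never improve it
  # beyond noise, and both must return finite sensible estimates
  expect_true(is.finite(me$logL))
  expect_gte(me$t_half, 0)
  expect_true(me$v_y >= 0)
  expect_false(identical(plain$logL, me$logL))
})
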