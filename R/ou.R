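#' Phylogenetic correction factor for evolutionary regressions
#'
#' `rho_ou(x) = 1 - (1 - exp(-x)) / x` with `x = alpha * T`, the factor by
#' which phylogenetic inertia attenuates a regression slope: the
#' evolutionary (observed) slope equals the optimal slope times `rho_ou`.
#' Monotone increasing from 0 (Brownian limit, `alpha = 0`) to 1
#' (instantaneous adaptation).
#'
#' @param x Non-negative numeric, `alpha * T`.
#' @return Value in `[0, 1]`. Vectorized.
#' @export
rho_ou <- function(x) {
  ifelse(x > 1e-4,
         1 - (1 - exp(-x)) / x,
         x / 2 - x^2 / 6 + x^3 / 24)  # series; avoids 0/0 at x = 0
}

#' Ornstein-Uhlenbeck covariance among tips
#'
#' Covariance of tip values for an OU process started at the ancestral
#' optimum: `V_ij = v_y * (1 - exp(-2 alpha s_ij)) * exp(-alpha d_ij)`,
#' where `s_ij` is the shared time from the root of tips i and j and
#' `d_ij` their patristic distance. The Brownian-motion limit
#' (`alpha = 0`) is handled analytically as `V_ij = sigma2 * s_ij` with the
#' diffusion variance `sigma2 = 2 * alpha * v_y` kept as the free
#' parameter; the white-noise limit (`alpha = Inf`) is `v_y` times the
#' identity.
#'
#' @param tree Ultrametric [ape::phylo] tree.
#' @param alpha Adaptation rate, `>= 0` (may be `Inf`).
#' @param v_y Stationary variance `sigma2 / (2 alpha)`, `>= 0`.
#' @param sigma2 Diffusion variance used in the `alpha = 0` Brownian limit;
#'   defaults to `2 * alpha * v_y`.
#' @return Species-by-species covariance matrix (tip label dimnames).
#' @export
ou_covariance <- function(tree, alpha, v_y, sigma2 = 2 * alpha * v_y) {
  if (is.na(alpha) || alpha < 0) stop("alpha must be >= 0")
  if (is.na(v_y) || v_y < 0) stop("v_y must be >= 0")
  S <- ape::vcv(tree)
  n <- nrow(S)
  if (is.infinite(alpha)) {
    V <- diag(v_y, n)
    dimnames(V) <- dimnames(S)
    return(V)
  }
  depth <- diag(S)
  if (alpha * max(depth) < 1e-8) {
    if (is.nan(sigma2)) stop("sigma2 required in the Brownian limit")
    return(sigma2 * S)
  }
  D <- outer(depth, depth, "+") - 2 * S     # patristic distances
  v_y * (1 - exp(-2 * alpha * S)) * exp(-alpha * D)
}

# Root-to-tip branch segments: data frame of (tip, edge, t_start, t_end)
# used by regime_weights; computed once per tree.
tip_path_segments <- function(tree) {
  ntip <- ape::Ntip(tree)
  depth <- ape::node.depth.edgelength(tree)
  parent <- integer(ntip + tree$Nnode)
  edge_of <- integer(ntip + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  edge_of[tree$edge[, 2]] <- seq_len(nrow(tree$edge))
  root <- ntip + 1
  segs <- vector("list", ntip)
  for (i in seq_len(ntip)) {
    node <- i
    rows <- list()
    while (node != root) {
      e <- edge_of[node]
      rows[[length(rows) + 1]] <- c(e, depth[parent[node]], depth[node])
      node <- parent[node]
    }
    m <- do.call(rbind, rows)
    segs[[i]] <- data.frame(edge = m[, 1], t_start = m[, 2], t_end = m[, 3])
  }
  names(segs) <- tree$tip.label
  segs
}

#' Hansen-model regime weight matrix
#'
#' Expected contribution of each regime's optimum to each tip's expected
#' value under an OU process with rate `alpha`: for tip i and regime k,
#' `W_ik` sums `exp(-alpha (T - t_end)) - exp(-alpha (T - t_start))` over
#' the root-to-tip branch segments painted with regime k, plus
#' `exp(-alpha T)` added to the column of the root's regime (the process
#' starts at the ancestral optimum). Rows sum to 1 for every `alpha`. As
#' `alpha -> 0` all weight collapses onto the root regime; as
#' `alpha -> Inf` onto the tip branch's regime.
#'
#' @param tree Ultrametric [ape::phylo] tree.
#' @param painting A `regime_painting` covering every branch
#'   (see [enumerate_mp_reconstructions()]).
#' @param alpha Adaptation rate, `>= 0` (may be `Inf`).
#' @return Tips-by-regimes weight matrix.
#' @export
regime_weights <- function(tree, painting, alpha) {
  if (is.na(alpha) || alpha < 0) stop("alpha must be >= 0")
  if (length(painting$edge_regime) != nrow(tree$edge) ||
      anyNA(painting$edge_regime)) {
    stop("painting does not cover every branch of the tree")
  }
  regimes <- sort(unique(c(painting$edge_regime, painting$root_regime)))
  ntip <- ape::Ntip(tree)
  Tdepth <- max(ape::node.depth.edgelength(tree))
  W <- matrix(0, ntip, length(regimes),
              dimnames = list(tree$tip.label, regimes))
  if (is.infinite(alpha)) {       # only the terminal branch survives
    term_edge <- match(seq_len(ntip), tree$edge[, 2])
    W[cbind(seq_len(ntip), match(painting$edge_regime[term_edge], regimes))] <- 1
    return(W)
  }
  segs <- tip_path_segments(tree)
  for (i in seq_len(ntip)) {
    s <- segs[[i]]
    w <- exp(-alpha * (Tdepth - s$t_end)) - exp(-alpha * (Tdepth - s$t_start))
    k <- match(painting$edge_regime[s$edge], regimes)
    for (j in seq_along(k)) W[i, k[j]] <- W[i, k[j]] + w[j]
    rk <- match(painting$root_regime, regimes)
    W[i, rk] <- W[i, rk] + exp(-alpha * Tdepth)
  }
  W
}

#' Generalized least squares under a known covariance
#'
#' Fits `y = X beta + e`, `e ~ N(0, V)`, returning the GLS coefficients,
#' their standard errors, the exact multivariate-normal log-likelihood at
#' the supplied `V`, and the phylogenetically corrected coefficient of
#' determination `R2 = 1 - (e' V^-1 e) / (e0' V^-1 e0)` where `e0` are the
#' residuals of the GLS intercept-only fit under the same `V`.
#'
#' @param X Design matrix (full column rank).
#' @param V Positive-definite covariance matrix.
#' @param y Response vector.
#' @return List with `coefficients`, `se`, `vcov`, `residuals`, `logL`,
#'   `R2_phylo`, `rss_gls` (the quadratic form `e' V^-1 e`).
#' @export
gls_fit <- function(X, V, y) {
  X <- as.matrix(X)
  n <- length(y)
  if (nrow(X) != n || nrow(V) != n) stop("dimension mismatch")
  R <- tryCatch(chol(V), error = function(e) stop("V is not positive definite"))
  if (qr(X)$rank < ncol(X)) stop("design matrix X is rank deficient")
  Ky <- backsolve(R, y, transpose = TRUE)      # R^-T y
  KX <- backsolve(R, X, transpose = TRUE)
  XtVX <- crossprod(KX)
  beta_cov <- solve(XtVX)
  beta <- drop(beta_cov %*% crossprod(KX, Ky))
  names(beta) <- colnames(X)
  resid <- drop(y - X %*% beta)
  Kr <- backsolve(R, resid, transpose = TRUE)
  rss <- sum(Kr^2)
  logdet <- 2 * sum(log(diag(R)))
  logL <- -0.5 * (n * log(2 * pi) + logdet + rss)
  ones <- matrix(1, n, 1)
  K1 <- backsolve(R, ones, transpose = TRUE)
  b0 <- sum(K1 * Ky) / sum(K1^2)
  Kr0 <- Ky - K1 * b0
  rss0 <- sum(Kr0^2)
  list(
    coefficients = beta,
    se = stats::setNames(sqrt(diag(beta_cov)), colnames(X)),
    vcov = beta_cov,
    residuals = resid,
    logL = logL,
    logdet = logdet,
    R2_phylo = if (rss0 > 0) 1 - rss / rss0 else NA_real_,
    rss_gls = rss
  )
}

# GLS pieces for a *unit-scale* covariance shape V0: profiles the scale
# analytically (scale_hat = rss/n) and returns the profiled logL.
gls_profile_scale <- function(X, V0, y) {
  fit <- gls_fit(X, V0, y)
  n <- length(y)
  scale_hat <- fit$rss_gls / n
  fit$scale_hat <- scale_hat
  fit$logL <- -0.5 * (n * log(2 * pi) + fit$logdet + n * log(scale_hat) + n)
  # SEs under the profiled scale
  fit$se <- fit$se * sqrt(scale_hat)
  fit$vcov <- fit$vcov * scale_hat
  fit
}
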