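# Exact correlation of two-sided normal p-values.
#
# For (Z1, Z2) bivariate normal with correlation r, the p-values
# p_i = 2 Phi(-|Z_i|) are Uniform(0, 1) with Pearson correlation
# rho_p(r) = (E[p1 p2] - 1/4) / (1/12). Because p depends on Z through
# |Z|, rho_p is an even function of r and hence a function of r^2, so the
# LD r-squared determines it without knowing the sign of r. E[p1 p2] is
# evaluated on the positive quadrant (where the folded density of
# (|Z1|, |Z2|) is smooth) by Gauss-Legendre quadrature; a monotone spline
# over an r^2 grid is cached per session.

.gaussLegendre <- function(n, a, b) {
  i <- seq_len(n - 1)
  beta <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- beta
  J[cbind(i + 1, i)] <- beta
  e <- eigen(J, symmetric = TRUE)
  list(x = (b - a) / 2 * e$values + (a + b) / 2,
       w = (b - a) * (e$vectors[1, ])^2)
}

.rhoPointwise <- function(r, n = 96, lim = 8.5) {
  if (abs(r) >= 1) return(1)
  g <- .gaussLegendre(n, 0, lim)
  u <- g$x
  fu <- pnorm(-u)
  s2 <- 1 - r^2
  phi2 <- function(U, V, rr) exp(-(U^2 - 2 * rr * U * V + V^2) / (2 * s2)) /
    (2 * pi * sqrt(s2))
  M <- outer(u, u, function(U, V) 2 * (phi2(U, V, r) + phi2(U, -V, r)))
  Epp <- 4 * drop(t(g$w * fu) %*% M %*% (g$w * fu))
  min(max((Epp - 0.25) / (1 / 12), 0), 1)
}

.rhoCache <- new.env(parent = emptyenv())

.rhoSpline <- function() {
  if (is.null(.rhoCache$fun)) {
    r2grid <- seq(0, 1, length.out = 201)
    vals <- vapply(sqrt(r2grid), .rhoPointwise, numeric(1))
    vals[length(vals)] <- 1
    .rhoCache$fun <- stats::splinefun(r2grid, vals, method = "hyman")
  }
  .rhoCache$fun
}

# Covariance of q_i = -2 ln p_i for two-sided p-values of bivariate-normal
# Z-scores with correlation r (an even function of r, so a function of
# r^2). q is marginally chi-square with 2 df: mean 2, variance 4, so the
# covariance runs from 0 at r = 0 to 4 at |r| = 1. Same folded-quadrant
# quadrature as .rhoPointwise; q(u) grows only quadratically, which the
# Gaussian factor absorbs.
.covLogPPointwise <- function(r, n = 96, lim = 8.5) {
  if (abs(r) >= 1) return(4)
  g <- .gaussLegendre(n, 0, lim)
  u <- g$x
  qu <- -2 * log(2 * pnorm(-u))
  s2 <- 1 - r^2
  phi2 <- function(U, V, rr) exp(-(U^2 - 2 * rr * U * V + V^2) / (2 * s2)) /
    (2 * pi * sqrt(s2))
  M <- outer(u, u, function(U, V) 2 * (phi2(U, V, r) + phi2(U, -V, r)))
  Eqq <- drop(t(g$w * qu) %*% M %*% (g$w * qu))
  min(max(Eqq - 4, 0), 4)
}

.covLogPSpline <- function() {
  if (is.null(.rhoCache$covFun)) {
    r2grid <- seq(0, 1, length.out = 201)
    vals <- vapply(sqrt(r2grid), .covLogPPointwise, numeric(1))
    vals[length(vals)] <- 4
    .rhoCache$covFun <- stats::splinefun(r2grid, vals, method = "hyman")
  }
  .rhoCache$covFun
}

# r^2 that corresponds to a given exact p-value correlation (inverse of
# the rho mapping), used when a caller supplies rho but the covariance
# model needs r^2.
.r2FromRho <- function(rho) {
  if (is.null(.rhoCache$inv)) {
    r2grid <- seq(0, 1, length.out = 201)
    vals <- pmin(pmax(.rhoSpline()(r2grid), 0), 1)
    vals[1] <- 0; vals[length(vals)] <- 1
    .rhoCache$inv <- stats::approxfun(vals, r2grid, rule = 2, ties = "ordered")
  }
  out <- .rhoCache$inv(as.vector(rho))
  attributes(out) <- attributes(rho)
  out
}
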