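# Maximum-likelihood log-spline density estimation on [0, 1].
#
# The log-density is modelled as a natural cubic spline (linear beyond the
# boundary knots) with knots at sample quantiles, normalized over [0, 1].
# The log-likelihood sum(B(x) beta) - n log Z(beta) is concave, so BFGS with
# the analytic gradient converges reliably.  Used by the Savage-Dickey Bayes
# factor to evaluate the posterior density of phi at the boundary value 0,
# where extrapolation through the linear left tail keeps the estimate finite
# even when no samples fall near 0.

logspline_density <- function(x, nknots = NULL, ngrid = 401) {
  n <- length(x)
  if (n < 50) stop("log-spline density estimation needs at least 50 samples")
  if (is.null(nknots)) nknots <- max(5, min(15, ceiling(2.5 * n^0.2)))
  kn <- unique(stats::quantile(x, seq(0, 1, length.out = nknots),
                               names = FALSE, type = 8))
  if (length(kn) < 4) stop("too few distinct knots (degenerate samples)")
  bk <- range(kn)
  interior <- kn[kn > bk[1] & kn < bk[2]]
  basis <- function(u) splines::ns(u, knots = interior, Boundary.knots = bk)
  Bx <- basis(x)
  grid <- seq(0, 1, length.out = ngrid)
  h <- grid[2] - grid[1]
  w <- rep(c(2, 4), length.out = ngrid)
  w[c(1, ngrid)] <- 1
  w <- w * h / 3 # Simpson rule
  Bg <- basis(grid)
  csum <- colSums(Bx)
  log_z <- function(beta) {
    eta <- drop(Bg %*% beta)
    m <- max(eta)
    m + log(sum(w * exp(eta - m)))
  }
  negll <- function(beta) -(sum(Bx %*% beta) - n * log_z(beta))
  grad <- function(beta) {
    eta <- drop(Bg %*% beta)
    f <- exp(eta - max(eta)) * w
    f <- f / sum(f)
    -(csum - n * drop(t(Bg) %*% f))
  }
  opt <- stats::optim(rep(0, ncol(Bx)), negll, grad, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  if (opt$convergence != 0) {
    warning("log-spline density fit did not fully converge")
  }
  lz <- log_z(opt$par)
  function(u) drop(basis(u) %*% opt$par) - lz
}
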