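# Gaussian-process regression on the unit box: Matern-5/2 kernel with
# per-dimension lengthscales (ARD), constant mean, Gaussian noise.
# Hyperparameters are fit by maximizing the log marginal likelihood with
# L-BFGS-B on log-parameters; the fit is deterministic for fixed data.

matern52 <- function(X1, X2, lengthscales, sf2) {
  X1s <- sweep(as.matrix(X1), 2, lengthscales, "/")
  X2s <- sweep(as.matrix(X2), 2, lengthscales, "/")
  d2 <- outer(rowSums(X1s^2), rowSums(X2s^2), "+") - 2 * tcrossprod(X1s, X2s)
  r <- sqrt(pmax(d2, 0))
  s5r <- sqrt(5) * r
  sf2 * (1 + s5r + (5 / 3) * r^2) * exp(-s5r)
}

gp_chol <- function(K, sn2) {
  n <- nrow(K)
  jitter <- 0
  for (k in 0:8) {
    L <- tryCatch(chol(K + diag(sn2 + jitter, n)), error = function(e) NULL)
    if (!is.null(L)) return(list(L = L, jitter = jitter))
    jitter <- max(1e-10, jitter * 10, mean(diag(K)) * 1e-10 * 10^k)
  }
  stop("kernel matrix is numerically singular even after jitter escalation")
}

gp_nlml <- function(logpar, X, yc, d) {
  ls <- exp(logpar[seq_len(d)])
  sf2 <- exp(logpar[d + 1])
  sn2 <- exp(logpar[d + 2])
  K <- matern52(X, X, ls, sf2)
  ch <- tryCatch(gp_chol(K, sn2), error = function(e) NULL)
  if (is.null(ch)) return(1e10)
  L <- ch$L
  alpha <- backsolve(L, forwardsolve(t(L), yc))
  n <- length(yc)
  val <- 0.5 * sum(yc * alpha) + sum(log(diag(L))) + 0.5 * n * log(2 * pi)
  if (!is.finite(val)) 1e10 else val
}

#' Fit a Gaussian process to scalar observations on the unit box
#'
#' @param X numeric matrix of inputs, n x d, each coordinate in `[0, 1]`.
#' @param y numeric response vector.
#' @param optimize refit hyperparameters by marginal-likelihood maximization
#'   (default); when `FALSE`, `init` is used as-is.
#' @param init optional list with `lengthscales`, `sf2`, `sn2` starting values.
#' @return an object of class `gp_fit`.
#' @export
gp_fit <- function(X, y, optimize = TRUE, init = NULL) {
  X <- as.matrix(X)
  d <- ncol(X)
  n <- nrow(X)
  stopifnot(n >= 2, length(y) == n)
  mu <- mean(y)
  yc <- y - mu
  vy <- max(stats::var(y), 1e-12)
  start <- list(lengthscales = init$lengthscales %||% rep(0.3, d),
                sf2 = init$sf2 %||% vy,
                sn2 = init$sn2 %||% max(1e-6 * vy, 1e-10))
  logpar <- log(c(start$lengthscales, start$sf2, start$sn2))
  if (optimize) {
    lower <- log(c(rep(0.01, d), 1e-8, 1e-10))
    upper <- log(c(rep(20, d), 1e4, 1))
    opt <- tryCatch(
      stats::optim(logpar, gp_nlml, X = X, yc = yc, d = d, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(maxit = 100, factr = 1e9)),
      error = function(e) NULL)
    if (!is.null(opt) && is.finite(opt$value) && opt$value < gp_nlml(logpar, X, yc, d)) {
      logpar <- opt$par
    }
  }
  ls <- exp(logpar[seq_len(d)])
  sf2 <- exp(logpar[d + 1])
  sn2 <- exp(logpar[d + 2])
  K <- matern52(X, X, ls, sf2)
  ch <- gp_chol(K, sn2)
  alpha <- backsolve(ch$L, forwardsolve(t(ch$L), yc))
  structure(list(X = X, y = y, mean = mu, lengthscales = ls, sf2 = sf2,
                 sn2 = sn2 + ch$jitter, L = ch$L, alpha = alpha,
                 fingerprint = c(n = n, d = d, ysum = sum(y))),
            class = "gp_fit")
}

#' Posterior mean and variance of a fitted GP
#'
#' @param fit a [gp_fit()].
#' @param Xnew matrix of query points (rows).
#' @return list with `mean` and `var` vectors (`var` is the latent posterior
#'   variance, floored at zero).
#' @export
gp_predict <- function(fit, Xnew) {
  Xnew <- matrix(as.numeric(Xnew), ncol = ncol(fit$X))
  Ks <- matern52(Xnew, fit$X, fit$lengthscales, fit$sf2)
  mu <- fit$mean + as.numeric(Ks %*% fit$alpha)
  v <- forwardsolve(t(fit$L), t(Ks))
  var <- pmax(fit$sf2 - colSums(v^2), 0)
  list(mean = mu, var = var)
}

# condition on an extra (fantasy) observation without refitting hyperparameters
gp_condition <- function(fit, xnew, ynew) {
  gp_fit(rbind(fit$X, matrix(xnew, nrow = 1)), c(fit$y, ynew),
         optimize = FALSE,
         init = list(lengthscales = fit$lengthscales, sf2 = fit$sf2, sn2 = fit$sn2))
}
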