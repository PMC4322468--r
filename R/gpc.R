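#' Kernel hyperparameters
#'
#' The linear covariance has two free hyperparameters on the log scale: the
#' signal scale `s = exp(log_signal)` multiplying the dot product and the
#' bias offset `b = exp(log_bias)` added to every kernel entry. Both control
#' the latent function's scaling and offset and are set by type-II maximum
#' likelihood (evidence maximization).
#'
#' @param log_signal,log_bias finite numbers (default 0, i.e. s = b = 1).
#' @return a `gp_hyperparams` list.
#' @export
gp_hyperparams <- function(log_signal = 0, log_bias = 0) {
  stopifnot(is.finite(log_signal), is.finite(log_bias))
  structure(list(log_signal = log_signal, log_bias = log_bias),
            class = "gp_hyperparams")
}

#' Linear covariance with scale and bias
#'
#' `K[i, j] = exp(log_signal) * <A_i, B_j> / d + exp(log_bias)` where `d` is
#' the feature dimension. The `1/d` normalization keeps hyperparameter scales
#' comparable across feature dimensions; it can be switched off.
#'
#' @param A,B matrices with samples in rows and a common column count.
#' @param hyp a [gp_hyperparams()].
#' @param d_normalize divide the dot product by the feature dimension
#'   (default TRUE).
#' @return `nrow(A)` x `nrow(B)` kernel matrix.
#' @export
linear_kernel <- function(A, B = A, hyp = gp_hyperparams(), d_normalize = TRUE) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (ncol(A) != ncol(B)) {
    stop("feature dimension mismatch: ", ncol(A), " vs ", ncol(B), call. = FALSE)
  }
  d <- if (d_normalize) ncol(A) else 1
  exp(hyp$log_signal) * tcrossprod(A, B) / d + exp(hyp$log_bias)
}

# robust N(z)/Phi(z)
probit_ratio <- function(z) exp(stats::dnorm(z, log = TRUE) - stats::pnorm(z, log.p = TRUE))

# Recompute posterior moments from site parameters, numerically stable form:
# B = I + S^1/2 K S^1/2, Sigma = K - K S^1/2 B^-1 S^1/2 K, mu = Sigma nu~.
ep_posterior <- function(K, tau_t, nu_t) {
  n <- nrow(K)
  s <- sqrt(tau_t)
  B <- diag(n) + (s %o% s) * K
  L <- chol(B)
  V <- backsolve(L, s * K, transpose = TRUE) # L^-T (S^1/2 K)
  Sigma <- K - crossprod(V)
  Sigma <- (Sigma + t(Sigma)) / 2
  list(Sigma = Sigma, mu = as.vector(Sigma %*% nu_t), L = L, sqrt_tau = s)
}

#' Expectation-propagation inference for probit-likelihood GP classification
#'
#' Approximates the posterior over the latent function values `f` under a
#' `GP(0, K)` prior and probit likelihood `Phi(y_i f_i)` by iterating
#' site-wise moment matching. Sites are visited in ascending index order with
#' no damping; if an update would drive a site precision negative it is
#' damped by 0.5 and, if still negative, clipped at 0. Convergence is
#' declared when the largest absolute site-parameter change in a sweep falls
#' below `tol` (default 1e-4), with a warning after `max_sweeps` (default 60).
#'
#' @param K positive semidefinite kernel matrix (a jitter of `1e-8` times its
#'   mean diagonal is added for safety).
#' @param y labels in `{+1, -1}`.
#' @param tol,max_sweeps convergence controls.
#' @return an `ep_state`: site parameters (`tau_tilde`, `nu_tilde`),
#'   posterior moments (`mu`, `Sigma`), the EP `log_marginal`, and
#'   convergence diagnostics.
#' @export
ep_inference <- function(K, y, tol = 1e-4, max_sweeps = 60) {
  n <- length(y)
  stopifnot(nrow(K) == n, ncol(K) == n, all(y %in% c(-1, 1)))
  K <- K + diag(1e-8 * mean(diag(K)) + 1e-12, n)
  ok <- tryCatch({ chol(K); TRUE }, error = function(e) FALSE)
  if (!ok) stop("kernel matrix is numerically indefinite even after jitter", call. = FALSE)

  tau_t <- numeric(n)
  nu_t <- numeric(n)
  Sigma <- K
  mu <- numeric(n)
  converged <- FALSE
  sweeps <- 0L
  for (sweep in seq_len(max_sweeps)) {
    max_delta <- 0
    for (i in seq_len(n)) {
      # cavity
      tau_ni <- 1 / Sigma[i, i] - tau_t[i]
      nu_ni <- mu[i] / Sigma[i, i] - nu_t[i]
      if (tau_ni <= 0) next # invalid cavity, skip this site this sweep
      s2_ni <- 1 / tau_ni
      mu_ni <- nu_ni / tau_ni
      # tilted (probit) moments
      denom <- sqrt(1 + s2_ni)
      z <- y[i] * mu_ni / denom
      r <- probit_ratio(z)
      mu_hat <- mu_ni + y[i] * s2_ni * r / denom
      s2_hat <- s2_ni - s2_ni^2 * r * (z + r) / (1 + s2_ni)
      if (s2_hat <= 0) next
      tau_new <- 1 / s2_hat - tau_ni
      nu_new <- mu_hat / s2_hat - nu_ni
      if (tau_new < 0) { # damp toward the old site, then clip
        tau_new <- 0.5 * tau_new + 0.5 * tau_t[i]
        nu_new <- 0.5 * nu_new + 0.5 * nu_t[i]
        if (tau_new < 0) {
          tau_new <- 0
          nu_new <- 0
        }
      }
      d_tau <- tau_new - tau_t[i]
      max_delta <- max(max_delta, abs(d_tau), abs(nu_new - nu_t[i]))
      tau_t[i] <- tau_new
      nu_t[i] <- nu_new
      # rank-1 posterior update
      si <- Sigma[, i]
      Sigma <- Sigma - (d_tau / (1 + d_tau * si[i])) * (si %o% si)
      mu <- as.vector(Sigma %*% nu_t)
    }
    post <- ep_posterior(K, tau_t, nu_t) # stable recompute each sweep
    Sigma <- post$Sigma
    mu <- post$mu
    sweeps <- sweep
    if (max_delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("EP did not converge in ", max_sweeps, " sweeps (last delta above tol)",
            call. = FALSE)
  }
  post <- ep_posterior(K, tau_t, nu_t)
  structure(
    list(
      tau_tilde = tau_t, nu_tilde = nu_t,
      mu = post$mu, Sigma = post$Sigma, L = post$L, sqrt_tau = post$sqrt_tau,
      K = K, y = y,
      log_marginal = ep_log_marginal(K, y, tau_t, nu_t, post),
      converged = converged, sweeps = sweeps
    ),
    class = "ep_state"
  )
}

# EP approximation of the log evidence. Standard decomposition: the Gaussian
# overlap -1/2 log|K + S~^-1| - 1/2 mu~' (K + S~^-1)^-1 mu~ plus per-site
# normalizers log Phi(z_i) + 1/2 log(s2_cav + 1/tau~) +
# (mu_cav - mu~)^2 / (2 (s2_cav + 1/tau~)); the 2*pi factors cancel exactly.
# Vacuous sites (tau~ clipped to 0) are floored at 1e-10 so their
# contributions cancel analytically.
ep_log_marginal <- function(K, y, tau_t, nu_t, post) {
  eps <- 1e-10
  tau_f <- pmax(tau_t, eps)
  mu_site <- nu_t / tau_f
  s <- sqrt(tau_f)
  n <- length(y)
  B <- diag(n) + (s %o% s) * K
  L <- chol(B)
  # cavity from the converged posterior
  dS <- diag(post$Sigma)
  tau_n <- pmax(1 / dS - tau_t, eps)
  nu_n <- post$mu / dS - nu_t
  s2_cav <- 1 / tau_n
  mu_cav <- nu_n / tau_n
  z <- y * mu_cav / sqrt(1 + s2_cav)
  w <- backsolve(L, s * mu_site, transpose = TRUE)
  logdet <- 2 * sum(log(diag(L))) - sum(log(tau_f)) # log|K + S~^-1|
  v <- s2_cav + 1 / tau_f
  -0.5 * logdet - 0.5 * sum(w^2) +
    sum(stats::pnorm(z, log.p = TRUE)) +
    0.5 * sum(log(v)) +
    sum((mu_cav - mu_site)^2 / (2 * v))
}

# ---- Gram-space core ------------------------------------------------------
# All heavy lifting happens on the n x n (normalized, centered) Gram matrix,
# the dual form appropriate for n << p imaging data. The feature interface
# below is a thin wrapper and gives identical results.

# Center a raw Gram matrix by the mean of the rows/cols in `tr`:
# <u - m, v - m> for all pairs, with m the mean of training features.
center_gram <- function(G, tr) {
  rm_tr <- rowMeans(G[, tr, drop = FALSE])
  mm <- mean(G[tr, tr])
  G - outer(rm_tr, rep(1, ncol(G))) - outer(rep(1, nrow(G)), rm_tr) + mm
}

ep_evidence_gram <- function(par, Gc, y, ep_tol, ep_max_sweeps) {
  K <- exp(par[1]) * Gc + exp(par[2])
  st <- suppressWarnings(ep_inference(K, y, tol = ep_tol, max_sweeps = ep_max_sweeps))
  st$log_marginal
}

# Fit on a centered training Gram block. Returns hyperparams + EP state.
gpc_fit_gram <- function(Gc_tr, y, hyperparams = gp_hyperparams(),
                         optimize = TRUE, bounds = c(-10, 10), maxit = 100,
                         ep_tol = 1e-4, ep_max_sweeps = 60) {
  if (!all(y %in% c(-1, 1))) stop("labels must be coded +1 / -1", call. = FALSE)
  if (length(unique(y)) < 2) stop("training labels contain a single class", call. = FALSE)
  par0 <- c(hyperparams$log_signal, hyperparams$log_bias)
  if (optimize) {
    opt <- stats::optim(par0,
                        function(p) -ep_evidence_gram(p, Gc_tr, y, ep_tol, ep_max_sweeps),
                        method = "L-BFGS-B", lower = bounds[1], upper = bounds[2],
                        control = list(maxit = maxit))
    # monotone-improvement contract: never return a worse point than the start
    if (-opt$value < ep_evidence_gram(par0, Gc_tr, y, ep_tol, ep_max_sweeps) - 1e-9) {
      opt$par <- par0
    }
    hyperparams <- gp_hyperparams(opt$par[1], opt$par[2])
  }
  K <- exp(hyperparams$log_signal) * Gc_tr + exp(hyperparams$log_bias)
  ep <- ep_inference(K, y, tol = ep_tol, max_sweeps = ep_max_sweeps)
  list(hyperparams = hyperparams, ep = ep)
}

# Predictive probabilities from a Gram-space fit: Kc_cross is the centered
# train x test kernel block (without hyperparameters), kc_diag the centered
# test self-products.
predict_gram <- function(fit, Kc_cross, kc_diag) {
  hyp <- fit$hyperparams
  ep <- fit$ep
  Ks <- exp(hyp$log_signal) * Kc_cross + exp(hyp$log_bias)
  kss <- exp(hyp$log_signal) * kc_diag + exp(hyp$log_bias)
  s <- ep$sqrt_tau
  Knu <- ep$K %*% ep$nu_tilde
  r <- ep$nu_tilde - s * backsolve(ep$L, backsolve(ep$L, s * Knu, transpose = TRUE))
  mu_s <- as.vector(crossprod(Ks, r))
  V <- backsolve(ep$L, s * Ks, transpose = TRUE)
  s2_s <- pmax(kss - colSums(V^2), 1e-12)
  p <- stats::pnorm(mu_s / sqrt(1 + s2_s))
  pmin(pmax(p, .Machine$double.eps), 1 - .Machine$double.eps)
}

#' Fit a Gaussian process classifier
#'
#' Centers the features by the training mean (stored for prediction), builds
#' the linear covariance, runs [ep_inference()] and, when `optimize = TRUE`,
#' maximizes the EP log marginal likelihood over `(log_signal, log_bias)`
#' with box-bounded L-BFGS-B from the fixed start `(0, 0)` within
#' `[-10, 10]^2` (type-II maximum likelihood; deterministic). All linear
#' algebra runs in the dual (n x n kernel) form, the natural representation
#' for imaging data where features vastly outnumber samples.
#'
#' @param X samples x features matrix (>= 2 rows).
#' @param y labels in `{+1, -1}`, both classes present.
#' @param hyperparams starting / fixed [gp_hyperparams()].
#' @param optimize optimize hyperparameters by evidence ascent (default TRUE).
#' @param d_normalize see [linear_kernel()].
#' @param bounds box bounds on both log hyperparameters.
#' @param maxit L-BFGS-B iteration cap.
#' @param ep_tol,ep_max_sweeps EP convergence controls.
#' @return a `gpc_model`.
#' @export
gpc_fit <- function(X, y, hyperparams = gp_hyperparams(), optimize = TRUE,
                    d_normalize = TRUE, bounds = c(-10, 10), maxit = 100,
                    ep_tol = 1e-4, ep_max_sweeps = 60) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (nrow(X) < 2) stop("need at least 2 training samples", call. = FALSE)
  center <- colMeans(X)
  Xc <- sweep(X, 2, center)
  Gc <- tcrossprod(Xc) / (if (d_normalize) ncol(Xc) else 1)
  fit <- gpc_fit_gram(Gc, y, hyperparams = hyperparams, optimize = optimize,
                      bounds = bounds, maxit = maxit, ep_tol = ep_tol,
                      ep_max_sweeps = ep_max_sweeps)
  structure(
    list(hyperparams = fit$hyperparams, ep = fit$ep, center = center, Xc = Xc,
         y = y, d_normalize = d_normalize, n = nrow(X), p = ncol(X)),
    class = "gpc_model"
  )
}

#' Predictive class probabilities from a fitted GP classifier
#'
#' For each test point the EP posterior gives a predictive latent Gaussian
#' `(mu*, s2*)`; the class-(+1) probability is `Phi(mu* / sqrt(1 + s2*))`.
#' Test features are centered by the stored training mean.
#'
#' @param object a `gpc_model`.
#' @param newdata test samples x features matrix.
#' @param ... unused.
#' @return numeric vector of probabilities of class `+1`, strictly in (0, 1).
#' @export
predict.gpc_model <- function(object, newdata, ...) {
  Xs <- as.matrix(newdata)
  if (ncol(Xs) != length(object$center)) {
    stop("test feature dimension ", ncol(Xs), " does not match training ",
         length(object$center), call. = FALSE)
  }
  Xs <- sweep(Xs, 2, object$center)
  d <- if (object$d_normalize) ncol(Xs) else 1
  predict_gram(object, tcrossprod(object$Xc, Xs) / d, rowSums(Xs^2) / d)
}

#' @export
print.gpc_model <- function(x, ...) {
  cat(sprintf(
    "<gpc_model> n = %d, p = %d; log_signal = %.3f, log_bias = %.3f; EP logZ = %.3f (%s, %d sweeps)\n",
    x$n, x$p, x$hyperparams$log_signal, x$hyperparams$log_bias,
    x$ep$log_marginal, if (x$ep$converged) "converged" else "NOT converged", x$ep$sweeps
  ))
  invisible(x)
}

#' Tidy a fitted GP classifier
#'
#' @param x a `gpc_model`.
#' @param ... unused.
#' @return tibble of hyperparameters (one row per parameter).
#' @export
tidy.gpc_model <- function(x, ...) {
  tibble::tibble(
    term = c("log_signal", "log_bias"),
    estimate = c(x$hyperparams$log_signal, x$hyperparams$log_bias)
  )
}

#' One-row model summary for a fitted GP classifier
#'
#' @param x a `gpc_model`.
#' @param ... unused.
#' @return one-row tibble: sample/feature counts, EP evidence, convergence.
#' @export
glance.gpc_model <- function(x, ...) {
  tibble::tibble(
    n = x$n, p = x$p,
    log_signal = x$hyperparams$log_signal, log_bias = x$hyperparams$log_bias,
    log_marginal = x$ep$log_marginal,
    ep_converged = x$ep$converged, ep_sweeps = x$ep$sweeps
  )
}

#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @export
glance <- function(x, ...) UseMethod("glance")
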