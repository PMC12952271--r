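#' Convert a dissociation constant to the log-affinity objective
#'
#' The affinity objective is `f_aff = log10(1 nM / Kd)`: 0 for a 1 nM
#' binder, positive for stronger (sub-nanomolar) binders, one unit per order
#' of magnitude.
#'
#' @param kd_nm Dissociation constant in nanomolar, > 0. Vectorized.
#' @return Numeric log-affinity value(s).
#' @export
#' @examples
#' kd_to_affinity(1)     # 0
#' kd_to_affinity(0.04)  # ~1.4
kd_to_affinity <- function(kd_nm) {
  if (any(!is.finite(kd_nm)) || any(kd_nm <= 0))
    stop("Kd must be finite and > 0 (nM)", call. = FALSE)
  log10(1 / kd_nm)
}

#' RBF kernel hyperparameters
#'
#' @param delta Output scale (prior variance), > 0.
#' @param lam Length scale, > 0.
#' @param sigma_n Observation noise standard deviation, >= 0.
#' @param C Constant prior mean.
#' @return Object of class `kernel_params`.
#' @export
kernel_params <- function(delta = 1, lam = 1, sigma_n = 0.1, C = 0) {
  if (delta <= 0 || lam <= 0 || sigma_n < 0)
    stop("require delta > 0, lam > 0, sigma_n >= 0", call. = FALSE)
  structure(list(delta = delta, lam = lam, sigma_n = sigma_n, C = C),
            class = "kernel_params")
}

#' Radial basis function kernel
#'
#' `k(u, v) = delta * exp(-||u - v||^2 / (2 lam^2))`; equals `delta` at
#' `u = v` and decays with squared Euclidean distance in embedding space.
#'
#' @param u,v Numeric vectors of equal length.
#' @param params A [kernel_params()] object.
#' @return Kernel value.
#' @export
rbf_kernel <- function(u, v, params) {
  if (length(u) != length(v))
    stop("kernel inputs must have equal dimension", call. = FALSE)
  params$delta * exp(-sum((u - v)^2) / (2 * params$lam^2))
}

# Squared-distance matrix between rows of A and rows of B.
sqdist <- function(A, B) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  d2
}

rbf_cross <- function(A, B, params) {
  params$delta * exp(-sqdist(A, B) / (2 * params$lam^2))
}

# Cholesky of K + sigma_n^2 I with escalating jitter; error if it never
# becomes positive definite.
chol_jitter <- function(M, jitters = c(0, 1e-8, 1e-6, 1e-4)) {
  for (j in jitters) {
    L <- tryCatch(chol(M + diag(j, nrow(M))), error = function(e) NULL)
    if (!is.null(L)) return(L)
  }
  stop("kernel matrix not positive definite after jitter escalation",
       call. = FALSE)
}

#' Gaussian-process regression model over sequence embeddings
#'
#' Builds (and caches) the Cholesky factorization of `K + sigma_n^2 I` for
#' the given training embeddings and targets. `n = 0` is allowed and yields
#' the prior (`mu = C`, `sigma2 = delta`) at every query.
#'
#' @param X Training embedding matrix (n x m), or NULL for an empty model.
#' @param Y Numeric training targets (length n).
#' @param params A [kernel_params()] object.
#' @return Object of class `gp_model` with cached factorization.
#' @export
gp_model <- function(X, Y, params) {
  stopifnot(inherits(params, "kernel_params"))
  if (is.null(X) || NROW(X) == 0L) {
    return(structure(list(params = params, X = NULL, Y = numeric(0),
                          L = NULL, alpha = numeric(0)),
                     class = "gp_model"))
  }
  X <- as.matrix(X)
  if (nrow(X) != length(Y)) stop("nrow(X) must equal length(Y)", call. = FALSE)
  K <- rbf_cross(X, X, params)
  L <- chol_jitter(K + diag(params$sigma_n^2, nrow(X)))
  alpha <- backsolve(L, forwardsolve(t(L), Y - params$C))
  structure(list(params = params, X = X, Y = Y, L = L, alpha = alpha),
            class = "gp_model")
}

#' @export
print.gp_model <- function(x, ...) {
  p <- x$params
  cat(sprintf(
    "<gp_model> n = %d, delta = %.4g, lambda = %.4g, sigma_n = %.4g, C = %.4g\n",
    NROW(x$X), p$delta, p$lam, p$sigma_n, p$C))
  invisible(x)
}

#' GP posterior mean and variance
#'
#' Posterior at query embeddings `Z`:
#' `mu(z) = C + k(z,X)' (K + sigma_n^2 I)^{-1} (Y - C)` and latent variance
#' `sigma2(z) = k(z,z) - k(z,X)' (K + sigma_n^2 I)^{-1} k(z,X)`. With
#' `noisy = TRUE` the aleatoric term `sigma_n^2` is added to the variance.
#'
#' @param model A fitted [gp_model()].
#' @param Z Query embedding matrix (rows = queries) or a single vector.
#' @param noisy Return the noisy predictive variance instead of the latent
#'   one.
#' @return List with numeric vectors `mu` and `sigma2` (`sigma2 >= 0`).
#' @export
gp_posterior <- function(model, Z, noisy = FALSE) {
  p <- model$params
  if (is.null(dim(Z))) Z <- matrix(Z, nrow = 1L)
  if (is.null(model$X)) {
    mu <- rep(p$C, nrow(Z))
    s2 <- rep(p$delta, nrow(Z))
  } else {
    Ks <- rbf_cross(model$X, Z, p)            # n x q
    mu <- p$C + drop(crossprod(Ks, model$alpha))
    V <- forwardsolve(t(model$L), Ks)         # n x q
    s2 <- pmax(p$delta - colSums(V^2), 0)
  }
  if (noisy) s2 <- s2 + p$sigma_n^2
  list(mu = mu, sigma2 = s2)
}

#' Log marginal likelihood of a GP model
#'
#' Evaluated on mean-centered targets:
#' `-(1/2) (Y-C)' A^{-1} (Y-C) - (1/2) log|A| - (n/2) log(2 pi)` with
#' `A = K + sigma_n^2 I`.
#'
#' @param model A [gp_model()].
#' @return Scalar log marginal likelihood.
#' @export
gp_mll <- function(model) {
  n <- NROW(model$X)
  if (n == 0L) return(0)
  r <- model$Y - model$params$C
  -0.5 * sum(r * model$alpha) - sum(log(diag(model$L))) - n / 2 * log(2 * pi)
}

#' Fit kernel hyperparameters by maximizing the marginal likelihood
#'
#' Gradient-based ascent of the log marginal likelihood on log-transformed
#' `(delta, lam, sigma_n)` plus the constant mean `C`, for a fixed step
#' budget (default 600 steps at learning rate 1e-3). `C` is trainable and
#' initialized to the training mean; `delta` to the target variance; `lam`
#' to the median pairwise embedding distance.
#'
#' @param X Training embedding matrix.
#' @param Y Numeric targets, length >= 2.
#' @param init Optional [kernel_params()] starting point.
#' @param steps Number of optimizer steps.
#' @param lr Learning rate.
#' @param optimizer `"gd"` (plain gradient ascent, default) or `"adam"`.
#' @param fit_C Whether to update the constant mean.
#' @return A fitted [gp_model()]; attribute `mll_trace` holds the per-step
#'   objective values.
#' @export
gp_fit_mll <- function(X, Y, init = NULL, steps = 600, lr = 1e-3,
                       optimizer = c("gd", "adam"), fit_C = TRUE) {
  optimizer <- match.arg(optimizer)
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 2L) stop("marginal-likelihood fitting requires n >= 2", call. = FALSE)
  if (is.null(init)) {
    d0 <- stats::var(Y)
    if (!is.finite(d0) || d0 <= 0) d0 <- 1
    D2 <- sqdist(X, X)
    med <- stats::median(sqrt(D2[upper.tri(D2)]))
    if (!is.finite(med) || med <= 0) med <- 1
    # start with half the variance attributed to noise: small noise inits
    # are prone to the length-scale-collapse local optimum of the MLL
    init <- kernel_params(delta = d0, lam = med, sigma_n = 0.5 * sqrt(d0),
                          C = mean(Y))
  } else D2 <- sqdist(X, X)

  th <- c(log(init$delta), log(init$lam), log(max(init$sigma_n, 1e-6)), init$C)
  mll_of <- function(th) {
    p <- kernel_params(exp(th[1]), exp(th[2]), exp(th[3]), th[4])
    E <- exp(-D2 / (2 * p$lam^2))
    A <- p$delta * E + diag(p$sigma_n^2, n)
    L <- chol_jitter(A)
    r <- Y - p$C
    alpha <- backsolve(L, forwardsolve(t(L), r))
    Ainv <- chol2inv(L)
    mll <- -0.5 * sum(r * alpha) - sum(log(diag(L))) - n / 2 * log(2 * pi)
    # d MLL / d theta = 0.5 * sum((alpha alpha' - A^{-1}) * dA/dtheta)
    W <- tcrossprod(alpha) - Ainv
    K <- p$delta * E
    g <- c(0.5 * sum(W * K),
           0.5 * sum(W * (K * D2 / p$lam^2)),
           0.5 * sum(diag(W)) * 2 * p$sigma_n^2,
           sum(alpha))
    list(mll = mll, grad = g)
  }

  m <- v <- numeric(4)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  trace <- numeric(steps)
  for (s in seq_len(steps)) {
    ev <- mll_of(th)
    if (!is.finite(ev$mll))
      stop("non-finite marginal likelihood at step ", s, "; params: ",
           paste(signif(th, 4), collapse = ", "), call. = FALSE)
    trace[s] <- ev$mll
    g <- ev$grad
    if (!fit_C) g[4] <- 0
    if (optimizer == "adam") {
      m <- b1 * m + (1 - b1) * g
      v <- b2 * v + (1 - b2) * g^2
      mh <- m / (1 - b1^s); vh <- v / (1 - b2^s)
      th <- th + lr * mh / (sqrt(vh) + eps)
    } else {
      th <- th + lr * g
    }
  }
  fit <- gp_model(X, Y, kernel_params(exp(th[1]), exp(th[2]), exp(th[3]), th[4]))
  attr(fit, "mll_trace") <- trace
  fit
}

#' Save / restore a GP model checkpoint
#'
#' A checkpoint is a single JSON file holding the kernel hyperparameters,
#' the training data (sequences or raw embeddings plus targets) and
#' optional provenance (encoder name, seed). Restoring rebuilds the
#' factorization, so predictions are bit-reproducible.
#'
#' @param model A [gp_model()].
#' @param path Output JSON path.
#' @param sequences Optional training sequences to store instead of raw
#'   embeddings (re-encoded on load with the named encoder).
#' @param encoder_name Encoder used to (re-)embed stored sequences.
#' @param seed Optional provenance seed to record.
#' @return `write_gp_checkpoint` invisibly returns `path`;
#'   `read_gp_checkpoint` returns a [gp_model()].
#' @export
write_gp_checkpoint <- function(model, path, sequences = NULL,
                                encoder_name = "onehot", seed = NULL) {
  ck <- list(params = unclass(model$params), Y = model$Y,
             encoder = encoder_name, seed = seed)
  if (!is.null(sequences)) ck$sequences <- sequences else ck$X <- model$X
  jsonlite::write_json(ck, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_gp_checkpoint
#' @export
read_gp_checkpoint <- function(path) {
  ck <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- kernel_params(ck$params$delta, ck$params$lam, ck$params$sigma_n,
                     ck$params$C)
  X <- if (!is.null(ck$sequences)) {
    enc <- get_encoder(ck$encoder)
    do.call(rbind, lapply(ck$sequences, enc$encode))
  } else as.matrix(ck$X)
  gp_model(X, as.numeric(ck$Y), p)
}

#' Confidence-bound acquisition value
#'
#' `mu(z) + beta * sigma(z)` with the latent posterior standard deviation:
#' `beta > 0` is optimistic (UCB, rewards uncertainty), `beta < 0` is
#' pessimistic (LCB), `beta = 0` is the posterior mean.
#'
#' @param model A [gp_model()].
#' @param Z Query embedding matrix or vector.
#' @param beta Exploration coefficient (typical values -1, 0, 1, 2).
#' @param noisy Use the noisy predictive variance instead of the latent one.
#' @return Numeric acquisition value(s).
#' @export
gp_acquisition <- function(model, Z, beta = 0, noisy = FALSE) {
  post <- gp_posterior(model, Z, noisy = noisy)
  post$mu + beta * sqrt(post$sigma2)
}
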