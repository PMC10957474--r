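#' Prior specification for the logistic-normal linear model
#'
#' The model in alr coordinates is
#' `eta ~ N(Lambda X, Sigma)` column-wise, with conjugate priors
#' `Lambda ~ MN(Theta, Sigma, Gamma)` (matrix normal) and
#' `Sigma ~ InvWishart(Xi, nu)`. Defaults follow the weakly informative
#' convention for this model family: `Theta = 0`, `Gamma = I_Q`,
#' `nu = D + 2` and `Xi = (nu - D) I`, which puts the prior mean of `Sigma`
#' at the identity in alr coordinates.
#'
#' @param D Number of compositional parts (features); the model has D-1
#'   log-ratio coordinates.
#' @param Q Number of covariate rows in the design matrix.
#' @param Theta (D-1) x Q prior mean of `Lambda` (default zero).
#' @param Gamma Q x Q positive-definite covariance across covariates
#'   (default identity).
#' @param nu Inverse-Wishart degrees of freedom (default `D + 2`; must
#'   exceed `D`).
#' @param Xi (D-1) x (D-1) positive-definite inverse-Wishart scale
#'   (default `(nu - D) I`).
#' @return A list of class `lnm_prior`.
#' @export
lnm_prior <- function(D, Q, Theta = NULL, Gamma = NULL, nu = NULL, Xi = NULL) {
  if (D < 2L) stop("need at least two features")
  if (is.null(nu)) nu <- D + 2
  if (nu <= D) stop("nu must exceed D for a proper inverse-Wishart")
  if (is.null(Theta)) Theta <- matrix(0, D - 1L, Q)
  if (is.null(Gamma)) Gamma <- diag(Q)
  if (is.null(Xi)) Xi <- (nu - D) * diag(D - 1L)
  check_spd <- function(M, nm) {
    if (!isTRUE(all.equal(M, t(M), tolerance = 1e-8)))
      stop(nm, " must be symmetric")
    ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0) stop(nm, " must be positive-definite")
  }
  check_spd(Gamma, "Gamma"); check_spd(Xi, "Xi")
  stopifnot(nrow(Theta) == D - 1L, ncol(Theta) == Q,
            nrow(Gamma) == Q, nrow(Xi) == D - 1L)
  structure(list(Theta = Theta, Gamma = Gamma, nu = nu, Xi = Xi,
                 D = D, Q = Q),
            class = "lnm_prior")
}

#' Conjugate posterior of the logistic-normal linear model
#'
#' Exact matrix-normal inverse-Wishart update for the multivariate linear
#' model on observed alr coordinates:
#' \deqn{\Gamma_N = (X X' + \Gamma^{-1})^{-1}}
#' \deqn{\Theta_N = (\eta X' + \Theta \Gamma^{-1}) \Gamma_N}
#' \deqn{\nu_N = \nu + N}
#' \deqn{\Xi_N = \Xi + (\eta - \Theta_N X)(\eta - \Theta_N X)' +
#'   (\Theta_N - \Theta)\Gamma^{-1}(\Theta_N - \Theta)'}
#' With `N = 0` samples the posterior equals the prior.
#'
#' @param eta (D-1) x N matrix of observed alr coordinates.
#' @param X Q x N design matrix (or the list returned by [build_design()]).
#' @param prior An [lnm_prior()].
#' @return A list of class `lnm_posterior` carrying the updated parameters,
#'   the data, and dimension bookkeeping.
#' @export
fit_conjugate <- function(eta, X, prior) {
  if (is.list(X) && !is.null(X$X)) {
    spec <- X$spec
    X <- X$X
  } else spec <- NULL
  if (!is.matrix(eta)) eta <- matrix(eta, nrow = 1)
  if (any(!is.finite(eta))) stop("eta contains non-finite values")
  N <- ncol(eta)
  if (N != ncol(X)) stop("eta and X disagree on sample count")
  stopifnot(inherits(prior, "lnm_prior"),
            nrow(eta) == prior$D - 1L, nrow(X) == prior$Q)
  Gi <- chol2inv(chol(prior$Gamma))
  Gamma_post <- chol2inv(chol(X %*% t(X) + Gi))
  Theta_post <- (eta %*% t(X) + prior$Theta %*% Gi) %*% Gamma_post
  resid <- eta - Theta_post %*% X
  dTheta <- Theta_post - prior$Theta
  Xi_post <- prior$Xi + tcrossprod(resid) + dTheta %*% Gi %*% t(dTheta)
  Xi_post <- (Xi_post + t(Xi_post)) / 2
  Gamma_post <- (Gamma_post + t(Gamma_post)) / 2
  structure(list(Theta_post = Theta_post, Gamma_post = Gamma_post,
                 Xi_post = Xi_post, nu_post = prior$nu + N,
                 prior = prior, eta = eta, X = X, spec = spec,
                 D = prior$D, Q = prior$Q, N = N),
            class = "lnm_posterior")
}

#' @export
print.lnm_posterior <- function(x, ...) {
  cat(sprintf("lnm_posterior: D = %d features, Q = %d covariates, N = %d samples (nu_post = %g)\n",
              x$D, x$Q, x$N, x$nu_post))
  invisible(x)
}

#' Draw exact posterior samples of Lambda and Sigma
#'
#' Because the alr coordinates are observed, the posterior is available in
#' closed form and draws are exact (no MCMC): per draw,
#' `Sigma ~ InvWishart(Xi_post, nu_post)` via the Bartlett construction, then
#' `Lambda | Sigma ~ MN(Theta_post, Sigma, Gamma_post)`.
#'
#' @param post An [fit_conjugate()] result.
#' @param S Number of draws (default 2000).
#' @param seed Integer seed; draws are bit-reproducible given the seed.
#' @return List of class `lnm_draws` with `Lambda` ((D-1) x Q x S),
#'   `Sigma` ((D-1) x (D-1) x S), the coordinate `system` ("alr"), reference
#'   index, term names and the seed.
#' @export
sample_posterior <- function(post, S = 2000L, seed = 1L) {
  stopifnot(inherits(post, "lnm_posterior"), S >= 1L)
  p <- post$D - 1L
  if (post$nu_post <= p + 1) {
    stop("nu_post too small for a finite inverse-Wishart mean")
  }
  set.seed(as.integer(seed))
  Xi_inv <- chol2inv(chol(post$Xi_post))
  Ws <- stats::rWishart(S, df = post$nu_post, Sigma = Xi_inv)
  Ru <- chol(post$Gamma_post)  # upper: t(Ru) %*% Ru = Gamma_post
  Lambda <- array(NA_real_, c(p, post$Q, S))
  Sigma <- array(NA_real_, c(p, p, S))
  for (s in seq_len(S)) {
    Sig <- chol2inv(chol(Ws[, , s]))
    Sig <- (Sig + t(Sig)) / 2
    Sigma[, , s] <- Sig
    Zs <- matrix(stats::rnorm(p * post$Q), p, post$Q)
    Lambda[, , s] <- post$Theta_post + t(chol(Sig)) %*% Zs %*% Ru
  }
  term_names <- if (!is.null(post$spec)) post$spec$term_names else
    colnames(post$Theta_post)
  structure(list(Lambda = Lambda, Sigma = Sigma, system = "alr",
                 ref = post$D, term_names = term_names,
                 spec = post$spec, seed = seed),
            class = "lnm_draws")
}

#' Convert posterior coefficient draws from alr to clr coordinates
#'
#' Applies [alr_to_clr_coeffs()] to every draw; the result has D feature rows
#' whose columns each sum to zero, and coefficient summaries no longer depend
#' on which alr reference was used for fitting.
#'
#' @param draws An `lnm_draws` object in the alr system.
#' @param feature_names Optional character vector of D feature IDs to attach.
#' @return An `lnm_draws` object with `system = "clr"` and D rows per draw.
#' @export
draws_to_clr <- function(draws, feature_names = NULL) {
  stopifnot(inherits(draws, "lnm_draws"))
  if (draws$system == "clr") return(draws)
  p <- dim(draws$Lambda)[1L]
  Q <- dim(draws$Lambda)[2L]
  S <- dim(draws$Lambda)[3L]
  D <- p + 1L
  out <- array(NA_real_, c(D, Q, S))
  for (s in seq_len(S)) {
    out[, , s] <- alr_to_clr_coeffs(draws$Lambda[, , s], ref = draws$ref)
  }
  if (!is.null(feature_names)) {
    stopifnot(length(feature_names) == D)
    dimnames(out)[[1L]] <- feature_names
  }
  structure(list(Lambda = out, Sigma = draws$Sigma, system = "clr",
                 ref = draws$ref, term_names = draws$term_names,
                 spec = draws$spec, seed = draws$seed),
            class = "lnm_draws")
}

#' Posterior mean of the coefficient draws
#' @param draws An `lnm_draws` object.
#' @return Matrix of per-entry means across draws.
#' @export
draws_mean <- function(draws) {
  apply(draws$Lambda, c(1, 2), mean)
}
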