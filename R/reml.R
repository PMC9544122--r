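#' Direct REML estimation of variance components
#'
#' Independent cross-check for the Gibbs sampler: maximises the restricted
#' log-likelihood of a Gaussian mixed model with covariance
#' `V = sum_k sigma2_k V_k + sigma2_R I` directly by dense algebra, with the
#' fixed effects profiled out. Suitable for moderate n (dense n x n solves
#' per evaluation).
#'
#' @param y response vector.
#' @param X fixed-effect design matrix (full column rank).
#' @param V_list named list of n x n covariance structure matrices, one per
#'   non-residual component (e.g. `Z A Z'` for the animal term, `Z Z'` for
#'   iid terms). The residual identity term is always added.
#' @param n_starts number of optimiser starts.
#' @return list with `sigma2` (named vector, components then `sigma2_R`),
#'   `se` (asymptotic standard errors from the observed information of the
#'   restricted likelihood; NA where the Hessian is not usable), `loglik`
#'   (maximised restricted log-likelihood, additive constant
#'   `-(n-p)/2 log(2 pi)` excluded), and `converged` (FALSE flags
#'   non-convergence, never silent).
#' @export
reml_varcomp <- function(y, X, V_list, n_starts = 3L) {
  y <- as.numeric(y)
  X <- as.matrix(X)
  n <- length(y)
  m <- length(V_list)
  stopifnot(n == nrow(X), all(vapply(V_list, function(V) all(dim(V) == n), TRUE)))

  nll <- function(lv) {
    s2 <- exp(lv)
    V <- diag(s2[m + 1L], n)
    for (k in seq_len(m)) V <- V + s2[k] * V_list[[k]]
    U <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(U)) return(1e10)
    logdetV <- 2 * sum(log(diag(U)))
    ViX <- backsolve(U, forwardsolve(t(U), X))
    Viy <- backsolve(U, forwardsolve(t(U), y))
    XtViX <- crossprod(X, ViX)
    Um <- tryCatch(chol(XtViX), error = function(e) NULL)
    if (is.null(Um)) return(1e10)
    logdetM <- 2 * sum(log(diag(Um)))
    bhat <- backsolve(Um, forwardsolve(t(Um), crossprod(X, Viy)))
    yPy <- sum(y * Viy) - sum(crossprod(X, Viy) * bhat)
    0.5 * (logdetV + logdetM + yPy)
  }

  v0 <- var(y)
  best <- NULL
  inits <- list(rep(log(v0 / (m + 1)), m + 1L),
                c(rep(log(v0 / (5 * (m + 1))), m), log(v0)),
                rep(log(v0), m + 1L))
  for (s in seq_len(min(n_starts, length(inits)))) {
    fit <- tryCatch(
      optim(inits[[s]], nll, method = "Nelder-Mead",
            control = list(maxit = 5000, reltol = 1e-12)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) stop("REML optimisation failed from every start")
  converged <- best$convergence == 0
  if (!converged) warning("REML optimiser did not report convergence")
  s2 <- exp(best$par)
  names(s2) <- c(names(V_list) %||% paste0("sigma2_", seq_len(m)), "sigma2_R")
  # observed-information SEs on the variance scale
  se <- rep(NA_real_, m + 1L)
  H <- tryCatch(stats::optimHess(s2, function(v) {
    if (any(v <= 0)) return(1e10)
    nll(log(v))
  }), error = function(e) NULL)
  if (!is.null(H)) {
    cov <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(cov)) {
      dg <- diag(cov)
      se[dg > 0] <- sqrt(dg[dg > 0])
    }
  }
  names(se) <- names(s2)
  list(sigma2 = s2, se = se, loglik = -best$value, converged = converged)
}

#' Restricted log-likelihood at given variance values
#'
#' Exposed so tests can verify that the maximised restricted likelihood is
#' at least the value attained at the generating truth.
#'
#' @inheritParams reml_varcomp
#' @param sigma2 variance values, components then residual (all > 0).
#' @return restricted log-likelihood (same additive constant as
#'   [reml_varcomp()]).
#' @export
reml_loglik <- function(y, X, V_list, sigma2) {
  m <- length(V_list)
  stopifnot(length(sigma2) == m + 1L, all(sigma2 > 0))
  n <- length(y)
  V <- diag(sigma2[m + 1L], n)
  for (k in seq_len(m)) V <- V + sigma2[k] * V_list[[k]]
  U <- chol(V)
  ViX <- backsolve(U, forwardsolve(t(U), X))
  Viy <- backsolve(U, forwardsolve(t(U), y))
  XtViX <- crossprod(X, ViX)
  Um <- chol(XtViX)
  bhat <- backsolve(Um, forwardsolve(t(Um), crossprod(X, Viy)))
  yPy <- sum(y * Viy) - sum(crossprod(X, Viy) * bhat)
  -0.5 * (2 * sum(log(diag(U))) + 2 * sum(log(diag(Um))) + yPy)
}

#' REML oracle for an animal-model design
#'
#' Builds the five-component covariance structures (pedigree A restricted to
#' phenotyped records, and the three iid incidence structures) from a
#' [build_design()] object and calls [reml_varcomp()].
#'
#' @param design a `model_design`.
#' @param A optional dense additive relationship matrix over
#'   `design$pedigree` (computed by [build_A()] when omitted).
#' @return as [reml_varcomp()], with components named
#'   [variance_component_names()].
#' @export
reml_oracle <- function(design, A = NULL) {
  stopifnot(inherits(design, "model_design"))
  if (length(design$y) > 2000L) {
    stop("reml_oracle uses dense algebra; n must be <= 2000")
  }
  if (is.null(A)) A <- build_A(design$pedigree)
  incid <- function(idx) {
    Z <- outer(idx, sort(unique(idx)), "==") * 1
    tcrossprod(Z)
  }
  V_list <- list(
    sigma2_A = A[design$animal_idx, design$animal_idx],
    sigma2_dam = incid(design$dam_idx),
    sigma2_pcage = incid(design$pcage_idx),
    sigma2_ocage = incid(design$ocage_idx)
  )
  reml_varcomp(design$y, design$X, V_list)
}
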