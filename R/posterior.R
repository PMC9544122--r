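#' Posterior mode of an MCMC chain
#'
#' Mode of a Gaussian-kernel density estimate with Silverman's rule-of-thumb
#' bandwidth, evaluated on a 512-point grid spanning the chain's range. A
#' constant chain returns that constant.
#'
#' @param chain numeric vector of posterior draws.
#' @return a single numeric.
#' @export
posterior_mode <- function(chain) {
  chain <- as.numeric(chain)
  if (length(chain) == 0L) stop("empty chain")
  if (max(chain) == min(chain)) return(chain[1])
  d <- density(chain, bw = "nrd0", n = 512, from = min(chain), to = max(chain))
  d$x[which.max(d$y)]
}

#' Highest posterior density interval
#'
#' The narrowest interval containing `ceiling(level * n)` of the sorted
#' draws.
#'
#' @param chain numeric vector of posterior draws (n >= 20).
#' @param level probability mass to cover.
#' @return named numeric `c(lower, upper)`.
#' @export
hpd_interval <- function(chain, level = 0.95) {
  chain <- sort(as.numeric(chain))
  n <- length(chain)
  if (n < 20L) stop("need at least 20 draws for an HPD interval")
  m <- ceiling(level * n)
  starts <- seq_len(n - m + 1L)
  widths <- chain[starts + m - 1L] - chain[starts]
  i <- which.min(widths)
  c(lower = chain[i], upper = chain[i + m - 1L])
}

#' MCMC sign probability (pMCMC)
#'
#' `2 * min(#draws > 0, #draws < 0) / n`, floored at `1/n`.
#'
#' @param chain numeric vector of posterior draws.
#' @return a single numeric in `[1/n, 1]`.
#' @export
pmcmc <- function(chain) {
  chain <- as.numeric(chain)
  n <- length(chain)
  if (n == 0L) stop("empty chain")
  max(2 * min(sum(chain > 0), sum(chain < 0)) / n, 1 / n)
}

#' Convergence diagnostics for a retained chain
#'
#' Lag-1 autocorrelation of the (thinned) chain, and the Geweke z score:
#' difference of means of the first 10% and last 50% of the chain divided by
#' the square root of the sum of their spectral-density-at-zero variance
#' estimates (as implemented in the coda package).
#'
#' @param chain numeric vector of at least 100 retained draws.
#' @return list with `lag1_autocorr` and `geweke_z`.
#' @export
chain_diagnostics <- function(chain) {
  chain <- as.numeric(chain)
  if (length(chain) < 100L) stop("chain too short for diagnostics (< 100 draws)")
  if (var(chain) == 0) return(list(lag1_autocorr = 0, geweke_z = 0))
  lag1 <- acf(chain, lag.max = 1L, plot = FALSE)$acf[2, 1, 1]
  gz <- unname(coda::geweke.diag(coda::mcmc(chain), frac1 = 0.1, frac2 = 0.5)$z)
  list(lag1_autocorr = lag1, geweke_z = gz)
}

#' Effective sample size of a chain
#'
#' Spectral-density estimate of the effective number of independent draws
#' (coda's estimator); used for Monte-Carlo standard errors of posterior
#' means.
#'
#' @param chain numeric vector of posterior draws.
#' @return a single numeric.
#' @export
effective_size <- function(chain) {
  as.numeric(coda::effectiveSize(coda::mcmc(as.numeric(chain))))
}

#' Narrow-sense heritability from posterior samples
#'
#' Per retained draw, `h2 = sigma2_A / (sigma2_A + sigma2_dam + sigma2_pcage
#' + sigma2_ocage + sigma2_R)`; the derived chain is summarised by its
#' kernel-density posterior mode and 95% HPD interval.
#'
#' @param samples a `posterior_samples` object, or a matrix/data.frame whose
#'   columns are the five variance chains (in [variance_component_names()]
#'   order).
#' @param level credible level for the HPD interval.
#' @return an object of class `heritability_estimate`: list with `chain`,
#'   `mode`, `lower`, `upper`, `level`.
#' @export
heritability <- function(samples, level = 0.95) {
  v <- if (inherits(samples, "posterior_samples")) samples$variances
       else as.matrix(samples)
  if (ncol(v) != 5L) stop("need the five variance-component chains")
  lens <- apply(v, 2, function(col) sum(!is.na(col)))
  if (length(unique(lens)) != 1L || anyNA(v)) {
    stop("variance chains are misaligned or contain missing draws")
  }
  h2 <- v[, 1] / rowSums(v)
  ci <- hpd_interval(h2, level)
  structure(list(chain = h2, mode = posterior_mode(h2),
                 lower = unname(ci["lower"]), upper = unname(ci["upper"]),
                 level = level),
            class = "heritability_estimate")
}

#' @export
print.heritability_estimate <- function(x, ...) {
  cat(sprintf("h2 posterior mode %.4f (%.0f%% HPD %.4f, %.4f; %d draws)\n",
              x$mode, 100 * x$level, x$lower, x$upper, length(x$chain)))
  invisible(x)
}

#' Summarise fixed-effect chains as a coefficient table
#'
#' One row per fixed-effect term: posterior mode, HPD bounds and pMCMC, in
#' the canonical reporting order.
#'
#' @param samples a `posterior_samples` object.
#' @param level credible level.
#' @return data.frame with columns `term`, `mode`, `lower`, `upper`,
#'   `pMCMC`.
#' @export
coefficient_table <- function(samples, level = 0.95) {
  stopifnot(inherits(samples, "posterior_samples"))
  B <- samples$beta
  rows <- lapply(colnames(B), function(term) {
    ch <- B[, term]
    ci <- hpd_interval(ch, level)
    data.frame(term = term, mode = posterior_mode(ch),
               lower = unname(ci["lower"]), upper = unname(ci["upper"]),
               pMCMC = pmcmc(ch), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
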