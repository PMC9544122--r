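#' Gene-drop additive genetic values down a pedigree
#'
#' Realises breeding values a ~ N(0, A * sigma2_A) by sequential simulation
#' (gene dropping) instead of factorising A: founders are drawn
#' N(0, sigma2_A); each non-founder is the mean of its parents' values plus
#' an independent Mendelian-sampling deviation
#' N(0, sigma2_A * (0.5 - (F_sire + F_dam)/4)) (with one known parent the
#' deviation variance is sigma2_A * (0.75 - F_parent/4)). Over replicates the
#' empirical covariance converges to A * sigma2_A.
#'
#' @param pedigree a pedigree data.frame (id, sire, dam).
#' @param sigma2_A additive genetic variance (>= 0).
#' @param seed RNG seed.
#' @return numeric vector of additive values named by id, in the order of
#'   `pedigree$id`.
#' @export
drop_breeding_values <- function(pedigree, sigma2_A, seed = NULL) {
  if (!is.numeric(sigma2_A) || sigma2_A < 0) stop("`sigma2_A` must be >= 0")
  sp <- validate_pedigree(pedigree)
  n <- nrow(sp)
  idx <- seq_len(n)
  names(idx) <- sp$id
  si <- unname(idx[sp$sire])
  di <- unname(idx[sp$dam])
  F <- unname(inbreeding(sp))
  with_seed(seed, {
    a <- numeric(n)
    z <- rnorm(n)
    for (i in seq_len(n)) {
      s <- si[i]; d <- di[i]
      if (is.na(s) && is.na(d)) {
        a[i] <- z[i] * sqrt(sigma2_A)
      } else if (!is.na(s) && !is.na(d)) {
        msv <- sigma2_A * (0.5 - 0.25 * (F[s] + F[d]))
        a[i] <- 0.5 * (a[s] + a[d]) + z[i] * sqrt(msv)
      } else {
        p <- if (is.na(s)) d else s
        msv <- sigma2_A * (0.75 - 0.25 * F[p])
        a[i] <- 0.5 * a[p] + z[i] * sqrt(msv)
      }
    }
    names(a) <- sp$id
    a[as.character(pedigree$id)]
  })
}
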