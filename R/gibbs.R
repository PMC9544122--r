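#' Fit the animal model by Gibbs sampling
#'
#' Runs the Markov chain for the five-variance-component animal model on a
#' [build_design()] object. Each sweep draws (i) all location effects (fixed
#' effects plus the animal, dam, parental-cage and offspring-cage random
#' vectors) jointly from their exact Gaussian full conditional via the
#' mixed-model equations, with the sparse pedigree-derived A-inverse on the
#' animal block, and (ii) each variance component from its scaled
#' inverse-chi-square full conditional: df `nu + q_term`, scale
#' `(nu V + SS_term)/(nu + q_term)`. A variance draw that underflows is
#' floored at machine epsilon and counted. A fixed `spec$seed` reproduces
#' the chain exactly.
#'
#' @param design a `model_design` from [build_design()].
#' @param spec a [model_spec()].
#' @param A_inverse optional sparse A-inverse; computed from
#'   `design$pedigree` by [build_A_inverse()] when omitted.
#' @param start_var starting value for every variance component; defaults to
#'   `var(y)/5`.
#' @return an object of class `posterior_samples`: list with `beta` (draws x
#'   10 matrix), `variances` (draws x 5 matrix, columns `sigma2_A`,
#'   `sigma2_dam`, `sigma2_pcage`, `sigma2_ocage`, `sigma2_R`), `spec`,
#'   `n_floored` and `design` metadata.
#' @export
gibbs_sample <- function(design, spec, A_inverse = NULL, start_var = NULL) {
  stopifnot(inherits(design, "model_design"), inherits(spec, "model_spec"))
  if (is.null(A_inverse)) A_inverse <- build_A_inverse(design$pedigree)
  A_inverse <- methods::as(methods::as(A_inverse, "generalMatrix"), "CsparseMatrix")
  start_var <- start_var %||% max(var(design$y) / 5, .Machine$double.eps)
  res <- with_seed(spec$seed, gibbs_mcmc_cpp(
    y = design$y, X = design$X,
    animal_idx = design$animal_idx,
    dam_idx = design$dam_idx, pcage_idx = design$pcage_idx,
    ocage_idx = design$ocage_idx,
    Ainv = A_inverse,
    n_dam = length(design$dam_levels),
    n_pcage = length(design$pcage_levels),
    n_ocage = length(design$ocage_levels),
    prior_V = spec$prior_V, prior_nu = spec$prior_nu,
    n_iter = spec$n_iter, burnin = spec$burnin, thin = spec$thin,
    start_var = start_var))
  colnames(res$beta) <- fixed_effect_terms()
  colnames(res$variances) <- variance_component_names()
  structure(list(beta = res$beta, variances = res$variances, spec = spec,
                 n_floored = res$n_floored, response = design$response,
                 n_records = length(design$y)),
            class = "posterior_samples")
}

#' Names of the five variance components
#' @return character vector.
#' @export
variance_component_names <- function() {
  c("sigma2_A", "sigma2_dam", "sigma2_pcage", "sigma2_ocage", "sigma2_R")
}

#' @export
print.posterior_samples <- function(x, ...) {
  cat(sprintf("<posterior_samples: '%s', %d records, %d retained draws>\n",
              x$response %||% "?", x$n_records %||% NA_integer_,
              nrow(x$variances)))
  invisible(x)
}
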