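#' Ground-truth trait architecture for simulation
#'
#' A `trait_truth` holds the generating values for one colouration metric:
#' the 10 fixed-effect coefficients (in the canonical design order, see
#' [fixed_effect_terms()]) and the five variance components. The derived
#' true narrow-sense heritability is
#' `h2 = sigma2_A / (sigma2_A + sigma2_dam + sigma2_pcage + sigma2_ocage + sigma2_R)`.
#'
#' @param beta numeric vector of length 10: intercept, year (2016), age
#'   slope (per day), sex (male), offspring treatment (short-bask), parental
#'   treatment (short-bask), sex:offspring, sex:parental,
#'   offspring:parental, sex:offspring:parental. Reference levels: 2015,
#'   female, long-bask.
#' @param sigma2_A additive genetic variance.
#' @param sigma2_dam maternal-identity variance.
#' @param sigma2_pcage parental-cage variance.
#' @param sigma2_ocage offspring-cage variance.
#' @param sigma2_R residual variance.
#' @return a list of class `trait_truth` with an added `h2_true` element.
#' @export
trait_truth <- function(beta, sigma2_A, sigma2_dam, sigma2_pcage,
                        sigma2_ocage, sigma2_R) {
  beta <- as.numeric(beta)
  if (length(beta) != 10L) stop("`beta` must have length 10")
  v <- c(sigma2_A, sigma2_dam, sigma2_pcage, sigma2_ocage, sigma2_R)
  if (any(!is.finite(v)) || any(v < 0)) stop("all variances must be finite and >= 0")
  tot <- sum(v)
  h2 <- if (tot > 0) sigma2_A / tot else 0
  structure(list(beta = setNames(beta, fixed_effect_terms()),
                 sigma2_A = sigma2_A, sigma2_dam = sigma2_dam,
                 sigma2_pcage = sigma2_pcage, sigma2_ocage = sigma2_ocage,
                 sigma2_R = sigma2_R, h2_true = h2),
            class = "trait_truth")
}

#' Convenience constructor: trait truth from heritability and variance shares
#'
#' Partitions a total phenotypic variance into the five components from a
#' target heritability and fractional shares for the dam, parental-cage and
#' offspring-cage effects (residual takes the remainder).
#'
#' @param h2 target narrow-sense heritability in `[0, 1)`.
#' @param sigma2_P total phenotypic variance.
#' @param dam_frac,pcage_frac,ocage_frac variance shares of the non-genetic
#'   structured components.
#' @param beta fixed effects; default is an intercept of 0.3 with all other
#'   terms 0.
#' @return a `trait_truth`.
#' @export
trait_truth_from_h2 <- function(h2, sigma2_P = 0.0036, dam_frac = 0.10,
                                pcage_frac = 0.05, ocage_frac = 0.05,
                                beta = c(0.3, rep(0, 9))) {
  if (h2 < 0 || h2 + dam_frac + pcage_frac + ocage_frac >= 1 + 1e-12) {
    stop("variance shares must sum to less than 1")
  }
  trait_truth(beta,
              sigma2_A = h2 * sigma2_P,
              sigma2_dam = dam_frac * sigma2_P,
              sigma2_pcage = pcage_frac * sigma2_P,
              sigma2_ocage = ocage_frac * sigma2_P,
              sigma2_R = (1 - h2 - dam_frac - pcage_frac - ocage_frac) * sigma2_P)
}

#' Default three-trait simulation truth
#'
#' Fixed effects are the published animal-model coefficient estimates for
#' brightness, elongation and contrast; heritabilities are the published
#' posterior modes (0.1619, 0.1810, 0.2304). Total phenotypic variance and
#' the non-genetic variance shares are package choices (documented in the
#' methods vignette): sigma2_P = 0.0036 per trait (phenotypic SD 0.06 on the
#' 0-1 brightness scale), with 10% maternal, 5% parental-cage and 5%
#' offspring-cage shares.
#'
#' @return named list of three `trait_truth` objects
#'   (brightness, elongation, contrast).
#' @export
default_truth <- function() {
  list(
    brightness = trait_truth(
      beta = c(0.3085, -0.0345, 0.0017, -0.0132, -0.0136, 0.0088,
               -0.0034, 0.0079, 0.0195, 0.0099),
      sigma2_A = 0.1619 * 0.0036, sigma2_dam = 0.10 * 0.0036,
      sigma2_pcage = 0.05 * 0.0036, sigma2_ocage = 0.05 * 0.0036,
      sigma2_R = (1 - 0.1619 - 0.20) * 0.0036),
    elongation = trait_truth(
      beta = c(0.0994, 0.0026, 0.0014, -0.0021, -0.0142, -0.0022,
               0.0136, 0.0033, -0.0019, -0.0141),
      sigma2_A = 0.1810 * 0.0036, sigma2_dam = 0.10 * 0.0036,
      sigma2_pcage = 0.05 * 0.0036, sigma2_ocage = 0.05 * 0.0036,
      sigma2_R = (1 - 0.1810 - 0.20) * 0.0036),
    contrast = trait_truth(
      beta = c(0.1382, -0.0386, 0.0011, -0.0157, -0.0153, 0.0085,
               -0.0053, 0.0118, 0.0094, 0.0096),
      sigma2_A = 0.2304 * 0.0036, sigma2_dam = 0.10 * 0.0036,
      sigma2_pcage = 0.05 * 0.0036, sigma2_ocage = 0.05 * 0.0036,
      sigma2_R = (1 - 0.2304 - 0.20) * 0.0036)
  )
}

#' Simulate phenotype records under the animal model
#'
#' Each trait value is the fixed-effect linear predictor plus the
#' individual's additive genetic value (gene-dropped down the pedigree), its
#' dam, parental-cage and offspring-cage effects (each iid Normal with its
#' component variance) and an iid Normal residual:
#' `y = X beta + a + dam + pcage + ocage + e`.
#'
#' @param pedigree pedigree data.frame covering every phenotyped individual.
#' @param covariates covariate table as from [simulate_pedigree()].
#' @param truth named list of `trait_truth` objects, one per trait.
#' @param seed RNG seed.
#' @return data.frame with column `id` plus one column per trait.
#' @export
simulate_records <- function(pedigree, covariates, truth = default_truth(),
                             seed = NULL) {
  stopifnot(is.data.frame(covariates), "id" %in% names(covariates))
  need <- c("sex", "year", "age", "parental_treatment", "offspring_treatment",
            "dam", "parental_cage", "offspring_cage")
  missing_col <- setdiff(need, names(covariates))
  if (length(missing_col) > 0L) {
    stop("covariate table lacks columns: ", paste(missing_col, collapse = ", "))
  }
  bad <- covariates$id[!complete.cases(covariates[, need])]
  if (length(bad) > 0L) {
    stop("records with missing covariates: ", paste(bad, collapse = ", "))
  }
  if (!all(covariates$id %in% pedigree$id)) {
    stop("phenotyped individuals absent from the pedigree: ",
         paste(setdiff(covariates$id, pedigree$id), collapse = ", "))
  }
  X <- fixed_effects_matrix(covariates)
  out <- data.frame(id = covariates$id, stringsAsFactors = FALSE)
  seeds <- make_subseeds(seed %||% sample.int(.Machine$integer.max - 1L, 1L),
                         length(truth))
  for (tr in seq_along(truth)) {
    tt <- truth[[tr]]
    stopifnot(inherits(tt, "trait_truth"))
    y <- with_seed(seeds[tr], {
      a <- drop_breeding_values(pedigree, tt$sigma2_A, seed = NULL)
      ranef <- function(f, s2) {
        lev <- unique(f)
        eff <- setNames(rnorm(length(lev), sd = sqrt(s2)), lev)
        unname(eff[f])
      }
      drop(X %*% tt$beta) + unname(a[covariates$id]) +
        ranef(covariates$dam, tt$sigma2_dam) +
        ranef(covariates$parental_cage, tt$sigma2_pcage) +
        ranef(covariates$offspring_cage, tt$sigma2_ocage) +
        rnorm(nrow(covariates), sd = sqrt(tt$sigma2_R))
    })
    out[[names(truth)[tr]]] <- y
  }
  out
}
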