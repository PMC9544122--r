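#' Canonical fixed-effect terms of the colouration animal model
#'
#' The model's fixed part, in the order the coefficient table is reported:
#' intercept (reference levels: year 2015, female, long-bask/long-bask),
#' year, age at photograph (days, entered uncentred), sex, offspring
#' treatment, parental treatment, the three two-way interactions and the
#' sex x offspring x parental three-way interaction.
#'
#' @return character vector of the 10 term names.
#' @export
fixed_effect_terms <- function() {
  c("intercept", "year_2016", "age", "sex_male", "offspring_short",
    "parental_short", "sex_male:offspring_short", "sex_male:parental_short",
    "offspring_short:parental_short",
    "sex_male:offspring_short:parental_short")
}

#' Fixed-effect design matrix from a covariate table
#'
#' Treatment coding against the reference levels 2015 / female / long-bask.
#'
#' @param covariates data.frame with columns `sex`, `year`, `age`,
#'   `offspring_treatment`, `parental_treatment`.
#' @return n x 10 numeric matrix with columns [fixed_effect_terms()].
#' @export
fixed_effects_matrix <- function(covariates) {
  yr_levels <- sort(unique(as.character(covariates$year)))
  if (length(yr_levels) > 2L) stop("more than two sampling years are not supported")
  if (length(yr_levels) == 1L) yr_levels <- c(yr_levels, paste0(yr_levels, "_other"))
  d <- data.frame(
    year = factor(as.character(covariates$year), levels = yr_levels),
    age = as.numeric(covariates$age),
    sex = factor(covariates$sex, levels = c("female", "male")),
    offspring_treatment = factor(covariates$offspring_treatment,
                                 levels = c("long", "short")),
    parental_treatment = factor(covariates$parental_treatment,
                                levels = c("long", "short"))
  )
  if (anyNA(d)) stop("covariates contain missing or out-of-level values")
  X <- stats::model.matrix(
    ~ year + age + sex + offspring_treatment + parental_treatment +
      sex:offspring_treatment + sex:parental_treatment +
      offspring_treatment:parental_treatment +
      sex:offspring_treatment:parental_treatment,
    data = d)
  structure(unname(X), dimnames = list(NULL, fixed_effect_terms()))
}

#' Animal-model specification
#'
#' Collects response name, variance priors and the MCMC schedule. Defaults
#' follow the published analysis: a scaled inverse chi-square prior with
#' scale `V = 1` and degree-of-belief `nu = 0.002` on every variance
#' component, 1,500,000 iterations, thinning 1,000, burn-in 1,000. The test
#' profile used throughout the package's own checks is much shorter
#' (e.g. 50,000 / 50 / 5,000); both are expressible here.
#'
#' @param response name of the trait column to model.
#' @param n_iter total MCMC iterations.
#' @param burnin iterations discarded before retention begins.
#' @param thin retention stride; the chain keeps
#'   `floor((n_iter - burnin)/thin)` draws.
#' @param prior_V scale of the variance prior.
#' @param prior_nu degree-of-belief of the variance prior (> 0).
#' @param seed RNG seed for the sampler.
#' @return a list of class `model_spec`.
#' @export
model_spec <- function(response, n_iter = 1500000L, burnin = 1000L,
                       thin = 1000L, prior_V = 1, prior_nu = 0.002,
                       seed = NULL) {
  s <- list(response = response, n_iter = as.integer(n_iter),
            burnin = as.integer(burnin), thin = as.integer(thin),
            prior_V = prior_V, prior_nu = prior_nu, seed = seed)
  if (s$prior_nu <= 0 || s$prior_V <= 0) stop("prior V and nu must be > 0")
  if (s$thin < 1L || s$thin > s$n_iter) stop("`thin` must lie in 1..n_iter")
  if (s$burnin < 0L || s$burnin >= s$n_iter) stop("`burnin` must be < n_iter")
  if ((s$n_iter - s$burnin) %/% s$thin < 1L) stop("schedule retains no draws")
  structure(s, class = "model_spec")
}

#' Build animal-model design structures
#'
#' Joins a response to its covariates, drops incomplete records
#' (complete-case analysis, with a message reporting the count), builds the
#' 10-column fixed-effect matrix and the incidence of the four random terms.
#' The animal term is linked to the pedigree: `animal_idx` indexes each
#' record's individual within `pedigree$id` order, the order used by
#' [build_A()] / [build_A_inverse()].
#'
#' @param records data.frame holding `id`, the response column and the
#'   covariate columns.
#' @param pedigree pedigree data.frame containing every phenotyped id.
#' @param response name of the response column.
#' @return list of class `model_design`: `y`, `X`, `animal_idx`, factor
#'   index vectors `dam_idx`, `pcage_idx`, `ocage_idx` (with level tables),
#'   `ids`, `pedigree`, `n_dropped`.
#' @export
build_design <- function(records, pedigree, response) {
  stopifnot(is.data.frame(records), "id" %in% names(records))
  if (!response %in% names(records)) {
    stop(sprintf("response column '%s' is absent from the records", response))
  }
  need <- c("sex", "year", "age", "parental_treatment", "offspring_treatment",
            "dam", "parental_cage", "offspring_cage")
  missing_col <- setdiff(need, names(records))
  if (length(missing_col) > 0L) {
    stop("records lack covariate columns: ", paste(missing_col, collapse = ", "))
  }
  keep <- complete.cases(records[, c("id", response, need)])
  n_dropped <- sum(!keep)
  if (n_dropped > 0L) {
    message(sprintf("build_design: dropped %d incomplete record(s); %d retained",
                    n_dropped, sum(keep)))
  }
  rec <- records[keep, , drop = FALSE]
  if (nrow(rec) == 0L) stop("no complete records to model")
  # canonical record order: by id, so fits are invariant to input row order
  rec <- rec[order(rec$id), , drop = FALSE]
  missing_ped <- setdiff(rec$id, pedigree$id)
  if (length(missing_ped) > 0L) {
    stop("phenotyped individuals absent from the pedigree: ",
         paste(missing_ped, collapse = ", "))
  }
  fidx <- function(x) {
    f <- factor(x)
    list(idx = as.integer(f), levels = levels(f))
  }
  dam <- fidx(rec$dam); pc <- fidx(rec$parental_cage); oc <- fidx(rec$offspring_cage)
  structure(list(
    y = as.numeric(rec[[response]]),
    X = fixed_effects_matrix(rec),
    animal_idx = match(rec$id, pedigree$id),
    dam_idx = dam$idx, dam_levels = dam$levels,
    pcage_idx = pc$idx, pcage_levels = pc$levels,
    ocage_idx = oc$idx, ocage_levels = oc$levels,
    ids = rec$id,
    pedigree = pedigree,
    response = response,
    n_dropped = n_dropped
  ), class = "model_design")
}
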