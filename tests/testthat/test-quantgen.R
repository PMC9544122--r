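make_records <- function(n = 8) {
  data.frame(
    id = sprintf("O%02d", seq_len(n)),
    sex = rep(c("female", "male"), length.out = n),
    year = rep(c("2015", "2016"), each = n / 2),
    age = seq(10, 40, length.out = n),
    parental_treatment = rep(c("long", "short"), length.out = n),
    offspring_treatment = rep(c("long", "short"), each = n / 2),
    dam = rep(c("d1", "d2"), each = n / 2),
    parental_cage = rep(c("p1", "p2"), each = n / 2),
    offspring_cage = rep(c("c1", "c2"), length.out = n),
    y = rnorm(n), stringsAsFactors = FALSE
  )
}

test_that("the fixed-effect design matrix matches the reported model", {
  rec <- make_records()
  X <- fixed_effects_matrix(rec)
  expect_equal(ncol(X), 10L)
  expect_equal(colnames(X), fixed_effect_terms())
  # reference-level animal: female, 2015, long/long -> intercept + age only
  ref <- rec[1, ]; ref$sex <- "female"; ref$year <- "2015"
  ref$offspring_treatment <- "long"; ref$parental_treatment <- "long"
  xr <- fixed_effects_matrix(ref)[1, ]
  expect_equal(unname(xr[c("intercept", "age")]), c(1, ref$age))
  expect_equal(unname(xr[setdiff(names(xr), c("intercept", "age"))]),
               rep(0, 8))
  # male, short-bask offspring and parents -> all interaction dummies are 1
  top <- ref; top$sex <- "male"; top$offspring_treatment <- "short"
  top$parental_treatment <- "short"
  xt <- fixed_effects_matrix(top)[1, ]
  expect_equal(unname(xt[c("sex_male:offspring_short", "sex_male:parental_short",
                           "offspring_short:parental_short",
                           "sex_male:offspring_short:parental_short")]),
               rep(1, 4))
})

test_that("build_design drops incomplete records and checks inputs", {
  rec <- make_records()
  ped <- data.frame(id = rec$id, sire = NA, dam = NA, stringsAsFactors = FALSE)
  rec$y[2] <- NA
  rec$age[5] <- NA
  expect_message(d <- build_design(rec, ped, "y"), "dropped 2")
  expect_equal(length(d$y), 6L)
  expect_equal(d$n_dropped, 2L)
  expect_error(build_design(rec, ped, "absent_trait"), "absent")
  expect_error(build_design(rec[, -4], ped, "y"), "lack covariate")
})

test_that("the model spec enforces the schedule invariants", {
  expect_error(model_spec("y", prior_nu = 0), "nu")
  expect_error(model_spec("y", n_iter = 100, thin = 10, burnin = 100),
               "burnin")
  expect_error(model_spec("y", n_iter = 100, thin = 200), "thin")
  s <- model_spec("y")
  expect_equal(c(s$n_iter, s$burnin, s$thin), c(1500000L, 1000L, 1000L))
  expect_equal(c(s$prior_V, s$prior_nu), c(1, 0.002))
})

test_that("the Gibbs chain is deterministic, positive and correctly sized", {
  st <- quick_study(seed = 301)
  design <- build_design(st$joined, st$sim$pedigree, "brightness")
  spec <- model_spec("brightness", n_iter = 3000, burnin = 300, thin = 3,
                     seed = 77)
  s1 <- gibbs_sample(design, spec)
  s2 <- gibbs_sample(design, spec)
  expect_identical(s1$beta, s2$beta)
  expect_identical(s1$variances, s2$variances)
  expect_equal(nrow(s1$variances), (3000L - 300L) %/% 3L)
  expect_true(all(s1$variances > 0))
  h2 <- heritability(s1)
  expect_true(all(h2$chain > 0 & h2$chain < 1))
  expect_true(h2$lower <= h2$mode && h2$mode <= h2$upper)
})

test_that("h2 is equivariant under a common rescaling of the phenotypes", {
  # scaling every phenotype by c and the prior scale V by c^2 maps the
  # sampler's trajectory exactly (location draws scale by c, variance draws
  # by c^2), so the h2 chain is reproduced draw for draw; with V held fixed
  # the ratio is only asymptotically scale-free (see the methods vignette)
  st <- quick_study(seed = 303,
                    config = breeding_config(n_parental_cages = 6L))
  d1 <- build_design(st$joined, st$sim$pedigree, "brightness")
  scaled <- st$joined; scaled$brightness <- scaled$brightness * 10
  d2 <- build_design(scaled, st$sim$pedigree, "brightness")
  s1 <- gibbs_sample(d1, model_spec("brightness", n_iter = 3000, burnin = 300,
                                    thin = 3, seed = 5),
                     start_var = 0.001)
  s2 <- gibbs_sample(d2, model_spec("brightness", n_iter = 3000, burnin = 300,
                                    thin = 3, seed = 5, prior_V = 100),
                     start_var = 0.1)
  expect_equal(heritability(s2)$chain, heritability(s1)$chain,
               tolerance = 1e-9)
  expect_equal(s2$variances, s1$variances * 100, tolerance = 1e-9)
})

test_that("order of input rows does not change the fit", {
  st <- quick_study(seed = 305)
  ped <- st$sim$pedigree
  met <- data.frame(image_id = st$records$id,
                    brightness = st$records$brightness)
  shuffled <- met[rev(seq_len(nrow(met))), ]
  r1 <- run_models(met, st$sim$covariates, ped, traits = "brightness",
                   n_iter = 2000, burnin = 200, thin = 2, seed = 9)
  r2 <- run_models(shuffled, st$sim$covariates, ped, traits = "brightness",
                   n_iter = 2000, burnin = 200, thin = 2, seed = 9)
  expect_identical(r1$fits$brightness$samples$variances,
                   r2$fits$brightness$samples$variances)
  expect_identical(r1$fits$brightness$coefficients,
                   r2$fits$brightness$coefficients)
})

test_that("REML matches the closed-form ANOVA estimator on balanced data", {
  set.seed(11)
  g <- 12L; m <- 6L # groups, replicates
  eff <- rnorm(g, sd = sqrt(2))
  y <- rep(eff, each = m) + rnorm(g * m, sd = 1.5)
  X <- matrix(1, g * m, 1)
  Z <- outer(rep(seq_len(g), each = m), seq_len(g), "==") * 1
  fit <- reml_varcomp(y, X, list(group = tcrossprod(Z)))
  grp <- rep(seq_len(g), each = m)
  msb <- m * var(tapply(y, grp, mean))
  msw <- sum((y - ave(y, grp))^2) / (g * (m - 1))
  expect_equal(unname(fit$sigma2["sigma2_R"]), msw, tolerance = 1e-4)
  expect_equal(unname(fit$sigma2["group"]), (msb - msw) / m, tolerance = 1e-4)
  expect_true(fit$converged)
  # the maximised restricted likelihood is at least its value at the truth
  expect_gte(fit$loglik + 1e-8,
             reml_loglik(y, X, list(tcrossprod(Z)), c(2, 1.5^2)))
})

test_that("posterior summaries behave on known distributions", {
  expect_equal(posterior_mode(rep(3.7, 50)), 3.7)
  set.seed(13)
  expect_equal(posterior_mode(rnorm(100000, 5, 1)), 5, tolerance = 0.1 / 5)
  expect_lt(posterior_mode(rexp(1000000)), 0.15)

  u <- runif(100000)
  w <- hpd_interval(u, 0.95)
  expect_equal(unname(w["upper"] - w["lower"]), 0.95, tolerance = 0.01 / 0.95)
  z <- rnorm(100000)
  hz <- hpd_interval(z)
  expect_equal(unname(hz["lower"] + hz["upper"]), 0, tolerance = 0.1)
  const <- rep(1.5, 25)
  expect_equal(unname(diff(hpd_interval(const))), 0)
  expect_error(hpd_interval(rnorm(10)), "at least 20")

  expect_equal(pmcmc(rep(1, 200)), 1 / 200)
  expect_equal(pmcmc(c(rep(1, 100), rep(-1, 100))), 1)
  expect_equal(pmcmc(c(rep(1, 975), rep(-1, 25))), 0.05)
})

test_that("diagnostics separate well-mixed from pathological chains", {
  set.seed(19)
  ok <- replicate(20, {
    ch <- rnorm(5000)
    d <- chain_diagnostics(ch)
    abs(d$lag1_autocorr) < 0.05 && abs(d$geweke_z) < 3
  })
  expect_gte(mean(ok), 0.95)
  walk <- cumsum(rnorm(5000))
  expect_gt(chain_diagnostics(walk)$lag1_autocorr, 0.9)
  shifted <- c(rnorm(2500), rnorm(2500, 5))
  expect_gt(abs(chain_diagnostics(shifted)$geweke_z), 5)
  expect_error(chain_diagnostics(rnorm(50)), "too short")
})

test_that("heritability is the variance-component ratio, draw by draw", {
  v <- matrix(1, nrow = 40, ncol = 5,
              dimnames = list(NULL, variance_component_names()))
  h <- heritability(v)
  expect_equal(unique(h$chain), 0.2)
  expect_equal(h$mode, 0.2)
  # vanishing additive variance -> mode near zero
  set.seed(23)
  v2 <- cbind(sigma2_A = rexp(500, 1e6), sigma2_dam = rexp(500) + 0.5,
              sigma2_pcage = rexp(500) + 0.5, sigma2_ocage = rexp(500) + 0.5,
              sigma2_R = rexp(500) + 0.5)
  expect_lt(heritability(v2)$mode, 0.01)
  v3 <- v; v3[5, 2] <- NA
  expect_error(heritability(v3), "misaligned")
})

test_that("pMCMC and the HPD interval agree on significance", {
  st <- quick_study(seed = 307)
  design <- build_design(st$joined, st$sim$pedigree, "brightness")
  s <- gibbs_sample(design, model_spec("brightness", n_iter = 3000,
                                       burnin = 300, thin = 3, seed = 41))
  tab <- coefficient_table(s)
  excl0 <- tab$lower > 0 | tab$upper < 0
  expect_true(all(tab$pMCMC[excl0] < 0.05))
})
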