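test_that("simulated breeding design reproduces the target study shape", {
  sim <- simulate_pedigree(breeding_config(seed = 42))
  cov <- sim$covariates
  # totals near the emulated study: ~179 offspring from ~37 dams
  expect_gt(nrow(cov), 179 * 0.85)
  expect_lt(nrow(cov), 179 * 1.15)
  n_dams <- length(unique(cov$dam))
  expect_gt(n_dams, 37 * 0.85)
  expect_lt(n_dams, 37 * 1.15)
  # every offspring has both parents recorded; founders have neither
  ped <- sim$pedigree
  off <- ped[ped$id %in% cov$id, ]
  expect_false(anyNA(off$sire) || anyNA(off$dam))
  founders <- ped[!ped$id %in% cov$id, ]
  expect_true(all(is.na(founders$sire) & is.na(founders$dam)))
  # covariates complete, treatments two-level, ages in the photographed range
  expect_true(all(stats::complete.cases(cov)))
  expect_setequal(unique(cov$offspring_treatment), c("long", "short"))
  expect_true(all(cov$age >= 6 & cov$age <= 62))
  expect_setequal(unique(cov$year), c("2015", "2016"))
})

test_that("clutches are split across offspring treatments", {
  sim <- simulate_pedigree(breeding_config(seed = 7))
  cov <- sim$covariates
  ped <- sim$pedigree
  sire_of <- setNames(ped$sire, ped$id)
  clutch <- paste(cov$dam, sire_of[cov$id], cov$year)
  by_clutch <- split(cov$offspring_treatment, clutch)
  sizes <- lengths(by_clutch)
  n_long <- vapply(by_clutch, function(x) sum(x == "long"), 0L)
  # split-clutch: within every clutch the treatment counts differ by <= 1
  expect_true(all(abs(n_long - (sizes - n_long)) <= 1L))
})

test_that("pedigree simulation is deterministic and errors on empty designs", {
  a <- simulate_pedigree(breeding_config(seed = 99))
  b <- simulate_pedigree(breeding_config(seed = 99))
  expect_identical(a, b)
  c <- simulate_pedigree(breeding_config(seed = 100))
  expect_false(identical(a$covariates, c$covariates))
  expect_error(breeding_config(offspring_per_clutch = c(0L, 0L)),
               "zero offspring")
  expect_error(breeding_config(p_wild_conceived = 1.3), "proportions")
})

test_that("wild-conceived clutches get unique dummy sires", {
  sim <- simulate_pedigree(breeding_config(seed = 5, p_wild_conceived = 1,
                                           n_seasons = 1L))
  ped <- sim$pedigree
  off <- ped[ped$id %in% sim$covariates$id, ]
  clutch_sires <- unique(off[, c("sire", "dam")])
  # every clutch sire is a dummy founder used by exactly one dam-clutch
  expect_false(anyDuplicated(clutch_sires$sire) > 0)
  expect_true(all(grepl("^DS", off$sire)))
})

test_that("gene dropping realises N(0, A sigma2_A)", {
  ped <- fixture_pedigrees()$full_and_half_sibs
  # zero additive variance -> all values exactly zero
  expect_identical(unname(drop_breeding_values(ped, 0, seed = 1)),
                   rep(0, nrow(ped)))
  # Monte-Carlo covariance structure against A from build_A
  A <- build_A(ped)
  n_rep <- 10000L
  draws <- with_seed(2024, {
    vapply(seq_len(n_rep),
           function(i) drop_breeding_values(ped, 1, seed = NULL),
           numeric(nrow(ped)))
  })
  # unrelated founder pair: |r| < 0.05 (A[s1, s2] = 0)
  expect_equal(A["s1", "s2"], 0)
  expect_lt(abs(cor(draws["s1", ], draws["s2", ])), 0.05)
  # full sibs from non-inbred unrelated parents: cov = 0.5 * sigma2_A
  expect_equal(A["o1", "o2"], 0.5)
  expect_lt(abs(cov(draws["o1", ], draws["o2", ]) - 0.5), 0.05)
  # half sibs: cov = 0.25 * sigma2_A
  expect_lt(abs(cov(draws["o1", ], draws["o3", ]) - 0.25), 0.05)
  # variances of non-founders are sigma2_A as well
  expect_lt(abs(var(draws["o1", ]) - 1), 0.05)
})

test_that("gene dropping rejects cyclic pedigrees, naming the individuals", {
  bad <- data.frame(id = c("a", "b"), sire = c("b", "a"),
                    dam = c(NA, NA), stringsAsFactors = FALSE)
  expect_error(drop_breeding_values(bad, 1), "cycle.*a.*b")
})

test_that("record simulation follows the generating model", {
  sim <- simulate_pedigree(breeding_config(seed = 11))
  # all variances zero, intercept only -> every phenotype equals the intercept
  tt <- trait_truth(beta = c(0.42, rep(0, 9)), 0, 0, 0, 0, 0)
  rec <- simulate_records(sim$pedigree, sim$covariates, list(y = tt), seed = 1)
  expect_equal(rec$y, rep(0.42, nrow(rec)), tolerance = 1e-12)
  # missing covariates are reported with record ids
  cov_bad <- sim$covariates
  cov_bad$age[c(3, 5)] <- NA
  expect_error(simulate_records(sim$pedigree, cov_bad, list(y = tt)),
               paste0(cov_bad$id[3], ".*", cov_bad$id[5]))
})

test_that("the published age slope is recovered by regression at large n", {
  big <- breeding_config(n_parental_cages = 60L,
                         clutches_per_dam_per_season = 2L, seed = 8)
  sim <- simulate_pedigree(big)
  tt <- trait_truth(beta = c(0.3085, 0, 0.0017, rep(0, 7)),
                    sigma2_A = 0, sigma2_dam = 0, sigma2_pcage = 0,
                    sigma2_ocage = 0, sigma2_R = 0.002)
  rec <- simulate_records(sim$pedigree, sim$covariates, list(b = tt), seed = 3)
  fit <- stats::lm(rec$b ~ sim$covariates$age)
  expect_equal(unname(coef(fit)[2]), 0.0017, tolerance = 0.15)
})

test_that("phenotypic variance matches the sum of the five components", {
  big <- breeding_config(n_parental_cages = 175L,
                         clutches_per_dam_per_season = 2L, seed = 21)
  sim <- simulate_pedigree(big)
  expect_gt(nrow(sim$covariates), 5000)
  tt <- trait_truth_from_h2(0.3, sigma2_P = 1, beta = c(0.5, rep(0, 9)))
  rec <- simulate_records(sim$pedigree, sim$covariates, list(y = tt), seed = 4)
  expect_equal(var(rec$y), 1, tolerance = 0.05)
})
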