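grey_swatch <- function(values) {
  # values: an H x W matrix of grey levels
  swatch_image(as.matrix(values))
}

test_that("brightness follows the printed formula exactly", {
  white <- swatch_image(array(255, dim = c(2, 2, 3)))
  expect_equal(mean_brightness(white), 1.0, tolerance = 1e-12)
  red <- array(0, dim = c(2, 2, 3)); red[, , 1] <- 255
  expect_equal(mean_brightness(swatch_image(red)), 1 / 3, tolerance = 1e-12)
  half <- grey_swatch(rbind(c(0, 255), c(255, 0)))
  expect_equal(mean_brightness(half), 0.5, tolerance = 1e-12)
  # invariant to pixel permutation
  expect_equal(mean_brightness(grey_swatch(rbind(c(255, 255), c(0, 0)))),
               mean_brightness(half), tolerance = 1e-12)
})

test_that("white balance scales channels against the standard", {
  u <- swatch_image(array(100, dim = c(2, 2, 3)))
  expect_identical(white_balance(u, c(255, 255, 255))$pixels, u$pixels)
  wb <- white_balance(u, c(200, 200, 200))
  expect_true(all(wb$pixels == 128)) # 100 * 255/200 = 127.5, rounded half-up
  expect_error(white_balance(u, c(0, 200, 200)), "zero")
})

test_that("k-means classification is pure, deterministic and near-optimal", {
  # exactly three distinct colours, k = 3 -> zero within-class variance
  vals <- matrix(rep(c(10, 120, 240), each = 4), nrow = 4)
  im <- grey_swatch(vals)
  map <- classify_colours(im, k = 3, seed = 1)
  expect_equal(map$k, 3L)
  for (cl in 1:3) {
    members <- im$pixels[, , 1][map$labels == cl]
    expect_equal(var(members), 0)
  }
  # classes are labelled bright to dark
  expect_true(all(diff(class_brightness(map)) < 0))
  # determinism under a fixed seed
  map2 <- classify_colours(im, k = 3, seed = 1)
  expect_identical(map$labels, map2$labels)
  # fewer distinct colours than k -> error
  expect_error(classify_colours(grey_swatch(matrix(7, 3, 3)), k = 2),
               "distinct colours")
  # two well-separated grey populations: misassignment < 0.1% against the
  # threshold-at-midpoint oracle
  pop <- with_seed(31, matrix(round(c(rnorm(1800, 40, 5), rnorm(1800, 220, 5))),
                              60, 60))
  pop[pop < 0] <- 0; pop[pop > 255] <- 255
  pmap <- classify_colours(grey_swatch(pop), k = 2, seed = 2)
  oracle <- ifelse(pop > 130, 1L, 2L) # label 1 = brighter class
  expect_lt(mean(pmap$labels != oracle), 0.001)
})

test_that("transition tallies match hand enumeration and brute force", {
  m <- colour_class_map(rbind(c(1, 2), c(1, 2)))
  t1 <- transition_counts(m, grid_step = 1)
  expect_equal(t1$N_LR, 2); expect_equal(t1$T_LR, 2)
  expect_equal(t1$N_UD, 2); expect_equal(t1$T_UD, 0)
  expect_equal(elongation(t1), 3.0, tolerance = 1e-12) # (3/4)/(1/4)

  stripes <- colour_class_map(rbind(c(1, 1), c(2, 2)))
  expect_equal(elongation(transition_counts(stripes)), 1 / 3, tolerance = 1e-12)

  # uniform map: no transitions in either direction
  u <- colour_class_map(matrix(1, 4, 5))
  tu <- transition_counts(u)
  expect_equal(tu$T_LR + tu$T_UD, 0)

  # transposition swaps the direction tallies
  set.seed(91)
  for (i in 1:20) {
    lab <- matrix(sample(1:3, 30, replace = TRUE), 5, 6)
    lab[1:3, 1] <- 1:3 # keep every class populated
    a <- transition_counts(colour_class_map(lab))
    b <- transition_counts(colour_class_map(t(lab)))
    expect_identical(c(a$N_LR, a$T_LR), c(b$N_UD, b$T_UD))
    expect_identical(a$tally_LR, b$tally_UD)
  }

  # tallies equal exhaustive brute force on all maps <= 12 pixels
  set.seed(17)
  for (i in 1:50) {
    h <- sample(2:4, 1); w <- sample(2:3, 1)
    lab <- matrix(sample(1:2, h * w, replace = TRUE), h, w)
    lab[1:2] <- 1:2
    for (gs in 1:2) {
      if (length(seq(1, h, by = gs)) < 2 || length(seq(1, w, by = gs)) < 2) next
      got <- transition_counts(colour_class_map(lab), grid_step = gs)
      want <- brute_force_tallies(lab, gs)
      expect_equal(got$N_LR, want$N_LR); expect_equal(got$T_LR, want$T_LR)
      expect_equal(got$N_UD, want$N_UD); expect_equal(got$T_UD, want$T_UD)
      expect_equal(unname(got$tally_LR), unname(want$tally_LR))
      expect_equal(unname(got$tally_UD), unname(want$tally_UD))
    }
  }

  expect_error(transition_counts(colour_class_map(rbind(c(1, 2), c(2, 1))),
                                 grid_step = 2), "degenerate")
})

test_that("elongation is exactly reciprocal under transposition", {
  set.seed(47)
  for (i in 1:100) {
    h <- sample(2:8, 1); w <- sample(2:8, 1)
    lab <- matrix(sample(1:3, h * w, replace = TRUE), h, w)
    lab[1:min(3, h * w)] <- seq_len(min(3, h * w))
    e1 <- elongation(transition_counts(colour_class_map(lab)))
    e2 <- elongation(transition_counts(colour_class_map(t(lab))))
    expect_equal(e1 * e2, 1, tolerance = 1e-12)
  }
})

test_that("class brightness and contrast follow their definitions", {
  m <- colour_class_map(rbind(c(1, 2), c(1, 2)),
                        centroids = rbind(c(255, 255, 255), c(0, 0, 0)))
  expect_equal(class_brightness(m), c(1, 0), tolerance = 1e-12)
  expect_equal(pattern_contrast(c(0.9, 0.2)), 0.7, tolerance = 1e-12)
  expect_equal(pattern_contrast(c(0.4, 0.4, 0.4)), 0, tolerance = 1e-12)
  expect_equal(pattern_contrast(c(1.0, 0.5, 0.0)), 1.0, tolerance = 1e-12)
  expect_error(pattern_contrast(0.5), "single colour class")

  # weighted mean of class brightness by pixel share equals the brightness
  # of the centroid-recoloured image
  p <- render_params(seed = 3, noise_sd = 3, image_height = 40L,
                     image_width = 40L)
  im <- render_swatch(p)
  map <- classify_colours(im, k = 3, seed = 4)
  shares <- as.numeric(table(factor(map$labels, 1:3))) / length(map$labels)
  recoloured <- map$centroids[map$labels, , drop = FALSE]
  expect_equal(sum(shares * class_brightness(map)),
               mean(recoloured) / 255, tolerance = 1e-12)
})

test_that("metrics are invariant to rotation, relabelling and grid step", {
  p <- render_params(seed = 29, anisotropy = 2, image_height = 100L,
                     image_width = 100L, noise_sd = 2)
  im <- render_swatch(p)
  m1 <- compute_metrics(im, k = 3, seed = 5, grid_step = 1)
  # 180 degree rotation leaves all three metrics unchanged
  rot <- swatch_image(array(im$pixels[100:1, 100:1, ], dim = dim(im$pixels)),
                      "rot")
  mr <- compute_metrics(rot, k = 3, seed = 5, grid_step = 1)
  expect_equal(mr$brightness, m1$brightness, tolerance = 1e-12)
  expect_equal(mr$elongation, m1$elongation, tolerance = 1e-6)
  expect_equal(mr$contrast, m1$contrast, tolerance = 1e-6)
  # brightness and contrast do not depend on the sampling stride;
  # elongation at stride 2 agrees within 15%
  m2 <- compute_metrics(im, k = 3, seed = 5, grid_step = 2)
  expect_equal(m2$brightness, m1$brightness, tolerance = 1e-12)
  expect_equal(m2$contrast, m1$contrast, tolerance = 1e-12)
  expect_equal(m2$elongation, m1$elongation, tolerance = 0.15)
  # elongation and contrast are invariant to relabelling of classes
  map <- classify_colours(im, k = 3, seed = 5)
  perm <- c(3L, 1L, 2L)
  relab <- colour_class_map(matrix(perm[map$labels], 100, 100),
                            centroids = map$centroids[order(perm), ])
  expect_equal(elongation(transition_counts(relab)),
               elongation(transition_counts(map)), tolerance = 1e-12)
  expect_equal(pattern_contrast(class_brightness(relab)),
               pattern_contrast(class_brightness(map)), tolerance = 1e-12)
})

test_that("scheme concordance behaves like a correlation", {
  a <- data.frame(image_id = sprintf("i%03d", 1:100),
                  brightness = seq(0.1, 0.9, length.out = 100),
                  elongation = seq(0.5, 2, length.out = 100),
                  contrast = seq(0.05, 0.8, length.out = 100))
  # identical vectors -> r = 1 for both statistics
  cc <- compare_metric_concordance(a, a)
  expect_equal(cc$pearson, rep(1, 3), tolerance = 1e-12)
  expect_equal(cc$spearman, rep(1, 3), tolerance = 1e-12)
  expect_equal(cc$n, rep(100L, 3))
  # a monotone nonlinear transform: Spearman 1, Pearson < 1
  b <- a; b$brightness <- exp(4 * a$brightness)
  cb <- compare_metric_concordance(a, b, metrics = "brightness")
  expect_equal(cb$spearman, 1, tolerance = 1e-12)
  expect_lt(cb$pearson, 1)
  # independent random vectors: |r| small
  set.seed(61)
  r <- a; r$brightness <- runif(100); r$elongation <- runif(100)
  r$contrast <- runif(100)
  a2 <- a; a2$brightness <- runif(100); a2$elongation <- runif(100)
  a2$contrast <- runif(100)
  ci <- compare_metric_concordance(a2, r)
  expect_true(all(abs(ci$pearson) < 0.25))
  # disjoint image sets -> error
  d <- a; d$image_id <- sprintf("j%03d", 1:100)
  expect_error(compare_metric_concordance(a, d), "share no image ids")
})
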