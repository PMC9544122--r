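#' Batch metric computation over a set of swatches
#'
#' Applies [compute_metrics()] to every image, skipping (with a
#' machine-readable reason) images that fail their preconditions — too few
#' distinct colours for the requested k, unreadable files, ids missing from
#' a manual k table — and reporting how many were kept and discarded.
#'
#' @param images either a named list of [swatch_image] objects or a
#'   directory containing PNG swatches.
#' @param k fixed number of colour classes applied to every image
#'   (fixed-k scheme), or `NULL` to use `k_table`.
#' @param k_table manual-k scheme: data.frame with columns `image_id`, `k`.
#' @param grid_step adjacency sampling stride.
#' @param seed master seed; each image's k-means gets its own sub-seed.
#' @return list with `metrics` (one row per usable image) and `skipped`
#'   (data.frame image_id, reason).
#' @export
run_metrics <- function(images, k = 3L, k_table = NULL, grid_step = 1L,
                        seed = 1L) {
  if (is.character(images)) {
    paths <- sort(list.files(images, pattern = "\\.png$", full.names = TRUE,
                             ignore.case = TRUE))
    ids <- sub("\\.png$", "", basename(paths), ignore.case = TRUE)
    loaders <- lapply(seq_along(paths), function(i) {
      function() read_swatch_png(paths[i], ids[i])
    })
    names(loaders) <- ids
  } else {
    stopifnot(is.list(images), length(images) > 0L)
    ids <- names(images) %||% vapply(images, function(im) im$image_id, "")
    loaders <- lapply(images, function(im) function() im)
    names(loaders) <- ids
  }
  if (length(loaders) == 0L) stop("no images to process")
  if (is.null(k) && is.null(k_table)) stop("supply either `k` or `k_table`")
  seeds <- make_subseeds(seed, length(loaders))
  rows <- list(); skipped <- list()
  for (i in seq_along(loaders)) {
    id <- names(loaders)[i]
    res <- tryCatch({
      im <- loaders[[i]]()
      ki <- if (!is.null(k_table)) {
        j <- match(id, k_table$image_id)
        if (is.na(j)) stop("image id absent from the manual k table")
        as.integer(k_table$k[j])
      } else as.integer(k)
      compute_metrics(im, k = ki, seed = seeds[i], grid_step = grid_step)
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) {
      skipped[[length(skipped) + 1L]] <-
        data.frame(image_id = id, reason = res, stringsAsFactors = FALSE)
    } else {
      rows[[length(rows) + 1L]] <- res
    }
  }
  if (length(rows) == 0L) stop("no usable images (all skipped)")
  metrics <- do.call(rbind, rows)
  rownames(metrics) <- NULL
  skipped <- if (length(skipped) > 0L) do.call(rbind, skipped)
             else data.frame(image_id = character(0), reason = character(0))
  message(sprintf("run_metrics: %d image(s) kept, %d discarded",
                  nrow(metrics), nrow(skipped)))
  list(metrics = metrics, skipped = skipped)
}

#' Fit the three colouration animal models
#'
#' Joins a metric table to covariates and a pedigree (on `image_id` = the
#' individual's id), then fits one independently seeded animal model per
#' trait and summarises each: Table-shaped coefficient summaries (posterior
#' mode, 95% HPD, pMCMC), variance-component summaries, the heritability
#' posterior, and convergence diagnostics.
#'
#' @param metrics metric table with column `image_id` and the trait columns.
#' @param covariates covariate table with column `id`.
#' @param pedigree pedigree data.frame.
#' @param traits trait columns to model.
#' @param n_iter,burnin,thin MCMC schedule applied to every trait.
#' @param seed master seed; each trait's chain gets its own sub-seed.
#' @return list of class `model_results`: per-trait list with elements
#'   `samples`, `coefficients`, `variance_summary`, `h2`, `diagnostics`,
#'   plus `meta`.
#' @export
run_models <- function(metrics, covariates, pedigree,
                       traits = c("brightness", "elongation", "contrast"),
                       n_iter = 50000L, burnin = 5000L, thin = 50L,
                       seed = 1L) {
  missing_tr <- setdiff(traits, names(metrics))
  if (length(missing_tr) > 0L) {
    stop("trait column(s) absent from the metric table: ",
         paste(missing_tr, collapse = ", "))
  }
  unmatched <- setdiff(metrics$image_id, covariates$id)
  if (length(unmatched) == nrow(metrics)) {
    stop("no metric row joins to a covariate record; offending ids: ",
         paste(head(unmatched, 10L), collapse = ", "))
  }
  if (length(unmatched) > 0L) {
    message("run_models: dropping metric rows without covariates: ",
            paste(unmatched, collapse = ", "))
  }
  joined <- merge(metrics, covariates, by.x = "image_id", by.y = "id")
  joined$id <- joined$image_id
  seeds <- make_subseeds(seed, length(traits))
  fits <- list()
  for (t in seq_along(traits)) {
    tr <- traits[t]
    design <- build_design(joined, pedigree, tr)
    spec <- model_spec(tr, n_iter = n_iter, burnin = burnin, thin = thin,
                       seed = seeds[t])
    samples <- gibbs_sample(design, spec)
    vs <- lapply(variance_component_names(), function(vn) {
      ch <- samples$variances[, vn]
      ci <- hpd_interval(ch)
      data.frame(component = vn, mode = posterior_mode(ch),
                 lower = unname(ci["lower"]), upper = unname(ci["upper"]),
                 stringsAsFactors = FALSE)
    })
    diag_h2 <- chain_diagnostics(heritability(samples)$chain)
    fits[[tr]] <- list(
      samples = samples,
      coefficients = coefficient_table(samples),
      variance_summary = do.call(rbind, vs),
      h2 = heritability(samples),
      diagnostics = list(
        sigma2_A = chain_diagnostics(samples$variances[, "sigma2_A"]),
        h2 = diag_h2
      ),
      n_records = samples$n_records
    )
  }
  structure(list(fits = fits,
                 meta = list(traits = traits, n_iter = n_iter, burnin = burnin,
                             thin = thin, seed = seed)),
            class = "model_results")
}

#' Write model results as JSON and a table-shaped CSV
#'
#' The JSON mirrors the per-trait summaries (schema version 1); the CSV has
#' one block of coefficient rows per trait in the canonical reporting order.
#'
#' @param results a `model_results` object.
#' @param json_path,csv_path output paths (`NULL` to skip either).
#' @return invisibly, the JSON-ready list.
#' @export
write_model_results <- function(results, json_path = NULL, csv_path = NULL) {
  stopifnot(inherits(results, "model_results"))
  out <- list(schema_version = "1", meta = results$meta)
  out$traits <- lapply(results$fits, function(f) {
    list(n_records = f$n_records,
         coefficients = f$coefficients,
         variance_components = f$variance_summary,
         h2 = list(mode = f$h2$mode, lower = f$h2$lower, upper = f$h2$upper),
         diagnostics = list(
           sigma2_A_lag1 = f$diagnostics$sigma2_A$lag1_autocorr,
           sigma2_A_geweke_z = f$diagnostics$sigma2_A$geweke_z,
           h2_lag1 = f$diagnostics$h2$lag1_autocorr,
           h2_geweke_z = f$diagnostics$h2$geweke_z))
  })
  if (!is.null(json_path)) {
    jsonlite::write_json(out, json_path, auto_unbox = TRUE, digits = 10,
                         pretty = TRUE)
  }
  if (!is.null(csv_path)) {
    tabs <- lapply(names(results$fits), function(tr) {
      cbind(trait = tr, results$fits[[tr]]$coefficients)
    })
    write.csv(do.call(rbind, tabs), csv_path, row.names = FALSE)
  }
  invisible(out)
}

#' Render one swatch per phenotyped individual
#'
#' The measurement layer of the synthetic world: each individual's latent
#' trait values set its rendering targets — mean brightness and class gap
#' directly (clipped to feasibility), and anisotropy as
#' `exp(slope * (elongation_latent - center))` so the latent elongation
#' scale maps monotonically onto pattern stretch.
#'
#' @param records data.frame with `id`, `brightness`, `elongation`,
#'   `contrast` latent values.
#' @param seed master seed (one sub-seed per image).
#' @param image_height,image_width,n_classes,noise_sd forwarded to
#'   [render_params()].
#' @param elong_center,elong_slope latent-to-anisotropy mapping.
#' @return named list of [swatch_image] objects, one per record.
#' @export
render_study_swatches <- function(records, seed = 1L, image_height = 60L,
                                  image_width = 40L, n_classes = 3L,
                                  noise_sd = 2, elong_center = 0.1,
                                  elong_slope = 4) {
  seeds <- make_subseeds(seed, nrow(records))
  out <- vector("list", nrow(records))
  names(out) <- records$id
  for (i in seq_len(nrow(records))) {
    mb <- min(max(records$brightness[i], 0.05), 0.95)
    gap <- min(max(records$contrast[i], 0.02), 2 * min(mb, 1 - mb))
    an <- exp(elong_slope * (records$elongation[i] - elong_center))
    p <- render_params(mean_brightness = mb, class_gap = gap, anisotropy = an,
                       n_classes = n_classes, image_height = image_height,
                       image_width = image_width, noise_sd = noise_sd,
                       seed = seeds[i])
    out[[i]] <- render_swatch(p, image_id = records$id[i])
  }
  out
}

#' Run the full synthetic study end to end
#'
#' Simulates a breeding design, latent traits and swatch images; measures
#' the three metrics from the images; fits the three animal models; and
#' writes `metrics.csv`, `results.json`, `results.csv`, `pedigree.csv`,
#' `covariates.csv` and `truth.json` under `out_dir`. Fully deterministic
#' under a fixed master seed (the seed fans out to the simulate / render /
#' metrics / model stages via [make_subseeds()]).
#'
#' @param out_dir output directory (created if needed).
#' @param seed master seed.
#' @param config a [breeding_config()] (its own seed field is ignored; the
#'   master seed governs).
#' @param truth named list of `trait_truth` objects.
#' @param k number of colour classes used for measurement.
#' @param grid_step adjacency stride.
#' @param n_iter,burnin,thin MCMC schedule.
#' @param image_height,image_width rendered swatch size.
#' @param write_images write one PNG per individual under
#'   `file.path(out_dir, "swatches")`.
#' @return invisibly, a list with the simulated tables, metric table and
#'   `model_results`.
#' @export
run_all <- function(out_dir, seed = 1L, config = breeding_config(),
                    truth = default_truth(), k = 3L, grid_step = 1L,
                    n_iter = 50000L, burnin = 5000L, thin = 50L,
                    image_height = 60L, image_width = 40L,
                    write_images = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- make_subseeds(seed, 4L)
  config$seed <- seeds[1]
  sim <- simulate_pedigree(config)
  records <- simulate_records(sim$pedigree, sim$covariates, truth,
                              seed = seeds[1])
  images <- render_study_swatches(records, seed = seeds[2],
                                  image_height = image_height,
                                  image_width = image_width)
  if (write_images) {
    img_dir <- file.path(out_dir, "swatches")
    dir.create(img_dir, showWarnings = FALSE)
    for (id in names(images)) {
      write_swatch_png(images[[id]], file.path(img_dir, paste0(id, ".png")))
    }
  }
  met <- run_metrics(images, k = k, grid_step = grid_step, seed = seeds[3])
  results <- run_models(met$metrics, sim$covariates, sim$pedigree,
                        n_iter = n_iter, burnin = burnin, thin = thin,
                        seed = seeds[4])
  write.csv(sim$pedigree, file.path(out_dir, "pedigree.csv"), row.names = FALSE)
  write.csv(sim$covariates, file.path(out_dir, "covariates.csv"),
            row.names = FALSE)
  write.csv(met$metrics, file.path(out_dir, "metrics.csv"), row.names = FALSE)
  truth_json <- lapply(truth, function(tt) {
    list(beta = as.list(tt$beta), sigma2_A = tt$sigma2_A,
         sigma2_dam = tt$sigma2_dam, sigma2_pcage = tt$sigma2_pcage,
         sigma2_ocage = tt$sigma2_ocage, sigma2_R = tt$sigma2_R,
         h2_true = tt$h2_true)
  })
  jsonlite::write_json(truth_json, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  write_model_results(results, json_path = file.path(out_dir, "results.json"),
                      csv_path = file.path(out_dir, "results.csv"))
  invisible(list(pedigree = sim$pedigree, covariates = sim$covariates,
                 records = records, metrics = met$metrics, results = results))
}

#' Heritability parameter-recovery benchmark
#'
#' For each true heritability on a grid and each replicate: simulate a study
#' (pedigree, covariates, latent records — the image measurement layer is
#' optional and off by default), fit the animal model, and record truth
#' against estimate. Summaries give bias, RMSE and 95% HPD coverage per
#' truth point.
#'
#' @param h2_grid true heritability values.
#' @param n_replicates replicates per truth point.
#' @param config a [breeding_config()].
#' @param sigma2_P total phenotypic variance of the simulated trait.
#' @param n_iter,burnin,thin MCMC schedule per fit.
#' @param seed master seed.
#' @param with_images if TRUE, traits are measured from rendered swatches
#'   instead of taken as the latent records.
#' @return list with `results` (one row per fit: h2_true, replicate, mode,
#'   lower, upper, covered) and `summary` (per truth point: mean mode, bias,
#'   RMSE, coverage).
#' @export
run_recovery <- function(h2_grid = c(0, 0.2, 0.5), n_replicates = 5L,
                         config = breeding_config(), sigma2_P = 0.0036,
                         n_iter = 20000L, burnin = 2000L, thin = 20L,
                         seed = 1L, with_images = FALSE) {
  grid <- expand.grid(h2_true = h2_grid, replicate = seq_len(n_replicates))
  seeds <- make_subseeds(seed, nrow(grid))
  rows <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    h2t <- grid$h2_true[g]
    sub <- make_subseeds(seeds[g], 4L)
    cfg <- config; cfg$seed <- sub[1]
    sim <- simulate_pedigree(cfg)
    truth <- list(brightness = trait_truth_from_h2(h2t, sigma2_P = sigma2_P,
                                                   beta = c(0.3, rep(0, 9))))
    rec <- simulate_records(sim$pedigree, sim$covariates, truth, seed = sub[2])
    if (with_images) {
      rec$elongation <- 0.1; rec$contrast <- 0.4
      images <- render_study_swatches(rec, seed = sub[3])
      met <- run_metrics(images, k = 3L, seed = sub[3])
      rec <- merge(data.frame(id = met$metrics$image_id,
                              brightness = met$metrics$brightness),
                   rec[, "id", drop = FALSE], by = "id")
    }
    joined <- merge(rec, sim$covariates, by = "id")
    design <- build_design(joined, sim$pedigree, "brightness")
    spec <- model_spec("brightness", n_iter = n_iter, burnin = burnin,
                       thin = thin, seed = sub[4])
    h2 <- heritability(gibbs_sample(design, spec))
    rows[[g]] <- data.frame(h2_true = h2t, replicate = grid$replicate[g],
                            mode = h2$mode, lower = h2$lower,
                            upper = h2$upper,
                            covered = h2$lower <= h2t & h2t <= h2$upper)
  }
  results <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(split(results, results$h2_true), function(d) {
    data.frame(h2_true = d$h2_true[1], n = nrow(d),
               mean_mode = mean(d$mode), bias = mean(d$mode - d$h2_true),
               rmse = sqrt(mean((d$mode - d$h2_true)^2)),
               coverage = mean(d$covered))
  }))
  rownames(summary) <- NULL
  list(results = results, summary = summary)
}
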