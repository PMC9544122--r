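#' Compute the three colouration metrics for one swatch
#'
#' Composition of the metric pipeline for a single image: optional white
#' balance, mean brightness over all pixels, k-means colour classification,
#' adjacency tallies, elongation and contrast.
#'
#' @param image a [swatch_image].
#' @param k number of colour classes for this image.
#' @param seed RNG seed for the k-means restarts.
#' @param grid_step adjacency sampling stride (default 1 = every pixel).
#' @param standard_rgb optional white-standard RGB; when supplied the image
#'   is white-balanced first.
#' @return one-row data.frame with columns `image_id`, `k_used`,
#'   `brightness`, `elongation`, `t_LR_density`, `t_UD_density`, `contrast`.
#' @export
compute_metrics <- function(image, k, seed = 1L, grid_step = 1L,
                            standard_rgb = NULL) {
  stopifnot(inherits(image, "swatch_image"))
  if (!is.null(standard_rgb)) image <- white_balance(image, standard_rgb)
  map <- classify_colours(image, k = k, seed = seed)
  tal <- transition_counts(map, grid_step = grid_step)
  dens <- transition_densities(tal)
  data.frame(
    image_id = image$image_id,
    k_used = as.integer(k),
    brightness = mean_brightness(image),
    elongation = elongation(tal),
    t_LR_density = unname(dens["t_LR_density"]),
    t_UD_density = unname(dens["t_UD_density"]),
    contrast = pattern_contrast(class_brightness(map)),
    stringsAsFactors = FALSE
  )
}

#' Concordance of metrics between two k-assignment schemes
#'
#' The number of colour classes k can be assigned per image by a human
#' observer or fixed at one value for all images. This compares the metric
#' vectors produced by two such schemes on the same images: Pearson and
#' Spearman correlations per metric, with the number of paired images.
#'
#' @param metrics_a,metrics_b metric tables from [compute_metrics()] /
#'   [run_metrics()] under the two schemes; matched on `image_id`.
#' @param metrics which metric columns to compare.
#' @return data.frame with columns `metric`, `pearson`, `spearman`, `n`.
#' @export
compare_metric_concordance <- function(metrics_a, metrics_b,
                                       metrics = c("brightness", "elongation",
                                                   "contrast")) {
  ids <- intersect(metrics_a$image_id, metrics_b$image_id)
  if (length(ids) == 0L) stop("the two schemes share no image ids")
  if (length(ids) < 3L) stop("need at least 3 paired images")
  a <- metrics_a[match(ids, metrics_a$image_id), , drop = FALSE]
  b <- metrics_b[match(ids, metrics_b$image_id), , drop = FALSE]
  out <- lapply(metrics, function(m) {
    data.frame(metric = m,
               pearson = cor(a[[m]], b[[m]], method = "pearson"),
               spearman = cor(a[[m]], b[[m]], method = "spearman"),
               n = length(ids), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
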