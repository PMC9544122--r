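#' Assign swatch pixels to colour classes by k-means
#'
#' Pixels are clustered on their (R, G, B) triples with k-means. The run is
#' restarted `nstart` times from centroids seeded at distinct observed
#' colours and the solution with the lowest within-cluster sum of squares is
#' kept (ties broken by the earliest restart). Classes are then relabelled in
#' strictly decreasing centroid brightness, so label 1 is always the
#' brightest class regardless of k-means internals.
#'
#' @param image a [swatch_image].
#' @param k number of colour classes (the analysis uses 2-5; any k >= 2 is
#'   accepted).
#' @param seed RNG seed controlling restart initialisation; a fixed seed
#'   gives an identical class map on repeated runs.
#' @param nstart number of restarts.
#' @return an object of class `colour_class_map`: list with `labels`
#'   (H x W integer matrix in 1..k), `k`, `centroids` (k x 3 matrix of mean
#'   RGB per class, rows ordered by decreasing brightness) and `image_id`.
#' @export
classify_colours <- function(image, k, seed = 1L, nstart = 10L) {
  stopifnot(inherits(image, "swatch_image"))
  k <- as.integer(k)
  if (k < 2L) stop("`k` must be at least 2")
  d <- dim(image$pixels)
  pix <- matrix(as.numeric(image$pixels), d[1] * d[2], 3L)
  ucol <- unique(pix)
  if (nrow(ucol) < k) {
    stop(sprintf("image '%s' has %d distinct colours, fewer than k = %d",
                 image$image_id, nrow(ucol), k))
  }
  fit <- with_seed(seed, {
    best <- NULL
    for (r in seq_len(nstart)) {
      centers <- ucol[sample.int(nrow(ucol), k), , drop = FALSE]
      km <- suppressWarnings(
        kmeans(pix, centers = centers, iter.max = 200L)
      )
      if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
    }
    best
  })
  # relabel in decreasing class brightness; ties broken by original index
  bright <- rowMeans(fit$centers) / 255
  ord <- order(bright, decreasing = TRUE)
  relab <- match(fit$cluster, ord)
  structure(list(
    labels = matrix(as.integer(relab), d[1], d[2]),
    k = k,
    centroids = unname(fit$centers[ord, , drop = FALSE]),
    image_id = image$image_id
  ), class = "colour_class_map")
}

#' Construct a colour-class map directly from labels
#'
#' Used for tests and for label maps produced outside k-means. Centroids
#' default to greys graded from bright (label 1) to dark (label k).
#'
#' @param labels H x W integer matrix with values in 1..k.
#' @param centroids optional k x 3 matrix of class colours.
#' @param image_id identifier.
#' @return a `colour_class_map`.
#' @export
colour_class_map <- function(labels, centroids = NULL, image_id = "map") {
  labels <- as.matrix(labels)
  k <- max(labels)
  if (!all(labels %in% seq_len(k))) stop("labels must be integers in 1..k")
  if (!all(seq_len(k) %in% labels)) stop("every class in 1..k must be non-empty")
  if (is.null(centroids)) {
    g <- round(seq(255, 0, length.out = k))
    centroids <- cbind(g, g, g)
  }
  centroids <- unname(as.matrix(centroids))
  if (nrow(centroids) != k) stop("need one centroid per class")
  structure(list(labels = matrix(as.integer(labels), nrow(labels), ncol(labels)),
                 k = as.integer(k), centroids = centroids,
                 image_id = as.character(image_id)),
            class = "colour_class_map")
}

#' Per-class brightness of a colour-class map
#'
#' Brightness of each class centroid via the same formula as
#' [mean_brightness()], returned in class-label order (hence decreasing,
#' since classes are labelled bright to dark).
#'
#' @param map a `colour_class_map`.
#' @return numeric vector of length k.
#' @export
class_brightness <- function(map) {
  stopifnot(inherits(map, "colour_class_map"))
  as.numeric(rowMeans(map$centroids) / 255)
}

#' Pattern contrast
#'
#' Brightness of the brightest colour class minus brightness of the darkest;
#' dimensionless, in `[0, 1]`.
#'
#' @param class_brightness_values per-class brightness values (length >= 2),
#'   e.g. from [class_brightness()].
#' @return a single numeric contrast.
#' @export
pattern_contrast <- function(class_brightness_values) {
  v <- as.numeric(class_brightness_values)
  if (length(v) < 2L) stop("contrast is undefined for a single colour class")
  max(v) - min(v)
}
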