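#' Rendering parameters for synthetic swatches
#'
#' Maps latent appearance targets onto a synthetic dorsal pattern: an
#' anisotropic Gaussian random field is thresholded at equal quantiles into
#' `n_classes` grey colour classes whose brightnesses are spaced so that the
#' brightest-minus-darkest class brightness equals `class_gap` and the
#' pixel-mean brightness equals `mean_brightness`.
#'
#' @param mean_brightness target swatch mean brightness in `[0, 1]`.
#' @param class_gap target contrast (brightest minus darkest class) in
#'   `[0, 1]`; `mean_brightness ± class_gap/2` must stay within `[0, 1]`.
#' @param anisotropy ratio of longitudinal to transverse correlation length
#'   (> 0). 1 is isotropic; larger values elongate pattern elements along
#'   the body axis (down columns), so measured elongation increases.
#' @param n_classes number of colour classes (2-5).
#' @param image_height,image_width swatch size in pixels.
#' @param noise_sd additive per-channel Gaussian noise, in 0-255 channel
#'   units.
#' @param base_scale geometric-mean correlation scale in pixels; the
#'   smoothing SDs are `base_scale * sqrt(anisotropy)` longitudinally and
#'   `base_scale / sqrt(anisotropy)` transversely.
#' @param seed RNG seed.
#' @return a validated list of class `render_params`.
#' @export
render_params <- function(mean_brightness = 0.5, class_gap = 0.4,
                          anisotropy = 1, n_classes = 3L,
                          image_height = 120L, image_width = 80L,
                          noise_sd = 2, base_scale = 4, seed = NULL) {
  p <- list(mean_brightness = mean_brightness, class_gap = class_gap,
            anisotropy = anisotropy, n_classes = as.integer(n_classes),
            image_height = as.integer(image_height),
            image_width = as.integer(image_width),
            noise_sd = noise_sd, base_scale = base_scale, seed = seed)
  if (p$mean_brightness < 0 || p$mean_brightness > 1) {
    stop("`mean_brightness` must lie in [0, 1]")
  }
  if (p$class_gap < 0 || p$class_gap > 1) stop("`class_gap` must lie in [0, 1]")
  if (p$mean_brightness - p$class_gap / 2 < -1e-12 ||
      p$mean_brightness + p$class_gap / 2 > 1 + 1e-12) {
    stop("infeasible brightness/gap combination: mean_brightness +/- class_gap/2 ",
         "must stay within [0, 1]")
  }
  if (!is.numeric(p$anisotropy) || p$anisotropy <= 0) {
    stop("`anisotropy` must be > 0")
  }
  if (p$n_classes < 2L || p$n_classes > 5L) stop("`n_classes` must be 2-5")
  if (p$image_height < 2L || p$image_width < 2L) stop("image must be >= 2 x 2")
  if (p$noise_sd < 0) stop("`noise_sd` must be >= 0")
  structure(p, class = "render_params")
}

# Circular (periodic) Gaussian smoothing along matrix columns with given SD.
smooth_columns <- function(m, sd) {
  if (sd <= 0) return(m)
  r <- max(1L, ceiling(3 * sd))
  kern <- exp(-0.5 * ((-r:r) / sd)^2)
  kern <- kern / sum(kern)
  apply(m, 2, function(col) {
    as.numeric(stats::filter(col, kern, circular = TRUE))
  })
}

#' Render a synthetic swatch image
#'
#' Generates a Gaussian white-noise field, smooths it with separable
#' Gaussian kernels (longitudinal SD `base_scale * sqrt(anisotropy)` down
#' columns, transverse SD `base_scale / sqrt(anisotropy)` across rows),
#' thresholds at equal quantiles into `n_classes` classes, colours each
#' class with a grey whose brightness is evenly spaced across `class_gap`
#' centred on `mean_brightness`, then adds independent per-channel Gaussian
#' noise and clips to `[0, 255]`.
#'
#' @param params a [render_params()].
#' @param image_id identifier for the produced [swatch_image].
#' @return a [swatch_image] with attribute `"truth"` (a list with the class
#'   grey levels, class brightness values and the generating parameters).
#' @export
render_swatch <- function(params = render_params(), image_id = "synthetic") {
  stopifnot(inherits(params, "render_params"))
  H <- params$image_height; W <- params$image_width
  k <- params$n_classes
  with_seed(params$seed, {
    field <- matrix(rnorm(H * W), H, W)
    sd_long <- params$base_scale * sqrt(params$anisotropy)
    sd_trans <- params$base_scale / sqrt(params$anisotropy)
    field <- smooth_columns(field, sd_long)            # along body axis
    field <- t(smooth_columns(t(field), sd_trans))     # across the body
    # equal-share classes; the highest field values become class 1 (brightest)
    breaks <- quantile(field, probs = seq_len(k - 1L) / k, names = FALSE)
    lab <- k - findInterval(field, breaks) # k..1 -> label 1 = top quantile
    bright <- params$mean_brightness +
      params$class_gap * (0.5 - (seq_len(k) - 1L) / (k - 1L))
    grey <- round(255 * bright)
    base <- matrix(grey[lab], H, W)
    px <- array(rep(base, 3L), dim = c(H, W, 3L))
    if (params$noise_sd > 0) {
      px <- px + array(rnorm(length(px), sd = params$noise_sd), dim = dim(px))
    }
    px <- array(pmin(255, pmax(0, round(px))), dim = c(H, W, 3L))
    out <- swatch_image(px, image_id)
    attr(out, "truth") <- list(class_grey = grey, class_brightness = bright,
                               params = params)
    out
  })
}
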