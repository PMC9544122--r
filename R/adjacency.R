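#' Adjacency transition tallies of a colour-class map
#'
#' The class-label grid is surveyed at a given grid density (`grid_step`
#' pixels between sampled rows/columns; 1 = every pixel). For every pair of
#' adjacent sampled pixels the ordered pair of class labels is tallied,
#' separately for the two directions:
#'
#' * left/right (`LR`): transversely adjacent pairs, i.e. neighbours within a
#'   row (across the body);
#' * up/down (`UD`): longitudinally adjacent pairs, i.e. neighbours within a
#'   column (along the body axis, head to tail).
#'
#' A *transition* is a pair whose labels differ.
#'
#' @param map a `colour_class_map`.
#' @param grid_step sampling stride in pixels (>= 1).
#' @return an object of class `transition_tallies`: counts `N_LR`, `T_LR`,
#'   `N_UD`, `T_UD`, the two k x k ordered tally matrices `tally_LR`,
#'   `tally_UD`, and `grid_step`.
#' @export
transition_counts <- function(map, grid_step = 1L) {
  stopifnot(inherits(map, "colour_class_map"))
  grid_step <- as.integer(grid_step)
  if (grid_step < 1L) stop("`grid_step` must be >= 1")
  lab <- map$labels
  rows <- seq(1L, nrow(lab), by = grid_step)
  cols <- seq(1L, ncol(lab), by = grid_step)
  if (length(rows) < 2L || length(cols) < 2L) {
    stop("sampled grid is degenerate: needs at least 2 rows and 2 columns")
  }
  g <- lab[rows, cols, drop = FALSE]
  k <- map$k
  tally <- function(a, b) {
    # ordered (first, second) label pairs as a k x k count matrix
    m <- matrix(0L, k, k)
    t <- table(factor(a, levels = seq_len(k)), factor(b, levels = seq_len(k)))
    m[seq_len(k), seq_len(k)] <- as.integer(t)
    m
  }
  # left/right: neighbours within a row (adjacent sampled columns)
  tally_LR <- tally(g[, -ncol(g)], g[, -1L])
  # up/down: neighbours within a column (adjacent sampled rows)
  tally_UD <- tally(g[-nrow(g), ], g[-1L, ])
  off <- function(m) sum(m) - sum(diag(m))
  structure(list(
    N_LR = sum(tally_LR), T_LR = off(tally_LR),
    N_UD = sum(tally_UD), T_UD = off(tally_UD),
    tally_LR = tally_LR, tally_UD = tally_UD,
    grid_step = grid_step
  ), class = "transition_tallies")
}

#' Pattern elongation from transition tallies
#'
#' Elongation compares transition densities in the two directions: it is
#' higher when up/down (longitudinal) transitions are rarer than left/right
#' (transverse) ones, i.e. when pattern elements fuse into lengthwise
#' stripes. The statistic is the add-one-smoothed density ratio
#'
#' \deqn{E = \frac{(T_{LR} + 1)/(N_{LR} + 2)}{(T_{UD} + 1)/(N_{UD} + 2)}}
#'
#' which is finite for every map, strictly increasing in transverse
#' transitions, strictly decreasing in longitudinal ones, and exactly
#' reciprocal under transposition of the label grid.
#'
#' @param tallies a `transition_tallies` object.
#' @return a single positive numeric.
#' @export
elongation <- function(tallies) {
  stopifnot(inherits(tallies, "transition_tallies"))
  dens_LR <- (tallies$T_LR + 1) / (tallies$N_LR + 2)
  dens_UD <- (tallies$T_UD + 1) / (tallies$N_UD + 2)
  dens_LR / dens_UD
}

#' Raw per-direction transition densities
#'
#' Unsmoothed `T/N` in each direction; emitted alongside elongation so that
#' alternative elongation definitions can be derived downstream.
#'
#' @param tallies a `transition_tallies` object.
#' @return named numeric vector `c(t_LR_density, t_UD_density)`.
#' @export
transition_densities <- function(tallies) {
  stopifnot(inherits(tallies, "transition_tallies"))
  c(t_LR_density = tallies$T_LR / tallies$N_LR,
    t_UD_density = tallies$T_UD / tallies$N_UD)
}
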