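#' Breeding-design configuration
#'
#' Describes the captive breeding design that the simulator emulates: adults
#' housed in breeding cages of several females to one male, two consecutive
#' breeding seasons, clutches split across two offspring thermal treatments
#' (long-bask vs short-bask), hatchlings reared in small group cages, a
#' fraction of first-season clutches conceived in the wild (each assigned a
#' unique dummy sire), and occasional re-pairing of a cage with a different
#' male between seasons.
#'
#' Defaults are tuned so that a simulated study has totals near the design
#' the package targets: roughly 180 phenotyped offspring from ~39 dams in
#' ~26 parental cage-seasons and ~40 offspring cages over 2 seasons.
#'
#' @param n_parental_cages number of physical breeding cages.
#' @param females_per_cage females housed with the single male of each cage.
#' @param n_seasons number of breeding seasons (years).
#' @param clutches_per_dam_per_season clutches contributing phenotyped
#'   offspring per dam per season.
#' @param offspring_per_clutch integer range (length 2) of phenotyped
#'   offspring per clutch.
#' @param p_wild_conceived probability that a first-season clutch was
#'   conceived before capture; such clutches get a unique dummy sire.
#' @param p_dam_repaired probability that a cage's male is replaced between
#'   seasons, so its dams' later clutches have a different sire.
#' @param offspring_cage_capacity integer range (length 2) of hatchlings per
#'   rearing cage.
#' @param seed RNG seed.
#' @return a validated list of class `breeding_config`.
#' @export
breeding_config <- function(n_parental_cages = 13L,
                            females_per_cage = 3L,
                            n_seasons = 2L,
                            clutches_per_dam_per_season = 1L,
                            offspring_per_clutch = c(2L, 3L),
                            p_wild_conceived = 0.25,
                            p_dam_repaired = 0.06,
                            offspring_cage_capacity = c(1L, 8L),
                            seed = NULL) {
  cfg <- list(n_parental_cages = as.integer(n_parental_cages),
              females_per_cage = as.integer(females_per_cage),
              n_seasons = as.integer(n_seasons),
              clutches_per_dam_per_season = as.integer(clutches_per_dam_per_season),
              offspring_per_clutch = as.integer(offspring_per_clutch),
              p_wild_conceived = p_wild_conceived,
              p_dam_repaired = p_dam_repaired,
              offspring_cage_capacity = as.integer(offspring_cage_capacity),
              seed = seed)
  counts <- c(cfg$n_parental_cages, cfg$females_per_cage, cfg$n_seasons,
              cfg$clutches_per_dam_per_season)
  if (any(counts < 1L)) stop("all design counts must be >= 1")
  if (length(cfg$offspring_per_clutch) != 2L ||
      any(cfg$offspring_per_clutch < 0L) ||
      diff(cfg$offspring_per_clutch) < 0L) {
    stop("`offspring_per_clutch` must be a non-decreasing pair of counts")
  }
  if (length(cfg$offspring_cage_capacity) != 2L ||
      any(cfg$offspring_cage_capacity < 1L) ||
      diff(cfg$offspring_cage_capacity) < 0L) {
    stop("`offspring_cage_capacity` must be a non-decreasing pair of counts >= 1")
  }
  for (p in c(cfg$p_wild_conceived, cfg$p_dam_repaired)) {
    if (!is.numeric(p) || p < 0 || p > 1) stop("proportions must lie in [0, 1]")
  }
  if (max(cfg$offspring_per_clutch) == 0L) {
    stop("configuration yields zero offspring (offspring_per_clutch is 0)")
  }
  structure(cfg, class = "breeding_config")
}

#' Simulate a pedigree and covariate table from a breeding design
#'
#' Wild-caught adults (all cage females and males) and dummy sires are
#' founders with unknown parents. Each dam produces clutches each season;
#' each clutch has one sire (the cage male of that season, or a unique dummy
#' founder for wild-conceived first-season clutches) and is split across the
#' two offspring thermal treatments (split-clutch design). Offspring carry
#' sex (independent 50/50), year, age at photograph (uniform integer on
#' 6..62 days), parental treatment (the cage's treatment that season),
#' offspring treatment, dam id, parental cage (cage x season level) and
#' offspring rearing cage.
#'
#' @param config a [breeding_config()].
#' @return list with `pedigree` (data.frame id, sire, dam; NA = unknown) and
#'   `covariates` (one row per offspring).
#' @export
simulate_pedigree <- function(config = breeding_config()) {
  stopifnot(inherits(config, "breeding_config"))
  with_seed(config$seed, simulate_pedigree_impl(config))
}

# uniform integer draw on [lo, hi] (safe when lo == hi)
sample_range <- function(lo, hi) {
  if (lo >= hi) return(lo)
  lo + sample.int(hi - lo + 1L, 1L) - 1L
}

simulate_pedigree_impl <- function(cfg) {
  nc <- cfg$n_parental_cages
  nf <- cfg$females_per_cage
  treatments <- c("long", "short")

  dam_ids <- sprintf("F%02d_%d", rep(seq_len(nc), each = nf), rep(seq_len(nf), nc))
  dam_cage <- rep(seq_len(nc), each = nf)

  # one male per cage per season; re-paired cages get a new founder male
  male_ids <- matrix(NA_character_, nc, cfg$n_seasons)
  male_ids[, 1] <- sprintf("M%02d_a", seq_len(nc))
  if (cfg$n_seasons > 1L) {
    for (t in 2:cfg$n_seasons) {
      repaired <- runif(nc) < cfg$p_dam_repaired
      male_ids[, t] <- ifelse(repaired, sprintf("M%02d_%s", seq_len(nc), letters[t]),
                              male_ids[, t - 1])
    }
  }

  # cage basking treatment reassigned each season
  cage_treatment <- matrix(sample(treatments, nc * cfg$n_seasons, replace = TRUE),
                           nc, cfg$n_seasons)

  off <- list()
  dummy_sires <- character(0)
  n_off <- 0L
  clutch_id <- 0L
  for (t in seq_len(cfg$n_seasons)) {
    for (f in seq_along(dam_ids)) {
      cage <- dam_cage[f]
      for (cl in seq_len(cfg$clutches_per_dam_per_season)) {
        clutch_id <- clutch_id + 1L
        size <- sample_range(cfg$offspring_per_clutch[1], cfg$offspring_per_clutch[2])
        if (size == 0L) next
        wild <- t == 1L && runif(1) < cfg$p_wild_conceived
        sire <- if (wild) {
          ds <- sprintf("DS%03d", length(dummy_sires) + 1L)
          dummy_sires <- c(dummy_sires, ds)
          ds
        } else male_ids[cage, t]
        # split-clutch: half long, half short, random extra for odd sizes
        treat <- sample(rep(treatments, length.out = size))
        for (j in seq_len(size)) {
          n_off <- n_off + 1L
          off[[n_off]] <- data.frame(
            id = sprintf("O%04d", n_off),
            sire = sire, dam = dam_ids[f],
            sex = NA_character_,
            year = as.character(2014L + t),
            age = sample(6:62, 1L),
            parental_treatment = cage_treatment[cage, t],
            offspring_treatment = treat[j],
            parental_cage = sprintf("PC%02d_S%d", cage, t),
            offspring_cage = NA_character_,
            season = t,
            stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  if (n_off == 0L) stop("configuration yields zero offspring")
  off <- do.call(rbind, off)
  off$sex <- sample(c("female", "male"), n_off, replace = TRUE)

  # rearing cages: group hatchlings of the same season and treatment into
  # cages with sizes drawn from the capacity range
  cage_counter <- 0L
  for (t in seq_len(cfg$n_seasons)) {
    for (tr in treatments) {
      idx <- which(off$season == t & off$offspring_treatment == tr)
      if (length(idx) == 0L) next
      idx <- sample(idx)
      # typical group sizes sit mid-range; capacity bounds still apply
      lo <- min(cfg$offspring_cage_capacity[2],
                cfg$offspring_cage_capacity[1] + 2L)
      hi <- max(lo, cfg$offspring_cage_capacity[2] - 1L)
      while (length(idx) > 0L) {
        cage_counter <- cage_counter + 1L
        size <- sample_range(lo, hi)
        take <- head(idx, size)
        off$offspring_cage[take] <- sprintf("OC%03d", cage_counter)
        idx <- idx[-seq_along(take)]
      }
    }
  }
  off$season <- NULL

  founders <- unique(c(dam_ids, as.vector(male_ids), dummy_sires))
  pedigree <- rbind(
    data.frame(id = founders, sire = NA_character_, dam = NA_character_,
               stringsAsFactors = FALSE),
    off[, c("id", "sire", "dam")]
  )
  rownames(pedigree) <- NULL
  covariates <- off[, c("id", "sex", "year", "age", "parental_treatment",
                        "offspring_treatment", "dam", "parental_cage",
                        "offspring_cage")]
  rownames(covariates) <- NULL
  list(pedigree = pedigree, covariates = covariates)
}
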