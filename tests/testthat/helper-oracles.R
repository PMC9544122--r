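# Independent oracles used across tests. These deliberately re-derive
# quantities from first principles (brute force / recursive definitions)
# rather than calling the package's own implementations.

# Exhaustive enumeration of adjacent sampled pixel pairs and their ordered
# label tallies.
brute_force_tallies <- function(labels, grid_step = 1L) {
  rows <- seq(1L, nrow(labels), by = grid_step)
  cols <- seq(1L, ncol(labels), by = grid_step)
  k <- max(labels)
  t_lr <- matrix(0L, k, k)
  t_ud <- matrix(0L, k, k)
  for (ri in seq_along(rows)) {
    for (ci in seq_along(cols)) {
      a <- labels[rows[ri], cols[ci]]
      if (ci < length(cols)) { # right neighbour in the sampled grid
        b <- labels[rows[ri], cols[ci + 1L]]
        t_lr[a, b] <- t_lr[a, b] + 1L
      }
      if (ri < length(rows)) { # down neighbour
        b <- labels[rows[ri + 1L], cols[ci]]
        t_ud[a, b] <- t_ud[a, b] + 1L
      }
    }
  }
  off <- function(m) sum(m) - sum(diag(m))
  list(N_LR = sum(t_lr), T_LR = off(t_lr), N_UD = sum(t_ud), T_UD = off(t_ud),
       tally_LR = t_lr, tally_UD = t_ud)
}

# Additive relationship by the plain recursive definition (A = 2 * kinship),
# no memoisation; fine for pedigrees of a handful of individuals.
recursive_A <- function(ped) {
  ids <- as.character(ped$id)
  sire <- as.character(ped$sire)
  dam <- as.character(ped$dam)
  parent <- function(x) if (is.na(x) || x == "") NA_character_ else x
  pos <- function(id) match(id, ids)
  kin <- function(i, j) {
    if (is.na(i) || is.na(j)) return(0)
    if (i == j) {
      return(0.5 * (1 + kin(parent(sire[pos(i)]), parent(dam[pos(i)]))))
    }
    # recurse through whichever appears later in the table (parents precede
    # offspring in all fixtures)
    if (pos(i) < pos(j)) { a <- j; b <- i } else { a <- i; b <- j }
    0.5 * (kin(parent(sire[pos(a)]), b) + kin(parent(dam[pos(a)]), b))
  }
  A <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  for (i in ids) for (j in ids) A[i, j] <- 2 * kin(i, j)
  A
}

# Fixture pedigrees (<= 8 members, parents listed before offspring).
fixture_pedigrees <- function() {
  list(
    parent_offspring = data.frame(
      id = c("s", "d", "o"), sire = c(NA, NA, "s"), dam = c(NA, NA, "d"),
      stringsAsFactors = FALSE),
    full_and_half_sibs = data.frame(
      id = c("s1", "s2", "d1", "o1", "o2", "o3"),
      sire = c(NA, NA, NA, "s1", "s1", "s2"),
      dam = c(NA, NA, NA, "d1", "d1", "d1"),
      stringsAsFactors = FALSE),
    full_sib_mating = data.frame(
      id = c("s", "d", "a", "b", "x"),
      sire = c(NA, NA, "s", "s", "a"),
      dam = c(NA, NA, "d", "d", "b"),
      stringsAsFactors = FALSE),
    three_generations = data.frame(
      id = c("g1", "g2", "g3", "p1", "p2", "o1", "o2", "o3"),
      sire = c(NA, NA, NA, "g1", "g1", "p1", "p1", "p2"),
      dam = c(NA, NA, NA, "g2", "g3", "p2", "g3", "g2"),
      stringsAsFactors = FALSE)
  )
}

# A small simulated study used by several model-level tests.
quick_study <- function(seed = 101L, h2 = 0.2, config = NULL) {
  cfg <- config
  if (is.null(cfg)) cfg <- breeding_config(seed = seed) else cfg$seed <- seed
  sim <- simulate_pedigree(cfg)
  truth <- list(brightness = trait_truth_from_h2(h2, sigma2_P = 0.0036))
  rec <- simulate_records(sim$pedigree, sim$covariates, truth, seed = seed + 1L)
  joined <- merge(rec, sim$covariates, by = "id")
  list(sim = sim, records = rec, joined = joined, h2_true = h2)
}
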