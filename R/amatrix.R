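#' Pedigree tables
#'
#' A pedigree is a data.frame with columns `id`, `sire`, `dam` (character;
#' `NA` or `""` = unknown parent, the founder convention). Every referenced
#' parent must either appear as an `id` or be unknown, ids must be unique,
#' and no individual may be its own ancestor.
#'
#' @param ped a data.frame with columns `id`, `sire`, `dam`.
#' @return the validated pedigree, parents before offspring (topologically
#'   sorted), with an attribute `"order"` giving the permutation applied.
#' @export
validate_pedigree <- function(ped) {
  stopifnot(is.data.frame(ped), all(c("id", "sire", "dam") %in% names(ped)))
  ped$id <- as.character(ped$id)
  ped$sire <- as.character(ped$sire)
  ped$dam <- as.character(ped$dam)
  ped$sire[!is.na(ped$sire) & ped$sire == ""] <- NA_character_
  ped$dam[!is.na(ped$dam) & ped$dam == ""] <- NA_character_
  if (anyDuplicated(ped$id)) {
    stop("duplicated pedigree ids: ",
         paste(unique(ped$id[duplicated(ped$id)]), collapse = ", "))
  }
  parents <- setdiff(stats::na.omit(c(ped$sire, ped$dam)), ped$id)
  if (length(parents) > 0L) {
    stop("parents not present in the pedigree: ", paste(parents, collapse = ", "))
  }
  ord <- pedigree_toposort(ped)
  out <- ped[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "order") <- ord
  out
}

# Kahn's algorithm; a cycle is reported with the individuals involved.
pedigree_toposort <- function(ped) {
  n <- nrow(ped)
  idx <- seq_len(n)
  names(idx) <- ped$id
  si <- idx[ped$sire]
  di <- idx[ped$dam]
  indeg <- (!is.na(si)) + (!is.na(di))
  children <- vector("list", n)
  for (i in idx) {
    if (!is.na(si[i])) children[[si[i]]] <- c(children[[si[i]]], i)
    if (!is.na(di[i])) children[[di[i]]] <- c(children[[di[i]]], i)
  }
  queue <- which(indeg == 0L)
  ord <- integer(0)
  while (length(queue) > 0L) {
    i <- queue[1L]; queue <- queue[-1L]
    ord <- c(ord, i)
    for (ch in children[[i]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(ord) < n) {
    stop("pedigree contains a cycle involving: ",
         paste(ped$id[setdiff(seq_len(n), ord)], collapse = ", "))
  }
  ord
}

#' Additive relationship matrix from a pedigree
#'
#' Builds Wright's numerator relationship matrix A by the tabular method over
#' topologically sorted individuals: for individual i with parents s, d (in
#' any earlier position), `A[i,i] = 1 + A[s,d]/2` (0 when either parent is
#' unknown) and `A[i,j] = (A[j,s] + A[j,d])/2` for earlier j, with unknown
#' parents contributing 0. A is symmetric positive semidefinite with diagonal
#' `1 + F` (F = inbreeding coefficient).
#'
#' @param ped a pedigree data.frame (see [validate_pedigree()]).
#' @return an n x n numeric matrix with dimnames = pedigree ids (original
#'   row order of `ped`).
#' @export
build_A <- function(ped) {
  sp <- validate_pedigree(ped)
  n <- nrow(sp)
  idx <- seq_len(n)
  names(idx) <- sp$id
  si <- idx[sp$sire]
  di <- idx[sp$dam]
  A <- matrix(0, n, n, dimnames = list(sp$id, sp$id))
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    A[i, i] <- 1 + if (!is.na(s) && !is.na(d)) 0.5 * A[s, d] else 0
    if (i > 1L) {
      j <- seq_len(i - 1L)
      aj <- 0.5 * ((if (!is.na(s)) A[j, s] else 0) + (if (!is.na(d)) A[j, d] else 0))
      A[i, j] <- aj
      A[j, i] <- aj
    }
  }
  # return in the caller's id order
  ids <- as.character(ped$id)
  A[ids, ids, drop = FALSE]
}

#' Inbreeding coefficients from a pedigree
#'
#' `F_i` is the kinship between the parents of i, computed by the recursive
#' kinship definition with memoisation (never forming dense A, so it scales
#' to large simulated pedigrees): `f(i,i) = (1 + f(s_i, d_i))/2` and, for j
#' not a descendant of i, `f(i,j) = (f(s_i,j) + f(d_i,j))/2`, with unknown
#' parents contributing 0.
#'
#' @param ped a pedigree data.frame.
#' @return numeric vector of F in the order of `ped$id`, named by id.
#' @export
inbreeding <- function(ped) {
  sp <- validate_pedigree(ped)
  n <- nrow(sp)
  idx <- seq_len(n)
  names(idx) <- sp$id
  si <- unname(idx[sp$sire])
  di <- unname(idx[sp$dam])
  pos <- idx # position in topological order
  memo <- new.env(hash = TRUE, parent = emptyenv())
  kin <- function(i, j) {
    if (is.na(i) || is.na(j)) return(0)
    if (i == j) return(0.5 * (1 + kin(si[i], di[i])))
    key <- if (i < j) paste0(i, "_", j) else paste0(j, "_", i)
    got <- memo[[key]]
    if (!is.null(got)) return(got)
    # recurse through the later-born individual's parents
    if (pos[i] < pos[j]) { a <- j; b <- i } else { a <- i; b <- j }
    val <- 0.5 * (kin(si[a], b) + kin(di[a], b))
    memo[[key]] <- val
    val
  }
  F <- vapply(seq_len(n), function(i) {
    if (is.na(si[i]) || is.na(di[i])) 0 else kin(si[i], di[i])
  }, numeric(1))
  names(F) <- sp$id
  F[as.character(ped$id)]
}

#' Sparse inverse of the additive relationship matrix
#'
#' A-inverse is assembled directly from pedigree structure by Henderson's
#' rules, accounting for inbreeding: each individual contributes
#' `alpha = 1/d_i` to the inverse, where `d_i` is the Mendelian sampling
#' variance ratio — `0.5 - (F_s + F_d)/4` with both parents known,
#' `0.75 - F_p/4` with one, and 1 with none. Never forms or inverts dense A.
#'
#' @param ped a pedigree data.frame.
#' @return a sparse symmetric [Matrix::Matrix] with dimnames = pedigree ids
#'   (original row order).
#' @export
build_A_inverse <- function(ped) {
  sp <- validate_pedigree(ped)
  n <- nrow(sp)
  idx <- seq_len(n)
  names(idx) <- sp$id
  si <- idx[sp$sire]
  di <- idx[sp$dam]
  F <- inbreeding(sp)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  add <- function(i, j, v) {
    ii <<- c(ii, i); jj <<- c(jj, j); xx <<- c(xx, v)
  }
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    dd <- if (!is.na(s) && !is.na(d)) 0.5 - 0.25 * (F[s] + F[d])
          else if (!is.na(s)) 0.75 - 0.25 * F[s]
          else if (!is.na(d)) 0.75 - 0.25 * F[d]
          else 1
    a <- 1 / dd
    add(i, i, a)
    if (!is.na(s) && !is.na(d)) {
      add(i, s, -a / 2); add(s, i, -a / 2)
      add(i, d, -a / 2); add(d, i, -a / 2)
      add(s, s, a / 4); add(d, d, a / 4)
      add(s, d, a / 4); add(d, s, a / 4)
    } else if (!is.na(s) || !is.na(d)) {
      p <- if (is.na(s)) d else s
      add(i, p, -a / 2); add(p, i, -a / 2)
      add(p, p, a / 4)
    }
  }
  Ainv <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
                               dimnames = list(sp$id, sp$id))
  ids <- as.character(ped$id)
  Ainv[ids, ids]
}
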