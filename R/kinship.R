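#' Kinship coefficient between two individuals
#'
#' The kinship coefficient phi(i, j) is the probability that two alleles
#' sampled at random, one from each individual, are identical by descent.
#' Computed by the classical recursion with memoisation:
#' phi(i, i) = (1 + phi(f_i, m_i)) / 2, and for i != j, recursing on the
#' individual of greater generation depth x,
#' phi(x, y) = (phi(f_x, y) + phi(m_x, y)) / 2, with unknown parents
#' contributing 0.
#'
#' @param ped a [pedigree].
#' @param i,j individual ids.
#' @return phi in `[0, 1]`.
#' @seealso [kinship_matrix()] for all-pairs computation,
#'   [kinship_oracle()] for the independent path-counting check.
#' @export
kinship <- function(ped, i, j) {
  a <- ped_index(ped, i)
  b <- ped_index(ped, j)
  memo <- new.env(parent = emptyenv(), hash = TRUE)
  phi_rec(ped, a, b, memo)
}

phi_rec <- function(ped, a, b, memo) {
  if (is.na(a) || is.na(b)) return(0)
  key <- if (a <= b) paste0(a, ":", b) else paste0(b, ":", a)
  hit <- memo[[key]]
  if (!is.null(hit)) return(hit)
  val <- if (a == b) {
    0.5 * (1 + phi_rec(ped, ped$fidx[a], ped$midx[a], memo))
  } else {
    # recurse on the deeper individual so recursion always climbs the DAG
    if (ped$depth[a] < ped$depth[b]) { tmp <- a; a <- b; b <- tmp }
    0.5 * (phi_rec(ped, ped$fidx[a], b, memo) +
           phi_rec(ped, ped$midx[a], b, memo))
  }
  memo[[key]] <- val
  val
}

#' Inbreeding coefficient
#'
#' F_i is the kinship of i's parents (the kinship of the pair that
#' effectively reproduced); 0 when either parent is unknown.
#'
#' @param ped a [pedigree].
#' @param i individual id.
#' @return F in `[0, 1]`.
#' @export
inbreeding <- function(ped, i) {
  a <- ped_index(ped, i)
  f <- ped$fidx[a]; m <- ped$midx[a]
  if (is.na(f) || is.na(m)) return(0)
  kinship(ped, ped$ind$id[f], ped$ind$id[m])
}

#' All-pairs kinship matrix
#'
#' Computes the full kinship matrix by a single pass over individuals in
#' generation order (each row derives from already-computed parent rows),
#' which is far faster than repeated pairwise recursion on large pedigrees.
#' The diagonal carries the self-kinship (1 + F_i) / 2.
#'
#' @param ped a [pedigree].
#' @param ids optional ids to restrict the returned matrix to (the
#'   computation always spans the whole pedigree).
#' @return symmetric numeric matrix with id dimnames.
#' @export
kinship_matrix <- function(ped, ids = NULL) {
  n <- ped$n
  ord <- order(ped$depth)
  pos <- integer(n)
  pos[ord] <- seq_len(n)
  fp <- pos[ped$fidx[ord]]    # parents' topological positions (NA propagates)
  mp <- pos[ped$midx[ord]]
  phi <- matrix(0, n, n)
  for (k in seq_len(n)) {
    f <- fp[k]; m <- mp[k]
    if (k > 1L) {
      prev <- seq_len(k - 1L)
      row <- numeric(k - 1L)
      if (!is.na(f)) row <- row + phi[f, prev]
      if (!is.na(m)) row <- row + phi[m, prev]
      row <- row * 0.5
      phi[k, prev] <- row
      phi[prev, k] <- row
    }
    phi[k, k] <- 0.5 * (1 + if (!is.na(f) && !is.na(m)) phi[f, m] else 0)
  }
  phi <- phi[pos, pos, drop = FALSE]
  dimnames(phi) <- list(ped$ind$id, ped$ind$id)
  if (!is.null(ids)) {
    ids <- as.character(ids)
    ped_index(ped, ids)   # validates
    phi <- phi[ids, ids, drop = FALSE]
  }
  phi
}

#' Inbreeding coefficients for all individuals
#'
#' @param ped a [pedigree].
#' @param phi optional precomputed full [kinship_matrix()] (id dimnames);
#'   computed if missing.
#' @return named numeric vector of F over all individuals.
#' @export
inbreeding_all <- function(ped, phi = NULL) {
  if (is.null(phi)) phi <- kinship_matrix(ped)
  F <- numeric(ped$n)
  has <- which(!is.na(ped$fidx) & !is.na(ped$midx))
  if (length(has))
    F[has] <- phi[cbind(ped$ind$id[ped$fidx[has]], ped$ind$id[ped$midx[has]])]
  stats::setNames(F, ped$ind$id)
}

#' Kinship by Wright's path-counting (independent oracle)
#'
#' Enumerates, for every common ancestor A, all pairs of ancestral paths
#' from i and from j to A that share no individual other than A, and sums
#' (1/2)^(n1 + n2 + 1) * (1 + F_A) over them, where n1 and n2 are the path
#' lengths in meioses. Exponential in pedigree depth; guarded to small
#' pedigrees. Serves as an independent check of [kinship()].
#'
#' @param ped a [pedigree] with at most `guard` individuals.
#' @param i,j individual ids.
#' @param guard maximum pedigree size accepted.
#' @return phi.
#' @export
kinship_oracle <- function(ped, i, j, guard = 500) {
  if (ped$n > guard)
    stop("kinship_oracle: pedigree larger than guard (", guard, ")")
  a <- ped_index(ped, i)
  b <- ped_index(ped, j)
  if (a == b) {
    f <- ped$fidx[a]; m <- ped$midx[a]
    Fa <- if (is.na(f) || is.na(m)) 0 else
      kinship_oracle(ped, ped$ind$id[f], ped$ind$id[m], guard)
    return(0.5 * (1 + Fa))
  }
  pa <- all_ancestry_paths(ped, a)
  pb <- all_ancestry_paths(ped, b)
  total <- 0
  for (p1 in pa) for (p2 in pb) {
    A <- p1[length(p1)]
    if (A != p2[length(p2)]) next
    # lines of descent may share no individual other than A
    if (length(intersect(p1[-length(p1)], p2[-length(p2)]))) next
    fA <- ped$fidx[A]; mA <- ped$midx[A]
    FA <- if (is.na(fA) || is.na(mA)) 0 else
      kinship_oracle(ped, ped$ind$id[fA], ped$ind$id[mA], guard)
    n1 <- length(p1) - 1L
    n2 <- length(p2) - 1L
    total <- total + 0.5^(n1 + n2 + 1) * (1 + FA)
  }
  total
}

# All upward paths from idx: list of index vectors idx .. ancestor,
# including the length-1 path (idx itself is a "common ancestor" candidate
# for parent-offspring pairs).
all_ancestry_paths <- function(ped, idx) {
  paths <- list(idx)
  out <- list(idx)
  while (length(paths)) {
    nxt <- list()
    for (p in paths) {
      tip <- p[length(p)]
      for (par in c(ped$fidx[tip], ped$midx[tip])) {
        if (!is.na(par)) nxt[[length(nxt) + 1L]] <- c(p, par)
      }
    }
    out <- c(out, nxt)
    paths <- nxt
  }
  out
}
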