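#' Assign ancestors of probands to marriage decades
#'
#' Every ancestor of any proband is assigned to the decade of its own
#' marriage year; ancestors without a marriage year are excluded and
#' reported in the `unassigned` tally.
#'
#' @param ped a [pedigree].
#' @param probands proband ids (defaults to the pedigree's proband set).
#' @return list: `decades` (named list decade -> character vector of member
#'   ids) and `unassigned` (ids of ancestors lacking a marriage year).
#' @export
assign_ancestors_to_decades <- function(ped, probands = ped$probands) {
  anc <- ancestors(ped, probands)
  dec <- decade_of(ped, anc)
  known <- !is.na(dec)
  decades <- split(anc[known], dec[known])
  decades <- decades[order(as.integer(names(decades)))]
  list(decades = decades, unassigned = anc[!known])
}

# rbind a list of decade rows, returning a typed empty frame when none.
bind_decade_rows <- function(rows) {
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows))
    return(data.frame(decade = integer(), statistic = character(),
                      mean = numeric(), ci_low = numeric(),
                      ci_high = numeric(), n = numeric()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-decade mean kinship with bootstrap confidence intervals
#'
#' For each decade: one member of every first-degree pair is dropped (same
#' deterministic rule as [remove_first_degree_probands()]), the mean kinship
#' over all remaining unordered pairs is the point estimate, and a
#' percentile bootstrap over members (resampling individuals, recomputing
#' the mean over induced pairs; pairs formed by two copies of the same
#' individual are excluded) gives the confidence interval.
#'
#' @param ped a [pedigree].
#' @param decade_members named list decade -> member ids, as produced by
#'   [assign_ancestors_to_decades()].
#' @param reps bootstrap replicates.
#' @param alpha 1 - confidence level.
#' @param seed integer seed (mandatory for reproducibility).
#' @param phi optional precomputed full [kinship_matrix()].
#' @return data.frame `decade, statistic, mean, ci_low, ci_high, n` (a tidy
#'   decade series); decades with fewer than 2 members after pruning are
#'   omitted with a warning.
#' @export
decade_mean_kinship <- function(ped, decade_members, reps = 1000,
                                alpha = 0.05, seed, phi = NULL) {
  stopifnot(reps >= 1)
  if (is.null(phi)) phi <- kinship_matrix(ped)
  set.seed(seed)
  rows <- list()
  for (dec in names(decade_members)) {
    members <- prune_first_degree(ped, decade_members[[dec]])
    m <- length(members)
    if (m < 2) {
      warning("decade ", dec, ": fewer than 2 members after pruning; omitted")
      next
    }
    sub <- phi[members, members, drop = FALSE]
    dg <- diag(sub)
    est <- (sum(sub) - sum(dg)) / (m * (m - 1))
    counts <- stats::rmultinom(reps, m, rep(1 / m, m))
    q <- sub %*% counts                       # m x reps
    num <- colSums(counts * q) - colSums(counts^2 * dg)
    den <- colSums(counts)^2 - colSums(counts^2)
    vals <- ifelse(den > 0, num / den, NA_real_)
    ci <- stats::quantile(vals, c(alpha / 2, 1 - alpha / 2),
                          names = FALSE, na.rm = TRUE)
    rows[[dec]] <- data.frame(decade = as.integer(dec), statistic = "kinship",
                              mean = est, ci_low = ci[1], ci_high = ci[2], n = m)
  }
  bind_decade_rows(rows)
}

#' Per-decade mean inbreeding with bootstrap confidence intervals
#'
#' Averages the inbreeding coefficient over decade members (no pair pruning:
#' F is a per-individual statistic) with a percentile bootstrap over
#' members.
#'
#' @inheritParams decade_mean_kinship
#' @return tidy decade series data.frame (statistic `"inbreeding"`).
#' @export
decade_mean_inbreeding <- function(ped, decade_members, reps = 1000,
                                   alpha = 0.05, seed, phi = NULL) {
  stopifnot(reps >= 1)
  Fall <- inbreeding_all(ped, phi = phi)
  set.seed(seed)
  rows <- list()
  for (dec in names(decade_members)) {
    members <- decade_members[[dec]]
    m <- length(members)
    if (m < 1) next
    Fv <- Fall[members]
    est <- mean(Fv)
    counts <- stats::rmultinom(reps, m, rep(1 / m, m))
    vals <- colSums(counts * Fv) / m
    ci <- stats::quantile(vals, c(alpha / 2, 1 - alpha / 2), names = FALSE)
    rows[[dec]] <- data.frame(decade = as.integer(dec), statistic = "inbreeding",
                              mean = est, ci_low = ci[1], ci_high = ci[2], n = m)
  }
  bind_decade_rows(rows)
}

#' Ancestors' diversity ratio
#'
#' ADR = (number of distinct ancestors) / (total ancestor occurrence) over
#' the probands' expanded genealogies. Values near 1 indicate diverse
#' ancestry; low values indicate ancestry concentrated on few individuals.
#'
#' @param ped a [pedigree].
#' @param probands non-empty proband ids.
#' @param max_gen generation cap passed to [ancestor_occurrences()].
#' @return list `n_distinct`, `occurrence`, `adr`.
#' @export
adr <- function(ped, probands = ped$probands, max_gen = Inf) {
  if (!length(probands)) stop("adr: empty proband set")
  total <- total_occurrences(ped, probands, max_gen = max_gen)
  occurrence <- sum(total)
  if (occurrence == 0) stop("adr: probands have no known ancestors")
  n_distinct <- sum(total > 0)
  list(n_distinct = n_distinct, occurrence = occurrence,
       adr = n_distinct / occurrence)
}

# Sparse ancestors x probands occurrence matrix (backbone of the ADR
# bootstrap); rows = all individuals of ped, columns = probands.
occurrence_matrix <- function(ped, probands) {
  triplets <- lapply(seq_along(probands), function(k) {
    occ <- ancestor_occurrences(ped, probands[k])
    if (!length(occ)) return(NULL)   # probands without known ancestors
    cbind(match(names(occ), ped$ind$id), k, occ)
  })
  tr <- do.call(rbind, Filter(Negate(is.null), triplets))
  if (is.null(tr)) stop("occurrence_matrix: no proband has known ancestors")
  Matrix::sparseMatrix(i = tr[, 1], j = tr[, 2], x = tr[, 3],
                       dims = c(ped$n, length(probands)),
                       dimnames = list(ped$ind$id, probands))
}

#' Per-decade ADR with a proband-subsampling bootstrap
#'
#' Each replicate draws `subset_size` probands without replacement and
#' computes, per decade, the ADR restricted to ancestors assigned to that
#' decade (distinct ancestors with at least one occurrence among the
#' subset's genealogies, over their summed occurrences). The point estimate
#' and percentile confidence interval are taken over replicates, matching
#' the equal-sample-size comparison design used for regional groups.
#'
#' @param ped a [pedigree].
#' @param probands proband ids.
#' @param subset_size probands drawn per replicate (<= number of probands).
#' @param reps replicates.
#' @param alpha 1 - confidence level.
#' @param seed integer seed.
#' @return tidy decade series data.frame (statistic `"ADR"`); `n` is the
#'   mean number of distinct decade ancestors across replicates.
#' @export
adr_by_decade_bootstrap <- function(ped, probands = ped$probands, subset_size,
                                    reps = 1000, alpha = 0.05, seed) {
  stopifnot(subset_size <= length(probands), subset_size >= 1, reps >= 1)
  A <- occurrence_matrix(ped, probands)
  dec <- decade_of(ped, ped$ind$id)
  keep <- !is.na(dec) & Matrix::rowSums(A) > 0
  decs <- sort(unique(dec[keep]))
  dlist <- split(which(keep), factor(dec[keep], levels = decs))
  set.seed(seed)
  est <- matrix(NA_real_, nrow = reps, ncol = length(decs),
                dimnames = list(NULL, decs))
  ndist <- matrix(NA_real_, nrow = reps, ncol = length(decs))
  np <- length(probands)
  for (r in seq_len(reps)) {
    sel01 <- numeric(np)
    sel01[sample.int(np, subset_size)] <- 1
    tot <- as.numeric(A %*% sel01)
    for (d in seq_along(decs)) {
      td <- tot[dlist[[d]]]
      occ <- sum(td)
      if (occ > 0) { est[r, d] <- sum(td > 0) / occ; ndist[r, d] <- sum(td > 0) }
    }
  }
  rows <- lapply(seq_along(decs), function(d) {
    v <- est[, d]
    if (all(is.na(v))) return(NULL)
    ci <- stats::quantile(v, c(alpha / 2, 1 - alpha / 2), names = FALSE, na.rm = TRUE)
    data.frame(decade = as.integer(decs[d]), statistic = "ADR",
               mean = mean(v, na.rm = TRUE), ci_low = ci[1], ci_high = ci[2],
               n = mean(ndist[, d], na.rm = TRUE))
  })
  bind_decade_rows(rows)
}

#' Ancestor occurrence distribution
#'
#' Ranks ancestors by their total occurrence over the probands' genealogies
#' (ties broken by id), exposing the "super-ancestor" concentration that a
#' low ADR reflects.
#'
#' @param ped a [pedigree].
#' @param probands proband ids.
#' @param top_k rows to return (default all).
#' @return data.frame `ancestor, occurrence, share` with shares summing to 1
#'   over the full (untruncated) table.
#' @export
occurrence_distribution <- function(ped, probands = ped$probands, top_k = Inf) {
  total <- total_occurrences(ped, probands)
  nz <- which(total > 0)
  df <- data.frame(ancestor = ped$ind$id[nz], occurrence = total[nz])
  df$share <- df$occurrence / sum(df$occurrence)
  df <- df[order(-df$occurrence, df$ancestor), , drop = FALSE]
  rownames(df) <- NULL
  utils::head(df, top_k)
}
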