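#' Construct a pedigree object
#'
#' A pedigree is a directed acyclic parent graph over individuals with
#' per-individual attributes. Unknown parents are encoded as `NA` internally
#' (`"0"` or empty in files). Validation checks id uniqueness, reference
#' integrity, parental sex consistency and acyclicity.
#'
#' @param ind data.frame with columns `id`, `father`, `mother` and optionally
#'   `sex` (`"M"`, `"F"`, `"U"`), `marriage_year` (integer or NA), `region`,
#'   `origin` (`"local"`, `"external"`, `"unknown"`).
#' @param probands character vector of proband ids (subset of `ind$id`).
#' @return An object of class `pedigree`: list with the individual table,
#'   integer parent indices (`fidx`, `midx`), generation depth per individual
#'   (founders = 0) and the proband set.
#' @export
pedigree <- function(ind, probands = character()) {
  stopifnot(is.data.frame(ind), all(c("id", "father", "mother") %in% names(ind)))
  ind <- as.data.frame(ind, stringsAsFactors = FALSE)
  ind$id <- as.character(ind$id)
  for (col in c("father", "mother")) {
    v <- as.character(ind[[col]])
    v[!is.na(v) & (v == "0" | v == "")] <- NA_character_
    ind[[col]] <- v
  }
  if (is.null(ind$sex)) ind$sex <- "U"
  ind$sex <- toupper(as.character(ind$sex))
  ind$sex[!ind$sex %in% c("M", "F")] <- "U"
  if (is.null(ind$marriage_year)) ind$marriage_year <- NA_integer_
  ind$marriage_year <- suppressWarnings(as.integer(ind$marriage_year))
  if (is.null(ind$region)) ind$region <- NA_character_
  if (is.null(ind$origin)) ind$origin <- "unknown"
  ind$origin <- as.character(ind$origin)
  ind$origin[!ind$origin %in% c("local", "external")] <- "unknown"

  if (anyNA(ind$id) || any(ind$id == ""))
    stop("pedigree: empty individual id")
  dup <- unique(ind$id[duplicated(ind$id)])
  if (length(dup))
    stop("pedigree: duplicate id(s): ", paste(dup, collapse = ", "))

  fidx <- match(ind$father, ind$id)
  midx <- match(ind$mother, ind$id)
  dangling <- c(ind$father[!is.na(ind$father) & is.na(fidx)],
                ind$mother[!is.na(ind$mother) & is.na(midx)])
  if (length(dangling))
    stop("pedigree: parent reference(s) to missing id(s): ",
         paste(unique(dangling), collapse = ", "))

  bad_f <- which(!is.na(fidx) & ind$sex[fidx] == "F")
  bad_m <- which(!is.na(midx) & ind$sex[midx] == "M")
  if (length(bad_f))
    warning("individual(s) recorded as father but sex F: ",
            paste(unique(ind$father[bad_f]), collapse = ", "))
  if (length(bad_m))
    warning("individual(s) recorded as mother but sex M: ",
            paste(unique(ind$mother[bad_m]), collapse = ", "))

  depth <- ped_depth(fidx, midx, ind$id)

  probands <- as.character(probands)
  missing_pb <- setdiff(probands, ind$id)
  if (length(missing_pb))
    stop("pedigree: proband id(s) not in pedigree: ",
         paste(missing_pb, collapse = ", "))

  structure(
    list(ind = ind, fidx = fidx, midx = midx, depth = depth,
         probands = probands, n = nrow(ind)),
    class = "pedigree"
  )
}

# Generation depth (founders 0); errors with a concrete cycle if one exists.
ped_depth <- function(fidx, midx, ids) {
  n <- length(ids)
  depth <- rep(NA_integer_, n)
  has_f <- !is.na(fidx)
  has_m <- !is.na(midx)
  repeat {
    fd <- rep(-1L, n)
    fd[has_f] <- depth[fidx[has_f]]
    md <- rep(-1L, n)
    md[has_m] <- depth[midx[has_m]]
    cand <- pmax(fd, md) + 1L            # NA while a needed parent is unresolved
    newly <- which(is.na(depth) & !is.na(cand))
    if (!length(newly)) break
    depth[newly] <- cand[newly]
  }
  if (anyNA(depth)) {
    # an unresolved individual always has an unresolved parent: walk until revisit
    path <- integer(0)
    cur <- which(is.na(depth))[1]
    while (!(cur %in% path)) {
      path <- c(path, cur)
      f <- fidx[cur]
      cur <- if (!is.na(f) && is.na(depth[f])) f else midx[cur]
    }
    cyc <- path[match(cur, path):length(path)]
    stop("pedigree: cycle detected: ",
         paste(ids[c(cyc, cur)], collapse = " -> "))
  }
  depth
}

#' @export
print.pedigree <- function(x, ...) {
  cat(sprintf("<pedigree> %d individuals, %d probands, max depth %d\n",
              x$n, length(x$probands), max(x$depth)))
  invisible(x)
}

# One generation step of the expanded ancestry tree in sparse form:
# parent indices and multiplicities given current indices/multiplicities.
step_up <- function(ped, idx, mult) {
  p <- c(ped$fidx[idx], ped$midx[idx])
  w <- c(mult, mult)
  ok <- !is.na(p)
  if (!any(ok)) return(list(idx = integer(0), mult = numeric(0)))
  tab <- rowsum(w[ok], p[ok])
  list(idx = as.integer(rownames(tab)), mult = as.numeric(tab[, 1]))
}

# Total path counts from a multiset of seed individuals to every ancestor.
total_occurrences <- function(ped, seeds, max_gen = Inf) {
  i <- ped_index(ped, seeds)
  tab <- rowsum(rep(1, length(i)), i)
  idx <- as.integer(rownames(tab))
  mult <- as.numeric(tab[, 1])
  occ <- numeric(ped$n)
  g <- 0
  while (g < max_gen && length(idx)) {
    s <- step_up(ped, idx, mult)
    idx <- s$idx
    mult <- s$mult
    occ[idx] <- occ[idx] + mult
    g <- g + 1
  }
  occ
}

ped_index <- function(ped, id) {
  i <- match(as.character(id), ped$ind$id)
  if (anyNA(i))
    stop("unknown individual id(s): ",
         paste(as.character(id)[is.na(i)], collapse = ", "))
  i
}

#' Read a pedigree table
#'
#' Reads a whitespace- or tab-separated pedigree file with a header. Required
#' columns: `id`, `father`, `mother`; recognised extras: `sex`,
#' `marriage_year`, `region`, `origin`, `proband` (0/1). `"0"` or empty
#' denotes an unknown parent. A 4-column PED-like core
#' (`id father mother sex`) is accepted.
#'
#' @param path file path.
#' @param probands optional character vector of proband ids; overrides any
#'   `proband` column.
#' @return a [pedigree] object.
#' @export
read_pedigree <- function(path, probands = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "", quote = "",
                          colClasses = "character",
                          stringsAsFactors = FALSE, comment.char = "")
  if (!all(c("id", "father", "mother") %in% names(df)))
    stop("pedigree file must have columns id, father, mother: ", path)
  if (is.null(probands) && "proband" %in% names(df))
    probands <- df$id[df$proband %in% c("1", "TRUE", "true")]
  if (is.null(probands)) probands <- character()
  pedigree(df[setdiff(names(df), "proband")], probands = probands)
}

#' Write a pedigree table
#'
#' Inverse of [read_pedigree()]: a write/read round trip reproduces the
#' pedigree structure, attributes and proband set.
#'
#' @param ped a [pedigree].
#' @param path output path (tab-separated, header, `0` = unknown parent).
#' @export
write_pedigree <- function(ped, path) {
  df <- ped$ind
  df$father[is.na(df$father)] <- "0"
  df$mother[is.na(df$mother)] <- "0"
  df$proband <- as.integer(df$id %in% ped$probands)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Ancestor occurrences of a proband
#'
#' The occurrence of an ancestor is the number of distinct genealogical paths
#' from the proband up to that ancestor, i.e. how many times the ancestor
#' appears in the fully expanded ancestry tree. The number of distinct
#' ancestors is the length of the returned vector.
#'
#' @param ped a [pedigree].
#' @param proband a single individual id.
#' @param max_gen maximum generation to expand (parents = 1); `Inf` expands
#'   the whole known ancestry.
#' @return named integer vector: ancestor id -> occurrence count.
#' @export
ancestor_occurrences <- function(ped, proband, max_gen = Inf) {
  if (length(proband) != 1) stop("ancestor_occurrences: one proband at a time")
  occ <- total_occurrences(ped, proband, max_gen = max_gen)
  nz <- which(occ > 0)
  stats::setNames(as.integer(occ[nz]), ped$ind$id[nz])
}

#' Ancestor id set of one or more individuals
#'
#' @param ped a [pedigree].
#' @param ids individual ids.
#' @param max_gen maximum generation (parents = 1).
#' @return character vector of ancestor ids (the individuals themselves are
#'   not included).
#' @export
ancestors <- function(ped, ids, max_gen = Inf) {
  cur <- unique(ped_index(ped, ids))
  seen <- logical(ped$n)
  g <- 0
  out <- logical(ped$n)
  while (length(cur) && g < max_gen) {
    par <- c(ped$fidx[cur], ped$midx[cur])
    par <- unique(par[!is.na(par)])
    new <- par[!out[par]]
    out[new] <- TRUE
    cur <- new
    g <- g + 1
  }
  ped$ind$id[out]
}

#' Genealogical completeness profile
#'
#' Completeness at generation `g` is the number of known ancestors occupying
#' the `2^g` expected ancestral slots divided by `2^g`. Each slot of the
#' expanded tree counts separately even when inbreeding collapses the tree,
#' so an ancestor filling two slots contributes twice.
#'
#' @param ped a [pedigree].
#' @param probands ids over which to compute and average; must be non-empty.
#' @param max_gen deepest generation `G` to report (parents = 1).
#' @return list with `per_proband` (probands x G matrix of C_g) and
#'   `mean` (length-G vector averaged over probands).
#' @export
completeness <- function(ped, probands, max_gen) {
  stopifnot(max_gen >= 1)
  if (!length(probands)) stop("completeness: empty proband set")
  idx <- ped_index(ped, probands)
  per <- matrix(0, nrow = length(idx), ncol = max_gen,
                dimnames = list(as.character(probands), paste0("g", seq_len(max_gen))))
  for (k in seq_along(idx)) {
    cur <- list(idx = idx[k], mult = 1)
    for (g in seq_len(max_gen)) {
      cur <- step_up(ped, cur$idx, cur$mult)
      per[k, g] <- sum(cur$mult) / 2^g
    }
  }
  list(per_proband = per, mean = colMeans(per))
}

#' Retain probands with perfect completeness up to a generation
#'
#' Keeps probands whose completeness is 1 for every generation up to
#' `min_gen` (the study's quality-control gate; e.g. 3 for rural regions,
#' 5 where early-generation records are richer). Individuals no longer
#' reachable from a retained proband are dropped.
#'
#' @param ped a [pedigree] with a non-empty proband set.
#' @param min_gen completeness must equal 1 for all g <= min_gen.
#' @return filtered [pedigree].
#' @export
filter_by_completeness <- function(ped, min_gen) {
  stopifnot(min_gen >= 1)
  if (!length(ped$probands)) stop("filter_by_completeness: no probands")
  cp <- completeness(ped, ped$probands, min_gen)
  keep <- ped$probands[apply(cp$per_proband >= 1, 1, all)]
  if (!length(keep)) warning("no proband is complete to generation ", min_gen)
  subset_pedigree(ped, keep)
}

# Restrict a pedigree to the given probands plus their ancestor closure.
subset_pedigree <- function(ped, probands) {
  keep_ids <- union(probands, ancestors(ped, probands))
  keep <- ped$ind$id %in% keep_ids
  ind <- ped$ind[keep, , drop = FALSE]
  rownames(ind) <- NULL
  pedigree(ind, probands = probands)
}

# First-degree pairs (parent-offspring or full siblings with both parents
# known) among the given ids; returns a 2-column matrix of id pairs (lo, hi).
first_degree_pairs <- function(ped, ids) {
  ids <- as.character(ids)
  idx <- ped_index(ped, ids)
  f <- ped$ind$father[idx]
  m <- ped$ind$mother[idx]
  out <- list()
  po_f <- !is.na(f) & f %in% ids
  po_m <- !is.na(m) & m %in% ids
  if (any(po_f)) out[[length(out) + 1L]] <- cbind(ids[po_f], f[po_f])
  if (any(po_m)) out[[length(out) + 1L]] <- cbind(ids[po_m], m[po_m])
  both <- !is.na(f) & !is.na(m)
  for (grp in split(ids[both], paste(f[both], m[both]))) {
    if (length(grp) > 1) out[[length(out) + 1L]] <- t(utils::combn(sort(grp), 2))
  }
  if (!length(out)) return(matrix(character(0), ncol = 2))
  mat <- do.call(rbind, out)
  unique(cbind(pmin(mat[, 1], mat[, 2]), pmax(mat[, 1], mat[, 2])))
}

#' Remove first-degree relationships among probands
#'
#' First degree means parent-offspring or full siblings (both parents shared
#' and known); half-siblings do not count. Conflicting pairs are processed
#' in lexicographic order and the lexicographically larger id of each pair
#' is dropped, then pairs are re-checked, making the cleaning deterministic.
#' With `seed` set, the member to drop is instead chosen at random.
#'
#' @param ped a [pedigree].
#' @param seed optional integer enabling the seeded-random drop rule.
#' @return [pedigree] with the pruned proband set (individuals are kept).
#' @export
remove_first_degree_probands <- function(ped, seed = NULL) {
  keep <- prune_first_degree(ped, ped$probands, seed = seed)
  ped$probands <- keep
  ped
}

# Shared pruning rule, also used per decade by the kinship series.
prune_first_degree <- function(ped, ids, seed = NULL) {
  ids <- sort(as.character(ids))
  if (!is.null(seed)) {
    rng <- local({ set.seed(seed); function(n) sample.int(n, 1) })
  }
  repeat {
    fd <- first_degree_pairs(ped, ids)
    if (!nrow(fd)) break
    # lexicographic order over (min, max) pairs
    lo <- pmin(fd[, 1], fd[, 2]); hi <- pmax(fd[, 1], fd[, 2])
    ord <- order(lo, hi)
    removed <- character(0)
    for (r in ord) {
      a <- lo[r]; b <- hi[r]
      if (a %in% removed || b %in% removed) next
      drop <- if (is.null(seed)) b else c(a, b)[rng(2)]
      removed <- c(removed, drop)
    }
    ids <- setdiff(ids, removed)
  }
  ids
}

#' Flag probands with recent external origin
#'
#' A proband is flagged when the proband itself or any ancestor within
#' generations 1..`depth` carries `origin = "external"` (a recent
#' immigrant). With `count_self = FALSE` the proband's own flag is ignored
#' and only ancestors are examined.
#'
#' @param ped a [pedigree].
#' @param probands proband ids (defaults to the pedigree's proband set).
#' @param depth how many generations up to examine (>= 1).
#' @param count_self whether the proband's own origin flag counts.
#' @return character vector of flagged proband ids.
#' @export
flag_recent_immigrants <- function(ped, probands = ped$probands, depth = 3,
                                   count_self = TRUE) {
  stopifnot(depth >= 1)
  ext <- ped$ind$id[ped$ind$origin == "external"]
  flagged <- vapply(probands, function(p) {
    if (count_self && ped$ind$origin[ped_index(ped, p)] == "external") return(TRUE)
    any(ancestors(ped, p, max_gen = depth) %in% ext)
  }, logical(1))
  as.character(probands[flagged])
}

#' Marriage decade of each individual
#'
#' @param ped a [pedigree].
#' @param ids ids (defaults to all individuals).
#' @return named integer vector of decades (year floored to 10); NA when the
#'   marriage year is unknown.
#' @export
decade_of <- function(ped, ids = ped$ind$id) {
  y <- ped$ind$marriage_year[ped_index(ped, ids)]
  stats::setNames(as.integer(10 * (y %/% 10)), as.character(ids))
}
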