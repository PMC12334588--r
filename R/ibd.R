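#' Read IBD segments (refinedIBD-style TSV)
#'
#' Nine tab-separated columns:
#' `sample1 hap1 sample2 hap2 chrom start end lod length_cM`, 1-based
#' inclusive start, exclusive end. Pairs are canonicalised so that
#' `sample1 < sample2` (haplotype columns swapped accordingly); chromosome
#' labels are opaque strings.
#'
#' @param path file path (a header line is optional and auto-detected).
#' @return object of class `ibd_segments`: data.frame with canonical pair
#'   key column `pair` (`"s1|s2"`).
#' @export
read_ibd_segments <- function(path) {
  first <- readLines(path, n = 1)
  has_header <- grepl("sample", first, ignore.case = TRUE)
  df <- utils::read.table(path, header = has_header, sep = "\t", quote = "",
                          stringsAsFactors = FALSE)
  if (ncol(df) != 9)
    stop("IBD file must have 9 columns, got ", ncol(df), ": ", path)
  names(df) <- c("sample1", "hap1", "sample2", "hap2", "chrom",
                 "start", "end", "lod", "length_cM")
  bad <- which(df$start >= df$end)
  if (length(bad))
    stop("IBD segment with start >= end at line(s): ",
         paste(bad + has_header, collapse = ", "))
  ibd_segments(df)
}

#' Construct an IBD segment set
#'
#' @param df data.frame with columns `sample1, hap1, sample2, hap2, chrom,
#'   start, end, lod, length_cM`.
#' @return canonicalised `ibd_segments` object.
#' @export
ibd_segments <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  stopifnot(all(c("sample1", "hap1", "sample2", "hap2", "chrom",
                  "start", "end", "lod", "length_cM") %in% names(df)))
  df$sample1 <- as.character(df$sample1)
  df$sample2 <- as.character(df$sample2)
  if (any(df$sample1 == df$sample2)) stop("IBD segment pairing a sample with itself")
  swap <- df$sample1 > df$sample2
  if (any(swap)) {
    tmp_s <- df$sample1[swap]; df$sample1[swap] <- df$sample2[swap]; df$sample2[swap] <- tmp_s
    tmp_h <- df$hap1[swap];    df$hap1[swap]    <- df$hap2[swap];    df$hap2[swap]    <- tmp_h
  }
  df$pair <- paste(df$sample1, df$sample2, sep = "|")
  class(df) <- c("ibd_segments", "data.frame")
  df
}

#' @export
print.ibd_segments <- function(x, ...) {
  cat(sprintf("<ibd_segments> %d segments, %d pairs, %d chromosome(s)\n",
              nrow(x), length(unique(x$pair)), length(unique(x$chrom))))
  invisible(x)
}

pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")

# union of half-open intervals [start, end): single sorted scan
merge_intervals <- function(start, end) {
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  keep_s <- numeric(0); keep_e <- numeric(0)
  for (k in seq_along(start)) {
    if (length(keep_e) && start[k] <= keep_e[length(keep_e)]) {
      keep_e[length(keep_e)] <- max(keep_e[length(keep_e)], end[k])
    } else {
      keep_s <- c(keep_s, start[k]); keep_e <- c(keep_e, end[k])
    }
  }
  data.frame(start = keep_s, end = keep_e)
}

pair_segments <- function(segset, pair) {
  segset[segset$pair == pair_key(pair[1], pair[2]), , drop = FALSE]
}

#' Merge a pair's IBD segments
#'
#' Unions overlapping or adjacent intervals within each haplotype
#' combination, and also across combinations (genome-position union).
#'
#' @param segset an [ibd_segments] set.
#' @param pair character vector of two sample ids.
#' @return list: `per_combo` data.frame
#'   (`chrom, hap1, hap2, start, end`) and `union` data.frame
#'   (`chrom, start, end`).
#' @export
merge_pair_segments <- function(segset, pair) {
  seg <- pair_segments(segset, pair)
  merge_one <- function(s) merge_intervals(s$start, s$end)
  per_combo <- do.call(rbind, lapply(
    split(seg, list(seg$chrom, seg$hap1, seg$hap2), drop = TRUE),
    function(s) cbind(chrom = s$chrom[1], hap1 = s$hap1[1], hap2 = s$hap2[1],
                      merge_one(s))))
  union <- do.call(rbind, lapply(split(seg, seg$chrom, drop = TRUE),
    function(s) cbind(chrom = s$chrom[1], merge_one(s))))
  empty <- function(cols) stats::setNames(
    data.frame(matrix(ncol = length(cols), nrow = 0)), cols)
  if (is.null(per_combo))
    per_combo <- empty(c("chrom", "hap1", "hap2", "start", "end"))
  if (is.null(union)) union <- empty(c("chrom", "start", "end"))
  rownames(per_combo) <- rownames(union) <- NULL
  list(per_combo = per_combo, union = union)
}

#' Read a genome manifest
#'
#' @param path TSV with header `chrom length_bp length_cM`.
#' @return data.frame; attribute `"total_cM"` holds the genome cM length.
#' @export
read_genome_manifest <- function(path) {
  m <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "length_bp", "length_cM") %in% names(m)))
  m$chrom <- as.character(m$chrom)
  attr(m, "total_cM") <- sum(m$length_cM)
  m
}

cM_per_bp <- function(manifest, chrom) {
  i <- match(chrom, manifest$chrom)
  if (anyNA(i)) stop("chromosome not in genome manifest: ",
                     paste(unique(chrom[is.na(i)]), collapse = ", "))
  manifest$length_cM[i] / manifest$length_bp[i]
}

#' Proportion of the genome shared IBD by a pair
#'
#' Total merged segment length in cM, summed over the four haplotype
#' combinations, divided by twice the genome length. The expectation is
#' about twice the kinship coefficient, so 0.125 corresponds to
#' third-degree relatives. Merged interval lengths are converted to cM via
#' the manifest's per-chromosome uniform rate.
#'
#' @param segset an [ibd_segments] set.
#' @param pair two sample ids.
#' @param manifest genome manifest (see [read_genome_manifest()]).
#' @return proportion in `[0, 1]` (under consistent detection).
#' @export
ibd_proportion <- function(segset, pair, manifest) {
  mc <- merge_pair_segments(segset, pair)$per_combo
  if (!nrow(mc)) return(0)
  len_cM <- (mc$end - mc$start) * cM_per_bp(manifest, mc$chrom)
  sum(len_cM) / (2 * sum(manifest$length_cM))
}

#' Build the relatedness graph over samples
#'
#' An undirected edge joins two samples when their IBD sharing proportion
#' reaches `ibd_prop` or (when a pedigree is supplied) their genealogical
#' kinship reaches `kinship_min`. Edges record which criterion fired.
#'
#' @param samples sample ids (graph nodes).
#' @param segset an [ibd_segments] set.
#' @param manifest genome manifest.
#' @param ped optional [pedigree] covering some or all samples.
#' @param ibd_prop IBD-proportion threshold (default 0.125).
#' @param kinship_min kinship threshold (default 0.0625).
#' @param phi optional precomputed kinship matrix (id dimnames) to avoid
#'   recomputation.
#' @return igraph graph; edge attribute `criterion` in
#'   `{"ibd", "kinship", "both"}`.
#' @export
build_relatedness_graph <- function(samples, segset, manifest, ped = NULL,
                                    ibd_prop = 0.125, kinship_min = 0.0625,
                                    phi = NULL) {
  samples <- sort(unique(as.character(samples)))
  g <- igraph::make_empty_graph(n = length(samples), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = samples)
  if (length(samples) < 2) return(g)
  if (!is.null(ped) && is.null(phi)) {
    in_ped <- intersect(samples, ped$ind$id)
    phi <- if (length(in_ped)) kinship_matrix(ped, in_ped) else NULL
  }
  # IBD edges: only pairs with segments can reach the threshold
  sub <- segset[segset$sample1 %in% samples & segset$sample2 %in% samples, ,
                drop = FALSE]
  rate <- if (nrow(sub)) cM_per_bp(manifest, sub$chrom) else numeric(0)
  denom <- 2 * sum(manifest$length_cM)
  ibd_pairs <- character(0)
  if (nrow(sub)) {
    props <- vapply(split(seq_len(nrow(sub)), sub$pair), function(rows) {
      s <- sub[rows, , drop = FALSE]
      tot <- 0
      for (grp in split(seq_along(rows),
                        paste(s$chrom, s$hap1, s$hap2))) {
        mi <- merge_intervals(s$start[grp], s$end[grp])
        tot <- tot + sum((mi$end - mi$start) * rate[rows[grp]][1])
      }
      tot / denom
    }, numeric(1))
    ibd_pairs <- names(props)[props >= ibd_prop]
  }
  # kinship edges
  kin_pairs <- character(0)
  if (!is.null(phi)) {
    ids <- intersect(samples, rownames(phi))
    if (length(ids) >= 2) {
      sm <- phi[ids, ids, drop = FALSE]
      ut <- which(upper.tri(sm) & sm >= kinship_min, arr.ind = TRUE)
      if (nrow(ut)) kin_pairs <- pair_key(ids[ut[, 1]], ids[ut[, 2]])
    }
  }
  all_pairs <- union(ibd_pairs, kin_pairs)
  if (length(all_pairs)) {
    parts <- strsplit(all_pairs, "|", fixed = TRUE)
    from <- vapply(parts, `[`, "", 1)
    to <- vapply(parts, `[`, "", 2)
    crit <- ifelse(all_pairs %in% ibd_pairs & all_pairs %in% kin_pairs, "both",
                   ifelse(all_pairs %in% ibd_pairs, "ibd", "kinship"))
    g <- igraph::add_edges(g, rbind(from, to))
    g <- igraph::set_edge_attr(g, "criterion", value = crit)
  }
  g
}

#' Maximally unrelated subset (greedy independent set)
#'
#' Repeatedly deletes the highest-degree node until the graph is edgeless;
#' ties are broken lexicographically (the larger id is deleted), making the
#' result deterministic. With `seed` set, ties (and only ties) are broken
#' at random. Exact maximum independent set is NP-hard; the greedy
#' heuristic is standard for relatedness pruning.
#'
#' @param graph igraph graph with vertex names.
#' @param seed optional integer for the seeded-random tie-break.
#' @return character vector of retained sample ids (an independent set).
#' @export
max_unrelated_subset <- function(graph, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g <- graph
  while (igraph::ecount(g) > 0) {
    deg <- igraph::degree(g)
    mx <- which(deg == max(deg))
    victim <- if (is.null(seed)) {
      nm <- sort(names(mx))
      nm[length(nm)]
    } else sample(names(mx), 1)
    g <- igraph::delete_vertices(g, victim)
  }
  sort(igraph::V(g)$name)
}

#' Proportion of carrier pairs sharing IBD at a position
#'
#' Numerator: unordered carrier pairs with at least one segment (any
#' haplotype combination) overlapping `[pos - window_bp, pos + window_bp]`
#' on `chrom`; denominator: all C(n, 2) carrier pairs.
#'
#' @param segset an [ibd_segments] set.
#' @param carriers at least two sample ids.
#' @param chrom chromosome label.
#' @param pos 1-based position.
#' @param window_bp half-window around the position (default 0: the exact
#'   position must be covered).
#' @return proportion in `[0, 1]`.
#' @export
sharing_at_position <- function(segset, carriers, chrom, pos, window_bp = 0) {
  carriers <- unique(as.character(carriers))
  if (length(carriers) < 2)
    stop("sharing_at_position: need at least 2 carriers")
  lo <- pos - window_bp
  hi <- pos + window_bp
  seg <- segset[segset$chrom == chrom & segset$start <= hi & segset$end > lo &
                  segset$sample1 %in% carriers & segset$sample2 %in% carriers, ,
                drop = FALSE]
  sharing_pairs <- unique(seg$pair)
  n <- length(carriers)
  length(sharing_pairs) / (n * (n - 1) / 2)
}

#' Classify a candidate founder variant from carrier IBD sharing
#'
#' Decision sequence:
#' 1. count the maximally unrelated carriers (independent set of the
#'    relatedness graph restricted to carriers); fewer than
#'    `min_unrelated` makes the variant **familial**;
#' 2. otherwise, if at least `min_sharing` of all carrier pairs share IBD
#'    at the variant position, the variant is a **founder** variant;
#' 3. otherwise it reflects **multiple introductions** into the
#'    population.
#'
#' @param variant_id variant identifier (carried through to the result).
#' @param carriers non-empty carrier sample ids.
#' @param segset an [ibd_segments] set.
#' @param manifest genome manifest.
#' @param chrom,pos variant position.
#' @param ped optional [pedigree] (adds the kinship edge criterion).
#' @param ibd_prop,kinship_min,min_unrelated,min_sharing thresholds
#'   (defaults 0.125, 0.0625, 5, 0.5).
#' @param window_bp half-window for [sharing_at_position()].
#' @param phi optional precomputed kinship matrix.
#' @return list of class `variant_classification`: label and all
#'   intermediate statistics.
#' @export
classify_variant <- function(variant_id, carriers, segset, manifest, chrom, pos,
                             ped = NULL, ibd_prop = 0.125, kinship_min = 0.0625,
                             min_unrelated = 5, min_sharing = 0.5,
                             window_bp = 0, phi = NULL) {
  carriers <- unique(as.character(carriers))
  if (!length(carriers)) stop("classify_variant: empty carrier set")
  graph <- build_relatedness_graph(carriers, segset, manifest, ped = ped,
                                   ibd_prop = ibd_prop,
                                   kinship_min = kinship_min, phi = phi)
  unrelated <- max_unrelated_subset(graph)
  share <- if (length(carriers) >= 2)
    sharing_at_position(segset, carriers, chrom, pos, window_bp) else NA_real_
  label <- if (length(unrelated) < min_unrelated) "familial"
  else if (!is.na(share) && share >= min_sharing) "founder"
  else "multiple_introductions"
  structure(list(variant_id = variant_id, label = label,
                 carriers = carriers, n_carriers = length(carriers),
                 unrelated = unrelated, n_unrelated = length(unrelated),
                 pair_sharing_at_pos = share,
                 thresholds = list(ibd_prop = ibd_prop,
                                   kinship_min = kinship_min,
                                   min_unrelated = min_unrelated,
                                   min_sharing = min_sharing,
                                   window_bp = window_bp)),
            class = "variant_classification")
}

#' @export
print.variant_classification <- function(x, ...) {
  cat(sprintf("<variant_classification> %s: %s (%d carriers, %d unrelated, sharing %.3f)\n",
              x$variant_id, x$label, x$n_carriers, x$n_unrelated,
              x$pair_sharing_at_pos))
  invisible(x)
}
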