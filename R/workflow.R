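#' Assemble a run configuration
#'
#' Central record of thresholds and seeds, serialised into outputs for
#' provenance. Defaults follow the screening design: completeness to
#' generation 3, at least 5 carriers, relative frequency difference at
#' least 10%, reference MAF at most 5%, IBD-proportion 0.125 and kinship
#' 0.0625 relatedness cutoffs, 50% pair sharing for a founder call, 2 cM
#' minimum segment length, 1000 bootstrap replicates.
#'
#' @param completeness_gen,immigrant_depth pedigree-cleaning settings.
#' @param min_carriers,min_rfd,max_ref_maf screen thresholds.
#' @param ibd_prop,kinship_min,min_unrelated,min_sharing,window_bp
#'   classification thresholds.
#' @param min_cM IBD segment length cutoff (cM).
#' @param reps bootstrap replicates.
#' @param subset_size ADR bootstrap subset size (default: all probands).
#' @param seed integer seed.
#' @return named list of class `run_config`.
#' @export
run_config <- function(completeness_gen = 3, immigrant_depth = 3,
                       min_carriers = 5, min_rfd = 0.10, max_ref_maf = 0.05,
                       ibd_prop = 0.125, kinship_min = 0.0625,
                       min_unrelated = 5, min_sharing = 0.5, window_bp = 0,
                       min_cM = 2, reps = 1000, subset_size = NULL,
                       seed = 1L) {
  cfg <- list(completeness_gen = completeness_gen,
              immigrant_depth = immigrant_depth,
              min_carriers = min_carriers, min_rfd = min_rfd,
              max_ref_maf = max_ref_maf, ibd_prop = ibd_prop,
              kinship_min = kinship_min, min_unrelated = min_unrelated,
              min_sharing = min_sharing, window_bp = window_bp,
              min_cM = min_cM, reps = reps, subset_size = subset_size,
              seed = as.integer(seed))
  for (nm in c("min_rfd", "max_ref_maf", "ibd_prop", "kinship_min",
               "min_sharing")) {
    if (cfg[[nm]] < 0 || cfg[[nm]] > 1)
      stop("run_config: ", nm, " must lie in [0, 1]")
  }
  structure(cfg, class = "run_config")
}

#' Run the genealogical analysis arm
#'
#' Cleans the pedigree in the study order — completeness gate, then
#' first-degree pruning among probands, then recent-immigrant removal —
#' logging counts removed at each step, and computes the per-decade mean
#' kinship, mean inbreeding and ADR series with bootstrap confidence
#' intervals.
#'
#' @param ped a [pedigree] with probands designated.
#' @param config a [run_config].
#' @param outdir optional directory; when given, tidy TSVs
#'   (`decade_series.tsv`, `cleaning_report.tsv`) are written.
#' @return list: `ped` (cleaned), `cleaning_report` (data.frame
#'   step/probands_before/removed/probands_after), `series` (tidy decade
#'   series over the three statistics), `adr_overall`.
#' @export
run_genealogy <- function(ped, config = run_config(), outdir = NULL) {
  if (!length(ped$probands)) stop("run_genealogy: no probands designated")
  steps <- list()
  n0 <- length(ped$probands)
  ped1 <- filter_by_completeness(ped, config$completeness_gen)
  steps[["completeness"]] <- c(n0, n0 - length(ped1$probands), length(ped1$probands))
  ped2 <- remove_first_degree_probands(ped1)
  steps[["first_degree"]] <- c(length(ped1$probands),
                               length(ped1$probands) - length(ped2$probands),
                               length(ped2$probands))
  flagged <- flag_recent_immigrants(ped2, depth = config$immigrant_depth)
  ped3 <- ped2
  ped3$probands <- setdiff(ped2$probands, flagged)
  steps[["recent_immigrants"]] <- c(length(ped2$probands), length(flagged),
                                    length(ped3$probands))
  report <- data.frame(step = names(steps),
                       probands_before = vapply(steps, `[`, 0, 1),
                       removed = vapply(steps, `[`, 0, 2),
                       probands_after = vapply(steps, `[`, 0, 3),
                       row.names = NULL)
  if (!length(ped3$probands))
    stop("run_genealogy: no probands left after cleaning")
  phi <- kinship_matrix(ped3)
  assign <- assign_ancestors_to_decades(ped3)
  kin <- decade_mean_kinship(ped3, assign$decades, reps = config$reps,
                             seed = config$seed, phi = phi)
  inb <- decade_mean_inbreeding(ped3, assign$decades, reps = config$reps,
                                seed = config$seed + 1L, phi = phi)
  subset_size <- if (is.null(config$subset_size)) length(ped3$probands) else
    min(config$subset_size, length(ped3$probands))
  adr_series <- adr_by_decade_bootstrap(ped3, subset_size = subset_size,
                                        reps = config$reps,
                                        seed = config$seed + 2L)
  series <- rbind(kin, inb, adr_series)
  out <- list(ped = ped3, cleaning_report = report, series = series,
              adr_overall = adr(ped3), config = config)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(series, file.path(outdir, "decade_series.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(report, file.path(outdir, "cleaning_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}

#' Run the variant analysis arm
#'
#' Screens annotated variants for regional enrichment
#' ([screen_variants()]), classifies each passing variant from carrier IBD
#' sharing ([classify_variant()]), and reports final carrier rates
#' recomputed on the maximally unrelated sample of each cluster.
#'
#' @param panel a [genotype_panel].
#' @param annotations annotation table (see [screen_variants()]).
#' @param segset an [ibd_segments] set.
#' @param manifest genome manifest.
#' @param cluster_a,cluster_b focal and comparison cluster labels
#'   (defaults: first two cluster labels in the panel).
#' @param ped optional [pedigree] adding the genealogical kinship
#'   criterion to the relatedness graph.
#' @param config a [run_config].
#' @param outdir optional directory for `screen.tsv` /
#'   `classification.tsv`.
#' @return list: `screen` (full screen table), `classification`
#'   (data.frame per passing variant: label, unrelated carrier count, pair
#'   sharing, MAFs and carrier rates on the full and maximally unrelated
#'   samples), `counts` (founder/familial/multiple_introductions/excluded
#'   tally), `unrelated_a` (the maximally unrelated sample of the focal
#'   cluster).
#' @export
run_variants <- function(panel, annotations, segset, manifest,
                         cluster_a = NULL, cluster_b = NULL, ped = NULL,
                         config = run_config(), outdir = NULL) {
  cl <- unique(panel$samples$cluster)
  if (is.null(cluster_a)) cluster_a <- cl[1]
  if (is.null(cluster_b)) cluster_b <- cl[2]
  if (is.na(cluster_b)) stop("run_variants: need two clusters")
  scr <- screen_variants(panel, annotations, cluster_a, cluster_b,
                         min_carriers = config$min_carriers,
                         min_rfd = config$min_rfd,
                         max_ref_maf = config$max_ref_maf)
  # maximally unrelated focal-cluster sample for reported rates
  a_samples <- panel$samples$sample[panel$samples$cluster == cluster_a]
  graph_a <- build_relatedness_graph(a_samples, segset, manifest, ped = ped,
                                     ibd_prop = config$ibd_prop,
                                     kinship_min = config$kinship_min)
  unrelated_a <- max_unrelated_subset(graph_a)
  sub_panel <- panel
  keep <- panel$samples$sample %in% unrelated_a |
    panel$samples$cluster != cluster_a
  sub_panel$geno <- panel$geno[keep, , drop = FALSE]
  sub_panel$samples <- panel$samples[keep, , drop = FALSE]
  rows <- list()
  for (k in which(scr$pass)) {
    vid <- scr$variant_id[k]
    vrow <- panel$variants[panel$variants$variant_id == vid, ]
    g <- panel$geno[, vid]
    carriers <- panel$samples$sample[!is.na(g) & g >= 1 &
                                       panel$samples$cluster == cluster_a]
    cls <- classify_variant(vid, carriers, segset, manifest,
                            chrom = vrow$chrom, pos = vrow$pos, ped = ped,
                            ibd_prop = config$ibd_prop,
                            kinship_min = config$kinship_min,
                            min_unrelated = config$min_unrelated,
                            min_sharing = config$min_sharing,
                            window_bp = config$window_bp)
    cru_a <- carrier_rate(sub_panel, cluster_a, vid)
    cru_b <- carrier_rate(sub_panel, cluster_b, vid)
    rows[[vid]] <- data.frame(
      variant_id = vid, hgvs = scr$hgvs[k], disease = scr$disease[k],
      label = cls$label, n_carriers = cls$n_carriers,
      n_unrelated = cls$n_unrelated,
      sharing_at_pos = cls$pair_sharing_at_pos,
      maf_a = scr$maf_a[k], maf_b = scr$maf_b[k], rfd = scr$rfd[k],
      ref_pop_maf = scr$ref_pop_maf[k],
      cr_a = scr$cr_a[k], cr_b = scr$cr_b[k],
      cr_a_unrelated = cru_a$display, cr_b_unrelated = cru_b$display,
      stringsAsFactors = FALSE)
  }
  classification <- if (length(rows)) do.call(rbind, rows) else NULL
  if (!is.null(classification)) rownames(classification) <- NULL
  counts <- c(founder = 0L, familial = 0L, multiple_introductions = 0L,
              excluded = sum(!scr$pass))
  if (!is.null(classification)) {
    tab <- table(classification$label)
    counts[names(tab)] <- counts[names(tab)] + as.integer(tab)
  }
  out <- list(screen = scr, classification = classification, counts = counts,
              unrelated_a = unrelated_a, config = config,
              clusters = c(a = cluster_a, b = cluster_b))
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(scr, file.path(outdir, "screen.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(classification))
      utils::write.table(classification, file.path(outdir, "classification.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}
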