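#' Simulate a complete analysis bundle with ground truth
#'
#' Runs the demography simulation, gene-drops haplotypes, plants variants
#' under the given scenarios, genotypes a panel of recently married
#' samples, and derives descent-exact IBD segments. The result feeds every
#' analysis stage and carries the generator's truth for validation.
#'
#' Two clusters are supported through two regions: scenario variants are
#' planted with origins restricted to the first region's samples, emulating
#' regionally enriched candidates against an urban-style comparison
#' cluster.
#'
#' @param config a [demography_config()]; all randomness derives from its
#'   seed.
#' @param scenarios list of [scenario_spec()] objects.
#' @param n_samples panel samples drawn per region (recycled).
#' @param manifest genome manifest (default [default_genome()]).
#' @param min_cM IBD length cutoff in cM (default 2).
#' @param proband_decades how many final decades define the proband /
#'   sampling window (default 2).
#' @param ibd_scope `"cluster_a"` (segments among first-region samples,
#'   the default), `"carriers"` (only carriers of planted variants) or
#'   `"all"` (all panel samples).
#' @return list of class `founder_bundle`: `ped` (probands = panel
#'   samples), `mosaic`, `panel` ([genotype_panel]), `annotations`,
#'   `segset`, `manifest`, `truth` (per-variant kind, origins, carriers),
#'   `config`.
#' @export
simulate_bundle <- function(config, scenarios, n_samples = 150,
                            manifest = default_genome(), min_cM = 2,
                            proband_decades = 2,
                            ibd_scope = c("cluster_a", "carriers", "all")) {
  ibd_scope <- match.arg(ibd_scope)
  ped <- simulate_pedigree(config)
  last <- max(ped$ind$marriage_year, na.rm = TRUE)
  from <- last - 10 * (proband_decades - 1)
  n_samples <- rep_len(n_samples, length(config$regions))
  set.seed(config$seed + 1L)
  samples <- character(0)
  clusters <- character(0)
  for (r in seq_along(config$regions)) {
    cand <- ped$ind$id[!is.na(ped$ind$marriage_year) &
                         ped$ind$marriage_year >= from &
                         ped$ind$region == config$regions[r]]
    take <- sort(sample(cand, min(n_samples[r], length(cand))))
    samples <- c(samples, take)
    clusters <- c(clusters, rep(config$regions[r], length(take)))
  }
  mosaic <- drop_haplotypes(ped, manifest, seed = config$seed + 2L,
                            keep = samples)
  cluster_a_samples <- samples[clusters == config$regions[1]]
  set.seed(config$seed + 3L)
  planted <- lapply(scenarios, function(sc)
    plant_variant(mosaic, ped, sc, samples, origin_samples = cluster_a_samples))
  vids <- vapply(planted, `[[`, "", "variant_id")
  if (anyDuplicated(vids)) stop("scenarios must use distinct positions")
  geno <- do.call(cbind, lapply(planted, `[[`, "genotypes"))
  colnames(geno) <- vids
  # two recruitment cohorts within each cluster (batch-effect checks)
  set.seed(config$seed + 4L)
  cohort <- paste0("cohort", sample(1:2, length(samples), replace = TRUE))
  meta <- data.frame(sample = samples, cluster = clusters, cohort = cohort,
                     stringsAsFactors = FALSE)
  variants <- data.frame(
    variant_id = vids,
    chrom = vapply(planted, `[[`, "", "chrom"),
    pos = vapply(planted, function(p) as.integer(p$pos), integer(1)),
    ref = "A", alt = "T", stringsAsFactors = FALSE)
  panel <- genotype_panel(geno, meta, variants)
  annotations <- data.frame(
    variant_id = vids, hgvs = paste0("SYN:", vids),
    chrom = variants$chrom, pos = variants$pos, ref = "A", alt = "T",
    clnsig = "pathogenic",
    review_status = "criteria provided, multiple submitters",
    vtype = "SNP", ref_pop_maf = 0,
    disease = vapply(planted, `[[`, "", "kind"),
    known_founder_flag = FALSE, stringsAsFactors = FALSE)
  ibd_samples <- switch(ibd_scope,
    cluster_a = cluster_a_samples,
    carriers = unique(unlist(lapply(planted, `[[`, "carriers"))),
    all = samples)
  segset <- derive_ibd_segments(mosaic, ibd_samples, min_cM = min_cM)
  truth <- lapply(planted, function(p)
    list(variant_id = p$variant_id, kind = p$kind, origins = p$origins,
         carriers = p$carriers,
         alt_count = sum(p$genotypes, na.rm = TRUE)))
  names(truth) <- vids
  ped$probands <- samples
  structure(list(ped = ped, mosaic = mosaic, panel = panel,
                 annotations = annotations, segset = segset,
                 manifest = manifest, truth = truth, config = config,
                 min_cM = min_cM),
            class = "founder_bundle")
}

#' Write a minimal GT-only VCFv4.2 file
#'
#' Plain-text emitter for synthetic panels (alt-allele doses 0/1/2/NA
#' rendered as 0/0, 0/1, 1/1, ./.).
#'
#' @param panel a [genotype_panel].
#' @param path output path.
#' @export
write_vcf <- function(panel, path) {
  v <- panel$variants
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(v)))
  gt_str <- function(d) {
    out <- rep("./.", length(d))
    out[!is.na(d) & d == 0] <- "0/0"
    out[!is.na(d) & d == 1] <- "0/1"
    out[!is.na(d) & d == 2] <- "1/1"
    out
  }
  hdr <- c("##fileformat=VCFv4.2",
           "##source=founderkit",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", panel$samples$sample), collapse = "\t"))
  body <- vapply(seq_len(nrow(v)), function(k) {
    paste(c(v$chrom[k], v$pos[k], v$variant_id[k], v$ref[k], v$alt[k],
            ".", "PASS", ".", "GT", gt_str(panel$geno[, k])), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write a bundle to disk as plain-text files
#'
#' Emits `pedigree.tsv`, `genotypes.vcf`, `samples.tsv`,
#' `annotations.tsv`, `ibd.tsv`, `genome.tsv` and `truth.json` into
#' `outdir`. The bundle is self-describing and re-loadable with
#' [read_bundle()].
#'
#' @param bundle a [simulate_bundle()] result.
#' @param outdir output directory.
#' @param force overwrite an existing non-empty directory.
#' @export
write_bundle <- function(bundle, outdir, force = FALSE) {
  if (dir.exists(outdir) && length(list.files(outdir)) && !force)
    stop("output directory exists and is not empty (use force = TRUE): ", outdir)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_pedigree(bundle$ped, file.path(outdir, "pedigree.tsv"))
  write_vcf(bundle$panel, file.path(outdir, "genotypes.vcf"))
  utils::write.table(bundle$panel$samples, file.path(outdir, "samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(bundle$annotations, file.path(outdir, "annotations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  seg <- bundle$segset
  utils::write.table(seg[, c("sample1", "hap1", "sample2", "hap2", "chrom",
                             "start", "end", "lod", "length_cM")],
                     file.path(outdir, "ibd.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  man <- bundle$manifest
  utils::write.table(man, file.path(outdir, "genome.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- list(format_version = 1L,
                seed = bundle$config$seed,
                min_cM = bundle$min_cM,
                regions = bundle$config$regions,
                variants = bundle$truth)
  jsonlite::write_json(truth, file.path(outdir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}

#' Read a bundle written by [write_bundle()]
#'
#' @param dir bundle directory.
#' @return list: `ped`, `panel`, `annotations`, `segset`, `manifest`,
#'   `truth`.
#' @export
read_bundle <- function(dir) {
  list(ped = read_pedigree(file.path(dir, "pedigree.tsv")),
       panel = read_genotypes(file.path(dir, "genotypes.vcf"),
                              file.path(dir, "samples.tsv")),
       annotations = read_annotations(file.path(dir, "annotations.tsv")),
       segset = read_ibd_segments(file.path(dir, "ibd.tsv")),
       manifest = read_genome_manifest(file.path(dir, "genome.tsv")),
       truth = jsonlite::read_json(file.path(dir, "truth.json")))
}
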