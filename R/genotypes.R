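#' Read a genotype panel from VCF plus sample metadata
#'
#' Parses a biallelic VCF (GT field required) into a sample x variant matrix
#' of alternate-allele counts (0/1/2, NA for missing) and joins sample
#' metadata (`sample cluster cohort` TSV). Multiallelic records are
#' rejected: split them upstream.
#'
#' @param vcf_path path to a VCF (optionally gzipped).
#' @param metadata_path path to a tab-separated table with header columns
#'   `sample`, `cluster` and optionally `cohort`.
#' @return object of class `genotype_panel`: list with `geno` (matrix,
#'   samples x variants), `samples` (metadata data.frame) and `variants`
#'   (data.frame `variant_id, chrom, pos, ref, alt`). Variant ids are
#'   `chrom:pos:ref:alt` unless the VCF ID field is set.
#' @export
read_genotypes <- function(vcf_path, metadata_path) {
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT)
  if (any(multi))
    stop("multiallelic record(s) at: ",
         paste(paste0(fix$CHROM[multi], ":", fix$POS[multi]), collapse = ", "))
  gt <- vcfR::extract.gt(v, element = "GT")
  geno <- apply(gt, 2, gt_to_dose)
  if (is.null(dim(geno))) geno <- matrix(geno, nrow = 1)
  vid <- ifelse(is.na(fix$ID) | fix$ID == ".",
                paste(fix$CHROM, fix$POS, fix$REF, fix$ALT, sep = ":"), fix$ID)
  variants <- data.frame(variant_id = vid, chrom = fix$CHROM,
                         pos = as.integer(fix$POS), ref = fix$REF,
                         alt = fix$ALT, stringsAsFactors = FALSE)
  geno <- t(geno)                       # samples x variants
  rownames(geno) <- colnames(gt)
  colnames(geno) <- vid
  meta <- utils::read.table(metadata_path, header = TRUE, sep = "\t",
                            colClasses = "character", stringsAsFactors = FALSE)
  if (!all(c("sample", "cluster") %in% names(meta)))
    stop("metadata must have columns sample, cluster")
  if (is.null(meta$cohort)) meta$cohort <- "cohort1"
  unmatched <- setdiff(rownames(geno), meta$sample)
  if (length(unmatched))
    stop("sample(s) in VCF absent from metadata: ",
         paste(unmatched, collapse = ", "))
  meta <- meta[match(rownames(geno), meta$sample), , drop = FALSE]
  rownames(meta) <- NULL
  genotype_panel(geno, meta, variants)
}

gt_to_dose <- function(gt) {
  al <- strsplit(gsub("\\|", "/", gt), "/", fixed = TRUE)
  vapply(al, function(a) {
    if (length(a) != 2 || any(a == ".") || any(is.na(a))) return(NA_real_)
    sum(a != "0")
  }, numeric(1))
}

#' Construct a genotype panel
#'
#' @param geno samples x variants matrix of alt-allele doses (0/1/2/NA).
#' @param samples data.frame with `sample`, `cluster`, `cohort`.
#' @param variants data.frame with at least `variant_id`.
#' @return `genotype_panel` object.
#' @export
genotype_panel <- function(geno, samples, variants) {
  stopifnot(nrow(geno) == nrow(samples), ncol(geno) == nrow(variants))
  if (anyNA(samples$cluster)) stop("every sample needs a cluster label")
  rownames(geno) <- samples$sample
  colnames(geno) <- variants$variant_id
  structure(list(geno = geno, samples = samples, variants = variants),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("<genotype_panel> %d samples x %d variants; clusters: %s\n",
              nrow(x$geno), ncol(x$geno),
              paste(names(table(x$samples$cluster)), collapse = ", ")))
  invisible(x)
}

cluster_rows <- function(panel, cluster) {
  rows <- which(panel$samples$cluster == cluster)
  if (!length(rows)) stop("cluster has no samples: ", cluster)
  rows
}

#' Alternate-allele frequency of a variant within a cluster
#'
#' Missing genotypes are excluded from numerator and denominator. The raw
#' alternate-allele frequency is returned (the screened pathogenic alleles
#' are alternate alleles); fold to the minor allele only when comparing to
#' an external reference population.
#'
#' @param panel a [genotype_panel].
#' @param cluster cluster label.
#' @param variant variant id.
#' @return frequency in `[0, 1]`, or NA (with a warning) when every
#'   genotype is missing.
#' @export
compute_maf <- function(panel, cluster, variant) {
  g <- panel$geno[cluster_rows(panel, cluster), variant]
  g <- g[!is.na(g)]
  if (!length(g)) {
    warning("all genotypes missing for ", variant, " in cluster ", cluster)
    return(NA_real_)
  }
  sum(g) / (2 * length(g))
}

#' Relative frequency difference between two clusters
#'
#' rfd = (maf_a - maf_b) / maf_a: the fraction of the focal cluster's
#' allele frequency not accounted for by the comparison cluster. 1 when the
#' allele is absent from the comparison cluster, 0 when frequencies are
#' equal, negative when the comparison cluster has the higher frequency.
#'
#' @param maf_a frequency in the focal cluster; must be > 0.
#' @param maf_b frequency in the comparison cluster.
#' @return rfd <= 1.
#' @export
relative_frequency_difference <- function(maf_a, maf_b) {
  if (any(is.na(maf_a)) || any(maf_a <= 0))
    stop("relative_frequency_difference: undefined at maf_a = 0")
  (maf_a - maf_b) / maf_a
}

#' Carrier rate of a variant within a cluster
#'
#' Carriers are heterozygotes only (dose 1); homozygous-alternate
#' individuals are counted separately, not as carriers. The conventional
#' display is `"1/x"` with x = n/n_het rounded half away from zero; the
#' exact fraction n_het/n is the canonical value.
#'
#' @param panel a [genotype_panel].
#' @param cluster cluster label.
#' @param variant variant id.
#' @return list `n_het`, `n_hom_alt`, `n_total` (non-missing), `rate`
#'   (exact fraction) and `display` (`"1/x"`, or `"0"` when no carrier).
#' @export
carrier_rate <- function(panel, cluster, variant) {
  g <- panel$geno[cluster_rows(panel, cluster), variant]
  g <- g[!is.na(g)]
  n_het <- sum(g == 1)
  n_tot <- length(g)
  disp <- if (n_het == 0 || n_tot == 0) "0" else
    paste0("1/", round_half_up(n_tot / n_het))
  list(n_het = n_het, n_hom_alt = sum(g == 2), n_total = n_tot,
       rate = if (n_tot > 0) n_het / n_tot else NA_real_, display = disp)
}

round_half_up <- function(x) floor(x + 0.5)

#' Screen variants for regional founder candidates
#'
#' Applies the screening filters in order, recording for each variant the
#' first failing rule:
#' 1. clinical class pathogenic / likely pathogenic / conflicting, or a
#'    previously reported founder variant (`known_founder_flag`);
#' 2. review status not among the excluded no-assertion statuses;
#' 3. variant type SNP / insertion / deletion;
#' 4. at least `min_carriers` heterozygous carriers in the focal cluster;
#' 5. relative frequency difference at least `min_rfd`;
#' 6. reference-population MAF at most `max_ref_maf` (missing reference
#'    frequency passes: the variant is unobserved in the reference).
#'
#' A variant whose focal-cluster frequency is 0 cannot be screened (the rfd
#' denominator is 0) and is reported with rule `"maf_a_zero"`, distinct
#' from a filter failure.
#'
#' @param panel a [genotype_panel].
#' @param annotations data.frame with columns `variant_id` (or
#'   `chrom,pos,ref,alt`), `hgvs`, `clnsig`, `review_status`, `vtype`,
#'   `ref_pop_maf`, `disease`, and optionally `known_founder_flag`.
#' @param cluster_a focal cluster label.
#' @param cluster_b comparison cluster label.
#' @param min_carriers,min_rfd,max_ref_maf thresholds (defaults 5, 0.10,
#'   0.05).
#' @return data.frame, one row per annotated variant present in the panel:
#'   frequencies, rfd, carrier counts/rates in both clusters, `pass`
#'   (logical) and `first_fail` (`NA` when passing). Attribute
#'   `"rule_counts"` tallies failures per rule. Row order follows
#'   `annotations` sorted by `variant_id`, so the result is invariant to
#'   input row order.
#' @export
screen_variants <- function(panel, annotations, cluster_a, cluster_b,
                            min_carriers = 5, min_rfd = 0.10,
                            max_ref_maf = 0.05) {
  if (min_rfd < 0 || min_rfd > 1 || max_ref_maf < 0 || max_ref_maf > 1)
    stop("screen_variants: thresholds must lie in [0, 1]")
  ann <- normalise_annotations(annotations)
  ann <- ann[ann$variant_id %in% panel$variants$variant_id, , drop = FALSE]
  ann <- ann[order(ann$variant_id), , drop = FALSE]
  excluded_status <- c("no assertion criteria provided",
                       "no classification provided",
                       "no classification for the individual variant")
  rows <- lapply(seq_len(nrow(ann)), function(k) {
    a <- ann[k, ]
    maf_a <- compute_maf(panel, cluster_a, a$variant_id)
    maf_b <- compute_maf(panel, cluster_b, a$variant_id)
    cr_a <- carrier_rate(panel, cluster_a, a$variant_id)
    cr_b <- carrier_rate(panel, cluster_b, a$variant_id)
    fail <- NA_character_
    rfd <- NA_real_
    class_ok <- a$clnsig %in% c("pathogenic", "likely_pathogenic", "conflicting") ||
      isTRUE(a$known_founder_flag)
    if (!class_ok) fail <- "clinical_class"
    else if (a$review_status %in% excluded_status) fail <- "review_status"
    else if (!a$vtype %in% c("SNP", "insertion", "deletion")) fail <- "variant_type"
    else if (is.na(maf_a) || maf_a == 0) fail <- "maf_a_zero"
    else {
      rfd <- relative_frequency_difference(maf_a, maf_b)
      if (cr_a$n_het < min_carriers) fail <- "min_carriers"
      else if (rfd < min_rfd) fail <- "min_rfd"
      else if (!is.na(a$ref_pop_maf) && a$ref_pop_maf > max_ref_maf)
        fail <- "ref_pop_maf"
    }
    data.frame(variant_id = a$variant_id, hgvs = a$hgvs, disease = a$disease,
               maf_a = maf_a, maf_b = maf_b, rfd = rfd,
               ref_pop_maf = a$ref_pop_maf,
               n_carriers_a = cr_a$n_het, carrier_rate_a = cr_a$rate,
               cr_a = cr_a$display, n_carriers_b = cr_b$n_het,
               carrier_rate_b = cr_b$rate, cr_b = cr_b$display,
               n_hom_alt_a = cr_a$n_hom_alt,
               pass = is.na(fail), first_fail = fail,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "rule_counts") <- table(out$first_fail, useNA = "no")
  out
}

normalise_annotations <- function(ann) {
  ann <- as.data.frame(ann, stringsAsFactors = FALSE)
  if (is.null(ann$variant_id)) {
    if (!all(c("chrom", "pos", "ref", "alt") %in% names(ann)))
      stop("annotations need variant_id or chrom/pos/ref/alt")
    ann$variant_id <- paste(ann$chrom, ann$pos, ann$ref, ann$alt, sep = ":")
  }
  if (is.null(ann$hgvs)) ann$hgvs <- ann$variant_id
  if (is.null(ann$disease)) ann$disease <- NA_character_
  if (is.null(ann$review_status)) ann$review_status <- "criteria provided"
  if (is.null(ann$ref_pop_maf)) ann$ref_pop_maf <- NA_real_
  ann$ref_pop_maf <- suppressWarnings(as.numeric(ann$ref_pop_maf))
  if (is.null(ann$known_founder_flag)) ann$known_founder_flag <- FALSE
  ann$known_founder_flag <- as.logical(ann$known_founder_flag)
  if (is.null(ann$clnsig)) stop("annotations need a clnsig column")
  if (is.null(ann$vtype)) stop("annotations need a vtype column")
  ann
}

#' Read a ClinVar-style annotation table
#'
#' @param path TSV with header; columns as in [screen_variants()].
#' @return normalised annotation data.frame.
#' @export
read_annotations <- function(path) {
  normalise_annotations(
    utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                      stringsAsFactors = FALSE))
}

#' Within-cluster MAF concordance between cohorts
#'
#' Compares per-variant allele frequencies between two recruitment cohorts
#' inside one cluster (a batch-effect check): a strong rank correlation
#' indicates frequencies are cohort-independent.
#'
#' @param panel a [genotype_panel].
#' @param cluster cluster label containing at least two cohorts.
#' @param variants variant ids (default: all panel variants).
#' @return list: `table` (data.frame `variant_id, maf_cohort1, maf_cohort2`)
#'   and `rank_correlation` (Spearman, over variants with at least one
#'   non-missing frequency pair).
#' @export
cohort_maf_concordance <- function(panel, cluster, variants = panel$variants$variant_id) {
  rows <- cluster_rows(panel, cluster)
  cohorts <- sort(unique(panel$samples$cohort[rows]))
  if (length(cohorts) < 2)
    stop("cluster ", cluster, " has fewer than 2 cohorts")
  c1 <- rows[panel$samples$cohort[rows] == cohorts[1]]
  c2 <- rows[panel$samples$cohort[rows] == cohorts[2]]
  if (!length(c1) || !length(c2)) stop("cohort with 0 samples")
  freq_of <- function(rws, v) {
    g <- panel$geno[rws, v]
    g <- g[!is.na(g)]
    if (!length(g)) NA_real_ else sum(g) / (2 * length(g))
  }
  m1 <- vapply(variants, function(v) freq_of(c1, v), numeric(1))
  m2 <- vapply(variants, function(v) freq_of(c2, v), numeric(1))
  tab <- data.frame(variant_id = variants, maf_cohort1 = m1, maf_cohort2 = m2,
                    stringsAsFactors = FALSE)
  ok <- !is.na(m1) & !is.na(m2)
  rc <- if (sum(ok) >= 2)
    suppressWarnings(stats::cor(m1[ok], m2[ok], method = "spearman")) else NA_real_
  list(table = tab, rank_correlation = rc)
}
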