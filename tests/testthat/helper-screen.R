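# Constructed 20-variant screen fixture: every filter rule is violated by
# at least one planted variant, and the expected pass set plus
# first-failing-rule labels are known by construction.
make_screen_fixture <- function(nA = 100, nB = 100) {
  spec <- list(
    # name,        clnsig,              review,                                    vtype,       hetA, homA, hetB, homB, refmaf, kff,  expected_fail
    list("pass_path_snp",   "pathogenic",        "criteria provided",                 "SNP",       10, 0, 1, 0, 0.001, FALSE, NA),
    list("pass_lp_ins",     "likely_pathogenic", "criteria provided",                 "insertion",  6, 0, 0, 0, 0.0,   FALSE, NA),
    list("pass_confl_del",  "conflicting",       "criteria provided",                 "deletion",   5, 0, 2, 0, 0.05,  FALSE, NA),
    list("pass_known_fdr",  "other",             "criteria provided",                 "SNP",        8, 0, 0, 0, 0.002, TRUE,  NA),
    list("fail_class",      "other",             "criteria provided",                 "SNP",        8, 0, 0, 0, 0.0,   FALSE, "clinical_class"),
    list("fail_review_a",   "pathogenic",        "no assertion criteria provided",    "SNP",        8, 0, 0, 0, 0.0,   FALSE, "review_status"),
    list("fail_review_b",   "pathogenic",        "no classification provided",        "SNP",        8, 0, 0, 0, 0.0,   FALSE, "review_status"),
    list("fail_review_c",   "pathogenic",        "no classification for the individual variant", "SNP", 8, 0, 0, 0, 0.0, FALSE, "review_status"),
    list("fail_type",       "pathogenic",        "criteria provided",                 "other",      8, 0, 0, 0, 0.0,   FALSE, "variant_type"),
    list("fail_carriers",   "pathogenic",        "criteria provided",                 "SNP",        4, 0, 0, 0, 0.0,   FALSE, "min_carriers"),
    list("fail_hom_not_cr", "pathogenic",        "criteria provided",                 "SNP",        4, 3, 0, 0, 0.0,   FALSE, "min_carriers"),
    list("fail_zero_het",   "pathogenic",        "criteria provided",                 "SNP",        0, 3, 0, 0, 0.0,   FALSE, "min_carriers"),
    list("fail_rfd_equal",  "pathogenic",        "criteria provided",                 "SNP",       10, 0, 10, 0, 0.0,  FALSE, "min_rfd"),
    list("fail_rfd_neg",    "pathogenic",        "criteria provided",                 "SNP",       10, 0, 20, 0, 0.0,  FALSE, "min_rfd"),
    list("fail_rfd_under",  "pathogenic",        "criteria provided",                 "SNP",       20, 0, 19, 0, 0.0,  FALSE, "min_rfd"),
    list("pass_rfd_low",    "pathogenic",        "criteria provided",                 "SNP",       10, 0, 8, 0, 0.0,   FALSE, NA),
    list("fail_ref_maf",    "pathogenic",        "criteria provided",                 "SNP",       10, 0, 0, 0, 0.06,  FALSE, "ref_pop_maf"),
    list("pass_ref_na",     "pathogenic",        "criteria provided",                 "SNP",        7, 0, 0, 0, NA,    FALSE, NA),
    list("fail_absent_a",   "pathogenic",        "criteria provided",                 "SNP",        0, 0, 3, 0, 0.0,   FALSE, "maf_a_zero"),
    list("pass_del_big",    "pathogenic",        "criteria provided",                 "deletion",  20, 0, 0, 0, 0.01,  FALSE, NA)
  )
  n <- nA + nB
  geno <- matrix(0, nrow = n, ncol = length(spec))
  for (k in seq_along(spec)) {
    s <- spec[[k]]
    hetA <- s[[5]]; homA <- s[[6]]; hetB <- s[[7]]; homB <- s[[8]]
    if (hetA > 0) geno[seq_len(hetA), k] <- 1
    if (homA > 0) geno[hetA + seq_len(homA), k] <- 2
    if (hetB > 0) geno[nA + seq_len(hetB), k] <- 1
    if (homB > 0) geno[nA + hetB + seq_len(homB), k] <- 2
  }
  samples <- data.frame(
    sample = sprintf("S%03d", seq_len(n)),
    cluster = rep(c("A", "B"), c(nA, nB)),
    cohort = rep(c("cohort1", "cohort2"), length.out = n),
    stringsAsFactors = FALSE)
  variants <- data.frame(
    variant_id = vapply(spec, `[[`, "", 1),
    chrom = "chr1", pos = seq_along(spec) * 100000L,
    ref = "A", alt = "T", stringsAsFactors = FALSE)
  panel <- genotype_panel(geno, samples, variants)
  annotations <- data.frame(
    variant_id = variants$variant_id,
    hgvs = paste0("NM_0000:c.", seq_along(spec), "A>T"),
    clnsig = vapply(spec, `[[`, "", 2),
    review_status = vapply(spec, `[[`, "", 3),
    vtype = vapply(spec, `[[`, "", 4),
    ref_pop_maf = vapply(spec, function(s) as.numeric(s[[9]]), numeric(1)),
    disease = "synthetic fixture",
    known_founder_flag = vapply(spec, `[[`, TRUE, 10),
    stringsAsFactors = FALSE)
  expected <- data.frame(
    variant_id = variants$variant_id,
    first_fail = vapply(spec, function(s) as.character(s[[11]]), character(1)),
    stringsAsFactors = FALSE)
  expected$pass <- is.na(expected$first_fail)
  list(panel = panel, annotations = annotations, expected = expected)
}
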