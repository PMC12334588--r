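#!/usr/bin/env Rscript

# Step 1: generate the synthetic study data.
#
# Two artefacts are produced under results/:
#   * an isolate-region pedigree (pedigree.tsv) emulating a founder
#     demography — small founder pool, declining immigration, high
#     fertility, within-region mating, post-settlement expansion;
#   * a two-cluster bundle (results/bundle/) with genotypes, ClinVar-style
#     annotations, descent-exact IBD segments and a truth record, carrying
#     planted founder / multiple-introduction / familial variants enriched
#     in the isolate cluster.

suppressMessages(library(founderkit))
seed <- 1L
dir.create("results", showWarnings = FALSE)

message("Simulating the isolate demography (30 decades) ...")
cfg_iso <- demography_config(seed = seed)
ped <- simulate_pedigree(cfg_iso)
last <- max(ped$ind$marriage_year, na.rm = TRUE)
ped <- select_probands(ped, last - 10, last)
write_pedigree(ped, "results/pedigree.tsv")
message(sprintf("  %d individuals, %d probands married %d-%d -> results/pedigree.tsv",
                ped$n, length(ped$probands), last - 10, last))

message("Simulating the two-cluster variant bundle ...")
cfg2 <- demography_config(regions = c("isolate", "urban"),
                          n_founder_couples = c(60, 150),
                          settlement_decade = c(1660, 1800),
                          max_couples = c(50, 80),
                          couples_growth = c(1.06, 1.05),
                          seed = seed + 100L)
scenarios <- list(
  scenario_spec("founder_single", "chr1", 120e6, target_carriers = 14),
  scenario_spec("founder_single", "chr2", 150e6, target_carriers = 14),
  scenario_spec("founder_single", "chr4", 40e6, target_carriers = 14),
  scenario_spec("multiple_introductions", "chr3", 90e6, k = 3,
                target_carriers = 12),
  scenario_spec("familial_recent", "chr4", 110e6, target_carriers = 4))
bundle <- simulate_bundle(cfg2, scenarios, n_samples = c(150, 150),
                          ibd_scope = "cluster_a")
write_bundle(bundle, "results/bundle", force = TRUE)
message(sprintf("  %d samples x %d planted variants, %d IBD segments -> results/bundle/",
                nrow(bundle$panel$geno), ncol(bundle$panel$geno),
                nrow(bundle$segset)))
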