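small_config <- function(seed, ...) {
  demography_config(n_founder_couples = 12, n_decades = 8, max_couples = 14,
                    couples_growth = 1.0, seed = seed, ...)
}

test_that("the demography simulator is reproducible and respects its schedule", {
  ped1 <- simulate_pedigree(small_config(5))
  ped2 <- simulate_pedigree(small_config(5))
  expect_identical(ped1$ind, ped2$ind)   # same seed, byte-identical

  # zero immigration: external individuals only at the settlement decade
  cfg0 <- demography_config(n_founder_couples = 12, n_decades = 6,
                            max_couples = 14, couples_growth = 1,
                            immigrant_schedule = matrix(0, 1, 6), seed = 3)
  ped0 <- simulate_pedigree(cfg0)
  ext <- ped0$ind$origin == "external"
  expect_true(all(ped0$ind$marriage_year[ext] == 1660))
  expect_gt(sum(!ext), 0)

  # an unsustainable demography errors rather than looping
  expect_error(simulate_pedigree(
    demography_config(n_founder_couples = 2, offspring_mean = 0,
                      n_decades = 4, immigrant_schedule = matrix(0, 1, 4),
                      seed = 1)),
    "extinct")
})

test_that("config invariants are enforced", {
  expect_error(demography_config(), "seed is mandatory")
  expect_error(demography_config(offspring_mean = -1, seed = 1))
  expect_error(demography_config(p_within_region = 1.5, seed = 1))
})

test_that("haplotype mosaics tile chromosomes and draw only from the assigned parent", {
  ped <- simulate_pedigree(small_config(9))
  man <- tiny_manifest()
  mos <- drop_haplotypes(ped, man, seed = 10)
  idx <- sample(seq_len(ped$n), 25)
  for (i in idx) {
    for (c in seq_len(nrow(man))) {
      tr <- mos$tracks[[i]][[c]]
      for (h in 1:2) {
        ends <- tr$hap[[h]]$end
        expect_equal(ends[length(ends)], man$length_bp[c])
        expect_true(all(diff(ends) > 0))
        # child haplotype ids are a subset of the designated parent's ids
        par <- if (h == 1) ped$fidx[i] else ped$midx[i]
        if (!is.na(par)) {
          pids <- unique(c(mos$tracks[[par]][[c]]$hap[[1]]$id,
                           mos$tracks[[par]][[c]]$hap[[2]]$id))
          expect_true(all(tr$hap[[h]]$id %in% pids))
        }
      }
    }
  }
  # restricting to a keep set materialises exactly the ancestor closure
  keep <- utils::tail(ped$ind$id, 3)
  mos2 <- drop_haplotypes(ped, man, seed = 10, keep = keep)
  closure <- union(keep, ancestors(ped, keep))
  has <- !vapply(mos2$tracks, is.null, TRUE)
  expect_setequal(ped$ind$id[has], closure)
})

test_that("crossover counts follow the Poisson expectation of the map length", {
  # founder couple with many children on a 1-Morgan chromosome
  n_kids <- 600
  ped <- pedigree(ped_df(
    id = c("F", "M", sprintf("K%03d", seq_len(n_kids))),
    father = c("0", "0", rep("F", n_kids)),
    mother = c("0", "0", rep("M", n_kids)),
    sex = c("M", "F", rep("U", n_kids))))
  man <- data.frame(chrom = "c1", length_bp = 100e6, length_cM = 100)
  mos <- drop_haplotypes(ped, man, seed = 21)
  # founder haplotype ids never repeat adjacently, so segments - 1 = crossovers
  xo <- vapply(seq_len(n_kids) + 2L, function(i)
    length(mos$tracks[[i]][[1]]$hap[[1]]$id) - 1L, integer(1))
  expect_lt(abs(mean(xo) - 1), 3 * sqrt(1 / n_kids))
  expect_gt(stats::var(xo), 0.5)  # Poisson-like dispersion, not degenerate

  # zero-length map: whole-haplotype transmission, no crossovers
  man0 <- data.frame(chrom = "c1", length_bp = 100e6, length_cM = 0)
  mos0 <- drop_haplotypes(ped, man0, seed = 22)
  expect_true(all(vapply(seq_len(n_kids) + 2L, function(i)
    length(mos0$tracks[[i]][[1]]$hap[[1]]$id), integer(1)) == 1L))
})

test_that("derived IBD segments are descent-exact", {
  # parent-offspring: the transmitted material covers the full genome at
  # min_cM = 0, giving an IBD proportion of exactly 0.5
  ped <- pedigree(ped_df(id = c("F", "M", "K"), father = c("0", "0", "F"),
                         mother = c("0", "0", "M"), sex = c("M", "F", "U")))
  man <- tiny_manifest()
  mos <- drop_haplotypes(ped, man, seed = 31)
  seg <- derive_ibd_segments(mos, c("F", "K"), min_cM = 0)
  expect_equal(ibd_proportion(seg, c("F", "K"), man), 0.5, tolerance = 1e-6)

  # unrelated founders share nothing
  expect_equal(nrow(derive_ibd_segments(mos, c("F", "M"), min_cM = 0)), 0)

  # segments are reproducible under the seed
  mosb <- drop_haplotypes(ped, man, seed = 31)
  expect_identical(derive_ibd_segments(mosb, c("F", "K"), min_cM = 0), seg)

  # the length cutoff only removes short segments
  seg2 <- derive_ibd_segments(mos, c("F", "K"), min_cM = 5)
  expect_true(all(seg2$length_cM >= 5))
  expect_true(nrow(seg2) <= nrow(seg))
})

test_that("sib-pair IBD proportions centre near one half", {
  ped <- sib_ped()
  man <- default_genome()
  props <- vapply(1:25, function(r) {
    mos <- drop_haplotypes(ped, man, seed = 500 + r)
    seg <- derive_ibd_segments(mos, c("S1", "S2"), min_cM = 0)
    ibd_proportion(seg, c("S1", "S2"), man)
  }, numeric(1))
  expect_lt(abs(mean(props) - 0.5), 0.05)
})

test_that("planted variants obey their scenario semantics", {
  cfg <- small_config(77)
  ped <- simulate_pedigree(cfg)
  man <- default_genome()
  last <- max(ped$ind$marriage_year, na.rm = TRUE)
  samples <- ped$ind$id[!is.na(ped$ind$marriage_year) &
                          ped$ind$marriage_year >= last - 10]
  mos <- drop_haplotypes(ped, man, seed = 78)

  set.seed(79)
  pv <- suppressWarnings(plant_variant(
    mos, ped, scenario_spec("founder_single", "chr1", 123e6,
                            target_carriers = 8), samples))
  expect_gte(length(pv$carriers), 2)
  # every carrier shares the origin haplotype at the position: full pair
  # sharing at min_cM = 0
  seg <- derive_ibd_segments(mos, pv$carriers, min_cM = 0)
  expect_equal(sharing_at_position(seg, pv$carriers, "chr1", 123e6), 1.0)
  # genotypes equal an independent mosaic readout at the position
  for (s in utils::head(samples, 20)) {
    i <- mosaic_index(mos, s)
    d <- sum(c(founder_id_at(mos, i, 1, 1, 123e6),
               founder_id_at(mos, i, 1, 2, 123e6)) %in% pv$origins$founder_hap)
    expect_equal(unname(pv$genotypes[s]), d)
  }

  # multiple introductions: k distinct origins
  pm <- suppressWarnings(plant_variant(
    mos, ped, scenario_spec("multiple_introductions", "chr2", 99e6, k = 2,
                            target_carriers = 8), samples))
  expect_equal(nrow(pm$origins), 2)
  expect_equal(length(unique(pm$origins$founder_hap)), 2)

  # familial: all carriers descend from the chosen origin individual
  pf <- suppressWarnings(plant_variant(
    mos, ped, scenario_spec("familial_recent", "chr3", 55e6,
                            target_carriers = 3), samples))
  expect_lte(length(pf$carriers), 4)
  for (cr in pf$carriers) {
    expect_true(pf$origins$individual %in%
                  c(cr, ancestors(ped, cr)))
  }
})

test_that("bundles round-trip through disk and agree with their truth record", {
  cfg <- demography_config(n_founder_couples = 14, n_decades = 8,
                           max_couples = 16, couples_growth = 1, seed = 404)
  scn <- list(scenario_spec("founder_single", "chr1", 100e6,
                            target_carriers = 6),
              scenario_spec("familial_recent", "chr2", 80e6,
                            target_carriers = 3))
  b <- suppressWarnings(simulate_bundle(cfg, scn, n_samples = 30,
                                        ibd_scope = "carriers"))
  dir <- file.path(withr::local_tempdir(), "bundle")
  write_bundle(b, dir)
  expect_error(write_bundle(b, dir), "force")
  back <- read_bundle(dir)
  expect_equal(back$ped$ind, b$ped$ind)
  expect_equal(unname(back$panel$geno), unname(b$panel$geno))
  expect_equal(back$panel$samples, b$panel$samples)
  expect_equal(nrow(back$segset), nrow(b$segset))
  # truth allele counts equal the VCF allele counts
  for (v in names(b$truth)) {
    expect_equal(sum(back$panel$geno[, v], na.rm = TRUE),
                 b$truth[[v]]$alt_count)
  }
  # carriers listed in the truth are exactly the dose >= 1 samples
  for (v in names(b$truth)) {
    got <- rownames(back$panel$geno)[!is.na(back$panel$geno[, v]) &
                                       back$panel$geno[, v] >= 1]
    expect_setequal(got, unlist(b$truth[[v]]$carriers))
  }
})
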