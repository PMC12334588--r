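# Pedigree fixtures built in code, plus brute-force oracles kept
# deliberately independent of the package's own algorithms.

ped_df <- function(...) {
  df <- data.frame(..., stringsAsFactors = FALSE)
  names(df)[1:3] <- c("id", "father", "mother")
  df
}

trio_ped <- function(probands = "C1") {
  pedigree(ped_df(id = c("F1", "M1", "C1"),
                  father = c("0", "0", "F1"),
                  mother = c("0", "0", "M1"),
                  sex = c("M", "F", "F")),
           probands = probands)
}

# full sibs S1, S2 plus their parents
sib_ped <- function(probands = character()) {
  pedigree(ped_df(id = c("F1", "M1", "S1", "S2"),
                  father = c("0", "0", "F1", "F1"),
                  mother = c("0", "0", "M1", "M1"),
                  sex = c("M", "F", "M", "F")),
           probands = probands)
}

# X and Y are first cousins (through brothers A and B)
cousins_ped <- function() {
  pedigree(ped_df(
    id     = c("GF", "GM", "A", "B", "SA", "SB", "X", "Y"),
    father = c("0", "0", "GF", "GF", "0", "0", "A", "B"),
    mother = c("0", "0", "GM", "GM", "0", "0", "SA", "SB"),
    sex    = c("M", "F", "M", "M", "F", "F", "M", "F")))
}

# X and Y are double first cousins (both parental couples are sib pairs)
double_cousins_ped <- function() {
  pedigree(ped_df(
    id     = c("G1", "G2", "G3", "G4", "A1", "A2", "B1", "B2", "X", "Y"),
    father = c("0", "0", "0", "0", "G1", "G1", "G3", "G3", "A1", "A2"),
    mother = c("0", "0", "0", "0", "G2", "G2", "G4", "G4", "B1", "B2"),
    sex    = c("M", "F", "M", "F", "M", "M", "F", "F", "M", "F")))
}

# K is the child of first cousins X and Y
child_of_cousins_ped <- function() {
  p <- cousins_ped()
  ind <- rbind(p$ind,
               data.frame(id = "K", father = "X", mother = "Y", sex = "U",
                          marriage_year = NA_integer_, region = NA_character_,
                          origin = "unknown"))
  pedigree(ind)
}

# Layered random-mating pedigree, independent of simulate_pedigree().
# Parents are drawn from all previously created individuals, so the result
# is acyclic by construction and can contain loops/inbreeding.
random_pedigree <- function(n_founders = 8, n_gen = 4, kids_per_gen = 8,
                            seed = 1, year0 = 1700) {
  set.seed(seed)
  id <- sprintf("R%03d", seq_len(n_founders))
  father <- rep(NA_character_, n_founders)
  mother <- rep(NA_character_, n_founders)
  sex <- rep(c("M", "F"), length.out = n_founders)
  year <- rep(year0, n_founders)
  for (g in seq_len(n_gen)) {
    males <- id[sex == "M"]
    females <- id[sex == "F"]
    for (k in seq_len(kids_per_gen)) {
      nid <- sprintf("R%03d", length(id) + 1L)
      id <- c(id, nid)
      father <- c(father, sample(males, 1))
      mother <- c(mother, sample(females, 1))
      sex <- c(sex, sample(c("M", "F"), 1))
      year <- c(year, year0 + 10L * g)
    }
  }
  father[is.na(father)] <- "0"
  mother[is.na(mother)] <- "0"
  pedigree(ped_df(id = id, father = father, mother = mother, sex = sex,
                  marriage_year = year))
}

# brute-force occurrence oracle: enumerate the expanded ancestry tree
occurrences_brute <- function(ped, id, max_gen = Inf) {
  climb <- function(who, gens_left) {
    if (gens_left <= 0) return(character(0))
    i <- match(who, ped$ind$id)
    out <- character(0)
    for (p in c(ped$ind$father[i], ped$ind$mother[i])) {
      if (!is.na(p)) out <- c(out, p, climb(p, gens_left - 1))
    }
    out
  }
  walked <- climb(id, max_gen)
  if (!length(walked)) return(stats::setNames(integer(0), character(0)))
  tab <- table(walked)
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}

# brute-force ADR from the occurrence oracle
adr_brute <- function(ped, probands) {
  all_occ <- list()
  for (p in probands) {
    occ <- occurrences_brute(ped, p)
    for (nm in names(occ)) {
      all_occ[[nm]] <- (if (is.null(all_occ[[nm]])) 0L else all_occ[[nm]]) + occ[[nm]]
    }
  }
  total <- sum(unlist(all_occ))
  list(n_distinct = length(all_occ), occurrence = total,
       adr = length(all_occ) / total)
}

# compact IBD segment construction: one row per call argument
make_segs <- function(...) {
  rows <- list(...)
  df <- do.call(rbind, lapply(rows, function(r) {
    data.frame(sample1 = r[[1]], hap1 = as.integer(r[[2]]),
               sample2 = r[[3]], hap2 = as.integer(r[[4]]),
               chrom = r[[5]], start = as.numeric(r[[6]]),
               end = as.numeric(r[[7]]), lod = 3,
               length_cM = (as.numeric(r[[7]]) - as.numeric(r[[6]])) / 1e6,
               stringsAsFactors = FALSE)
  }))
  ibd_segments(df)
}

tiny_manifest <- function() {
  m <- data.frame(chrom = c("chr1", "chr2"),
                  length_bp = c(100e6, 50e6),
                  length_cM = c(100, 50))
  attr(m, "total_cM") <- 150
  m
}

# small two-cluster panel built by hand
toy_panel <- function(geno, clusters, cohorts = NULL) {
  ns <- nrow(geno)
  samples <- data.frame(
    sample = sprintf("S%02d", seq_len(ns)),
    cluster = rep_len(clusters, ns),
    cohort = if (is.null(cohorts)) "cohort1" else rep_len(cohorts, ns),
    stringsAsFactors = FALSE)
  variants <- data.frame(
    variant_id = paste0("v", seq_len(ncol(geno))),
    chrom = "chr1", pos = seq_len(ncol(geno)) * 1000L,
    ref = "A", alt = "T", stringsAsFactors = FALSE)
  genotype_panel(geno, samples, variants)
}
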