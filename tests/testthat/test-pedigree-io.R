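test_that("a trio file reads into a validated pedigree, invariant to row order", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tfather\tmother\tsex",
               "C1\tF1\tM1\tF",
               "F1\t0\t0\tM",
               "M1\t0\t0\tF"), path)
  ped <- read_pedigree(path, probands = "C1")
  expect_s3_class(ped, "pedigree")
  expect_equal(ped$n, 3)
  expect_equal(sum(!is.na(ped$fidx)), 1)  # only C1 has a known father
  occ <- ancestor_occurrences(ped, "C1")
  expect_equal(occ, c(F1 = 1L, M1 = 1L))

  # reordering rows changes nothing observable
  writeLines(c("id\tfather\tmother\tsex",
               "M1\t0\t0\tF",
               "F1\t0\t0\tM",
               "C1\tF1\tM1\tF"), path)
  ped2 <- read_pedigree(path, probands = "C1")
  occ2 <- ancestor_occurrences(ped2, "C1")
  expect_equal(occ2[order(names(occ2))], occ[order(names(occ))])
  expect_equal(completeness(ped2, "C1", 2)$mean,
               completeness(ped, "C1", 2)$mean)
})

test_that("validation rejects duplicates, dangling parents and cycles by name", {
  expect_error(pedigree(ped_df(id = c("A", "A"), father = c("0", "0"),
                               mother = c("0", "0"))),
               "duplicate id.*A")
  expect_error(pedigree(ped_df(id = "A", father = "GHOST", mother = "0")),
               "missing id.*GHOST")
  # X is its own grandparent
  expect_error(pedigree(ped_df(id = c("X", "P"),
                               father = c("P", "X"),
                               mother = c("0", "0"))),
               "cycle")
  # parental sex inconsistency is reported, not silently fixed
  expect_warning(pedigree(ped_df(id = c("A", "B"), father = c("0", "A"),
                                 mother = c("0", "0"),
                                 sex = c("F", "M"))),
                 "father but sex F")
})

test_that("write/read round trip is the identity on structure and attributes", {
  ped <- random_pedigree(n_founders = 10, n_gen = 4, kids_per_gen = 10, seed = 11)
  ped$probands <- utils::tail(ped$ind$id, 5)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_pedigree(ped, path)
  ped2 <- read_pedigree(path)
  expect_equal(ped2$ind, ped$ind)
  expect_equal(ped2$probands, ped$probands)
  expect_equal(ped2$depth, ped$depth)
})

test_that("ancestor occurrences count distinct genealogical paths", {
  # parents who are full first cousins: the shared great-grandparents of the
  # child appear twice in the expanded tree
  ped <- pedigree(ped_df(
    id     = c("GG1", "GG2", "A", "B", "SA", "SB", "X", "Y", "K"),
    father = c("0", "0", "GG1", "GG1", "0", "0", "A", "B", "X"),
    mother = c("0", "0", "GG2", "GG2", "0", "0", "SA", "SB", "Y"),
    sex    = c("M", "F", "M", "M", "F", "F", "M", "F", "U")))
  occ <- ancestor_occurrences(ped, "K")
  expect_equal(occ[["GG1"]], 2L)
  expect_equal(occ[["GG2"]], 2L)
  expect_equal(occ[["X"]], 1L)
  expect_equal(sum(occ), 2 + 4 + 4)  # full slots at g = 1..3

  # 4 distinct grandparents -> 6 ancestors, occurrence 1 each
  ped2 <- double_cousins_ped()
  occ2 <- ancestor_occurrences(ped2, "X", max_gen = 2)
  expect_equal(sort(names(occ2)), sort(c("A1", "B1", "G1", "G2", "G3", "G4")))
  expect_true(all(occ2 == 1L))
})

test_that("occurrences match exhaustive path enumeration on random pedigrees", {
  for (seed in 1:6) {
    ped <- random_pedigree(n_founders = 6, n_gen = 6, kids_per_gen = 6,
                           seed = seed)
    for (id in sample(ped$ind$id, 5)) {
      got <- ancestor_occurrences(ped, id)
      want <- occurrences_brute(ped, id)
      expect_equal(got[order(names(got))], want[order(names(want))],
                   info = paste("seed", seed, "id", id))
    }
  }
})

test_that("completeness counts known ancestors per expected slot", {
  trio <- trio_ped()
  cp <- completeness(trio, "C1", 2)
  expect_equal(unname(cp$mean), c(1, 0))

  # exactly one known grandparent -> C_2 = 0.25
  ped <- pedigree(ped_df(id = c("GF", "P", "M", "C"),
                         father = c("0", "GF", "0", "P"),
                         mother = c("0", "0", "0", "M")))
  expect_equal(unname(completeness(ped, "C", 2)$mean), c(1, 0.25))

  # fully known 5-generation ancestry, built by explicit binary expansion
  ped5 <- local({
    rows <- list(list(id = "P", father = "F1", mother = "M1"))
    frontier <- c("F1", "M1")
    for (g in 2:6) {
      nxt <- character(0)
      for (a in frontier) {
        if (g <= 5) {
          rows[[length(rows) + 1]] <- list(id = a, father = paste0(a, "f"),
                                           mother = paste0(a, "m"))
          nxt <- c(nxt, paste0(a, "f"), paste0(a, "m"))
        } else {
          rows[[length(rows) + 1]] <- list(id = a, father = "0", mother = "0")
        }
      }
      frontier <- nxt
    }
    df <- do.call(rbind, lapply(rows, as.data.frame))
    pedigree(df)
  })
  expect_equal(unname(completeness(ped5, "P", 5)$mean), rep(1, 5))
  expect_error(completeness(trio, character(0), 2), "empty proband")
})

test_that("completeness gate retains exactly the perfectly complete probands", {
  trio <- trio_ped()
  expect_equal(filter_by_completeness(trio, 1)$probands, "C1")
  expect_warning(out <- filter_by_completeness(trio, 2), "no proband")
  expect_length(out$probands, 0)

  # occurrence/completeness consistency: total occurrences equal the summed
  # known-slot counts
  ped <- random_pedigree(seed = 3)
  for (id in sample(ped$ind$id, 4)) {
    cp <- completeness(ped, id, 10)
    expect_equal(sum(ancestor_occurrences(ped, id)),
                 sum(cp$per_proband[1, ] * 2^(1:10)))
  }
})

test_that("first-degree pruning among probands is deterministic and idempotent", {
  # parent and child probands: the lexicographically larger id goes
  ped <- trio_ped(probands = c("C1", "F1"))
  out <- remove_first_degree_probands(ped)
  expect_equal(out$probands, "C1")

  # three full siblings -> exactly one retained
  sibs <- pedigree(ped_df(id = c("F", "M", "S1", "S2", "S3"),
                          father = c("0", "0", "F", "F", "F"),
                          mother = c("0", "0", "M", "M", "M")),
                   probands = c("S1", "S2", "S3"))
  out2 <- remove_first_degree_probands(sibs)
  expect_equal(out2$probands, "S1")

  # property: no first-degree pair remains, and the operation is idempotent
  ped3 <- random_pedigree(n_founders = 8, n_gen = 3, kids_per_gen = 12, seed = 9)
  ped3$probands <- ped3$ind$id
  pruned <- remove_first_degree_probands(ped3)
  expect_equal(nrow(first_degree_pairs(pruned, pruned$probands)), 0)
  expect_equal(remove_first_degree_probands(pruned)$probands, pruned$probands)
})

test_that("recent-immigrant flagging respects the generation depth", {
  ids <- c("E4", "A3", "A2", "A1", "P")
  ped <- pedigree(ped_df(id = ids,
                         father = c("0", "E4", "A3", "A2", "A1"),
                         mother = c("0", "0", "0", "0", "0"),
                         sex = "M",
                         origin = c("external", "local", "local", "local",
                                    "local")),
                  probands = "P")
  # external ancestor at generation 4 is beyond depth 3
  expect_length(flag_recent_immigrants(ped, depth = 3), 0)
  expect_equal(flag_recent_immigrants(ped, depth = 4), "P")

  # a proband who is itself external is flagged unless count_self is off
  ped2 <- pedigree(ped_df(id = "Z", father = "0", mother = "0",
                          origin = "external"), probands = "Z")
  expect_equal(flag_recent_immigrants(ped2), "Z")
  expect_length(flag_recent_immigrants(ped2, count_self = FALSE), 0)
})
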