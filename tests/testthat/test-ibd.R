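test_that("IBD segment files parse with canonical pair ordering", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "ibd.tsv")
  writeLines(c("sample1\thap1\tsample2\thap2\tchrom\tstart\tend\tlod\tlength_cM",
               "SB\t2\tSA\t1\tchr1\t1000000\t5000000\t4.2\t4"), path)
  seg <- read_ibd_segments(path)
  expect_equal(nrow(seg), 1)
  expect_equal(seg$sample1, "SA")   # canonicalised
  expect_equal(seg$hap1, 1)         # haplotypes swapped with the samples
  expect_equal(seg$hap2, 2)
  expect_equal(seg$pair, "SA|SB")

  # duplicated lines are both kept (merging is explicit)
  writeLines(c("sample1\thap1\tsample2\thap2\tchrom\tstart\tend\tlod\tlength_cM",
               "SA\t1\tSB\t1\tchr1\t1\t100\t3\t0.1",
               "SA\t1\tSB\t1\tchr1\t1\t100\t3\t0.1"), path)
  expect_equal(nrow(read_ibd_segments(path)), 2)

  writeLines(c("sample1\thap1\tsample2\thap2\tchrom\tstart\tend\tlod\tlength_cM",
               "SA\t1\tSB\t1\tchr1\t500\t100\t3\t0.1"), path)
  expect_error(read_ibd_segments(path), "start >= end")
})

test_that("pair segment merging unions overlaps within and across combinations", {
  seg <- make_segs(list("a", 1, "b", 1, "chr1", 100, 200),
                   list("a", 1, "b", 1, "chr1", 150, 300),
                   list("a", 2, "b", 1, "chr1", 1000, 2000))
  m <- merge_pair_segments(seg, c("a", "b"))
  combo11 <- m$per_combo[m$per_combo$hap1 == 1 & m$per_combo$hap2 == 1, ]
  expect_equal(c(combo11$start, combo11$end), c(100, 300))
  expect_equal(nrow(m$per_combo), 2)       # disjoint combos stay separate
  expect_equal(m$union$start, c(100, 1000))

  # empty pair
  m0 <- merge_pair_segments(seg, c("a", "zzz"))
  expect_equal(nrow(m0$per_combo), 0)
})

test_that("interval union length matches IRanges and a coverage-array oracle", {
  set.seed(99)
  for (rep in 1:20) {
    n <- sample(1:12, 1)
    start <- sample(1:500, n, replace = TRUE)
    end <- start + sample(1:80, n, replace = TRUE)
    got <- merge_intervals(start, end)
    ir <- IRanges::reduce(IRanges::IRanges(start = start, end = end - 1L))
    expect_equal(got$start, IRanges::start(ir))
    expect_equal(got$end, IRanges::end(ir) + 1L)
    covered <- logical(600)
    for (k in seq_len(n)) covered[start[k]:(end[k] - 1L)] <- TRUE
    expect_equal(sum(got$end - got$start), sum(covered))
  }
})

test_that("IBD proportion normalises merged sharing by twice the genome", {
  man <- tiny_manifest()   # 150 cM total
  # one haplotype combination covering the whole genome: parent-offspring
  seg <- make_segs(list("c", 1, "p", 1, "chr1", 1, 100e6 + 1),
                   list("c", 1, "p", 2, "chr2", 1, 50e6 + 1))
  expect_equal(ibd_proportion(seg, c("p", "c"), man), 0.5)
  expect_equal(ibd_proportion(seg, c("c", "p"), man), 0.5)  # symmetric
  expect_equal(ibd_proportion(seg, c("x", "y"), man), 0)    # no segments
  # overlapping duplicates do not double-count
  dup <- make_segs(list("a", 1, "b", 1, "chr1", 1, 60e6),
                   list("a", 1, "b", 1, "chr1", 30e6, 60e6))
  expect_equal(ibd_proportion(dup, c("a", "b"), man),
               (60e6 - 1) * 1e-6 / 300, tolerance = 1e-9)
})

test_that("relatedness graph edges fire on IBD, kinship, or both", {
  man <- tiny_manifest()
  # a-b share 30% of the genome; cousins X-Y have kinship 0.0625 and no IBD
  seg <- make_segs(list("a", 1, "b", 1, "chr1", 1, 90e6))  # 90 cM / 300 = 0.3
  ped <- cousins_ped()
  g <- build_relatedness_graph(c("a", "b", "X", "Y"), seg, man, ped = ped)
  expect_equal(igraph::ecount(g), 2)
  eattr <- igraph::E(g)$criterion
  ends <- igraph::as_edgelist(g)
  ibd_edge <- which(apply(ends, 1, function(r) setequal(r, c("a", "b"))))
  kin_edge <- which(apply(ends, 1, function(r) setequal(r, c("X", "Y"))))
  expect_equal(eattr[ibd_edge], "ibd")
  expect_equal(eattr[kin_edge], "kinship")
  # below both thresholds: no edge
  g2 <- build_relatedness_graph(c("a", "b"), seg, man, ibd_prop = 0.5)
  expect_equal(igraph::ecount(g2), 0)
})

test_that("greedy unrelated subset is deterministic and near-optimal", {
  tri <- igraph::make_full_graph(3)
  tri <- igraph::set_vertex_attr(tri, "name", value = c("a", "b", "c"))
  expect_length(max_unrelated_subset(tri), 1)

  lone <- igraph::make_empty_graph(4, directed = FALSE)
  lone <- igraph::set_vertex_attr(lone, "name", value = letters[1:4])
  expect_equal(max_unrelated_subset(lone), letters[1:4])

  brute_mis <- function(g) {
    nm <- igraph::V(g)$name
    best <- 0
    for (k in seq_len(2^length(nm)) - 1) {
      sel <- nm[bitwAnd(k, 2^(seq_along(nm) - 1)) > 0]
      if (length(sel) > best &&
          igraph::ecount(igraph::induced_subgraph(g, sel)) == 0)
        best <- length(sel)
    }
    best
  }
  set.seed(4)
  for (rep in 1:8) {
    n <- sample(6:12, 1)
    g <- igraph::sample_gnp(n, 0.3)
    g <- igraph::set_vertex_attr(g, "name", value = sprintf("n%02d", 1:n))
    got <- max_unrelated_subset(g)
    expect_equal(igraph::ecount(igraph::induced_subgraph(g, got)), 0)
    expect_gte(length(got), ceiling(brute_mis(g) / 2))
    expect_identical(got, max_unrelated_subset(g))  # deterministic
  }
})

test_that("sharing at a position counts overlapping carrier pairs", {
  # 5 carriers, all 10 pairs overlap the position
  carriers <- sprintf("c%d", 1:5)
  rows <- list()
  for (i in 1:4) for (j in (i + 1):5)
    rows[[length(rows) + 1]] <- list(carriers[i], 1, carriers[j], 1,
                                     "chr1", 40e6, 60e6)
  seg <- do.call(make_segs, rows)
  expect_equal(sharing_at_position(seg, carriers, "chr1", 50e6), 1.0)
  # position outside every segment
  expect_equal(sharing_at_position(seg, carriers, "chr1", 80e6), 0)
  # a window can rescue a near miss
  expect_equal(sharing_at_position(seg, carriers, "chr1", 61e6,
                                   window_bp = 2e6), 1.0)

  # 6 carriers, exactly 3 of 15 pairs share at the position
  c6 <- sprintf("d%d", 1:6)
  seg6 <- make_segs(list(c6[1], 1, c6[2], 1, "chr1", 10e6, 30e6),
                    list(c6[3], 2, c6[4], 1, "chr1", 15e6, 25e6),
                    list(c6[5], 1, c6[6], 2, "chr1", 19e6, 21e6),
                    list(c6[1], 1, c6[3], 1, "chr1", 70e6, 90e6))
  expect_equal(sharing_at_position(seg6, c6, "chr1", 20e6), 0.2)
  expect_error(sharing_at_position(seg6, "d1", "chr1", 20e6), "at least 2")
})

test_that("classification follows the familial / founder / multiple decision order", {
  man <- tiny_manifest()
  # 5 mutually unrelated carriers all sharing at the position -> founder
  carriers <- sprintf("c%d", 1:5)
  rows <- list()
  for (i in 1:4) for (j in (i + 1):5)
    rows[[length(rows) + 1]] <- list(carriers[i], 1, carriers[j], 1,
                                     "chr1", 49e6, 52e6)
  seg <- do.call(make_segs, rows)
  cls <- classify_variant("v", carriers, seg, man, "chr1", 50e6)
  expect_equal(cls$label, "founder")
  expect_equal(cls$n_unrelated, 5)
  expect_equal(cls$pair_sharing_at_pos, 1)

  # 6 carriers forming one related clique -> familial
  rows2 <- list()
  c6 <- sprintf("f%d", 1:6)
  for (i in 1:5) for (j in (i + 1):6)
    rows2[[length(rows2) + 1]] <- list(c6[i], 1, c6[j], 1, "chr1", 1, 90e6)
  seg2 <- do.call(make_segs, rows2)
  cls2 <- classify_variant("v", c6, seg2, man, "chr1", 50e6)
  expect_equal(cls2$label, "familial")
  expect_lt(cls2$n_unrelated, 5)

  # 5 unrelated carriers with sub-threshold sharing -> multiple introductions
  seg3 <- make_segs(list(carriers[1], 1, carriers[2], 1, "chr1", 49e6, 52e6))
  cls3 <- classify_variant("v", carriers, seg3, man, "chr1", 50e6)
  expect_equal(cls3$label, "multiple_introductions")

  expect_error(classify_variant("v", character(0), seg, man, "chr1", 1),
               "empty carrier")
})

test_that("classification is invariant to carrier and row order", {
  man <- tiny_manifest()
  carriers <- sprintf("c%d", 1:5)
  rows <- list()
  for (i in 1:4) for (j in (i + 1):5)
    rows[[length(rows) + 1]] <- list(carriers[i], 1, carriers[j], 1,
                                     "chr1", 49e6, 52e6)
  seg <- do.call(make_segs, rows)
  set.seed(2)
  seg_sh <- ibd_segments(seg[sample(nrow(seg)), setdiff(names(seg), "pair")])
  cls1 <- classify_variant("v", carriers, seg, man, "chr1", 50e6)
  cls2 <- classify_variant("v", rev(carriers), seg_sh, man, "chr1", 50e6)
  expect_equal(cls1$label, cls2$label)
  expect_equal(cls1$n_unrelated, cls2$n_unrelated)
  expect_equal(cls1$pair_sharing_at_pos, cls2$pair_sharing_at_pos)
})
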