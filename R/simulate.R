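#' Demography configuration for the synthetic founder-effect generator
#'
#' Describes a regional settlement: a small founder pool arriving at the
#' settlement decade, a declining schedule of immigrant couples, high
#' fertility, and predominantly within-region mating. Decades act as
#' generation ticks: couples married in one decade produce the children who
#' marry in the next.
#'
#' @param regions region labels.
#' @param n_founder_couples founder couples per region at settlement
#'   (recycled over regions).
#' @param settlement_decade first decade of each region (recycled).
#' @param n_decades number of decades simulated.
#' @param offspring_mean Poisson mean number of children per couple.
#' @param immigrant_schedule regions x decades matrix of immigrant couples
#'   per decade; default `round(0.4 * n_founder_couples * 0.88^t)`, a
#'   non-increasing schedule emulating declining immigration.
#' @param p_within_region probability a marriage is within-region.
#' @param max_couples cap on couples marrying per region in the settlement
#'   decade (recycled); bounds population size.
#' @param couples_growth per-decade multiplicative growth of the marriage
#'   cap (recycled), emulating sustained population expansion after
#'   settlement; the cap at decade t since settlement is
#'   `round(max_couples * couples_growth^t)`.
#' @param seed integer seed (mandatory).
#' @return object of class `demography_config`.
#' @export
demography_config <- function(regions = "isolate",
                              n_founder_couples = 60,
                              settlement_decade = 1660,
                              n_decades = 30,
                              offspring_mean = 2.6,
                              immigrant_schedule = NULL,
                              p_within_region = 0.95,
                              max_couples = 50,
                              couples_growth = 1.06,
                              seed) {
  if (missing(seed)) stop("demography_config: seed is mandatory")
  nr <- length(regions)
  n_founder_couples <- rep_len(n_founder_couples, nr)
  settlement_decade <- rep_len(settlement_decade, nr)
  max_couples <- rep_len(max_couples, nr)
  couples_growth <- rep_len(couples_growth, nr)
  stopifnot(n_decades >= 1, offspring_mean >= 0,
            p_within_region >= 0, p_within_region <= 1,
            all(n_founder_couples >= 0), all(max_couples >= 1),
            all(couples_growth > 0))
  if (is.null(immigrant_schedule)) {
    immigrant_schedule <- t(vapply(seq_len(nr), function(r)
      round(0.4 * n_founder_couples[r] * 0.88^(seq_len(n_decades) - 1)),
      numeric(n_decades)))
  }
  immigrant_schedule <- matrix(immigrant_schedule, nrow = nr, ncol = n_decades)
  stopifnot(all(immigrant_schedule >= 0))
  structure(list(regions = regions, n_founder_couples = n_founder_couples,
                 settlement_decade = settlement_decade, n_decades = n_decades,
                 offspring_mean = offspring_mean,
                 immigrant_schedule = immigrant_schedule,
                 p_within_region = p_within_region, max_couples = max_couples,
                 couples_growth = couples_growth,
                 seed = as.integer(seed)),
            class = "demography_config")
}

#' Simulate a pedigree under a founder-effect demography
#'
#' Generation-synchronous simulation: each decade, immigrant founder
#' couples arrive per the schedule (`origin = "external"`), the previous
#' decade's children marry (within-region with probability
#' `p_within_region`, avoiding parent-offspring and sibling unions), and
#' each couple draws a Poisson number of children. Marriage years are
#' recorded; children who never marry remain with an unknown marriage
#' year. Fully reproducible given the config seed.
#'
#' @param config a [demography_config].
#' @return a [pedigree] (no probands designated; see [select_probands()]).
#' @export
simulate_pedigree <- function(config) {
  stopifnot(inherits(config, "demography_config"))
  set.seed(config$seed)
  id <- character(0); father <- character(0); mother <- character(0)
  sex <- character(0); myear <- integer(0); region <- character(0)
  origin <- character(0)
  counter <- 0L
  new_ind <- function(sx, f, m, yr, reg, org) {
    counter <<- counter + 1L
    nid <- sprintf("I%06d", counter)
    id <<- c(id, nid); father <<- c(father, f); mother <<- c(mother, m)
    sex <<- c(sex, sx); myear <<- c(myear, yr); region <<- c(region, reg)
    origin <<- c(origin, org)
    nid
  }
  nr <- length(config$regions)
  # singles available to marry in the current decade, per region
  singles <- stats::setNames(vector("list", nr), config$regions)
  for (r in seq_len(nr)) singles[[r]] <- list(id = character(0), f = character(0),
                                              m = character(0), sex = character(0))
  year0 <- min(config$settlement_decade)
  for (t in seq_len(config$n_decades)) {
    year <- year0 + 10L * (t - 1L)
    couples <- list()
    for (r in seq_len(nr)) {
      reg <- config$regions[r]
      since <- (year - config$settlement_decade[r]) %/% 10L
      if (since < 0) next
      n_new <- if (since == 0) config$n_founder_couples[r] else
        config$immigrant_schedule[r, min(since + 1L, config$n_decades)]
      if (n_new > 0) for (k in seq_len(n_new)) {
        h <- new_ind("M", NA_character_, NA_character_, year, reg, "external")
        w <- new_ind("F", NA_character_, NA_character_, year, reg, "external")
        couples[[length(couples) + 1L]] <- list(f = h, m = w, region = reg,
                                                n_imm = TRUE)
      }
    }
    # native marriages, capped by the growing per-decade schedule
    since_all <- pmax((year - config$settlement_decade) %/% 10L, 0L)
    n_native_cap <- stats::setNames(
      round(config$max_couples * config$couples_growth^since_all),
      config$regions)
    for (cp in couples) n_native_cap[cp$region] <- n_native_cap[cp$region] - 1L
    pools <- lapply(singles, function(s) {
      list(male = which(s$sex == "M"), female = which(s$sex == "F"))
    })
    taken <- lapply(singles, function(s) logical(length(s$id)))
    for (r in sample(seq_len(nr))) {
      reg <- config$regions[r]
      males <- pools[[r]]$male
      if (!length(males)) next
      for (mi in sample(males, length(males))) {
        if (n_native_cap[reg] <= 0) break
        if (taken[[r]][mi]) next
        r2 <- if (nr == 1 || stats::runif(1) < config$p_within_region) r else
          sample(setdiff(seq_len(nr), r), 1)
        fem <- pools[[r2]]$female
        fem <- fem[!taken[[r2]][fem]]
        if (!length(fem)) next
        # avoid first-degree unions: no shared known parent
        ok <- fem
        mf <- singles[[r]]$f[mi]; mm <- singles[[r]]$m[mi]
        shared <- (!is.na(singles[[r2]]$f[fem]) & singles[[r2]]$f[fem] %in% stats::na.omit(c(mf))) |
                  (!is.na(singles[[r2]]$m[fem]) & singles[[r2]]$m[fem] %in% stats::na.omit(c(mm)))
        ok <- fem[!shared]
        if (!length(ok)) next
        fi <- if (length(ok) == 1) ok else sample(ok, 1)
        taken[[r]][mi] <- TRUE
        taken[[r2]][fi] <- TRUE
        hid <- singles[[r]]$id[mi]; wid <- singles[[r2]]$id[fi]
        myear[match(hid, id)] <- year
        myear[match(wid, id)] <- year
        region[match(wid, id)] <- reg   # spouse joins the couple's region
        couples[[length(couples) + 1L]] <- list(f = hid, m = wid, region = reg,
                                                n_imm = FALSE)
        n_native_cap[reg] <- n_native_cap[reg] - 1L
      }
    }
    if (!length(couples))
      stop("simulate_pedigree: no couples formed in decade ", year,
           "; population extinct (increase founders, immigration or fertility)")
    # offspring become the next decade's marriage pool
    for (r in seq_len(nr)) singles[[r]] <- list(id = character(0), f = character(0),
                                                m = character(0), sex = character(0))
    if (t < config$n_decades) {
      for (cp in couples) {
        nk <- stats::rpois(1, config$offspring_mean)
        if (nk == 0) next
        r <- match(cp$region, config$regions)
        for (k in seq_len(nk)) {
          sx <- if (stats::runif(1) < 0.5) "M" else "F"
          cid <- new_ind(sx, cp$f, cp$m, NA_integer_, cp$region, "local")
          singles[[r]]$id <- c(singles[[r]]$id, cid)
          singles[[r]]$f <- c(singles[[r]]$f, cp$f)
          singles[[r]]$m <- c(singles[[r]]$m, cp$m)
          singles[[r]]$sex <- c(singles[[r]]$sex, sx)
        }
      }
    }
  }
  pedigree(data.frame(id = id, father = father, mother = mother, sex = sex,
                      marriage_year = myear, region = region, origin = origin,
                      stringsAsFactors = FALSE))
}

#' Designate probands by marriage-year window and region
#'
#' @param ped a [pedigree].
#' @param from_year,to_year inclusive marriage-year window.
#' @param region optional region filter.
#' @return the pedigree with its proband set replaced.
#' @export
select_probands <- function(ped, from_year, to_year, region = NULL) {
  sel <- !is.na(ped$ind$marriage_year) &
    ped$ind$marriage_year >= from_year & ped$ind$marriage_year <= to_year
  if (!is.null(region)) sel <- sel & ped$ind$region %in% region
  ped$probands <- ped$ind$id[sel]
  ped
}

#' Default synthetic genome manifest
#'
#' Four autosomes totalling 1000 cM (10 Morgans) with a uniform
#' 1 cM / Mb map, a desk-scale stand-in for a full genome.
#'
#' @return genome manifest data.frame (`chrom length_bp length_cM`).
#' @export
default_genome <- function() {
  m <- data.frame(chrom = paste0("chr", 1:4),
                  length_bp = c(350e6, 300e6, 200e6, 150e6),
                  length_cM = c(350, 300, 200, 150))
  attr(m, "total_cM") <- sum(m$length_cM)
  m
}

# --- haplotype mosaics -----------------------------------------------------

# A track is list(end = increasing breakpoints (last = chrom length in bp),
# id = value on (prev_end, end]). Founder haplotype ids are integers unique
# per haplotype; src tracks carry the parental haplotype (1/2) instead.

track_value_at <- function(track, pos) {
  track$id[min(findInterval(pos, track$end, left.open = TRUE) + 1L,
               length(track$end))]
}

# collapse adjacent intervals with equal values
track_simplify <- function(ends, ids) {
  if (length(ids) > 1) {
    keep <- c(ids[-1] != ids[-length(ids)], TRUE)
    ends <- ends[keep]; ids <- ids[keep]
  }
  list(end = ends, id = ids)
}

# extract sub-track of (lo, hi] from a track (lo/hi are continuous cut
# positions, almost surely distinct from stored breakpoints)
track_slice <- function(track, lo, hi) {
  j1 <- findInterval(lo, track$end) + 1L
  j2 <- min(findInterval(hi, track$end, left.open = TRUE) + 1L,
            length(track$end))
  ends <- track$end[seq.int(j1, j2)]
  ends[length(ends)] <- hi
  list(end = ends, id = track$id[seq.int(j1, j2)])
}

# one meiosis: recombine a parent's two tracks (Haldane model: Poisson
# crossovers at rate = length in Morgans, uniform positions, random start)
gamete <- function(h1, h2, L_bp, L_morgan) {
  k <- stats::rpois(1, L_morgan)
  h0 <- sample.int(2, 1)
  if (k == 0) {
    src <- list(end = L_bp, id = h0)
    return(list(hap = if (h0 == 1) h1 else h2, src = src))
  }
  cuts <- sort(stats::runif(k, 0, L_bp))
  bounds <- c(cuts, L_bp)
  hs <- rep(c(h0, 3L - h0), length.out = length(bounds))
  ends <- numeric(0); ids <- integer(0)
  lo <- 0
  for (b in seq_along(bounds)) {
    sl <- track_slice(if (hs[b] == 1) h1 else h2, lo, bounds[b])
    ends <- c(ends, sl$end); ids <- c(ids, sl$id)
    lo <- bounds[b]
  }
  list(hap = track_simplify(ends, ids),
       src = track_simplify(bounds, hs))
}

#' Gene-drop founder haplotypes through a pedigree
#'
#' Founders receive unique haplotype ids; every meiosis recombines the
#' transmitting parent's two haplotypes under the Haldane (no-interference)
#' model with crossover count Poisson at the chromosome's Morgan length and
#' uniform positions. Haplotype 1 of each individual is the paternal
#' gamete, haplotype 2 the maternal one. Source tracks record which
#' parental haplotype each interval came from, so allele descent through
#' any internal individual can be traced exactly.
#'
#' @param ped a [pedigree].
#' @param manifest genome manifest (see [default_genome()]).
#' @param seed integer seed.
#' @param keep optional ids: mosaics are materialised only for these
#'   individuals and their ancestor closure (individuals without sampled
#'   descendants contribute nothing to a panel, so skipping them is exact).
#' @return object of class `haplotype_mosaic`: nested list
#'   `tracks[[individual]][[chrom]]` with `hap` (two founder-id tracks) and
#'   `src` (two parental-source tracks; NULL for founders), plus the
#'   manifest and the pedigree's ids. Individuals outside the `keep`
#'   closure have NULL tracks.
#' @export
drop_haplotypes <- function(ped, manifest, seed, keep = NULL) {
  set.seed(seed)
  n <- ped$n
  nc <- nrow(manifest)
  Lbp <- manifest$length_bp
  Lm <- manifest$length_cM / 100
  tracks <- vector("list", n)
  ord <- order(ped$depth)
  if (!is.null(keep)) {
    closure <- union(as.character(keep), ancestors(ped, keep))
    ord <- ord[ped$ind$id[ord] %in% closure]
  }
  for (i in ord) {
    f <- ped$fidx[i]; m <- ped$midx[i]
    percr <- vector("list", nc)
    for (c in seq_len(nc)) {
      if (is.na(f) && is.na(m)) {
        percr[[c]] <- list(hap = list(list(end = Lbp[c], id = 2L * i - 1L),
                                      list(end = Lbp[c], id = 2L * i)),
                           src = list(NULL, NULL))
      } else {
        # unknown single parents are treated as unique founders on the fly
        g1 <- if (!is.na(f)) gamete(tracks[[f]][[c]]$hap[[1]],
                                    tracks[[f]][[c]]$hap[[2]], Lbp[c], Lm[c])
          else list(hap = list(end = Lbp[c], id = 2L * i - 1L), src = NULL)
        g2 <- if (!is.na(m)) gamete(tracks[[m]][[c]]$hap[[1]],
                                    tracks[[m]][[c]]$hap[[2]], Lbp[c], Lm[c])
          else list(hap = list(end = Lbp[c], id = 2L * i), src = NULL)
        percr[[c]] <- list(hap = list(g1$hap, g2$hap),
                           src = list(g1$src, g2$src))
      }
    }
    tracks[[i]] <- percr
  }
  structure(list(tracks = tracks, manifest = manifest, ids = ped$ind$id),
            class = "haplotype_mosaic")
}

#' @export
print.haplotype_mosaic <- function(x, ...) {
  cat(sprintf("<haplotype_mosaic> %d individuals x %d chromosomes\n",
              length(x$tracks), nrow(x$manifest)))
  invisible(x)
}

mosaic_index <- function(mosaic, ids) {
  i <- match(as.character(ids), mosaic$ids)
  if (anyNA(i)) stop("id(s) not in mosaic: ",
                     paste(ids[is.na(i)], collapse = ", "))
  i
}

# founder haplotype id carried by (individual, chrom index, hap, pos)
founder_id_at <- function(mosaic, ind_idx, chrom_idx, hap, pos) {
  track_value_at(mosaic$tracks[[ind_idx]][[chrom_idx]]$hap[[hap]], pos)
}

#' Derive exact IBD segments from a haplotype mosaic
#'
#' For each sample pair and haplotype combination, emits the maximal
#' intervals on which both haplotypes carry the same founder haplotype id,
#' converted to cM via the manifest, keeping segments of at least `min_cM`.
#' This is descent-based truth: no detector false positives or negatives
#' beyond the length cutoff.
#'
#' @param mosaic a [drop_haplotypes()] result.
#' @param samples sample ids among which to derive segments (all unordered
#'   pairs), or a 2-column matrix/data.frame of specific pairs.
#' @param min_cM minimum segment length in cM (the detector-style cutoff;
#'   default 2).
#' @return an [ibd_segments] set.
#' @export
derive_ibd_segments <- function(mosaic, samples, min_cM = 2) {
  pairs <- if (is.matrix(samples) || is.data.frame(samples)) {
    as.matrix(samples)
  } else {
    samples <- unique(as.character(samples))
    if (length(samples) < 2) matrix(character(0), ncol = 2) else
      t(utils::combn(samples, 2))
  }
  man <- mosaic$manifest
  out <- vector("list", 0L)
  for (p in seq_len(nrow(pairs))) {
    a <- mosaic_index(mosaic, pairs[p, 1])
    b <- mosaic_index(mosaic, pairs[p, 2])
    for (c in seq_len(nrow(man))) {
      rate <- man$length_cM[c] / man$length_bp[c]
      for (ha in 1:2) for (hb in 1:2) {
        ta <- mosaic$tracks[[a]][[c]]$hap[[ha]]
        tb <- mosaic$tracks[[b]][[c]]$hap[[hb]]
        ends_u <- sort(unique(c(ta$end, tb$end)))
        starts_u <- c(0, ends_u[-length(ends_u)])
        mid <- (starts_u + ends_u) / 2
        ida <- ta$id[findInterval(mid, ta$end) + 1L]
        idb <- tb$id[findInterval(mid, tb$end) + 1L]
        eq <- ida == idb
        r <- rle(eq)
        stop_i <- cumsum(r$lengths)
        start_i <- stop_i - r$lengths + 1L
        for (k in which(r$values)) {
          lo <- starts_u[start_i[k]]
          hi <- ends_u[stop_i[k]]
          len <- (hi - lo) * rate
          if (len >= min_cM) {
            out[[length(out) + 1L]] <- data.frame(
              sample1 = pairs[p, 1], hap1 = ha,
              sample2 = pairs[p, 2], hap2 = hb,
              chrom = man$chrom[c],
              start = floor(lo) + 1, end = floor(hi) + 1,
              lod = round(3 + len, 2), length_cM = round(len, 4),
              stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  if (!length(out)) {
    return(ibd_segments(data.frame(
      sample1 = character(0), hap1 = integer(0), sample2 = character(0),
      hap2 = integer(0), chrom = character(0), start = numeric(0),
      end = numeric(0), lod = numeric(0), length_cM = numeric(0))))
  }
  ibd_segments(do.call(rbind, out))
}

#' Scenario specification for variant planting
#'
#' @param kind `"founder_single"`, `"multiple_introductions"` or
#'   `"familial_recent"`.
#' @param chrom,pos variant position.
#' @param k number of independent origin haplotypes (multiple-introduction
#'   scenarios; >= 2).
#' @param target_carriers desired carrier count among the panel samples.
#' @param max_gen_above for familial scenarios: the origin individual sits
#'   at most this many generations above the sampled carriers (default 3).
#' @return `scenario_spec` list.
#' @export
scenario_spec <- function(kind, chrom, pos, k = 3, target_carriers = 10,
                          max_gen_above = 3) {
  kind <- match.arg(kind, c("founder_single", "multiple_introductions",
                            "familial_recent"))
  if (kind == "multiple_introductions" && k < 2)
    stop("multiple_introductions requires k >= 2")
  structure(list(kind = kind, chrom = chrom, pos = pos, k = k,
                 target_carriers = target_carriers,
                 max_gen_above = max_gen_above),
            class = "scenario_spec")
}

#' Plant a variant on the mosaic under a scenario
#'
#' `founder_single`: the alternate allele rides exactly one founder
#' haplotype, chosen so that the number of panel carriers is as close as
#' possible to the target; genotypes are read off the mosaic at the
#' position. `multiple_introductions`: the same allele rides `k` distinct
#' founder haplotypes with approximately balanced carrier groups.
#' `familial_recent`: the allele arises on one haplotype of a non-founder
#' individual at most `max_gen_above` generations above the sampled
#' carriers and descends through recorded transmissions only.
#'
#' @param mosaic a [drop_haplotypes()] result.
#' @param ped the pedigree the mosaic was dropped on.
#' @param scenario a [scenario_spec].
#' @param samples panel sample ids to genotype.
#' @param origin_samples samples among which the origin haplotype is chosen
#'   and carrier targets evaluated (default all of `samples`; restrict to
#'   one cluster to plant a regionally enriched variant).
#' @return list: `variant_id`, `chrom`, `pos`, `kind`, `origins`
#'   (description of origin haplotypes), `genotypes` (named 0/1/2 vector
#'   over `samples`), `carriers` (samples with dose >= 1).
#' @export
plant_variant <- function(mosaic, ped, scenario, samples,
                          origin_samples = samples) {
  samples <- as.character(samples)
  origin_samples <- as.character(origin_samples)
  stopifnot(all(origin_samples %in% samples))
  cidx <- match(scenario$chrom, mosaic$manifest$chrom)
  if (is.na(cidx)) stop("scenario chromosome not in manifest: ", scenario$chrom)
  sidx <- mosaic_index(mosaic, samples)
  fid <- vapply(sidx, function(i)
    c(founder_id_at(mosaic, i, cidx, 1, scenario$pos),
      founder_id_at(mosaic, i, cidx, 2, scenario$pos)), numeric(2))
  # fid: 2 x n matrix of founder haplotype ids at the position
  if (scenario$kind %in% c("founder_single", "multiple_introductions")) {
    k <- if (scenario$kind == "founder_single") 1L else as.integer(scenario$k)
    cand <- carrier_counts_by_origin(
      fid[, samples %in% origin_samples, drop = FALSE])
    if (nrow(cand) < k)
      stop("only ", nrow(cand), " founder haplotypes present at position; ",
           "cannot plant ", k, " origins")
    per <- scenario$target_carriers / k
    cand <- cand[order(abs(cand$carriers - per), -cand$carriers, cand$origin), ]
    origins <- cand$origin[seq_len(k)]
    dose <- colSums(matrix(fid %in% origins, nrow = 2))
    achieved <- sum(dose[samples %in% origin_samples] > 0)
    if (achieved < scenario$target_carriers)
      warning("planted ", scenario$kind, ": achieved ", achieved,
              " carriers (target ", scenario$target_carriers, ")")
    origin_desc <- data.frame(founder_hap = origins)
  } else {
    pick <- pick_familial_origin(mosaic, ped, scenario, samples, cidx,
                                 origin_samples = origin_samples)
    dose <- pick$dose
    origin_desc <- data.frame(individual = pick$origin_id, hap = pick$hap)
    if (sum(dose > 0) < 2)
      warning("familial plant achieved ", sum(dose > 0), " carriers")
  }
  genotypes <- stats::setNames(as.integer(dose), samples)
  vid <- sprintf("%s:%d:%s", scenario$chrom, as.integer(scenario$pos),
                 scenario$kind)
  list(variant_id = vid, chrom = scenario$chrom, pos = scenario$pos,
       kind = scenario$kind, origins = origin_desc, genotypes = genotypes,
       carriers = samples[dose > 0])
}

carrier_counts_by_origin <- function(fid) {
  ids <- sort(unique(as.numeric(fid)))
  carriers <- vapply(ids, function(o) sum(colSums(fid == o) > 0), numeric(1))
  data.frame(origin = ids, carriers = carriers)
}

# children-of index: list over individuals of child indices
children_index <- function(ped) {
  kids <- vector("list", ped$n)
  for (side in list(ped$fidx, ped$midx)) {
    has <- which(!is.na(side))
    sp <- split(has, side[has])
    for (nm in names(sp)) {
      at <- as.integer(nm)
      kids[[at]] <- c(kids[[at]], sp[[nm]])
    }
  }
  kids
}

# choose a recent non-founder origin whose descent gives a small familial
# carrier group among the samples; returns the per-sample dose
pick_familial_origin <- function(mosaic, ped, scenario, samples, cidx,
                                 origin_samples = samples,
                                 max_candidates = 80) {
  cand_ids <- setdiff(ancestors(ped, origin_samples,
                                max_gen = scenario$max_gen_above),
                      ped$ind$id[is.na(ped$fidx) & is.na(ped$midx)])
  if (!length(cand_ids)) stop("no non-founder candidate origin found")
  cand_ids <- sort(cand_ids)
  if (length(cand_ids) > max_candidates)
    cand_ids <- sample(cand_ids, max_candidates)
  kids <- children_index(ped)
  best <- NULL
  for (oid in cand_ids) {
    for (h in 1:2) {
      dose <- familial_descent_dose(mosaic, ped, kids, oid, h, cidx,
                                    scenario$pos, samples)
      nc <- sum(dose > 0)
      if (nc >= 1) {
        # prefer groups of >= 2 carriers near (never above) the target
        score <- abs(nc - scenario$target_carriers) +
          1000 * (nc > scenario$target_carriers) + 5000 * (nc < 2)
        if (is.null(best) || score < best$score)
          best <- list(origin_id = oid, hap = h, dose = dose, score = score)
      }
    }
  }
  if (is.null(best))
    stop("no familial origin with a sampled carrier at the position")
  best
}

# exact descent of an allele arising on (origin individual, haplotype):
# a child inherits iff its source track at the position points at the
# parental haplotype carrying the allele; only the origin's descendants
# are visited
familial_descent_dose <- function(mosaic, ped, kids, origin_id, origin_hap,
                                  cidx, pos, samples) {
  o <- ped_index(ped, origin_id)
  carr <- matrix(FALSE, ped$n, 2)
  carr[o, origin_hap] <- TRUE
  # breadth-first down the descendant closure in depth order
  frontier <- o
  seen <- logical(ped$n)
  seen[o] <- TRUE
  desc <- integer(0)
  while (length(frontier)) {
    ch <- unique(unlist(kids[frontier]))
    ch <- ch[!seen[ch]]
    if (!length(ch)) break
    seen[ch] <- TRUE
    desc <- c(desc, ch)
    frontier <- ch
  }
  for (i in desc[order(ped$depth[desc])]) {
    if (is.null(mosaic$tracks[[i]])) next
    for (h in 1:2) {
      par <- if (h == 1) ped$fidx[i] else ped$midx[i]
      if (is.na(par) || !any(carr[par, ])) next
      src <- mosaic$tracks[[i]][[cidx]]$src[[h]]
      if (is.null(src)) next
      carr[i, h] <- carr[par, track_value_at(src, pos)]
    }
  }
  sidx <- mosaic_index(mosaic, samples)
  as.integer(carr[sidx, 1]) + as.integer(carr[sidx, 2])
}
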