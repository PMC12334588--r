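---
title: "Genealogical founder-effect statistics and rare founder-variant classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genealogical founder-effect statistics and rare founder-variant classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`founderkit` characterises regional founder effects from two directions:
deep genealogies (kinship, inbreeding and ancestor-diversity trajectories)
and genotype panels (a screen for rare pathogenic variants enriched in a
regional cluster, followed by an identity-by-descent classification of how
each candidate entered the population). Because the data that motivate
this design — multi-century parish-register genealogies joined to cohort
genotypes — are access-restricted wherever they exist, the package ships a
synthetic demography and gene-dropping generator so that every stage can
be validated against known ground truth.

## The genealogical statistics

**Kinship.** The kinship coefficient $\varphi(i,j)$ is the probability
that two alleles drawn at random, one from each individual, are identical
by descent. It is computed with the classical recursion
$\varphi(i,i) = \tfrac12\bigl(1+\varphi(f_i,m_i)\bigr)$ and, for $i \ne j$
with $x$ the individual of greater generation depth,
$\varphi(x,y) = \tfrac12\bigl(\varphi(f_x,y)+\varphi(m_x,y)\bigr)$, where
unknown parents contribute zero. `kinship()` memoises pairwise calls;
`kinship_matrix()` fills the all-pairs matrix in one topological pass,
which is what the decade series use. An independent implementation of
Wright's path-counting formula
($\sum_A \sum_{\text{paths}} (1/2)^{n_1+n_2+1}(1+F_A)$ over common
ancestors $A$ and non-overlapping path pairs) lives in `kinship_oracle()`
and is used only for verification: the two routes agree to $10^{-12}$ on
randomly generated pedigrees, which is the package's error budget for
carrying kinship in double precision rather than exact rationals.

**Inbreeding.** $F_i = \varphi(f_i, m_i)$ — the kinship of the pair that
actually reproduced — and 0 when a parent is unknown. The identity
$\varphi(i,i) = \tfrac12(1+F_i)$ is asserted across all fixtures.

**Ancestors' diversity ratio.** For a proband set, every distinct
genealogical path from a proband to an ancestor counts as one
*occurrence*; the ADR is the number of distinct ancestors divided by the
total occurrence. It equals 1 exactly when no ancestor appears twice and
decreases as ancestry concentrates on few founders, which is the
signature of a founder effect. Occurrences are computed by dynamic
programming over the parent DAG (one generation-stratified sweep), and
the same sweep seeded with all probands at once yields population totals.

**Decade series.** Each ancestor of the probands is assigned to the
decade of its own marriage year (ancestors without a marriage year are
excluded and tallied; assigning by the couple's union decade would be the
natural alternative and differs only for spouses married across a decade
boundary). Per decade the package reports the mean kinship over all
unordered member pairs — after dropping one member of every first-degree
pair, since parent–offspring and sibling pairs would otherwise dominate
small decades — the mean inbreeding over members, and the ADR restricted
to that decade's ancestors. First-degree pruning is re-run independently
within each decade rather than inherited from the proband-level cleaning:
the decades partition different individuals, so a single global pruning
would be ill-defined.

**Confidence intervals.** The reference implementations behind the
published decade plots compute "95% confidence intervals estimated using
1000 simulations" without stating what is resampled. Here the intervals
are nonparametric percentile bootstraps over decade members (for kinship
and inbreeding) and over probands (for the ADR, drawing a fixed-size
subset without replacement per replicate so that regions of different
sizes are comparable). When a kinship resample duplicates an individual,
pairs formed by two copies of the same person are excluded from the
numerator, keeping the replicate statistic consistent with the point
estimate, which excludes self-pairs. All resampling is seeded and
bit-for-bit reproducible.

## Pedigree cleaning

Cleaning follows the order completeness → first-degree → recent
immigrants. Completeness at generation $g$ is the number of known
ancestors occupying the $2^g$ expected slots divided by $2^g$ (slots are
counted separately even when inbreeding collapses the tree); the gate
retains probands with $C_g = 1$ for all $g \le$ `completeness_gen`
(3 by default, matching the rural-region setting; 5 is the appropriate
value where deeper records are required). First degree means
parent–offspring or full siblings; half-siblings are not first degree.
Pruning processes conflicting pairs in lexicographic order and drops the
larger id, a deterministic stand-in for the random choice used on the
real data (a seeded-random mode is available). Recent-immigrant removal
flags probands with an `external` origin within `immigrant_depth`
generations; whether the proband's own flag counts is configurable
(`count_self`), since the "within three generations" convention does not
say whether the proband is generation 0 or 1 — it defaults to counting.

## The variant screen

For a focal cluster A against a comparison cluster B, each annotated
variant passes through six ordered filters: (1) clinical class
pathogenic / likely pathogenic / conflicting, or a previously reported
founder variant; (2) review status not among the no-assertion statuses;
(3) type SNP / insertion / deletion; (4) at least 5 heterozygous carriers
in A; (5) relative frequency difference
$\mathrm{RFD} = (\mathrm{MAF}_A - \mathrm{MAF}_B)/\mathrm{MAF}_A \ge 0.10$;
(6) reference-population MAF $\le 5\%$. The first failing rule is
recorded per variant and tallied. MAF is the raw alternate-allele
frequency among non-missing genotypes (the screened pathogenic alleles
are alternates; folding to the minor allele applies only to the external
reference comparison). A variant absent from A cannot be screened — the
RFD denominator is zero — and is reported as a distinct condition, not a
filter failure. Carriers are heterozygotes only; homozygous-alternate
individuals are counted and reported separately because recessive cases
may exist. The display form "1/x" rounds $n/n_\text{het}$ half away from
zero; the exact fraction is always retained. The 5-carrier rule is
applied at the screening step, before any restriction to unrelated
individuals; the unrelated restriction enters in classification and in
the final reported rates.

## IBD classification

Segments arrive in a refinedIBD-style table (pair of samples and
haplotypes, position, LOD, cM length) and are canonicalised so the
lexicographically smaller sample comes first. The IBD-sharing proportion
of a pair is the merged segment length in cM, summed over the four
haplotype combinations, divided by twice the genome length, so its
expectation is about $2\varphi$ and the 0.125 cutoff corresponds to
third-degree relatives (0.125 = 2 × 0.0625, the companion kinship
cutoff). Merged interval lengths are converted with each chromosome's
uniform cM/bp rate from the genome manifest. Two samples are *related*
when either the IBD proportion reaches 0.125 or (when a pedigree covers
them) the genealogical kinship reaches 0.0625; the maximally unrelated
subset is obtained by greedily deleting the highest-degree node of the
relatedness graph (lexicographic tie-break) until no edge remains — exact
maximum independent set is NP-hard, and the greedy heuristic is the
standard choice for relatedness pruning, kept deterministic.

A candidate variant is classified in a fixed order: fewer than 5
unrelated carriers → **familial** (the familial test precedes the founder
test, mirroring the exclusion-first narrative of the original procedure);
otherwise, if at least 50% of all carrier pairs share at least one
segment overlapping the variant position → **founder**; otherwise →
**multiple introductions**. "Around the variant's position" is read
strictly: the segment must cover the position itself (`window_bp = 0`),
with a symmetric window available for looser matching. The sharing
denominator uses all carrier pairs, not only unrelated ones, and the
computation is per focal cluster; both are configurable. Final carrier
rates are recomputed on the maximally unrelated sample of the cluster.

## The synthetic generator

`simulate_pedigree()` runs a generation-synchronous demography in which
each decade is one generation tick: the founder couples arrive at the
settlement decade, immigrant couples arrive per a non-increasing schedule
(default `round(0.4 · founders · 0.88^t)`), the previous decade's
children marry — within region with probability 0.95, never a parent or
sibling — capped by a marriage quota that grows 6% per decade, and each
couple draws a Poisson(2.6) number of children. Real inter-generation
intervals are closer to 30 years; compressing them to the decade grid
keeps the decade axis ordinal without changing any of the statistics
being exercised. The growth dimension matters: without post-settlement
expansion, a 30-generation isolate of a few hundred individuals
accumulates so much background relatedness that typical sample pairs
exceed the third-degree cutoffs, which is not the regime the pipeline
targets — in the motivating data, well over 95% of genotyped individuals
are unrelated at those cutoffs. The defaults (60 founder couples, cap 50
growing 6%/decade, declining immigration, 30 decades) end with a few
hundred marriages per decade and late-decade mean kinship of order
$10^{-2}$: a deliberately scaled-down isolate that still shows rising
inbreeding, low ADR and mostly-unrelated samples.

`drop_haplotypes()` gene-drops founder haplotypes with Haldane crossovers
(Poisson count at the chromosome's Morgan length, uniform positions, no
interference) on a default genome of 4 autosomes totalling 10 Morgans
with a uniform 1 cM/Mb map; `derive_ibd_segments()` then emits
descent-exact IBD segments above a cM cutoff (2 cM by default, the
detector setting being emulated). Variant planting covers three origin
hypotheses: a single founder haplotype, $k \ge 2$ independent founder
haplotypes, and a recent familial mutation arising on a non-founder
haplotype at most 3 generations above the samples and descending only
through recorded transmissions. Origins are chosen to bring the panel
carrier count as close as possible to the target (never above it for
familial plants, which must stay small), and the generator warns when a
target is unreachable.

What the generator does **not** model, and what passing tests therefore
do not show: detector error (derived segments have no false positives or
negatives beyond the length cutoff, unlike real phased-genotype IBD
calls), genotyping error and missingness, non-uniform recombination maps
or interference, mutation beyond the single planted allele per scenario,
remarriage and non-monogamy, and record-linkage noise in the pedigree
itself. Results on real data inherit all of those error sources.

## Numerical and design notes

* Kinship in double precision; agreement with the path-counting oracle to
  $10^{-12}$ is enforced in the tests.
* All tie-breaks (pruning, greedy independent set, occurrence ranking)
  are lexicographic on ids, making every cleaning step deterministic;
  seeded-random alternatives exist where the original procedure chose
  randomly.
* Degenerate inputs are errors, not silent results: empty proband sets,
  probands without ancestors, a zero focal MAF in the RFD, fewer than two
  carriers at a sharing computation, clusters without samples.
* Decades with fewer than two members after pruning are omitted from the
  kinship series with a warning rather than reported as NaN.
* Bootstrap CIs are percentile intervals; with 1000 replicates the
  2.5%/97.5% quantiles are stable to the third digit in the regimes used
  here.
* Problem sizes in the shipped analyses: pedigrees of roughly 8–16
  thousand individuals, panels of 150 samples per cluster, 50-replicate
  recovery experiments on single-region isolates — sizes chosen so the
  full suite runs on a laptop-class single core.

## Known limitations

The IBD-proportion normalisation assumes the detector covers the whole
manifest genome; restricting the manifest to well-covered autosomes is
the caller's responsibility. The greedy unrelated subset is a
well-behaved heuristic, not an optimum, so `n_unrelated` can undercount
by a small margin on adversarial graphs. The ADR bootstrap treats the
proband list as the population (finite-population corrections are not
applied). Familial planting requires at least one recent ancestor with
two or more sampled carrier descendants; in very sparse panels it falls
back to a single-carrier family with a warning.
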