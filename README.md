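# founderkit

Tools for characterising **regional founder effects** from deep
genealogies and genotype panels, written for population and statistical
geneticists working on regional isolates — populations (such as Quebec's
regional clusters) where a small founder pool, high fertility and
within-region marriage concentrated ancestry and raised the frequency of
specific rare pathogenic variants.

The package implements two analysis arms over a common set of containers
(pedigrees, genotype panels, IBD segment sets) plus a synthetic generator
that makes every stage verifiable without access-restricted data:

**Genealogy arm.**

* Kinship coefficient φ(i,j) by the classical recursion
  (φ(i,i) = ½(1+φ(f_i,m_i)); φ(x,y) = ½(φ(f_x,y)+φ(m_x,y)) recursing on
  the deeper individual), with an independent Wright path-counting oracle
  (Σ_A Σ_paths (½)^(n₁+n₂+1)(1+F_A)) used in the tests;
* inbreeding F_i = φ(f_i, m_i), the kinship of the pair that actually
  reproduced;
* the ancestors' diversity ratio
  ADR = (distinct ancestors) / (total ancestor occurrence), where an
  ancestor's occurrence counts every appearance in the probands' expanded
  genealogical trees — low values flag concentrated ancestry;
* per-decade trajectories of all three with seeded percentile-bootstrap
  95% confidence intervals, after the standard cleaning: genealogical
  completeness gate (C_g = 1 up to generation 3 by default), deterministic
  first-degree pruning, recent-immigrant removal.

**Variant arm.**

* A screen for regionally enriched rare pathogenic variants: ClinVar-style
  class/review/type filters, ≥ 5 heterozygous carriers, relative
  frequency difference RFD = (MAF_A − MAF_B)/MAF_A ≥ 10 %, reference
  population MAF ≤ 5 %; carrier rates displayed "1/x";
* classification of each passing variant from identity-by-descent
  sharing among its carriers: **familial** if fewer than 5 carriers are
  mutually unrelated (IBD proportion < 0.125 and kinship < 0.0625),
  **founder** if ≥ 50 % of carrier pairs share IBD over the variant's
  position, otherwise **multiple introductions**.

**Synthetic generator.** A generation-synchronous founder demography
(founder couples, declining immigrant-couple schedule, Poisson fertility,
within-region mating, growing marriage quota), Haldane gene-dropping of
founder haplotypes along a 4-autosome / 10-Morgan genome, descent-exact
IBD segments with a 2 cM cutoff, and variant planting under
single-founder, multiple-introduction and recent-familial scenarios, all
with a recorded truth.

## Worked example

The `analysis/` directory holds the three pipeline drivers; they write
their tables under `results/`.

```sh
Rscript analysis/01_simulate.R    # pedigree + two-cluster bundle
Rscript analysis/02_genealogy.R   # decade series, ADR, cleaning report
Rscript analysis/03_variants.R    # screen + IBD classification
```

Step 2 prints (seed 1):

```
               step probands_before removed probands_after
1      completeness            1054      12           1042
2      first_degree            1042     760            282
3 recent_immigrants             282      11            271
kinship    ... last decade 1940: 0.03205 [0.03116, 0.03284]
inbreeding ... last decade 1940: 0.03118 [0.02989, 0.03255]
Spearman trend of decade mean inbreeding: 0.994
Overall ADR: 2.083e-07 (5588 distinct ancestors / 2.683e+10 occurrences)
```

Reading this: of 1054 probands married in the simulated isolate's last
two decades, 271 survive cleaning (sibling-rich cohorts lose many
probands to first-degree pruning). Mean kinship and inbreeding among the
ancestors of each decade rise steadily after settlement — the Spearman
trend of 0.99 is the founder-effect signature — reaching ≈ 0.032 in the
final decade of this deliberately small synthetic isolate. The overall
ADR is tiny because occurrences are counted over the full expanded trees,
which grow exponentially with depth; the per-decade ADR series is the
comparable quantity.

Step 3 prints:

```
Screened 5 variants: 4 pass, 1 excluded
                            variant_id      maf_a       maf_b       rfd cr_a  cr_b  pass   first_fail
1        chr1:120000000:founder_single 0.04666667 0.003333333 0.9285714 1/11 1/150  TRUE         <NA>
...
4       chr4:110000000:familial_recent 0.01333333 0.000000000 1.0000000 1/38     0 FALSE min_carriers
Counts: 3 founder, 0 familial, 1 multiple introductions, 1 excluded
Truth agreement on classified variants: 4 / 4
```

The three planted single-founder variants pass the screen (carrier rate
1/11 in the isolate cluster against 1/150 in the urban cluster, RFD
≈ 0.93) and are classified founder (≥ 50 % pair sharing at the position,
≥ 5 unrelated carriers); the three-origin plant shows only 27 % sharing
and is called multiple introductions; the small familial plant falls
below the 5-carrier screen rule, exactly as designed.

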