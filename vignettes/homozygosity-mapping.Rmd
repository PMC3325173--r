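---
title: "Homozygosity mapping and recessive variant discovery: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Homozygosity mapping and recessive variant discovery: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rohscan)
```

`rohscan` discovers candidate recessive disease genes in families whose
affected children show elevated genome-wide homozygosity.  This vignette is
the package's account of the underlying models: what each stage assumes,
which parameters matter and why they default the way they do, what the
simulator does and does not emulate, and where the method's known
limitations lie.

## Autozygosity and the inbreeding coefficient

When both parents inherit a chromosomal segment from a common ancestor,
their child can receive two copies of the same ancestral haplotype — the
segment is *autozygous* (identical by descent, IBD).  The expected
autozygous fraction of the genome is the inbreeding coefficient F, the
probability that the two alleles at a locus are IBD.  `rohscan` computes F
exactly by the recursive kinship algorithm: F(child) equals the kinship
coefficient of its parents, with

* phi(a, a) = (1 + F(a)) / 2,
* phi(a, b) = [phi(father(a), b) + phi(mother(a), b)] / 2, recursing
  through whichever individual lies deeper in the pedigree (so the
  recursion never walks through an ancestor of the other argument),
* missing parent links contributing 0.

```{r}
c(first_cousin  = inbreeding_coefficient(make_cousin_pedigree(1), "CH1"),
  second_cousin = inbreeding_coefficient(make_cousin_pedigree(2), "CH1"))
```

First-cousin offspring are expected to be autozygous over 6.25% of the
genome, second-cousin offspring over ~1.6%.  Individual realizations vary
widely: autozygous segments arrive in large blocks (mean length ~100/k cM
after k meioses around the loop, ~17 cM for first cousins), so a genome
contains relatively few of them.

## ROH detection

Autozygous segments are detected as *runs of homozygosity* in SNP-array
genotypes.  A run is a maximal marker interval satisfying, within it:

* at most `max_consecutive_het = 2` consecutive heterozygous calls;
* at most `max_het_per_window = 3` heterozygous calls in every window of
  `window_size = 10` consecutive markers lying fully inside the run (runs
  shorter than the window apply only the consecutive rule);
* homozygous first and last markers — runs never begin or end on a
  heterozygous or missing call.

Reported runs must exceed `min_length_cM = 5` (strict, matching the "> 5 cM"
convention for plotting and counting runs) and span at least
`min_markers = 25` markers — the marker floor is our guard against
sparse-region artifacts where two markers could span "5 cM".  Heterozygote
tolerance absorbs genotyping error inside true autozygous segments; missing
calls are neutral (they are not heterozygous, do not break a run, but do
occupy window positions).

Two deliberate contracts deserve emphasis:

* **Maximal-interval semantics.**  The detector returns every maximal
  interval satisfying the rules; it is verified against a brute-force
  enumeration oracle in the test suite.  Because validity is hereditary on
  homozygous-bounded subintervals, maximal runs can *overlap* in contrived
  heterozygote patterns.  Genome summaries therefore quote the sum of
  segment lengths (overlap is vanishingly rare in realistic data), while
  the monotonicity properties in the tests are stated on union coverage,
  where they hold exactly.
* **Length convention.**  A segment's genetic length is the cM distance
  between its first and last markers, with no extension toward flanking
  markers — conservative and reproducible.

The X chromosome is excluded for male samples (hemizygous by construction,
so "homozygosity" there is vacuous) and from genome-percentage
denominators.

### Sensitivity to marker density

Rule-based ROH detection is calibrated to the marker grid.  At array-scale
density (hundreds of markers per cM) chance runs exceeding 5 cM are
essentially impossible and boundary effects are negligible.  At the
desk-scale grid used by the simulator's default (1 marker per 0.1 cM,
35,000 markers), the same rules let runs leak a few markers past true
segment boundaries and occasionally assemble chance runs > 5 cM in
non-autozygous genome: in our own experiments, detected percent-in-ROH for
first-cousin offspring averages ~2 percentage points above the true
autozygous fraction, while at 0.05–0.02 cM spacing the bias shrinks to
under 0.2 points.  The detector is exact for its contract — the bias is a
property of the tolerance rules at sparse densities, and it is why
detection-level summaries on sparse grids should be read as upper bounds on
autozygosity.  The outbred-control property in the tests is accordingly run
at dense spacing (0.02 cM), where detected homozygosity in outbred genomes
stays below the 1.6% reference level.

## Shared ROH across a sibship

A candidate locus must be covered by an ROH in *every* affected child, with
allele-concordant homozygous genotypes, and must not be covered by an ROH
of an unaffected sibling.  Concordance is evaluated per marker: an interval
is broken where two affected samples are homozygous for opposite alleles.
Tolerated heterozygous calls and missing data are neutral here — the
literal alternative (requiring homozygosity at every non-missing marker)
would split intervals at exactly the error calls the detector was designed
to absorb, and would make even a single sample's shared-ROH set differ from
its own ROH set.  With one affected child and no unaffected siblings the
shared intervals are exactly that child's runs.  No minimum length is
imposed on the shared intersection: a shared core of < 1 cM inside long
individual runs is still informative for overlaying variants.

## Relatedness statistics

For a sample pair, each jointly genotyped autosomal marker contributes to
exactly one IBS class: IBS0 (opposite homozygotes), IBS1, or IBS2
(concordant genotypes), with IBS2* the heterozygous subset of IBS2.  Then

* `IBS2*_ratio = IBS2* / (IBS2* + IBS0)` — under random mating, per marker
  P(het, het) = 4p²q² and P(opposite homozygotes) = 2p²q², so the
  expectation for unrelated pairs is 2/3 *regardless of the allele
  frequency spectrum*; parent–offspring pairs have IBS0 = 0 and ratio 1;
  the ratio is undefined (returned as `NA`, with a message) when
  IBS2* + IBS0 = 0.
* `% informative = (IBS0 + IBS2*) / (IBS0 + IBS1 + IBS2)`.

Genome-wide IBD proportions Z0/Z1/Z2 are estimated by the method of
moments: observed IBS0/1/2 totals are matched to their expectations given
per-marker allele frequencies, solved sequentially, truncated at zero and
renormalized to the simplex; `PI_HAT = Z1/2 + Z2`.  We omit finite-sample
bias-correction terms: frequencies here are either supplied (simulations)
or estimated from pedigree founders, and the package's checks operate at
tolerances where the correction is immaterial.  Founder-only frequency
estimation avoids kin inflation; markers with MAF < 0.01 are excluded for
numerical stability, as is the X chromosome.  No relatedness
*classification* is performed — the statistics are reported and plotted,
thresholds being study-specific.

## Variant filtration

The exome cascade mirrors standard practice: mapping-quality thresholds are
strict (`>` 25 for SNPs, `>` 10 for indels, per the upstream caller's
conventions); variants present in a common-variant catalog are removed by
exact allele-aware matching (idempotent); consequences are classified
against transcript models:

* `splice_site`: within 2 bp of an intron boundary — the canonical GT/AG
  dinucleotides.  Variants deeper into the intron are `noncoding`;
  noncanonical splice-region variants are deliberately *not* promoted.
* `frameshift`: CDS indel with length change not divisible by 3; in-frame
  CDS indels are protein-altering and classed `coding_nonsynonymous`.
* CDS SNVs: codon translation on the coding strand (standard nuclear code,
  reverse-complemented for minus-strand models) decides
  synonymous/nonsynonymous.  The classifier is verified against an
  independent full-CDS translation oracle.

"Rare" at this stage means catalog-absent; control-cohort frequency is a
*prioritization* criterion, applied later, mirroring the cascade's order.
Three disjoint candidate streams are extracted for a proband: homozygous
(autosomal hom-alt), compound-heterozygous (genes with ≥ 2 rare deleterious
hets, excluding genes already in the homozygous stream), and X-hemizygous
(male probands).

## Segregation models

Fully penetrant recessive inheritance is assumed.  For the homozygous
model, a variant segregates when every affected child is homozygous
alternate, both parents heterozygous, and no unaffected sibling homozygous
alternate.  A homozygous-reference parent facing a homozygous-alternate
child is a `mendel_error` (sequencing error, somatic/cell-line artifact, or
de novo) and is reported as such rather than silently failed.  Affected
genotypes missing at the variant downgrade the verdict to
`segregates_incomplete` — kept visible because real families are often
partially genotyped.  Monozygotic twins, when annotated, collapse to one
informative genotype.

Compound heterozygotes are phased through the trio: a variant carried by
exactly one parent is assigned to that parent; a pair segregates when one
variant comes from each parent (*trans*), every affected sibling carries
both, and no unaffected sibling carries both.  Both-from-one-parent is
*cis* (fails); ambiguous or untransmitted origin is `unphaseable`.  With
more than two variants in a gene, all pairs are enumerated and the gene
segregates if any pair passes.  One wording ambiguity was resolved
explicitly: descriptions of unaffected siblings as "heterozygous or
homozygous for the alternate allele" are read as the *non-mutant* allele —
the implemented rule is heterozygous-or-homozygous-reference, since an
unaffected sibling homozygous for the mutation would contradict full
penetrance.

X-linked variants segregate when affected males are hemizygous alternate,
the mother heterozygous, the father hemizygous reference (or missing), and
no unaffected brother hemizygous alternate; a homozygous-reference mother
flags a `mendel_error` (maternal inheritance is what distinguishes a real
variant from a cell-line artifact).

## Prioritization

Segregating homozygous candidates are overlaid on the shared-ROH intervals;
exclusions are then applied in a fixed order — shared-ROH membership,
control prevalence, brain expression, known involvement in another
disorder, noncanonical splice annotation — recording the *first* failing
criterion (and retaining all failures for export).  Unknown annotations
never exclude.  Control prevalence excludes on any control homozygote, or
on allele frequency above a configurable ceiling defaulting to 0.5% — the
operative published rule was "zero homozygotes", and retained variants sat
at ≤ 0.07%, so the ceiling only needs to be comfortably below the ~5%
frequency at which a fully penetrant recessive allele would be implausible;
it is exposed as a parameter rather than a hidden constant.  Neuronal
activity / expression evidence is treated as supporting annotation for
ranking, never as an exclusion filter.  Cascade reports print stage
percentages with half-down rounding (77.5% prints 77), the convention that
reproduces published cascade tables cell for cell.

## Burden testing

The case/control screen counts *individuals* carrying a qualifying
recessive genotype in a gene set: homozygous (or hemizygous) alternate for
a qualifying variant, or heterozygous for two distinct qualifying variants
in one gene — unphased compound heterozygosity, appropriate for cohorts
without parents.  Qualifying variants are missense-class with allele
frequency ≤ 5% computed *within the combined cohort* (the screen is
self-contained; external counts can be substituted).  Individuals are
deduplicated across the gene set, so the reported carrier count answers
"how many individuals carry at least one qualifying recessive genotype".
Enrichment in cases is tested with a one-tailed Fisher's exact test,
implemented in log space from `lchoose` sums and verified to 1e-12 against
full hypergeometric enumeration; the direction is fixed to
enrichment-in-cases.

## The simulator

`simulate_family()` generates ground-truth data for all of the above:

* **Topologies**: outbred nuclear families, or parents joined by a first-
  or second-cousin loop (shared grand-/great-grandparental couple), plus
  custom pedigrees.
* **Map**: 22 autosomes with human-like relative genetic lengths scaled to
  3500 cM total, markers every 0.1 cM, physical positions at 1 Mb/cM; an X
  chromosome (180 cM) only for X-linked designs.
* **Founders**: haplotype alleles drawn i.i.d. per marker with alt-allele
  frequency ~ U(0.05, 0.5), the typical folded spectrum of array panels.
* **Meiosis**: Haldane model — Poisson(L/100) crossovers, uniform in cM,
  no interference, one sex-averaged map.  Descent is tracked by founder
  haplotype labels, so true autozygous segments are known exactly.
* **Noise**: genotype error 0.002 and missingness 0.005 per call, typical
  array QC residuals; both configurable, and the error model never creates
  heterozygous calls on the male X.
* **Variants**: 700 background exome variants (95% catalog-known common,
  5% rare; consequence mix 60% nonsynonymous / 30% synonymous / 5% splice /
  5% frameshift — a documented constant, as only relative filtering
  behaviour matters), with genotypes propagated through the same descent
  and control counts drawn per variant.  Causal variants are implanted on a
  founder haplotype chosen so that the model's genotype pattern holds for
  all affected and no unaffected children — for the homozygous model, on a
  haplotype shared autozygously by all affected children inside a segment
  long enough (> 5.5 cM) to be mappable, reflecting how such families are
  ascertained.  If no site exists, descent is resimulated (up to 100
  attempts).  Exome variant genotypes are emitted error-free, standing for
  validated (assay-confirmed) calls.
* **Seeds**: one seed fully determines a family; batch runs derive one
  seed per family so families are independently reproducible.

What the simulator does *not* emulate — and what passing tests therefore do
not establish about real data: linkage disequilibrium between markers,
population structure and real allele-frequency spectra, sex-specific
recombination and crossover interference, batch/cluster artifacts of array
genotyping, capture bias and depth-dependent error of exome sequencing, and
incomplete penetrance or phenocopies.

## Problem sizes and numerical choices

The test suite validates the detector against exhaustive interval
enumeration on 500 random chromosomes of up to 200 markers; the Fisher tail
against complete enumeration of every 2x2 table with N ≤ 50; the
consequence classifier against 1000 random transcripts; autozygosity
recovery on 50 first-cousin replicates at the full 3500 cM / 0.1 cM grid;
and end-to-end causal-gene recovery on 20 simulated families (the implanted
gene is expected to be the unique surviving candidate in ≥ 90% and among
survivors in all).  Truth-level autozygosity checks use 40 replicates at
0.5 cM spacing — the true IBD fraction does not depend on marker density,
so the coarser grid simply trades resolution for speed.

Numerical conventions: variant positions are 1-based (VCF convention); ROH
BED exports are 0-based half-open; missing data is "." in TSVs; PED
phenotype coding follows the PLINK dialect; per-marker allele dictionaries
are built from observed alleles, so a marker observed only in one
homozygous state reads back as homozygous reference — orientation is not
recoverable from PED data.  The `IBS2*_ratio` returns `NA` (not 0) on an
empty denominator.  Fisher p-values are clamped to (0, 1].

## Known limitations

* Rule-based ROH calls on sparse marker grids overestimate autozygosity
  (see the density analysis above); summaries should be interpreted
  relative to the panel density, or detection re-run at denser spacing.
* Maximal tolerant runs may overlap in adversarial heterozygote patterns;
  summed segment lengths can then double-count a short flank.
* Phasing uses parental carrier status only; a variant carried by both
  parents is unphaseable rather than statistically phased.
* The burden screen's compound-heterozygote rule is unphased: two
  heterozygous variants in cis count as a carrier, an acknowledged
  over-count inherent to cohorts without parental genotypes.
* Validation merging removes only proband-contradicted variants; discordant
  validation calls in other family members replace the genotype and are
  logged, not treated as removals.
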