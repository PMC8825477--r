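---
title: "Molecular karyotyping from SSR allele dosage: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Molecular karyotyping from SSR allele dosage: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(macploidy)
```

`macploidy` infers chromosome compositions of progeny from a diploid x
triploid cross using microsatellite (SSR) peak ratios, and validates the
whole inference chain against a forward simulator of triploid meiosis.
This vignette explains the models, the tunable parameters, the numerical
choices, and what the simulator does and does not emulate.

## The dosage model (MAC-PR)

At one locus in one sample, alleles are binned fragment sizes and the data
are their fluorescence signals. With per-allele amplification efficiencies
$e_a$ and an integer dosage vector $d$ ($d_a \ge 1$), the expected signal
proportion of allele $a$ is $d_a e_a / \sum_b d_b e_b$. We minimise the
squared distance between observed and expected proportions over all $d$
whose total lies in a candidate set.

Three facts shape the selection rule among candidate totals:

1. **Scalar-multiple degeneracy.** Proportions cannot distinguish $d$ from
   $2d$: configurations `ab` and `aabb` predict identical ratios. In a cross
   where the mother produces reduced (1n) eggs and shares no alleles with
   the father, every true offspring vector contains a dosage-1 maternal
   allele and is therefore *primitive* (gcd 1). Exact residual ties are
   resolved to the primitive vector, and non-primitive winners of the
   restricted second pass are reduced by their gcd afterwards. This is an
   assumption about the cross type, stated here openly; for systems with
   unreduced eggs it must be revisited.
2. **Overfitting by large totals.** Totals 5 and 6 offer a finer grid of
   expected proportions and can beat the true total's residual by a few
   $10^{-3}$ under noise, while genuinely different dosage vectors are
   separated by residual gaps of roughly $0.03$ or more. Among totals tied
   within `tie_tolerance` (default 0.01) the smallest wins.
3. **The modal prior.** Most loci of a sample share its ploidy. Totals are
   fitted twice: pass one independently per locus; pass two re-fits only
   loci deviating from the sample's modal total, restricting candidates to
   the modal value ±1 and preferring the modal total among near-ties. In a
   triploid genome, three-copy loci outnumber two-copy loci by an order of
   magnitude, so a near-tie between those readings should go to three; the
   cost is that a genuinely deviant locus whose drift crosses the tie
   threshold is pulled to the mode, which the chromosome-level aggregation
   then has to out-vote.

**Candidate totals** default to 1–6. The egg contributes exactly one copy
of each chromosome and pollen contributes 0–4, so per-locus totals of 1
(egg-only chromosomes) through 5 genuinely occur; 6 is headroom. Analyses
of material where single-copy chromosomes are implausible can restrict the
set per call.

**Amplification efficiencies** come from the parents, whose per-locus
dosages are known (2 for the diploid mother, 3 for the triploid father):
$e_a \propto \text{signal}_a / \text{dosage}_a$, renormalised to geometric
mean 1 per locus. Because each parental allele is typically observed once
per run, these raw ratios carry the full peak noise; since amplification
bias declines smoothly with fragment length, per-allele log-efficiencies
are shrunk halfway toward the fitted size trend when three or more parental
alleles are available (`shrink = 0.5`; set 0 for raw ratios). Alleles never
seen in a parent fall back to $\exp(\text{size\_decay} \cdot (s - \bar s))$.
Normalised signal proportions below `min_prop = 0.02` are treated as
stutter/background and dropped; peak binning uses single-linkage clustering
at `bin_tolerance = 0.5` bp (dinucleotide repeats are ≥ 2 bp apart), with
over-wide clusters split at their largest gap.

The `ambiguous` flag marks calls where a *different* total fits within
`tie_tolerance` — excluding the scalar-multiple family, which is resolved
by policy rather than uncertain. Ambiguous calls are retained but
down-weighted downstream.

## Chromosome calls, structural variants, ploidy

A chromosome's copy number is anchored at the sample's genome-wide modal
total whenever at least one *unambiguous* locus on that chromosome supports
it; otherwise the weighted mode of its locus totals decides (ambiguous loci
weigh 0.5, ties break toward the genome modal, then larger). The anchoring
rule reads within-chromosome deviants as segmental variants rather than
whole-chromosome changes — a tetraploid with chromosome-6 loci at
(3, 3, 4) is a tetraploid with a deletion, not a trisomic — while the
non-ambiguity requirement stops a single noise-flagged locus from dragging
a truly aneuploid chromosome back to the mode.

Maximal runs of adjacent loci (by map order) deviating in one direction
form one structural-variant event; a run covering at least half the
chromosome's loci is flagged `ambiguous`, because the data equally support
the complementary interpretation (deletion at the run vs duplication at the
rest). An event whose member loci all carried ambiguous dosage fits is
additionally `weak`.

Ploidy classification takes the euploid baseline $m \in \{3, 4\}$ as the
modal chromosome copy number (snapping to the nearer of 3/4 if outside);
any chromosome below $m$ *or* any non-weak deletion event makes the sample
`hypo-`, any chromosome above with none below `hyper-`, both directions
`complex`. Deletions demote but duplications do not promote: a genome with
four copies of every chromosome but a deleted fragment is not a full
tetraploid, whereas the converse promotion is not implied. Classification
requires 15 of 19 chromosomes called (`quorum`); zero-copy calls are
allowed by the types but have never been observed in this cross type.

## Heterozygosity and paternal transmission

$H_o$ at a locus is the fraction of genotyped individuals whose
configuration holds ≥ 2 distinct alleles — a deliberately simple
definition that is well defined across mixed ploidies; it is isolated in
one function so an allele-frequency-based alternative can be swapped in.
Chromosome values are unweighted means of member loci, rounded to 3
decimals only at report time. Paternal transmission removes one maternal
allele from the configuration (a mother-specific allele when present,
else a parent-shared one; configurations with no maternal allele are
flagged as possible null alleles and excluded) and scores whether ≥ 2
distinct alleles remain; the father must be heterozygous at the locus for
the pair to be informative. Group summaries pool over informative
(sample, locus) pairs — robust to missing loci — with sample-averaged
values reported alongside. The $H_o$–allele-count association uses the
standard Pearson correlation with its exact t-based p-value.

## The meiosis simulator

Triploid meiosis is modelled per chromosome at the chromatid level: each
homolog replicates into two sister chromatids; crossovers exchange distal
segments between chromatids of different homologs. Modes:

* **normal** (probability $1 - p_{FDR} - p_{SDR}$): each chromosome
  independently sends 1 or 2 of its 3 homologs to the pole with equal
  probability — the simplest model consistent with the unequal 1:2
  anaphase segregation of a trivalent; pairing configurations are not
  separately modelled.
* **FDR** (first-division restitution): one chromatid from *each* homolog
  — non-sister chromatids, high heterozygosity retention.
* **SDR**: the two sister chromatids of one homolog — low retention. SDR
  is included for the retention comparison even though restitution in this
  cross type is argued to be FDR; `p_sdr` defaults to 0.

Each transmitted copy is then lost with `elimination_rate` (lagging
chromosomes), and restitution gametes additionally capture a leftover
sister chromatid with `gain_rate` — the route to 4-copy chromosomes in
unreduced pollen and hence hyper-tetraploid offspring, mirroring fused
telophase-II nuclei carrying up to four marker-chromosome signals.
`gain_rate` defaults to `elimination_rate / 5`: with per-chromosome loss
around 0.05–0.06, a gain rate near 0.01 reproduces the observed ordering
of hypo- > eu- > hyper-tetraploid frequencies in this cross type. Pollen
below `viability_min_chromosomes = 29` (just above $3x/2 = 28.5$) is
rejected as inviable, encoding the absence of offspring below
$x + 3x/2$ chromosomes.

Crossovers default to `single_obligate_uniform`: one obligate crossover
per chromosome at the four-strand stage, position uniform along the arm.
Under this model the closed-form retention of parental heterozygosity is
$P(\text{proximal}) + \tfrac12 P(\text{distal}) = 0.75$ for FDR and
$P(\text{distal}) = 0.50$ for SDR, with exactly 1 and 0 when crossovers
are off. The literature's "approximately 80% vs 40%" figures rest on
unstated crossover assumptions, so the package pins its own model's
closed forms and asserts only the FDR > SDR ordering against the
literature values. `fdr_sdr_retention` redraws locus positions uniformly
each replicate by default, so the Monte-Carlo mean converges to the
closed form rather than to one particular layout's value; fixed layouts
are honoured when supplied.

Peak synthesis emits, per genotype × locus × allele,
$\text{signal} = \text{base} \cdot \text{dosage} \cdot
\text{decay}^{(s - s_{\min})} \cdot \mathrm{LogNormal}(0, \sigma)$, with
reported sizes jittered by `size_jitter = 0.08` bp around the true allele
size. Defaults: `sigma = 0.1` (10% multiplicative CV, typical of
fragment-analysis peak areas), `size_decay = 0.997` (≈ 0.3% efficiency
loss per bp), `base_signal = 2000` fluorescence units.

### The default cross

`example_parents()` builds a fully heterozygous triploid father (three
distinct alleles per locus, one per homolog) and a diploid mother whose
allele sets are, by default, disjoint from the father's at every one of
the 47 panel loci. Disjointness is what makes every true dosage vector
primitive and hence exactly recoverable from ratios; real crosses share
alleles at many loci (pass `shared_markers` to emulate that), and at
shared loci monoallelic configurations arise whose total is genuinely
undetermined by ratios — no method choice can recover those exactly, which
is why the package's exact-recovery guarantees are stated for the disjoint
design. The 47-locus panel covers all 19 chromosomes with the published
marker names and chromosome assignments; size windows and dyes are
synthetic plumbing.

## What passing tests do and do not show

On simulated data the pipeline recovers 100% of locus configurations,
chromosome calls and ploidy classes at $\sigma = 0$, and at
$\sigma = 0.1$ (n = 60, three seeds) at least 95% of chromosome calls and
90% of class labels. Real electropherograms add stutter ladders,
pull-up between dyes, null alleles, plateaued peaks and size-calling
drift that the noise model does not emulate; the simulator's accuracy
figures are therefore upper bounds on real-data performance, and its role
is to verify the inference logic, not to certify field accuracy.

## Numerical choices and degenerate inputs

Dosage enumeration is exhaustive over compositions (at most
$\binom{5}{4}$-scale spaces; no compiled code needed) and pinned in the
tests against an independently coded enumerator. Exact residual ties use a
$10^{-9}$ collapse; report rounding is 3 decimals for proportions and 1
for percentages, applied only at output. Zero total signal at a locus is
treated as missing data; chromosomes with no genotyped loci yield `NA`
calls and count against the classification quorum; an all-rejected
parameter corner in the simulator fails after a bounded number of
attempts rather than spinning. Problem sizes in the test suite (n = 10–60
offspring, $10^4$ meiosis replicates) were chosen to give sampling errors
well inside the asserted tolerances.

## Known limitations

* Inversions and translocations are invisible to marker dosage; breakpoints
  are resolved only to marker runs.
* Monoallelic loci carry no ratio information; their totals rest entirely
  on the modal prior (moot for disjoint parents, real for shared ones).
* The `Ho` definition is presence-based, not GenoDive's frequency-based
  estimator family; values are comparable within, not across, definitions.
* The meiosis model treats chromosomes independently; no chiasma
  interference, no trivalent-configuration-specific segregation.
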