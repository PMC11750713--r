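---
title: "Tumor-informed ctDNA detection at ppm tumor fractions: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tumor-informed ctDNA detection at ppm tumor fractions: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrdppm)
```

## The problem

After surgery for early-stage solid tumors, residual disease sheds circulating
tumor DNA (ctDNA) into plasma at tumor fractions that are often below 100
parts per million (ppm) of the total cell-free DNA (cfDNA), and frequently in
the single-digit ppm range. A single somatic locus sequenced at realistic
unique-molecule depth cannot resolve such fractions: at 2,000 unique molecules
per locus, a 3 ppm tumor fraction yields an expected 0.006 tumor molecules.
The tumor-informed strategy implemented here recovers sensitivity by
*aggregation*: whole-genome sequencing of tumor and matched normal tissue
yields thousands of patient-specific somatic SNVs, a bespoke hybrid-capture
panel tracks up to ~1,800 of them in plasma, and the tumor signal is summed
across all targets before a single detection decision is made. At ~1,666
unique molecules per target, the same 3 ppm sample presents an expected nine
tumor molecules across the panel — detectable, provided the background error
is suppressed far enough that nine molecules are inconsistent with noise.

The package implements the four stages of that strategy — bespoke panel
design, duplex molecular consensus, Poisson detection, and a synthetic cfDNA
simulator — as a tested pipeline that runs at desk scale without any patient
data.

## Panel design

Candidate somatic SNVs (consumed as a VCF from a tumor/matched-normal caller;
calling itself is out of scope) pass four filters:

* tumor allele frequency strictly above 10%;
* no overlap with any exclusion interval — known germline SNPs, common
  regions of clonal hematopoiesis (CHIP), high polymorphism, mapping
  difficulty, systematic bias, short tandem repeats, low complexity, and the
  HLA locus. CHIP handling is purely positional (a supplied region set) on
  top of the matched-normal subtraction performed by the caller;
* local GC content below 80%, computed over a 121 bp window centred on the
  variant (a probe-sized window; the exact width is a package choice, and
  the filter is insensitive to it on realistic sequence);
* single-nucleotide substitutions only — indels and structural variants are
  not designable targets.

Each surviving variant is scored by signal-to-noise,
$\mathrm{score} = \mathrm{AF} / e(s)$, where $e(s)$ is the background error
rate of its substitution class (below), and the top `panel_cap` (default
1,800) variants are selected. Ranking by the ratio rather than by a raw
product of AF and error rate is a deliberate design choice: maximizing
AF × error would concentrate the panel on the *noisiest* substitution
classes, inflating the aggregate noise mean and destroying the ppm-scale
limit of detection that aggregation exists to deliver; only the
high-signal/low-noise direction produces LODs in the observed 1–3 ppm range.
Ties break on (lower error rate, higher AF, genomic coordinate), so a panel
is a pure function of its inputs and a written panel is byte-reproducible.

The panel additionally carries 43 common population SNVs for quality
assurance (sample–panel mismatch and contamination checks): eligibility
requires population frequency ≥ 20%, Hardy–Weinberg equilibrium, and
location outside the HLA region; among eligible SNVs those with the most
even subpopulation representation (smallest max−min spread across
subpopulation frequencies) are chosen, with seeded tie-breaking.

After manufacture, the panel is screened against plasma from an unrelated
healthy donor: any MRD target showing *any* non-reference molecule is
deactivated in the logical panel. Deactivated targets remain in the manifest
but contribute nothing to signal, molecule totals, or noise.

### The substitution error model

Background noise is modelled per ordered substitution class (12 classes,
`A>C` … `T>G`; no strand collapsing, since targets are defined on the
reference strand). Each class rate is the ratio of aggregated alt-supporting
unique molecules to aggregated total unique molecules across a cohort of
healthy plasma samples (the assay's reference cohort exceeds 200 samples).
Rates are floored at `rate_floor` (default 1e-8) so that a class with zero
observed errors still carries a finite rate: the aggregate noise mean
$\lambda$ must never degenerate to zero, otherwise a single stray molecule
would yield $p = 0$ and spurious certainty.

## Duplex molecular consensus

Plasma reads arrive as aligned, paired fragments (SAM/BAM). No unique
molecular identifiers are assumed; deduplication is positional, with an
allele-aware correction, exactly in this order:

1. **Group** read pairs by their paired mapped positions — the (chrom,
   start, end) outer fragment coordinates. Each group is a candidate unique
   molecule.
2. **Split** groups that positional grouping has merged: a non-reference
   allele carried by a strict subset of a group's reads *and* observed in at
   least two other groups is evidence of two co-coordinate founder
   molecules, and the allele-carrying reads are isolated into their own
   group. One split (highest-frequency qualifying allele) is applied per
   group per pass; passes repeat to a fixpoint. Reads are conserved exactly.
3. **Mask** bases with Phred quality below 29.
4. **Remove** reads with more than 20% of bases masked.
5. Form a provisional majority consensus and **remove** reads whose unmasked
   bases diverge from it by more than 2.5% (denominator: positions unmasked
   in both read and provisional consensus; masking precedes divergence so
   that low-quality tails cannot dominate the distance).
6. Recompute the per-position consensus over surviving reads, **masking**
   positions with less than 90% agreement among contributing unmasked bases.
7. **Duplex check**: accept the molecule only if at least one surviving read
   derives from each original DNA strand (strand inferred from read-pair
   orientation: read1-forward = top, read1-reverse = bottom). The
   requirement is per molecule, not per base.

Rejections are typed (`single_strand`, `all_reads_removed`) and counted in
the QC output. The production re-alignment of consensus sequences with an
external aligner is out of scope here; coordinates pass through unchanged.
Consensus output is invariant under read reordering (all tie-breaks are
deterministic), and re-running consensus on emitted molecules reproduces
them.

Per-target observations then count, for each panel target, the unique
molecules with a determinate base call at the locus (consensus base equal to
ref or alt; masked or third-allele bases are no-calls) and the subset
supporting the alt allele.

## Detection

For a sample with per-target totals $M_t$, alt counts $k_t$, and class error
rates $e_t$, aggregated over *active* targets only:

$$k = \sum_t k_t, \qquad M = \sum_t M_t, \qquad \lambda = \sum_t e_t M_t.$$

The tumor fraction is reported as $\mathrm{ppm} = 10^6 \, k / M$, and
detection is a one-tailed Poisson test of the observed aggregate signal
against the expected noise: $p = P(X \ge k)$ for $X \sim
\mathrm{Poisson}(\lambda)$, computed by the survival function (numerically
stable in the far tail, and floored at the smallest positive double so the
$p \in (0,1]$ contract survives underflow at overwhelming signal). The
sample is ctDNA-positive when $p \le 0.001$, boundary inclusive. The
threshold enforces an analytical specificity above 99.9% by construction and
is independent of everything that affects observed levels; detection never
rests on an allele-frequency cutoff. A reported ppm may legitimately fall
below the sample's LOD. When the plasma volume is known, the count is also
reported as tumor molecules per ml (extraction efficiency fixed at 1 — the
volume rescaling is defined only up to that constant).

### Predicted limit of detection

The 95% LOD of a panel is the tumor fraction detected with 95% probability
at the fixed threshold. The analytic construction: the critical count is
$k_{\mathrm{crit}} = \min\{k : P(\mathrm{Poisson}(\lambda) \ge k) \le
0.001\}$; the required total signal mean is $\mu^* = \min\{\mu :
P(\mathrm{Poisson}(\mu) \ge k_{\mathrm{crit}}) \ge 0.95\}$ (bisection; the
tail is strictly increasing in $\mu$, and $\mu^*$ equals the closed-form
gamma quantile $q_{\Gamma(k_{\mathrm{crit}})}(0.95)$, which the test suite
uses as an independent oracle); then

$$\mathrm{LOD}_{95} = \frac{10^6}{M}\,(\mu^* - \lambda).$$

A Monte-Carlo variant simulates detection over a bisection on the spiked
signal and agrees with the analytic value within Monte-Carlo error; the two
routes cross-check each other. The LOD falls as $M$ grows and rises with
$\lambda$. At $M \approx 3 \times 10^6$ and $\lambda \le 0.5$ the construction
gives $k_{\mathrm{crit}} = 4$–$5$ and an LOD of ~2.5–2.9 ppm; the exact
per-panel value depends on the panel's class composition. This construction
is a reasoned stand-in for the production assay's proprietary LOD formula,
anchored to the same observable outputs (ppm-scale LODs at full panel
depth).

### Cohort stratification

Detected samples are split at the median ppm of the detected subset:
`negative` (not detected), `low` (ppm ≤ median), `high` (ppm > median).
Values equal to the median go to `low` — the conservative risk grouping.
Survival modelling on the resulting groups is out of scope.

## The simulator

The simulator stands in for controlled-access patient plasma and defines the
conditions under which the package's claims are tested:

* **Reference and variants** — a uniform random genome; somatic SNVs with
  AF ~ Beta(5, 5) (clonal-ish, centred at 0.5, essentially never below the
  10% cut), a configurable fraction placed inside generated exclusion
  intervals, and truth labels attached. Variant loci keep a minimum spacing
  of 200 bp so each cfDNA fragment spans one target, as in a genome-wide
  sparse panel.
* **Background cohorts** — per sample and class, Binomial alt-molecule
  counts at true class rates. Two rate presets bracket the assay:
  `raw_class_rates()` (~5e-6 mean; transitions 8e-6, transversions 3e-6),
  the pre-selection background scale, and `duplex_class_rates()` (~1.5e-7
  mean), the consensus-suppressed noise floor that low-noise selected
  targets attain — the scale at which a full panel reaches $\lambda \le 0.5$
  and 1–3 ppm LODs.
* **Plasma samples** — per target, Poisson molecule yields (default 1,666
  per target, ~3e6 molecules on a full panel — the depth regime that makes
  ppm-scale LODs reachable; read-level tests state smaller per-scenario
  yields); each molecule tumor-derived with probability $f$ or
  alt-by-error with its target's rate; fragments fixed at 166 bp
  (mononucleosomal cfDNA); duplex families with per-strand Poisson(2) read
  counts zero-truncated on the pair total, so ~23% of families are
  single-stranded and duplex rejection is exercised without dominating;
  per-base sequencing errors at 1e-3 and a two-level quality profile (Q37
  with 5% Q20, straddling the Q29 mask).
* **Fast path** — `simulate_target_observations()` draws post-consensus
  per-target observations directly ($M_t \sim$ Poisson, $k_t \sim$
  Binomial($M_t$, $f + (1-f)e_t$)), which is exact for detection-level
  studies and makes full-scale specificity/LOD/recovery simulations run in
  seconds.

Everything is bit-reproducible under a fixed seed, including written SAM.

Two deliberate deviations from naive expectations are worth recording.
First, per-strand zero-truncation of family sizes would make single-strand
families impossible and the duplex rule vacuous; truncating the *pair total*
instead keeps the rule active. `min_reads_per_strand = 2` restores the
guaranteed-duplex regime used by the exact-recovery test. Second, under
uniform fragment placement two molecules of one target can share fragment
coordinates, and positional consensus then genuinely cannot separate them
(the allele split only works when their alleles differ) — so molecule counts
after consensus fall slightly below simulated counts. That is a real
property of positional deduplication, not a bug; the
`distinct_fragments` option removes collisions when a test needs exact
count recovery.

### What the simulator does not emulate

Sequencer-specific error spectra, GC and mappability bias, fragment-length
variation, FFPE damage, real CHIP dynamics, and alignment artifacts are all
absent. Passing tests therefore demonstrate that the *method* — ranking,
consensus rules, aggregation, and the Poisson decision — behaves as claimed
under its own stated error model, not that any particular sequencing
platform attains these numbers on patient plasma.

## Validation at desk scale

The acceptance suite runs a full-scale panel (1,800 targets designed from
2,200 simulated candidates on a 1.2 Mb synthetic genome, 43 QA SNVs) with
fast-path sampling for the distribution-level claims, and a reduced
read-level scale (100 targets, ~30 molecules/target, families ≥ 2 per
strand) for the consensus claims:

* 10,000 tumor-free samples through the caller leave the detected fraction
  at or below the 0.1% the threshold promises (specificity ≥ 99.9%, binomial
  CI respected);
* the Monte-Carlo 95% LOD of the full-scale panel at the suppressed noise
  floor lands in 1–3 ppm and agrees with the analytic construction;
* reads are conserved under group splitting, every emitted molecule has both
  strands, and with 1e-3 per-base error the post-consensus error over >2e5
  called bases is below 1e-5;
* spike-ins at 30/100/1,000 ppm are recovered by mean estimated ppm within
  10% over 200 replicates. Recovery is only meaningful at the suppressed
  noise floor: ppm is raw $k/M$ with no noise subtraction, so on the raw
  background scale ($\lambda \approx 13$ at full depth) the background alone
  adds ~15% at a 30 ppm spike. The assay's answer to that bias is target
  selection and consensus — which is precisely the λ ≤ 0.5 regime.

`scripts/acceptance.R` recomputes the specificity figure from scratch
(cohort → error model → panel → 10,000 null samples) for any seed.

## Known limitations

* Consensus is substitution-only: indel-aware consensus, overlapping-mate
  reconciliation beyond best-quality merging, and soft-clip handling beyond
  skipping are not implemented.
* The LOD formula is this package's own construction; it reproduces the
  published output range, not the proprietary algorithm.
* Tumor AF is used as called (variant-read fraction); no purity/CCF
  adjustment.
* The SAM reader expects proper mate pairs with M-only CIGARs (the
  simulator's convention); anything else is skipped and counted, not
  rescued.
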