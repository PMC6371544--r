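---
title: "Detecting selection signatures in serial cohorts: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting selection signatures in serial cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`temposcan` compares SNP-array genotypes of cohorts sampled at successive
points of a breeding timeline and locates the genome regions reshaped by
sustained directional selection. This vignette is the package's account of
the science: what each statistic assumes, which tunable parameters matter,
what the forward simulator does and does not emulate, and where the design
was genuinely open.

## 1. Data model and orientation convention

All analyses run on biallelic SNPs over a shared map (`snp_map`). At every
SNP, **allele 1 is the alphabetically lower of the two observed bases**, and
dosage matrices count copies of allele 1. This convention is closed under
every input route (PED/MAP text, VCF REF/ALT in either orientation) and
makes "frequency of allele 1" well-defined without strand or reference
information; re-orientation is an involution, and heterozygosity — the only
quantity entering HD — is invariant under it. Internal interval coordinates
are 0-based half-open (the BED convention); every reported table uses
1-based bp positions. Missing genotypes are excluded SNP-wise from the
frequency denominator (complete-case frequencies); how the original
array-data analyses handled missingness is generally unstated, and
complete-case is the assumption-free default. Hemizygous genotypes (males on
X) can be declared through a per-sample `ploidy` vector so each contributes
one allele.

## 2. Single-SNP statistics and threshold calibration

For cohorts $A,B$ with allele-1 frequencies $p_A,p_B$:

$$\mathrm{AFD}_i = |p_A - p_B|, \qquad
  \mathrm{HD}_i = 2p_A(1-p_A) - 2p_B(1-p_B).$$

AFD is symmetric; HD is signed (first-listed cohort minus second) so that
heterozygosity *loss* and *gain* under selection remain distinguishable.
Heterozygosity is the expected value $2p(1-p)$ computed from cohort
frequencies, not the observed heterozygote fraction: the long-range scan is
defined entirely in terms of frequencies, and expected heterozygosity is the
only frequency-derived choice (observed heterozygosity would additionally
respond to inbreeding and genotyping artefacts).

Raw AFD between cohorts mixes selection with drift and sampling noise. The
package calibrates a threshold empirically (`calibrate_random_afd`): the AFD
distribution between two disjoint subsets of *one* cohort — animals bred to
the same goals, so any difference is non-selective — is computed in full,
and its maximum, rounded to the nearest 0.01, is the recommended cut. With
the large cohort splits of a real study this lands near 0.10; with small
simulated cohorts it is honestly larger. All thresholds in the package are
inclusive (`>=`).

A second noise filter is *direction consistency* (`direction_consistent`):
keep SNPs whose frequency moved the same way in both selection phases
(sign$(p_{II}-p_I)$ = sign$(p_{III}-p_{II}) \neq 0$) with total change at
least the calibrated cut. Ties count as inconsistent (strict
same-direction), the conservative reading.

## 3. The long-range scan

Per SNP $j$ the windowed mean of a site statistic $S$ is

$$X_j = \frac{\sum_{i=l_j}^{u_j} S_i}{u_j - l_j + 1},$$

with windows either a fixed SNP count (odd, symmetric around $j$) or a fixed
span (all SNPs within half the span of $j$'s position). Windows never cross
chromosome ends; edge windows are truncated asymmetrically rather than
dropped, so every SNP has a value. $X$ is standardized within each
chromosome, $Z_j = (X_j - \bar X)/s_X$, to absorb chromosome-level
differences in baseline differentiation (e.g. from regional recombination
rates).

Numerical choices worth stating:

* $s_X$ is the sample standard deviation ($n-1$). At array scale the
  $n$ vs $n-1$ distinction is negligible; sample sd keeps the
  $X=[1,2,3]\Rightarrow Z=[-1,0,1]$ identity exact for unit tests.
* $X_j$ is computed by rolling cumulative sums and verified against naive
  re-summation to $10^{-12}$; flagged-missing $S_i$ are dropped with the
  denominator reduced, and a window with no usable statistic is flagged.
* A chromosome whose usable $X$ values are constant has no scale; its sd is
  treated as zero below a relative tolerance of $10^{-10}$ and its $Z$ is
  flagged rather than standardized.

**Signature calling** (`call_signatures`) uses a peak-and-extend rule: each
maximal run of consecutive SNPs with $|Z| \ge 2$ containing at least one SNP
with $|Z| \ge 3$ is one signature; its boundaries are the outermost
qualifying SNP positions, its peak the maximum-$|Z|$ SNP (leftmost on ties).
$Z_{AFD}$ is one-sided — AFD is non-negative, only excess differentiation is
a signature — while $Z_{HD}$ is two-sided with the run required to be
sign-consistent and the peak's sign reported, since selection can both erase
and (locally) raise heterozygosity. "Extends on both sides of the peak" is
operationalized as *no gaps*: one sub-threshold SNP terminates the run. The
default window set is {0.5, 1, 2, 3} Mb fixed-distance; windows advance one
SNP at a time so every SNP is a window center.

How calls from several window sizes consolidate into one region list is not
prescribed anywhere; `merge_across_windows` takes the interval union of
overlapping or bookended signatures per chromosome, recording contributing
window sizes and the best peak, and labels its output with that merge rule.
This is a declared choice, not a reproduction of any published catalogue.

## 4. Extended haplotype homozygosity

For a core haplotype with $c \ge 2$ carriers, EHH at a flanking SNP is the
probability that two random carriers are identical over all SNPs from the
core edge to that SNP:

$$\mathrm{EHH} = \frac{\sum_g \binom{e_g}{2}}{\binom{c}{2}},$$

with $e_g$ the sizes of the carrier groups identical over that stretch.
EHH is 1 at the core and non-increasing outward (groups only refine); the
implementation is incremental grouping, checked against all-pairs counting.
The **decay distance** per direction is the bp distance from the core edge
to the last *consecutive* SNP with EHH at or above the threshold (default
0.6); the first sub-threshold SNP terminates the extension, with no
interpolation between SNPs — conservative and exactly reproducible. The
total distance adds both directions and the core span.

Core enumeration (`scan_cores`) slides a fixed-count core (default 5 SNPs,
the scale at which haplotypes like "GGCGG" are tabulated in array studies)
across every offset and profiles every core haplotype above a frequency
floor (default 0.05); LD-driven core pre-selection used by some legacy tools
is intentionally not replicated. When counting "regions with decay
$\ge$ some span", overlapping qualifying cores are merged into maximal
regions first (`count_long_ehh_regions`), since a single long haplotype
qualifies many overlapping cores. Whether published region counts tally
cores, haplotypes, or merged regions is typically unstated; merging is this
package's declared rule. EHH runs on phased panels only — phasing real
unphased data is out of scope.

## 5. Cohort structure, effect correlations, annotation

* `ibs_distances`: $d(a,b) = 1 - \overline{(2 - |d_a - d_b|)/2}$ over
  co-observed SNPs — the standard allele-sharing IBS distance, computed via
  dosage-class indicator cross-products and verified against a per-pair
  loop.
* `classical_mds`: Torgerson metric MDS (`stats::cmdscale`), eigenvalue-
  ordered, with a deterministic sign convention (largest-magnitude
  coordinate positive per axis), so serial cohorts plot identically across
  runs. Four dimensions by default; non-metric MDS is deliberately avoided
  as it is neither deterministic nor eigenvalue-ordered.
* `effect_correlation`: Pearson $r$ between two traits' per-SNP effects
  over a SNP subset (e.g. inside signatures), after removing exclusion
  intervals — the motivating case is a region holding a single gene with an
  extreme antagonistic effect, which otherwise dominates the estimate. The
  p-value is the usual $t$ transform of $r$, reported descriptively only.
* `annotate_signatures`: genes overlapping a signature are "contained"
  (distance 0); genes whose nearest edge is within `proximity_bp` of a
  boundary are "proximal" with the gap reported. Published usage quotes
  proximities from roughly 1.0 to 2.5 Mb without defining a cut, so the
  default 1.5 Mb is a parameter, not a reproduction.

## 6. The forward simulator: what it emulates

`simulate_cohorts` generates the three-cohort design with known truth:

1. **Founders** — `n_founder_haplotypes` distinct haplotypes with per-SNP
   allele-1 frequencies drawn from Unif(0.05, 0.95), matching SNP-array
   ascertainment toward common variants. The default founder count is
   deliberately small (40 haplotypes): intensively selected livestock
   populations descend from a few dozen founder animals, and this
   bottleneck is what gives them their long-range LD.
2. **Founding + burn-in** — the diploid population (`pop_size`, default
   500) is drawn from the founder panel, then evolved neutrally for
   `burnin_generations` (default 20) at `burnin_recomb_mult` (default 20)
   times the recombination rate. The multiplier is the standard
   forward-simulation rescaling trick: 20×20 ≈ 400 generation-equivalents
   of ancestral recombination, which breaks exact founder copies into
   haplotype blocks of a few hundred kb, so baseline haplotypes coalesce
   "deep" while a sweep's carriers coalesce recently. Without this, every
   standing haplotype has a recent common ancestor and baseline EHH is
   indistinguishable from a swept haplotype's.
3. **Two selection phases** — `generations_phase1/2` (default 20 + 20,
   i.e. two ~20-year periods at a ~1-year effective generation interval for
   a closed experimental herd; the real generation interval is a free
   parameter, not an estimate). Each sweep locus carries selection
   coefficient $s$ with multiplicative viability $(1+s)$ per selected-allele
   copy — the simplest scheme with monotone expected trajectories — and may
   be active in either or both phases, emulating "old" and "new" signature
   peaks. The selected allele is implanted on a fixed number of founder
   haplotypes at `sweep_init_freq` (default 0.10): sweeps in array data are
   soft sweeps from initially uncommon standing variants, and the published
   exemplar haplotype rose from 0.05.
4. **Recombination** — crossovers per chromosome are Poisson with rate
   `recomb_rate_per_bp × length` (default $10^{-8}$/bp ≈ 1 cM/Mb),
   positions uniform. Uniform rate is a simplification; regional rate
   variation (e.g. suppressed recombination in chromosome centers) can be
   emulated by splitting chromosomes, but no rate map is built in.
5. **Cohorts** — diploids are sampled without replacement at generations 0,
   $g_1$, $g_1+g_2$ (defaults 100/100/100, a desk-scale version of the
   hundreds-to-thousands of a real study), yielding dosage matrices, the
   retained phased panels, and per-generation truth trajectories of every
   sweep locus. All randomness flows from one seed; a fixed seed reproduces
   the result bit-for-bit.
6. **Effect tables** — `simulate_effect_table` draws bivariate-normal
   per-SNP effects with target correlation $\rho$ (default −0.27, the scale
   of published milk-yield × fertility antagonism), optionally stronger
   inside designated intervals (per-interval $\rho$), emulating
   antagonistic pleiotropy concentrated in signature regions.

**What the simulator does not emulate** — and therefore what passing tests
do *not* show about real data: no mutation after founding, no migration or
bottlenecks during the selection phases, no realistic chromosome-specific
recombination maps or LD-decay curves, no genotyping error, random mating
rather than pedigree/assortative structure, and cohorts drawn from one
closed population rather than a national breed. Results on simulations
validate the *statistics and their implementation*, not the demographic
realism of any particular population.

## 7. Validation design and problem sizes

The test suite follows a dual-route principle: every fast implementation is
checked against an independent brute-force oracle (rolling window means vs
per-window re-summation at 50K SNPs; grouping EHH vs all-pairs counting on
50×200 panels; indicator-algebra IBS vs a per-pair loop; `cor()` vs a
two-pass Pearson), and the statistics' defining properties (AFD symmetry,
HD antisymmetry, per-chromosome $Z$ mean 0 / sd 1, EHH monotonicity,
threshold-count monotonicity) are asserted on simulated data.

Parameter recovery uses one 30 Mb chromosome at 50K-chip density (600 SNPs,
50 kb spacing) — sizes chosen as the smallest map on which 0.5–3 Mb windows
and Mb-scale EHH decay are meaningful. A strong implanted sweep
($s = 0.5$, population 500, 40 generations, 100 replicates) must be
overlapped by a called $Z_{AFD}$ signature in ≥ 90% of replicates, while
drift-only genomes yield few signatures, decreasing in the call threshold.
The haplotype-level checks run at $s = 0.1$, a sweep still *ongoing* at
sampling time — the regime array studies actually observe (the exemplar
haplotype reached only 0.32 after 40 years) — where the selected core
haplotype's frequency rises across all three cohorts and the locus's
dominant haplotype roughly doubles its EHH decay distance. The paired EHH
comparison deliberately contrasts each cohort's *own* leading haplotype at
the swept core: re-profiling the selected haplotype among its handful of
chance carriers in the baseline cohort conditions on tiny carrier counts,
whose EHH is upward-biased and noisy.

The effect-correlation contrast appears twice at two scales, for two
reasons. The pass/fail test plants a large contrast (−0.90 inside called
signatures vs −0.21 outside) on the 600-SNP map, because with only a few
dozen SNPs inside signatures the sampling error of $r$ (≈ 0.16) would
swallow a realistic contrast. The acceptance script instead reports the
realistic emulation at chip scale: 60,671 SNPs, genome-wide $\rho = -0.27$,
−0.30 inside 125 "fertility-signature" blocks (~19 SNPs each) and −0.21
inside 109 other blocks (~14 SNPs each), where the estimates resolve to
±0.02–0.05.

## 8. Known limitations

* Signature calling on a *single* simulated chromosome is conservative: the
  swept region inflates its own chromosome's mean and sd before
  standardization. With a full multi-chromosome genome this
  self-contamination shrinks; it is visible at desk scale.
* `merge_across_windows` and the long-EHH region dedup rule are declared
  consolidation choices; different rules give different region *counts*
  (not different regions), and published counts cannot be matched without
  the original genotypes in any case.
* The random-AFD threshold depends on the split sizes; small subsets give
  honest but large thresholds. Report the full distribution, not just the
  cut.
* EHH requires phased panels; the package does not phase.
* X-chromosome handling treats declared hemizygotes as one-allele
  contributors and otherwise analyses X like an autosome; dedicated
  male/female frequency models are out of scope.
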