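---
title: "Error models and anomaly thresholds for rare mutant-allele detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Error models and anomaly thresholds for rare mutant-allele detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(raremut)
```

## The detection problem

Circulating tumor DNA is a small minority of plasma cell-free DNA, so a
mutant allele may be present at fractions of 0.1% or less among reads of
an amplicon sequenced to a depth of 100,000 or more. At that depth, raw
sequencer-plus-PCR error rates (read error rates, RERs) of 0.01%–1% per
position drown naive variant calling. `raremut` treats the problem as
anomaly detection: for every possible base change ("substitution type":
one position and one ref→alt conversion), the null distribution of
error events is estimated from a panel of normal samples, and a change
is called a mutation only when its observed event count falls in the
extreme upper tail of that null.

All counting is normalized to **events per 100,000 reads**
(`normalize_to_per100k()`), which makes samples at different depths
comparable and puts the fitted parameters on a fixed scale.

## Null models and the three-way criteria

For one substitution type with panel rates $x_1,\dots,x_n$ (events per
100,000 reads across $n$ normal samples), let $m$ and $v$ be the mean
and the second central moment (variance with the $n$ denominator — the
method-of-moments convention; `denominator = "n-1"` is available). The
family is chosen as:

1. $m < 1$: Poisson with a conservative floor $\lambda = 1$. Types this
   quiet give too little information to estimate an intensity, and the
   floor guards against calling on 2–3 stray events.
2. $m \ge 1$ and $v/m \le 1.2$: Poisson with
   $\lambda = \lceil m \rceil$.
3. $m \ge 1$ and $v/m > 1.2$: negative binomial. Overdispersion is
   modeled as a gamma-fluctuating Poisson intensity, under which the
   event count is negative binomial with
   $r = \lceil m^2/(v-m) \rceil$ and, after the integer round-up,
   $p = r/(r+m)$ so that the fitted mean $r(1-p)/p$ still equals $m$.
   (The mean is the better-estimated moment; re-solving $p$ keeps it
   exact while the round-up perturbs only the dispersion.)

Equality at the 1.2 cutoff goes to the simpler Poisson model. Integer
round-up of $\lambda$ and $r$ is deliberate: both push thresholds up,
i.e. toward conservatism. If $v - m$ is positive but so small that
$r > 10^6$, the fit falls back to Poisson (numerically
indistinguishable; a warning is emitted).

Known constitutional SNPs must not be modeled as errors; by default the
G→A conversion at cDNA position 2,361 (a frequent synonymous SNP in
exon 20) is excluded from fitting.

## Threshold convention and realized test size

The calling threshold is

$$T = \min\{\,k \ge 0 : P(X > k) \le \alpha\,\}, \qquad \alpha = 2\times10^{-5}\ \text{per test},$$

with tails evaluated exactly (`ppois`/`pnbinom` survival functions; the
test suite cross-checks them against direct pmf summation). The calling
rule is **events per 100,000 reads ≥ T**, with no rounding of the
normalized value before comparison. Under this convention the
conservative floor model gives $T = 7$:

```{r threshold}
m <- fit_poisson(compute_moments(c(0.1, 0.3, 0.2)), floor = TRUE)
m
upper_tail_prob(m, 6:7)
```

Note the asymmetry this convention creates: $P(X > T) \le \alpha$ but
the realized per-test size of the rule "events ≥ T" is
$P(X \ge T) = P(X > T-1)$, which may exceed $\alpha$ (here
$8.3\times10^{-5}$ at $T=7$). The two requirements — the stated
$\alpha$ and the stated rule — cannot both hold exactly for a discrete
null; `raremut` pins the convention that yields the published-style
thresholds and always reports the realized size (`realized_size` on the
model, `tail_prob` on every call) so the inflation is visible. No
multiplicity correction is applied by default (per-test $\alpha$,
expecting roughly one false positive per 100 samples across a 500-type
scan); `compute_threshold(..., bonferroni = n)` is available.

The **detection limit** at depth $d$ is $100\,T_d/d$ percent, where
$T_d$ is the threshold for the null intensity rescaled to $d$
(real-valued intensity, used only inside this curve; fitted models
always carry integer parameters). For a $\lambda = 1$ locus at 100,000
reads this is 0.007%, i.e. below one mutant allele in 10,000.

## Exon 19 deletions: template matching

Indel read errors are far more frequent than substitution errors, so
multi-base exon 19 deletions are not called from per-position indel
counts. Instead each read is assigned by glocal alignment score to the
best of nine sequences: the intact exon 19 amplicon or one of eight
templates carrying a representative deletion (cDNA intervals 2233–2247,
2235–2246, 2235–2249, 2236–2250, 2236–2256, 2238–2252, 2239–2247,
2239–2256; shipped in `extdata/exon19_deletion_templates.tsv`).
Scattered single-base indel errors essentially never outscore the
intact reference over a template's full deleted span, which is what
makes the screen specific. Ties go to the intact reference, then to the
first template in interval order. The deletion's null model is the
Poisson floor ($T = 7$).

The reported deletion fraction divides the reads of the *chosen*
(maximum-count) template by all exon-19-assigned reads. Counting only
the chosen template (rather than summing all templates) is a genuine
ambiguity in the underlying procedure; the chosen-template reading is
the default because diverse real deletions produce incomplete matches
scattered across templates, and the maximum-count template is the
quantity used for frequency estimation. `deletion_fraction(...,
numerator = "all")` switches to the sum.

## Quantitation limit

A plasma assay draws on roughly 5,000 template molecules, so a fraction
$f$ contributes about $5000f$ mutant copies to the PCR input: at 0.3%
that is ~15 copies, with binomial coefficient of variation
$\approx 1/\sqrt{15} \approx 26\%$. Estimated fractions below 0.3% are
therefore flagged `below_quantitation` — still *detected* (detection
needs only ≥ T events among 100,000 reads), but not reliable in
magnitude. The simulator reproduces this: the squared CV of replicate
estimates at 0.3% is ~10× that at 3%, pure binomial scaling.

## What the simulator emulates (and what it does not)

`simulate_normal_panel()` draws, per position, a total error intensity
from a log-normal (default `meanlog = log 6`, `sdlog = 1.3`, events per
100,000 reads), gives one random alternate base 80% of the position's
error mass (error spectra are strongly position- and pattern-specific,
with one dominant conversion per position), and makes each type
overdispersed with probability 0.95 via gamma intensity fluctuation
targeting a variance/mean ratio of 3. These defaults produce panels
whose category composition is dominated by quiet (floor) and
overdispersed types with a small plain-Poisson band, the qualitative
structure the criteria were designed for. Read depths are log-uniform
on [44,400, 373,000]; a log-uniform (rather than uniform) draw on the
observed range reproduces the reported *average* depth (~160,000),
which a uniform draw would overshoot.

The named target loci are pinned to their reported error regimes: the
activating-mutation sites (exon 19 deletion partner positions, L858R)
are quiet category-1 sites, L861Q sits in the plain-Poisson band
(intensity 2.5, fitting to $\lambda = 3$), and T790M is a high-error
overdispersed position (intensity 20, ratio 3 — an order-of-magnitude
choice for a known noisy site, not a fitted value).

`simulate_assay()` uses two-stage sampling — mutant templates
$\sim \mathrm{Binomial}(5000, f)$, then reads allocated by the sampled
molecule fraction — plus per-type error counts. `simulate_reads()`
materializes index-prefixed reads for the alignment path.

Not emulated: flow-space/homopolymer error physics, PCR amplification
noise beyond the molecule bottleneck (no parameters are available; the
bottleneck alone reproduces the 0.3% quantitation behavior), quality
scores, paired ends, and sample-quality differences between plasma and
leukocyte DNA. Passing tests therefore demonstrate the statistical
machinery — thresholds, screening, quantitation — under the assumed
error structure, not robustness to artifacts outside it (e.g.
oxidative-damage mutations that inflate real-data false positives in
whole-region scans).

## Numerical and design notes

* **Variance/mean ratio and depth.** Rates are per-100k, so a type
  observed at depth $d$ has its count ratio multiplied by $10^5/d$ on
  the rate scale. Deep panels thus damp the ratio slightly; the
  law-of-large-numbers statement "Poisson types have ratio → 1" is
  exact at the 100,000-read reference depth.
* **Alignment.** Glocal (read-global, reference-local) affine-gap
  alignment via `Biostrings::pairwiseAlignment`; match +1, mismatch −3,
  gap open 5, gap extend 2. Reads scoring below 0.3× their length are
  unaligned; the reverse complement is then tried and logged. `N` bases
  score 0 against everything and are excluded from pileup depth.
  Identical reads are collapsed before alignment, so deep amplicon
  data align in time proportional to the number of *distinct* reads.
* **Coordinates.** 1-based inclusive cDNA and GRCh37 chr7 everywhere;
  0-based half-open conversions happen only in the BED/VCF writers.
  Deletion VCF records are left-anchored on the preceding base.
* **Degenerate inputs.** Zero depth at a queried position is an error
  (undefined rate), an empty exon 19 read set makes the deletion
  fraction undefined, a panel of fewer than two samples cannot be
  fitted, and target loci on read-free amplicons appear in reports as
  uncalled placeholder rows so every locus occurs exactly once.
* **Reference sequences.** The shipped amplicon set uses the real
  cDNA/genomic coordinate maps and the real reference bases at the
  modeled loci, with synthetic filler sequence elsewhere (file name and
  docs say so); any real reference can be supplied through
  `amplicon_reference()`. The exact boundaries of the 169-base scoring
  window are a package choice (55 + 57 + 57 bases around the loci) and
  configurable.

## Problem sizes used by the test suite

Simulation-backed tests run at sizes chosen to make their statistical
assertions sharp but cheap: 48-sample panels (hundreds of types),
count-level assays at depth 100,000, read-level end-to-end runs at
1,000–3,000 reads, 10^6-draw null resampling for per-test size, and
200–400 replicate assays for bias/dispersion checks. The dilution
series uses fractions 0.1%–50% with three replicates per point; the
duplicate-assay check uses 20 samples with fractions log-uniform in
[0.3%, 50%].

## Known limitations

* Whole-region scanning at per-test $\alpha = 2\times10^{-5}$ controls
  false positives only as well as the panel models the test data; on
  real plasma data, residual artifacts make a 48-sample panel
  insufficiently conservative for many types, so scan output should be
  treated as hypothesis generation.
* Per-100k normalization makes single events at shallow depth exceed
  low thresholds (one event in 3,000 reads is 33 per 100,000); the
  method is designed for depths ≥ 100,000 and reports depths so callers
  can gate on them.
* Thresholds assume the panel and the assay share an error process;
  sample-type and batch effects are not modeled.
* No Bayesian shrinkage of per-type parameters; method-of-moments with
  round-up only.
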