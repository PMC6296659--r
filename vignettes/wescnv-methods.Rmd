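---
title: "Methods: read-depth CNV and aneuploidy detection in wescnv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: read-depth CNV and aneuploidy detection in wescnv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`wescnv` detects copy-number variants (CNVs) and whole-chromosome
aneuploidy from whole-exome sequencing (WES) read depth, annotates and
tiers the calls for clinical-style review, and evaluates concordance
against array-based gold-standard call sets. Because raw clinical exomes
cannot ship with a package, a seeded synthetic cohort generator is a
first-class component: it produces data with the statistical structure
the callers assume, so every stage is testable end to end.

# The read-depth model

## Window counts

Capture regions are tiled into 100 bp windows (`bin_capture_regions()`).
A trailing remainder at least half a window wide becomes its own window;
a shorter remainder is merged into the preceding window, so windows tile
each region exactly and never cross region boundaries.

## Reference aggregation

For each test sample the caller builds an aggregate background from the
most similar other samples (`select_reference()`). Candidates are ranked
by Pearson correlation of log-transformed, total-normalized window
profiles; members accrue greedily, in rank order, while the predicted
beta-binomial variance of the test read fraction keeps falling, up to
`max_members` (default 10). Aggregation is by **summation** of member
counts, not averaging — the emission model needs genuine counts.
Candidates whose chrY coverage class differs from the test sample are
excluded up front: a sex-mismatched background otherwise converts every
chrY window into a spurious whole-chromosome call.

## Emission model

With test count $y_w$ and aggregated reference count $r_w$ in window
$w$, and $n_w = y_w + r_w$, the diploid expectation of the test fraction
is
$$\phi_w = \frac{\hat y_w}{\hat y_w + r_w}, \qquad
  \hat y_w = r_w \cdot \frac{\sum_w y_w}{\sum_w r_w},$$
and a copy-number state $c$ moves it by dosage odds:
$$f_w(c) = \frac{(c/2)\,\phi_w}{(c/2)\,\phi_w + 1 - \phi_w},$$
floored at $10^{-4}$ so the homozygous-deletion limit keeps a proper
density. Emissions are beta-binomial
$\mathrm{BB}(y_w;\, n_w, f_w(c), \theta)$ with mean fraction $f$ and
overdispersion $\theta$ (shapes $a = f(1-\theta)/\theta$,
$b=(1-f)(1-\theta)/\theta$; $\theta = 0$ is binomial). $\theta$ is
estimated by the method of moments from the excess variance of $y_w$
around $\mathrm{Binomial}(n_w, \phi_w)$ over autosomal windows, floored
at zero. Windows with $n_w = 0$ carry no evidence and contribute a zero
log-ratio; this mirrors the known failure mode where poorly captured
exons silently drop out of calling.

## Segmentation and scoring

Each chromosome is decoded by Viterbi under a 3-state HMM over
$c \in \{1, 2, 3\}$. The diploid state persists with probability
$1 - q$ per window ($q = 10^{-4}$ by default: CNVs are rare at window
resolution) and CNV states with $1 - 1/L$ ($L = 50$ windows, the
expected CNV length). Maximal non-diploid runs become calls. Each call
is scored with a Bayes factor,
$$\mathrm{BF} = \sum_{w \in \text{call}} \log_{10}
  \frac{\mathrm{BB}(y_w; n_w, f_w(c), \theta)}
       {\mathrm{BB}(y_w; n_w, f_w(2), \theta)},$$
the log10 likelihood ratio of the called state to diploid along the
decoded path. This per-window-sum form is exactly testable against an
exhaustive-path oracle, which the test suite does on every instance up
to 12 windows.

A fourth (homozygous-deletion) HMM state would destabilize decoding
because its emission mean collapses to the floor; instead, deletion
calls whose observed depth ratio falls below 0.15 (configurable) are
relabeled CN 0 after decoding. The observed ratio itself is the mean of
$y_w / (r_w\,\phi_w/(1-\phi_w))$ — observed over expected-diploid — and
`round(2 * ratio)` clipped to $[0, 4]$ gives the integer CN label
(half rounds away from zero, so the boundary is deterministic).

# Aneuploidy and mosaicism

Reads are counted inside capture windows only, and each sample is
rescaled so all samples share the same total (`k_s = \bar T / T_s`).
Each chromosome's adjusted count is divided by its cross-sample mean to
give a coverage ratio $\rho$: a trisomy sits near 1.5, a mosaic loss of
a single-copy chromosome at $1 - f$. chrX and chrY ratios are computed
within the sample's sex group (supplied, or inferred from the chrY read
share). Outliers are flagged per chromosome with the two-sided Grubbs
test at $\alpha = 0.05$, iteratively (capped at 10% of samples) so two
aberrant samples cannot mask each other. The mosaic fraction is
recovered by inverting the dosage relation: $\hat f = 2|\rho - 1|$ on a
diploid baseline, $\hat f = |1 - \rho|$ on the haploid male chrY,
clipped to $[0, 1]$.

Two deliberate choices here:

* **The cross-sample mean includes the test sample** (configurable via
  `exclude_test`). Inclusion makes the per-chromosome mean ratio
  exactly 1 — a clean invariant — at the cost of damping a true
  outlier's ratio by roughly $f/(2N)$; at cohort sizes of 20+ the
  damping is percent-level and is accepted rather than corrected, like
  the total-renormalization damping of a trisomy (about 2% for a
  chromosome-21-sized target share).
* **A finding requires both the Grubbs rejection and an estimated
  mosaic fraction of at least `mosaic_min` (default 0.2).** The bare
  Grubbs test fires at rate $\alpha$ per chromosome by construction, so
  a cohort scanned over 20+ chromosomes would surface a trivial
  deviation in most runs; the magnitude gate turns "statistically
  extreme" into "biologically meaningful" and gives event-free cohorts
  a near-zero finding rate while leaving real trisomies
  ($\hat f \approx 1$) and mosaic losses ($\hat f \ge 0.3$) untouched.

# Annotation and tiering

Calls are annotated with size, number of overlapped exon targets,
cohort recurrence (other samples with a same-direction call at $\ge$ 50%
reciprocal overlap), best Jaccard similarity to a same-direction record
in a classified-interval database together with that record's
classification, the maximum population frequency among overlapping
polymorphism records, and the fraction of overlapped het SNPs whose
allele fraction lies in the band expected under the call's copy number
(near 0/1 for deletions, around 1/3 or 2/3 for duplications; band
half-width 0.1, widening as $2\sqrt{0.25/n}$ below 30× site depth).
Direction concordance is required for database matches — similarity
between a deletion and a gain record is clinically meaningless even
when the intervals coincide.

Tiers encode the review thresholds: `high` needs BF > 100, $\ge 3$
exons, recurrence $\le 2$, and either size > 100 kb or a pathogenic
match at Jaccard $\ge 0.5$; `medium` needs BF > 20 within the
recurrence cap; everything else is `low`. The Jaccard floor of 0.5 and
the recurrence cap of 2 are package choices (exposed in
`tier_thresholds()`): published filter tables bin these quantities
without printing operative cutoffs.

# Concordance with array call sets

A gold (array) call is *potentially detectable* if it overlaps any
capture window by $\ge 1$ bp; *non-repeated* if no other sample carries
a same-direction gold call at $\ge$ 50% reciprocal overlap; *adequately
covered* if it overlaps a characterized gene's exon (symbols matching
`^LOC|pseudogene` are treated as uncharacterized — a configurable proxy,
since no operative list exists) with cohort-median window depth
$\ge 10$. Matching requires a same-sample, same-chromosome,
same-direction WES call overlapping $\ge 1$ bp (reciprocal-overlap
matching is available but not the default, because the evaluation this
mirrors did not state one); the best match maximizes basepair Jaccard.
Sensitivity percentages are rounded half-up to one decimal — this
reproduces published two-interval similarities except one case where
the computed 98.6 sits one rounding step above a printed 98.5, which is
documented rather than special-cased.

# The synthetic cohort generator

`simulate_counts()` draws window counts with mean
$d_s\,\mu_w\,D\,\mathrm{CN}_{s,w}/P$ where $D$ is the target mean depth
(default 62×, a realistic clinical exome), $d_s$ a per-sample depth
factor (log-normal, CV 0.1), $\mu_w$ a shared per-window capture
efficiency (log-normal, $\sigma = 0.4$, reproducing the strong
window-to-window variation of exome capture), and $P$ the dosage
denominator (2 for autosomes and chrX, 1 for chrY). Noise is
negative-binomial with variance $\mu(1 + \delta\mu)$, $\delta = 0.02$
by default — the overdispersion the beta-binomial caller must absorb.
Mosaic events scale the effective copy number as $P + f(\mathrm{CN}-P)$;
polymorphic regions are realized as multi-sample CNVs with carrier
probability 0.3. Sex is a per-sample attribute; the generator assigns
chrY about 5% of a chromosome's usual target count because exome
designs capture far less of chrY than of an autosome — with equal-size
sex chromosomes, male/female library totals diverge enough to distort
every autosomal coverage ratio. A `mean_gap_bp` parameter controls
physical target spacing so megabase-scale events fit on synthetic
chromosomes. Het-SNP allele counts are binomial around 1/2 (diploid),
1/3 or 2/3 (duplication, random phase), or near 0/1 (hemizygous), at
Poisson site depth. The "array" view of the truth
(`derive_array_callset()`) keeps focal events at or above 10 kb
(a typical clinical array floor), perturbs endpoints by up to 2 kb —
a free parameter, since array breakpoint precision is not quantified in
the source material — and drops whole-chromosome events, which arrays
report as karyotype-level findings.

What the generator does **not** emulate: GC-content bias, mappability
structure, batch effects between capture kits, relatedness, or tumor
subclonality. Passing tests therefore demonstrate correctness of the
statistical machinery under the stated model, not performance on any
particular real cohort.

# Problem sizes used by the test suite

The acceptance tests run a pilot-style cohort (8 samples, 7
chromosomes, ~3,600 windows, 100 replicate seeds), a mosaic-chrY cohort
(100 male exomes, ~122,000 windows), a 1,000-event
deletion-vs-duplication simulation (100 cohorts of 10 samples), 200
Viterbi-vs-enumeration instances up to 12 windows, and 1,000
brute-force Jaccard pairs. These sizes were chosen so the whole suite
completes in minutes on a laptop while keeping Monte-Carlo error well
inside the asserted tolerances.

# Known limitations

* Reference-set quality bounds sensitivity: events recurring across
  many cohort samples (polymorphic loci) contaminate the background and
  are systematically under-called — the dominant failure mode for
  read-depth callers, and visible here in the recurrence annotation
  rather than corrected.
* Breakpoints are window-resolution; no sub-window refinement.
* Duplications are intrinsically harder than deletions (a 1.5× shift is
  fewer standard errors from diploid than a 0.5× shift at equal depth);
  the suite asserts this asymmetry rather than hiding it.
* chrY calling in females is undefined and skipped; segmental
  (arm-level) aneuploidy is out of scope, as are GC correction and
  tumor/normal workflows.
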