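---
title: "Methods: from raw screen plates to epistasis intervals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from raw screen plates to epistasis intervals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mapkscreen)
library(dplyr)
```

# The analysis problem

A genome-wide RNAi screen in Drosophila S2 cells reads out RAS/MAPK pathway
activity as a quantitative phospho-MAPK (pMAPK) immunofluorescence signal,
one dsRNA reagent per well of a 96-well plate. Turning those raw intensities
into a list of pathway regulators, each positioned within the
RAS→RAF→MEK→MAPK cascade, takes a chain of statistical steps, and each step
of that chain is a module of this package:

1. **Plate normalization** — each well is expressed as a log-ratio to the
   in-plate GFP-dsRNA negative controls (`normalize_wells()`), with
   Z′-factor QC of the control separation (`zprime()`, `screen_qc()`).
2. **Hit calling** — a reagent is a hit when it clears a cutoff margin in
   the same direction in both the primary and a confirmation round
   (`call_primary_hits()`).
3. **Promoter false-positive filtering** — reagents whose effect runs
   through the inducible metallothionein expression system rather than the
   pathway are flagged by comparing their reporter-screen effect to their
   pMAPK effect (`promoter_filter()`).
4. **Epistasis assignment** — each validated candidate's six-assay profile
   is correlated with three predetermined interval profiles by a weighted
   uncentered Pearson correlation and assigned to the best-matching
   interval (`classify_epistasis()`).
5. **Specificity scoring and profile clustering** — composite penalties for
   non-specific behaviour (`specificity_score()`) and unsupervised
   clustering of functional profiles (`cluster_profiles()`).
6. **Expression follow-up** — qPCR log2-ratio calls with Student's t-tests
   (`expression_call()`) and classification of sequenced splice isoforms
   into normal / truncated / frameshifted products
   (`classify_splice_product()`).

A synthetic-screen generator (`generate_screen()`) with known ground truth
makes the whole chain testable end to end.

# Plate normalization and QC

Raw immunofluorescence intensities vary multiplicatively between plates
(staining, illumination, cell density), so all analysis happens on a log
scale. Each well's value is

$$v = \log_{10}\!\frac{\text{signal}}{\operatorname{center}(\text{GFP
wells on the same plate})}$$

The center is the **median** of the negative-control wells by default: a
single contaminated control well (a real hazard at 4 controls per plate)
then barely moves the reference. The geometric mean is available
(`center = "geomean"`); under it control wells average exactly zero after
normalization, which is convenient for diagnostics. Epistasis-type pMAPK
assays are reported in log10; expression ratios in log2
(`log_base = 2`), matching how each family of results is conventionally
tabulated. Zero-signal wells are rejected with a count by default; a
configurable pseudocount is available for count-like data.

Assay robustness is summarized by the Z′ factor
$Z' = 1 - 3(\sigma_p + \sigma_n)/|\mu_p - \mu_n|$, computed with sample
(n−1) standard deviations; $Z' > 0.5$ marks a robust assay. The statistic
is undefined when the control means coincide and is flagged rather than
returned as a number.

# The epistasis statistic

The positioning logic: a regulator acting upstream of RAF cannot suppress
signaling driven by constitutively active RAF or MEK, while a regulator
acting downstream of MEK suppresses everything. Six activation assays —
RAS^V12^, three activated RAF variants, MEK^EE^, and MEK^EE^ with PTP-ER
co-depletion — give each gene a six-value profile whose *shape* encodes its
interval:

| interval | ideal profile |
|---|---|
| RAS-RAF | 1 0 0 0 0 0 |
| RAF-MEK | 1 1 1 1 0 0 |
| MEK-MAPK | 1 1 1 1 1 1 |

Profiles are compared with a weighted **uncentered** Pearson correlation

$$r = \frac{\sum_i w_i x_i y_i}{\sqrt{\sum_i w_i x_i^2\,\sum_i w_i y_i^2}},
\qquad w = [3\,1\,1\,1\,1\,2]$$

Uncentered, because the comparison is between directions through the
origin: a gene with no effect has no direction, and mean-centering would
manufacture one. The weights up-weight the RAS^V12^ assay (the primary
readout, measured with the most replication) and the PTP-ER co-depletion
assay (the strongest discriminator of the most downstream interval). The
sign of $r$ carries the regulator direction: knockdown of a *positive*
regulator lowers pathway output, giving negative profile values and
negative $r$.

Assignment takes the interval with the largest $|r|$ ("highest distance"
read as largest absolute correlation, since the sign encodes direction,
not distance). Two qualifications:

* if all three correlations lie within $[-0.5, 0.5]$ the gene is
  **unassigned** ("?");
* the **confidence score** is $|r_{best}| - |r_{second}|$; calls below 0.2
  keep their interval but are flagged **ambiguous** "(A)". The published
  tables use a 0.2 confidence threshold without printing the score's
  formula; the margin between best and runner-up is the natural monotone
  choice and reproduces the threshold's behaviour at the ideal profiles.

Two closed forms anchor the scale. The ideal RAS-RAF and MEK-MAPK profiles
correlate at $\sqrt{w_1/\sum w} = 1/\sqrt 3 \approx 0.577$; and a uniformly
suppressed profile ($x = [-1,\dots,-1]$) gives $r = -1$ to MEK-MAPK but
$-\sqrt{2/3} \approx -0.816$ to RAF-MEK, hence confidence
$1 - \sqrt{2/3} \approx 0.18$ — *below* 0.2. A perfect MEK-MAPK regulator
is therefore intrinsically flagged ambiguous at the default threshold;
that is a property of the profile geometry, not an implementation
artifact, and the census reports interval and status separately so both
readings are available.

Tie-breaks: an exact tie in $|r|$ is reported ambiguous with confidence 0
and the co-leading interval in `tied_with`. An exactly-zero profile
(possible for inert genes in noise-free simulation) is unassigned with
`NA` correlations; the low-level `weighted_uncentered_pearson()` instead
raises an error on zero-norm input so that a true zero vector is never
silently mapped to $r = 0$.

A note on pure noise: because $r$ is scale-invariant, a pure-noise profile
is a random direction in six dimensions, and such a direction exceeds the
0.5 cutoff with a confident margin for one of the three (mutually
correlated) profiles roughly a third of the time — at *any* noise
magnitude. Pure noise is therefore "mostly", not "almost always",
inconclusive under direct classification. In the screen design this is
immaterial: genes only reach epistasis classification after reproducing as
hits in two rounds, and that gate is what keeps inert genes out of the
interval tables. The end-to-end tests measure noise-gene behaviour through
that gate.

# Hit calling and the promoter filter

A hit must clear the cutoff margin in the same direction twice
(primary and confirmation), which controls for well-level flukes. The
numeric cutoffs were not published; defaults of ±0.3 log10 (≈2-fold) are
exposed in `hit_config()`, and the end-to-end tests use ±3·noise_sd.

The six activation assays are all driven by the same inducible
metallothionein promoter, so a gene that perturbs that expression system
mimics a downstream regulator. Dedicated reporter screens (pMet-GFP,
pMet-HA-RasV12) measure that artifact directly. The published cutoff is
described as a function of the primary pMAPK signal but its exact form was
not released; this package reconstructs it as a linear rule — fail when
$|reporter| \ge b + a\,|pMAPK|$, defaults $a = 0.5$, $b = 0.3$ — which
captures the intended behaviour (the larger the claimed pathway effect,
the larger the reporter effect needed to explain it away) with two
transparent parameters.

# Specificity score and clustering

The published specificity system lists its components (pJNK assays,
pMet-GFP expression, prior-screen occurrence, protein/transcript impact)
but not its aggregation formula. The package implements an additive
weighted penalty model: each component maps to a penalty in $[0,1]$
(ratio-to-pMAPK for the JNK and reporter effects, capped count for
prior-screen occurrence, flag for non-specific Western results, scaled
excess for nuclear retention and cell-count loss), and the final score is
$1 - $ the weighted mean penalty, so worsening any component can only
lower the score. Missing components are skipped with renormalized weights
and reported. Group thresholds (high ≥ 2/3, low < 1/3) are tertile-style
defaults, all exposed in `specificity_config()`.

Functional-profile clustering uses distance $1 -$ uncentered correlation
with average linkage: genes acting in one complex share effect shape and
sign, merge near distance 0, and surface as clades. Input rows are sorted
by gene id before agglomeration so the tree is reproducible regardless of
input order; constant-zero profiles are rejected by name since they have
no direction.

# Expression calls and splice products

qPCR comparisons use the unpaired two-tailed Student's t-test (pooled
variance) on log2 replicate values, and the knockdown rule *log2 ratio
< −0.75 and p < 10⁻⁴*. Raw p-values are reported, as in the original
analysis; Benjamini–Hochberg adjustment is available behind a flag for
users screening many transcripts.

Sequenced isoform clones arrive as exon inclusion masks over a transcript
model. Classification is frame arithmetic on the CDS overlap of each
exon: loss of any start-codon base → `no_start`; loss of any stop-codon
base → `F`; otherwise removed (skipped) plus inserted (retained CDS
intron) length ≡ 0 mod 3 → `T` (in-frame) or, with nothing removed, `N`;
any other total → `F`. Retained introns count only when the CDS spans
their junction — the long first intron of the model below precedes the
CDS, so its retention leaves the protein normal.

The shipped `mapk_exon_model()` is **synthetic**: the real transcript's
exon lengths are not reproduced, only the frame properties that drive the
published qualitative outcomes (exon I noncoding; start codon in exon II;
CDS portions of exons IV and VII ≡ 0 mod 3; exon III's not; stop in exon
VIII). The classifier itself is validated against a
translation-by-provenance oracle on 1,000 random exon models in the test
suite.

# The synthetic screen generator

`generate_screen()` emulates the screen's design so that every stage has
testable ground truth: 96-well plates with 4 GFP negative-control wells
and 4 positive-control wells (mek, signal down; PTP-ER, signal up) on
every plate, round-robin gene layout in plate order, a per-plate log10
bias, and additive Gaussian noise on the log10 scale (equivalently
log-normal intensity noise — immunofluorescence errors are
multiplicative). Planted regulator classes follow the three ideal
profiles with a sign and effect size; promoter-artifact genes effect all
six promoter-driven assays plus the reporters; JNK-non-specific genes add
equal pJNK effects.

Defaults, chosen once as the study conditions and not revisited:

* `noise_sd = 0.06` log10 and positive-control effects −1.0 / +0.44:
  under the Z′ formula these put the strong (mek-like) control near
  Z′ ≈ 0.64 and the weak (PTP-ER-like) control near Z′ ≈ 0.18, the range
  reported for the original assay, which is what makes the simulated QC
  realistic.
* `plate_effect_sd = 0.05`: a ±12% typical plate bias, a mild but visible
  batch effect of the kind plate normalization exists to remove.
* class fractions 70% inert, 5/3/12% per interval, 6% promoter artifacts,
  4% JNK-non-specific: mirrors the published interval split among
  validated hits (RAS-RAF ≈ 16, RAF-MEK ≈ 8–13, MEK-MAPK ≈ 69) with
  enough artifacts for the filters to catch.
* `P(positive regulator) = 0.7`: most published hits lowered pMAPK.
* effect size 1.0 log10 exactly (`effect_sd = 0`), so noise-free runs
  reproduce planted profiles bit-exactly — the basis of several oracle
  tests.

What the simulator does **not** emulate: cell-count covariation with
signal, spatial (edge) well effects, plate-order drift (an optional hook
exists in the design but is off), reagent off-target sequence effects, and
heavy-tailed outlier wells. Passing tests therefore demonstrate the
statistical machinery, not robustness to every artifact of real plates.

# Worked example

```{r pipeline}
res <- run_pipeline(sim_config(n_genes = 120, seed = 5))
res
res$census
```

```{r qc}
head(res$qc)
```

Problem sizes used in the shipped tests and acceptance script — 300-gene
screens over 20 seeds for recovery, 1,000 random exon models, 1,000
simulated transcripts for the qPCR rule — were picked to give stable
Monte-Carlo estimates at interactive runtimes; all are parameters, not
limits.

# Known limitations

* The confidence score is a reconstruction (monotone surrogate at the
  published 0.2 threshold), as are the promoter-filter cutoff and the
  specificity aggregation; each sits behind an explicit config object.
* The published per-gene supplementary tables are spreadsheet files that
  are not redistributed here; `read_supplementary_s3()` consumes a
  TSV/CSV export of that layout, so the published counts can be
  reproduced only when the user supplies the file.
* Z′ is a two-group summary; it does not model plate-order drift within a
  screening campaign.
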