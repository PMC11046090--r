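---
title: "Absolute quantification by scheduled MRM with concatamer internal standards: models and design choices"
author: "mrmquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Absolute quantification by scheduled MRM: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrmquant)
```

## The measurement problem

Targeted proteomics on a triple quadrupole measures *transitions*:
precursor/fragment (Q1/Q3) m/z pairs specific to one peptide. Absolute
quantification adds an internal standard: an artificial concatamer
protein (QconCAT) built by linking one or more proteotypic peptides per
target protein, expressed with (13C6/15N2)-lysine and
(13C6/15N4)-arginine so that digestion releases a heavy-labelled twin of
every endogenous ("light") peptide. Because light and heavy co-elute and
fragment identically, the ratio of their peak areas, multiplied by the
known spiked amount of the standard, yields the endogenous amount in
fmol per microgram of total protein.

`mrmquant` implements this workflow end to end — in-silico digestion and
peptide mass arithmetic, proteotypic selection, concatamer assembly and
validation, scheduled-MRM assay construction, chromatogram simulation
with known ground truth, ratio-dot-product-gated quantification, and the
downstream three-group differential statistics.

## Peptide chemistry

Digestion follows textual cleavage rules: trypsin cuts C-terminal to K
or R except before P; lysyl endopeptidase (LysC) cuts after every K,
including before P. The sequential LysC-then-trypsin protocol is modelled
as the *union* of the two site sets — this reproduces the final peptide
population without simulating digestion kinetics, which the workflow
never needs. Missed-cleavage products are available (flagged) but the
assay design uses fully cleaved peptides only, the conservative default
when the monitored peptide list must be unambiguous.

All masses are monoisotopic (the instrument operates at unit resolution,
so isotope envelopes are never resolved and never modelled) and live in
one plain-text table shipped with the package, which both the
implementation and the test oracles read. Cysteines carry a fixed
carbamidomethyl (+57.02146 Da) modification because samples are reduced
and alkylated with iodoacetamide before digestion; no variable
modifications are modelled. The heavy label adds +8.014199 Da (K) or
+10.008269 Da (R) to the precursor and to y-ions, which contain the
C-terminus; b-ions are identical between light and heavy. Isoleucine and
leucine are distinct letters with identical mass: uniqueness checks are
sequence-level, as proteotypic logic requires.

## Proteotypic selection and concatamer assembly

Selection criteria for proteotypic peptides are not standardised; the
defaults here are common MRM practice and fully configurable: length
7–20 residues, fully tryptic with a K/R C-terminus, unique across the
entire proteome digest, no methionine (oxidation-prone), no N-terminal
glutamine (pyro-Glu). Survivors are ranked deterministically — length
closest to 12 residues, ties broken alphabetically — so a build is
reproducible from its inputs. Proteins with no surviving candidate go to
a failure report rather than being silently dropped.

Assembly packs peptides into `ceiling(n / 50)` constructs (capacity
configurable). The single structural hazard is an R|P junction, which no
enzyme in the protocol cleaves; input order is kept unless such a
conflict exists, in which case a greedy pass places P-starting peptides
after K-ending ones. If that cannot succeed the assembly fails hard by
default — a construct that silently fails to release a peptide would
corrupt every downstream concentration — with an optional spacer residue
as an explicit escape hatch. Every construct is validated by digesting
its full sequence and requiring each peptide to be released exactly
once. Terminal tags (e.g. a His-tag for Ni-resin purification) are
carried as opaque sequences outside quantification, empty by default.

## Scheduled assay construction

Per-transition voltages come from linear functions of the m/z values:

| parameter | formula | applies to |
|---|---|---|
| DP  | 0.049 · Q1 + 42.6 | all precursors |
| CE  | 0.036 · Q1 + 6.9  | 2+ precursors |
| CE  | 0.054 · Q1 − 2.4  | 3+ precursors |
| CXP | 0.0391 · Q3 − 2.23 | all fragments |
| EP  | 10 | constant |

The two CE ramps are assigned to 2+ and 3+ precursors respectively,
matching the vendor convention of listing the 2+ ramp first. Q1/Q3
resolution ("unit", 0.7 Da half-width) is recorded as metadata only; no
peak-shape modelling happens in m/z space.

Each peptide is monitored by at least three transitions, by default the
highest-index y-ions from the candidate series y3…y(L−1) at 1+ — longer
y-ions are more sequence-specific, and y1/y2 are excluded as
uninformative. The precursor is 2+ unless its 2+ m/z exceeds 1250, then
3+. b-ions and 2+ fragments exist behind options but are off by default.
Retention times are supplied by a table (from the simulator or the user);
the package deliberately contains no RT prediction model, keeping the
assay builder deterministic and testable.

Scheduling acquires each transition in a window of predicted RT ± 1 min
(120 s total) with a 1 s target scan time. The concurrency report sweeps
window boundaries; dwell per transition at load *n* is
`(1000 ms − n · 2 ms) / n` with a 2 ms default switching overhead, and a
warning lists regions where dwell falls below 5 ms.

Acylcarnitine profiling uses a precursor-ion scan for the common product
at m/z 85.05; collision energy depends on acyl chain length: −20 V up to
C8, −25 V for C10–C14, −35 V for C16–C18. Chain lengths 9 and 15 fall
between the printed class ranges and are assigned to the next class up.

## What the simulator emulates — and what it does not

The chromatogram simulator exists so that every downstream stage can be
tested against known ground truth. Each transition's trace is a Gaussian
peak (σ = 0.05 min by default) sampled on the 1 s acquisition grid
inside its scheduling window. Light amplitude ∝ concentration × relative
transition intensity; heavy amplitude ∝ spiked amount × the *same*
relative intensity — the shared fragmentation pattern is what drives the
ratio dot product to 1 on clean data. Noise is mean-one multiplicative
log-normal at a stated CV (default 5%) plus a small flat baseline;
interference adds an extra Gaussian to chosen light transitions with an
amplitude factor relative to that transition's peak. Light and heavy
co-elute exactly by default; RT jitter is configurable to exercise the
RT-matching failure mode. Everything is reproducible from a recorded
seed.

Not emulated: peak tailing, ionisation suppression and matrix effects,
cross-run RT drift, detector saturation, and real interference
structure. Passing tests therefore demonstrate the correctness of the
*computational* pipeline under its stated model, not robustness to every
failure mode of real chromatography.

The study simulator mirrors the three-genotype design the statistics
serve (3 groups, n = 5 per group for proteins, n = 10 for metabolites):
log-normal baseline abundances (meanlog = log 50, sdlog = 1, spanning
the 2–3 decades typical of metabolic-enzyme panels), mean-one
multiplicative within-group noise at 10% CV, and planted fold changes
multiplied into one group. The demonstration pipeline plants 30 of 247
analytes at fold change 2 — 247 matching the size of a detected
metabolic-protein panel in this kind of muscle study.

## Quantification rules

Peak areas are trapezoidal integrals above a flat baseline estimated
from the mean of the first and last *k* = 3 samples in the window; on
very short traces *k* shrinks (`k_eff = max(1, min(k, n %/% 3))`) so the
endpoints alone define the baseline, and negative baseline-subtracted
intensities clamp to zero. Endpoint-mean baselining is deterministic and
exact for the Gaussian fixtures; it is not a general chromatographic
baseline model.

Interference elimination computes per-transition light/heavy ratios and
removes transitions deviating from the median ratio by more than
`kMad × MAD` (kMad = 5) *and* more than 20% of the median. The relative
floor matters: with only three transitions the MAD of three noisy ratios
is an unstable scale estimate, and a pure MAD rule falsely flags roughly
one clean peptide in ten; requiring a 20% relative deviation removes
that instability while still catching any interference large enough
(≥ 0.5× peak amplitude) to bias the result. If elimination would leave
fewer than three transitions the peptide is flagged
`fail_min_transitions` and never silently quantified.

A peptide passes QC only if (i) the ratio dot product — the normalised
dot product between the light and heavy per-transition area vectors —
strictly exceeds 0.9, (ii) light and heavy apexes co-elute within 0.1
min (the tolerance is not standardised; 0.1 min is a few peak sigmas and
configurable), and (iii) at least three transitions remain. The
light/heavy ratio is the *sum* of retained light areas over the sum of
retained heavy areas — summing weights transitions by signal, which is
more stable than averaging per-transition ratios when the weakest
transition is near the noise floor (the mean-of-ratios alternative is
available via `ratioMethod = "mean"`). Concentration is
ratio × spiked amount, in fmol/μg. Protein values are the mean of
passing peptides, with count and CV reported; the roll-up rule is a
package choice, since a mean over one-or-few peptides is the only
defensible default when peptide-level weights are unknown.

## Differential layer

Fold change is the ratio of arithmetic group means. The two-sample t
test defaults to Welch (unequal variances are the norm for abundance
data; the pooled Student test is available and the two differ at these
group sizes, which is why the flavor is explicit). Volcano selection
uses strict gates: fold change > 1.5 or < 1/1.5 — the symmetric reading
of "|fold change| > 1.5" on the log scale — and p < 0.05; a
Benjamini–Hochberg column is carried for reporting but the selection
gate is the raw p-value, matching how such thresholds are conventionally
applied. One-way ANOVA is followed by pairwise comparisons against a
reference group with Šidák adjustment `1 − (1 − p)^m` over the m
comparisons made per analyte (not across analytes, mirroring
"versus-reference" annotation practice). PCA is an SVD of the centred
(optionally unit-scaled) sample matrix with a deterministic sign
convention — the largest-magnitude loading of each component is made
positive. Heat-map matrices are per-analyte z-scores with average-linkage
clustering on Euclidean distance; zero-variance analytes get z = 0 with
a warning rather than NaNs.

Degenerate inputs follow explicit conventions: zero variance in both
groups gives p = 1 (equal means) or 0 (unequal); a zero-norm area vector
gives rdotp = 0; a zero heavy sum cannot pass QC.

## Problem sizes and determinism

The shipped experiments run at the scale the workflow targets: 1,123
peptides packed at capacity 50 (→ 23 constructs, 100% release), 200
simulated peptides with log-uniform ratios in [0.1, 10] for recovery
(median |relative error| < 5% at 5% noise CV, exact to 1e−9 noiseless),
100 seeded interference cases, and differential calibration on 1,000
null analytes plus ten 247-analyte planted-effect studies. All
randomness flows from explicit integer seeds; the same seed reproduces
every table byte for byte.

## Known limitations

* No RT prediction, no iRT calibration, no cross-run alignment.
* No isotope envelopes, neutral losses, a/c/x/z ions, or semi-tryptic
  peptides.
* The simulator's noise model is multiplicative log-normal; detector
  shot noise and baseline drift are not represented.
* Protein roll-up is an unweighted mean of passing peptides.
* Construct design stops at the amino-acid level: no codon optimisation
  or expression modelling.
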