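---
title: "Classifying CRISPR editing outcomes by repair pathway"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying CRISPR editing outcomes by repair pathway}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crisprRepair)
```

## The model

A Cas9-induced double-strand break in an embryo is resolved by competing
repair pathways, and amplicon genotyping of each embryo returns a mosaic
mixture of alleles, each with a percent frequency. `crisprRepair` assigns
each allele to a repair category by rules operating purely on the allele's
indel description relative to the reference locus:

* **UNEDITED** — no indel.
* **HDR** — the allele reproduces the locus's programmed donor edit
  *exactly* (same edit type, interval and written-in sequence, reference
  flanks otherwise).
* **NHEJ** — any insertion occurred (insertion or deletion–insertion),
  the allele is a substitution that is not the programmed edit
  (templateless, mutagenic end joining), the deletion is a single base,
  or the deletion's junction microhomology is below `mh_min`.
* **MMEJ** — a pure deletion of at least 2 nt whose junction microhomology
  length lies in `[mh_min, mh_max]`.

The load-bearing definition is *junction microhomology as placement
ambiguity*. A deletion whose two boundaries share an *m*-nt repeat can be
reported at *m* + 1 different coordinates that all yield the same edited
sequence. `normalize_deletion()` shifts any reported interval to its
left-most (canonical) placement and counts the alternatives; that count is
the microhomology length, and `detect_microhomology()` reads the repeated
sequence at the canonical left boundary. Operationalizing "microhomology
near the deletion" as the flanking junction repeat (rather than a distal
homology search) matches how MMEJ deletion products are drawn and scored
in outcome studies: the underlined repeated arm abuts the deleted block.
It also makes classification *placement-invariant*: any reported
coordinates for the same physical deletion produce the same call, which is
essential because upstream trace-decomposition tools do not guarantee
left-aligned coordinates (the readers therefore always re-normalize).

Guides are located by scanning both strands for the protospacer
immediately 5′ of an IUPAC PAM match (default `NGG`), with the blunt cut
placed 3 nt 5′ of the PAM — standard SpCas9 geometry, configurable via
`cut_offset`. Ambiguous protospacer placement is an error rather than
"first match": silently mis-anchoring the cut would corrupt every
downstream attribution. Minus-strand guides are stored in locus-forward
coordinates; all microhomology logic operates on the forward reference and
is strand-agnostic.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `mh_min` | 2 nt | smallest junction repeat accepted as MMEJ evidence |
| `mh_max` | 25 nt | largest repeat counted as MMEJ; longer repeats are capped and flagged `mh_capped` (annealing over much longer homology resembles single-strand annealing, which this package deliberately does not model) |
| `repair_window` | 50 nt | an indel must begin or end within this distance of the cut (after normalization) to be attributed to it; others are `unattributable` |
| `bias_low`, `bias_high` | 0.5, 2 | NHEJ/MMEJ ratio boundaries; the balanced class is closed (`0.5 ≤ R ≤ 2`), so MMEJ-biased is strictly `R < 0.5` |
| `eff_threshold` | 66.7 % | efficiency stratification boundary; "low" is strictly `E <` threshold |

Two interactions are worth noting. A single-base deletion is NHEJ even
when it sits in a homopolymer (1-nt ambiguity): the single-base rule takes
precedence, and with the default `mh_min = 2` the interaction is moot
anyway. A deletion–insertion allele is NHEJ because "an insertion
occurred" is the first rule; both choices are configurable only by
reclassifying upstream, not by hidden switches.

Raising `mh_min` can only ever demote alleles from MMEJ to NHEJ (the
junction length is computed once and thresholded), which the test suite
checks as a monotonicity property.

## Aggregation

`embryo_profiles()` sums percent frequencies per category within an embryo
and computes editing efficiency on the attributable mass,
`E = 100·(f_NHEJ + f_MMEJ + f_HDR) / (f_NHEJ + f_MMEJ + f_HDR + f_UNEDITED)`,
which reduces to `100 − f_UNEDITED` when an embryo's alleles sum to 100.
Frequencies summing above `100 + freq_tolerance` are a hard error
(malformed allele table), not a silent renormalization.

`summarize_guide()` averages category frequencies over embryos and takes
the NHEJ/MMEJ ratio **of the means**, not the mean of per-embryo ratios:
single embryos with zero MMEJ mass would otherwise contribute infinite
terms, and the ratio of means is invariant under proportional mosaicism
(uniformly rescaling one embryo's allele frequencies). `R = Inf` is the
sentinel for zero MMEJ mean with positive NHEJ mean (class NHEJ-biased);
both means zero give class `undefined`, which `bias_census()` excludes
from its denominator. Reported percentages are rounded to 2 decimals;
ratios are returned at full precision (reporting code may round to 3).

For knock-in trials, `hdr_fold_change()` normalizes every treated-arm
replicate by its locus's baseline-arm mean efficiency and averages the
folds, unweighted, across replicate pairs; loci with a zero baseline mean
cannot be normalized and are excluded and reported. This per-locus
baseline-mean standardization is one defensible reading of a "fold change
across loci" analysis; where the underlying standardization of a published
fold is unspecified, recovery is demonstrated on synthetic cohorts with a
known fold rather than claimed against the published value.

## The synthetic cohort generator

`simulate_cohort()` emulates the *shape* of embryo genotyping data: per
guide its own random locus, per embryo 1–4 mosaic alleles (uniform) with
frequencies drawn by normalizing exponential spacings (symmetric Dirichlet),
summing to exactly 100 before rounding, and per allele a category drawn
from a configurable simplex over unedited / NHEJ-insertion / NHEJ-deletion
/ MMEJ-deletion / HDR.

Truth labels are defined with respect to the classifier's own operational
rules, and the generator *earns* that by construction rather than
assumption:

* **MMEJ deletions** delete one copy of a repeat cassette `R–filler–R`
  planted in the locus. Cassette boundaries are base-constrained so the
  junction ambiguity is exactly the planted repeat length — it can neither
  left-extend nor overshoot — and every cassette is verified at build time
  by exhaustive placement enumeration (a brute force independent of
  `normalize_deletion()`). Emitted coordinates are a *random* placement
  among the equivalent ones, so downstream normalization is genuinely
  exercised.
* **NHEJ deletions** are rejection-sampled near the cut until their
  junction ambiguity is below `mh_min` (or length 1); an iteration cap
  turns pathological configs into an explicit infeasibility error.
* **NHEJ insertions** insert random sequence at the cut; **HDR** alleles
  apply the programmed edit exactly (a 6-nt EcoRI-style `GAATTC`
  substitution spanning the cut is planted automatically when the HDR
  weight is positive).

Default distributions, chosen once as field-plausible: NHEJ deletion
lengths geometric with mean 6 nt capped at 30; insertion lengths geometric
with mean 2 nt capped at 10; microhomology lengths uniform on 2–8 nt.
The 2–8 default support is the widest for which one 240-nt locus can host
every cassette with all planted deletion boundaries inside the default
±50 nt repair window; longer microhomologies (to 25 nt) are available by
configuring a narrower support or a wider window/locus, and
`generate_locus()` fails loudly on infeasible combinations rather than
silently dropping lengths. MMEJ deletion lengths equal repeat length + 2
(the cassette filler), a consequence of fixing cassettes at locus build
time; the deletion-length distribution governs NHEJ deletions only.

What the simulator does *not* emulate: sequencing noise, chromatogram
deconvolution error, partial/imperfect HDR tracts, large structural
rearrangements, or any biophysical MMEJ propensity (deletion-pattern
prediction). Passing round-trip tests therefore demonstrates that the
classifier inverts the generative rules exactly — not that it is robust to
upstream decomposition error on real traces.

## Off-target bookkeeping

Three pure table operations mirror standard off-target workflows without
running any caller or aligner:

* `consensus_variants()` intersects `(chrom, pos, ref, alt)` keys across
  exactly three callers; matching is exact-key, assuming callers emit
  normalized variants (a documented limitation — no cross-caller indel
  left-alignment is attempted).
* `call_integration_breakpoints()` clusters genome-side positions of
  reference–donor chimeric reads by single linkage within a 100-nt window
  (split-read scatter around one junction) and applies inclusive support
  thresholds, both 10 and 20 by default.
* `coverage_loss()` compares mean depth in a ±50-nt window around the cut
  with the amplicon's outer flanks (outer 20 % of positions, 10 % per
  side): `max(0, 1 − inner/flank)`, clipped to [0, 1], scale-invariant by
  construction. This is an operationalization of "proportion of lost
  coverage"; published values of that quantity depend on read-level
  definitions that cannot be recovered from summary figures, so the
  statistic is validated on constructed profiles, not against published
  percentages.

## Numerical choices and degenerate inputs

0-based half-open coordinates everywhere internally; readers convert
1-based inclusive tables at the boundary (`one_based = TRUE`). Deletions
touching either locus end still normalize correctly; empty intervals and
out-of-bounds coordinates are errors, not clamps. `detect_microhomology()`
refuses non-canonical intervals instead of silently fixing them, keeping
the canonicalization step visible in pipelines. Frequency closure is
checked with a 0.5 % tolerance on input and ±0.1 on the output partition.
Test problem sizes were chosen to probe the combinatorics thoroughly while
keeping the suite quick: 10,000 random locus/deletion pairs (loci to
200 nt, alphabet sizes 2 and 4 so repeats are common) for the placement
oracle, an 88-guide × 10-embryo cohort for round-trip classification, and
50-embryo cohorts per target ratio with pre-registered 3.29-standard-error
recovery bands.

## Known limitations

* HDR calling is exact-match; imperfect HDR at the donor site is reported
  `unattributable` rather than modeled.
* SSA is never called as an outcome class; repeats beyond `mh_max` are
  flagged, not reclassified.
* The classifier consumes allele tables; it cannot rescue errors made by
  the upstream trace decomposition that produced them.
* Statistical output is descriptive (counts, proportions, ratios, folds);
  significance testing on embryo replicates is left to standard tools.
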