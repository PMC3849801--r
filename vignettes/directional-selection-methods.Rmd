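---
title: "Detecting directional selection on protein physicochemical properties"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting directional selection on protein physicochemical properties}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dirsel)
```

## The model

Selection acting on a protein phenotype can leave a directional trace:
replacements at unrelated sites that all shift one physicochemical
property the same way. `dirsel` formalizes this. Given a set of inferred
amino-acid replacements, each replacement *i* is scored through a single
quantitative property scale as a signed change
$X_i = v(\text{to}_i) - v(\text{from}_i)$, and the hypothesis of **no net
change**, $H_0: \mu = 0$, is tested with a two-tailed one-sample t-test:

$$ t = \frac{\bar X}{s_{\bar X}}, \qquad
   s_{\bar X} = \sqrt{\frac{\sum X_i^2 - (\sum X_i)^2/N}{N-1}} \Big/ \sqrt{N},
   \qquad \mathrm{df} = N - 1 . $$

The test treats the $X_i$ as independent draws from a common
distribution. That assumption deserves scrutiny: replacements on one
branch share a genetic background, sites are not exchangeable, and the
support of $X_i$ is the discrete set of residue-pair differences. The
t-test is used here as a deliberately simple screen — the calibration
section below quantifies how far its type-I error drifts from nominal
under a discrete null at realistic $N$ (answer: little).

p-values come from the exact Student-t distribution, not a normal
approximation: realistic replacement counts are small (the bundled
worked example has $N = 15$; the copepod comparisons have 11 and 40).

### Assumptions and degenerate inputs

* Only the 20 standard amino acids are scored. Gaps and ambiguity codes
  are **excluded with logged counts, never imputed**: at delta time a
  non-standard residue is an error; at extraction time
  (`diff_aligned()`) such columns are filtered into the `filter`
  attribute so that `matches + mismatches + gap + nonstandard` equals
  the alignment length.
* $N = 1$ leaves the statistic undefined: the result is flagged
  `degenerate` with `p = NA` rather than dropped, because single-difference
  pairs are routine in BLAST screening and silently losing them would bias
  a scan.
* Zero variance with nonzero mean (all deltas identical) gives `p = 0`,
  zero variance at mean zero gives `p = 1`; both are flagged.
* Results with $N < 5$ (`min_n`) carry a `low_n` advisory flag: the
  normality assumption is untestable at tiny $N$.

### Sign convention

Published worked-example tables print deltas as value(first-listed) −
value(second-listed); the natural evolutionary reading is derived −
ancestral. The package default is `to_minus_from` (derived minus
ancestral); `from_minus_to` flips every sign. The two conventions negate
$t$ and the net change and leave the two-tailed p identical, so the
choice is presentational. Reproduction tests use `from_minus_to` to
match the printed table.

## The property panel

`builtin_scales()` ships 25 scales in eight categories — hydrophobicity,
ionization constants, molecular size & composition, non-bonded energy,
polarity & polarizability, secondary structure, solvent accessibility,
tertiary structure — chosen to cover the breadth of amino-acid property
space. Provenance is recorded per scale:

* `h` (Kyte–Doolittle hydropathy) is `reference`: its 20 values
  reproduce all 15 deltas of the bundled worked example exactly and are
  the panel's verification anchor.
* 21 scales are `aaindex`: transcribed from the AAindex database entry
  whose description and units match the intended property; the `source`
  field records the accession (e.g. surrounding hydrophobicity →
  PONP800101, polar requirement → WOEC730101, bulkiness → ZIMJ680102).
* Three properties — compressibility `K0`, helical contact area `Ca`,
  and mean rms fluctuational displacement `F` — have **no AAindex
  entry**, and their literature values were not obtainable offline. They
  are **synthetic stand-ins** backed by a documented proxy of the most
  closely related available quantity (residue volume, mean area buried
  on transfer, and a flexibility index, respectively), labelled
  `provenance = "synthetic"` in the data, in their names, and here. No
  test asserts their values; treat conclusions that hinge on these three
  columns as provisional until real scales are substituted (a one-line
  edit of `inst/extdata/builtin_scales.tsv`, or `read_aaindex()` on the
  real records).

Deltas are reported in each scale's **native units**; no normalization
is applied. The t statistic is invariant under linear rescaling of a
scale, so normalization would change nothing inferential while
obscuring the units of the mean and net change.

External panels load from the AAindex1 flat-file dialect
(`read_aaindex()`), with records carrying any `NA` value skipped and
reported — a scale that cannot score every replacement cannot enter the
test. Symbols are ASCII-ized (`V0`, `mu`, `Pa`, `Pb`, `K0`) so they
survive TSV and command lines.

## Partitions

Replacements are pooled before testing: whole sequence,
`partition_windows(window, step)`, or named regions
(`partition_regions()`, e.g. structurally annotated proton input/output
regions of a membrane pump, read from a TSV or converted from BED with
the 0-based half-open to 1-based inclusive shift).

Windows are defined in **residue coordinates**, not replacement index,
so they stay comparable to structural annotations; the final truncated
window is kept and flagged rather than dropped (dropping it would
silently unweight the C-terminus). A window at least as long as the
sequence collapses to the single whole-sequence partition. Overlapping
regions are allowed and tested independently; no multiplicity
correction is applied across partitions or properties by default —
raw p-values are primary, matching the screening character of the
method — with Benjamini–Hochberg available behind `adjust = TRUE`.

## Significance symbols

Summary grids use the field's signed notation: `+`/`-` repeated once per
significance tier met, sign following the mean. The tier semantics of
one-versus-three symbols are not uniquely fixed by published usage
(captions mention a "lower significance" tier at p = 0.1 alongside
p < 0.05 claims); the package adopts the only self-consistent monotone
reading — defaults p < 0.1 / 0.05 / 0.01 mapping to one/two/three
symbols — and exposes `tiers` everywhere. This is an interpretation, not
an established standard; reports of record should quote the numeric
p-values from the TSV/JSON output, which carry everything at 12
significant digits.

## Synthetic data and calibration

`sample_null_replacements()` draws replacements uniformly over the 380
ordered pairs of distinct standard residues, at distinct random sites.
This is the simplest null consistent with the hypothesis actually
tested, which lives purely at the property level ("no net change"); it
deliberately ignores codon structure, mutational bias, and
site-specific constraint. A green calibration therefore establishes
that the t-test is honest *for this null* — not that real proteins
evolve this way. By antisymmetry the enumeration mean of any scale over
the 380 pairs is exactly zero, which is what makes the uniform law
centred.

`sample_biased_replacements()` tilts the pair law exponentially,
$P(\text{pair}) \propto \exp(b\, X / \mathrm{sd}(X))$ under a chosen
scale. The design sketch for this generator was acceptance–rejection
with a delta-increasing acceptance weight; the implementation samples
the 380-pair distribution directly with those weights instead — the
same model family ($b = 0$ reduces exactly to the null; the expected
delta is strictly increasing in $b$) at deterministic cost, which keeps
seeding trivial. Scaling by the enumerated standard deviation makes
$b$ comparable across scales of different units.

Measured with `simulate_null_rejection()` (fixed seed, vectorized over
trials), the null rejection rate at p < 0.05 for the hydropathy scale at
$N = 15$ sits near 0.051 — slightly above nominal because the deltas
are discrete, not normal — inside the binomial 3σ acceptance band
[0.040, 0.062] used in the test suite. `simulate_power()` shows the
rejection rate rising monotonically with the tilt (near 1 by $b = 4$ at
$N = 15$).

## Numerical and design notes

* The t core guards $\sum X_i^2 - (\sum X_i)^2/N$ against tiny negative
  round-off with a floor at zero.
* Report rendering is pure: fixed column order, `%.12g` numerics, no
  timestamps — identical inputs give byte-identical documents, and every
  symbol-grid cell is recomputable from the TSV.
* The analysis path is fully deterministic; randomness exists only in
  the simulation subcommand behind an explicit seed, and seeded calls
  restore the caller's RNG state.
* Coordinates are 1-based inclusive throughout, in the frame of the
  first/query sequence; BLAST HSP sites are mapped to query coordinates
  via `qstart` and the query's non-gap positions.
* Pairwise only: multi-sequence alignments with a phylogeny are
  supported through externally produced per-branch replacement tables
  (`read_replacement_table()`), not by internal ancestral
  reconstruction, which is a solved problem upstream (e.g. codeml) and
  out of scope here.

## Known limitations

* **The copepod COI case study ships red.** The acceptance test that
  reproduces the published copepod cytochrome oxidase subunit I counts
  (11 and 40 differences in the first 215 residues of two species
  pairs, and 5 whole-alignment properties at p < 0.05) needs four
  GenBank records that cannot be redistributed here and cannot be
  fetched without network access. The workflow itself is implemented
  (`fetch_or_load_fasta()` with an accession cache, invertebrate
  mitochondrial translation, `diff_aligned()`, the 25-property panel);
  on a networked machine, populate the cache with
  `allow_fetch = TRUE` and the test runs in full. Offline it fails with
  the documented fetch-disabled error, and we prefer that honest red to
  a skipped or stubbed test. Independently, its property-count clause
  depends on the three synthetic stand-in scales above, so even with
  data it is a fragile reproduction and any discrepancy should be
  documented rather than tuned away.
* The method detects *directional* shifts only; balanced or episodic
  selection that leaves the mean delta near zero is invisible to it,
  and a significant result identifies a property trend, not the sites
  responsible.
* Properties are tested marginally; the 25 scales are correlated, so
  counting significant properties overstates independent evidence.
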