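# dirsel — directional selection analysis of protein physicochemical properties

`dirsel` detects **directional (Darwinian) selection** in proteins: the
signature of several amino-acid replacements, scattered across a sequence,
all pushing one physicochemical property in the same direction — steadily
less hydrophobic, more polar, smaller. It is aimed at molecular
evolutionists and comparative genomicists who have protein pairs (from
alignments, BLAST reports, or ancestral-reconstruction output) and want a
property-level complement to rate-ratio (dN/dS-style) selection tests.
Because the method works directly on amino acids, it needs no underlying
nucleotide information and applies to `blastp` output where dN/dS cannot.

## The statistic

Each inferred replacement at a residue site is scored through one
quantitative amino-acid property scale as a signed change
*X<sub>i</sub>* = value(derived) − value(ancestral) (or the reverse, by a
flag). For *N* replacements, the null hypothesis of **no net change**
(H₀: μ = 0) is evaluated with a two-tailed one-sample t-test:

```
t = X̄ / s_X̄ ,   s_X̄ = sqrt( (ΣX²ᵢ − (ΣXᵢ)²/N) / (N−1) ) / sqrt(N) ,   df = N − 1
```

A significantly positive (negative) mean marks replacements accumulating in
the same physicochemical direction. Tests run per property — a built-in
panel of 25 scales across eight categories, or any library read from an
AAindex-format flat file — and per sequence partition (whole sequence,
sliding windows, or named regions such as functional domains).

## Worked example

The bundled fixture is a published pairwise comparison of the chimpanzee
and human SAGE1 proteins: 15 replacements over 805 residues, scored with
the Kyte–Doolittle hydropathy scale `h`:

```r
library(dirsel)
rl <- sage1_replacements()
dv <- replacement_deltas(rl, builtin_scales()[["h"]], "from_minus_to")
directional_t_test(dv)
#> <directional_test> scale h (from_minus_to), n = 15
#>   mean = 1.80667  se = 1.04551  net change = +27.1
#>   t = 1.72802 on 14 df, two-tailed p = 0.105966  [none]
```

The net hydropathy change of +27.1 leans positive but does not reach
significance at α = 0.05 (p ≈ 0.106) — with 15 replacements the test has
limited power. The full 25-property panel is one call:

```r
head(run_property_panel(rl, convention = "from_minus_to"), 3)
#>   scale       category  n   mean     t      p net_change direction
#> 1     h Hydrophobicity 15 1.8067 1.728 0.1060      27.10      none
#> 2    Hp Hydrophobicity 15 1.0487 1.748 0.1023      15.73      none
#> 3    Ht Hydrophobicity 15 0.4167 1.810 0.0918       6.25      none
```

`mean` is the average signed property change per replacement (native scale
units), `net_change = n × mean`, and `p` is the two-tailed probability of a
mean this far from zero under H₀. Partitioned analyses and the compact
signed-symbol grid (`+`/`-` per significance tier) come from
`partition_windows()` / `partition_regions()`, `run_partition_panels()`,
and `report_matrix(..., "grid")`.

## Command line

```sh
exec/dirsel analyze --mode protein-pair --input pair.fasta \
    --properties h --convention from_minus_to --format tsv
exec/dirsel analyze --mode blast --input hits.tsv --partition window \
    --window-size 50
exec/dirsel scales list
exec/dirsel simulate --seed 1 --trials 10000 --n 15
```

Exit codes: 0 success, 2 input error, 3 no replacements to test.

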