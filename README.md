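# gp32footprint

Single-nucleotide-resolution footprint mapping of the bacteriophage T4
single-stranded DNA binding protein (gp32) on short 2-aminopurine-labeled
oligo(dT) lattices — for biophysicists analyzing fluorescence titration,
acrylamide (Stern–Volmer) quenching, and CD exciton-coupling data for
cooperative large-ligand binding.

## What it computes

**Exact finite-lattice cooperative binding.** Ligands of site size *n* (7 nt
for gp32) bind nonoverlapping on a lattice of *N* nucleotides; a
configuration with *m* ligands and *j* abutting interfaces has weight
(*K*<sub>a</sub>*L*)<sup>*m*</sup> ω<sup>*j*</sup>. The partition function,
per-position coverage θ<sub>p</sub> and mean occupancy come from a
log-domain transfer recursion, cross-checked against brute-force
enumeration. A saturated cluster of *m* ligands has only *m* − 1
interfaces, so the effective per-ligand constant on a finite lattice is
*K*<sub>a</sub>ω<sup>(m−1)/m</sup>: exponent 0.67 on a 21-mer, 0.75 on a
28-mer.

**Three analysis stages**, mirroring the experimental workflow:

- `titrate`: background/dilution correction, *F/F*<sub>max</sub>
  normalization, equivalence-point stoichiometry by first-six/last-six
  line intersection, *F*<sub>P</sub>/*F*<sub>0</sub> enhancement mapping,
  optional inverse model fit;
- `quench`: Stern–Volmer *K*<sub>SV</sub> = slope of *F*<sub>0</sub>/*F*
  vs [Q] by OLS, half-quench concentration 1/*K*<sub>SV</sub>,
  position-by-ratio summary surface;
- `cd`: replicate averaging, mdeg → Δε/2-AP conversion
  (mdeg / (32980 · c · l · n<sub>AP</sub>)), 325 nm exciton-peak titration
  profiles with plateau and initial slope.

**A synthetic-data generator** (`generate_*`) emulates all three assays —
stock-addition dilution, unlabeled-construct background, replicate noise,
an apparent lattice-competence shortfall that puts 21-mer equivalence
points at ≈ 2.9 monomers/lattice, and a 5′-first site-filling priority for
the CD stage — so the whole pipeline is testable with no instrument files.

## Worked example

```r
library(gp32footprint)

cfg <- generator_config()                                   # the stated world
fl  <- generate_fluorescence_titration(cfg, seed = 1)       # 8 constructs x 3 reps
tit <- analyze_titrations(fl$titrations, fl$background)
tit$summary[, c("construct", "stoichiometry_mean", "enhancement_mean")]
#>   construct stoichiometry_mean enhancement_mean
#> 1     21T10           2.777852         4.519107
#> 2     21T11           2.869130         3.923375
#> 3     21T12           2.796577         4.045747
#> 4     21T13           2.956020         3.936072
#> 5     21T14           2.860949         3.947998
#> 6      21T7           2.791900         4.559093
#> 7      21T8           2.750227         4.456443
#> 8      21T9           2.858843         4.549006
```

Each 21-mer construct saturates near 2.9 added gp32 monomers per lattice
(the stated competence-corrected capacity of a 21-nt lattice for 7-nt
ligands), and 5′-proximal probes (21T7–21T10) recover enhancement ratios
near 4.5 while 3′-proximal ones sit at or below 4.0.

```r
q <- generate_quench_series(cfg, gp32_ratio = 3, seed = 1)  # at saturation
round(analyze_quench(q$series)$surface$matrix[, 1], 2)
#>    7    8    9   10   11   12   13   14
#> 2.59 2.07 1.52 1.76 2.01 2.40 2.70 3.01
```

At saturation every probe position is shielded relative to the no-protein
reference (*K*<sub>SV</sub> ≈ 3.5 M⁻¹), with the deepest protection — less
than half the free value — at position 9, near the 5′ end of the central
binding site.

```r
cd <- generate_cd_titration(cfg, seed = 1)
analyze_cd(cd$spectra, cd$metadata)$profiles[["21T8,9"]]
#> <cd_titration_profile> 13 ratios; plateau 0.202, initial slope -0.875 per ratio
```

The 5′-proximal dimer probe's exciton peak collapses steeply to a plateau
of Δε/2-AP ≈ 0.2; the 3′-proximal probes decay later and retain more
residual amplitude (0.35 on the 21-mer, 0.5 on the 28-mer).

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli/footprint.R", package = "gp32footprint"))')
Rscript "$CLI" run --seed 1 --outdir out        # simulate + analyze + manifest
Rscript "$CLI" simulate --seed 1 --outdir out   # raw CSVs only
Rscript "$CLI" titrate --outdir out             # re-analyze CSVs on disk
Rscript "$CLI" model --length 21 --ratio 3      # lattice-model query
```

See `vignettes/footprint-methods.Rmd` for the model, the generator's
assumptions and every numerical convention.
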