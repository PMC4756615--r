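# cdlkit

Conformation-dependent geometry restraints for the protein backbone, in R.

Backbone bond angles are not constants. They shift systematically — by
several degrees — with the backbone conformation, i.e. with the φ and ψ
torsions. Restraint libraries that give each bond angle a single ideal
value (the conventional single-value library, SVL) therefore pull
well-determined structures away from their true geometry.
A conformation-dependent library (CDL) instead stores, for each residue
class and each 10° × 10° (φ, ψ) bin, an empirical target mean and
standard deviation for every backbone bond length and angle.

`cdlkit` implements that mechanism end to end for structural biologists
and methods developers who want to build, inspect, apply, or test such
libraries:

- **Measure** backbone internal coordinates (5 bond lengths, 7 bond
  angles, φ/ψ/ω torsions) from PDB files, per altloc conformer.
- **Look up** targets by residue class (`Gly` / `Pro` / `IleVal` /
  `General`, plus a next-is-proline flag) and binned (φ, ψ), with a
  total fallback chain down to single values. CDL targets apply only
  across *trans* peptide bonds (|ω| ≥ 150°); cis and twisted linkages,
  termini and non-standard residues get SVL targets, and `mode = "svl"`
  switches conformation dependence off entirely.
- **Build tables empirically** from a corpus of high-resolution
  structures (resolution/occupancy/B-factor/altloc/trans filtering,
  per-cell Welford accumulation, 4σ trimming, minimum-count emission).
- **Idealize** geometry by minimizing the weighted harmonic objective
  `E = w · Σ ((x − μ(class, φ, ψ)) / σ)²` with analytic gradients; each
  restraint is weighted `1/σ²`, and targets are re-looked-up from the
  current coordinates at every macrocycle.
- **Validate** structures against both libraries at once: bond-angle and
  bond-length RMSDs, the same restricted to the "CDL-unique"
  observations whose targets actually differ, 6σ outlier counts, and
  resolution-binned cohort summaries.
- **Simulate** ground-truth peptides and corpora (exact internal
  coordinates, known conformation-dependent means, Gaussian scatter), so
  every claim above is testable without downloading anything.

## Worked example

Simulate a corpus whose true N–Cα–C mean varies with conformation as
`μ(φ, ψ) = 111 + 5 sin φ cos ψ` (σ = 1.2°), build a table from it, and
use the table to idealize and validate a perturbed peptide:

```r
library(cdlkit)
mu <- function(phi, psi) 111 + 5 * sin(phi*pi/180) * cos(psi*pi/180)
spec <- corpus_spec(n_structures = 80, length_range = c(8, 10),
  phi_psi = list(type = "uniform", phi_range = c(-70, -50),
                 psi_range = c(-50, -30)),
  mu = list("N-CA-C" = mu), noise_sigma = c("N-CA-C" = 1.2),
  resolution = 0.9, seed = 11)
corp <- simulate_corpus(spec)
tab <- build_cdl_table(corp$structures, builder_config())
subset(tab$entries, param == "N-CA-C")[, c("phi_lo","psi_lo","mean","sigma","count")]
#>    phi_lo psi_lo     mean    sigma count
#> 10    -60    -40 107.6667 1.050678   143
#> 22    -60    -50 108.1823 1.172128   144
#> 34    -70    -40 107.4653 1.163673   140
#> 46    -70    -50 107.7463 1.182672   137
```

The recovered bin means track the truth (e.g. μ(−65°, −45°) = 107.80°
against the recovered 107.75 ± 1.2/√137) and each bin carries its own
mean, σ and count. A lookup returns the target with its provenance:

```r
cdl_lookup(tab, assign_key("ALA", "LEU", "SER"), -63, -42, "N-CA-C")
#> $mean  107.7463   $sigma  1.182672   $source "CDL"   $count 137
```

Idealization pulls a noisy peptide onto those conformation-dependent
targets (the objective drops from 2.4 × 10³ to ~10⁻⁵ over the monotone
within-macrocycle trace), after which validation shows the signature
the mechanism predicts — near-zero residuals against the CDL, a
visible residual against the single-value targets, concentrated in the
angles whose targets actually differ:

```r
s <- perturb(build_peptide(rep("ALA", 8), phi = -63, psi = -42), 0.02, seed = 2)
res <- idealize(s, tab, mode = "cdl", macrocycles = 3)
rep <- validate_structure(res$structure, tab)
rep$stats[, c("library", "rmsd_angles_all", "rmsd_angles_cdl_unique", "n_angle_outliers")]
#>   library rmsd_angles_all rmsd_angles_cdl_unique n_angle_outliers
#> 1     CDL    1.094307e-05           1.817602e-06                0
#> 2     SVL    1.017413e-01           2.138182e-01                0
```

A command-line interface wrapping the same functions ships at
`system.file("exec", "cdlkit", package = "cdlkit")`, with subcommands
`measure`, `lookup`, `build-table`, `restraints`, `idealize`,
`validate` and `synth`.

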