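---
title: "Conformation-dependent backbone restraints: model, tables, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conformation-dependent backbone restraints: model, tables, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdlkit)
```

## The model

Protein backbone covalent geometry is conventionally restrained toward a
single ideal value per bond or angle per residue type — a *single-value
library* (SVL). Both quantum-chemical calculations on dipeptides and
surveys of atomic-resolution crystal structures show that this picture is
too rigid: backbone bond angles shift systematically by several degrees
as the backbone torsions $(\phi, \psi)$ change. A
*conformation-dependent library* (CDL) replaces the constant target with
a function of conformation: for a parameter $x$ (one of five backbone
bond lengths or seven bond angles), a residue class $g$, and a
$(\phi,\psi)$ bin $b$, the library stores an empirical mean and standard
deviation $(\mu_{g,b,x}, \sigma_{g,b,x})$. Restrained idealization then
minimizes the weighted harmonic objective

$$
E(\mathbf{r}) \;=\; w \sum_{i}
\left( \frac{x_i(\mathbf{r}) - \mu_{g_i, b_i, x_i}}
            {\sigma_{g_i, b_i, x_i}} \right)^{2},
$$

so each restraint carries its own weight $1/\sigma^2$, and $w$ is a
single user-adjustable overall scale. Because the targets depend on the
coordinates through $(\phi,\psi)$, they are refreshed at the start of
each *macrocycle* (outer iteration) and held fixed within it, keeping
every inner minimization a smooth well-defined problem.

Conformation-dependent targets are defined only for residues joined by
*trans* peptide bonds. A parameter receives a CDL target only when the
owning residue has defined $\phi$ and $\psi$ and every peptide bond
involved in defining them — which includes any bond the parameter spans —
is trans ($|\omega| \ge 150^\circ$). Cis ($|\omega| \le 30^\circ$) and
twisted linkages, chain termini, and non-standard residues fall back to
the single-value slice. Treating twisted $\omega$ as non-trans (rather
than trans) is a deliberate choice: a distorted peptide plane is outside
the empirical domain of the binned tables. The `mode = "svl"` switch
turns conformation dependence off entirely and is honoured by every
entry point.

## Residue classes and binning

The lookup key is deliberately small: the residue class of the central
residue — `Gly` (no C$\beta$), `Pro` (ring-constrained N), `IleVal`
($\beta$-branched), `General` (all others) — plus a flag for whether the
*following* residue is proline, which perturbs the carbonyl region of
the preceding residue. The preceding residue of the triplet does not
appear in the key: the parameters that physically span the $i{-}1 \to i$
bond are owned by residue $i{-}1$ and are looked up under *its* key.
This is a documented reduction of a full triplet interface that keeps
empirical tables estimable from desk-scale corpora while retaining the
class structure that matters most.

$(\phi,\psi)$ space is tiled by half-open square bins,
$\mathrm{lo} = w\lfloor x/w \rfloor$ with a default width of
$10^\circ$, so every defined conformation maps to exactly one bin and
$+180^\circ$ wraps to $-180^\circ$. Bins are step-wise: no interpolation
is performed at lookup time. Interpolating between neighbouring bins is
a possible refinement, but it changes the estimator the tables were
built with and is left as an extension.

Lookups are total by construction. The fallback chain runs: exact
(key, bin, parameter) entry with a sufficient observation count; the
same bin under the (`General`, next-is-Pro) key; the same bin under
(`General`, not-Pro); finally the single-value slice for the residue's
own class. Table loading verifies that the single-value slice covers
every (class, parameter) pair (glycine's C$\beta$ entries exempt), so a
gap surfaces at load time, never mid-refinement.

## Deriving tables empirically

`build_cdl_table()` reproduces, at desk scale, the codification
procedure that turns a structure corpus into a table:

1. **Corpus filter.** Keep structures solved at 1.0 Å resolution or
   better (structures without resolution metadata are excluded, not
   assumed good). Within them keep residues whose backbone atoms all
   have full occupancy, B factor $\le 30$ Å$^2$, a single conformation,
   and trans flanking peptide bonds.
2. **Accumulation.** Each accepted residue with defined $(\phi,\psi)$
   contributes its measured parameters to the (key, bin, parameter)
   cell. The streaming accumulator uses Welford updates and is
   order-independent to below $10^{-9}$; finalization re-uses the
   retained per-cell values (a two-pass design chosen for exactness over
   streaming approximation).
3. **Trimming.** Two rounds of 4$\sigma$ trimming per cell, on by
   default and disable-able. The source papers of empirical libraries
   describe their outlier handling elsewhere; some rejection is
   indispensable because a single mis-fitted residue can shift a small
   cell by degrees.
4. **Emission.** Cells with a final count of at least `min_count`
   (default 20) are written; smaller cells are dropped so that lookup
   falls back rather than serving noise. Sigmas are clamped up to floors
   of $0.5^\circ$ / 0.005 Å so a degenerate cell can never produce a
   near-infinite weight. The single-value slice is computed from the
   same accepted observations pooled over conformation, backfilled from
   the built-in defaults for pairs the corpus never observed.

The defaults (bin width $10^\circ$, `min_count` 20, the sigma floors,
4$\sigma$/2 rounds) balance conformational resolution against
statistical noise at the corpus sizes this package targets; all are
recorded in the table metadata so a table is self-describing.

## The synthetic generator

`build_peptide()` places backbone atoms sequentially by
natural-extension (each atom from three predecessors at a prescribed
bond length, bond angle and torsion; order N, C$\alpha$, C per residue,
with the next N placed by $\psi$, the next C$\alpha$ by $\omega$ and the
next C by $\phi$). The carbonyl O is placed in the peptide plane at the
CA–C–O angle with torsion $\psi + 180^\circ$, which makes O–C–N(+1) an
implied parameter: the three angles at the carbonyl carbon sum to
$360^\circ$ when coplanar. C$\beta$ is placed to satisfy both of its
defining angles exactly, on a fixed side of the N–CA–C plane. The
build–measure round trip is exact to numerical precision at zero noise;
this is the anchor property the rest of the test suite leans on.

`simulate_corpus()` draws per-residue internal values as
$\mu_x(\phi,\psi) + \mathcal{N}(0, \sigma_x)$ with every random draw
recorded in a manifest, so the table builder's estimates can be compared
against a known truth. The generator emulates what matters for the
mechanism under test — geometry that varies smoothly with conformation,
Gaussian measurement scatter, resolution metadata — and deliberately
not what does not: there are no side chains beyond C$\beta$, no packing
or solvent, no correlated or resolution-dependent coordinate error
model, and the $(\phi,\psi)$ sampling schemes (uniform patches or a
two-cluster helix/sheet mixture) are test conveniences, not a
Ramachandran prior. Passing the recovery tests therefore demonstrates
that the estimator is correct, not that any particular corpus of real
structures would yield any particular table.

The recovery experiment used by the tests and the acceptance script
fixes these conditions: a true N–C$\alpha$–C surface
$\mu(\phi,\psi) = 111 + 5\sin\phi\cos\psi$ degrees, scatter
$\sigma = 1.2^\circ$, 320 chains of 8–10 residues sampled uniformly over
a $3\times3$-bin helical patch ($\phi \in [-80,-50)$,
$\psi \in [-50,-20)$), giving upwards of 200 accepted observations per
bin. Recovered bin means are required to lie within
$3\sigma/\sqrt{n}$ of the truth at bin centres for at least 95% of bins,
and the recovered scatter within 15% of $1.2^\circ$. These sizes were
chosen once as the smallest corpus at which per-bin standard errors
(about $0.08^\circ$) are an order of magnitude below the signal
amplitude.

## Idealization numerics

Within a macrocycle the objective is minimized over the Cartesian
coordinates of all restrained atoms with analytic gradients (standard
vertex-angle and bond-vector derivatives; the $\sin\theta$ denominator
is guarded at $10^{-10}$, irrelevant for realistic backbone angles).
The inner minimizer is L-BFGS run in bounded chunks; each chunk ends at
an accepted iterate, so the recorded trace is monotone non-increasing by
construction and the tests assert it. Targets are frozen within the
macrocycle; at the next macrocycle start the bin is chosen by the
half-open rule at the current coordinates, with no hysteresis at bin
boundaries — a structure idealized from near a boundary simply converges
under whichever bin it occupies at each refresh. Analytic gradients are
verified against central finite differences (step $10^{-6}$ Å, relative
agreement $10^{-5}$).

Only the geometric objective is implemented. There is no experimental
data term, no automatic overall-weight optimization (the overall weight
is a plain user scalar), and no nonbonded, torsional, planarity or
chirality terms: `idealize()` demonstrates the per-macrocycle update
mechanism, it is not a general-purpose regularizer. A consequence worth
knowing: with only length and angle terms the torsions are free, so
large perturbations can drift $(\phi,\psi)$ across bin boundaries; the
per-macrocycle refresh is exactly what keeps the targets consistent
when that happens.

## Validation conventions

`validate_structure()` scores every observation against both libraries.
The "CDL-unique" subset contains the observations whose targets actually
differ between the libraries — the place where conformation dependence
is visible. Outliers are counted against the $\sigma$ of the library
being validated against (CDL $\sigma$ for CDL validation, SVL $\sigma$
for SVL), with the conventional threshold of $6\sigma$. Cohort
summaries bin structures by resolution in half-open 0.1 Å bins and
average *per-structure* statistics (each structure counts once,
regardless of size); bins with fewer than 50 structures are flagged
low-confidence. Per-structure averaging and the per-library outlier
$\sigma$ are documented choices where either convention would be
defensible.

## Alternative locations

Torsions and observations are computed per altloc conformer: atoms
carrying the conformer's identifier are used where present and
blank-altloc atoms are shared, so each conformer yields its own
observation and restraint stream. No averaging across conformers is
invented. The corpus filter simply excludes residues with alternative
locations from table building (while judging the trans gate of their
neighbours on an existing conformer), which is the conservative choice
for empirical derivation.

## Known limitations

- Cis-peptide linkages always fall back to single values; a
  conformation-dependent treatment of cis peptides would need its own
  (much sparser) empirical tables.
- Side-chain geometry beyond C$\beta$ is out of scope throughout.
- The built-in single-value defaults are generic textbook-style numbers
  intended as a fallback and for synthetic work; they do not reproduce
  any published library's exact values, and this package ships no
  published CDL tables — it builds tables from whatever corpus it is
  given.
- PDB input is fixed-column single-model; mmCIF is not supported.
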