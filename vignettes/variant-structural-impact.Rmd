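---
title: "Structure-guided analysis of missense variants: models and methods"
author: "VariantLens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structure-guided analysis of missense variants: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(VariantLens)
```

VariantLens quantifies what a single amino-acid substitution does to a
protein structure. This vignette is the package's own account of the
models it implements, the parameters that matter, the numerical choices
made where the design was genuinely open, and what the synthetic test
fixtures do and do not establish about real data.

## The analysis, stage by stage

### Walker A annotation

The Walker A motif G-x-x-x-x-G-K-[T/S] is the canonical nucleotide-binding
signature of P-loop NTPases: the four x residues form the phosphate-binding
loop and the conserved lysine coordinates the ATP γ-phosphate (the terminal
threonine is sometimes serine). `findWalkerA()` matches this pattern with
the x positions deliberately unrestricted — an x may itself be glycine, as
in the DNA2 instance GMPGTGKT — and reports *all* matches, overlapping ones
included: motif instances are rare enough that completeness is safer than
greedy suppression. `classifyPosition()` assigns each residue exactly one
role; the x roles carry the "(P-loop)" tag because a substitution there
perturbs the phosphate cradle rather than the catalytic lysine itself.

Author residue numbering is preserved verbatim everywhere. Homologous
structures with offset numbering (the human and mouse DNA2 sequences differ
by one) are reconciled only through an explicit, user-supplied
`shiftNumbering()` call — never inferred.

### Superposition and displacement

`superpose()` computes the least-squares optimal rigid transform by the
Kabsch/SVD method, pairing atoms by (chain, residue number, insertion code,
atom name). For wild-type/mutant displacement profiling the default fit
selection is every shared Cα *excluding the P-loop and a two-residue
flank*: the moving region must not bias the reference frame, and localised
conformational change then shows up cleanly in the per-atom Euclidean
displacements. The superposition frame is a documented choice — the
alternative (all-atom fit) shrinks apparent displacements by distributing
them into the frame.

### Steric clashes

A clash is a non-bonded heavy-atom pair with van der Waals overlap
(radius sum minus distance) above a tolerance, default 0.4 Å with a bundled
Bondi-style radius table. With those radii an arginine guanidinium nitrogen
1.8 Å from a backbone carbonyl oxygen has overlap 3.07 − 1.8 = 1.27 Å —
far past any tolerance, which is exactly the classification the analysis
needs to reproduce. Pairs joined by a covalent path of three bonds or fewer
are excluded; bonds are inferred by distance *within* a residue plus the
explicit backbone links (peptide C–N, nucleotide O3′–P) between consecutive
residues. Atoms of unrelated residues are never treated as bonded however
close they are — a 1.8 Å contact between residues *is* the clash signal,
not a bond. (A naive global distance-based bond inference would silently
swallow precisely the severe clashes of interest.) Disulfide bridges are
not modelled as bonds; for cysteine-rich structures this can flag the S–S
pair itself, a documented limitation.

### Rotamers

`enumerateRotamers()` generates every χ-angle combination on a uniform grid
(default 30°, i.e. (360/30)⁴ = 20 736 conformations for arginine) by
rotating the existing side-chain atoms about each χ bond, and scores each
conformation by the summed overlap of its side-chain atoms against the rest
of the structure. This pure clash score deliberately replaces proprietary
force-field "stability scores": the statement it supports — *no rotamer of
the introduced side chain is sterically acceptable in the wild-type pocket*
— needs only steric exclusion, not energetics. Glycine and alanine have no
rotatable χ and are rejected explicitly.

### Polar interactions and the energy scale

Hydrogen bonds are detected as donor/acceptor heavy-atom pairs within
3.5 Å; salt bridges (both partners formally charged at pH 7) are accepted
to 4.0 Å. No angular term is used: the input models may lack hydrogens, and
a distance-only criterion matches what dotted-line contact diagrams encode
while staying model-independent. Each contact is assigned the standard
interaction-energy scale — ~1 kcal/mol between uncharged polar groups,
~2 kcal/mol between a charged and an uncharged group, ~4 kcal/mol between
two charged groups — as a pure function of the charge class. Formal charges
follow pH-7 conventions (Arg/Lys/His and the N-terminus positive; Asp/Glu,
phosphate oxygens and the C-terminus negative); the titration stage can
revise individual residues when it finds non-standard protonation.
`diffInteractions()` keys contacts on chain/residue-number/atom-name so the
mutated residue matches by number across the pair, making "gained" and
"lost" a clean symmetric set difference.

### Continuum electrostatics

The linear Poisson–Boltzmann equation ∇·ε∇φ − ε_s κ² λ φ = −4πρ is solved
by finite differences: trilinear charge assignment to the eight surrounding
nodes, dielectric values assigned at edge midpoints (protein interior where
the midpoint falls inside the van der Waals union, solvent outside), ion
accessibility λ zeroed within a 2 Å Stern layer around the solute, and
screened-monopole (Debye–Hückel) Dirichlet boundaries. Successive
over-relaxation runs in compiled code with ω = 2/(1 + sin(π/n)), relative
residual tolerance 10⁻⁶ and a 20 000-sweep cap; the convergence flag is
honest and non-convergence is a warning, not a silent pass.

Defaults mirror standard protein continuum practice: ε = 4 inside the
protein, 80 in water, 300 K, 0.1 M ionic strength, Coulomb constant
332.06 kcal·Å/(mol·e²), β recomputed from the temperature. Three-step grid
focusing (2.5, 1.0, 0.3 Å; coarsest grid = solute bounding box + 40 %
margin, finer grids = region of interest + 8 Å with boundaries interpolated
from the coarser solution) brings the fine-grid error of the Born-ion test
well inside the 3 % tolerance against the closed form ΔG = (332.06 q²/2a)(1/ε_out − 1/ε_in),
with the error shrinking monotonically from the 2.5 Å level down. The
molecular volume is the plain vdW union (probe rolling available but off by
default) — simpler than a solvent-excluded surface and a documented
deviation from molecular-surface codes.

Intrinsic pKa shifts use the standard two-environment thermodynamic cycle:
the charging free energy of a site in the protein (all other titratable
sites neutral, fixed background charges present) minus the same energy in
the model compound — the site's own residue, in its in-situ conformation,
alone in solvent. Both environments are solved on *identical* grids so the
grid self-energy cancels exactly. The interaction matrix W is the energy
between unit charge-difference distributions of two sites in the protein
environment, symmetrised by averaging the two one-sided estimates
(the tests assert reciprocity and agreement with the Coulomb closed form
within 5 % on the pair fixture). The bundled charge set is a simplified formal-charge model
(unit charges distributed over the terminal atoms of each ionisable group;
neutral states zero); users supply refined per-atom charge sets through the
same site-definition format.

### Multi-site titration

The microstate energy implemented is

E(x) = Σ_μ x_μ ΔG_intr,μ(pH) + ½ Σ_{μ≠ν} q_μ(x_μ) q_ν(x_ν) W_μν

with x_μ ∈ {0,1} the protonation indicator and q the state's formal charge.
The sign convention ΔG_intr(pH) = ln(10)·kT·(pH − pKa_intr) applies to
*both* acids and bases: with the protonation indicator as the state
variable, this — and only this — makes an isolated site reproduce
Henderson–Hasselbalch, ⟨x⟩ = 1/(1 + 10^(pH − pKa)), exactly, and keeps the
reference-pKa bases (Lys 10.4, Arg 12.0) protonated at pH 7 as they must
be. Averages come from exact Boltzmann enumeration over all 2ⁿ microstates
(hard-guarded at n = 20) or from Metropolis Monte Carlo: one sweep is n
single-site flips plus a joint flip for every pair coupled more strongly
than 2 kcal/mol (defaults 100 000 sweeps, 10 000 burn-in), seeded through
R's RNG for bitwise reproducibility. Standard errors are batch means,
floored by a Laplace-smoothed binomial bound so a site that never flips
still reports non-zero uncertainty.

Histidine is modelled as two coupled proton sites (Nε reference pKa 7.0,
Nδ 6.6) carrying ±½ formal charges so the doubly protonated microstate sums
to +1 and the neutral tautomers to 0; the doubly *de*protonated
(imidazolate) microstate is excluded by a configurable +10 kcal/mol
penalty. Site-resolved W columns are used for the two His sites.

One property deserves emphasis because it is commonly mis-stated: an
*individual* site's titration curve in a coupled system need not be
monotone in pH. In spin variables the pairwise term of E(x) is
antiferromagnetic, so site–site correlations can be negative and a site's
curve can rise locally in strongly coupled systems. What thermodynamics
does guarantee —
and what the tests assert — is that every *isolated* site is exactly
monotone and that the *total* protonation of any system is non-increasing
in pH, its derivative being −β ln10 kT·Var(Σx).

`pkaCurve()` reports the half-protonation pH by linear interpolation on a
pH 0–14 grid with 0.25 steps; a curve that never crosses ½ in range is
flagged, not extrapolated. `reportPattern()` defines a site's standard
state as the one its *reference* pKa implies at the evaluation pH — Asp/Glu
deprotonated, Lys/Arg/His protonated, and also Cys/Tyr protonated at pH 7 —
and reports a deviation when the probability of the non-standard state
exceeds ½, e.g. a glutamate held protonated by an adjacent DNA-phosphate
group while its reference state is deprotonated.

## The synthetic-data generator

`makeFixture()` builds every structure the test-suite needs from ideal bond
lengths and angles — no experimental coordinates enter the package. Each
bundle carries ground truth computed *at generation time by an independent
in-module oracle*, never by the pipeline under test: the P-loop peptide's
motif location comes from a regular-expression scan; displaced-pair
magnitudes are encoded by construction; the crowded pocket is verified by
random-χ sampling with a direct distance check; the Born ion and Coulomb
pair carry closed forms; titration systems carry probabilities from a
scalar double-loop enumeration. The `variant_pair` fixture encodes the
geometry under study — a helical Walker A scaffold, an ATP whose
γ-phosphate shifts 6 Å while the head group shifts 1 Å, a
lysine–γ-phosphate bridge lost and an inter-domain arginine–aspartate
bridge gained, a glutamate 50 Å from the nucleotide — so the pipeline's
measurements can be checked against constructed truth.

What passing these tests shows: the measurement machinery (superposition,
clash and contact detection, the PB solver, the titration statistics) is
correct at stated tolerances. What it does not show: agreement with any
particular experimental or predicted model of a real protein. Real
structures add coordinate error, alternate conformations, hydrogens,
heterogeneous ligands and force-field-optimised geometries that ideal
fixtures do not emulate; conclusions about a real variant inherit the
quality of the input models.

## Problem sizes and runtime choices

The shipped tests and the acceptance script run the solver at the sizes the
physics needs and no larger: the Coulomb check on a 65³ grid at 0.5 Å, the
Born cycle through the full 2.5/1.0/0.3 Å focusing ladder, site-energy
fixtures on two-level ladders (2.0/0.8 Å) where the uniform-dielectric
answer is boundary-dominated, Monte Carlo runs of 20 000–50 000 sweeps on
5–10-site systems, and rotamer grids of 60° in pipeline contexts (the 30°
default remains the analysis setting). The pipeline's electrostatics stage
is opt-in via `pipelineConfig(electrostatics = ...)`, defaulting to on for
structures up to 500 residues; for widely separated titratable sites the
finest focus region grows with the site bounding box, and the
`levels` entry is the intended control.

## Known limitations

* Distance-only hydrogen-bond detection accepts some geometrically poor
  contacts a directional model would reject.
* The bundled charge set is a formal-charge simplification; quantitative
  pKa work on real proteins should supply refined charges (the
  site-definition format accepts them, including metal-cluster charges).
* The vdW-union dielectric boundary omits re-entrant solvent exclusion,
  slightly overestimating solvent penetration between close atoms.
* Rotamer enumeration rotates existing side-chain atoms; it does not
  rebuild missing side chains, and bond lengths/angles stay fixed at input
  values.
* No conformational relaxation accompanies protonation-state changes, and
  no nonlinear PB, membrane slabs or constant-pH dynamics are provided.
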