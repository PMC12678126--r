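# VariantLens

Structure-guided interpretation of missense variants in nucleotide-binding
proteins, for structural bioinformaticians and molecular modellers who need
to turn a wild-type/mutant model pair into a quantitative, reproducible
impact report.

A single amino-acid substitution in a Walker A (P-loop) motif — the
nucleotide-binding signature **G-x-x-x-x-G-K-[T/S]**, whose conserved lysine
coordinates the ATP γ-phosphate — can rearrange the whole ATP-binding
geometry of a helicase without abolishing binding. VariantLens implements
the analyses needed to characterise such a variant:

* **Motif annotation** — locate every Walker A instance in a chain and
  classify the variant position (G1, x1–x4 "P-loop", G2, K, T/S).
* **Geometry** — Kabsch (SVD) superposition and per-atom displacement
  profiles; steric-clash detection by van der Waals overlap
  (overlap = r₁ + r₂ − d > 0.4 Å by default, Bondi-style radii); side-chain
  rotamer enumeration on a uniform χ grid scored by summed overlap;
  hydrogen-bond / salt-bridge inventories with the charge-class energy
  scale (~1 kcal/mol uncharged–uncharged, ~2 charged–uncharged,
  ~4 charged–charged) and gained/lost diffing between wild type and mutant.
* **Continuum electrostatics** — a finite-difference linear
  Poisson–Boltzmann solver (SOR on the 7-point stencil, edge-centred
  dielectrics, Debye–Hückel boundary, three-step grid focusing at
  2.5/1.0/0.3 Å) producing intrinsic pKa shifts relative to reference
  values (Asp 4.0, Glu 4.4, Cys 9.5, Tyr 9.6, Lys 10.4, Arg 12.0, His
  Nε 7.0 / Nδ 6.6) and the site–site interaction matrix **W**.
* **Multi-site titration** — equilibrium protonation probabilities

  ⟨x_i⟩ = Σ_x x_i exp(−β[Σ_μ x_μ ΔG_intr,μ + ½ Σ_{μ≠ν} q_μ q_ν W_μν]) / Z

  over all 2ⁿ protonation microstates, by exact enumeration (n ≤ 20) or
  seeded Metropolis Monte Carlo, with titration curves, half-protonation
  pKa values, and deviations from standard protonation states.
* **Synthetic data** — every fixture needed to test the above (ideal
  P-loop peptides, displaced structure pairs, crowded rotamer pockets, Born
  ions, Coulomb pairs, coupled titration systems) generated from ideal
  geometry with analytic or independently enumerated ground truth.
* **Pipeline** — `runVariantReport()` orchestrates all stages and emits a
  JSON/text report with full provenance.

## Worked example

Scan the mouse DNA2 P-loop segment and run the variant pipeline on a
synthetic wild-type/mutant pair in which a P-loop threonine is replaced by
arginine:

```r
library(VariantLens)

hits <- findWalkerA("GMPGTGKT", 649:656, "A")
hits[[1]]
#> Walker A motif hit on chain A: GMPGTGKT (649-656), K at 655
classifyPosition(hits[[1]], 653)
#> [1] "x4 (P-loop)"

fx  <- makeFixture("variant_pair", seed = 1)
rep <- runVariantReport(structures(fx)[[1]], structures(fx)[[2]],
                        variantSpec("A", 652, "T", "R"),
                        groundTruth(fx)$regions,
                        pipelineConfig(electrostatics = FALSE, chi_grid = 60))
rep
#> VariantReport T652R (chain A, residue 652)
#>   motif role: x4 (P-loop)
#>   clashes at variant residue: 1
#>   interactions gained/lost: 1/1
```

The motif role says the substituted residue sits at the fourth "x" slot of
the phosphate-binding loop. The gained interaction is an inter-domain
Arg–Asp salt bridge (charged–charged, 4 kcal/mol class) absent in the wild
type; the lost one is the conserved-lysine–γ-phosphate bridge. The
displacement table in `rep` reports the γ-phosphate moving 6 Å while the
ATP head group moves only 1 Å — the geometry the fixture encodes.

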