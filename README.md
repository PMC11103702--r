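# glmrh

Hydrodynamic radii of intrinsically disordered and multidomain proteins
from sequence and disorder annotation, via the globule-linker model (GLM)
with minimum-dissipation hydrodynamics.

## Who this is for

Experimentalists and modellers who measure translational diffusion of
disordered proteins (FCS, PFG-NMR, SEC, DLS, AUC) and want a
first-principles, fitting-parameter-free prediction of the hydrodynamic
radius R<sub>h</sub> from nothing more than the sequence and a per-residue
disorder prediction (or explicit folded-domain intervals).

## The model in brief

1. **Coarse-graining.** Residue runs with disorder probability < 50% for
   ≥ 3 consecutive residues are ordered; disordered loops of ≤ 14 residues
   flanked by ordered runs are absorbed into one folded domain. Each
   domain becomes a single sphere of radius
   (3m / 4πρ<sub>globular</sub>)<sup>1/3</sup> + a<sub>hydration</sub>
   (ρ<sub>globular</sub> = 0.52 Da/Å³, a<sub>hydration</sub> = 3 Å); each
   disordered residue becomes a bead of steric diameter 3.8 Å whose
   hydrodynamic radius is inflated to 4.2 Å.
2. **Ensembles.** Conformations are drawn from the self-avoiding random
   walk of spheres (consecutive spheres touch, bond directions uniform,
   conditioned on no non-adjacent overlap) with an exact recursive
   dimerization sampler (compiled, seeded, reproducible).
3. **Hydrodynamics.** R<sub>h</sub> is estimated from the
   ensemble-averaged trace mobility matrix
   A<sub>ij</sub> = 2πη Tr⟨**μ**<sub>ij</sub>⟩ of the generalized
   Rotne–Prager–Yamakawa model (well defined for overlapping beads): the
   minimum dissipation approximation gives
   R<sub>h</sub> = Σ<sub>ij</sub> (A<sup>−1</sup>)<sub>ij</sub>, the
   tightest single-point short-time bound on long-time diffusion. The
   classical Kirkwood–Riseman estimates
   (full and simplified) are computed alongside.

Benchmark tooling scores predictors with RMSD, RMSRD, the coefficient of
determination R² (and its adjusted form), and third quartiles of absolute
and relative errors, against leave-one-out power-law baselines.

## A worked example

```r
library(glmrh)
fx <- generate_fixture(list(c("disordered", 30), c("ordered", 50),
                            c("disordered", 30)), seed = 7)
fit <- glm_rh(fx$track, n_conformers = 100, seed = 1)
fit
#> Globule-linker hydrodynamic model
#>   110 residues -> 61 beads (1 globules, 60 linkers)
#> R_h (minimum dissipation): 23.57 A +/- 0.18 (SEM)
#> R_h (Kirkwood, full):      18.00 A
#> R_h (Kirkwood, simplified): 19.34 A
#> ensemble: 100 conformers, seed 1
predict(fit, "diffusion")
#> [1] 9.091e-11   # m^2/s at 293.15 K in water
```

The synthetic protein has a 50-residue folded domain (one globule bead of
~17 Å) between two 30-residue disordered tails (one 4.2 Å bead per
residue). The minimum-dissipation radius (23.6 Å) exceeds both Kirkwood
estimates, as it must: the Kirkwood formula tracks the geometric centre,
which is suboptimal when bead sizes differ strongly. The SEM column is the
batch-means Monte Carlo error of the 100-conformer ensemble.

Real proteins enter through files instead of fixtures:

```r
seqs  <- read_fasta("protein.fasta")
track <- read_disorder_track("protein.diso", sequence = seqs[[1]])
fit   <- glm_rh(track, n_conformers = 100, seed = 1)
```

or from the shell via the thin CLI in `inst/scripts/glmrh`
(`predict`, `sample`, `benchmark`, `fixture` subcommands).

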