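# secsans

Analysis of SEC-SANS experiments on protein complexes in solution: the
complete chain from per-frame elution data to size parameters, shape
parameters, and low-resolution structure.

## The problem

Size-exclusion chromatography coupled inline to small-angle neutron
scattering (SEC-SANS) separates the species of a polydisperse protein
solution immediately before they cross the neutron beam, so each
elution peak yields its own scattering curve I(Q). This resolves
mixtures — e.g. coexisting 2:1 and 2:2 complexes of the fluorescence
recovery protein (FRP) with a compact orange carotenoid protein (OCP)
variant — that conventional SANS would average into one curve.

For each extracted fraction the package computes the standard
solution-scattering characterization:

- **Guinier analysis**: I(Q) ≈ I(0)·exp(−Q²Rg²/3) at low Q, fitted by
  weighted least squares of ln I vs Q² over an automatically selected
  (or Q·Rg-band) window → radius of gyration Rg and forward scattering
  I(0).
- **P(r) by regularized indirect Fourier transform**: inversion of
  I(Q) = 4π ∫ P(r) sin(Qr)/(Qr) dr on [0, Dmax] with a curvature
  penalty (discrepancy-principle regularization) and a Dmax scan;
  Rg² = ∫r²P dr / 2∫P dr.
- **Kratky diagnostics**: Q²I(Q) bell shape (folded) vs high-Q plateau
  (unfolded).
- **Form-factor fitting**: orientation-averaged elliptical cylinder
  (minor radius a, axis ratio ν, length L) via double Gauss–Legendre
  quadrature with the Λ₁(t) = 2J₁(t)/t cross-section kernel, fitted by
  bounded weighted least squares; sphere and circular cylinder
  included.
- **Ab initio reconstruction**: dummy-atom models on a hexagonal
  lattice, simulated annealing against the curve with a compactness
  penalty, P1 or exact P2 symmetry, multipole-expansion scoring with a
  Debye-sum cross-check, multi-run alignment/averaging and NSD.
- **Atomistic scattering**: Debye sums over PDB structures with
  neutron scattering lengths, implicit hydrogens, labile-H exchange
  and displaced-solvent contrast, plus a coarse two-rigid-block pose
  search.

A synthetic-run generator emulates the experiment (two overlapping
Gaussian elution peaks of elliptical-cylinder species on the
instrument grid Q = 0.03–0.25 Å⁻¹, 6 Å ± 10% wavelength smearing,
counting-statistics noise), so the whole chain is testable without
beamline data.

## Worked example

```r
library(secsans)

comps <- make_reference_components()        # two-species study geometry
run   <- simulate_run(comps, seed = 42)     # 60 frames, counting noise
scattergram(run)
#> Scattergram: 60 frames, 2 peak(s) at frame(s): 18, 36

run_pipeline(run)
#> == Fraction: high_mw ==
#>   Guinier:   Rg = 30.99 A, I(0) = 0.05208 (0.93 < QRg < 1.24)
#>   P(r):      Rg = 31.29 A, I(0) = 0.05176, Dmax = 90 A
#>   Kratky:    folded
#>   Cylinder:  a = 13.06 A, nu = 2.14, L = 99.0 A, chi^2 = 0.97
#> == Fraction: low_mw ==
#>   Guinier:   Rg = 26.49 A, I(0) = 0.05247 (0.79 < QRg < 1.25)
#>   P(r):      Rg = 26.31 A, I(0) = 0.05207, Dmax = 70 A
#>   Kratky:    folded
#>   Cylinder:  a = 14.53 A, nu = 2.09, L = 72.6 A, chi^2 = 0.812
```

Reading the report: the first-eluting fraction is larger (Guinier
Rg ≈ 31 Å vs 26.5 Å; larger Dmax) and more elongated (cylinder length
≈ 99 Å vs 73 Å at nearly equal cross-section radii ≈ 13–15 Å) — the
signature separating a 2:2-like elongated complex from a 2:1-like
compact one. The cylinder fits recover the generating geometries
(L = 100 and 73 Å) within a few percent at reduced χ² ≈ 1, and both
fractions are classified folded, as compact complexes should be.

A thin command-line front end over the same functions lives in
`inst/cli/secsans.R`:

```sh
Rscript inst/cli/secsans.R guinier curve.dat --qrg-window 0.35,1.26
Rscript inst/cli/secsans.R pr curve.dat --scan 60,160,10
Rscript inst/cli/secsans.R pipeline run_dir/ --seed 1
```

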