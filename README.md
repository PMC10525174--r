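# directECGI

Direct (non-iterative) reconstruction of epicardial potential sources from
body-surface ECG recordings — electrocardiographic imaging (ECGI) by
equivalence-principle surface sources and an eigenfunction expansion of the
finite-element volume conductor.

## The problem

The inverse problem of electrocardiography asks for the electric sources on
the heart's surface (the epicardium) that generated a set of potentials
measured by an electrode vest on the torso. The classical route solves it
iteratively: guess sources, solve the forward problem, compare with the
measurements, update — often with Tikhonov-style regularization, and at a
computational cost that rules out bedside use.

`directECGI` implements a direct alternative. By the equivalence (Huygens)
principle, the measured potentials, interpolated over the whole torso
surface, can themselves be treated as a secondary source layer that
reproduces the interior field. Expanding the volume potential in
eigenfunctions of the conductivity operator turns the reconstruction into a
single precomputable matrix product per beat — the expensive eigenanalysis
happens once per torso model, and the per-beat inverse runs in milliseconds.
The package is aimed at researchers in computational cardiac
electrophysiology and bioelectric inverse problems who want a transparent,
fully testable reference implementation with a self-contained synthetic
test bed.

## The method

1. **Volume conductor.** A hexahedral FEM mesh with per-element tissue
   mixing: an element containing tissues with volume fractions `f_n` and
   conductivities `σ_n` gets `σ_e = Σ f_n σ_n` (S/m). Assembly of
   `K = Σ_e σ_e ∫ ∇N_i·∇N_j dV` (2×2×2 Gauss) gives the discrete
   generalized Laplacian with insulated (natural) boundary.

2. **Eigenbasis.** Generalized symmetric eigenpairs `K V̂_n = λ_n M V̂_n`
   with the lumped volume mass `M`, so `V̂ᵀ M V̂ = I`. Modes are sorted by
   ascending `λ`; small-eigenvalue modes carrying negligible signal power
   (Parseval: the squared expansion weight is the modal power) are
   discarded by a 99.9 %-energy rule, which is what keeps the retained
   spectrum well conditioned (`max λ / min λ`).

3. **Surface source.** Sparse electrode recordings are interpolated onto
   every outer-surface node by pyramid patches (apex at each electrode,
   tetrahedral sub-elements towards the neighbouring electrodes), exact at
   the electrodes and constant-preserving. The interpolated distribution
   `V_d` is the Huygens voltage source, zero off the surface.

4. **Weights by orthogonality.** `w_m(t) = ∫_S V_d V̂_m dS`, realized with
   the lumped surface mass as a precomputed geometric factor matrix:
   `w(t) = [V]_geomᵀ V_d(t)` — one matrix product per beat. (A branch
   current source `I = Y_ij (V_dj − V_di)/ΔL_ij` with weights
   `w_m = ∫_S I V̂_m dS / (λ − λ_m)` is available as a flagged
   alternative.)

5. **Epicardial projection.** The volume expansion `V = Σ w_m V̂_m` is
   projected on the heart surface with the FEM shape functions,
   `V_epic,k = ∫_S_epic Σ w_m V̂_m N_k dS / ∫ N_k² dS`; under mass lumping
   the shape functions are exactly orthogonal and the projection is the
   nodal restriction.

6. **Self-validation.** The reconstructed epicardial sources are
   forward-solved (epicardial Dirichlet data, insulated torso) back to the
   electrodes and compared with the input recordings by per-electrode
   Pearson correlation over the beat.

A parametric synthetic torso (layered elliptical cylinder with an interior
heart block, PQRST-like raised-cosine activation, vest-style electrode
lattice, seeded measurement noise) makes the whole chain testable without
clinical data.

## Worked example

```r
library(directECGI)

## 1. Build the synthetic torso and its vest-style electrode layout
cfg    <- synth_config()                   # 22 levels x 32 sectors, 14 x 10 cm
mesh   <- build_synthetic_torso(cfg)
layout <- synthetic_electrode_layout(mesh) # 128 electrodes
mesh
#> Hexahedral volume-conductor mesh
#>   nodes: 3190 (930 on outer surface)
#>   elements: 2688 (64 heart)
#>   tissues: myocardium=0.1 S/m, muscle=0.2 S/m, lung=0.05 S/m, fat=0.04 S/m
#>   outer faces: 928, epicardial faces: 96

## 2. Simulate a beat and synthesize the "measured" ECG
truth      <- simulate_epicardial_activation(mesh)
recordings <- synthesize_recordings(mesh, truth, layout)
dim(recordings)
#> [1] 128 740                              # 128 electrodes x 740 ms @ 1 kHz

## 3. Run the direct inverse and self-validate
result <- run_pipeline(mesh, recordings, layout, pipeline_config())
#> eigenanalysis: 240 modes on 3190 nodes
#> retained 240 / 240 modes; condition number 33.91 -> 33.91
#> self-validation: mean CC 0.9942 over 128 electrodes
result
#> Direct inverse result
#>   retained modes: 240 / 240, condition 33.91 -> 33.91
#>   self-validation mean CC: 0.9942 (min 0.9868)
#>   timings (s): assembly 0.68, eigenanalysis 4.08, interpolation 0.50,
#>                weights 0.05, projection 0.03, validation 0.47
```

The mean correlation coefficient of 0.994 (worst electrode 0.987) says the
epicardial sources recovered by the direct inverse regenerate the measured
surface potentials almost exactly; `result$epicardial` holds the
reconstructed node-by-time epicardial potential map (mV), exportable with
`write_epicardial_csv()` or `write_vtk_mesh()` for visualization. The
eigenanalysis line illustrates the cost split: ~4 s of one-off
pre-processing versus milliseconds for the per-beat inverse.

A thin command-line front end wraps the same functions:

```sh
directECGI synth --out data/                     # mesh + layout + recordings
directECGI eigs  --mesh data/mesh.json --out basis.json
directECGI run   --mesh data/mesh.json --recordings data/recordings.csv \
                 --layout data/layout.csv --basis basis.json --out results/
```

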