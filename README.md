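# bindscape

Trajectory-based decoding of inhibitor binding mechanisms for
bromodomain-like receptors, in R.

Bromodomains (BRD4, BRD9 and relatives) are acetyl-lysine reader modules
and prominent drug targets. Understanding *why* an inhibitor binds one
family member more tightly than another requires looking at whole
conformational ensembles, not single structures: which inter-domain
residue contacts distinguish one bound state from another, how binding
reshapes the free-energy landscape, and which energy components and
residues pay for the affinity difference. `bindscape` implements that
analysis workflow end to end for conformational ensembles (multi-model
PDB or plain coordinate tables), together with a synthetic-ensemble
generator with planted, recoverable structure so that every stage can be
validated against ground truth.

## What it computes

**Contact-map deep learning with saliency.** Each frame becomes a binary
residue contact map, M[i,j] = 1 iff the Cα–Cα distance ≤ 4.5 Å
(heavy-atom rule optional), rendered as an N×N grayscale image. A small
2D CNN — two 1×1 convolutions (16, 32 filters), each followed by 2×2
max-pooling and ReLU, then fully connected 512/128 layers with dropout
0.5 and a softmax head — classifies frames by bound inhibitor.
Vanilla-gradient saliency |∂ score_k / ∂ pixel| is masked by the contact
map of the most populated structural cluster's medoid and aggregated
over structural-domain pairs (αZ, ZA-loop, αA, αB, BC-loop, αC),
ranking which inter-domain contacts the classifier found
class-characteristic. The CNN (forward, backprop, Adam) is implemented
in-package on BLAS matrix algebra and verified against finite
differences and a multinomial-logistic oracle.

**PCA and free-energy landscapes.** Cα-coordinate covariance
C = ⟨(q−⟨q⟩)(q−⟨q⟩)ᵀ⟩ after iterative-mean superposition;
eigenvalue variance fractions; projections onto the leading
eigenvectors; 2D free-energy surfaces G = −k_B T ln(P/P_max) by
Boltzmann inversion at 300 K; persistence-based basin detection with
representative frames; per-residue mode displacements.

**Structural metrics.** Kabsch superposition, best-fit RMSD series with
frequency-distribution peak detection, RMSF about the iterative mean,
mass-weighted radius of gyration, Shrake–Rupley solvent-accessible
surface area, and hydrogen-bond occupancy under the strict
D···A < 3.5 Å and D–H···A > 120° criteria.

**MM-GBSA energetics.** Single-trajectory binding free energies
ΔG_bind = ΔE_ele + ΔE_vdW + ΔG_gb + ΔG_surf − TΔS with Coulomb
(k_e = 332.0636 kcal·Å/mol·e²), Lennard-Jones (Lorentz–Berthelot),
pairwise Still-form generalized Born with supplied Born radii, and
ΔG_surf = γ·ΔSASA with γ = 0.0072 kcal/mol/Å²; component means ± sd,
cross-system comparisons, per-residue decomposition with a 0.8 kcal/mol
key-residue threshold, a Schlitter quasi-harmonic entropy bound, and
ΔG_exp from IC50.

## Worked example

Aggregate published MM-GBSA component means for H1B bound to BRD4, and
compare against the same inhibitor bound to BRD9:

```r
library(bindscape)
b4 <- reference_binding_free_energy("BRD4", "H1B")
print(b4)
#> <binding_free_energy> (kcal/mol)
#>           mean sd
#> dEele   -29.97 NA
#> dEvdw   -41.78 NA
#> dGgb     42.71 NA
#> dGsurf   -5.70 NA
#> dGpol    12.74 NA
#> neg_TdS  18.65 NA
#> dGbind  -16.09 NA
b9 <- reference_binding_free_energy("BRD9", "H1B")
round(compare_systems(b4, b9), 2)
#>     dEele     dEvdw      dGgb    dGsurf     dGpol   neg_TdS    dGbind favorable
#>    -13.85     -6.96      9.64     -0.59     -4.21      6.46     -5.30     -7.55
```

Reading: H1B binds BRD9 5.30 kcal/mol more favorably than BRD4; the van
der Waals term strengthens by 6.96 and the favorable-force sum
(ΔE_vdW + ΔG_surf) by 7.55 kcal/mol, partly offset by a 6.46 kcal/mol
larger entropy penalty.

Train the contact-map classifier on a synthetic three-class ensemble
with one planted inter-domain contact per class:

```r
spec <- synthetic_spec(40, list(c(4, 28), c(12, 37), c(20, 33)),
                       sigma = 0.3, frames_per_class = 100, seed = 1)
gen <- generate_class_ensembles(spec)
stacks <- lapply(gen$class_ensembles, contact_map_stack)
ds <- join_image_datasets(lapply(1:3, function(k)
  set_labels(maps_to_images(stacks[[k]]), rep(k, 100))))
ds <- split_train_val(ds, 0.8, seed = 1)
fit <- train_classifier(build_model(cnn_spec(40, 3, seed = 1)), ds,
                        epochs = 10)
print(fit)
#> <train_result> 10 epochs, validation accuracy 95.00%, loss 0.0736
fit$confusion
#>     pred
#> true  1  2  3
#>    1 20  0  0
#>    2  2 18  0
#>    3  1  0 19
```

Each confusion row sums to its class's validation count; the few
misclassified frames are those whose planted contact was broken by the
0.3 Å coordinate noise. `run_pipeline()` chains all stages (simulate →
featurize → train → attribute → metrics → pca → gbsa → report) from one
config and writes a manifest; see the methods vignette
(`vignettes/bindscape-methods.Rmd`) for the models, conventions and
parameter choices.

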