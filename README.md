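# fedasc

Privacy-preserving federated transfer learning for **direct attenuation and
scatter correction (ASC) of ⁶⁸Ga PET images**, at desk scale.

In ⁶⁸Ga-PSMA/DOTA-TATE whole-body PET, CT-based correction is the step that
introduces the two classic ⁶⁸Ga artefacts: photopenic **halo** rings around
very hot organs (scatter over-correction under a non-negativity constraint)
and **mismatch** bands at the lung–diaphragm interface (PET/CT spatial
disagreement). A network that regresses the corrected image directly from
the *uncorrected* one never sees the CT — so a model trained on clean pairs
reproduces artefact-free corrected images even where the clinical
correction is artefacted. Training such models needs multi-centre data that
cannot be pooled, which motivates the comparison this package implements:

* **CeBa** — each centre trains on its own data;
* **CeZe** — all data pooled centrally;
* **FTL** — differentially private federated averaging (DP-FedAvg with
  L2-clipped updates, Gaussian server noise, μ-GDP accounting) followed by
  per-centre fine-tuning into personalized models.

The package is aimed at methodologists who want a fully reproducible,
CPU-sized testbed for this pipeline: a synthetic multi-centre phantom
cohort with controllable scanner heterogeneity and artefact injectors, the
clinical preprocessing chain, a compact trainable image regressor, the
federated/DP machinery, image-quality metrics and the rater statistics used
in such studies.

## The core model

The regressor is a nested-U encoder–decoder: every stage is a residual
U-block (conv → batch-norm → ReLU chains with internal down/up-sampling and
a residual skip), with deep supervision — side outputs from each decoder
stage enter the loss next to the fused output:

L(θ) = ‖ŷ_fused − y‖² / n + Σ_s ‖ŷ_side(s) − y‖² / n,

optimized with Adam (lr 10⁻³, decoupled weight decay 10⁻⁴). Federated
round r with clients k: Δ_k = θ_k − θ_{r−1} is clipped to ‖Δ_k‖₂ ≤ C, and

θ_r = θ_{r−1} + Σ_k w_k Δ̃_k + N(0, (z·C·max_k w_k)² I),

which costs μ = 1/z per round in Gaussian differential privacy; R rounds
compose to μ = √R / z, converted to (ε, δ) by
δ(ε) = Φ(−ε/μ + μ/2) − e^ε Φ(−ε/μ − μ/2).

All of this — including the reverse-mode tape behind the network, with
compiled im2col/pooling kernels — lives in the package with no
deep-learning framework dependency.

## A worked example

```r
library(fedasc)

# three heterogeneous centres, 6 clean patients each, 64x64 phantoms
profiles <- make_centre_profiles(3, seed = 1, n_clean = 6, n_artefact = 2,
                                 matrix_size = 64)
cohort  <- generate_cohort(profiles, seed = 1)
pairs   <- preprocess_cohort(cohort, target = c(64, 48))
split   <- split_cohort(cohort$manifest, seed = 1)
split_sizes(split)
#> # A tibble: 3 x 3
#>   centre_id  test train
#>   <chr>     <int> <int>
#> 1 1             2     4
#> 2 2             2     4
#> 3 3             2     4

# train the DP federated transfer scenario on the training split
get <- function(sub) {
  d <- split[split$subset == sub, ]
  lapply(split(d$patient_id, d$centre_id),
         function(ids) lapply(ids, function(p) pairs[[p]]))
}
cfg <- network_config(n_stages = 2, base_channels = 6, rsu_inner_depth = 2,
                      batch_size = 4, learning_rate = 0.005, seed = 1)
fit <- train_ftl(get("train"), NULL, cfg,
                 fl_config(n_rounds = 10, fine_tune_epochs = 5, seed = 1),
                 dp_config(clip_norm = 2, noise_multiplier = 0.05))
fit$spend
#> <privacy_spend: mu = 63.2456 over 10 rounds>
#> eps_0.5   eps_1   eps_2   eps_4   eps_8
#>       1       1       1       1       1

# evaluate the personalized models on the test split
records <- evaluate_scenarios(list(ftl = fit$personalized), get("test"))
summarize_metrics(dplyr::filter(records, domain == "suv"))
```

`summarize_metrics()` reports each group as mean ± SD with a 95% CI —
e.g. a `mean_mae` of 0.31 in the `suv` domain means predicted and reference
corrected images differ by 0.31 SUV on average inside the body. The privacy
print-out says those ten rounds at noise multiplier z = 0.05 amount to a
μ-GDP cost of √10/0.05 ≈ 63 (a deliberately weak guarantee at toy scale;
z is the dial).

There is also a command-line pipeline (`exec/fedasc`) with subcommands
`simulate`, `preprocess`, `train --scenario {ceba,ceze,ftl}`, `evaluate`,
`stats` and `report`, each writing a manifest with its config hash and
seeds.

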