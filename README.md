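# netpert

Perturbation pattern prediction on biological networks.

When one species in a biochemical reaction network is perturbed and held at
a displaced level, the steady-state values of all other species shift. The
full response pattern is the **sensitivity matrix**
`S[i, j] = dx_i / dx_j` — the change in species `i` per unit sustained
displacement of species `j`. Computing `S` exactly needs the kinetic
parameters (through the Jacobian `J` of the rate equations at steady
state), which are rarely measured. netpert is for systems biologists who
want to (a) compute the exact ground truth when a Jacobian is available,
(b) predict the pattern from network topology alone when it is not, and
(c) quantify how much a learned, rank-based "enhancement" of the topology
prediction recovers.

## What it computes

* **Ground truth** (`ground_truth_sensitivity`): column `j` solves the
  linear response `J[-j,-j] dx = -J[-j,j]` with the source clamped; an
  independent ODE-integration oracle (`ode_perturbation_oracle`) verifies
  it.
* **Influence network** (`build_influence_network`): the directed signed
  graph of nonzero off-diagonal Jacobian entries — the kinetics-free
  topology.
* **Topology-only predictors**: first-neighbor (`S_ij = 1` for direct
  neighbors), distance (`S_ij = 1/(1 + hops)`), and propagation
  (`S = (1-α)(I - αW)^-1` with the degree-normalized walk `W`), each in
  directed/undirected (and signed, for propagation) variants.
* **Enhancement factor** (`enhancement_factor`, `apply_enhancement`):
  rank each Jacobian column by magnitude (ascending, zeros tied at rank
  1), compress with `scaled_rank = ceil(log2(rank)) + 1`, normalize each
  column by its diagonal; the resulting matrix `E` is multiplied into the
  distance model. Upper bounds with the true ranks
  (`upper_bound_scores`) show the ceiling this information provides.
* **GCN enhancement prediction** (`assemble_full_graph` /
  `assemble_sparse_graph`, `train_gcn`, `predict_enhancement`): a
  two-layer graph convolutional network
  `Z = softmax(M ReLU(M X W1) W2)`, `M = D^-1/2 (A+I) D^-1/2`, learns
  per-node impact labels across a corpus (Adam, lr 0.01, dropout 0.5, up
  to 200 epochs) and reconstructs a predicted factor
  `E_hat[i,j] = class(i)/class(j)`. Two batching regimes: one giant graph
  with an extra center node wired to each network's hub, or a
  block-diagonal adjacency with a pooling matrix.
* **Evaluation** (`spearman_score`, `benchmark_models`): per-column
  Spearman rank correlation `rho = cov(rg_X, rg_Y)/(sd(rg_X) sd(rg_Y))`
  between prediction and truth (diagonal excluded, midrank ties), averaged
  over columns and models; plus network-property profiling
  (`network_properties`) and property/accuracy correlations with
  random-expectation bands (`property_accuracy_correlation`).
* **Synthetic corpus** (`generate_model`, `generate_ensemble`): stable,
  repository-like dynamical models (5–60 species, sparse signed Jacobians,
  diagonal-dominant stability, linear or Hill kinetics) so the entire
  pipeline runs with no external data.

## Worked example

```r
library(netpert)

m <- generate_model(generator_config(n_species = 6, seed = 42))
m
#> <dynamical_model> synth_n6_seed42: 6 species, 8 off-diagonal Jacobian entries, rhs attached

net <- build_influence_network(m)
truth <- ground_truth_sensitivity(m)

S_dist <- distance_model(net)
spearman_score(abs(S_dist), abs(truth))
#> distance score: 0.904

E <- enhancement_factor(m)
E
#> <enhancement_factor> synth_n6_seed42: 6 x 6, scaled labels in 1..4
spearman_score(abs(apply_enhancement(E, S_dist)), abs(truth))
#> enhanced score: 0.922
```

The distance model alone ranks this model's true responses at Spearman
0.90; multiplying in the true rank-based enhancement factor raises it to
0.92 — the enhancement sharpens, within each source column, which targets
respond most.

On a corpus, `benchmark_models` tabulates every method against the ground
truth:

```r
models <- generate_ensemble(20, seed = 7)
benchmark_models(models, methods = c("biochemical",
                                     "propagation_signed_directed",
                                     "distance_directed",
                                     "upper_bound_scaled_impact"))
#> <benchmark_report> 20 models
#>                       method mean_score n_models
#>                  biochemical      1.000       20
#>  propagation_signed_directed      0.556       20
#>            distance_directed      0.549       20
#>    upper_bound_scaled_impact      0.554       20
```

The biochemical row is the ground truth scored against itself (exactly 1);
the signed directed propagation model is the strongest topology-only
predictor, the directed distance model close behind, and the true-rank
enhancement bound sits above the distance model.

A thin command-line front end is installed at
`inst/cli/netpert` (`generate`, `predict`, `enhance`, `train`,
`benchmark` subcommands over the same functions).

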