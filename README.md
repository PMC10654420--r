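# ipfrefine

Fixed-backbone protein sequence design (inverse protein folding, IPF) in
R, built around two ideas:

1. **A memory-efficient global graph attention network.** A protein
   backbone is a k-nearest-neighbor residue graph (k = 30 by Cα
   distance) with SE(3)-invariant node features (backbone dihedrals,
   chain directions) and edge features (radial-basis encodings of the 25
   inter-atomic distances among N, Cα, C, O and a virtual Cβ, sequence
   offsets, Cα directions), embedded by geometric-vector-perceptron
   layers. In each attention layer every residue attends to **every**
   other residue: the attention logit of pair (i, j) is
   `q_i·k_j / sqrt(d) + b_ij`, where the additive bias `b_ij` is read
   from the edge feature `w_B'e_ij` when (i, j) is a graph edge and from
   a learnable per-layer *pseudo-edge feature* `w_B'β` when it is not.
   Non-edges therefore cost one scalar per layer instead of a d-vector
   per pair, so edge-feature memory stays O(N·k + L) rather than O(N²),
   while attention remains global. Attention weights aggregate both node
   and edge features; edge features are themselves updated from the new
   node features. The sequence is decoded in one shot (no
   autoregression).

2. **Entropy-guided refinement of a base model.** Any existing design
   model ("base model") that outputs an N×20 per-residue probability
   matrix can be refined: positions are ranked by Shannon entropy
   `en_i = −Σ_a p_i(a) ln p_i(a)`, the lowest-entropy fraction is kept
   as visible sequence context (argmax tokens), everything else is
   masked, the network re-predicts all positions in one pass, and
   finally refiner and base are fused per residue as a convex
   combination with weights `exp(−en) / (exp(−en) + exp(−en_b))`. The
   designed residue is the argmax of the fused distribution. Low-entropy
   base predictions are empirically far more accurate than average, so
   this filters noise out of the residue context before it propagates.

The network is trained by masked-sequence reconstruction: 70% of the
native residues are masked, 3% (of the total length) of the remaining
visible ones are swapped to a random different amino acid, and the model
minimizes the negative log-likelihood of the whole native sequence.

The package also implements partial sequence design (fill in unknown
positions, fixed residues are authoritative), single-point mutation
scanning (mask one site, read off the probability of a target amino
acid, combine with distance to a binding-site center into a ranked
quality score), evaluation metrics (recovery; nssr — the fraction of
designed/native pairs with BLOSUM62 score > 0; perplexity; confusion
matrix; bootstrap median confidence intervals), and a synthetic-data
module that generates ideal-geometry toy backbones with a
geometry-coupled sequence rule so that the entire pipeline trains and
tests without any external data.

## Worked example

```r
library(ipfrefine)

# a reproducible toy world: ideal-geometry backbones whose sequences
# follow a deterministic rule on local structure (with a few rule
# variants, so sequence context carries real information)
train <- make_toy_dataset(150, length_range = c(30, 55), seed = 101)
test  <- make_toy_dataset(10,  length_range = c(30, 55), seed = 202)

model <- ipf_model(d = 32, L = 3, k = 30, seed = 1)
fit <- ipf_train(train, model,
                 train_config(epochs = 12, batch_size = 8,
                              learning_rate = 2e-3, seed = 3),
                 corruption_config(mask_frac = 0.70, replace_frac = 0.03,
                                   seed = 5))
print(fit)
#> <ipf_model> d=32, L=3, k=30, mode=global_pseudo, 49,120 parameters
#>   trained 12 epochs; best val loss 0.8588 (epoch 12)

# refine a (simulated) base model's predictions
st  <- test$structures[[1]]
nat <- test$sequences[1]
base <- simulate_base_profile(nat, base_sim_spec(accuracy = 0.5,
                                                 coupling = 0.95, seed = 7))
res <- design_entire(st, base, fit, refine_config(keep_fraction = 0.35))

recovery(untokenize(max.col(base$probs, ties.method = "first")), nat)
#> [1] 0.5777778
recovery(res$sequence, nat)                     # after refinement
#> [1] 0.8
nssr(res$sequence, nat)
#> [1] 0.8222222
perplexity(res$profile, nat)
#> [1] 2.105567
```

(The numbers above are from this exact script; recovery of the refined
sequence varies by a few points with the seeds. On toy data nssr is
typically close to recovery because the synthetic sequence rule draws
amino acids uniformly, without a biochemical similarity structure.)

Partial design and mutation scanning:

```r
partial <- partial_sequence(sub("^.{5}", "XXXXX", nat))  # redesign 5 sites
design_partial(st, partial, fit)$sequence

scan <- scan_mutations(st, nat, fit,
                       mutation_scan_config(target_aa = "R",
                                            candidate_sites = c(3, 9, 17, 25),
                                            binding_center = colMeans(st$CA),
                                            combine_weight = 0.5, top_n = 2))
```

## Command line

A thin wrapper over the same functions ships in `inst/cli/ipfrefine.R`:

```sh
Rscript inst/cli/ipfrefine.R make-toyset --n 10 --out-dir toys --seed 1
Rscript inst/cli/ipfrefine.R train-toy --n 32 --epochs 5 --out model.json
Rscript inst/cli/ipfrefine.R design --pdb toys/toy_001.pdb --chain A \
    --base-probs toys/toy_001_base.tsv --model model.json \
    --keep-fraction 0.35 --out design.fasta
Rscript inst/cli/ipfrefine.R evaluate --designed design.fasta \
    --native toys/toy_001.fasta --out metrics.json
```

Every run writes a `.provenance.json` beside its output (merged options,
package version, timestamp). Exit codes: 0 success, 2 usage error,
1 runtime error.

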