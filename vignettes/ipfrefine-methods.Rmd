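---
title: "Methods: entropy-guided refinement for inverse protein folding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: entropy-guided refinement for inverse protein folding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the model implemented by **ipfrefine**, the
assumptions behind it, every tunable parameter with its default and
rationale, the synthetic data the package trains and tests on, and the
numerical choices a maintainer would want recorded. Nothing here states
an empirical result that the test suite or `scripts/acceptance.R` does
not itself compute.

## The design problem

Inverse protein folding asks for an amino-acid sequence compatible with
a given backbone. Modern design models disagree most where their
evidence is weakest, and autoregressive or iterative decoders feed those
weak predictions back into the residue context, where errors propagate
through the structure graph. The strategy implemented here separates the
two concerns: *select* trustworthy residue context, then *use* it with a
network that can see the whole structure at once.

## Graph representation

A single chain is reduced to its backbone atoms N, C$\alpha$, C, O. The
residue graph connects each residue to its $k = 30$ nearest neighbors
by C$\alpha$ distance (the field-standard proximity graph; ties are
broken toward the lower residue index after rounding distances to
$10^{-6}$ Å, so the graph is reproducible under rigid motion of the
coordinates).

Node features are the sines and cosines of the backbone dihedrals
$\phi, \psi, \omega$ (angles undefined at the termini encode as
$(0,0)$) and the unit chain-direction vectors from the previous and to
the next C$\alpha$. Edge features for $j \to i$ are Gaussian
radial-basis encodings of the 25 ordered atom-pair distances among
$\{$N, C$\alpha$, C, O, virtual C$\beta\}$ (16 centers evenly spaced on
$[2, 22]$ Å, width equal to the spacing — the defaults of the k-NN
featurization lineage this construction follows), a one-hot encoding of
the sequence offset $i - j$ clipped to $[-32, 32]$, and the
C$\alpha$-direction unit vector. The virtual C$\beta$ uses the fixed
tetrahedral construction $C\beta = C\alpha - 0.58273431\,(b \times c)
+ 0.56802827\,b - 0.54067466\,c$ with $b = C\alpha - N$,
$c = C - C\alpha$; it is applied to every residue (glycine included)
and is deliberately chiral — a mirrored backbone produces different
features, as it must.

Two geometric-vector-perceptron (GVP) layers embed these features:
vector channels are mixed by channel-wise linear maps and enter the
scalar track only through their norms, scalars gate the vector
channels. Only the scalar track feeds the attention stack, so the final
embeddings are exactly invariant under rotations and translations while
norms of mixed vector channels still encode relative geometry (e.g. the
angle between the incoming and outgoing chain directions). Defaults: 16
hidden vector channels, 32 hidden scalars, embedding width $d$; token
embedding width 16 for the 21-symbol alphabet (20 amino acids plus the
unknown token `X`). The GVP channel counts and $d$ are configuration,
not claims about any published model.

## Memory-efficient global attention

Each of $L$ layers computes single-head attention over **all** residue
pairs. The logit of pair $(i,j)$ is $q_i \cdot k_j / \sqrt{d} + B_{ij}$
with the additive bias read from the edge feature,
$B_{ij} = w_B^\top e_{ij}$ for graph edges, and from a learnable
per-layer *pseudo-edge feature* $\beta$ for all non-edges — including
the self pair, since the k-NN edge set excludes self. Because every
non-edge shares one $\beta$ per layer, the bias of all non-edges is a
single scalar, and edge-feature memory stays $O(Nk + L)$ instead of the
$O(N^2)$ a fully connected edge tensor would need. Attention weights
aggregate node values and (renormalized over neighbors, weight
$\gamma_i = \sum_{j \in \mathcal N_i} A_{ij}$) edge features; the
concatenation maps back to width $d$, followed by a residual connection
and per-node LayerNorm. Edge features are then updated from
$[h_i \,\|\, e_{ij} \,\|\, h_j]$ with their own residual and LayerNorm.
After the last layer a linear head and softmax give each residue a
distribution over the 20 amino acids — one shot, no autoregression.

Degenerate cases are defined, not special-cased away: a single-residue
graph attends to itself with weight 1 and a zero edge-aggregation term
($\gamma$ would be $0/0$; it is defined as a zero contribution).
LayerNorm uses $\varepsilon = 10^{-5}$; GVP norms use
$\sqrt{\cdot + 10^{-8}}$ so gradients exist at zero vectors (chain
termini).

For long chains the attention is computed in row chunks (128 rows by
default) at inference, so no $N \times N$ activation is retained; the
chunked and monolithic paths agree to machine precision and the test
suite asserts it. Two reference variants exist for comparison and
testing: `global_dense` materializes the full $(N^2) \times d$ edge
tensor (the pseudo-edge ablation; with $\beta$ written into its
non-edge slots it is mathematically identical to the sparse path, which
is the oracle test), and `local` restricts the softmax to graph
neighbors (the local-attention ablation).

Training minimizes the negative log-likelihood of the native sequence.
Because no automatic differentiation is available in this stack, the
reverse-mode gradients of the entire pipeline (GVPs, token embedding,
attention stack, output head) are derived and implemented by hand; the
test suite checks them against central finite differences across every
parameter group. The optimizer is Adam ($\beta_1 = 0.9$,
$\beta_2 = 0.999$, learning rate $2 \times 10^{-3}$ in the package's
experiments) with minibatch gradient averaging. The loss covers **all**
positions by default (the model learns to reconstruct the whole
sequence, including the visible context); `masked_only` is available as
configuration. Backpropagation is implemented for the default
`global_pseudo` mode; the dense and local variants are inference-only
ablations.

## Masked-sequence corruption

Each epoch each training sequence is freshly corrupted: exactly
$\mathrm{round}(0.70\,N)$ positions become the unknown token, and
$\mathrm{round}(0.03\,N)$ of the *remaining visible* positions are
replaced by an amino acid drawn uniformly from the 19 other types. "3%"
is read as 3% of the total length (10% of the visible 30%) — the two
published readings coincide only under this interpretation, which is
recorded here as the package's choice. Replacement excludes the native
type so the corruption rate is exact; replaced positions stay
"visible", which is the point: the model must learn that context can
lie. The `mask_frac = 1` setting reproduces the no-partial-input
ablation.

## Entropy-guided refinement

Given a base model's per-residue distributions $p^b_i$, their Shannon
entropies $en^b_i = -\sum_a p^b_i(a) \ln p^b_i(a)$ rank the predictions
by confidence. The `floor(keep_fraction * N)` lowest-entropy positions
are kept as visible context (tokens = base argmax; entropy ties break
toward the lower index, argmax ties toward the earlier letter of the
alphabet `ACDEFGHIKLMNPQRSTVWY`); the rest are masked. One forward pass
re-predicts everything, and per residue the refiner and base
distributions are fused,
$$\hat p_i = \frac{e^{-en_i}}{e^{-en_i} + e^{-en^b_i}}\, p_i +
\frac{e^{-en^b_i}}{e^{-en_i} + e^{-en^b_i}}\, p^b_i,$$
the design being the argmax of $\hat p_i$. Keep fractions are
calibrated per base model (0.10 GVP-GNN, 0.10 ProteinMPNN, 0.15
ProteinMPNN-C, 0.35 ESM-IF1 — better base models earn more trust);
unknown base models default to 0.15.

In partial design, given residues are authoritative: they are copied to
the output verbatim even if the refiner disagrees, matching the
design-shell benchmark protocol. Mutation scanning is a special case:
one site is masked, the probability of the target amino acid at that
site measures compatibility with the context, and it is combined with
the C$\alpha$ distance to a user-supplied binding-site center into
`quality = w * rank_pct(prob, desc) + (1-w) * rank_pct(dist, asc)` with
$w = 0.5$ by default. Percentile ranks were chosen because only "a
combination" of the two signals is specified anywhere; ranks make the
two scales commensurable without distributional assumptions. Surface
sites and the binding center are inputs, not computations — they come
from external predictors in practice.

## Synthetic data: what it emulates and what it does not

`generate_backbone()` builds chains from internal coordinates (N–CA
1.458 Å, CA–C 1.525 Å, C–N 1.329 Å, ideal angles, $\omega = 180°$;
helix $\phi,\psi = (-57°, -47°)$, strand $(-120°, 120°)$, coil drawn
from a broad torsion range; carbonyl O in the C plane opposite the next
N), optionally with isotropic Gaussian coordinate noise. The generator
records its ground-truth torsions, which makes featurization tests
exact.

`couple_sequence()` maps local descriptors — 40° $\phi/\psi$ bins, a
coarse contact-count bin (C$\alpha$ pairs within 8 Å), a terminal flag —
through a seeded hash table to an amino acid. Given the rule, the map
is deterministic, so Bayes-optimal recovery at zero noise is 100% and a
descriptor-lookup classifier bounds what the network can learn. A
dataset mixes a small number of *rule variants* (default 4) that remap
a fixed 30% subset of descriptor keys: the variant of a held-out
protein cannot be read off its backbone, but visible residues reveal
it. This is the toy analog of the many-to-many relation between local
environment and amino acid in real proteins, and it is what makes
partial sequence input genuinely informative — without it, a
sufficiently trained structure-only model would leave context nothing
to add, and the partial-input ablation would be unmeasurable.

`simulate_base_profile()` emulates a base model with a target accuracy
and a confidence–correctness *coupling*: with probability `coupling`,
correct positions get a sharp row (target probability
$1/(1 + 19e^{-\lambda})$ at concentration $\lambda$, off-target mass
uniform) and incorrect ones a flat row; otherwise sharpness is an
independent coin. Coupling 0 makes entropy useless; coupling near 1
reproduces the empirical situation in which the lowest-entropy decile
of a ~50%-accurate model is ~95% correct.

What the toy world does **not** emulate: side chains and packing,
amino-acid similarity structure (toy letters are drawn uniformly, so
nssr ≈ recovery there, unlike real proteins), realistic Ramachandran
densities, long-range evolutionary covariation, experimental coordinate
error beyond isotropic noise. Passing the toy benchmarks therefore
demonstrates that the machinery learns and that the refinement logic
behaves as designed — not that any particular recovery level transfers
to real structures.

## Problem sizes used by the tests and the acceptance script

The package's experiments are sized for a single CPU: the main
toy-world model is $d = 32$, $L = 3$, $k = 30$ trained for 12 epochs on
200 structures of length 30–60 (held-out evaluation on 50); the
partial-input ablation comparison trains $d = 24$ pairs of models
(default vs. `mask_frac = 1`) for 12 epochs on 100 structures of length
25–40 per seed, over 10 seeds, scoring masked-position recovery with
70% of the native sequence given, averaged over two masking draws — a
protocol mirroring design-shell benchmarks, where the redesigned
positions are a minority and the fixed majority is exactly the context
a partial-input model should exploit. Memory-scaling measurements use
one layer at $d = 64$, $k = 30$, $N \in \{64, 128, 256, 512\}$, with
allocation profiling (`Rprofmem`) because total allocated bytes are
deterministic, unlike garbage-collector high-water marks. The
`scripts/acceptance.R` pipeline trains on 150 structures and evaluates
on 40 so the whole script reruns in minutes.

## Known limitations

Single chains only; no mmCIF, no multi-model ensembles, no ligands.
Single-head attention (the update equations are single-head; heads
would be a config extension). The naive edge update does not enforce
triangle-inequality consistency between edges. Training at desk scale
is deliberately small: the package ships no pretrained weights and
makes no claim to reproduce published benchmark recoveries, which
require externally trained base models and full-scale datasets.
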