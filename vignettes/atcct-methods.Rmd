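---
title: "Predicting drug-ATC associations with a convolution-transformer encoder"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting drug-ATC associations with a convolution-transformer encoder}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

The Anatomical Therapeutic Chemical (ATC) classification assigns each drug
one or more codes in a five-level hierarchy: level 1 is the anatomical
group (one letter, e.g. `A`), level 2 the therapeutic subgroup (`A03`),
levels 3 and 4 pharmacological and chemical subgroups (`A03A`, `A03AA`),
and level 5 the individual substance. A drug's missing codes are candidate
new indications, so predicting unobserved (drug, code) pairs is a route
into drug repositioning. `atcct` casts the task as binary link prediction
at levels 1-4: given a drug and a candidate code at one level, output the
probability that the association holds. Level 5 is out of scope — its
codes are unique per substance and carry no generalisable structure.

## Model

### Input features

Three drug-drug similarity channels are computed once per corpus:

* **CS** — Tanimoto (intersection over union) on 1024-bit circular
  fingerprint bit sets;
* **DDI** — Jaccard on sets of interaction partners: drugs that interact
  with the same third drugs are presumed functionally similar;
* **SE** — Jaccard on side-effect profiles.

A drug with no recorded feature set has similarity 0 to everything,
including itself: an empty set is missing evidence, not vacuous identity.
DDI similarity treats the interaction network as an untyped, undirected
partner-set relation, and the two drugs' partner sets are used as-is (no
exclusion of the pair itself).

Code-code similarity uses the weighted-hierarchical similarity (WHS). With
$S^k_i$ the set of prefixes of code $a_i$ truncated to levels $1..k$,
$N_k(a_i,a_j) = |S^k_i \cap S^k_j|$ the number of shared levels, and

$$W_k^n = \sum_{i=0}^{n-1}(k-i)^2, \qquad W_k^0 = 0,$$

the similarity at target level $k$ is

$$\mathrm{WHS}_k(a_i,a_j) = \frac{2\,W_k^{N_k(a_i,a_j)} + k^2}{2\,W_k^k + k^2} \in (0, 1].$$

The quadratic increments $(k-n)^2$ make agreement at shallow levels worth
more than agreement at deep levels, where categories are finer. Two
comparator measures are implemented for benchmarking: the unweighted
prefix-overlap ratio $\mathrm{RNPSim}_k = (2N_k+1)/(2k+1)$, which
coincides with WHS exactly at level 1, and the inverse-frequency kernel
similarity $\mathrm{NPSim}(a_i,a_j) = w(a_i)\,w(a_j)\,e^{-0.25\,d(a_i,a_j)}$
with $w(a) = 1/\mathrm{freq}(a)$. Two conventions in NPSim are fixed here
because its source leaves them open: the distance is the tree distance
through the deepest common ancestor, $d = 2(k - N_k)$ (zero for identical
codes), and no renormalisation is applied even though the inverse-frequency
weights make the value unbounded above — both choices are documented
behaviour, not bugs. Frequency weights are computed from training-split
associations only, to keep test-set frequencies out of the features.

### Masked association features

For a target pair $(d, a)$ the model sees, per channel, a
$2 \times (m_k + n)$ matrix ($n$ drugs, $m_k$ codes at level $k$), with
columns aligned across the two rows:

* row 1: $d$'s association row over the $m_k$ codes, then $d$'s
  similarity row over the $n$ drugs;
* row 2: $a$'s code-similarity row over the $m_k$ codes, then $a$'s
  association column over the $n$ drugs.

Aligned columns carry the evidence: ATC-block column $j$ pairs "does $d$
carry code $j$" with "how close is $j$ to $a$"; drug-block column $i$
pairs "how similar is drug $i$ to $d$" with "does drug $i$ carry $a$".
Association entries are masked in two stages before feature assembly:
every held-out (test-fold) pair's cell is zeroed, and each sample's own
cell is zeroed in its feature matrix. No label the model is asked about is
therefore visible in any input, which the test suite asserts cell by cell.
The within-row block order (ATC block first) is a fixed layout contract;
only the column alignment between the rows is load-bearing.

### Encoder and head

Each channel's feature matrix passes through a convolution-transformer
encoder: a 1D convolution over the column axis (the 2 rows are input
channels; kernel 16, stride 8, `model_width` output channels by default)
produces $L = \lfloor (n + m_k - 16)/8 \rfloor + 1$ tokens; sinusoidal
positional encodings are added; then a stack of transformer (TR) blocks —
multi-head scaled dot-product attention
$\mathrm{softmax}(QK^\top/\sqrt{d_k})V$ with $h$ heads of width
$d_k = \mathrm{model\_width}/h$, followed by a two-layer ReLU feed-forward
network, each sublayer wrapped in residual + layer norm (post-norm) with
dropout — and average pooling over the $L$ tokens yields one embedding per
channel. The three embeddings are concatenated and a fully connected layer
plus sigmoid produces the probability. Each channel has its own encoder
weights (a shared-weights switch exists for ablation), so the head is
channel-position-aware by design: permuting the channel inputs changes the
prediction.

Transformer defaults follow the published optimum for this architecture:
dropout 0.1, 16 heads, feed-forward width 128, 3 TR blocks. The
convolution geometry, token width, positional-encoding type and norm
placement are not published; kernel 16 / stride 8 / width 128,
sinusoidal encodings and post-norm blocks are this package's declared
choices (all config-exposed), sized so that level-4 feature rows of a
full-scale corpus (~3.5k columns) reduce to a manageable token count. A
`"none"` positional-encoding option preserves the literal
no-positional-encoding reading.

### Training

Binary cross-entropy on balanced pairs with Adam. Negative pairs are drawn
once per level, uniformly without replacement from the zero cells of the
association table, to equal the positive count; the balanced set is then
split into label-stratified cross-validation folds (stratification keeps
small folds from degenerating; fold metrics are computed per fold and
averaged, never pooled). Full-scale defaults are 50 epochs, batch 32,
learning rate 1e-4. On the small synthetic benchmarks used throughout the
tests (hundreds of pairs, 20 epochs) the package uses 1e-2: with only a
few hundred Adam steps available, pilot runs of the training loss showed
1e-4 leaves the model far from convergence, and 1e-2 was the largest rate
that remained stable; it was selected on optimisation health, not on test
metrics. Training aborts with a diagnostic if the loss becomes
non-finite.

Two numerically interchangeable engines implement the encoder: a compiled
RcppArmadillo path (default) and a base-R reference path
(`options(atcct.engine = "r")`). The analytic gradients of both are
verified in the test suite against central finite differences, and the
two engines against each other. All randomness (sampling, folds,
initialisation, shuffling, dropout) derives from user-visible seeds
through a fixed seed-splitting rule, so every run is reproducible from
its recorded configuration.

## The synthetic benchmark

Real corpora at scale require licensed database extracts, so the package
ships a generator with planted, tunable signal. It emulates:

* an ATC-format hierarchy with configurable branching (default
  `c(4, 3, 2, 2)`: 48 leaves), drugs assigned uniformly to leaves, and a
  30% chance of a second, independently chosen leaf code per drug;
* within-branch feature enrichment, with "branch" fixed at the level-2
  subtree: all drugs of a branch share its 32 fingerprint bits (plus ~1%
  background bits), interact within the branch with probability 0.3
  (background 1%), and draw from a 20-side-effect branch pool (each with
  probability 0.6, on 1% background over a 500-effect universe);
* missing annotations: each (drug, leaf) association is dropped with
  probability 0.05, never a drug's last one. Dropping at the leaf level
  keeps truth tables at different levels exactly consistent under prefix
  truncation. Spurious 0→1 corruption is left to the robustness
  protocol's injection operation.

These defaults are one-time choices pinned before the evaluation suite
was run. What the generator does *not* emulate: realistic chemistry (bits
are abstract, not derived from structures), typed or directional
interactions, code-frequency skew, and — deliberately — learnable second
codes: the random extra leaf gives each corpus ~20% of positives whose
channels carry no supporting signal, which caps attainable AUROC around
0.9 and keeps the benchmark from being trivially separable. Passing the
planted-signal tests therefore shows the pipeline recovers recoverable
signal without leakage; it says nothing about absolute performance on
real pharmacological data.

## Evaluation protocols

* **AUROC** is computed as the Mann-Whitney statistic with ties counted
  one half; **AUPRC** as the uninterpolated step-curve area. Both
  conventions are pinned by brute-force oracles in the tests (pairwise
  counting; exhaustive threshold sweep) to 1e-9.
* **Cross-validation** reports mean ± sd over folds.
* **Channel ablation** re-runs cross-validation for channel subsets; the
  head width adapts to the number of channels present.
* **Robustness** perturbs each fold's training labels only — a fraction
  $-f$ relabels $\lfloor f P \rfloor$ training positives as negatives, a
  fraction $+f$ adds $\lfloor f P \rfloor$ unobserved pairs as positives —
  and measures the shift in test metrics against the untouched baseline.
* A **permuted-label control** destroys every label-feature relation
  before folding; its AUROC brackets chance. With one global permutation
  the learner can still exploit the permutation's chance correlations
  corpus-wide, so values a few points above 0.5 are expected at small
  sample sizes.

The shipped evaluation suite runs the full protocol on a 200-drug default
corpus at level 3 with 5 folds and a reduced encoder (width 32, 4 heads,
2 TR blocks, 20 epochs) — sizes chosen so the whole study is a few
minutes of CPU; the same machinery scales to 10 folds and the full-width
model through configuration.

## Degenerate inputs and numerical choices

* Empty-vs-empty set similarity is 0 everywhere (documented above).
* Probabilities are clamped to $[10^{-12}, 1-10^{-12}]$ inside the loss
  only; reported scores are raw sigmoid outputs, strictly inside (0, 1).
* Layer norm uses $\varepsilon = 10^{-5}$; softmax subtracts the row
  maximum before exponentiation.
* Codes deeper than the requested level are truncated, never rejected;
  duplicates after truncation collapse to one matrix row/column.
* An association table whose zero cells cannot match its positives
  refuses negative sampling; a feature shorter than the convolution
  kernel refuses encoding. Both are validation errors, not silent
  degradation.

## Known limitations

* Cold-start drugs (no known associations at any level) are out of scope;
  their association rows are all zero and the model has no evidence path.
* The benchmark generator's ceiling (above) means headline numbers on it
  are not comparable to numbers on real corpora.
* Training is CPU-bound single-process; the intended scale is corpora of
  a few thousand drugs.
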