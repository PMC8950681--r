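---
title: "Methods: per-residue disorder prediction from topological and compositional sequence features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: per-residue disorder prediction from topological and compositional sequence features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(idpred)
```

## The problem

Intrinsically disordered protein regions (IDRs) are stretches of a
protein chain that do not adopt a stable tertiary structure. They are
central to signalling, regulation and molecular recognition, and are
annotated residue by residue: each amino acid of a protein is either
ordered (0) or disordered (1). `idpred` implements a per-residue
classifier for this task built from a 35-channel feature description of
every residue and a deep convolutional classifier, together with the
synthetic data machinery needed to exercise and validate every stage
without any external database or sequence search.

## Feature construction

All features are computed over a sliding window of odd length $N$
(default $N = 33$) centred on each residue; a window sweep on pooled
cross-validation metrics motivates that default, with performance
flattening for $N \ge 33$.

### Persistent entropy (1 channel)

Each window $\beta_j$ of $N$ residues is embedded on the unit cylinder
in $\mathbb{R}^3$: residue $m$ with alphabet index
$i \in \{1..20\}$ (order `A R N D C Q E G H I L K M F P S T W Y V`)
maps to

$$\left(\cos\tfrac{2\pi i}{20},\; \sin\tfrac{2\pi i}{20},\;
\tfrac{m-1}{N-1}\right).$$

The angle encodes residue identity, the height encodes position, so a
window becomes a 3-D point cloud whose shape reflects the local
sequence composition *and* arrangement. On this cloud we build the
Vietoris–Rips filtration in the ball-intersection convention (a simplex
enters at scale $\varepsilon$ equal to half the largest pairwise
distance among its vertices) and read off the persistence diagram
$\{(\varepsilon_{s_i}, \varepsilon_{e_i})\}$. The **persistent
entropy**

$$E = -\sum_i p_i \log_2 p_i, \qquad
p_i = \frac{\ell_i}{\sum_k \ell_k}, \qquad
\ell_i = \varepsilon_{e_i} - \varepsilon_{s_i}$$

is the Shannon entropy of the normalised bar lengths: low when one
scale dominates the window's shape, high when structure exists at many
scales. It is invariant to isometries of the cloud and to global
scaling, which also makes it independent of the factor-of-two
difference between the ball-intersection and distance-threshold Rips
conventions.

Three quantities the formulation leaves open are fixed as follows:

* **Filtration cap.** Infinite bars must be truncated for the entropy
  to exist. The cap defaults to half the cloud diameter: the complete
  dimension-0 merge tree is then observed and exactly one dimension-0
  class is truncated at the cap. The cap is configurable.
* **Homology dimensions.** Dimensions 0 and 1 are pooled into a single
  diagram by default (`max_dim = 1`). On a cylinder, clustering
  (dimension 0) and loops (dimension 1) are the informative signals;
  dimension 2 is supported but adds cost and little structure at
  $N = 33$.
* **Zero-length bars** are dropped (their $p_i = 0$ contributes
  nothing), and an empty diagram has entropy 0.

The reduction itself is exact: simplices are enumerated explicitly,
sorted by (filtration value, dimension, lexicographic vertex order) so
ties reduce deterministically, and the GF(2) boundary matrix is reduced
per dimension with bitset columns. A brute-force global reduction
written independently in R is kept in the test suite and must agree
exactly (within $10^{-9}$) on randomly generated clouds.

### PCAA2 and PCAA3 (2 channels)

The probabilities of two and three consecutive amino acids are
estimated once from a reference corpus $\Omega$: counts $S_k$ over the
$400$ dipeptides and $8000$ tripeptides (sliding by one residue),
probabilities $P_k = S_k / \sum S_k$, then min–max scaling to $[0,1]$
(if all probabilities are equal the scaled values are defined to be 1).
For a protein, each residue receives the mean of the scaled values of
the (at most $k$) k-mers covering it; at the termini the mean runs over
the existing k-mers only. K-mers containing nonstandard letters are
skipped in counting and contribute 0 to the averages, which keeps the
probability normalised over the standard alphabet.

The corpus is a constructor argument. When training a predictor the
tables default to the training proteins only; building them on a larger
corpus that includes evaluation material is possible via
`kmer_records` but mixes information across the split, so it is not the
default.

### Profile and scale channels (30 channels) and sequence entropies (2)

* **Rows 1–20**: the 20 columns of a PSI-BLAST position-specific
  scoring matrix (log-odds, used raw; the pipeline is monotone in the
  search output). When no PSSM is available a BLOSUM62 row per residue
  can stand in (`pssm_missing = "blosum62"`), which preserves the
  composition signal but carries no evolutionary information; the
  default is an error so the substitution is always explicit.
* **Rows 21–27**: steric parameter, polarizability, volume,
  hydrophobicity, isoelectric point, helix and sheet probability —
  transcribed from AAindex (accessions CHAM810101, CHAM820101,
  GRAR740103, KYTJ820101, ZIMJ680104, CHOP780201, CHOP780202).
* **Rows 28–30**: three structural-propensity channels. The packaged
  defaults are published flexibility/coil/B-factor scales (AAindex
  BHAR880101, CHAM830101, VINM940101) chosen to measure the same
  signals as missing-density-style disorder propensities; any
  20-value tables can be substituted with `load_scales()`, and users
  with access to other published propensity sets can drop them in
  without code changes.
* **Rows 31–33**: Shannon entropy of the window's residue composition,
  topological entropy, and the persistent entropy track above.
* **Rows 34–35**: PCAA2 and PCAA3.

The 30 scalar channels (PSSM and scales) are per-residue values
averaged over the window **with zero padding** at the chain ends; the
entropy channels are computed on windows padded **with copies of the
terminal residues**. The two padding conventions are deliberate — each
follows the definition of the corresponding feature family — and only
the 30 scalar channels are window-averaged; the entropy tracks are
already window functionals and are not smoothed a second time.

Topological entropy adapts subword complexity to a 20-letter alphabet:
for the largest word length $n$ with $20^n + n - 1 \le N$ the value is
$\log_{20}(\#\text{distinct } n\text{-subwords of the first }
20^n + n - 1\text{ window characters})/n \in [0, 1]$. At the default
$N = 33$ this calibrates to $n = 1$, i.e. the normalised log-count of
distinct residues among the first 20 window characters — degenerate
but well-defined; windows below 20 raise an error.

Nonstandard residues (`B J O U X Z`) are accepted in records and
handled per channel: the scale channels read them as 0, k-mers
containing them are skipped, and inside an entropy window they are
replaced by the window's most frequent standard residue (ties broken
toward the lowest alphabet index) so the track keeps length $L$.

## The classifier

Each residue's 35-vector is processed independently:

1. **MLP 1**: hidden layers of 35 and 3675 ReLU units. The 3675-vector
   output is reshaped to a $35 \times 35 \times 3$ image.
2. **Convolutional backbone**: the sixteen 3×3 convolutions and five
   2×2 max-pools of VGG19 (fully connected stages removed), with
   "same" spatial padding so pooling maps
   $35 \to 17 \to 8 \to 4 \to 2 \to 1$.
3. **Projection and skip connection**: the flattened backbone output is
   a vector of the final channel width, not 3675, so a trainable linear
   projection restores width 3675 — the minimal addition that lets the
   backbone output be summed elementwise with MLP 1's output, which the
   architecture requires.
4. **MLP 2**: one 3675-unit ReLU hidden layer with dropout 0.5, then a
   single sigmoid unit giving $P(\text{disordered})$. A residue is
   called disordered when the probability is $\ge$ the threshold
   (default 0.5, configurable).

Training minimises the mean binary cross-entropy of mini-batches
("packages") of 128 residues pooled and shuffled across all training
proteins, by plain SGD with learning rate $10^{-4}$, until the change
in mean epoch loss falls below a tolerance (default $10^{-4}$) or a
maximum epoch count is reached. Probabilities are clipped to
$[10^{-7}, 1 - 10^{-7}]$ inside the loss. Two design choices the
architecture description leaves open:

* **Input standardisation.** The raw channels differ in scale by two
  orders of magnitude (volumes up to 170, entropies below 5), which
  cripples fixed-learning-rate SGD. `train_network()` computes
  per-channel mean/sd on the training residues, stores them in the
  model, and standardises inside every forward pass. Feature matrices
  themselves stay raw, so the feature contracts are unaffected.
* **Backbone scale and initialisation.** `model_config("full")` uses
  the published VGG19 channel widths (64–512);
  `model_config("small")` divides them by 8 and is the default for
  desk-scale work — the dense stages (which carry most parameters,
  ~14.2M at small scale) are fixed by the 3675-width contract and are
  not scaled. All weights use seeded He-normal initialisation; conv
  weights can instead be supplied explicitly (e.g. published VGG19
  weights) via `backbone_weights`. No weight file ships with the
  package, so `pretrained_backbone = TRUE` without weights errors
  rather than downloading anything. No class re-weighting is applied
  despite the roughly 1:4 disorder:order imbalance, matching the
  training procedure being reproduced.

Forward and backward passes are explicit; 3×3 convolution and pooling
run as compiled im2col + gemm kernels in single precision (activation
gradients do not need double precision; parameter updates accumulate in
double on the R side), dense algebra uses BLAS in double precision.
The package pins the OpenBLAS thread pool to one thread at load time
(override with `IDPRED_BLAS_THREADS`), because an auto-sized pool
thrashes when a container exposes fewer CPUs than the hardware
reports; with one thread every result is also independent of the
machine's core count.

## Evaluation

Residue-level confusion counts (positive class = disordered) give
sensitivity, specificity, balanced accuracy
$\mathrm{BACC} = (\mathrm{Sens} + \mathrm{Spec})/2$ and the Matthews
correlation coefficient. Conventions for degenerate tables: an empty
MCC marginal gives $\mathrm{MCC} = 0$ (the standard convention for
constant predictions); an undefined sensitivity or specificity is
reported as `NaN` with a warning. Counts are pooled over all residues
of all proteins by default (`per_protein = TRUE` gives per-protein
rows). Cross-validation splits at the protein level with a seeded
assignment that depends only on the ids and the seed; metrics are
reported per fold and pooled over held-out residues (pooling, rather
than averaging per-fold metrics, is the default).

## The synthetic corpus

`generate_corpus()` produces labelled proteins with the statistical
structure the predictor assumes: alternating ordered/disordered blocks
(geometric lengths, disordered mean 30 residues; ordered means scaled
so the target 20% disorder fraction is met in expectation — the
fraction seen in curated disorder corpora), residues drawn from
state-specific compositions that up-weight the disorder-promoting set
P, E, S, Q, K, G and the order-promoting set W, C, F, I, Y, V, L by a
factor of 3 over uniform, and fabricated PSSMs equal to integer-rounded
log-odds of the generating composition against the corpus background
plus Gaussian noise (sd 0.5), written and re-read through the real
ASCII PSSM code path. `default_planted_config("small")` fixes the
documented study conditions used by the package's own evaluation: 60
proteins of length 120–200; `"standard"` gives 400 proteins of length
100–600. Everything is a pure function of the seed.

What the generator does **not** emulate: long-range sequence
correlations, evolutionary conservation structure in the profiles
(rows are conditionally independent given the state), ambiguous or
conflicting disorder annotations, and real disorder's length and
position biases. Passing the recovery test therefore shows that the
pipeline can extract a compositional disorder signal end to end — not
that it matches published benchmark performance on curated corpora,
which additionally requires genuine PSI-BLAST profiles and full-scale
training.

## The recovery experiment

The package's stand-in for full-corpus benchmarking trains the
small-scale model on the first 45 proteins of the small planted corpus
and evaluates on the held-out 15 (about 7,000 and 2,400 residues).
K-mer tables come from the training proteins only. Training uses the
default schedule (packages of 128, SGD at $10^{-4}$) for up to 4
epochs — the loss drops steeply in the first epochs on this separable
signal and held-out balanced accuracy exceeds 0.9 already within 2 —
and the whole experiment runs in minutes on one CPU. The problem sizes
here (corpus of 60, window 33, up to 4 epochs) are the package's
documented desk-scale conditions; the same functions run the full
protocol (ten-fold cross-validation, `"full"` backbone) unchanged at
larger scale.

```{r recovery, eval = FALSE}
corpus <- generate_corpus(default_planted_config("small", seed = 7))
tr <- corpus$records[1:45, ]; te <- corpus$records[46:60, ]
pred <- train_predictor(tr, corpus$pssms, window = 33,
                        tc = train_config(max_epochs = 4, seed = 7))
m <- evaluate_predictions(predict_corpus(pred, te, corpus$pssms), te)
m[, c("sens", "spec", "bacc", "mcc")]
```

## Numerical notes and limitations

* Rips filtration values use exact pairwise distances; no grid
  discretisation of the scale parameter. Determinism comes from the
  sorted simplex order and the fixed reduction; two runs on the same
  cloud are bitwise identical.
* The persistence reduction is combinatorial in window size; the
  default $N = 33$ (5,456 triangles per window) costs well under a
  millisecond per window, but `max_dim = 2` multiplies the simplex
  count by roughly 8 and is only intended for exploration.
* Dropout draws and shuffling come from R's RNG under the training
  seed, so a fit is reproducible from (features, labels, config,
  seed) on the same BLAS.
* Training at `"full"` backbone scale is supported but slow in this
  implementation (the point of the package is the method, not GPU
  performance); the `"small"` backbone retains the architecture's
  structure wholesale.
* Ten-fold cross-validation at full corpus scale is implemented
  (`cross_validate()`) and exercised in the tests at reduced size;
  published-benchmark replication additionally needs the original
  corpora and genuine profiles, which the package deliberately does
  not download.
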