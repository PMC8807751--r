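# eegstgcn

Dynamic-graph spatial–temporal convolution for four-class motor-imagery
EEG classification in R.

## The problem

In a motor-imagery brain–computer interface, a subject *imagines* moving
the left hand, right hand, feet or tongue; each imagined movement leaves a
class-discriminable signature in multichannel EEG. Classifying these
trials is hard because the informative structure is jointly **spatial**
(which electrodes co-vary — the functional connectivity of the cortex),
**spectral** (band power in the 4–40 Hz range, especially the 8–13 Hz mu
rhythm) and **temporal** (the signature evolves over the 4.5 s trial).

`eegstgcn` treats the electrode array as a graph G = (V, E, A): electrodes
are nodes, and the adjacency A ∈ R^(N×N) carries connection weights. The
classifier is a spectral graph convolutional network whose graph is

1. **initialised from data** — A₀[i, j] = I(Xᵢ; Xⱼ), the mutual
   information between channels i and j estimated by histogram binning of
   the recorded signals; and
2. **updated during training** — after each epoch,
   A[i, j] ← max(0, cos(eᵢ, eⱼ)), the rectified cosine similarity between
   the learned embeddings of nodes i and j, so the graph adapts to what
   the network has learned (set `update_adjacency = FALSE` to freeze the
   initial matrix instead).

Each of the stacked spatial–temporal blocks applies

- **temporal attention** E′ (T×T, row-stochastic) mixing the time axis,
- **spatial attention** S′ (N×N, row-stochastic) re-weighting node
  interactions,
- **Chebyshev graph convolution**
  y = Σₚ θₚ Tₚ(L̃) x over the scaled normalized Laplacian
  L̃ = 2L/λmax − I, L = I − D^(−1/2) A D^(−1/2),
- a depthwise **temporal convolution**, with ReLU activations.

Training uses Adam with L1/L2 regularisation under a **flooding loss**
R̃ = |R − b| + b (b = 0.5), which stops the training loss from collapsing
below b on small EEG datasets. Inputs are differential-entropy (DE)
features — DE = ½·ln(2πeσ²) per channel, sub-band and 0.5 s segment —
computed over 11 equal sub-bands of 4–40 Hz and "double-folded" so the
per-node feature length equals the node count.

The package ships the full surrounding toolbox: EDF and plain-text
container I/O, zero-phase Butterworth band-pass filtering, cue-locked
epoching, PSD/DASM/RASM/ASM/DCAU features, eight adjacency constructions
(geometric, cosine, Jaccard, MI, kNN, distance-threshold, random,
MI-masked hybrids), stratified cross-validation, and a synthetic EEG
generator with planted block connectivity that makes every stage testable
offline.

## Worked example

Simulate a small four-class recording with planted connectivity, recover
the channel graph by mutual information, and train the classifier:

```r
library(eegstgcn)

spec <- synthetic_spec(n_channels = 8, trials_per_class = 50, seed = 11)
ts   <- simulate_trials(spec)          # 200 trials, 8 ch, 250 Hz, 4.5 s

fold  <- stratified_folds(ts$labels, 2, seed = 5)
train <- subset_trials(ts, which(fold == 1))
test  <- subset_trials(ts, which(fold == 2))

inp_tr <- prepare_inputs(train, band_spec(4, 40, 4))   # DE features + MI graph
inp_te <- prepare_inputs(test,  band_spec(4, 40, 4), stats = inp_tr$stats)

cfg   <- train_config(learning_rate = 5e-3, epochs = 30, n_blocks = 2, seed = 2)
model <- build_model(cfg, inp_tr$A, inp_tr$dims)
model <- train_model(model, inp_tr$x, inp_tr$labels)

evaluate_model(model, inp_te$x, inp_te$labels)
#> accuracy 1.0000  macro F1 1.0000  macro precision 1.0000
```

The printed line is the held-out metrics report: on this strongly
separable synthetic fixture the 2-block network classifies every test
trial correctly. Shuffling the dataset's labels before the same pipeline
drops accuracy to chance (~0.25), confirming the model learns the planted
class structure rather than an artefact. The graph itself is recoverable
without any training:

```r
A <- mi_adjacency(ts)                  # mutual-information channel graph
make_planted_graph(spec)               # ground truth to compare against
```

A thin command-line front end with `simulate`, `features`, `adjacency`,
`train`, `evaluate` and `cv` subcommands is installed at
`system.file("cli/eegstgcn", package = "eegstgcn")`.

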