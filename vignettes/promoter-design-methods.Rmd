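---
title: "Designing bacterial promoters with a diffusion generator and a transformer strength predictor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing bacterial promoters with a diffusion generator and a transformer strength predictor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Bacterial promoters — the 50 or so base pairs immediately upstream of a
transcription start site (TSS) — set the transcription rate of the genes
they control. Synthetic biology wants large libraries of novel,
high-activity promoters, but the sequence space (4^50 for a 50-nt
promoter) is hopeless to search experimentally. `promodiff` implements a
two-model design loop:

1. a **denoising diffusion probabilistic model (DDPM)** learns the
   distribution of natural promoter sequences (unsupervised, from
   one-hot encodings) and generates novel sequences from Gaussian noise;
2. a **transformer-encoder regressor** learns to predict promoter
   strength from labelled data and screens the generated candidates, so
   that only promising sequences go to the bench.

Around these sit the evaluation statistics used to judge generation
fidelity (k-mer spectra and their cross-set Pearson correlation,
positional k-mer profiles, sequence-logo information content) and an
in-silico saturation mutagenesis that maps which positions the trained
predictor considers important.

# Data model and encodings

A `PromoterSet` wraps a `Biostrings::DNAStringSet` of equal-length
sequences over {A, T, C, G} with an optional vector of strictly positive
strengths (dRNA-seq-style expression values, arbitrary units). Three
encodings are implemented:

* **One-hot** (`oneHotEncode`): an L x 4 matrix, channel order
  (A, T, C, G); this is the diffusion state `x0`. Decoding takes a
  per-row argmax with ties broken toward the lowest channel, so decoding
  is total and deterministic on arbitrary real matrices.
* **Three token streams** (`tokenEncoding`): single-nucleotide tokens
  0–3; overlapping dinucleotide tokens 4–19 in row-major order over
  (A,T,C,G)x(A,T,C,G), with the last position zero-padded to the codes
  A0..G0 = 20–23 so that all three streams share the sequence length; and
  position indices 0..L-1. The dinucleotide stream gives the predictor
  direct access to base-stacking context; the position stream feeds a
  learned position embedding.
* **Strength normalization**: strengths are right-skewed, so they are
  log10-transformed and then min-max normalized to [0, 1]
  (`logTransform`, `minMaxNormalize`). The min/max are fitted on the
  training set and stored in every trained model, so test strengths and
  inverse transforms always use training-set parameters. Nonpositive
  strengths are an error by default; an optional pseudocount (default
  1.0 when enabled) is available for count-like data with zeros.

Positions are reported both 0-based and TSS-relative (index i maps to
i - L, so the last base is -1).

# The diffusion generator

The forward process corrupts a one-hot matrix over `T` steps with the
closed-form kernel

x_t = sqrt(ab_t) x0 + sqrt(1 - ab_t) eps,  eps ~ N(0, I),

where ab_t is the running product of (1 - beta_t). The reverse process
starts from pure noise and repeatedly removes the noise predicted by a
learned network, with reverse-step variance sigma_t^2 = beta_t; the final
x0 estimate is decoded by argmax.

Choices the underlying theory leaves open, and what this package does:

* **Schedule.** Linear beta ramp. Defaults: T = 1000, beta from 1e-4 to
  0.02. For cheaper runs at T = 200 the package scales the endpoint up to
  beta_end = 0.1 so that the cumulative noise matches the T = 1000
  schedule (ab_T ~ 4e-5). Without this rescaling a T = 200 run retains
  ~13% of the signal at the terminal step, which contradicts sampling
  from pure noise and visibly degrades samples.
* **Noise predictor.** A small 1-D convolutional residual network over
  the length axis: input projection of the 4 channels to `hidden`
  (default 64), a learned per-position embedding (fixed L makes this
  natural and lets the model represent position-specific base usage), a
  sinusoidal timestep embedding injected into every residual block
  through learned projections, and `blocks` (default 2) residual blocks
  of two same-padded convolutions (kernel 5) with ReLU. One-hot inputs
  are used as raw {0,1} reals without rescaling to [-1, 1].
* **Objective.** Noise prediction under mean absolute error (L1), with
  timesteps drawn uniformly per example. A 10% held-out split of the
  sequences is corrupted once with frozen draws and scored each epoch, so
  the monitoring loss is comparable across epochs; it should fall
  sharply and then plateau.
* **Optimizer.** Adam at 1e-3. All randomness (shuffling, timesteps,
  noise, sampling) flows from a single integer seed, and a fixed seed
  reproduces training and sampling bit-for-bit on one machine.
* **Checkpoints.** Every 10 epochs by default, enabling learning-curve
  analyses such as `kmerPccTrajectory()`.

# The strength predictor

The regressor embeds the three token streams through three embedding
tables of width `dModel` (default 64) and sums them, then applies
`layers` = 2 pre-norm transformer encoder layers (multi-head scaled
dot-product self-attention with 4 heads, feed-forward width 128, dropout
0.1 on sublayer outputs), mean-pools over positions, and maps to a
scalar through a linear head. Pre-norm placement was chosen for training
stability at these depths; it does not change the attention mechanism.

The loss is `wMse * MSE + wPcc * (1 - PCC)` with equal default weights —
the correlation term directly optimizes the ranking agreement that the
screening task cares about, while the MSE term anchors magnitudes. A
constant-prediction batch makes the correlation term undefined; the
package falls back to MSE for that batch and warns, which avoids NaN
poisoning early in training. Evaluation (`evaluatePredictor`) reports
the Pearson correlation on the normalized scale the model was trained
on. Early stopping monitors a 10% held-out split with patience 20.

The CNN baseline (`trainCNNBaseline`) shares the loss, normalization and
evaluation pathway but consumes one-hot input through two same-padded
convolutions (width 32, kernel 7) and a position-wise linear readout.

The attention and convolution inner loops are compiled (RcppArmadillo);
the exported `selfAttention()` is a plain-R reference implementation of
the same formula, and the test suite checks the two routes against each
other.

# Saturation mutagenesis

`saturationMutagenesis()` samples promoters from the test set (default
200), and for every position and each of the three alternative bases
predicts the strength change of the point mutant on the normalized scale
(raw scale available). Mutations are classified `within_group`
(A<->T, C<->G) or `cross_group` (between the A/T and C/G groups).
Summaries report per-position mean |delta| by class and per-(ref, alt)
box statistics (1.5 IQR whiskers); `regionContrast()` compares planted
or canonical element windows (e.g. -10 and -35 boxes) against the rest
of the sequence.

# The synthetic fixture generator

`generateFixture()` draws study-scale datasets with known ground truth:
an i.i.d. AT-rich background (A/T 0.3, C/G 0.2 — bacterial upstream
regions are AT-rich), a TATAAT-like PWM planted at start L-12 (the -10
box) and a TTGACA-like PWM at L-36 (the -35 box), each with consensus
probability 0.7 per column, and the strength law

S = 10^(a * score + b + N(0, sigma)),

where `score` is the summed log-odds of the drawn bases under the PWMs
versus the background. Defaults m = 2000, L = 50, a = 0.15, b = 1,
sigma = 0.25. These were chosen once so that (i) strengths are strictly
positive and right-skewed, exercising the log10/min-max pipeline;
(ii) the latent signal-to-noise ratio puts the best attainable test
correlation near 0.87, so a competent predictor can clear 0.5 with a
wide margin while the problem stays non-trivial; (iii) the exact
consensus appears at the planted window in ~12% of sequences, giving the
positional profile a sharp, known peak.

What the fixture does *not* emulate: real promoter datasets have
correlated backgrounds, motif spacing variability, measurement-specific
noise and far weaker sequence-to-strength relationships (the realistic
ceiling for strength prediction from 50 nt alone is low). Passing the
recovery suite therefore demonstrates that the algorithms work as
specified on data of known structure, not that any particular accuracy
will be reached on biological data.

# Problem sizes and numerical choices

The recovery suite and the acceptance script run the full pipeline at a
reduced scale chosen as realistic-but-fast: 2000 fixtures of 50 nt,
T = 200 diffusion steps with 60 training epochs, 1000 sampled
sequences, 15 predictor epochs, and 200 mutagenized promoters (60 in the
test suite). At these sizes the diffusion model reaches a 2-mer spectrum
correlation of ~0.95+ against its training set and the transformer sits
within ~0.04 of the fixture's theoretical correlation ceiling.

Other numerical conventions: argmax ties decode to the lowest channel;
layer norm uses eps = 1e-5; k-mer spectra divide by the total window
count m(n-k+1) and densify over all 4^k k-mers (zeros included) before
correlation, so absent k-mers inform the comparison; logo information
content is IC = 2 + sum_b p_b log2 p_b with 0 log 0 = 0 and no
small-sample correction by default (a flag enables the 3/(2m ln 2)
correction); the degenerate-variance cases (constant vectors) are
explicit errors rather than silent zeros.

# Known limitations

* The DDPM is unconditional; there is no conditioning on strength or
  classifier guidance, so screening happens post hoc through the
  predictor, as in the design loop this package implements.
* Training runs on CPU via BLAS matrix kernels; it is sized for
  thousands of short sequences, not genome-scale corpora.
* The shuffled-label null for the predictor is not exactly zero at
  finite n: a model trained on permuted labels can still output a
  nonflat function of sequence composition whose predictions correlate
  with the truth at the +-0.15 level for n = 2000. Comparisons against
  the null should use a margin (the suite requires real >= null + 0.3)
  rather than expecting the null to vanish.
* One-hot diffusion treats the simplex only implicitly (decoding by
  argmax); no categorical/discrete diffusion variant is provided.
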