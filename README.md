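# promodiff

Design bacterial promoters in silico: a **denoising diffusion
probabilistic model (DDPM)** generates novel promoter sequences from
noise after unsupervised training on natural promoters, and a
**transformer-encoder regressor** predicts promoter strength to screen
the generated candidates. The package is aimed at synthetic-biology and
regulatory-genomics groups who want a CPU-runnable, fully seeded
implementation of this generate-then-screen loop, together with the
evaluation statistics used to judge it.

## What it implements

**Generation.** Promoters of fixed length L are one-hot encoded
(channels A, T, C, G). The forward diffusion process corrupts a clean
matrix x₀ over T steps,

    x_t = √(ᾱ_t)·x₀ + √(1-ᾱ_t)·ε,   ε ~ N(0, I),   ᾱ_t = ∏_{s≤t}(1-β_s),

with a linear β schedule. A convolutional residual network with
positional and sinusoidal timestep embeddings is trained to predict ε
under an L1 loss; ancestral sampling runs the learned reverse kernel
from pure noise and decodes by per-position argmax.

**Screening.** Sequences are encoded as three integer token streams
(nucleotides 0–3; overlapping dinucleotides 4–19 with zero-padded final
codes 20–23; positions 0..L-1), embedded, and passed through transformer
encoder layers with multi-head scaled dot-product self-attention,
softmax(QKᵀ/√d_k)·V. Strengths are log₁₀-transformed and min-max
normalized; training minimizes w₁·MSE + w₂·(1−PCC), where PCC is the
Pearson correlation. A CNN baseline shares the same loss and evaluation
pathway.

**Evaluation & interpretation.** Sliding-window k-mer frequency spectra
and their cross-set Pearson correlation; positional k-mer profiles;
sequence-logo information content (IC = 2 + Σ p·log₂p bits); and
in-silico saturation mutagenesis (every position × 3 alternative bases,
with A↔T/C↔G vs cross-group mutation classes and per-position
sensitivity summaries).

**Synthetic fixtures.** A seeded generator of promoter-like datasets
with planted −10/−35 motifs (TATAAT/TTGACA-like PWMs) over an AT-rich
background and a known exponential strength law, so the whole pipeline
is testable end to end without any external data.

## Worked example

```r
library(promodiff)

## a seeded dataset with planted -10/-35 motifs and known strength law
fix   <- generateFixture(fixtureSpec(count = 2000, seed = 11))
split <- splitDataset(fix, testFraction = 0.2, seed = 5)   # 4:1

## train the diffusion generator and sample new promoters
ddpm <- trainDDPM(fix, buildSchedule(200, 1e-4, 0.1),
                  epochs = 60, seed = 3)
gen  <- samplePromoters(ddpm, 1000, seed = 4)

## fidelity of the generated set
kmerPcc(gen, fix, k = 2)
#> [1] 0.9660912
prof <- positionalProfile(gen, "TATAAT")
prof$tss_position[which.max(prof$frequency)]
#> [1] -12

## train the strength predictor and screen the samples
tf <- trainPredictor(split$train, predictorConfig(epochs = 15, seed = 7))
evaluatePredictor(tf, split$test)
#> [1] 0.8191686
head(sort(predictStrength(tf, gen, scale = "raw"), decreasing = TRUE), 3)
#>    gen_8  gen_491  gen_362
#> 506.0820 246.6553 207.6597
```

The 2-mer correlation of 0.97 says the sampled sequences reproduce the
dinucleotide composition of the training set almost exactly, and the
positional profile shows the generator placing the TATAAT consensus at
the planted −10 window. The test-set correlation of 0.82 approaches this
fixture's noise ceiling (~0.86), i.e. the transformer recovers most of
the planted sequence-to-strength law; ranking the raw-scale predictions
screens the strongest candidates.

Mutation mapping with the trained model:

```r
recs <- saturationMutagenesis(split$test, tf, sampleSize = 60, seed = 17)
regionContrast(positionSummaries(recs),
               list(minus10 = c(-12, -7), minus35 = c(-36, -31)))
#>    region        class region_mean complement_mean
#> 1 minus10  cross_group  0.07060578      0.02056375
#> 2 minus10 within_group  0.08142839      0.01999727
#> 3 minus35  cross_group  0.09098769      0.01778440
#> 4 minus35 within_group  0.09286011      0.01843840
```

Predicted strength is 3–5× more sensitive to mutations inside the
planted −10/−35 windows than elsewhere — the predictor has localized the
functional elements.

Real promoter tables (CSV/TSV with `id,sequence,strength` columns, or
FASTA) load with `readPromoterTable()`; `runDesignPipeline()` (or the
`inst/scripts/promodiff` command-line wrapper) orchestrates the whole
generate–screen–evaluate–mutscan workflow from one config and writes
tables plus a JSON report.

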