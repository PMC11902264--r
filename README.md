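# pepdiff

Conditional denoising-diffusion design of polypeptide sequences under
per-residue secondary-structure constraints.

## What problem this solves

De novo peptide design often starts from a *structural* specification: "two
flexible caps around a 12-residue alpha-helix", or the full per-residue
DSSP string of a known protein chain. `pepdiff` implements a denoising
diffusion probabilistic model (DDPM) over amino-acid sequences of 1-250
residues in which that specification is the conditioning signal: residues
are encoded as normalized numeric codes, corrupted with Gaussian noise, and
a learned sequence-to-sequence denoiser -- bidirectional LSTM stacks fused
with the embedded condition through multi-head self- and cross-attention
with learnable rotary position embeddings -- iteratively reconstructs clean
sequences from pure noise. It is aimed at computational protein scientists
who want an inspectable, fully self-contained implementation of
structure-conditioned sequence diffusion: every component, from the noise
schedule to backpropagation through the LSTM/attention network, is in this
package and covered by tests.

## The model in brief

* **Forward process**: $x_t = \sqrt{\bar\alpha_t}\,x_0 +
  \sqrt{1-\bar\alpha_t}\,\epsilon$ with a cosine schedule over $T = 64$
  timesteps ($\bar\alpha_0 = 1$, $\bar\alpha_T < 0.01$).
* **Denoiser**: predicts the clean sequence $x_0$; trained with MSE over all
  batch x length elements, one shared timestep per batch.
* **Classifier-free guidance**: condition positions are dropped during
  training; at sampling time
  $x_{CFG} = x_{uncond} + W\,(x_{cond} - x_{uncond})$ with condition scale
  $W = 1$ by default.
* **Reverse loop**: 64 iterations of denoise -> guide -> re-noise ->
  clamp-correct, then nearest-code quantization back to residues.
* **Evaluation**: per-residue concordance $A_{pr} = n/N$ between condition
  and observed structure, and generation diversity
  $S_{avg} = \sum_i S_i / N_{pair}$, the mean pairwise percent identity over
  the upper triangle of the similarity matrix for sequences generated under
  one condition.

A synthetic corpus generator with a known class-conditional residue grammar
makes the whole pipeline trainable and testable offline; a corpus module can
alternatively extract paired (sequence, DSSP-string) records from PDB/mmCIF
files.

## Worked example

Train a tiny model for a few seconds on the deterministic grammar (each
secondary-structure class emits exactly one residue, e.g. helix -> L) and
generate under a capped 16-residue helix condition:

```r
library(pepdiff)

corpus <- sampleCorpus(deterministicGrammar(lengthRange = c(10L, 32L)),
                       200, seed = 1)
corpus
#> PolypeptideSet with 200 records
#>   lengths: 10-32 (median 21)
#>   synth_000001  GGGVVVVVVVVVV...
#>   synth_000002  GLLGGVVVVVVVVVGG...
#>   synth_000003  VVGGGGGGGG...

model <- newDenoiser(tinyDenoiserConfig(), cosineSchedule(64), seed = 1)
model
#> PepDenoiser
#> DenoiserConfig: seqLen 32, condEmbed 32, lstm 2xbi-64, heads 4, blocks 1, ff 64
#> NoiseSchedule: T = 64, alphaBar[T] = 1e-06
#>   trainable parameters: 367,025

fit <- trainPhase(model, corpus,
                  trainConfig(lrStart = 2e-3, lrEnd = 5e-4, batchSize = 8L,
                              epochs = 4L, datasetFractions = 1, seed = 2))
round(fit$epochLoss, 3)
#> [1] 0.147 0.104 0.083 0.080

g <- generateSequence(fit$model, buildHelixCondition(16),
                      generationSettings(seed = 3))
aaSeqs(g$record)
#> [1] "KIIIKKKKLLLLLLLL"
```

After only 100 optimization steps the model has learned the dominant rule
of the grammar -- helix positions emit L (the run of L's) -- while the cap
positions are still wrong; the loss curve shows it is still descending. The
mean epoch losses are MSE in normalized-code units (chance level ~0.33 for
these sequence lengths). A fully trained run (the 2,000-step setting used
by `scripts/acceptance.R`) reaches ~0.90 per-position accuracy on held-out
conditions. The diversity protocol on this deterministic grammar collapses
to $S_{avg} = 100\%$ -- identical sequences are the *correct* outcome when
the conditional distribution is a point mass; diversity below 100% appears
under stochastic grammars:

```r
div <- diversityProtocol(fit$model, buildHelixCondition(16), k = 5, seed = 4)
round(div$savg, 2)
#> [1] 100
```

The shell entry point `inst/scripts/pepdiff.R` wires the same functions into
`simulate`, `build-corpus`, `train`, `generate` and `evaluate` commands.

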