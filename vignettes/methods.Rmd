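---
title: "Bilingual sequence-structure modeling at desk scale: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bilingual sequence-structure modeling at desk scale: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Overview

`foldlingo` implements, at a scale that trains in minutes on one CPU, the full
pipeline of a bilingual protein language model that translates between
amino-acid (AA) sequences and the 20-state 3Di structural alphabet: the
dual-alphabet tokenizer, dataset curation, the two-phase training schedule
(span denoising, then bidirectional translation), the stochastic decoding
stack, a convolutional per-residue 3Di classifier over encoder embeddings,
alignment-based generation metrics with roundtrip filtering, and the
remote-homology / annotation-transfer evaluation machinery.

Because the real training corpus (millions of predicted structures) and
billion-parameter checkpoints are far outside desk scale, every component is
exercised on a *synthetic bilingual world* whose statistical structure mimics
what the method assumes about real data. The synthetic world makes each claim
testable: the structure string is a known function of the sequence, so Bayes
accuracy is known, negative controls can be built by construction, and
hierarchy labels are exact.

# The synthetic bilingual world

`generate_world()` draws proteins from a three-level fold/superfamily/family
hierarchy. Each fold has an independent random AA motif; superfamily and
family motifs are mutated copies (substitution rates 0.30 and 0.15); each
protein is a mutated (rate 0.06), randomly cropped copy of its family motif
with length uniform in 30--60 residues. These rates give same-family pairs a
clear identity margin over cross-family pairs (verified by an alignment-based
test), which is what gives homology detection and annotation transfer their
signal.

The structure string is produced by a fixed surjective local map `g`: the
(center, right-neighbour) AA pair inside a window (default width 3) is hashed
by a low-discrepancy multiplicative hash into the unit interval and quantized
through a Zipf-shaped distribution over the 20 3Di letters (exponent `skew`,
default 1), followed by a majority vote over every 3-window that creates
secondary-structure-like runs. Three design targets drove this choice, each a
property reported for the real 3Di alphabet on large predicted-structure
collections:

* **learnable** -- with `noise_rate = 0` the conditional entropy of the
  structure token given its AA window is zero, so a competent sequence model
  can approach perfect translation accuracy;
* **imbalanced** -- under the default skew the three most frequent tokens
  (named v, d, p here) cover over half of all residues, reproducing the
  severe class imbalance of real 3Di strings;
* **locally smooth** -- the majority vote produces runs, the analogue of
  secondary-structure elements.

Independent per-position noise (`noise_rate`, default 0.05) corrupts tokens
uniformly; `noise_rate = 1` destroys the AA/3Di dependence entirely and is
the negative-control condition. Per-protein quality scores are drawn from a
two-component Beta mixture on [40, 100] (a high component, Beta(8, 1.5), and
with probability `low_plddt_frac` a low component, Beta(2, 5)), so a
controllable fraction (~15% by default) falls below the quality-filter
threshold of 70. Clusters are nested inside families; hierarchy labels are
dot-separated strings compared by level prefix.

What the world does **not** emulate: physically realistic structures, real
AA composition and length distributions, long-range structural contacts
(the map is strictly local), or the database-scale redundancy structure of
real protein collections. Passing tests therefore demonstrate that the
machinery is correct and that the method behaves as designed when its
assumptions hold -- not that the toy model would perform on real proteins.

# Tokenizer and curation

The bilingual vocabulary holds the 20 upper-case AA letters (plus X for
ambiguous codes), the 20 lower-case 3Di letters (casing is the collision
guard between the two alphabets), two translation-direction prefix tokens,
`n_sentinel` span-corruption sentinels (default 128; the toy models use 16)
and pad/EOS/unknown. Tokenization is strictly character-level; ids are
contiguous and the AA/3Di id ranges are disjoint by construction.

Curation applies three filters with strict boundary semantics (equality
survives): quality < 70, length < 30, and single-token fraction > 0.95,
counting multiply-failing records under the first failing rule.
`cluster_split()` shuffles clusters with a seed and moves them whole into
validation/test until the requested number of proteins accumulates; the
highest-quality member of each held-out cluster is its representative.
`cap_cluster()` performs greedy max-min diversity selection starting from the
representative; the diversity distance defaults to alignment-based AA
dissimilarity and is pluggable, since the profile-based clustering tools used
at full scale are out of scope here.

# The translation model

The model is a small encoder-decoder transformer: tied input/output
embeddings, a bidirectional encoder, and an autoregressive decoder with
causal self-attention and cross-attention. Blocks are pre-norm RMSNorm, the
feed-forward uses ReLU with hidden width 4d, and every attention carries a
learned relative-position bias over clipped offsets (17 buckets at +/-8), the
scheme of the T5 family this architecture follows. One deliberate inductive
bias: the cross-attention bias is initialized with a mild preference (+2
logits) for the source position one ahead of the decoder position, which is
where the aligned residue sits once the direction prefix shifts the source.
Translation between AA and 3Di is monotone and position-aligned, so this
initialization only accelerates the alignment discovery the model would
otherwise spend hundreds of steps on; it is learnable and can be unlearned.

Both passes, forward and backward, are written out by hand in base matrix
algebra (the environment provides no automatic differentiation), and a
finite-difference gradient check over every parameter tensor guards the
derivatives in the test suite.

Training follows the two-phase schedule: phase 1 minimizes span-denoising
cross-entropy with batches alternating between the AA and 3Di modalities
(teaching the model the new tokens without abandoning either alphabet);
phase 2 minimizes translation cross-entropy with batches alternating between
the two directions, under a max-length curriculum
(`phase2_max_len_schedule`). Span corruption masks `round(0.15 * L)` tokens
in spans of mean length 3 (uniform random compositions, geometric-like),
replaces the i-th span by sentinel i and trains the decoder to emit the
dropped spans behind their sentinels; the construction is exactly invertible.

The published recipe fine-tuned a 3-billion-parameter pretrained checkpoint
with learning rates 1e-3 (denoising) and 1e-5 (translation), 100K steps at
length 256 then 600K at 512. A from-scratch toy model needs from-scratch
magnitudes: the defaults keep the two-phase structure and the phase ordering
but use 1e-3/3e-4 (the tests and the acceptance script use 2e-3 for the
translation phase, which converges fastest at this width), and the length
schedule is scaled down ~300-fold. Toy dimensions are 2+2 layers, width 128,
4 heads by default; the test-suite models use width 64, which reaches the
same accuracy on this world in less time. Gradient-norm clipping at 1 and
Adam (0.9/0.999) are config defaults.

# Decoding

`process_logits()` applies, in this fixed order: repetition penalty (positive
logits divided, negative multiplied -- so the penalty always reduces a
repeated token's probability), temperature, top-k truncation, nucleus
truncation (minimal probability-sorted prefix reaching `top_p`, boundary
token included), the optional target-alphabet mask, then softmax. The order
is the convention of the generation framework the published configuration
keys come from; it matters, and it is fixed.

Both published generation configurations ship as presets:
`decode_config_folding()` (AA to 3Di: sampling on, 3 beams, temperature 1.2,
top-p 0.95, top-k 6, repetition penalty 1.2) and
`decode_config_inverse_folding()` (3Di to AA: sampling on, temperature 1.0,
top-p 0.85, top-k 3, repetition penalty 1.2). Combining beams with sampling
is interpreted as *stochastic beam search*: each live beam extends by
sampling from its processed distribution, beams are ranked by
length-normalized log-probability (exponent 1, ties by beam index), finished
beams freeze, and the best finished beam is returned. Ancestral sampling is
the single-beam case; with sampling off, decoding is greedy/deterministic
beam search. All sampling is reproducible given `seed`.

# Structure head, alignment and roundtrip

The fast inference path drops the decoder: a two-layer CNN (kernel 7, 32
hidden channels -- the published work inherits its CNN from a
secondary-structure setup without restating dimensions, so these are declared
defaults, config-exposed) classifies each residue into 20 3Di states from
frozen encoder embeddings. Thresholding the per-residue confidence trades
coverage against precision monotonically; sub-threshold residues are emitted
as the placeholder `x` to keep outputs length-aligned, with a probability
sidecar TSV.

`nw_align()` is a Gotoh global aligner under a custom substitution matrix
with affine gaps (a run of k gap columns costs `gap_open + k * gap_extend`,
defaults -10/-1), deterministic traceback (diagonal > up > left), verified
against exhaustive enumeration over all global alignments on small inputs.
PIDE uses the full alignment length as denominator -- the conservative
convention, switchable to the shorter-sequence length; similarity
additionally reports the positive-score fraction, since it is genuinely
ambiguous which of the two a printed "sequence similarity" means. The 3Di
substitution matrix shipped with the package is **synthetic** (+6 identity,
+1 between tokens preferring the same secondary-structure class, -3
otherwise): the real structure-search matrix is derived from structural data
that is out of scope here, and any Foldseek-format matrix file can be
supplied instead.

Roundtrip accuracy scores an inverse-folding candidate by translating the
generated AA sequence back to 3Di and aligning it to the native 3Di string.
`generate_with_roundtrip()` samples candidates until one reaches 70% rountrip
PIDE or ten attempts are spent, and keeps the best candidate -- the published
filtering rule with both knobs exposed.

# Evaluation machinery

The homology statistic walks each query's ranked hits best-first: hits
sharing the query's label prefix down to the evaluated level are true
positives, a hit from a different fold ends the walk, and same-fold hits of a
different finer label are neutral. Per-query sensitivity is TPs found over
all possible TPs; queries with no possible TP are excluded (and counted).
The aggregate reported is the mean per-query sensitivity, equal to the area
under the sorted per-query sensitivity curve that `autoplot()` draws; the
exact computation behind the corresponding published aggregate is inherited
from an external benchmark harness and not restated there, so this package
declares its statistic rather than asserting identity.

EAT transfers the full hierarchy label of the Euclidean-nearest lookup
neighbor (mean-pooled encoder embeddings; ties by lookup order) and scores
each level hierarchically: a level is credited only if all coarser levels are
correct, which makes per-level accuracy non-increasing from coarse to fine by
construction.

# Numerical choices and degenerate inputs

* RMSNorm epsilon 1e-6; softmax rows are max-shifted before exponentiation.
* Empty sequences: alignment against an empty string is all gap columns with
  PIDE 0; `encode` of an empty string is just the prefix and EOS.
* Nucleus boundary: the token that crosses `top_p` is kept (with a 1e-12
  float guard); top-k ties at the threshold keep lower indices first.
* The alignment traceback resolves exact score ties in the fixed order
  diagonal, up, left, making results byte-reproducible.
* All randomness flows from explicit seeds (`withr::with_seed`), so worlds,
  training runs, corruptions and sampled decodes are reproducible.

# Problem sizes

The test suite and the acceptance script run the pipeline end to end at the
following sizes, chosen so the whole suite trains and evaluates in tens of
minutes on one CPU: a 5000-protein noise-free world (~150 validation and
~150 test proteins in whole clusters), a width-64 model trained for 60
denoising and 2400 translation steps at batch 16, a 400-protein
training set for the CNN head (10 epochs), 25 held-out proteins for
roundtrip filtering,
40 queries against 70 targets for the homology benchmark and 60 queries for
EAT. The negative-control world uses 1200 proteins at `noise_rate = 1` with
a short training run, which is ample for the model to collapse to the
marginal token distribution.

# Known limitations

* The structure map is strictly local, so nothing tests long-range
  structural consistency; real 3Di strings encode tertiary contacts.
* The model is intentionally tiny; conclusions about scaling behaviour or
  real-data accuracy cannot be drawn from it.
* The shipped substitution matrix is synthetic (see above).
* Stochastic beam search is one reasonable semantics for combining beams
  with sampling; the published configuration does not define the hybrid
  precisely, and other frameworks implement other semantics.
* Inverse-folding quality is measured only through sequence-level quantities
  (PIDE, KL naturalness, roundtrip accuracy); structural metrics (lDDT,
  TM-score, RMSD) require 3D predictors and are out of scope.
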