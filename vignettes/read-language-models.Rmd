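---
title: "Pretraining nucleotide language models on aligned short reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pretraining nucleotide language models on aligned short reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(readlm)
```

## The problem

Most nucleotide language models are trained on assembled genomes. Exome
sequencing, however, produces aligned 151-bp reads with heavy redundancy
(coverage depths from 1 to 180 reads per position), occasional sequencing
errors, and — buried inside that redundancy — the handful of bases per read
where a subject's genome differs from the reference. `readlm` is a
desk-scale toolkit for studying how to pretrain a decoder transformer
*directly on those reads*: how to pack fragments into fixed-length contexts,
how to throw away redundant reads without losing variant evidence, how to
reweight the training loss so rare variant bases are not drowned out by
reference bases, and how the resulting representations perform on
variant-centered classification tasks.

Everything runs on one CPU at toy scale. The mechanics — packing, filtering,
weighting, attention masking, two-phase training — are the object of study;
absolute accuracies from cluster-scale runs on real exomes are not
reproducible at this scale and are out of scope.

## The read simulator defines the study conditions

`sim_config()` fixes the synthetic-data conditions. The defaults are the
conditions the rest of the toolkit assumes:

* 151-bp reads; per-position depth bounded in [1, 180];
* about one substitution per kilobase in donor genomes
  (`variant_rate = 1e-3`) and one sequencing error per kilobase of read
  (`base_error_rate = 1e-3`), so a typical read carries roughly 1–2
  non-reference bases;
* integer Phred qualities from a clipped normal (mean 30, sd 5, clipped to
  [2, 40]) — enough structure for quality-based filtering to have a
  meaningful ranking signal;
* a "multispecies" stand-in: a second genome diverged from the reference by
  substitutions at rate 0.15;
* substitutions only. Indels and soft-clipped alignments are deliberately
  out of scope everywhere (simulator, SAM reader, packing), matching the
  restriction of the modelling problem to matched bases.

**Coverage model.** Depth targets are drawn per tile (7 × read length ≈ 1 kb)
uniformly on `[coverage_min, coverage_max]`, and reads are laid down in
non-overlapping abutting "layers": depth level $\ell$ covers exactly the
tiles whose target is at least $\ell$. Because the tile length is an exact
multiple of the read length, per-position depth *equals* the tile target at
every whole-read-covered position. We chose this layered placement over
uniform random placement inside tiles because it is the simplest scheme that
makes the coverage contract — interior depth always inside the configured
bounds — hold deterministically rather than in expectation; randomness lives
in the per-tile targets, the sequencing errors and the qualities. The final
sub-read-length tail of a contig is left uncovered rather than covered by
overlapping reads, which would break the upper depth bound.

Per-subject draws in `simulate_cohort()` use sub-seeds hashed from
(master seed, subject index), so cohorts are reproducible and subjects are
independent.

## Formats and coordinates

In memory every coordinate is 0-based, half-open. 1-based coordinates
appear only at format boundaries: SAM `POS` and VCF `POS`. The SAM writer
emits coordinate-sorted single-end records with `@SQ`/`@RG` headers and
`<len>M` CIGARs; the readers skip (with counted warnings, not errors)
unmapped, secondary/supplementary, indel-containing and multi-allelic
records, since those are declared out of scope. The readers are small
line-based parsers so that error messages can point at offending lines and
fixtures stay human-readable; one test cross-checks the SAM we write against
`samtools view`.

## Tokenization

The vocabulary is fixed at nine symbols — `PAD`=0, `BOS`, `SEP`, `MASK`,
then `A C G T N` on contiguous ids — well under the 16-entry embedding
budget the model is designed around. Contig identity deliberately does not
get tokens: it lives in packed-context metadata. This keeps the vocabulary
minimal and sidesteps inventing a contig-token scheme with no principled
definition at desk scale.

## Packing reads into contexts

A context is `BOS`, then each packed read's bases followed by one `SEP`,
then `PAD` to length $L$ (default 1024). The separator gives a causal model
an unambiguous read-boundary signal; with 151-bp reads the effective
nucleotide capacity of a 1024-slot context is just over 1000 bp, which is
why a "1024-token context" and "~1000 bp of sequence" describe the same
design. Reads are never split across contexts, and contexts never mix
contigs (or subjects, via `pack_cohort()`): a read's local context is kept
intact, which is precisely the property the consecutive strategy exploits.

Four read strategies plus a reference baseline are implemented:

* **consecutive** — ascending genomic order;
* **random** — a seeded uniform shuffle within each contig;
* **spaced** — greedy passes that only pack a read if it does not overlap
  the previously packed read, so intervals within a context are pairwise
  disjoint;
* **overlapping** — maximal chains of overlapping/abutting reads merged
  into one contiguous consensus (per-position majority vote over covering
  reads; ties resolve to the reference base), then packed consecutively and
  split at $L-2$ boundaries when longer than a context;
* **reference** — the reference genome chunked into $(L-2)$-token windows,
  one per context.

`loss_mask` is false exactly on `BOS` and `PAD` slots; `SEP` slots are
predicted like any other token so the model learns read boundaries.

## Filtration

The filtration criterion is not uniquely determined by its goals (discard
low-quality redundancy, keep variant evidence), so the package commits to
one deterministic realization: rank all reads by
(carries-a-variant, mean Phred quality, read id) and keep the top
$\lceil n/k \rceil$, then repair: any (position, allele) that some input
read supports but the retained slice does not is fixed by swapping its
best-ranked carrier in for the worst-ranked retained *non-variant* read.
The repair is best-effort by construction — when the retained budget is
smaller than the number of variant-carrying reads there is no non-variant
read left to sacrifice, and the cardinality contract
$|{\rm retained}| = \lceil n/k \rceil$ takes precedence. An alternative
reading of "filtration" as per-position coverage capping was considered and
documented as out of scope.

## Dynamic importance weighting

The pileup `build_pileup()` tallies per-position allele counts
$c(p, a)$ and depth $d(p)$. In dynamic mode each nucleotide slot carrying
allele $a$ at position $p$ receives the raw weight

$$u(p,a) = \left(\frac{c(p,a)}{d(p)} + \varepsilon\right)^{-\alpha},$$

clipped to $[1/\text{clip}_{\max}, \text{clip}_{\max}]$. This is the
minimal family that is inverse in the empirical allele frequency and gives
variant alleles strictly larger weights than reference alleles, with a
tunable strength $\alpha$ ($\alpha = 0$ reduces exactly to uniform).
Nucleotide weights are then normalized to mean 1 *among themselves*, and
loss-masked structural slots (`SEP`) keep weight exactly 1. This two-part
normalization is deliberate: it makes the corpus mean over all loss-masked
slots exactly 1 (the loss scale is comparable across weighting modes) *and*
makes the all-alleles-equally-frequent case collapse to exactly uniform
weights, which a single joint normalization cannot do simultaneously.

Defaults $\alpha = 1$, $\varepsilon = 10^{-6}$, clip 100 are declared, not
inferred — the production constants behind the method are unknown. One
practical note: with $\alpha = 1$ a singleton sequencing error at depth $d$
receives weight $\approx d$, which can exceed the weight of a true variant
shared by several reads; the clip exists to bound exactly this pathology,
and experiments that compare weighting modes on error-containing cohorts
should set the clip near the variant-frequency scale (for a cohort of $S$
subjects, a homozygous single-subject variant has frequency $\approx 1/S$,
so clip $\approx S$).

## The transformer

A pre-layer-norm decoder transformer written in base R with hand-derived
backpropagation (no deep-learning runtime is required):

* blocks: LN → multi-head attention → residual; LN → 4× GELU feed-forward →
  residual; final LN; untied output projection;
* objectives: causal next-token, or BERT-style MLM with bidirectional
  attention and the standard 80/10/10 corruption at a 15% masking rate
  (only the rate is prescribed; 80/10/10 is the canonical recipe that
  "BERT-style" names);
* positional encodings: rotary (rotation of query/key pairs, making
  attention scores a function of relative offset), learnable absolute,
  fixed sinusoidal, and relative shared-bias-per-offset (a per-head bias
  table indexed by $i - j$, shared across layers);
* attention windows: causal-local — slot $i$ sees slots $(i-w, i]$; under
  MLM the window is symmetric, $|i - j| < w$. Both definitions reproduce
  dense attention exactly at $w = L$, which is tested bitwise;
* optimizer: AdamW with a fixed learning rate (decoupled decay on matrices
  only). Schedules are irrelevant at toy scale and deliberately omitted.

Unstated architectural details (expansion ratio 4, exact GELU, pre-LN,
N(0, 0.02²) initialization with residual-projection scaling) are
conventional defaults, declared in `model_config()` and documented here as
assumptions. Correctness rests on finite-difference gradient checks for
every positional encoding and both objectives, exhaustive causality
perturbation tests, and the dense-window equivalence above. Desk-scale
defaults are 4 layers × 128 hidden; the production-scale reference point
(20 × 1856) is expressible in configuration but never instantiated by tests.

## Training, evaluation, ablations

`train_two_phase()` implements the two-phase recipe: phase 1 samples only
corpus A (reference-genome contexts, teaching the backbone the reference
first), phase 2 draws each batch from corpus B (subject reads) with
probability `mix_ratio`, else from A. "50:50" and "14:86" mixes map to
`mix_ratio` 0.5 and 0.86, and "15% of the second corpus" maps to
`subset_fraction = 0.15` — the only reading that keeps the two knobs
independent; it is a documented interpretation, not an asserted fact about
the original method. The loss trace records the phase boundary and the
per-batch corpus choice, and identical seeds reproduce traces bitwise.

`next_token_accuracy()` scores, at every slot whose successor is
loss-masked, the argmax over the four bases A/C/G/T against the true
successor. Structural tokens are excluded from targets and candidates, and
`N` is excluded from the candidate set as an ambiguity code rather than a
base call — a uniform-random scorer then sits at exactly chance 1/4, which
is also how the evaluation is validated. `run_ablation_grid()` trains one
seeded model per cell over any subset of the axes (packing, filtration,
weighting, objective, positional encoding, window, subject count, mix
ratio) and evaluates every cell on every requested preparation, mirroring
the all-to-all comparison design; cell failures are recorded without
aborting the grid.

## Downstream tasks

`build_variant_benchmark()` constructs variant-centered windows: the
reference window centered on the variant with the alternate allele
substituted at the center, against control windows at random non-variant
positions. Windows near contig edges shift inward rather than pad, so all
sequences share one length and no padding symbol leaks label information.
`split_dataset()` uses the 70/12/18 convention with per-class rounding under
stratification. `finetune_classifier()` attaches a linear head to
mean-pooled final-layer embeddings and fine-tunes the full backbone,
selecting by validation MCC and reporting test MCC once.
`probe_layers()` freezes the backbone, extracts mean-pooled embeddings at
every layer (layer 0 = post-embedding), and cross-validates a two-layer MLP
(`nnet`, hidden width 64 by default, weight decay; we use decay + a fixed
iteration cap rather than fold-internal early stopping) per layer.
Mean-over-non-PAD pooling for both fine-tuning and probing is an assumption,
documented here. Multi-task aggregation, where used, is a plain mean of
per-task MCCs. The MCC itself returns 0 whenever a denominator factor is
zero.

One practical consequence of mean pooling is worth knowing: pooled
embeddings of an *untrained* backbone carry composition information but not
positional information, so tasks keyed to a specific slot (like the center
base) are only learnable through fine-tuning when the backbone has an
absolute positional signal (learnable or sinusoidal encodings) it can use
to route that slot — the package's fine-tuning tests use a learnable-PE
backbone for exactly this reason.

## Problem sizes used by the tests

The test-suite and acceptance checks run deliberately small instances,
chosen once as the smallest sizes at which each property is meaningfully
exercised: reference contigs of 1.5–160 kb; cohorts of up to 25 subjects;
contexts of 34–1024 slots; models from 1 × 8 to 4 × 128. The memorization
check trains a 4 × 128 causal model on a periodic ACGT genome packed into
34-slot contexts; the weighting comparison uses the 5-subject cohort at
variant rate 5 × 10⁻³ with coverage 8–12 over a 2 kb contig, 512-slot
contexts and a 2 × 64 rotary model trained for a fixed 200-step budget —
each subject's contexts are scored at that subject's own variant positions
(where the true next base is the alternate allele), the quantity dynamic
weighting is designed to improve; the probing checks use a 200-record
composition-separable fixture. The pipeline's default configuration
(`inst/extdata/pipeline_toy.yaml`) runs the full chain on a 6 kb, 2-subject
cohort.

## What passing tests do and do not show

The simulator emulates coverage structure, substitution variants, errors
and qualities, but not paired-end inserts, sequencing-by-synthesis error
profiles, indels, structural variation, GC bias or real exome capture
targets. Passing tests therefore demonstrate that the *mechanics* are
implemented correctly and that the method's directional claims hold on
clean synthetic data; they say nothing about absolute performance on real
exomes, which requires cluster-scale training on real cohorts.

## Known limitations

* Substitutions only, end to end.
* Training is plain-R CPU code: ~0.2 s per forward+backward on a 512-slot
  context with a 2 × 64 model; fine for toy studies, not for real corpora.
* Variant preservation under filtration is best-effort once the retained
  budget is smaller than the number of variant-carrying reads.
* `N` never appears in simulated data (references are clean by
  construction); the token exists for imported reads.
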