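---
title: "Counting functional groups: the model and methods behind nummolgen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting functional groups: the model and methods behind nummolgen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`nummolgen` generates drug-like molecules under *quantitative*
functional-group constraints: not "contains a hydroxyl" but "contains
exactly two". This vignette is the package's own account of the model, its
assumptions, the parameters that matter, and what the desk-scale tests do
and do not demonstrate.

## 1. The representation

### Triplets over a fixed 27-type vocabulary

A molecule is canonicalized (Open Babel canonical SMILES, via ChemmineOB)
and matched against a fixed, ordered vocabulary of 27 functional-group
patterns, yielding one triplet *(type, count, positions)* per vocabulary
entry. Positions are the 0-based atom-index sets of each pattern instance
over the canonical-SMILES atom order — the only atom order that is
reproducible across runs. Absent groups keep their slot with count 0, so
every molecule occupies the same dense 27-dimensional constraint space and
batches align without ragged bookkeeping.

Three conventions are deliberate:

* **Symmetric-duplicate collapsing.** A benzene ring matches an aromatic
  six-ring pattern twelve ways (rotations × reflections); all map the same
  atom set and count as *one* chemical instance. Counts are per instance,
  not per automorphism.
* **Overlap across types is retained.** An ester oxygen also matches the
  ether pattern; both triplets keep their instances. Nothing in the
  constraint semantics forbids overlap, and removing it would make counts
  depend on an arbitrary precedence order.
* **Implicit-hydrogen graphs.** Patterns are written against the
  implicit-H molecular graph; explicit-H input is sanitized first.

The vocabulary membership itself is a curated choice (hydroxyl, the
carbonyl family, the amine series, halogens, sulfur and phosphorus groups,
5/6-membered aromatic rings, multiple bonds — see
`inst/extdata/fg_vocabulary_default.tsv`): the constraint-space dimension
(27) is fixed, the member list is versioned with the package, and checkpoint
files carry a content hash of it so a model can never be silently resumed
against a different vocabulary.

Substructure matching is implemented in-package (a backtracking matcher
over a restricted SMARTS dialect) because no installed R binding exposes
*match atom indices*, which the position component requires. Counting
agreement is continuously cross-checked in the tests against two
independent oracles: Open Babel's SMARTS engine (a different codebase) and
a naive enumeration written longhand in the test helpers.

### Dual sequences

An annotation serializes into two strictly aligned streams:

```
[FG:hydroxyl] [NUM] pos4 [SEP] pos9 [SEP]  ...  [FG:nitro] [NUM] [NONE]  [BOS] C C ( = O ) ... [EOS]
      0         2    0     0    0    0     ...       0       0     0       0   0 0 0 0 0 0      0
```

one header block per group in vocabulary order — `[FG:name] [NUM]` then the
instances' position tokens with a trailing `[SEP]` per instance, or
`[NONE]` for absent groups — followed by the SMILES as atom-level regex
tokens. The numeric stream carries the raw count at each `[NUM]` slot and 0
elsewhere; both streams always have equal length, and encoding/decoding is
exactly invertible (asserted corpus-wide in the tests). Counts are *not*
normalized: the raw-injection channel of the model adds the scalar
directly, so the numeric stream stays on the count scale.

The template places all headers before the SMILES. The alternative —
interleaving group headers with the SMILES — would break the clean
prompt/continuation split that constrained generation relies on.

## 2. The model

### Numerical embedding

Each position's scalar $n$ enters through three channels:

* raw injection: $e^{raw} = e^{text} + n$, the scalar broadcast over all
  $d$ coordinates — preserves the value itself;
* sign embedding: a learned 3-row table indexed by $\mathrm{sign}(n) \in
  \{-1, 0, +1\}$ — zero gets its own row, because "absent" is a category,
  not a small magnitude;
* soft magnitude quantization: $|n|$ goes through two small GELU MLPs
  (1 → 32 → K) whose softmax outputs weight two learnable bin tables
  ($K = 16$ bins), the second scaled by a learnable $\lambda$
  (initialized 1). Soft binning keeps the embedding continuous in $|n|$ —
  nearby counts get nearby embeddings — while still giving the model
  discrete-ish anchors.

The fused stream is $E^{fusion} = E^{text} + (n\mathbf{1} + e^{sign} +
e^{mag})$. The raw text embedding is *not* added twice: the numerical
increment is the sum of the three channels' contributions beyond
$E^{text}$. (The alternative reading, $E^{fusion} = E^{text} + e^{num}$
with $e^{num}$ already containing $e^{raw} = E^{text} + n$, would
double-count the token embedding; anyone reconciling against other
implementations should check this convention first.)

### Dual-stream differential attention

Every block runs multi-head causal self-attention twice — once on the text
stream, once on the fused stream — with **one shared set** of Q/K/V/output
projections, and isolates the differential $H_{diff} = H_{fusion} -
H_{text}$: the attention shift attributable purely to the numerical
channel, uncontaminated by weight differences. Both streams then receive
the same update, residual + Norm followed by SwiGLU + Norm (RMS
normalization by default, standard layer normalization configurable); the
fusion update is assembled as common-mode plus differential,
$\mathrm{Norm}(E^{fusion} + H_{text} + H_{diff})$.

One design point deserves an honest paragraph. An update that adds *only*
the differential to the fusion residual — dropping the common-mode
$H_{text}$ — looks attractive on paper but has two defects we considered
disqualifying. First, with the numerical channel off it degenerates: the
fusion stream collapses to a stack of normalizations with no attention
path at all, which is not "a plain decoder". Second, because the text
stream keeps updating normally, the two streams diverge after one block
even when they start identical, so the channel-off identity
($H_{diff} \equiv 0$ at *every* depth) can never hold beyond block 1.
Keeping the common-mode term makes the zero-channel reduction exact and
bitwise at all depths — with `channel_on = FALSE` the package's forward
pass is verified, against an independently written single-stream decoder,
to produce identical logits — while $H_{diff}$ remains computed and
exposed per block (`want_streams = TRUE`) as the interpretable numerical
increment. Under this update the text stream is the common-mode baseline
and does not alter the fusion value, so the training path skips
materializing it.

Token logits and the numeric head (one linear projection per position,
predicting the *next* position's numeric value) read the fusion stream
after a final normalization. Positional information is a learned absolute
embedding added to the text embedding (and hence shared into the fusion
stream). Attention is causal in both streams: the model is autoregressive
and nothing may peek ahead.

### Pocket conditioning

Protein pockets enter as precomputed residue-embedding matrices
($L_p \times d_p$; in tests, seeded Gaussian fixtures — the package never
runs a protein language model). A single cross-attention layer before the
decoder stack lets every sequence position query the residues; its output
projection is zero-initialized, so at step 0 the conditional model equals
the unconditional one *exactly* — fine-tuning starts from a provably
unchanged policy and opens the gate only as gradients demand. The layer
can optionally be inserted per block, but the default applies it once at
the embedding, where the conditioning information joins the representation
the same way the numerical increments do.

## 3. Training

**Stage 1 — pretraining.** The composite loss is next-token cross-entropy
plus numeric mean-squared error. The MSE is masked to positions whose next
token is `[NUM]`: everywhere else the target is identically zero and the
regression signal would drown. Optimization is plain Adam (lr 8e-3 for the
desk-scale models here; 3e-3 is a safer default for larger runs), fully
seeded: same seed, same checkpoint, bitwise.

A subtlety the tests make explicit: the numeric head predicts each group's
count *before* that count is revealed, so its loss is bounded below by the
corpus' prefix ambiguity — the average conditional variance of counts
given the header so far. On the 32-molecule memorization fixture this
floor is ≈ 0.046 (computed independently by prefix-partition enumeration),
and the trained model reaches it while the cross-entropy falls to ~0.007.
Total loss therefore plateaus slightly above the floor, not at zero, and
the memorization guarantee is stated on reconstruction (≥ 95% of held-in
molecules reproduced exactly under greedy decoding) plus CE, not on the
raw total. At generation time the ambiguity is immaterial: counts are
teacher-forced as the prompt.

**Stage 2 — conditional fine-tuning.** Same loss, cross-attention active,
pockets paired with sequences. The separability test pairs four fixture
pockets with four scaffold families and verifies that, after fine-tuning,
matched pocket-molecule pairs score a strictly lower cross-entropy than
mismatched ones — the conditioning channel is demonstrably consumed.

**Stage 3 — RL alignment.** Augmented-likelihood policy gradient: sample
molecules from the current policy (temperature 1, grammar-constrained),
score them, and minimize the mean of
$(\log \pi_{prior}(S) + \sigma R(S) - \log \pi_\theta(S))^2$, where
log-probabilities are summed over the *sampled* token positions (forced
header anchors carry no decision and are excluded). The prior is a deep
frozen copy of the starting policy; with $\sigma = 0$ the objective is
minimized exactly at the prior, and the implementation provably does not
move (probe-set KL is 0 to machine precision). $\sigma$ defaults to 120 —
roughly the magnitude of a 40-60-token sequence log-probability, so the
reward term and the anchor term arrive on comparable scales; it is a
configuration knob, the underlying method fixes no value. Invalid SMILES
receive reward 0 and stay in the loss (the components of the reward are
undefined for them; a fixed floor keeps the objective finite). All-invalid
batches are skipped with a warning; a long run of them aborts.

**The reward** is $R = 0.4 f(T(dock)) + 0.3 f(QED) + 0.3 f(SA_{norm})$
with $f(x, b) = (1 + e^{-k(x-b)})^{-1}$, $k = 10$, thresholds $b_{dock} =
-3.0$, $b_{qed} = 0.2$, $b_{sa} = 0.5$. Two conventions are load-bearing:

* $T$ negates the raw docking affinity (kcal/mol, lower = stronger) before
  the increasing sigmoid, so stronger binders score higher; $b_{dock}$
  applies on the negated scale. Without the negation an increasing sigmoid
  would *penalize* strong binders. Note the consequence: with realistic
  affinities around −7, the dock component sits deep in sigmoid saturation
  (≈ 1) and the QED/SA terms drive the gradient. Tests of strict
  monotonicity therefore probe near the threshold.
* SA enters on the normalized $[0,1]$ scale, $(10 - raw)/9$, higher =
  easier — the only scale on which $b_{sa} = 0.5$ is meaningful.

## 4. Generation

Decoding is grammar-constrained by the template. From a bare count vector,
the structural anchors (`[FG:*]`, `[NUM]` with its count, `[NONE]`,
`[BOS]`) are teacher-forced and the model fills in only what it can know:
position tokens inside present groups (one instance run + `[SEP]` per
instance, instance length capped at 12 atoms) and the SMILES continuation
after `[BOS]`, restricted to SMILES tokens and `[EOS]`. Positions cannot
be part of a count-only prompt — they describe atoms of a molecule that
does not exist yet — which is why the grammar samples them; passing a full
annotation instead forces the entire header, the mode the memorization
check uses. Sampling modes: greedy (temperature → 0 limit), temperature,
top-k. Decoding keeps per-layer key/value caches, and the incremental path
is tested to reproduce the full forward pass to 1e-10.

Raw model output is returned as-is; validity is the evaluator's business,
and invalid strings are themselves informative (they depress validity and
receive zero reward in RL).

## 5. Evaluation choices

* **Lipinski** is reported in *both* conventions in circulation — fraction
  passing all five rules, and mean rules satisfied on the 0-5 scale —
  explicitly labeled, because the two are routinely conflated. The five
  rules here: MW ≤ 500, logP ≤ 5, HBD ≤ 5, HBA ≤ 10, rotatable bonds ≤ 10
  (descriptors from Open Babel; rotatable bonds by the package's documented
  convention).
* **QED** is the published desirability-composite over eight descriptors
  (MW, logP, HBA, HBD, TPSA, rotatable bonds, aromatic rings, structural
  alerts). The alert term uses a small curated pattern set expressible in
  the package's dialect; absolute values therefore differ slightly from
  other toolkits' QED, while ordering and range behave identically.
* **SA** is a complexity heuristic (size, rings, branching, heteroatom
  load) on the conventional raw 1-10 scale, not a fragment-contribution
  score — a fragment database is not shippable here. It is deterministic,
  smooth, and used consistently on the normalized scale.
* **Diversity** is mean pairwise Tanimoto distance over radius-2 circular
  fingerprints folded to 2048 bits, computed on the package's molecular
  graph.
* **Constraint compliance**: MSE averages squared count deviations over
  molecules *and* groups; EMR demands exact equality on all 27 entries;
  FMR tolerates ±3 on every entry — so EMR ≤ FMR by construction, and the
  suite asserts it on every batch. FMR applies the tolerance to *all*
  groups, constrained or not; restricting it to nonzero-target groups
  would be the other defensible reading, and switching is a one-line
  change. Invalid molecules count as failures for EMR/FMR and are excluded
  (with their count reported) from the MSE.
* **Success rate** uses the strict thresholds Vina < −8.18, QED > 0.25,
  SA > 0.59; boundary values are not successes.
* Uniqueness and novelty compare canonical SMILES strings, not InChI:
  cheaper, and exact for the achiral chemistry the fixtures cover.

## 6. Synthetic fixtures: what they emulate, and what they don't

`generate_corpus()` enumerates scaffold × substituent combinations (eight
drug-like scaffolds, 24 substituents), canonicalizes, deduplicates and
samples with a seed — producing valid, ≤ 40-atom molecules whose group
counts span 0-4, enough to exercise the numeric channel over a nontrivial
range. Pocket fixtures are seeded Gaussian matrices; the surrogate docking
scorer maps graph descriptors (heavy atoms, rings) smoothly onto a
realistic kcal/mol range, bitwise deterministic per molecule.

Passing tests on these fixtures demonstrates that the machinery is correct:
codecs invert, gradients are exact, training memorizes, conditioning is
consumed, RL climbs its reward. They do *not* demonstrate chemical
generalization: the corpus has no stereochemistry, no charged species
beyond nitro, no macrocycles, a narrow property distribution, and pocket
"embeddings" carry no biology. Results at publication scale (tens of
millions of molecules, real docking, a real protein language model) are
explicitly out of this package's scope; the desk-scale problem sizes used
by the tests and the acceptance script (24-32-molecule training sets,
~1,000-molecule codec corpora, 30-40 RL steps) are a deliberate choice to
keep the full pipeline reproducible on one CPU in minutes.

## 7. Numerical and degenerate-input choices

* Sigmoids use the numerically stable two-branch form; they saturate to
  exactly 0/1 in floating point rather than overflow.
* RMSNorm uses $\epsilon = 10^{-6}$; norm gains initialize to 1, weights
  to N(0, 0.02²), the cross-attention gate to zero, $\lambda$ to 1.
* Greedy decoding breaks logit ties by lowest token id; determinism
  everywhere else comes from seeding alone.
* Empty metric inputs raise classed `metric_undefined` errors, never
  return 0 — a 0 validity and an undefined validity are different facts.
* Over-length sequences are a hard error at batching time; there is no
  silent truncation anywhere.
* The padding token id is 0; padded positions are excluded from both loss
  terms via the mask and asserted so.

## 8. Known limitations

* The SMARTS dialect covers the vocabulary shipped (element, aromaticity,
  connectivity X, degree D, hydrogen count H, ring membership R, charge,
  bond orders, `;`/`,`/`!` logic) but not recursive SMARTS or ring-bond
  counts; extending the vocabulary may require extending the matcher.
* Aromatic ring counting covers 5- and 6-membered rings.
* QED/SA are package variants (see §5); compare trends, not third-party
  absolute values.
* Single-CPU, single-process: no device selection, no distributed
  training, by design.
* The RL objective inherits the usual augmented-likelihood caveat: with a
  saturating reward it mostly inflates likelihood uniformly; improvement
  is clearest from moderately trained priors with validity headroom, which
  is exactly how the improvement test is set up.
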