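# nummolgen

Functional-group-**count**-guided molecular generation in R.

## The problem

Structure-based drug design needs molecules that balance binding affinity
against physicochemical quality, and the *number* of functional groups is a
key dial: over-functionalization hurts synthesizability and drug-likeness,
under-functionalization costs affinity, and activity cliffs make the
difference between 1 and 2 hydroxyls consequential. Sequence generators can
be told *which* groups to include, but standard Transformers handle *how
many* poorly — tokenizing a count destroys its ordinal structure.

`nummolgen` implements a generator that treats counts as first-class
numerical inputs:

* **Triplet annotation.** Every molecule is annotated over a fixed 27-entry
  functional-group vocabulary as triplets *(type cᵢ, number nᵢ, positions
  pᵢ)*, where positions are the atom-index sets of each pattern instance on
  the canonical SMILES; absent groups keep their slot with count 0
  (`[NONE]`), so all molecules live in the same dense 27-dimensional
  constraint space.
* **Dual sequences.** Each annotation is serialized into two strictly
  aligned streams: a text stream
  `[FG:name] [NUM] pos… [SEP] … [BOS] smiles… [EOS]` and a numeric stream
  that is nᵢ at each `[NUM]` slot and 0 elsewhere.
* **Numerically-aware Transformer.** A scalar channel decomposes each
  count into raw injection (eᵢʳᵃʷ = eᵢᵗᵉˣᵗ + nᵢ, broadcast over all
  coordinates), a learned sign embedding over sign(nᵢ) ∈ {−1, 0, +1}, and a
  soft magnitude quantization (two GELU-MLP softmaxes over K = 16 learnable
  bins, eᵢᵐᵃᵍ = Σₖ pₖ⁽q⁾vₖ⁽q⁾ + λ Σₖ pₖ⁽r⁾vₖ⁽r⁾). Decoder blocks run
  causal self-attention on the text stream and the numerically fused stream
  in parallel with one shared weight set, isolate the differential
  H_diff = H_fusion − H_text, and update each stream with residual + Norm +
  SwiGLU + Norm. With the numerical channel off, the model is *bitwise* a
  plain causal decoder.
* **Three-stage training.** (1) unconditional pretraining under
  L = CE(token) + MSE(count); (2) pocket-conditional fine-tuning through
  zero-initialized (gated) cross-attention over precomputed protein-residue
  embeddings; (3) policy-gradient RL minimizing
  E[(log π_prior(S) + σ·R(S) − log π_θ(S))²] against a frozen prior, with
  R = 0.4·f(dock) + 0.3·f(QED) + 0.3·f(SA), f a sigmoid with scale k = 10.
* **Evaluation suite.** Validity / uniqueness / novelty, both Lipinski
  conventions (all-5 fraction and mean rules 0–5), QED, normalized SA,
  pairwise-Tanimoto diversity (radius-2 circular fingerprints, 2048 bits),
  the success-rate thresholds (Vina < −8.18, QED > 0.25, SA > 0.59, strict),
  and constraint compliance: count-vector MSE, exact-match rate (EMR) and
  fuzzy-match rate (FMR, every group within ±3).

Everything runs at desk scale with zero downloads: the synthetic-fixture
module generates seeded scaffold×substituent corpora, pocket-embedding
stand-ins, and a deterministic surrogate docking scorer.

## Worked example

```r
library(nummolgen)

vocab  <- build_vocabulary("default")          # 27 functional-group types
ann    <- annotate_molecule("CC(=O)Oc1ccccc1C(=O)O", vocab)   # aspirin
print(ann)
#> <molecule_annotation> CC(=O)Oc1ccccc1C(=O)O
#>   hydroxyl         n=1
#>   carboxylic_acid  n=1
#>   ester            n=1
#>   ether            n=1
#>   aromatic_ring6   n=1

count_vector(ann)[c("hydroxyl", "ester", "aromatic_ring6")]
#>       hydroxyl          ester aromatic_ring6
#>              1              1              1

# train a small generator on a synthetic corpus and sample under constraints
corpus <- generate_corpus(corpus_spec(n_molecules = 32, seed = 11))
anns   <- annotate_molecules(corpus, vocab)
tok    <- build_token_vocabulary(anns, vocab)
seqs   <- lapply(anns, encode_dual, tok_vocab = tok)
model  <- nmf_pretrain(seqs, tok, vocab,
                       config = nmf_config(vocab_size = length(tok$tokens),
                                           d_model = 64, n_layers = 2,
                                           n_heads = 4, max_len = 160),
                       epochs = 200, lr = 8e-3, seed = 0)
print(model)
#> <nummolgen_model> stage=pretrained  d=64 layers=2 heads=4 K=16  V=63  104,097 parameters
#>   final training loss: total=0.0540 (ce=0.0069, mse=0.0471)

gen <- nmf_generate(model, anns, mode = "greedy", seed = 0)
mean(gen$smiles == vapply(anns, `[[`, character(1), "canonical_smiles"))
#> [1] 1        # all 32 held-in molecules reconstructed exactly

quality_report(gen$smiles, reference = corpus)
#> <quality_report> n=32
#>   validity   1.000   uniqueness 1.000   novelty 0.000
#>   Lipinski   all5=1.000 mean-rules=5.00
#>   QED 0.681   SA(norm) 0.873   diversity 0.826
```

The printed numbers mean: every sampled string is a valid molecule, all 32
are distinct, none is novel (expected — the prompts are the training
molecules' own headers), all pass Lipinski, and the set keeps substantial
pairwise-Tanimoto diversity.

The CLI mirrors the library:

```sh
Rscript inst/cli/nummolgen.R annotate --in mols.smi --vocab default --out ann.jsonl
Rscript inst/cli/nummolgen.R pretrain --config pretrain.yaml
Rscript inst/cli/nummolgen.R evaluate --generated gen.smi --targets targets.csv --out report.json
```

## Exit codes

The CLI exits 0 on success and 1 on any classed error (parse, config,
contract violations); errors are printed as `error [class]: message`.
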