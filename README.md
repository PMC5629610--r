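# bionorm

Biomedical entity normalization: map disease/disorder mentions in text to
concepts of a reference terminology (or to NIL when no concept applies).
`bionorm` is aimed at text-mining practitioners who have a TSV lexicon, a
PubTator-style annotated corpus, and optionally a pre-trained word-embedding
file, and want a self-contained, reproducible normalizer.

The method is a two-stage pipeline:

1. **Sieve candidate generation** in three priority tiers — CI: exact match
   of the normalized mention against training mentions and KB names; CII:
   exact match after a morphological rewrite (abbreviation expansion,
   word reorder, digit/roman/word numerals, hyphenation, suffix
   alternation, word-level synonyms, Porter stemming, coordination
   splitting); CIII: word-overlap partial match, with an optional NIL
   pseudo-candidate. The first non-empty tier is the candidate set E.
2. **CNN pairwise ranking.** Mention and candidate are encoded by
   convolution over word embeddings (widths 2/3, 1-max pooling) into
   v_m, v_y ∈ R^p; the joint vector [v_m, v_y, v_sem, v_mor] — with
   bilinear similarity v_sem = v_mᵀMv_y/√p and two word-overlap features
   v_mor — feeds a ReLU hidden layer and a two-class softmax:
   score(m,y) = e^{o_hᵀq₁} / (e^{o_hᵀq₀} + e^{o_hᵀq₁}). The top-scoring
   candidate is the prediction. Training is class-balanced two-class
   cross-entropy over (mention, candidate, 0/1) pairs by seeded SGD —
   forward and backward passes are hand-derived base-R matrix algebra
   (no tensor library required).

Singleton candidate sets at CI/CII (and CIII with NIL off) are
rule-determined and returned directly with score 1.0. Accuracy is always
bounded by *candidate recall* (the fraction of mentions whose gold concept
made it into E), which the evaluator reports as the ranking ceiling.

## Worked example

Everything below is generated on the fly — no external data.

```r
library(bionorm)

kb <- new_kb(c("C1", "C2", "C3"),
             c("Hypotension", "Hypotensin", "Coronary artery disease"))
cs <- generate_candidates("Hypotensive", kb, config = norm_config(nil_enabled = FALSE))
cs
#> <candidate set> mention "Hypotensive" tier CII (2 candidates)
cs$candidates$matched_name
#> [1] "Hypotension" "Hypotensin"
```

An end-to-end run on a synthetic corpus (200 concepts in families sharing a
type word, 1,000 mentions, half the concepts carrying a zero-word-overlap
"semantic" synonym tied to a planted embedding vector):

```r
spec <- fixture_spec(n_concepts = 200, n_mentions = 1000,
                     semantic_pair_fraction = 0.5, t = 16, seed = 1)
fx  <- make_fixture(spec)
m   <- fx$corpus$mentions
tr  <- m[1:700, ]; te <- m[701:1000, ]
lex <- build_training_lexicon(tr)
st  <- compute_word_stats(fx$kb_fix$kb, lex)
pairs  <- build_pairs(tr, fx$kb_fix$kb, lex, norm_config(), fx$corpus$docs)
params <- train(pairs, train_config(t = 16, p_per_width = 8, hidden = 16,
                                    lr = 0.01, epochs = 20, seed = 1),
                st, fx$embeddings)
res <- normalize_corpus(te, fx$kb_fix$kb, lex, params, norm_config(), st)
evaluate(res, te)
#> <evaluation> n=300 accuracy=0.9067 candidate_recall=0.9833 ambiguity=0.0200
#>   tier   n  accuracy    recall
#> 1   CI  98 0.9489796 0.9489796
#> 2  CII  32 1.0000000 1.0000000
#> 3 CIII 170 0.8647059 1.0000000
```

Accuracy is read per tier: CI errors are ambiguous surfaces (several gold
ids for one form), CIII mentions are ranked among ~9 same-family candidates
distinguishable only through the embedding signal. A morphology-only
baseline (`baseline_rank()`) reaches 0.583 on the same split: the ~32-point
gap is the planted semantic signal that only the embedding-based ranker can
exploit. Candidate recall < 1 because a few surfaces fall outside every
rule's reach — the ranking ceiling the evaluator always reports.

## Command line

```sh
Rscript inst/cli/bionorm fixtures make --spec spec.cfg --out-dir work/
Rscript inst/cli/bionorm train --kb work/kb.tsv --corpus work/corpus.pubtator \
        --config train.cfg --embeddings work/embeddings.txt --out work/model.json
Rscript inst/cli/bionorm normalize --kb work/kb.tsv --corpus work/corpus.pubtator \
        --ckpt work/model.json --train-corpus work/corpus.pubtator --out work/pred.tsv
Rscript inst/cli/bionorm evaluate --pred work/pred.tsv --gold work/corpus.pubtator
```

Config files are flat `key = value` text; prediction TSV columns are
`doc_id start end mention predicted_id score tier` with NIL written as
`CUI-less`.

## Layout

* `R/lexicon_kb.R` — KB/corpus I/O, abbreviation detection, word statistics
* `R/candidate_gen.R` — the three-tier sieve cascade and its rule resources
* `R/ranker_net.R` — the six-layer ranking network (forward + backward)
* `R/pipeline.R` — pair building, SGD training, CV, evaluation
* `R/synthetic.R` — deterministic synthetic KB/corpus/embedding generator
* `vignettes/bionorm-methods.Rmd` — model details, assumptions, limitations
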