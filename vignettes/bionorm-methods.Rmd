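---
title: "Normalizing biomedical entity mentions with sieve candidate generation and CNN ranking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Normalizing biomedical entity mentions with sieve candidate generation and CNN ranking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bionorm)
```

## The problem

Entity normalization maps a textual mention ("tremulousness", "ADA-SCID") to
a concept identifier in a reference terminology (SNOMED CT, MeSH/OMIM). For
diseases and disorders the dominant difficulty is *variation* — many surface
forms per concept — with a long tail of *ambiguity* (one surface, several
concepts) and *absence* (no concept at all; the "CUI-less"/NIL case).
Rule-based sieve systems handle variation well but rank candidates by fixed
rule priority, which fails when two candidates are morphologically close but
semantically distinct. `bionorm` implements a two-stage architecture: rules
propose, a small convolutional network disposes.

## Candidate generation

Sieve rules are grouped into three priority tiers:

* **CI (exact match):** the normalized mention equals a training-set mention
  or a KB name. Normalization is a single shared tokenizer: lowercase, split
  hyphens and slashes, strip other punctuation. One consequence is that
  hyphen/space variation ("5-hydroxytriptamine") is already neutralized at
  CI; the explicit hyphen rewriting rule is retained but is subsumed by the
  tokenizer.
* **CII (exact match after morphological rewriting):** abbreviation
  expansion (Schwartz–Hearst initial-character matching, with a
  first-segment fallback for hyphenated acronyms like "ADA-SCID"),
  subject/object reorder, numeral style replacement (digit/roman/word),
  suffix alternation from an editable table, word-level synonyms from an
  editable table, Porter stemming, and splitting of a single coordination
  ("optic and peripheral neuropathy"). All rules within the tier are equal
  priority; their matches are unioned and deduplicated.
* **CIII (partial match):** every lexicon name sharing at least one content
  word with the mention, ordered by shared-word count then name, truncated
  at a configurable cap (default 100). When NIL handling is enabled a NIL
  pseudo-candidate joins every CIII set.

The first non-empty tier is the candidate set *E* passed to the ranker.
Singleton sets from CI/CII (and CIII singletons when NIL is off) are
rule-determined: they are returned directly with score 1.0 and are excluded
from ranking and from training.

**Stem matching.** Strict Porter stem equality cannot retrieve truncated
derivational variants (no Porter rule strips the "-in" of "hypotensin", so
"hypotensive" → stem "hypotens" never equals "hypotensin"). Stem keys
therefore also match when one is a prefix of the other with at most two
trailing characters of slack (shorter key ≥ 5 characters). This is the
narrowest extension that reaches such forms without flooding the tier.

## The ranking network

For a mention *m* (l words) and candidate *y* (k words), each word is a
t-dimensional embedding (default t = 50). Convolution filters of widths 2
and 3 (50 each by default, p total) slide over the token matrix; each filter
map passes through ReLU and 1-max pooling, giving encodings v_m and v_y of
length p. Texts shorter than a filter width are zero-padded on the right.
The joint layer concatenates

> v_joint = [ v_m, v_y, v_sem, v_mor ],

where v_sem = v_mᵀ M v_y / √p is a learned bilinear similarity and v_mor
holds two morphological features in [0,1]: the Jaccard ratio of the word
sets, and an inverse-mention-frequency-weighted cosine over word indicators
(imf(w) = log(N/(1+df(w))) over the pooled lexicon names, floored at a small
positive value inside the cosine so the feature stays bounded). A ReLU
hidden layer (default width 100) and a two-class softmax produce

> score(m, y) = exp(o_hᵀq₁) / (exp(o_hᵀq₀) + exp(o_hᵀq₁)) ∈ (0, 1).

The top-scoring candidate (possibly NIL, which is embedded through a
reserved learned token) is the prediction; ties break by edit distance of
the matched name to the mention, then concept id, so ranking is invariant
to candidate input order.

### Numerical choices

* **v_sem scaling.** Standardizing the bilinear term by p makes it an
  average of p² products and it vanishes against the O(1) morphological
  features — in planted-signal experiments the trained network simply never
  used it. Scaling by √p keeps it at the order of the other joint-layer
  entries; this is the package's one deliberate deviation from an otherwise
  natural "divide by p" choice.
* **M initialization.** M starts at the identity, so v_sem begins as the
  inner product ⟨v_m, v_y⟩ — already informative under pre-trained
  embeddings — and training refines it. A random M start wastes the early
  epochs rediscovering the diagonal.
* **Filter/hidden init.** Glorot-style fan scaling; embeddings start
  uniform in [−0.25, 0.25] (the symmetric reading of the degenerate printed
  range) unless a pre-trained table overrides them.
* **Padding.** Zero columns on the right up to the widest filter, so every
  input has at least one full window.

## Training

Each annotated training mention contributes one labeled pair per candidate
in its set: label 1 iff the candidate id is a gold id of that surface form
(a surface with several gold ids yields several positives; no
disambiguation is attempted). Three practical rules matter:

* **Leave-one-surface-out.** When building a training mention's candidate
  set, the mention's own surface is removed from the training lexicon —
  otherwise every training mention exact-matches itself and all sets
  collapse to untrainable CI singletons.
* **Class balancing.** Candidate sets yield roughly an 8:1
  negative:positive ratio; positives are up-weighted by n_neg/n_pos in the
  two-class cross-entropy so the optimizer does not settle at the negative
  prior.
* **Vocabulary retention.** The parameter table keeps the full vocabulary
  of a supplied pre-trained embedding file, not only words seen in training
  pairs; inference-time words must find their pre-trained vectors (the
  original setting pre-trains on a 219-million-word corpus precisely so the
  test vocabulary is covered).

Optimization is plain per-pair SGD, bit-reproducible given the seed; the
training loss, initialization and epoch shuffling all derive from it.
Cross-validated model selection (`cross_validate()`) splits mentions into
seeded folds, rebuilds the training lexicon per fold (so test surfaces are
unseen), and picks the grid point with the best mean fold accuracy.

## Synthetic fixtures: the stated world

`fixture_spec()`/`make_fixture()` generate a self-contained KB, corpus and
embedding table emulating the two hard phenomena: morphologically similar
but semantically different names (family members sharing a type word), and
morphologically different but semantically equivalent names (zero-overlap
alias synonyms tied to latent concept vectors). Concepts come in families
(default 8) sharing a type word; each concept has a unique distinctive word
tied to a latent vector. Corpus mentions are: verbatim names, inverse
morphological variants (hyphenation, reorder, numeral style, suffix
alternation), "semantic" mentions (a fresh word embedded near the gold
concept's latent vector plus the family word — resolvable only through the
embedding signal, since every family candidate ties on word overlap),
ambiguous surfaces (two gold ids), and NIL mentions (fresh words matching
nothing). Defaults: 200 concepts, 1,000 mentions, semantic-pair fraction
0.5, ambiguity 4%, NIL 10%, embedding noise 0.1 — chosen once as a
realistic desk-scale regime and not revisited.

What a green test establishes: that the cascade recovers planted variants
at the intended tiers, that NIL flows through generation, ranking, training
and evaluation, and that the trained ranker extracts a semantic signal that
morphology cannot. What it does not establish: performance on real corpora
(real lexical statistics, real abbreviation conventions, licensed
terminologies) — the paper-scale accuracies are explicitly out of scope.

## Evaluation

`evaluate()` reports accuracy (NIL is an ordinary label), candidate recall
(the fraction of mentions whose gold id entered the ranked set — the
ceiling any ranker can reach, the "upper boundary"), the ambiguity rate
(fraction of evaluated mentions whose surface carries >1 gold id in the
reference annotations), a per-tier breakdown and an error list. Accuracy ≤
candidate recall by construction, and the test suite asserts it on every
run.

## Known limitations

* Pure-R training: fine at desk scale (thousands of pairs, minutes), not at
  corpus scale; there is no GPU path.
* The rule resources (suffix pairs, word synonyms, stopwords) are small
  seed tables, not a reconstruction of any published system's dictionaries.
* Abbreviation detection is per-document; no cross-document propagation.
* Composite splitting handles a single coordination only.
* Mentions with several gold ids are trained with all positives and no
  disambiguation, mirroring the stated scope.
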