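---
title: "Detecting adverse drug reaction signals in health forum posts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting adverse drug reaction signals in health forum posts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adrsignal)
library(dplyr)
```

## The problem

Spontaneous reporting systems miss the large majority of adverse drug
reactions (ADRs), and clinical trials are underpowered for rare ones.
Health-forum posts are an early, high-volume complement: patients describe
reactions in their own words, often months before the first case report
appears in the literature. Turning that text into statistical signals takes
a chain of steps — retrieving the posts that mention a drug, extracting
reaction mentions from colloquial prose, normalizing them onto medical
concepts, counting unique reporters, and deciding which drug–reaction pairs
stand out against a null background. `adrsignal` implements that chain as a
set of data-frame-first functions plus a synthetic corpus generator that
makes the whole pipeline testable without any proprietary data.

This vignette documents the model at each stage, the tunable parameters and
their defaults, the numerical conventions, and what the synthetic
benchmarks do and do not demonstrate.

## Corpus retrieval

A drug corpus is the set of posts whose body contains at least one alias of
the drug (generic or brand name). Matching is deliberately simple —
exact-string, case-insensitive, at alphanumeric word boundaries — because
the retrieval step should be auditable: `"erlotinib"` matches anywhere a
token boundary surrounds it and never inside `"erlotinibx"`. Fuzzy or
spelling-variant matching is out of scope. When two drugs with the same
mechanism are studied as one class (e.g. two checkpoint inhibitors), their
corpora are merged with deduplication by `post_id`, so a post mentioning
both counts once downstream.

Posts carry a day-precision date validated against a configurable window
(default 2000-01-01 to today; forum archives of interest start around
2005). A post mentioning several study drugs is a member of every matching
corpus: attribution is unresolvable at post level, so the package includes
it conservatively everywhere and the unique-user counting absorbs the
double exposure.

## Mention extraction

Reaction mentions are extracted by a per-token classifier over a BIO tag
scheme with two entity types, ADR and indication (`O`, `B-ADR`, `I-ADR`,
`B-IND`, `I-IND`). Distinguishing the two matters: the same word
("psoriasis") is an indication in one sentence and a reaction in another.

The input representation is a word embedding table trained on the unlabeled
corpus by skip-gram with negative sampling (default dimension 150, window
5, minimum frequency 2, 5 negatives, 5 epochs of SGD with linear
learning-rate decay from 0.05). Tokens below the frequency cutoff share an
out-of-vocabulary vector (the mean input vector). The tagger concatenates
the embeddings of a ±2-token window (zero vectors beyond sentence
boundaries), applies one tanh hidden layer (default 300 units) and a
softmax over the five tags, and is trained by mini-batch SGD (batch 64,
learning rate 0.1) on cross-entropy for a fixed epoch count (default 30).
All training is deterministic for a fixed seed: two runs serialize to
byte-identical model files.

Numerical conventions, all deterministic:

* Sentence splitting is rule-based (terminal punctuation and newlines);
  tokens are maximal alphanumeric-plus-apostrophe runs with half-open
  character offsets into the raw body.
* Gold spans that cut into a token are snapped *outward* to the covering
  tokens with a warning — snapping never truncates annotated text.
* At decoding time an `I-x` tag with no open entity is reinterpreted as
  `B-x`; spans are maximal B/I runs, and a span's score is the mean
  probability of its tokens' assigned tags.
* Evaluation is micro-averaged precision/recall/F with either strict
  matching (offsets and label all equal) or one-to-one greedy overlap
  matching; strict is the default and the stricter of the two.
  Inter-annotator agreement is the same micro-F with one annotator taken as
  gold.

## Concept normalization

The target lexicon is built from seed concepts, one per reaction group.
Eight cutaneous groups are configured by default — rash, acne, pruritus,
nail changes, xerosis, hypohidrosis, bullous eruption, psoriasis. Each seed
contributes its preferred name and synonyms; the "nail changes" seed is
additionally expanded one hierarchy level down (is-a children such as
ingrown toenail or peeling of nails), the one group whose clinical
vocabulary is spread over many sibling concepts. Physician-curated
colloquial phrases ("stopped sweating completely") are attached per group,
because patients rarely use concept names.

Entries are indexed by the lemma bag of their name and queried with the
identical tokenize–lemmatize preprocessing — the congruence is load-bearing
and is enforced by using literally the same function. The lemmatizer is a
small dictionary-backed one (irregular forms such as *been → be*, plus
conservative suffix rules that deliberately leave medical *-is/-us* terms
like *psoriasis* intact), so the colloquial mention *"finger nails have
been peeling"* becomes the query *finger nail have be peel* and resolves to
*Peeling of nails* (C0263531). Scoring is TF-IDF cosine; stop-words are
retained in the bag and simply down-weighted by their low inverse document
frequency. Ties break by larger lemma overlap, then lexicographic concept
id, so results are reproducible. A mention that shares no lemma with any
entry returns no match rather than a forced best guess, and only spans
tagged ADR (not indications) are normalized by default.

## Signal statistics and calibration

The association statistic is the proportional reporting ratio over
unique-user counts:

$$\mathrm{PRR}(D,R) = \frac{n_{DR}/n_D}{n_{\bar{D}R}/n_{\bar{D}}}$$

with $n_{DR}$ the unique users reporting both $D$ and $R$ in a post, $n_D$
the unique users reporting *any* reaction with $D$, $n_{\bar{D}R}$ the
unique users reporting $R$ with a comparison drug, and $n_{\bar{D}}$ the
unique users reporting at least one reaction with any drug other than $D$.
Users are deduplicated per (drug, group) for the numerator counts and per
drug for the denominators. Degenerate tables follow fixed conventions: a
zero comparator with cases yields `Inf` (reported, never silently flagged),
no cases yields 0, and a zero denominator is an error rather than a number.
An optional Haldane-style +0.5 continuity correction exists but is off by
default; the uncorrected ratio is the reference behaviour.

The flagging threshold is calibrated empirically. All comparison-drug ×
target-group pairs form the candidate control set (27 × 8 = 216 in the
default configuration); pairs with a known association (adverse effect or
indication) are removed, then pairs excluded by manual review for
co-prescription or syndromic confounding. The threshold is the 95th
percentile of the finite control PRRs, using type-7 linear interpolation
between order statistics — pinned because reproducibility requires one
definition; interpolation can leave at most one value more than the nominal
5% above the threshold, which the acceptance tolerance absorbs. A pair is
flagged when its PRR strictly exceeds both the calibrated threshold and the
conventional fixed rule PRR > 1.

## Time to detection

Lead time is the whole-month difference between the first forum report of a
pair and its earliest literature publication date, positive when the forum
leads; days are ignored because literature dates are month-resolved.
Cumulative post-count curves have one point per distinct posting date and
end at the total record count. By default the curves are fed by the
pipeline's extracted records; a manually reviewed record set can replace
them, since first-report claims ultimately rest on human reading of the
posts.

## The synthetic corpus generator

`gen_config()` specifies a forum: per user a Poisson post count (mean 3);
per post each drug is mentioned independently with probability
`mention_prob` (default 0.03 — a given drug appears in a few percent of
community posts); conditional on a mentioned drug each reaction group is
emitted with the pair's emission probability (background 0.01; planted
pairs override it). Reaction phrases are canonical concept names or, with
probability 0.3, colloquial variants; drug mentions occasionally use the
brand alias; indication sentences and neutral filler complete the post.
Gold spans are emitted at the exact inserted offsets and the gold pair
table lists every (mentioned drug, emitted group) per post. Everything is
byte-identical under a fixed seed.

Because one user's posts are independent given the Poisson count, the
expected unique-user counts have closed forms via per-user inclusion
probabilities $1 - e^{-\lambda q}$, where $q$ is the per-post event
probability (itself a product over independent mention and emission
events). `expected_prr()` combines the four expectations through the PRR
formula — a plug-in approximation to the estimator's expectation that is
exact in the large-user limit, and is validated against a direct
Monte-Carlo simulation of the generative process in the test suite.

Two properties of this expectation are worth knowing. First, under an
exchangeable null it equals 1 exactly only for a two-drug symmetric
configuration; with many drugs the nonlinear unique-user deduplication
biases it slightly below 1 (≈0.83 at the default rates with 20 drugs) —
a known small-count property of ratio statistics, and one reason the
threshold is calibrated empirically rather than fixed at a theoretical
null value. Second, raising a planted emission rate raises the expected
PRR strictly throughout the operating range (up to ≈0.2) but saturates and
can dip at extreme rates, because the planted pair also inflates the
drug's any-reaction denominator $n_D$.

The benchmark configurations are fixed once:

* `demo_gen_config()` — 5000 users, one target drug against nine
  comparison drugs, a single planted pair (erlotinib → hypohidrosis,
  emission 0.2) with closed-form expected PRR ≈ 3.97. The gold-bypass
  pipeline recovers it within ~10% mean relative error over ten seeds, and
  the flagged signal table contains exactly the planted pair.
* `null_gen_config()` — 20 drugs × 8 groups, all emissions equal (0.02),
  used to verify that at most ~5% of control pairs exceed the calibrated
  threshold.
* The tagger benchmark trains on 500 templated posts and evaluates
  strict-match micro-F on a held-out same-template split (it reaches 1.0;
  the acceptance bar is 0.90).

**What these benchmarks do not show.** The generator's language is
templated: a fixed sentence inventory, a small neutral filler vocabulary,
phrases inserted verbatim. Template sentences are linearly separable, so a
perfect synthetic F-score says the architecture, BIO decoding and
evaluation plumbing are correct — not that the tagger would reach such
performance on real colloquial forum text, where published F-measures for
this class of model are far lower. Likewise the generative
model has no reply threads, no topic drift, no misspellings, and emission
independence across groups; real negative-control distributions are wider
(co-prescription and syndromic confounding are exactly why the manual
exclusion step exists). The synthetic results validate correctness and
statistical behaviour of the machinery, not clinical performance.

Problem sizes in the shipped tests — 5000 users and ten seeds for the
statistical checks, 500 training posts for the tagger, a 35-entry lexicon —
were chosen as the smallest sizes at which the binomial noise bands in the
acceptance criteria are comfortably resolved.

## Degenerate inputs and edge behaviour

* Empty drug corpora are valid (a drug nobody discusses); empty post bodies
  tokenize to nothing and tag to no spans.
* A tagger trained on entity-free data predicts all-O everywhere.
* Calibration refuses fewer than 10 finite control PRRs and excludes
  infinite ones with a warning; all-infinite input is an error.
* Pipeline configuration is validated before any stage runs (target and
  comparison sets must be disjoint, referenced paths must exist); a stage
  failure aborts with the stage name, retaining the tables already written.

## Known limitations

* The lemmatizer is intentionally small; out-of-dictionary irregular forms
  fall through to suffix rules.
* Ranked retrieval is bag-of-lemmas TF-IDF; no phrase or proximity scoring,
  no spelling correction, no multi-concept mention resolution.
* PRR is the only disproportionality statistic implemented, without
  confidence intervals — the calibrated-threshold design replaces interval
  reasoning with an empirical null.
* The closed-form `expected_prr()` is a plug-in approximation; at very
  small user counts the estimator's finite-sample bias is visible (the
  tests quantify it).
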