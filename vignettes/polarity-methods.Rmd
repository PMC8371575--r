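---
title: "Methods: polarity estimation and echo-chamber analytics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: polarity estimation and echo-chamber analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, conventions and numerical choices
behind `polarnet`, in the spirit of a methods section: what is computed,
under which assumptions, and where the design was genuinely open.

## Interaction graphs and preprocessing

The retweet network is a weighted directed graph: an edge $(u, v)$ with
weight $w(u, v)$ records that $u$ retweeted $v$ that many times. The
mention network is built the same way from every mentioned id in any tweet
(retweets, quotes, replies or direct mentions), one count per tweet.
Self-loops are dropped at construction; a self-retweet carries no
endorsement signal.

Preprocessing follows the fixed default order **location filter →
empty-profile filter → graph construction → edge-weight filter → degree
filter → bot removal**. The stages are individually exported, so other
orders are possible, but the pipeline logs and uses this one. Choices that
the standard description of this kind of analysis leaves open, and how we
resolved them:

* **Edge-weight filter** (`w >= 2` by default) keeps nodes even when they
  become isolated; dropping nodes is the degree filter's job.
* **Degree filter**: a user survives when *either* in-degree or out-degree
  (unique-neighbour counts, measured once on the input graph) reaches the
  threshold (10 by default). The either-direction reading keeps pure
  broadcasters (high out-degree) and pure sources (high in-degree), both
  of which the downstream role analysis needs. The filter is single-pass:
  it is not iterated to a k-core, so a node can be left isolated by the
  removal of its neighbours.
* **Bot removal** drops the top `ceil(fraction × n_scored)` users by bot
  score; users without a score are exempt and counted in a message. Ties
  at the cut are broken by user id (lexicographically smaller ids removed
  first) so the filter is deterministic.
* **US-location predicate**: the packaged default is a case-insensitive
  match against state names (word-boundary substrings), state
  abbreviations (standalone tokens) and common country spellings. It is a
  deliberately simple, pluggable predicate — not a geocoder.

## Weak supervision

Seed labels come from two sources, combined with hashtag precedence:

1. **Profile hashtags.** `#`-prefixed tokens are extracted from the
   NFC-normalised, lowercased profile description only — never from tweet
   text, where hashtags can be used adversarially to inject opposing
   content. A strict majority of left- vs right-lexicon hashtags labels
   the user; any tie (including 0–0) yields no label.
2. **Media endorsements.** An endorsement is a retweet of an outlet
   account (quote tweets count by default, configurable) or a link whose
   registered domain belongs to an outlet. With at least two endorsements,
   the mean outlet bias $m$ on the 1–5 scale labels the user left when
   $m \le 2$ and right when $m > 4$.

The packaged lexicon ships only well-known example hashtags; a full
curated lexicon is a required input for real analyses. Registered domains
are taken as the last two dot-labels of the host — multi-label public
suffixes (`co.uk`) are not special-cased, a documented simplification.

## The polarity model

The model assumes **retweet homophily**: users who retweet each other are
more likely to share ideology, so their profile embeddings should be
close. Each (deduplicated, undirected) edge of the filtered retweet graph
is a positive pair $(i, j)$; for a non-neighbour $k$ the triplet loss

$$\max\left(\lVert s_i - s_j\rVert - \lVert s_i - s_k\rVert + \epsilon,\ 0\right)$$

is minimised over the shared encoder parameters (a Siamese arrangement),
with Euclidean distance and margin $\epsilon = 1$, the standard
sentence-embedding configuration. Directionality is disregarded, and edge
weights only serve the $w \ge 2$ filter; weight-proportional pair
sampling exists as a flag, off by default.

Two negative-sampling strategies are implemented. *one-neg* draws one
uniform non-neighbour per anchor. *mult-neg* (the default) uses, for the
pair at batch index $k$, all other in-batch positives $s_{j_{k'}}$,
$k' \ne k$, as negatives; its batch loss is tested for exact equality
against an explicit double-loop oracle.

Training details are not pinned down by the published description of this
model family, so the package fixes and logs its own: plain minibatch
gradient descent, batch size 32, 8 epochs, learning rate 0.05, all in
`polarity_control()`. When an embedding coincides with its positive or
negative the unit direction is taken as the zero vector (a valid
subgradient). With a fixed `rng_seed` training is bit-reproducible.

The packaged **hash encoder** tokenises profiles (lowercased,
`#`-preserving word tokens), hashes tokens into 512 buckets with a stable
polynomial hash, L2-normalises the count vector and applies a trainable
linear map to 16 dimensions. It captures exactly the distributional
signal the synthetic corpora carry. The `sentence_encoder()` adapter
wraps any external embedding function (e.g. a transformer encoder served
out of process) behind the same contract; such encoders are frozen —
the package does not backpropagate through external models. Graph-only
baselines (node2vec, GraphSAGE) are interface stubs; mean word-embedding
and label-propagation baselines are implemented.

A **ridge logistic head** (fixed penalty $\lambda = 10^{-3}$, via glmnet)
maps embeddings through a sigmoid to scores in $[0, 1]$, fitted on seeds
with left → 0, right → 1. Model quality is measured by stratified 5-fold
cross-validated AUC on the seeds, the appropriate metric given the
left-skewed seed balance. Scores for **all** users (seeds included) are
rank-binned into deciles whose sizes differ by at most one, ties broken
by user id; seeds are included in the binning since every downstream
statistic is defined over all users.

## Random-walk controversy

Echo chambers are quantified by the decile-generalised controversy matrix

$$\mathrm{RWC}(A, B) = \Pr(\text{start in } A \mid \text{end in } B),$$

estimated from an equal budget of walks per starting decile (10,000 by
default, start nodes uniform within the decile) and column-normalised so
that conditioning on the end decile controls for where high-degree
vertices sit. Walk conventions, each of which the loose verbal definition
leaves open, are fixed as:

* steps are uniform over out-neighbours, ignoring edge weights (weighted
  stepping is a flag, off by default);
* `max_len` (default 10) counts edges traversed;
* a walk ends **at** a revisited node, **on arrival at** an authoritative
  node (so a walk may *start* at an authoritative node and still move),
  at a node with no out-neighbours, or wherever it stands after
  `max_len` steps;
* authoritative nodes are each decile's top-`k` by in-degree (ties at
  rank `k` broken by user id). At reference scale `k = 1000` per decile
  (about 4%); on desk-scale fixtures the pipeline uses the fractional
  form `k = 0.04` so that the authoritative set keeps the same relative
  size.

`exact_rwc_small()` enumerates every self-avoiding trajectory under
identical rules (guarded to at most 12 nodes) and provides the exact
distribution; the Monte-Carlo estimator is tested to agree within three
binomial standard errors per cell, and columns must sum to 1 within
$10^{-9}$. Columns in which no walk terminated are reported as undefined
rather than renormalised.

## Partisan analytics

* **Groups:** left / neutral / right are the bottom, middle and top 20% of
  polarity scores, implemented on the rank deciles as {1,2}, {5,6},
  {9,10} — rank-based so the 20% stays exact under score ties.
* **Influence:** five measures (verified flag, followers, retweet
  in-degree, mention in-degree, PageRank on the retweet network); for
  numeric measures exactly `ceil(0.05 n)` users are flagged, ties at the
  cut broken by user id. In-degrees are unique-neighbour counts by
  default ("most retweeted *by others*"), with weighted degrees behind a
  flag.
* **PageRank** is computed by power iteration with damping 0.85,
  transition probabilities proportional to edge weights and dangling mass
  redistributed uniformly; it is tested against a dense linear-solve
  oracle at $10^{-8}$ and cross-checked against igraph.
* **Audience distributions** pool all unique (retweeter, retweeted) pairs
  per decile of the retweeted user (split by verified status) and report
  the share of the pooled audience in each polarity group. Pooling is the
  default because a per-user average over-weights rarely retweeted users;
  the per-user mean is available via a flag.
* **Role summaries** report per (group × verified) cell the mean, median
  and quartiles of original-tweet fraction, bot score, retweet in/out
  degree and followers, plus a one-way ANOVA F-test per statistic across
  the three groups (pooled over verification status; statistics with zero
  variance return NA rather than a spurious test).

## The synthetic generator

`generate_corpus()` emulates the *structure* that the analyses rely on:
a directed block-model retweet graph with two or three communities (the
right block smaller and denser, mirroring the empirically reported
asymmetry), per-pair retweet counts drawn as $1 + \mathrm{Geom}(p_{stop})$
so both weight-1 (filtered) and weight-2+ (kept) edges occur,
bag-of-tokens profiles from community distributions with a shared-token
overlap, unambiguous partisan hashtags planted on a fraction of partisan
users (these become seeds with 100% precision by construction), media
endorsements with known bias, per-community verified rates, log-normal
follower counts and Beta bot scores (right-shifted). Mention events add
the retweeted author per retweet plus extra direct mentions with milder
community mixing.

It does **not** emulate natural language (profiles have no grammar, only
distributional token signal), temporal dynamics, bot behaviour, or
hashtag ambiguity. Passing tests on these corpora therefore demonstrate
the *mechanics* of the pipeline — filters, objectives, estimators,
analytics — and parameter recovery under planted structure; they say
nothing about real-corpus accuracy, which depends on transformer-quality
profile encoders and curated lexicons/catalogs.

Fixture scales were chosen to exercise every code path at desk scale:
`tiny` (12 users; exact-oracle territory; weight/degree thresholds
relaxed to `w_min = 1`, `d_min = 0` because a 12-node graph cannot
survive reference-scale filters), `separable` (600 users, 2 communities,
within-rates 0.10/0.18, cross-rate 0.002, 30% seed planting) and
`echo_asym` (600 users, 3 communities; right within-rate 0.30 vs left
0.10; cross edges concentrated left↔neutral). On `separable` the full
pipeline recovers planted polarity with cross-validated AUC ≥ 0.9 and
Spearman ρ ≥ 0.8 against ground-truth community centres; on `echo_asym`
the far-right audience own-group share exceeds the far-left one and the
right controversy diagonal dominates, the planted analogue of the
reported 80%-vs-40% audience asymmetry.

## Determinism and numerical notes

Every stochastic step (generator, pair shuffling, negative draws, fold
assignment, walk sampling) runs under an explicit seed via
`withr::with_seed`, and the pipeline derives stage seeds from one master
`rng_seed`; identical configs reproduce artifacts byte-for-byte. Label
propagation clamps seeds at 0/1, averages neighbours (edge-weighted) over
the undirected graph and stops when the max absolute change falls below
`1e-6`; nodes with no path to a seed are flagged unpredicted rather than
given the initial 0.5. Decile binning requires $n \ge 10$ and fails
loudly below it.

## Known limitations

* The hash encoder is intentionally simple; it cannot capture semantics
  or word order, so real-data runs should plug in a sentence encoder.
* Registered-domain matching ignores multi-label public suffixes.
* The degree filter's either-direction reading and the pooled audience
  construction are documented choices among defensible alternatives; both
  have flags or clearly separated code paths for the alternatives.
* ANOVA on heavy-tailed degree/follower distributions is reported as-is
  (mirroring standard practice in this analysis family); a rank-based
  test would be more robust.
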