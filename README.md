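# polarnet

Polarity estimation and echo-chamber analytics on retweet networks.

## The problem

During politicised public-health events, who reaches whom on social media is
shaped by political identity: users preferentially retweet (endorse) accounts
that share their leaning, and insulated "echo chambers" form in which
information rarely crosses ideological lines. Quantifying this requires
(1) a per-user estimate of political polarity at corpus scale with only weak
supervision, and (2) graph statistics that measure how insulated the
resulting communities are.

`polarnet` implements both halves as an end-to-end, reproducible pipeline:

1. **Interaction graphs.** A tweet stream (JSON Lines) becomes a weighted
   directed retweet network `G = (V, E)` with `w(u, v)` = number of retweets
   of `v` by `u`, and an analogous mention network. Preprocessing keeps
   edges with `w >= 2`, users with in- or out-degree `>= 10`, US-located
   users with non-empty profiles, and drops the top 10% of users by
   externally supplied bot score.
2. **Weak supervision.** Seed users get left/right pseudo labels from
   partisan hashtags in their profile descriptions (strict majority;
   profile text only) and from media-outlet endorsements (mean AllSides-style
   bias `m` over `>= 2` endorsements: left if `m <= 2`, right if `m > 4`),
   with the hashtag label taking precedence on disagreement.
3. **Polarity model.** A profile encoder is fine-tuned on the retweet graph
   with a Siamese triplet objective: for each retweet pair `(i, j)` and
   non-neighbour `k`,

   `L = max(||s_i - s_j|| - ||s_i - s_k|| + margin, 0)`

   (Euclidean distance, margin 1), with either one uniformly sampled
   negative per anchor or in-batch multiple negatives. A ridge logistic
   head on the seed embeddings then scores every user in `[0, 1]`
   (0 = far-left, 1 = far-right); users are binned into rank deciles.
   The packaged encoder is a fast trainable hash bag-of-tokens linear
   encoder; any sentence-embedding function can be plugged in through the
   same contract. Mean word-embedding and label-propagation baselines are
   included.
4. **Echo-chamber analytics.** A decile-generalised Random Walk Controversy
   matrix `RWC(A, B) = Pr(start in A | end in B)`, estimated with random
   walks (halting on revisits, authoritative high in-degree nodes, dead
   ends or after 10 steps; 10,000 walks per decile) and verifiable against
   an exact trajectory-enumeration oracle on small graphs; plus influence
   reports (verified, followers, retweet/mention in-degree, PageRank; top
   5% cut), audience-polarity distributions, most-retweeted-by-group
   rankings and user-role summaries with one-way ANOVA tests.
5. **Synthetic corpora.** A block-model generator with planted communities,
   community token distributions, unambiguous partisan hashtags, media
   endorsements and heavy-tailed metadata, so every stage is testable with
   known ground truth and no platform data.

## Worked example

```r
library(polarnet)

## simulate a polarized corpus, preprocess, label seeds, fit, score
cfg <- pipeline_config(out_dir = "run", fixture = "separable", rng_seed = 1)
run_pipeline(cfg)

fit <- readRDS("run/model.rds")
print(fit)
#> Retweet-aware polarity model
#>   graph nodes: 509 | seeds: 202 (left 126 / right 76)
#>   encoder: hash_encoder (d = 16) | sampling: mult_neg | epochs: 8
#>   final epoch mean triplet loss: 0.6080

summary(fit)
#> Polarity model summary
#>   users scored: 509 | seeds: 202 (left 126 / right 76)
#>   5-fold cross-validated AUC on seeds: 1.000
#>   score quantiles:
#>    0%   25%   50%   75%  100%
#> 0.000 0.005 0.020 0.987 1.000

head(predict(fit), 3)
#>   user_id       score decile
#> 1   u0001 0.007674549      4
#> 2   u0002 0.016170144      5
#> 3   u0004 0.021072440      6
```

509 of the 600 simulated users survive preprocessing; 202 receive seed
labels from their planted profile hashtags or endorsements (left-skewed,
as in real corpora). The bimodal score quantiles reflect the two planted
communities, and the 5-fold AUC of 1.000 on seeds shows the embedding
separates them cleanly. `run/rwc_retweet.csv` holds the decile-by-decile
controversy matrix and `run/audience.csv`, `run/influence_report.csv`,
`run/roles_cells.csv` the partisan analytics.

A thin command-line wrapper is installed at
`inst/scripts/polarity-pipeline.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts/polarity-pipeline.R", package="polarnet"))')" \
  --out run --fixture echo_asym --seed 1
```

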