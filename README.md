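# crowdcount

Aggregation and validation of crowdsourced wildlife counts from aerial
images.

## The problem

Drone surveys of wildlife colonies — here, endangered Galápagos marine
iguanas (*Amblyrhynchus cristatus*) — produce tens of thousands of image
tiles that someone has to search for animals. Online citizen-science
platforms distribute each tile to 20–30 independent volunteers, who answer
a presence question and drop a point mark on every animal they see. The
raw product is therefore 20–30 conflicting opinions per image, and the
scientific questions are: how should they be combined into one consensus
detection and one consensus count, and how accurate is that consensus
against experts?

`crowdcount` implements that aggregation and validation pipeline for
anyone running a point-annotation crowdsourcing campaign:

* **Consensus detection.** An image is consensus-present when at least
  *t* of its *n* classifications answered "yes". The package evaluates
  every threshold *t* = 1..11 against an expert gold standard and selects
  the smallest *t* attaining maximal agreement (the *minimum threshold*),
  alongside the classical majority vote *t* = ⌊n/2⌋ + 1. A low threshold
  can beat the majority vote because hard images are found only by a few
  highly skilled volunteers.
* **Consensus counts** by four aggregation methods: the median and the
  mode (max tie-break) of the per-volunteer counts, and the number of
  spatial clusters of the pooled point marks under DBSCAN and HDBSCAN
  (both implemented in the package, Euclidean pixel distances; a cluster
  needs `min_cluster_size = 5` marks — five volunteers agreeing on a
  location — to count as an animal).
* **Validation metrics.** Percentage agreement of summed counts, the
  exact decomposition `cs_total = expert_total − undercounted +
  overcounted`, exact-match rates, and summaries stratified by phase,
  image quality or abundance category (`low` 1–5, `medium` 6–10,
  `high` >10).
* **Statistical comparison** of methods: quasi-Poisson GLMs with
  analysis-of-deviance tests, Tukey-adjusted pairwise contrasts via
  emmeans, and a Nagelkerke pseudo-R² ranking of how well each method's
  counts carry the expert presence signal.
* **A volunteer simulator** that reproduces the statistical structure of
  such a campaign (≈90% blank tiles, zero-truncated negative-binomial
  counts with 84% of occupied tiles under five animals, heavy-tailed
  volunteer activity, ~15% anonymous classifications, skill and
  visibility mixtures, quality-dependent detection, Gaussian mark
  jitter), so every stage is testable without any data download.

## Worked example

```r
library(crowdcount)

cfg   <- sim_config(n_images = 600, random_seed = 42)  # simulated campaign
study <- simulate_study(cfg)
analysis <- consensus_analysis(study$classifications, study$gold)
analysis
```

```
Consensus analysis of 600 images (30 classifications/image expected)
  threshold in use: 6 yes votes (search selected 6; target 95% met)
  consensus-present images: 53 (experts: 54)
Detection vs experts over 600 images
  overall agreement:        99.5%
  expert-present agreement: 96.3% (n = 54)
  expert-absent agreement:  99.8% (n = 546)
  false negatives 3.7%, false positives 0.2%

Count aggregation vs experts:
  method scope expert_total cs_total pct_agreement undercounted pct_under
  median   all          162       98          60.5           65      40.1
    mode   all          162       96          59.3           67      41.4
 hdbscan   all          162      138          85.2           25      15.4
  dbscan   all          162      136          84.0           26      16.0
  ...
```

Reading this: the threshold search picked 6 yes votes as the smallest
threshold maximising agreement with the experts on this 600-image draw
(at the full 4,345-image scale it settles at 5); detection agreement is
high and false negatives dominate false positives; summed counts
undercount the truth under every method, least so for HDBSCAN, whose
pooled-mark clusters recover 85% of the expert total here. The same
objects expose each stage separately — `tally_presence()`,
`threshold_search()`, `consensus_presence()`, `count_images()`,
`compare_counts()`, `phase_summary_table()`, `stratified_accuracy()`,
`fit_quasipoisson()`, `pairwise_contrasts()`, `method_fit_ranking()` —
and `read_classifications()` / `read_gold_standard()` ingest real
exports (a flat one-row-per-mark CSV, or the platform dialect with a
JSON annotations column).

A thin command-line front end with `simulate`, `threshold-search`,
`aggregate-counts` and `metrics` subcommands is installed under
`inst/cli/crowdcount`.

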