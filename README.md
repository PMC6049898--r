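# cpiem

Detect cooperatively bound transcription-factor (TF) pairs from ChIP-seq
**peak intensities alone** — no sequence model, no knockout required.

## The problem

When TF B binds DNA cooperatively with TF A, knocking out B makes A's peak
disappear or weaken. Knockout ChIP-seq is the ground truth for cooperative
binding but is rarely available. A robust empirical observation across
bacterial, yeast and mouse datasets is that a **cooperatively bound target
TF binds more weakly** than a non-cooperatively bound one. `cpiem` exploits
this: at every genomic region where a peak of A overlaps a peak of B by at
least one base pair, it models the intensity pair $(x, y)$ of the two peaks
with a nine-parameter two-component mixture

$$p(x,y) \;=\; w\, f_c(x)\, g_c(y) \;+\; (1-w)\, f_n(x)\, g_n(y),$$

with log-normal (default), gamma or Gaussian marginals, fits it by
expectation maximization, and converts the fit into a per-region Bayes
posterior probability of cooperative binding:

$$P(\mathrm{coop}\mid x,y) \;=\;
\frac{w f_c(x) g_c(y)}{w f_c(x) g_c(y) + (1-w) f_n(x) g_n(y)}.$$

Regions with posterior above a threshold $\alpha$ are called cooperative.

The package also provides everything needed to validate and stress the
detector end to end:

* **narrowPeak/BED I/O** with a configurable intensity column and a
  summit-trimming control transform (`read_narrowpeak`, `trim_to_summit`);
* **overlap pairing** of target and partner peaks (`find_overlapping_pairs`);
* **knockout-based labels** — peak loss and rank-change evidence —
  (`label_from_knockout`, `rank_peaks`);
* **baseline detectors**: summit-distance thresholding
  (`peak_distance_detect`) and the cooperative index $\Delta = (I'-I)/I$
  over external occupancy-model predictions (`cooperative_index`);
* **indirect-binding filter**: PWM best-hit scanning against a
  negative-control percentile threshold (`best_hit_score`,
  `sample_unbound_windows`, `indirect_binding_filter`);
* **evaluation**: ROC/auROC (= normalized Mann–Whitney U), precision-recall,
  exact Wilcoxon rank-sum, mutual information, $R^2$ (`roc_curve`, ...);
* **a synthetic-data generator** producing fully labeled peak files,
  knockout replicates, genomes and truth tables (`sim_config`,
  `simulate_experiment`), so the whole pipeline runs with no downloads.

## Worked example

Simulate a knockout-validation experiment, run the detector on the
wild-type data only, and check it against the knockout truth:

```r
library(cpiem)

cfg <- sim_config(n_pairs = 800, genome_length = 600000, seed = 42)
ex  <- simulate_experiment(cfg)

# doubly bound regions from the two wild-type experiments
pairs <- find_overlapping_pairs(ex$wt_target[[1]], ex$partner)
nrow(pairs)
#> [1] 910

model <- fit_cpiem(pairs, family = "lognormal", seed = 1)
model
#> Two-component lognormal intensity mixture
#>   cooperative fraction w = 0.4033
#>   coop target      location =   1.0001  scale =   0.5522
#>   coop partner     location =   1.9563  scale =   0.6347
#>   noncoop target   location =   2.5454  scale =   0.4821
#>   noncoop partner  location =   2.1261  scale =   0.6351
#>   log-likelihood -5643.0436 after 39 iterations (converged)

post  <- posterior_coop(model, pairs)
calls <- classify_pairs(post, alpha = 0.5)
sum(calls)
#> [1] 355
```

The fit recovers the generating conditions (cooperative fraction 0.4,
target log-means 1.0 vs 2.5) from the unlabeled wild-type intensity pairs.
Scoring the posteriors against the simulation truth:

```r
truth <- ex$truth$cooperative[pairs$target_idx]
roc_curve(truth, post)
#> ROC curve: 342 cooperative vs 568 non-cooperative, auROC = 0.9853

# the summit-distance baseline carries no signal here, by construction
roc_curve(truth, -pairs$summit_distance)
#> ROC curve: 342 cooperative vs 568 non-cooperative, auROC = 0.4888
```

The detector separates cooperative from non-cooperative regions almost
perfectly (auROC 0.99), while peak distance performs at chance — peak
intensities carry the signal. Against labels derived from the simulated
knockout (`label_from_knockout`, loss-only mode), the $\alpha = 0.5$ calls
recover 269 of 287 knockout-confirmed cooperative regions at an
86/(86+537) ≈ 14% false-positive rate.

A command-line front end wrapping the same workflow (subcommands `detect`,
`validate`, `distance`, `filter-indirect`, `evaluate`, `simulate`) is
installed at `system.file("cli", "cpiem.R", package = "cpiem")`.

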