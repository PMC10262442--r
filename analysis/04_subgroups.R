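#!/usr/bin/env Rscript
# Step 4: stratified average treatment effects.
#
# Repeats the aggregate-index TMLE within WAMI terciles (fixed cutoffs
# >=21 / >=17 / <17) and within the high-risk subgroups (adolescent
# mothers, parity > 1, in-laws present, CESD > 18). Exposure cutpoints are
# the full-sample quartiles; nuisances are refit per stratum; strata under
# 100 mothers are skipped.

suppressPackageStartupMessages(library(ancempower))

records <- utils::read.csv("results/cohort.csv")
res <- run_analysis(
  records,
  indices = "aggregate",
  outcomes = c("ge4_vs_1to3", "count"),
  learners = c("glm", "lasso", "ridge"),
  n_folds = 10, seed = 2019L,
  stratify = TRUE, min_stratum_n = 100L, gcomp = FALSE
)

write_analysis(res, "results/subgroups")
est <- res$estimates
strat <- est[est$stratifier != "none" & est$comparison == "high_vs_low", ]
cat("high-vs-low ATE by stratum (outcome: P(>=4 | >=1 visit)):\n")
sub <- strat[strat$outcome == "ge4_vs_1to3", ]
for (i in seq_len(nrow(sub))) {
  r <- sub[i, ]
  cat(sprintf("  %-14s %-11s n=%4d  psi %+.3f (%+.3f, %+.3f)\n",
              r$stratifier, r$stratum, r$n, r$psi, r$ci_lower, r$ci_upper))
}
if (length(res$skipped)) {
  cat("skipped strata:\n")
  cat(paste0("  ", res$skipped, collapse = "\n"), "\n")
}
cat("wrote results/subgroups/estimates.csv and analysis.json\n")
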