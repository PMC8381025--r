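#!/usr/bin/env Rscript

# Accuracy study: how well do CTT percent-correct subscores, per-strand
# Rasch mastery (MML + MAP, theta > 0) and joint DINA MAP profiles recover
# true strand mastery, as the number of items per strand (5/10/15/20) and
# the inter-attribute correlation (0 to 0.9) vary?
#
# Full design: 5 correlation levels x 50 replicate forms x 1,000 examinees,
# 50 items per form. Writes results/simulation/accuracy_long.csv,
# accuracy_table.csv (strand x model rows, one column per rho) and
# run_log.json. Takes a few minutes per correlation level on one core.

library(dcmastery)

out_dir <- "results/simulation"
study <- run_simulation_study(
  list(rhos = c(0, 0.3, 0.5, 0.7, 0.9),
       strand_sizes = c(5L, 10L, 15L, 20L),
       n_persons = 1000L, n_forms = 50L, seed = 2026L),
  out_dir = out_dir, progress = TRUE)

cat("\nMean classification accuracy (rows: strand x model, cols: rho):\n\n")
print(study$pivot, digits = 3, row.names = FALSE)

cat("\nHeadline patterns:\n")
for (r in names(study$results)) {
  m <- study$results[[r]]$mean_accuracy
  cat(sprintf(
    " %s: accuracy rises with strand size for every model (%s); DINA - CTT gap %.3f to %.3f\n",
    r,
    paste(ifelse(apply(m, 1, function(v) all(diff(v) > -0.01)),
                 rownames(m), paste0(rownames(m), "(!)")), collapse = ", "),
    min(m["dina", ] - m["ctt", ]), max(m["dina", ] - m["ctt", ])))
}
cat("\nWrote", out_dir, "\n")
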