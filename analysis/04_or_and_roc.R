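#!/usr/bin/env Rscript
# Statistical cascade, part 2: dichotomized univariate odds ratios for MPR
# and ROC curves with Youden-optimal cutoffs for the spatial metrics, in the
# chemoimmunotherapy squamous subset. Requires 01 and 02.
#
# Outputs: results/or_table.csv, results/roc_summary.csv,
#          results/roc_points.csv

suppressPackageStartupMessages({
  library(tmespatial)
  library(dplyr)
})

pm <- readr::read_csv("results/patient_metrics.csv", show_col_types = FALSE)
sub <- filter(pm, arm == "NAIC", histology == "SCC")

metric_vars <- c("density_PDL1", "density_PD1", "density_CAF", "density_TAEC",
                 "mean_nnd_um", "proximity_raw", "proximity_per1000")

or_tab <- bind_rows(lapply(metric_vars, function(vv) {
  v <- sub[[vv]]; ok <- !is.na(v)
  tryCatch({
    lab <- dichotomize(v[ok])
    mutate(univariate_or(lab, sub$MPR[ok]), variable = vv,
           cut = attr(lab, "cut"), .before = 1)
  }, error = function(e) NULL)
}))
readr::write_csv(or_tab, "results/or_table.csv")
cat("Univariate odds ratios for MPR (low vs high at the median):\n")
print(as.data.frame(or_tab[, c("variable", "or", "ci_lower", "ci_upper",
                               "p", "corrected")]),
      row.names = FALSE, digits = 3)

roc_summary <- list(); roc_points <- list()
for (vv in c("mean_nnd_um", "proximity_raw", "proximity_per1000")) {
  v <- sub[[vv]]; ok <- !is.na(v)
  rr <- roc_curve(v[ok], sub$MPR[ok])
  roc_points[[vv]] <- mutate(rr$points, variable = vv, .before = 1)
  roc_summary[[vv]] <- tibble::tibble(
    variable = vv, auc = rr$auc, threshold = rr$threshold,
    sensitivity = rr$sensitivity, specificity = rr$specificity,
    flipped = rr$flipped)
}
roc_summary <- bind_rows(roc_summary)
readr::write_csv(roc_summary, "results/roc_summary.csv")
readr::write_csv(bind_rows(roc_points), "results/roc_points.csv")
cat("\nROC for MPR prediction (orientation auto-chosen):\n")
print(as.data.frame(roc_summary), row.names = FALSE, digits = 3)
cat("Wrote results/or_table.csv, results/roc_summary.csv, results/roc_points.csv\n")
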