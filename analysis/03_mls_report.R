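#!/usr/bin/env Rscript
# Step 3 — maximal-lifespan estimates and the published-number report.
#
# First reproduces every published statistic from its published inputs
# (tail ages, fitted parameters, half-widths, chimerism fractions), then
# runs the same estimators on the synthetic study from step 1.

suppressPackageStartupMessages(library(maxspan))

report <- reproduce_reference_results()
print(report)
write_report_json(report, "results/reference_report.json")
utils::write.csv(report$table, "results/reference_report.csv",
                 row.names = FALSE)

cat("\n--- same estimators on the synthetic study ---\n")
co <- apply_mortality_policy(
  read_cohort_csv("results/synthetic_cohort.csv", t_intervention = 15))
rec <- co$records
m_ctl <- suppressWarnings(
  mls_direct(rec$age_months[rec$group == "control"],
             sum(rec$group == "control")))
m_exp <- mls_direct(rec$age_months[rec$group == "experimental"],
                    sum(rec$group == "experimental"))
fit <- read_params_json("results/gompertz_fit_preintervention.json")
m_tail <- mls_model_tail(fit)
m_comb <- combine_weighted(m_ctl, mls_estimate(m_tail$value, 0.6,
                                               method = "model_tail"))
print(m_ctl); print(m_tail); print(m_comb); print(m_exp)
cat(sprintf("synthetic extension: %.1f %%\n",
            extension_percent(m_exp$value, m_comb$value)))
cat(sprintf("synthetic fold past 15 months: %.2f\n",
            survival_fold(m_exp$value, m_comb$value, 15)))

if (!report$all_match)
  cat("\nNOTE: the model-tail value computes to 17.35 with the published\n",
      "rounded parameters and is flagged as a 1-decimal mismatch against\n",
      "the published 17.2 (inside its published +-0.6 half-width).\n",
      sep = "")
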