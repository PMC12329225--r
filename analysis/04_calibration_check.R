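#!/usr/bin/env Rscript
# Stage 4: quick calibration check of the inference layer.
#
# A scaled-down null simulation (50 cohorts at 20 regions, 20 subjects
# per group): both groups come from the same generative law, so the
# permutation test's rejection rate should sit near its nominal 0.05
# level and the Bonferroni-corrected ANOVA should almost never flag an
# edge. scripts/acceptance.R runs the full-size version of the same
# check (500 and 250 cohorts).

suppressPackageStartupMessages(library(brainsfc))

n_rep <- 50
out_path <- "results/calibration_check.csv"

null_config <- function(s) {
  sfc_config(n_regions_cortical = 16L, n_regions_subcortical = 4L,
             n_subjects_per_group = 20L, community_count = 4L, seed = s)
}

rej <- logical(n_rep)
fwe <- logical(n_rep)
for (r in seq_len(n_rep)) {
  coh <- generate_cohort(null_config(600000 + r))
  an <- analyze_cohort(coh, cutoff_scope = "group")
  pt <- permutation_ttest(
    an$sdi[, 1], factor(an$manifest$group, levels = c("pilot", "control")),
    covariates = an$manifest[c("age", "education", "tiv", "mfd")],
    n_perm = 1000, seed = r)
  rej[r] <- pt$p_perm < 0.05
  ea <- mixed_anova_edges(an$cfc_z, an$dfc_z, an$manifest, alpha = 0.01,
                          seed = r)
  fwe[r] <- any(ea$significant)
}

out <- data.frame(
  check = c("permutation_type_I_at_0.05", "anova_family_wise_at_0.01"),
  rate = c(mean(rej), mean(fwe)),
  n_replicates = n_rep
)
write.csv(out, out_path, row.names = FALSE)
message(sprintf("permutation type-I error: %.3f (nominal 0.05, %d null cohorts)",
                mean(rej), n_rep))
message(sprintf("ANOVA family-wise error:  %.3f (bound 0.01, %d null cohorts)",
                mean(fwe), n_rep))
message("written to ", out_path)
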