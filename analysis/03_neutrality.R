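#!/usr/bin/env Rscript
# Neutrality tests for the first simulated replicate of each regime:
# Tajima's D against the beta interval and against IS/FS simulated nulls,
# the corrected D-type statistic, and Fu's Fs with its one-tailed
# critical values. Writes a test table shaped like a standard
# neutrality-test report.

suppressPackageStartupMessages(library(finitesites))

indir <- "results/simulated"
if (!file.exists(file.path(indir, "manifest.tsv")))
  stop("run analysis/01_simulate.R first")

n_reps_null <- 1500L
alpha_by_profile <- c(CR = 0.102, ND2 = 0.279)
rows <- NULL

for (profile in c("CR", "ND2")) {
  aln <- read_alignment(file.path(indir,
                                  sprintf("%s_rep01.fasta", tolower(profile))))
  cfg <- study_profile(profile)
  sm <- summarize_polymorphism(aln)
  gm <- gamma_rate_model(alpha_by_profile[[profile]],
                         if (profile == "CR") 12L else 1L)

  # nulls conditioned on this data set's own estimates: Watterson for the
  # finite-sites null, pairwise for the IS null of Fs
  pW <- coalescent_params(sm$n, sm$theta_W * sm$L_eff)
  pPi <- coalescent_params(sm$n, max(sm$pi_total, 0.5))
  nd_D_fs <- build_null("D", "FS", pW, n_reps = n_reps_null, seed = 811,
                        L = sm$L_eff, subst = cfg$model, rates = cfg$rates)
  nd_fs_is <- build_null("Fs", "IS", pPi, n_reps = n_reps_null, seed = 812)
  nd_fs_fs <- build_null("Fs", "FS", pW, n_reps = n_reps_null, seed = 813,
                         L = sm$L_eff, subst = cfg$model, rates = cfg$rates)

  res <- neutrality_tests(aln, rates = gm,
                          nulls = list(D = nd_D_fs, Fs = nd_fs_fs))
  beta <- tajima_beta_interval(sm$n)
  rows <- rbind(rows, data.frame(
    profile = profile,
    D = round(res$D, 3),
    beta_lower = round(beta$lower, 3), beta_upper = round(beta$upper, 3),
    D_sig_beta = res$D_beta$significant,
    FS_lower = round(res$D_null$interval[1], 3),
    FS_upper = round(res$D_null$interval[2], 3),
    D_sig_FS = res$D_null$significant,
    Ds_star_plus = round(res$Ds_star_plus, 3),
    Ds_sig_beta = res$Ds_beta$significant,
    Fs = round(res$Fs, 3),
    Fs_crit_IS = round(critical_values(nd_fs_is, tail = "lower"), 3),
    Fs_crit_FS = round(critical_values(nd_fs_fs, tail = "lower"), 3),
    Fs_sig_FS = res$Fs_null$significant))
}

write.table(rows, "results/neutrality_table.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
cat("neutrality test table (simulated neutral data):\n")
print(rows, row.names = FALSE)
cat("\nThese data are neutral by construction, so significance calls\n")
cat("should appear at roughly the nominal 5% rate; note how the FS\n")
cat("interval of D sits higher than the beta interval under the\n")
cat("strong-heterogeneity CR regime.\n")
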