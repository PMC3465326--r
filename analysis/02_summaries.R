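#!/usr/bin/env Rscript
# Polymorphism summary table for the simulated data sets: the classical
# statistics plus the gamma-corrected finite-sites estimators, mirroring
# the layout L, n, k, h, S, eta, I, pi, theta_W, theta_pi, theta_S*.

suppressPackageStartupMessages(library(finitesites))

indir <- "results/simulated"
if (!file.exists(file.path(indir, "manifest.tsv")))
  stop("run analysis/01_simulate.R first")
manifest <- read.delim(file.path(indir, "manifest.tsv"))

alpha_by_profile <- c(CR = 0.102, ND2 = 0.279)

rows <- NULL
for (r in seq_len(nrow(manifest))) {
  mf <- manifest[r, ]
  aln <- read_alignment(file.path(
    indir, sprintf("%s_rep%02d.fasta", tolower(mf$profile), mf$rep)))
  sm <- summarize_polymorphism(aln)
  gm <- gamma_rate_model(alpha_by_profile[[mf$profile]])
  th_pi <- corrected_theta("pi", sm$pi, sm$n, sm$L_eff, gm)$theta_hat
  th_ss <- corrected_theta("Sstar", sm$eta, sm$n, sm$L_eff, gm)$theta_hat
  rows <- rbind(rows, data.frame(
    profile = mf$profile, rep = mf$rep, L = sm$L_eff, n = sm$n, k = sm$k,
    h = round(sm$h, 3), h_sd = round(sm$h_sd, 3), S = sm$S, eta = sm$eta,
    I = sm$I, pi = round(sm$pi, 4), theta_W = round(sm$theta_W, 4),
    theta_pi = round(th_pi, 4), theta_Sstar = round(th_ss, 4),
    alpha = alpha_by_profile[[mf$profile]]))
}
dir.create("results", showWarnings = FALSE)
write.table(rows, "results/summary_table.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

cat("polymorphism summaries with corrected estimators:\n")
print(rows, row.names = FALSE)
infl <- with(rows, tapply(theta_Sstar / theta_W, profile, mean))
cat(sprintf("\nmean inflation of theta_S* over theta_W: CR %.0f%%, ND2 %.0f%%\n",
            100 * (infl[["CR"]] - 1), 100 * (infl[["ND2"]] - 1)))
cat("The strong-heterogeneity (CR) regime hides more mutations, so its\n")
cat("finite-sites correction is systematically larger.\n")
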