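#!/usr/bin/env Rscript
# Generate study-scale synthetic data sets under the two fitted
# mitochondrial regimes (control-region-like and ND2-like), write them as
# FASTA with a replicate manifest, and record the genealogies. These
# data sets are the inputs of the downstream analysis scripts.

suppressPackageStartupMessages(library(finitesites))

master_seed <- 20121005L
n_reps <- 5L
outdir <- "results/simulated"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

manifest <- NULL
for (profile in c("CR", "ND2")) {
  cfg <- study_profile(profile)
  for (i in seq_len(n_reps)) {
    seed <- master_seed + 100L * match(profile, c("CR", "ND2")) + i
    gen <- simulate_genealogy(
      coalescent_params(31, cfg$theta_site * cfg$L), seed = seed)
    aln <- mutate_finite_sites(gen, cfg$theta_site * cfg$L, cfg$L,
                               cfg$model, cfg$rates)
    stem <- sprintf("%s_rep%02d", tolower(profile), i)
    write_alignment(aln, file.path(outdir, paste0(stem, ".fasta")))
    ape::write.tree(ape::as.phylo(gen),
                    file.path(outdir, paste0(stem, ".nwk")))
    sm <- summarize_polymorphism(aln)
    manifest <- rbind(manifest, data.frame(
      profile = profile, rep = i, seed = seed, n = sm$n, L = sm$L,
      k = sm$k, S = sm$S, eta = sm$eta,
      pi = round(sm$pi, 5), theta_W = round(sm$theta_W, 5)))
  }
}
write.table(manifest, file.path(outdir, "manifest.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)

cat(sprintf("wrote %d alignments + genealogies to %s\n",
            nrow(manifest), outdir))
cat("replicate summaries (per-site pi and theta_W):\n")
print(manifest, row.names = FALSE)
cat("\nNote the recurring signature of the CR regime: eta > S (multiple\n")
cat("hits at fast sites) while the ND2 regime stays near eta == S.\n")
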