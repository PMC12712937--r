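#!/usr/bin/env Rscript

# Stage 5 — motif activity inference.
#
# Scores every promoter against the H-T 4 and T-T 3 di-motif PSAMs, the PRE
# mono-motif and decoy PSAMs (window-product affinities summed over both
# strands), fits the contrast fold-changes on all affinities jointly, and
# derives per-sample rescaled activities from the log2FC matrix of stage 3.

suppressMessages(library(predimotif))

fix <- "results/fixtures"
genome <- read_fasta(file.path(fix, "genome.fa"))

consensus_block <- function(left, gap, right) {
  cbind(psam_from_sequence(left, off = 0.25),
        matrix(1, 4, gap, dimnames = list(c("A", "C", "G", "T"))),
        psam_from_sequence(right, off = 0.25))
}
set.seed(170)
decoys <- lapply(1:4, function(i) psam_from_sequence(
  paste(sample(c("A", "C", "G", "T"), 10, replace = TRUE), collapse = ""),
  off = 0.25))
names(decoys) <- paste0("decoy", 1:4)
psams <- c(list(HT4 = consensus_block("TGAAACA", 4, "TGAAACA"),
                TT3 = consensus_block("TGTTTCA", 3, "TGAAACA"),
                PRE = psam_from_sequence("TGAAACA", off = 0.25)), decoys)
write_meme_motifs(psams, "results/05_psams.meme")

N <- promoter_affinity(psams, genome)

# signed activities per contrast
cts <- c("wt_t60_vs_t0", "kar4_t60_vs_wt_t60", "kar4_t60_vs_kar4_t0")
fits <- do.call(rbind, lapply(cts, function(nm) {
  tab <- read_contrast_table(file.path(fix, "contrasts", paste0(nm, ".tsv")))
  y <- tab$lfc[match(rownames(N), tab$gene)]
  f <- suppressWarnings(fit_activity(N, y))
  f$contrast <- nm
  f
}))
write.table(fits, "results/05_activity_contrasts.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("Signed -log10 p of motif activities per contrast:\n")
print(reshape(fits[, c("motif", "contrast", "signed_logp")],
              idvar = "motif", timevar = "contrast", direction = "wide"),
      digits = 3)

# per-sample activities, rescaled within each motif
lfc_tab <- read.delim("results/03_logfc_matrix.tsv", check.names = FALSE)
lfc <- as.matrix(lfc_tab[, -1]); rownames(lfc) <- lfc_tab$gene
per_sample <- suppressWarnings(activity_per_sample(N, lfc))
write.table(per_sample, "results/05_activity_per_sample.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
tt3 <- per_sample[per_sample$motif == "TT3", ]
cat("Rescaled T-T 3 activity is highest in:",
    tt3$sample[which.max(tt3$rescaled_beta)], "\n")
ht4 <- per_sample[per_sample$motif == "HT4", ]
cat("Rescaled H-T 4 activity is highest in:",
    ht4$sample[which.max(ht4$rescaled_beta)], "\n")
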