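#!/usr/bin/env Rscript

# Stage 3 — gene classification by pheromone induction and Kar4 dependence.
#
# Applies the threshold rules (|log2FC| >= 1, padj < 0.01 for the named
# sets; t60-artifact removal against the mock-treatment control) to the
# five contrasts, then computes promoter perfect-PRE fractions per set with
# hypergeometric enrichment (the Table-1-style summary) and the
# pseudocounted per-sample log2 fold-change matrix used for activity
# inference.

suppressMessages(library(predimotif))

fix <- "results/fixtures"
cts <- lapply(c("wt_t60_vs_t0", "ste12_t60_vs_wt_t60", "kar4_t60_vs_wt_t60",
                "kar4_t60_vs_kar4_t0", "wt_t60ctrl_vs_t0"), function(nm)
  read_contrast_table(file.path(fix, "contrasts", paste0(nm, ".tsv"))))
contrasts <- do.call(contrast_set, cts)

labels <- classify_genesets(contrasts)
write.table(labels, "results/03_gene_labels.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("Gene classes:\n")
print(table(labels$label))
cat(sum(!is.na(labels$kar4_only)), "genes carry a kar4-only co-label;",
    sum(labels$t60_artifact), "flagged as t60 artifacts\n")

# promoter perfect-PRE content per set (500 bp upstream windows)
genome <- read_fasta(file.path(fix, "genome.fa"))
promoters <- substring(genome, pmax(1, nchar(genome) - 499), nchar(genome))
sets <- split(labels$gene, labels$label)
tab1 <- promoter_perfect_pre_fraction(sets, promoters,
                                      universe = labels$gene)
write.table(tab1, "results/03_perfect_pre_fractions.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("Fraction of promoters with a perfect PRE (TGAAACA, either strand):\n")
print(tab1, digits = 3)

# per-sample log2FC matrix against the wild-type untreated reference
tpm_tab <- read.delim(file.path(fix, "tpm.tsv"), check.names = FALSE)
tpm <- as.matrix(tpm_tab[, -1]); rownames(tpm) <- tpm_tab$gene
lfc <- logfc_matrix(tpm, c("wt_t0_r1", "wt_t0_r2"), pseudocount = 0.5)
write.table(data.frame(gene = rownames(lfc), round(lfc, 4),
                       check.names = FALSE),
            "results/03_logfc_matrix.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("log2FC matrix:", nrow(lfc), "genes x", ncol(lfc), "samples\n")
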