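CONTRAST_NAMES <- c("wt_t60_vs_t0", "ste12_t60_vs_wt_t60",
                    "kar4_t60_vs_wt_t60", "kar4_t60_vs_kar4_t0",
                    "wt_t60ctrl_vs_t0")

#' Assemble the five-contrast set used for gene classification
#'
#' @param wt_t60_vs_t0,ste12_t60_vs_wt_t60,kar4_t60_vs_wt_t60,kar4_t60_vs_kar4_t0,wt_t60ctrl_vs_t0
#'   Contrast tables with columns `gene`, `lfc`, `padj` (see
#'   [read_contrast_table()]).
#' @return Named list of the five tables; duplicate gene ids within a
#'   contrast are an error.
#' @export
contrast_set <- function(wt_t60_vs_t0, ste12_t60_vs_wt_t60,
                         kar4_t60_vs_wt_t60, kar4_t60_vs_kar4_t0,
                         wt_t60ctrl_vs_t0) {
  cs <- list(wt_t60_vs_t0 = wt_t60_vs_t0,
             ste12_t60_vs_wt_t60 = ste12_t60_vs_wt_t60,
             kar4_t60_vs_wt_t60 = kar4_t60_vs_wt_t60,
             kar4_t60_vs_kar4_t0 = kar4_t60_vs_kar4_t0,
             wt_t60ctrl_vs_t0 = wt_t60ctrl_vs_t0)
  for (nm in names(cs)) {
    stopifnot(all(c("gene", "lfc", "padj") %in% names(cs[[nm]])))
    if (anyDuplicated(cs[[nm]]$gene))
      stop("duplicate gene ids in contrast ", nm)
  }
  cs
}

# lfc and padj of a contrast aligned to a gene universe; genes absent from
# the contrast come back with lfc 0 and padj NA (non-significant there).
align_contrast <- function(ct, genes) {
  i <- match(genes, ct$gene)
  list(lfc = ifelse(is.na(i), 0, ct$lfc[i]),
       padj = ct$padj[i][seq_along(genes)])
}

sig_up <- function(al, lfc_thresh, padj_thresh) {
  !is.na(al$padj) & al$padj < padj_thresh & al$lfc >= lfc_thresh
}
sig_down <- function(al, lfc_thresh, padj_thresh) {
  !is.na(al$padj) & al$padj < padj_thresh & al$lfc <= -lfc_thresh
}

#' Per-sample log2 fold-change matrix from TPM values
#'
#' A pseudocount is added to every TPM value, then each sample is compared
#' against the mean of the pseudocounted reference samples:
#' log2((tpm + pc) / mean(tpm_ref + pc)).
#'
#' @param tpm Genes x samples numeric matrix (rownames are genes).
#' @param reference_sample_ids Column names of the reference (control)
#'   samples.
#' @param pseudocount Added to all TPM values first (default 0.5).
#' @return Genes x samples matrix of log2 fold-changes.
#' @export
logfc_matrix <- function(tpm, reference_sample_ids, pseudocount = 0.5) {
  tpm <- as.matrix(tpm)
  if (length(reference_sample_ids) == 0L) stop("empty reference set")
  stopifnot(all(reference_sample_ids %in% colnames(tpm)), all(tpm >= 0))
  x <- tpm + pseudocount
  ref_mean <- rowMeans(x[, reference_sample_ids, drop = FALSE])
  log2(x / ref_mean)
}

#' Flag genes whose apparent pheromone response is a t60 treatment artifact
#'
#' Genes that are significantly changed in the same direction, at or beyond
#' the fold-change threshold, in both the pheromone contrast
#' (wt_t60_vs_t0) and the mock-treatment control contrast
#' (wt_t60ctrl_vs_t0) are flagged as potential false positives of the t60
#' treatment itself.
#'
#' @param contrasts Contrast set from [contrast_set()].
#' @param lfc_thresh Absolute log2 fold-change threshold (default 1).
#' @param padj_thresh Adjusted p-value threshold (default 0.05, the broad
#'   up/down-list threshold).
#' @return Character vector of flagged gene ids.
#' @export
flag_t60_artifacts <- function(contrasts, lfc_thresh = 1, padj_thresh = 0.05) {
  genes <- union(contrasts$wt_t60_vs_t0$gene, contrasts$wt_t60ctrl_vs_t0$gene)
  a <- align_contrast(contrasts$wt_t60_vs_t0, genes)
  b <- align_contrast(contrasts$wt_t60ctrl_vs_t0, genes)
  both_up <- sig_up(a, lfc_thresh, padj_thresh) &
    sig_up(b, lfc_thresh, padj_thresh)
  both_down <- sig_down(a, lfc_thresh, padj_thresh) &
    sig_down(b, lfc_thresh, padj_thresh)
  genes[both_up | both_down]
}

#' Classify genes by pheromone induction and Kar4 dependence
#'
#' Threshold rules over the five contrasts:
#' pheromone-induced genes (wt_t60_vs_t0 lfc >= `lfc_thresh`, significant,
#' not a t60 artifact) that are Ste12-dependent (ste12 contrast <=
#' -`lfc_thresh`, significant) are split into Kar4-dependent (additionally
#' kar4_t60_vs_wt_t60 <= -`lfc_thresh`, significant) and Kar4-independent
#' (the rest). Downregulation is mirrored into `pheromone_down`.
#' kar4-delta-only genes respond at least 2-fold more strongly without
#' Kar4: kar4_t60_vs_wt_t60 and kar4_t60_vs_kar4_t0 both significantly
#' >= `lfc_thresh` (up; mirrored for down). kar4_only_up may co-occur with
#' pheromone_up_kar4_independent and is then reported as a co-label.
#' Genes in `exclude` (by default KAR4 itself, whose dependence class is
#' not identifiable from these data) are flagged for removal from
#' Kar4-dependent counts.
#'
#' @param contrasts Contrast set from [contrast_set()].
#' @param lfc_thresh Absolute log2 fold-change threshold, inclusive
#'   ("at least 2-fold" = lfc >= 1; default 1).
#' @param padj_thresh Adjusted p threshold for the named gene sets
#'   (default 0.01).
#' @param artifact_padj_thresh Threshold passed to [flag_t60_artifacts()]
#'   (default 0.05).
#' @param exclude Gene ids flagged as excluded (default "KAR4").
#' @return data.frame with columns `gene`, `label` (primary class),
#'   `kar4_only` ("up", "down" or NA co-label), `excluded`, `t60_artifact`.
#' @export
classify_genesets <- function(contrasts, lfc_thresh = 1, padj_thresh = 0.01,
                              artifact_padj_thresh = 0.05,
                              exclude = c("KAR4")) {
  genes <- sort(unique(unlist(lapply(contrasts, function(ct) ct$gene))))
  al <- lapply(contrasts, align_contrast, genes = genes)
  artifacts <- genes %in% flag_t60_artifacts(contrasts, lfc_thresh,
                                             artifact_padj_thresh)

  wt_up <- sig_up(al$wt_t60_vs_t0, lfc_thresh, padj_thresh) & !artifacts
  wt_down <- sig_down(al$wt_t60_vs_t0, lfc_thresh, padj_thresh) & !artifacts
  ste12_dep_up <- wt_up & sig_down(al$ste12_t60_vs_wt_t60, lfc_thresh,
                                   padj_thresh)
  ste12_dep_down <- wt_down & sig_up(al$ste12_t60_vs_wt_t60, lfc_thresh,
                                     padj_thresh)
  kar4_dep <- ste12_dep_up & sig_down(al$kar4_t60_vs_wt_t60, lfc_thresh,
                                      padj_thresh)
  kar4_only_up <- sig_up(al$kar4_t60_vs_wt_t60, lfc_thresh, padj_thresh) &
    sig_up(al$kar4_t60_vs_kar4_t0, lfc_thresh, padj_thresh)
  kar4_only_down <- sig_down(al$kar4_t60_vs_wt_t60, lfc_thresh, padj_thresh) &
    sig_down(al$kar4_t60_vs_kar4_t0, lfc_thresh, padj_thresh)

  label <- rep("all_other", length(genes))
  label[kar4_only_up] <- "kar4_only_up"
  label[kar4_only_down] <- "kar4_only_down"
  label[ste12_dep_down] <- "pheromone_down"
  label[ste12_dep_up] <- "pheromone_up_kar4_independent"
  label[kar4_dep] <- "pheromone_up_kar4_dependent"

  co <- rep(NA_character_, length(genes))
  co[kar4_only_up & label != "kar4_only_up"] <- "up"
  co[kar4_only_down & label != "kar4_only_down"] <- "down"

  data.frame(gene = genes, label = label, kar4_only = co,
             excluded = genes %in% exclude, t60_artifact = artifacts,
             stringsAsFactors = FALSE)
}

#' Fraction of each gene set with a perfect promoter PRE, with enrichment p
#'
#' A gene counts if its promoter sequence contains at least one exact
#' TGAAACA on either strand. Enrichment of each set against the population
#' (by default the union of all sets) is an upper-tail hypergeometric test.
#'
#' @param gene_sets Named list of gene-id vectors.
#' @param promoters Named character vector of promoter sequences keyed by
#'   gene id (strand-aware upstream sequence; genes without a promoter are
#'   dropped with a warning).
#' @param universe Population gene ids (default: union of the sets).
#' @return data.frame with `set`, `n`, `with_pre`, `fraction`, `p`.
#' @export
promoter_perfect_pre_fraction <- function(gene_sets, promoters,
                                          universe = NULL) {
  if (is.null(universe)) universe <- unique(unlist(gene_sets))
  missing <- setdiff(universe, names(promoters))
  if (length(missing) > 0L) {
    warning(length(missing), " gene(s) without promoter sequence dropped")
    universe <- setdiff(universe, missing)
    gene_sets <- lapply(gene_sets, intersect, y = universe)
  }
  has_pre <- vapply(promoters[universe],
                    function(s) nrow(find_perfect_pre(s)) > 0L, logical(1))
  K <- sum(has_pre); N <- length(universe)
  out <- lapply(names(gene_sets), function(nm) {
    set <- intersect(gene_sets[[nm]], universe)
    k <- sum(has_pre[set]); n <- length(set)
    data.frame(set = nm, n = n, with_pre = k,
               fraction = if (n > 0) k / n else NA_real_,
               p = if (n > 0) hypergeom_tail(k, K, n, N) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Fraction of a gene set above an external fold-change threshold
#'
#' @param gene_set Gene ids of the set (non-empty).
#' @param values Named numeric vector of external per-gene values (e.g. an
#'   overexpression fold-change table); genes missing from it are treated
#'   as below threshold.
#' @param threshold Inclusion threshold (value >= threshold counts).
#' @param universe Population for the hypergeometric test (default: names
#'   of `values`).
#' @return One-row data.frame with `n`, `above`, `fraction`, `p`.
#' @export
set_induction_fraction <- function(gene_set, values, threshold,
                                   universe = names(values)) {
  if (length(gene_set) == 0L) stop("empty gene set")
  above <- names(values)[!is.na(values) & values >= threshold]
  K <- length(intersect(above, universe)); N <- length(universe)
  set <- intersect(gene_set, universe)
  k <- length(intersect(gene_set, above)); n <- length(set)
  data.frame(n = n, above = k, fraction = k / n,
             p = hypergeom_tail(min(k, min(K, n)), K, n, N),
             stringsAsFactors = FALSE)
}
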