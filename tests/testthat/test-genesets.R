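# minimal contrast-set builder: per-gene named lfc vectors, padj 0 where an
# effect is planted and 1 elsewhere (noise-free tables)
make_contrasts <- function(effects) {
  genes <- rownames(effects)
  cts <- lapply(colnames(effects), function(ct)
    data.frame(gene = genes, lfc = effects[, ct],
               padj = ifelse(effects[, ct] != 0, 0, 1)))
  names(cts) <- colnames(effects)
  do.call(contrast_set, cts)
}

contrast_cols <- c("wt_t60_vs_t0", "ste12_t60_vs_wt_t60",
                   "kar4_t60_vs_wt_t60", "kar4_t60_vs_kar4_t0",
                   "wt_t60ctrl_vs_t0")

test_that("log fold-change matrix applies pseudocount before averaging", {
  tpm <- matrix(c(4.5, 1.5, 2.5), nrow = 1,
                dimnames = list("g1", c("s", "ref1", "ref2")))
  m <- logfc_matrix(tpm, c("ref1", "ref2"))
  expect_equal(m["g1", "s"], 1.0)  # log2(5 / mean(2, 3)) = log2(2)
  tpm2 <- matrix(2.5, 1, 2, dimnames = list("g", c("a", "ref")))
  expect_equal(logfc_matrix(tpm2, "ref")["g", "a"], 0.0)
  tpm3 <- matrix(0, 1, 2, dimnames = list("g", c("a", "ref")))
  expect_equal(logfc_matrix(tpm3, "ref")["g", "a"], 0.0)
  expect_error(logfc_matrix(tpm, character(0)), "empty reference")
})

test_that("t60 artifacts require same-direction significance in both contrasts", {
  eff <- matrix(0, 3, 5, dimnames = list(c("both_up", "pher_only", "opposite"),
                                         contrast_cols))
  eff["both_up", c(1, 5)] <- c(1.3, 1.5)
  eff["pher_only", 1] <- 2
  eff["opposite", c(1, 5)] <- c(2, -2)
  cs <- make_contrasts(eff)
  expect_equal(flag_t60_artifacts(cs), "both_up")
})

test_that("classification applies the four-class threshold rules", {
  eff <- matrix(0, 6, 5, dimnames = list(
    c("indep", "dep", "k4only", "down", "induced_not_ste12", "flat"),
    contrast_cols))
  eff["indep", ] <- c(2.0, -2.5, -0.2, 2, 0)
  eff["dep", ] <- c(3.0, -3.0, -1.5, 0.5, 0)
  eff["k4only", ] <- c(0.1, 0, 2.2, 2.5, 0)
  eff["down", ] <- c(-2.0, 2.0, 0, 0, 0)
  eff["induced_not_ste12", 1] <- 2.5
  cls <- classify_genesets(make_contrasts(eff))
  lab <- setNames(cls$label, cls$gene)
  expect_equal(unname(lab["indep"]), "pheromone_up_kar4_independent")
  expect_equal(unname(lab["dep"]), "pheromone_up_kar4_dependent")
  expect_equal(unname(lab["k4only"]), "kar4_only_up")
  expect_equal(unname(lab["down"]), "pheromone_down")
  expect_equal(unname(lab["induced_not_ste12"]), "all_other")
  expect_equal(unname(lab["flat"]), "all_other")
})

test_that("thresholds are inclusive at exactly 2-fold and artifacts are removed", {
  eff <- matrix(0, 3, 5, dimnames = list(c("boundary", "below", "artifact"),
                                         contrast_cols))
  eff["boundary", 1:2] <- c(1.0, -1.0)   # exactly 2-fold both ways
  eff["below", 1:2] <- c(0.999, -2)
  eff["artifact", c(1, 2, 5)] <- c(2, -2, 2)
  cls <- classify_genesets(make_contrasts(eff))
  lab <- setNames(cls$label, cls$gene)
  expect_equal(unname(lab["boundary"]), "pheromone_up_kar4_independent")
  expect_equal(unname(lab["below"]), "all_other")
  expect_equal(unname(lab["artifact"]), "all_other")
  expect_true(cls$t60_artifact[cls$gene == "artifact"])
})

test_that("kar4-only co-labels and exclusions are reported", {
  eff <- matrix(0, 2, 5, dimnames = list(c("dual", "KAR4"), contrast_cols))
  eff["dual", ] <- c(2, -2, 1.5, 2, 0)   # induced, Ste12-dep, stronger in kar4
  eff["KAR4", ] <- c(3, -3, -2, 0.1, 0)
  cls <- classify_genesets(make_contrasts(eff))
  dual <- cls[cls$gene == "dual", ]
  expect_equal(dual$label, "pheromone_up_kar4_independent")
  expect_equal(dual$kar4_only, "up")
  k4 <- cls[cls$gene == "KAR4", ]
  expect_equal(k4$label, "pheromone_up_kar4_dependent")
  expect_true(k4$excluded)
})

test_that("classification is invariant to input row order and idempotent", {
  cfg <- sim_config(n_genes = 200L, sigma = 0)
  sim <- simulate_promoters(cfg, seed = 31)
  de <- simulate_de_tables(sim$truth, cfg, seed = 32)
  cls1 <- classify_genesets(de$contrasts)
  shuffled <- lapply(de$contrasts, function(ct) ct[sample(nrow(ct)), ])
  cls2 <- classify_genesets(do.call(contrast_set, shuffled))
  expect_equal(cls1, cls2)
  # exact recovery of planted classes at sigma = 0
  want <- c(kar4_independent = "pheromone_up_kar4_independent",
            kar4_dependent = "pheromone_up_kar4_dependent",
            kar4_only = "kar4_only_up", background = "all_other")
  truth_label <- want[sim$truth$class[match(cls1$gene, sim$truth$gene)]]
  expect_equal(cls1$label, unname(truth_label))
})

test_that("promoter perfect-PRE fractions count both strands", {
  proms <- c(a = paste0(strrep("C", 40), "TGAAACA", strrep("C", 40)),
             b = paste0(strrep("C", 40), "TGTTTCA", strrep("C", 40)),
             c = strrep("CA", 50))
  res <- promoter_perfect_pre_fraction(list(all = c("a", "b", "c")), proms)
  expect_equal(res$fraction, 2 / 3)
  res <- promoter_perfect_pre_fraction(list(one = "c", uni = c("a", "b", "c")),
                                       proms, universe = c("a", "b", "c"))
  expect_equal(res$p[res$set == "uni"], 1.0)  # set = universe
  expect_warning(
    promoter_perfect_pre_fraction(list(s = c("a", "zz")), proms,
                                  universe = c("a", "zz")),
    "without promoter")
})

test_that("set induction fractions and planted enrichment p-values", {
  vals <- c(a = 3, b = 0.1)
  expect_equal(set_induction_fraction(c("a", "b"), vals, 1,
                                      universe = c("a", "b"))$fraction, 0.5)
  expect_equal(set_induction_fraction(c("a", "b"), vals, 0.05,
                                      universe = c("a", "b"))$fraction, 1.0)
  # planted enrichment: 40% of a 50-gene set above threshold vs 1% background
  universe <- paste0("g", 1:2000)
  vals <- setNames(rep(0, 2000), universe)
  set <- paste0("g", 1:50)
  vals[paste0("g", 1:20)] <- 2          # 40% of the set
  vals[paste0("g", 1951:2000)] <- 2     # sparse elsewhere
  res <- set_induction_fraction(set, vals, 1, universe)
  expect_lt(res$p, 1e-6)
  expect_error(set_induction_fraction(character(0), vals, 1), "empty")
})
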