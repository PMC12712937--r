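# small genome helper: one chromosome of background with optional planted
# segments (list of list(at = 0-based, seq = string))
make_chrom <- function(len, plant = list(), seed = 1) {
  set.seed(seed)
  s <- random_seq(len)
  for (p in plant) {
    substr(s, p$at + 1, p$at + nchar(p$seq)) <- p$seq
  }
  s
}

test_that("site expansion merges nearby sites and clamps to chromosome bounds", {
  genome <- c(chr1 = make_chrom(1000))
  sites <- data.frame(chrom = "chr1", point = c(100L, 150L),
                      site_id = c("a", "b"))
  r <- prepare_regions(sites, half_width = 60, merge_gap = 60, genome = genome)
  expect_equal(r[, c("start", "end", "id")],
               data.frame(start = 40L, end = 211L, id = "a|b"))
  r <- prepare_regions(data.frame(chrom = "chr1", point = 500L), 120, 60, genome)
  expect_equal(c(r$start, r$end), c(380L, 621L))
  expect_equal(r$end - r$start, 241L)
  r <- prepare_regions(data.frame(chrom = "chr1", point = 10L), 120, 60, genome)
  expect_equal(c(r$start, r$end), c(0L, 131L))
  expect_error(prepare_regions(data.frame(chrom = "chr1", point = 2000L),
                               120, 60, genome), "beyond")
  # distant sites stay separate
  sites <- data.frame(chrom = "chr1", point = c(100L, 400L))
  expect_equal(nrow(prepare_regions(sites, 60, 60, genome)), 2L)
})

test_that("region-set scanning assigns planted best matches and keeps empty regions", {
  # FIG1 fragment padded into background: best must be HT 4
  genome <- c(chr1 = make_chrom(600, list(list(at = 291, seq = FIG1_FRAGMENT)),
                                seed = 8),
              chr2 = paste(rep("A", 400), collapse = ""),
              chr3 = make_chrom(400, list(list(at = 150,
                                               seq = "TGTTTCAGGGTGAAACA")),
                                seed = 9))
  regions <- data.frame(chrom = c("chr1", "chr2", "chr3"),
                        start = c(180L, 50L, 80L), end = c(421L, 291L, 321L),
                        id = c("r1", "r2", "r3"))
  res <- scan_region_set(regions, genome, enumerate_configs(50))
  expect_equal(nrow(res$best), 3L)
  b1 <- res$best[res$best$region_id == "r1", ]
  expect_equal(c(b1$orientation, b1$spacing), c("HT", "4"))
  expect_true(is.na(res$best$orientation[res$best$region_id == "r2"]))
  b3 <- res$best[res$best$region_id == "r3", ]
  expect_equal(c(b3$orientation, b3$spacing), c("TT", "3"))
  # histogram counts only regions with a best; totals conserve regions
  h <- config_histogram(res$best)
  expect_equal(sum(h$count) + sum(is.na(res$best$orientation)), nrow(regions))
  expect_error(scan_region_set(data.frame(chrom = "chr1", start = 0L,
                                          end = 10L, id = "tiny"), genome),
               "shorter")
})

test_that("configuration histograms count best matches", {
  best <- data.frame(region_id = c("a", "b", "c"),
                     orientation = c("HT", "HT", "TT"),
                     spacing = c(4L, 4L, 3L))
  h <- config_histogram(best)
  expect_equal(h$count[h$orientation == "HT" & h$spacing == 4], 2L)
  expect_equal(h$count[h$orientation == "TT" & h$spacing == 3], 1L)
  expect_equal(nrow(config_histogram(best[0, ])), 0L)
})

test_that("top-k membership ranks one entry per configuration", {
  ranked <- data.frame(region_id = "r", strand = "+", start = 0L,
                       orientation = c("TT", "HT", "HH", "HT", "TT", "HH"),
                       spacing = c(3L, 4L, 0L, 14L, 29L, 7L),
                       m1 = 0L, m2 = 0L, p = 1e-8, q = sort(runif(6)) * 1e-3)
  expect_true(topk_contains(ranked, "HT", 4, k = 5))
  expect_false(topk_contains(ranked, "HH", 7, k = 5))
  expect_true(topk_contains(ranked[1:3, ], "HH", 0, k = 5))
  expect_error(topk_contains(ranked, "HT", 4, k = 0), "k must be")
})

test_that("rank_configs keeps one best entry per configuration in q order", {
  m <- assign_qvalues(scan_dimotifs(make_chrom(
    300, list(list(at = 100, seq = "TGAAACAAACATGAAACA")), seed = 12),
    enumerate_configs(30), region_id = "r"))
  rk <- rank_configs(m)
  expect_false(any(duplicated(paste(rk$orientation, rk$spacing))))
  expect_equal(rk$q, sort(rk$q))
  expect_equal(c(rk$orientation[1], rk$spacing[1]), c("HT", "4"))
})

test_that("curated H-T 4 selection enforces mismatch and distance rules", {
  # site with an HT-4 (1,1) motif 80 bp from the centre: kept
  ht4_11 <- "TGACACAAACATGAAACT"  # m1 = 1, m2 = 1
  ht4_30 <- "TGCCCCAAACATGAAACA"  # m1 = 3, m2 = 0
  genome <- c(c1 = make_chrom(600, list(list(at = 380, seq = ht4_11)), seed = 4),
              c2 = make_chrom(600, list(list(at = 380, seq = ht4_30)), seed = 5),
              c3 = make_chrom(600, list(list(at = 450, seq = ht4_11)), seed = 6))
  sites <- data.frame(chrom = c("c1", "c2", "c3"),
                      point = c(300L, 300L, 300L),
                      site_id = c("s1", "s2", "s3"))
  regions <- prepare_regions(sites, half_width = 200, genome = genome)
  res <- scan_region_set(regions, genome, enumerate_configs(20),
                         max_mm_per_pre = 3)
  cur <- curated_ht4_filter(res$matches, regions, sites, genome,
                            max_mm_per_pre = 2, max_center_dist = 100)
  expect_equal(cur$site_id, "s1")       # s2 fails mismatch cap, s3 distance
  expect_equal(cur$seq, ht4_11)
  expect_equal(cur$category, "1_1")
  # idempotence: curated 18-mers rescan to HT 4 with the recorded mismatches
  re <- scan_dimotifs(cur$seq, data.frame(orientation = "HT", spacing = 4L))
  expect_equal(re[re$start == 0 & re$strand == "+", c("m1", "m2")],
               cur[, c("m1", "m2")], ignore_attr = TRUE)
})

test_that("curated selection reports minus-strand motifs in consensus orientation", {
  ht4 <- "TGAAACAAACATGAAACA"
  genome <- c(c1 = make_chrom(600, list(list(at = 290, seq = revcomp(ht4))),
                              seed = 14))
  sites <- data.frame(chrom = "c1", point = 300L, site_id = "s1")
  regions <- prepare_regions(sites, half_width = 150, genome = genome)
  res <- scan_region_set(regions, genome, enumerate_configs(10))
  cur <- curated_ht4_filter(res$matches, regions, sites, genome)
  expect_equal(nrow(cur), 1L)
  expect_equal(cur$strand, "-")
  expect_equal(cur$seq, ht4)
  expect_equal(cur$start, 290L)
})

test_that("mismatch spectra normalise within each class", {
  sp <- mismatch_spectrum(c("0_0", "0_1", "1_2", "1_2"),
                          c("X", "X", "Y", "Y"))
  expect_equal(sp$fraction[sp$class == "X"], c(0.5, 0.5))
  expect_equal(sp$fraction[sp$class == "Y"], 1.0)
  expect_equal(as.numeric(tapply(sp$fraction, sp$class, sum)), c(1, 1))
  expect_error(mismatch_spectrum(c("0_0"), NA), "unlabeled")
})
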