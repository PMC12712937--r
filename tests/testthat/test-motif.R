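test_that("revcomp complements the PRE, maps N to N, and is an involution", {
  expect_equal(revcomp("TGAAACA"), "TGTTTCA")
  expect_equal(revcomp("ACGTN"), "NACGT")
  set.seed(11)
  for (i in 1:20) {
    s <- random_seq(sample(1:50, 1))
    expect_equal(revcomp(revcomp(s)), s)
    expect_equal(revcomp(s), oracle_revcomp(s))
  }
  expect_error(revcomp("ACGU"), "alphabet")
})

test_that("configuration enumeration covers 3 orientations x spacings in order", {
  cfg <- enumerate_configs(100)
  expect_equal(nrow(cfg), 303)
  expect_equal(enumerate_configs(0),
               data.frame(orientation = c("HH", "HT", "TT"),
                          spacing = c(0L, 0L, 0L)))
  expect_equal(nrow(enumerate_configs(1)), 6)
  expect_equal(cfg$orientation, sort(cfg$orientation))
  expect_true(all(tapply(cfg$spacing, cfg$orientation,
                         function(x) identical(x, 0:100))))
  expect_error(enumerate_configs(-1))
})

test_that("per-slot mismatch counting is a Hamming distance with N as mismatch", {
  expect_equal(mismatches("TCAAACA", "TGAAACA"), 1)
  expect_equal(mismatches("CAAAACA", "TGAAACA"), 2)
  expect_equal(mismatches("TGANACA", "TGAAACA"), 1)
  expect_error(mismatches("TGAAAC", "TGAAACA"), "7-mers")
})

test_that("match p-value equals binomial closed forms under uniform background", {
  expect_equal(match_pvalue(0, 0), 1 / 4^14)
  expect_equal(match_pvalue(1, 0), 43 / 4^14)
  expect_equal(match_pvalue(0, 1), 43 / 4^14)
  expect_equal(match_pvalue(7, 7), 1.0)
  # monotone in total mismatches
  p <- sapply(0:14, function(m) match_pvalue(m, 0, orientation = "TT"))
  expect_true(all(diff(p) > 0))
  expect_error(match_pvalue(8, 7))
})

test_that("match-count tail matches exhaustive enumeration at reduced width", {
  # same convolution machinery, checked against full sequence-space sums
  bg_u <- c(A = .25, C = .25, G = .25, T = .25)
  bg_at <- c(A = .35, C = .15, G = .15, T = .35)
  for (bg in list(bg_u, bg_at)) {
    for (tmpl in c("TGAAACA", "TGTTTCAG")) {
      tail <- predimotif:::match_tail_distribution(tmpl, bg)
      for (k in c(0, 3, nchar(tmpl))) {
        expect_equal(tail[k + 1], oracle_match_tail(tmpl, k, bg),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("scanner reproduces the printed promoter-fragment di-motifs", {
  # FIG1 fragment: suboptimal H-T 4 with one mismatch in each PRE
  b <- best_match(assign_qvalues(scan_dimotifs(FIG1_FRAGMENT)))
  expect_equal(b[, c("orientation", "spacing", "m1", "m2")],
               data.frame(orientation = "HT", spacing = 4L, m1 = 1L, m2 = 1L),
               ignore_attr = TRUE)
  # KAR3 fragment: H-T 4 with mismatch pair (1, 2)
  m <- assign_qvalues(scan_dimotifs(KAR3_FRAGMENT))
  bht <- best_match(m[m$orientation == "HT", ])
  expect_equal(bht$spacing, 4L)
  expect_equal(bht$m1, 1L)
  expect_equal(bht$m2, 2L)
  # structure-model 29-mer: perfect H-T 4 at offset 6 on the top strand
  m <- scan_dimotifs(HT4_29MER)
  perfect <- m[m$m1 == 0 & m$m2 == 0, ]
  expect_equal(perfect[, c("strand", "start", "orientation", "spacing")],
               data.frame(strand = "+", start = 6L, orientation = "HT",
                          spacing = 4L), ignore_attr = TRUE)
  # 60-mer DNA-model sequence: perfect HT 4, TT 3 and TT 14
  m <- scan_dimotifs(DNA_MODEL_60MER)
  perfect <- m[m$m1 == 0 & m$m2 == 0, ]
  got <- sort(paste(perfect$orientation, perfect$spacing))
  expect_equal(got, sort(c("HT 4", "TT 3", "TT 14")))
  # all three are perfect matches with equal q; the spacing tie-break picks
  # the smallest spacer, TT 3
  b <- best_match(assign_qvalues(m))
  expect_equal(c(b$orientation, b$spacing), c("TT", "3"))
})

test_that("scanner equals the brute-force substring oracle on random sequences", {
  cfg <- enumerate_configs(30)
  set.seed(42)
  for (i in 1:25) {
    s <- random_seq(sample(20:120, 1))
    mm <- sample(0:3, 1)
    expect_equal(canon_matches(scan_dimotifs(s, cfg, mm)),
                 oracle_scan(s, cfg, mm), ignore_attr = TRUE)
  }
})

test_that("scanning a sequence and its reverse complement gives mirrored matches", {
  cfg <- enumerate_configs(20)
  set.seed(7)
  for (i in 1:10) {
    s <- random_seq(150)
    fwd <- scan_dimotifs(s, cfg, 2)
    rev_ <- scan_dimotifs(revcomp(s), cfg, 2)
    # HT matches swap strands; start reflects because both scans index the
    # template on the match strand of the same double-stranded molecule
    ht_f <- fwd[fwd$orientation == "HT", ]
    ht_r <- rev_[rev_$orientation == "HT", ]
    ht_r$strand <- chartr("+-", "-+", ht_r$strand)
    expect_equal(canon_matches(ht_f), canon_matches(ht_r))
    # HH/TT patterns are strand-symmetric: same configs found, with starts
    # reflected and slots swapped
    for (o in c("HH", "TT")) {
      a <- fwd[fwd$orientation == o, ]
      b <- rev_[rev_$orientation == o, ]
      b$start <- nchar(s) - b$start - (14 + b$spacing)
      b2 <- b; b2$m1 <- b$m2; b2$m2 <- b$m1
      expect_equal(canon_matches(a), canon_matches(b2))
    }
  }
})

test_that("scanner rejects degenerate inputs", {
  expect_error(scan_dimotifs(""), "empty")
  expect_error(scan_dimotifs("ACGTACGTACGT"), "14")
  expect_error(scan_dimotifs(FIG1_FRAGMENT, max_mm_per_pre = 4), "between 0 and 3")
})

test_that("q-values follow Benjamini-Hochberg over the scan family", {
  m <- data.frame(region_id = "r", strand = "+", start = 0:3,
                  orientation = "HT", spacing = 4L, m1 = 0L, m2 = 0L,
                  p = c(0.01, 0.02, 0.03, 0.04))
  expect_equal(assign_qvalues(m)$q, rep(0.04, 4))
  one <- m[1, ]; one$p <- 0.005
  expect_equal(assign_qvalues(one)$q, 0.005)
  expect_error(assign_qvalues(m[0, ]), "empty")
})

test_that("best-match ranking follows the stated tie-break chain", {
  m <- data.frame(region_id = "r", strand = c("+", "+", "-", "+"),
                  start = c(30L, 10L, 5L, 5L),
                  orientation = c("HT", "TT", "HT", "HT"),
                  spacing = c(4L, 3L, 4L, 14L),
                  m1 = c(0L, 0L, 0L, 0L), m2 = c(0L, 0L, 0L, 0L),
                  p = rep(1e-8, 4), q = rep(1e-8, 4))
  b <- best_match(m)
  expect_equal(c(b$orientation, b$spacing), c("TT", "3"))  # smallest spacing
  # fewer total mismatches knocks out the TT 3; equal spacing and start
  # leave the strand tie-break
  m$m1 <- c(0L, 1L, 0L, 0L); m$q <- c(1e-8, 2e-8, 1e-8, 1e-8)
  m$start <- c(5L, 10L, 5L, 5L)
  expect_equal(best_match(m)$strand, "+")  # + strand beats - at equal start
  # single match returns itself; nothing survives a strict p filter
  expect_equal(best_match(m[2, ])$orientation, "TT")
  expect_null(best_match(m, p_threshold = 1e-12))
})

test_that("mismatch categories are sorted pairs", {
  expect_equal(mismatch_category(0, 0), "0_0")
  expect_equal(mismatch_category(1, 2), "1_2")
  expect_equal(mismatch_category(2, 1), "1_2")
  expect_equal(mismatch_category(c(0, 2), c(1, 0)), c("0_1", "0_2"))
})

test_that("perfect PRE finder reports both strands at top-strand coordinates", {
  expect_equal(find_perfect_pre("TGAAACA"),
               data.frame(start = 0L, strand = "+"), ignore_attr = TRUE)
  expect_equal(find_perfect_pre("TGTTTCA"),
               data.frame(start = 0L, strand = "-"), ignore_attr = TRUE)
  hits <- find_perfect_pre(DNA_MODEL_60MER)
  expect_equal(nrow(hits), 3)
  expect_equal(sum(hits$strand == "+"), 2)
  expect_equal(sum(hits$strand == "-"), 1)
})

test_that("count matrices conserve totals and convert to PSAM correctly", {
  cm <- build_count_matrix(c("TGAAACAAACATGAAACA", "TGACACATACATGAAACC"))
  expect_equal(unname(colSums(cm)), rep(2, 18))
  expect_equal(cm[c("A", "C"), 4], c(A = 1L, C = 1L))
  one <- build_count_matrix("ACGT")
  expect_true(all(colSums(one == 1) == 1))
  set.seed(3)
  seqs <- replicate(9, random_seq(12))
  expect_equal(unname(colSums(build_count_matrix(seqs))), rep(9, 12))
  expect_error(build_count_matrix(c("ACGT", "ACG")), "equal length")

  expect_equal(unname(pspm_to_psam(matrix(c(.7, .1, .1, .1), 4, 1))[, 1]),
               c(1, 1 / 7, 1 / 7, 1 / 7))
  expect_equal(unname(pspm_to_psam(matrix(.25, 4, 1))[, 1]), rep(1, 4))
  expect_warning(z <- pspm_to_psam(matrix(c(1, 0, 0, 0), 4, 1)),
                 "zero affinities")
  expect_equal(unname(z[, 1]), c(1, 0, 0, 0))
  expect_silent(pspm_to_psam(matrix(c(1, 0, 0, 0), 4, 1), epsilon = 0.01))
})

test_that("MEME minimal motif files round-trip", {
  motifs <- list(PRE = counts_to_pspm(build_count_matrix("TGAAACA")),
                 HT4 = psam_from_sequence("TGAAACAGGGGTGAAACA", off = .5))
  path <- withr::local_tempfile(fileext = ".meme")
  write_meme_motifs(motifs, path)
  back <- read_meme_motifs(path)
  expect_equal(names(back), names(motifs))
  for (nm in names(motifs))
    expect_equal(back[[nm]], motifs[[nm]], tolerance = 1e-5)
})
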