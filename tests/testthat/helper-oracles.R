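# Independent oracles used by the equivalence tests. These deliberately use
# different algorithms from the package implementation: direct substring
# Hamming comparison for scanning, full-space enumeration for the p-value
# and hypergeometric tails, pairwise-comparison counting for Mann-Whitney.

# Worked sequences used across tests (pheromone-response promoter fragments
# and the double-stranded DNA model input).
FIG1_FRAGMENT <- "TGACACATACATGAAACC"
KAR3_FRAGMENT <- "TCAAACAAAATCAAAACA"
HT4_29MER <- "AGATGATGAAACAAACATGAAACATCTGC"
DNA_MODEL_60MER <-
  "GAGTAAAAGAATTTTGTGTTTCAGGGTGAAACAGATCTGAAACACAAGAGCTTATGCATT"

oracle_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

# Brute-force di-motif scan: for every (config, offset, strand), extract the
# two 7-mer slots by substring and compare character-by-character.
oracle_scan <- function(seq, configs, max_mm) {
  slot_words <- list(HT = c("TGAAACA", "TGAAACA"),
                     TT = c("TGTTTCA", "TGAAACA"),
                     HH = c("TGAAACA", "TGTTTCA"))
  hamming_vec <- function(words, expected) {
    mm <- integer(length(words))
    for (j in 1:7)
      mm <- mm + (substr(words, j, j) != substr(expected, j, j))
    mm
  }
  out <- list(); k <- 0
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else oracle_revcomp(seq)
    L <- nchar(s)
    for (i in seq_len(nrow(configs))) {
      orient <- configs$orientation[i]; sp <- configs$spacing[i]
      if (orient != "HT" && strand == "-") next
      n_off <- L - 14L - sp
      if (n_off < 0L) next
      off <- 0:n_off
      w1 <- substring(s, off + 1L, off + 7L)
      w2 <- substring(s, off + 8L + sp, off + 14L + sp)
      m1 <- hamming_vec(w1, slot_words[[orient]][1])
      m2 <- hamming_vec(w2, slot_words[[orient]][2])
      ok <- m1 <= max_mm & m2 <= max_mm
      if (!any(ok)) next
      k <- k + 1
      out[[k]] <- data.frame(strand = strand, start = off[ok],
                             orientation = orient, spacing = sp,
                             m1 = m1[ok], m2 = m2[ok],
                             stringsAsFactors = FALSE)
    }
  }
  if (k == 0)
    return(data.frame(strand = character(0), start = integer(0),
                      orientation = character(0), spacing = integer(0),
                      m1 = integer(0), m2 = integer(0)))
  res <- do.call(rbind, out)
  res[order(res$orientation, res$spacing, res$strand, res$start), ]
}

# Canonical sort for comparing match tables.
canon_matches <- function(m) {
  m <- m[, c("strand", "start", "orientation", "spacing", "m1", "m2")]
  m <- m[order(m$orientation, m$spacing, m$strand, m$start), ]
  rownames(m) <- NULL
  m
}

# Exhaustive match-count tail for a reduced-width template: enumerate every
# sequence over ACGT of the template width and count those matching in at
# least `min_match` positions, weighting by background probability.
oracle_match_tail <- function(template, min_match, background) {
  bases <- c("A", "C", "G", "T")
  tmpl <- strsplit(template, "")[[1]]
  w <- length(tmpl)
  grid <- do.call(expand.grid, rep(list(bases), w))
  matches <- rowSums(mapply(function(col, t) as.character(col) == t,
                            grid, tmpl))
  probs <- apply(grid, 1, function(row) prod(background[as.character(row)]))
  sum(probs[matches >= min_match])
}

# Hypergeometric upper tail by enumerating all C(N, n) draws.
oracle_hypergeom_tail <- function(k_obs, K, n, N) {
  draws <- combn(N, n)
  succ <- colSums(draws <= K)  # elements 1..K are the successes
  mean(succ >= k_obs)
}

# Mann-Whitney U by pairwise comparison; exact two-sided p by enumerating
# every assignment of the pooled values to the x-group.
oracle_mwu <- function(x, y) {
  U_of <- function(a, b)
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  U <- U_of(x, y)
  pooled <- c(x, y)
  nx <- length(x)
  centre <- nx * length(y) / 2
  Us <- apply(combn(length(pooled), nx), 2, function(idx)
    U_of(pooled[idx], pooled[-idx]))
  list(U = U, p = mean(abs(Us - centre) >= abs(U - centre) - 1e-12))
}

# BH step-up computed literally from the definition.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(1, adj)
  out
}

# OLS coefficients by the normal equations.
oracle_ols <- function(X, y) {
  Xi <- cbind(1, X)
  solve(t(Xi) %*% Xi, t(Xi) %*% y)[, 1]
}

random_seq <- function(len, probs = c(A = .25, C = .25, G = .25, T = .25)) {
  paste(sample(names(probs), len, replace = TRUE, prob = probs),
        collapse = "")
}
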