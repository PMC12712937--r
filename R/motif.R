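#' The PRE consensus 7-mer
#'
#' The pheromone response element bound by Ste12, 5'-TGAAACA-3'. Its reverse
#' complement is TGTTTCA.
#'
#' @return The string "TGAAACA".
#' @export
pre_consensus <- function() "TGAAACA"

PRE_F <- "TGAAACA"
PRE_R <- "TGTTTCA"
PRE_W <- 7L

#' Reverse complement of DNA sequences
#'
#' Alphabet \{A,C,G,T,N\}; N maps to N. Vectorised; an involution.
#'
#' @param x Character vector of sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x))
  if (any(grepl("[^ACGTN]", x))) stop("sequence outside alphabet {A,C,G,T,N}")
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Enumerate all PRE di-motif configurations
#'
#' A configuration is an orientation (HH, HT, TT) plus a spacer length. The
#' canonical top-strand templates are HT: TGAAACA-N^s-TGAAACA,
#' TT: TGTTTCA-N^s-TGAAACA, HH: TGAAACA-N^s-TGTTTCA; template length 14 + s.
#'
#' @param max_spacing Largest spacer length (default 100, giving 303
#'   configurations).
#' @return data.frame with columns `orientation` and `spacing`, ordered by
#'   orientation (HH < HT < TT) then spacing ascending.
#' @export
enumerate_configs <- function(max_spacing = 100L) {
  if (length(max_spacing) != 1L || is.na(max_spacing) || max_spacing < 0)
    stop("max_spacing must be a single non-negative integer")
  data.frame(
    orientation = rep(c("HH", "HT", "TT"), each = max_spacing + 1L),
    spacing = rep(0L:as.integer(max_spacing), times = 3L),
    stringsAsFactors = FALSE
  )
}

# Expected 7-mers for the two PRE slots of each orientation (top-strand
# template). HT is genuinely stranded; HH and TT templates are their own
# reverse complements as patterns (with slots swapped).
dimotif_slots <- function(orientation) {
  switch(orientation,
         HT = c(PRE_F, PRE_F),
         TT = c(PRE_R, PRE_F),
         HH = c(PRE_F, PRE_R),
         stop("unknown orientation: ", orientation))
}

#' Hamming distance between a 7-mer window and an expected 7-mer
#'
#' N counts as a mismatch against any expected base.
#'
#' @param window,expected Strings of length 7.
#' @return Integer mismatch count, 0-7.
#' @export
mismatches <- function(window, expected) {
  if (nchar(window) != PRE_W || nchar(expected) != PRE_W)
    stop("mismatches() compares 7-mers")
  sum(strsplit(window, "")[[1]] != strsplit(expected, "")[[1]])
}

# Per-offset mismatch counts of every 7-mer window of `chars` (a character
# vector of single bases) against the 7-mer `pattern`. Returns a vector of
# length length(chars) - 6; N never equals a base so it counts as a mismatch.
mismatch_profile <- function(chars, pattern) {
  nw <- length(chars) - PRE_W + 1L
  if (nw < 1L) return(integer(0))
  pat <- strsplit(pattern, "")[[1]]
  mm <- integer(nw)
  for (j in seq_len(PRE_W)) {
    mm <- mm + (chars[j:(j + nw - 1L)] != pat[j])
  }
  mm
}

# Tail probabilities for the exact match-count significance model: given the
# 14 template bases (spacer excluded) and a background base distribution,
# the number of matching positions in a random iid sequence is a sum of
# independent Bernoulli(pi_j) indicators with pi_j = background[template_j].
# Returns tail[k + 1] = P(X >= k), k = 0..14, by exact convolution.
match_tail_distribution <- function(template, background) {
  stopifnot(abs(sum(background) - 1) < 1e-9)
  bases <- strsplit(template, "")[[1]]
  pi <- unname(background[bases])
  if (any(is.na(pi))) stop("template base without background probability")
  dist <- 1  # P(X = 0) for zero positions
  for (p in pi) dist <- c(dist * (1 - p), 0) + c(0, dist * p)
  rev(cumsum(rev(dist)))
}

#' Match p-value for a di-motif occurrence with a given mismatch pair
#'
#' Tail probability that a random iid-background sequence matches the 14
#' constrained template positions (both PRE slots; the spacer is
#' unconstrained) in at least 14 - m1 - m2 positions. Computed by exact
#' convolution of the per-position Bernoulli match indicators; under a
#' uniform background this reduces to a binomial tail.
#'
#' @param m1,m2 Per-slot mismatch counts.
#' @param background Named base probabilities (A, C, G, T) summing to 1.
#' @param orientation Orientation whose template supplies the 14 bases
#'   (irrelevant under a uniform background).
#' @return Tail probability in (0, 1].
#' @export
match_pvalue <- function(m1, m2,
                         background = c(A = .25, C = .25, G = .25, T = .25),
                         orientation = "HT") {
  if (m1 + m2 > 2L * PRE_W) stop("m1 + m2 cannot exceed 14")
  tail <- match_tail_distribution(paste(dimotif_slots(orientation),
                                        collapse = ""), background)
  tail[2L * PRE_W - m1 - m2 + 1L]
}

#' Scan a sequence for PRE di-motif matches
#'
#' Every (configuration, offset, strand) whose two PRE slots each carry at
#' most `max_mm_per_pre` mismatches against the configuration template is
#' reported; spacer content is unconstrained. HT templates are stranded and
#' scanned on both strands; HH and TT templates are reverse-complement
#' invariant patterns and are scanned once, reported on the + strand.
#' `start` is the 0-based offset of the template on the match strand.
#'
#' @param seq A single sequence string (>= 14 nt) over \{A,C,G,T,N\}.
#' @param configs Configurations to scan, as from [enumerate_configs()].
#' @param max_mm_per_pre Per-slot mismatch tolerance, 0-3 (default 2).
#' @param region_id Label copied into the output.
#' @param background Background base probabilities for the match p-value.
#' @return data.frame with columns `region_id`, `strand`, `start`,
#'   `orientation`, `spacing`, `m1`, `m2`, `p` (no rows if nothing matches).
#' @export
scan_dimotifs <- function(seq, configs = enumerate_configs(100L),
                          max_mm_per_pre = 2L, region_id = "seq",
                          background = c(A = .25, C = .25, G = .25, T = .25)) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (!nzchar(seq)) stop("empty sequence")
  if (nchar(seq) < 2L * PRE_W) stop("sequence shorter than minimal template (14 nt)")
  if (max_mm_per_pre < 0L || max_mm_per_pre > 3L)
    stop("max_mm_per_pre must be between 0 and 3")
  if (nrow(configs) == 0L) stop("configs must be non-empty")
  seq <- toupper(seq)

  # per-strand mismatch profiles against the two PRE words
  strands <- list(`+` = seq, `-` = revcomp(seq))
  prof <- lapply(strands, function(s) {
    ch <- strsplit(s, "")[[1]]
    list(A = mismatch_profile(ch, PRE_F), R = mismatch_profile(ch, PRE_R))
  })
  tails <- lapply(stats::setNames(nm = c("HH", "HT", "TT")), function(o)
    match_tail_distribution(paste(dimotif_slots(o), collapse = ""), background))

  out <- vector("list", nrow(configs) * 2L)
  k <- 0L
  for (i in seq_len(nrow(configs))) {
    orient <- configs$orientation[i]
    s <- configs$spacing[i]
    slot_keys <- if (orient == "HT") c("A", "A")
                 else if (orient == "TT") c("R", "A") else c("A", "R")
    scan_strands <- if (orient == "HT") c("+", "-") else "+"
    for (strand in scan_strands) {
      p1 <- prof[[strand]][[slot_keys[1]]]
      p2 <- prof[[strand]][[slot_keys[2]]]
      nw <- length(p1)
      n_off <- nw - PRE_W - s  # number of valid template offsets
      if (n_off < 1L) next
      i1 <- seq_len(n_off)
      i2 <- i1 + PRE_W + s
      ok <- p1[i1] <= max_mm_per_pre & p2[i2] <= max_mm_per_pre
      if (!any(ok)) next
      m1 <- p1[i1][ok]; m2 <- p2[i2][ok]
      k <- k + 1L
      out[[k]] <- data.frame(
        region_id = region_id, strand = strand, start = i1[ok] - 1L,
        orientation = orient, spacing = s, m1 = m1, m2 = m2,
        p = tails[[orient]][2L * PRE_W - m1 - m2 + 1L],
        stringsAsFactors = FALSE)
    }
  }
  if (k == 0L)
    return(data.frame(region_id = character(0), strand = character(0),
                      start = integer(0), orientation = character(0),
                      spacing = integer(0), m1 = integer(0), m2 = integer(0),
                      p = numeric(0), stringsAsFactors = FALSE))
  res <- do.call(rbind, out[seq_len(k)])
  rownames(res) <- NULL
  res
}

#' Benjamini-Hochberg q-values for a table of di-motif matches
#'
#' The adjustment family is all matches produced by one scan (one region-set
#' invocation).
#'
#' @param matches Match table with a `p` column.
#' @return The table with a `q` column appended.
#' @export
assign_qvalues <- function(matches) {
  if (nrow(matches) == 0L) stop("empty match list")
  matches$q <- bh_adjust(matches$p)
  matches
}

#' Best di-motif match of a region
#'
#' Minimum q after filtering to matches with p at or below the threshold;
#' ties are broken by smaller total mismatches, then smaller spacing, then
#' leftmost start, then strand (+ before -).
#'
#' @param matches Match table for one region, with `q` assigned.
#' @param p_threshold Match-calling p-value cutoff (default 0.01).
#' @return One-row data.frame, or NULL if no match survives the filter.
#' @export
best_match <- function(matches, p_threshold = 0.01) {
  if (is.null(matches) || nrow(matches) == 0L) return(NULL)
  m <- matches[matches$p <= p_threshold, , drop = FALSE]
  if (nrow(m) == 0L) return(NULL)
  ord <- order(m$q, m$m1 + m$m2, m$spacing, m$start,
               match(m$strand, c("+", "-")))
  m[ord[1L], , drop = FALSE]
}

#' Sorted mismatch-pair category label
#'
#' Order-invariant: (1,2) and (2,1) both give "1_2"; "0_0" means no
#' mismatch in either PRE.
#'
#' @param m1,m2 Per-slot mismatch counts (vectorised).
#' @return Character vector of labels.
#' @export
mismatch_category <- function(m1, m2) {
  paste(pmin(m1, m2), pmax(m1, m2), sep = "_")
}

#' Find exact PRE occurrences on both strands
#'
#' Minus-strand occurrences (TGTTTCA on the top strand) are reported at
#' their top-strand coordinates.
#'
#' @param seq Sequence string.
#' @return data.frame with columns `start` (0-based, top strand) and
#'   `strand`.
#' @export
find_perfect_pre <- function(seq) {
  seq <- toupper(seq)
  ch <- strsplit(seq, "")[[1]]
  fwd <- which(mismatch_profile(ch, PRE_F) == 0L) - 1L
  rev_ <- which(mismatch_profile(ch, PRE_R) == 0L) - 1L
  out <- data.frame(start = c(fwd, rev_),
                    strand = rep(c("+", "-"), c(length(fwd), length(rev_))),
                    stringsAsFactors = FALSE)
  out[order(out$start, out$strand), , drop = FALSE]
}

#' Per-position base counts of aligned motif sequences
#'
#' Input sequences must be equal length and oriented so both PRE slots read
#' in the consensus direction (e.g. the 18-mers of curated H-T 4 matches).
#'
#' @param seqs Character vector of equal-length sequences over ACGT.
#' @return 4 x W integer matrix with rows A, C, G, T; every column sums to
#'   `length(seqs)`.
#' @export
build_count_matrix <- function(seqs) {
  stopifnot(length(seqs) > 0L)
  w <- unique(nchar(seqs))
  if (length(w) != 1L) stop("sequences must be equal length")
  if (any(grepl("[^ACGT]", seqs))) stop("count matrix input must be ACGT only")
  m <- matrix(0L, nrow = 4L, ncol = w, dimnames = list(c("A", "C", "G", "T")))
  chars <- do.call(rbind, strsplit(seqs, ""))
  for (b in rownames(m)) m[b, ] <- colSums(chars == b)
  m
}

#' Convert base counts to a position-specific probability matrix
#'
#' @param counts 4 x W count matrix (rows A, C, G, T).
#' @return 4 x W matrix with unit column sums.
#' @export
counts_to_pspm <- function(counts) {
  sweep(counts, 2L, colSums(counts), "/")
}

#' Convert a PSPM to a position-specific affinity matrix
#'
#' Per position, affinities are (p + epsilon) / max(p + epsilon), so the
#' most probable base has affinity exactly 1.
#'
#' @param pspm 4 x W probability matrix (columns sum to 1).
#' @param epsilon Regularising pseudoprobability (default 0). With
#'   `epsilon = 0`, positions with zero-probability bases yield zero
#'   affinities and are flagged with a warning.
#' @return 4 x W affinity matrix with per-position maxima of exactly 1.
#' @export
pspm_to_psam <- function(pspm, epsilon = 0) {
  stopifnot(epsilon >= 0, nrow(pspm) == 4L)
  if (any(abs(colSums(pspm) - 1) > 1e-9)) stop("PSPM columns must sum to 1")
  x <- pspm + epsilon
  mx <- apply(x, 2L, max)
  if (any(mx == 0)) stop("all-zero PSPM column with epsilon = 0")
  if (epsilon == 0 && any(pspm == 0))
    warning("PSAM contains zero affinities; consider epsilon > 0")
  sweep(x, 2L, mx, "/")
}

#' One-hot PSAM for a fixed sequence
#'
#' Convenience constructor: affinity 1 for the template base, `off` for the
#' other bases, at every position.
#'
#' @param seq Template string over ACGT.
#' @param off Affinity of non-template bases (default 0.25).
#' @return 4 x nchar(seq) affinity matrix.
#' @export
psam_from_sequence <- function(seq, off = 0.25) {
  bases <- strsplit(toupper(seq), "")[[1]]
  stopifnot(all(bases %in% c("A", "C", "G", "T")), off >= 0, off <= 1)
  m <- matrix(off, nrow = 4L, ncol = length(bases),
              dimnames = list(c("A", "C", "G", "T")))
  m[cbind(match(bases, rownames(m)), seq_along(bases))] <- 1
  m
}

#' Write motif matrices in MEME minimal format
#'
#' @param motifs Named list of 4 x W matrices (rows A, C, G, T). PSPMs are
#'   written as letter-probability matrices; PSAMs share the same block
#'   layout.
#' @param path Output path.
#' @param background Background frequencies recorded in the header.
#' @return Invisibly, `path`.
#' @export
write_meme_motifs <- function(motifs, path,
                              background = c(A = .25, C = .25, G = .25, T = .25)) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "", "strands: + -", "",
               "Background letter frequencies",
               paste(sprintf("%s %.5f", names(background), background),
                     collapse = " "), ""), con)
  for (nm in names(motifs)) {
    m <- motifs[[nm]]
    writeLines(c(paste("MOTIF", nm),
                 sprintf("letter-probability matrix: alength= 4 w= %d", ncol(m))),
               con)
    writeLines(apply(m, 2L, function(col) paste(sprintf("%.6f", col),
                                                collapse = " ")), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read motif matrices from MEME minimal format
#'
#' @param path Path written by [write_meme_motifs()] or any MEME minimal
#'   motif file.
#' @return Named list of 4 x W matrices with rows A, C, G, T.
#' @export
read_meme_motifs <- function(path) {
  lines <- readLines(path)
  starts <- grep("^MOTIF ", lines)
  if (length(starts) == 0L) stop("no MOTIF blocks in ", path)
  out <- list()
  for (s in starts) {
    nm <- sub("^MOTIF\\s+(\\S+).*$", "\\1", lines[s])
    hdr <- s + 1L
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[hdr]))
    rows <- lines[(hdr + 1L):(hdr + w)]
    m <- t(vapply(strsplit(trimws(rows), "\\s+"),
                  function(x) as.numeric(x), numeric(4)))
    out[[nm]] <- matrix(t(m), nrow = 4L,
                        dimnames = list(c("A", "C", "G", "T")))
  }
  out
}
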