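#' Expand and merge binding sites into scan regions
#'
#' Each site point expands to a symmetric window of `half_width` on each
#' side (2 * half_width + 1 bases). Sites on one chromosome whose points lie
#' within `merge_gap` of each other are merged into one region spanning
#' `half_width` upstream of the first site to `half_width` downstream of the
#' last, to avoid scanning duplicated sequence. Regions are clamped to
#' chromosome bounds.
#'
#' @param sites data.frame with columns `chrom`, `point` (0-based) and
#'   optionally `site_id`.
#' @param half_width Half window size in bp (e.g. 120 for 241 bp regions).
#' @param merge_gap Maximum distance between site points to merge
#'   (default 60).
#' @param genome Named character vector of chromosome sequences (names are
#'   chromosome ids), used for clamping.
#' @return data.frame with columns `chrom`, `start`, `end`, `id` (ids of
#'   merged sites joined with "|"), 0-based half-open.
#' @export
prepare_regions <- function(sites, half_width, merge_gap = 60L, genome) {
  stopifnot(half_width > 0L, all(c("chrom", "point") %in% names(sites)))
  if (is.null(sites$site_id))
    sites$site_id <- paste0("site_", seq_len(nrow(sites)))
  chrom_len <- nchar(genome)
  if (any(!sites$chrom %in% names(genome)))
    stop("site chromosome not in genome")
  if (any(sites$point >= chrom_len[sites$chrom] | sites$point < 0L))
    stop("site beyond chromosome end")
  sites <- sites[order(sites$chrom, sites$point), , drop = FALSE]
  out <- list(); k <- 0L
  for (chr in unique(sites$chrom)) {
    s <- sites[sites$chrom == chr, , drop = FALSE]
    grp <- cumsum(c(1L, diff(s$point) > merge_gap))
    for (g in unique(grp)) {
      pts <- s$point[grp == g]
      k <- k + 1L
      out[[k]] <- data.frame(
        chrom = chr,
        start = max(0L, min(pts) - as.integer(half_width)),
        end = min(chrom_len[[chr]], max(pts) + as.integer(half_width) + 1L),
        id = paste(s$site_id[grp == g], collapse = "|"),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Extract region sequences from a genome
#'
#' @param regions data.frame with `chrom`, `start`, `end`, `id` (0-based
#'   half-open).
#' @param genome Named character vector of chromosome sequences.
#' @return Named character vector keyed by region id.
#' @export
region_sequences <- function(regions, genome) {
  stopifnot(all(regions$chrom %in% names(genome)))
  out <- substring(genome[regions$chrom], regions$start + 1L, regions$end)
  names(out) <- regions$id
  out
}

#' Scan a set of regions for PRE di-motifs and assign best matches
#'
#' All matches from the whole region set form one Benjamini-Hochberg family
#' (one scan invocation). Each region receives a best match by lowest
#' q-value (ties: fewer total mismatches, smaller spacing, leftmost,
#' + strand first) among matches with p at or below `match_p_threshold`;
#' regions with no surviving match are retained with NA best so they stay in
#' the denominators of downstream summaries.
#'
#' @param regions Region table from [prepare_regions()].
#' @param genome Named character vector of chromosome sequences.
#' @param configs Configurations to scan.
#' @param max_mm_per_pre Per-slot mismatch tolerance.
#' @param match_p_threshold Match-calling p cutoff (default 0.01).
#' @param background Background base probabilities.
#' @return List with `matches` (all matches with q), `best` (one row per
#'   region; NA columns when no match survives) and `ranked` (named list:
#'   per region, the per-configuration best matches ordered by rank).
#' @export
scan_region_set <- function(regions, genome, configs = enumerate_configs(100L),
                            max_mm_per_pre = 2L, match_p_threshold = 0.01,
                            background = c(A = .25, C = .25, G = .25, T = .25)) {
  seqs <- region_sequences(regions, genome)
  if (any(nchar(seqs) < 14L)) stop("region shorter than minimal template")
  all_matches <- do.call(rbind, lapply(names(seqs), function(id)
    scan_dimotifs(seqs[[id]], configs, max_mm_per_pre, region_id = id,
                  background = background)))
  if (is.null(all_matches) || nrow(all_matches) == 0L) {
    all_matches <- data.frame(region_id = character(0), strand = character(0),
                              start = integer(0), orientation = character(0),
                              spacing = integer(0), m1 = integer(0),
                              m2 = integer(0), p = numeric(0), q = numeric(0))
  } else {
    all_matches <- assign_qvalues(all_matches)
  }
  na_best <- data.frame(strand = NA_character_, start = NA_integer_,
                        orientation = NA_character_, spacing = NA_integer_,
                        m1 = NA_integer_, m2 = NA_integer_, p = NA_real_,
                        q = NA_real_, stringsAsFactors = FALSE)
  best <- do.call(rbind, lapply(regions$id, function(id) {
    b <- best_match(all_matches[all_matches$region_id == id, , drop = FALSE],
                    match_p_threshold)
    if (is.null(b)) cbind(data.frame(region_id = id), na_best)
    else b[, c("region_id", names(na_best))]
  }))
  rownames(best) <- NULL
  ranked <- lapply(stats::setNames(nm = regions$id), function(id)
    rank_configs(all_matches[all_matches$region_id == id, , drop = FALSE],
                 match_p_threshold))
  list(matches = all_matches, best = best, ranked = ranked)
}

#' Rank configurations of one region by their best surviving match
#'
#' One entry per configuration (that configuration's best match in the
#' region), ordered by the [best_match()] tie-break chain.
#'
#' @param matches Match table of one region with `q` assigned.
#' @param p_threshold Match-calling p cutoff.
#' @return data.frame of per-configuration best matches, best first.
#' @export
rank_configs <- function(matches, p_threshold = 0.01) {
  m <- matches[matches$p <= p_threshold, , drop = FALSE]
  if (nrow(m) == 0L) return(m)
  key <- paste(m$orientation, m$spacing)
  per_cfg <- do.call(rbind, lapply(split(m, key), best_match,
                                   p_threshold = p_threshold))
  ord <- order(per_cfg$q, per_cfg$m1 + per_cfg$m2, per_cfg$spacing,
               per_cfg$start, match(per_cfg$strand, c("+", "-")))
  out <- per_cfg[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Histogram of best di-motif configurations
#'
#' @param best Best-match table from [scan_region_set()].
#' @return data.frame with `orientation`, `spacing`, `count`, sorted by
#'   count descending; regions with no best match are excluded from the
#'   counts (but not from the region total).
#' @export
config_histogram <- function(best) {
  b <- best[!is.na(best$orientation), , drop = FALSE]
  if (nrow(b) == 0L)
    return(data.frame(orientation = character(0), spacing = integer(0),
                      count = integer(0)))
  tab <- stats::aggregate(list(count = b$spacing),
                          by = list(orientation = b$orientation,
                                    spacing = b$spacing), FUN = length)
  tab <- tab[order(-tab$count, tab$orientation, tab$spacing), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Is a configuration among a region's top-k ranked configurations?
#'
#' @param ranked Ranked per-configuration table of one region (an element of
#'   `scan_region_set()$ranked`).
#' @param orientation,spacing Queried configuration.
#' @param k Number of top configurations considered (default 5).
#' @return TRUE if the configuration appears among the k lowest-q
#'   configurations.
#' @export
topk_contains <- function(ranked, orientation, spacing, k = 5L) {
  if (k < 1L) stop("k must be >= 1")
  if (is.null(ranked) || nrow(ranked) == 0L) return(FALSE)
  top <- ranked[seq_len(min(k, nrow(ranked))), , drop = FALSE]
  any(top$orientation == orientation & top$spacing == spacing)
}

#' Curated H-T 4 match selection, one 18-mer per site
#'
#' For each site, H-T 4 matches with at most `max_mm_per_pre` mismatches in
#' either PRE and whose 18-mer centre lies within `max_center_dist` of the
#' site point are considered; the best-ranked one is kept. Sites with no
#' qualifying match contribute nothing. The returned 18-mer reads both PRE
#' slots in the consensus direction (minus-strand matches are reverse
#' complemented).
#'
#' @param matches Match table with `q` (whole region set).
#' @param regions Region table the matches refer to.
#' @param sites Site table (`chrom`, `point`, optional `site_id`).
#' @param genome Named character vector of chromosome sequences.
#' @param max_mm_per_pre Curation mismatch cap (default 2).
#' @param max_center_dist Maximum distance from 18-mer centre to site point
#'   (default 100).
#' @return data.frame with `site_id`, `chrom`, `start` (top-strand, 0-based),
#'   `strand`, `m1`, `m2`, `category`, `seq` (the 18-mer).
#' @export
curated_ht4_filter <- function(matches, regions, sites, genome,
                               max_mm_per_pre = 2L, max_center_dist = 100L) {
  if (is.null(sites$site_id))
    sites$site_id <- paste0("site_", seq_len(nrow(sites)))
  tmpl_len <- 18L  # 7 + 4 + 7
  m <- matches[matches$orientation == "HT" & matches$spacing == 4L &
               matches$m1 <= max_mm_per_pre & matches$m2 <= max_mm_per_pre, ,
               drop = FALSE]
  out <- list(); k <- 0L
  for (i in seq_len(nrow(sites))) {
    reg <- regions[regions$chrom == sites$chrom[i] &
                   regions$start <= sites$point[i] &
                   regions$end > sites$point[i], , drop = FALSE]
    if (nrow(reg) == 0L) next
    reg <- reg[1L, ]
    cand <- m[m$region_id == reg$id, , drop = FALSE]
    if (nrow(cand) == 0L) next
    # top-strand chromosome coordinate of the 18-mer
    cand$chrom_start <- ifelse(cand$strand == "+",
                               reg$start + cand$start,
                               reg$end - cand$start - tmpl_len)
    centre <- cand$chrom_start + (tmpl_len - 1L) / 2
    cand <- cand[abs(centre - sites$point[i]) <= max_center_dist, ,
                 drop = FALSE]
    if (nrow(cand) == 0L) next
    b <- best_match(cand, p_threshold = 1)
    s18 <- substring(genome[[sites$chrom[i]]], b$chrom_start + 1L,
                     b$chrom_start + tmpl_len)
    if (b$strand == "-") s18 <- revcomp(s18)
    k <- k + 1L
    out[[k]] <- data.frame(site_id = sites$site_id[i], chrom = sites$chrom[i],
                           start = b$chrom_start, strand = b$strand,
                           m1 = b$m1, m2 = b$m2,
                           category = mismatch_category(b$m1, b$m2),
                           seq = s18, stringsAsFactors = FALSE)
  }
  if (k == 0L)
    return(data.frame(site_id = character(0), chrom = character(0),
                      start = integer(0), strand = character(0),
                      m1 = integer(0), m2 = integer(0),
                      category = character(0), seq = character(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-class mismatch-category spectrum
#'
#' Fractions of sites per mismatch category, computed independently within
#' each class (each class's fractions sum to 1).
#'
#' @param categories Character vector of mismatch category labels (e.g.
#'   from [mismatch_category()]), one per site.
#' @param class_labels Class label per site (no NAs).
#' @return data.frame with `class`, `category`, `n`, `fraction`.
#' @export
mismatch_spectrum <- function(categories, class_labels) {
  if (length(categories) != length(class_labels))
    stop("categories and class_labels must align")
  if (any(is.na(class_labels))) stop("unlabeled match")
  tab <- as.data.frame(table(class = class_labels, category = categories),
                       stringsAsFactors = FALSE)
  names(tab)[3] <- "n"
  tab <- tab[tab$n > 0L, , drop = FALSE]
  totals <- tapply(tab$n, tab$class, sum)
  tab$fraction <- tab$n / as.numeric(totals[tab$class])
  tab <- tab[order(tab$class, tab$category), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}
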