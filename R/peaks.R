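#' Associate binding peaks with nearby gene and LTR feature starts
#'
#' Every feature start within `window` bp of the peak point (in either
#' direction, regardless of strand) yields an association, so bidirectional
#' promoters give one peak two gene associations. A peak whose nearest
#' associated feature start is an LTR, or whose point lies inside a supplied
#' LTR interval, is flagged LTR-associated; the flag is propagated to all of
#' that peak's gene associations for downstream filtering.
#'
#' @param peaks data.frame with columns `peak_id`, `chrom`, `point`.
#' @param feature_starts data.frame from [read_feature_starts()].
#' @param window Maximum association distance in bp (default 500).
#' @param ltr_regions Optional data.frame (`chrom`, `start`, `end`, 0-based
#'   half-open) of LTR feature bodies for the inside-an-LTR rule.
#' @return data.frame with `peak_id`, `feature_id`, `feature_type`,
#'   `distance`, `ltr_flag`.
#' @export
associate_peaks <- function(peaks, feature_starts, window = 500L,
                            ltr_regions = NULL) {
  stopifnot(all(c("peak_id", "chrom", "point") %in% names(peaks)))
  out <- list(); k <- 0L
  for (i in seq_len(nrow(peaks))) {
    f <- feature_starts[feature_starts$chrom == peaks$chrom[i], , drop = FALSE]
    if (nrow(f) == 0L) next
    d <- abs(f$pos - peaks$point[i])
    hit <- d <= window
    if (!any(hit)) next
    nearest_is_ltr <- f$feature_type[which.min(d)] == "LTR"
    inside_ltr <- FALSE
    if (!is.null(ltr_regions)) {
      lr <- ltr_regions[ltr_regions$chrom == peaks$chrom[i], , drop = FALSE]
      inside_ltr <- any(lr$start <= peaks$point[i] & peaks$point[i] < lr$end)
    }
    flag <- nearest_is_ltr || inside_ltr || any(f$feature_type[hit] == "LTR")
    k <- k + 1L
    out[[k]] <- data.frame(peak_id = peaks$peak_id[i],
                           feature_id = f$feature_id[hit],
                           feature_type = f$feature_type[hit],
                           distance = d[hit],
                           ltr_flag = nearest_is_ltr || inside_ltr,
                           any_ltr_in_window = flag,
                           stringsAsFactors = FALSE)
  }
  if (k == 0L)
    return(data.frame(peak_id = character(0), feature_id = character(0),
                      feature_type = character(0), distance = integer(0),
                      ltr_flag = logical(0), any_ltr_in_window = logical(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-gene statistics from the most significant associated peak
#'
#' When several peaks associate with one gene, the statistics (occupancy,
#' fold-change, Q-value, ...) are copied from the peak with the lowest
#' Q-value (most negative `logQ`); ties are broken by higher occupancy,
#' then leftmost coordinate, making the choice invariant to input order.
#' A gene with any LTR-flagged peak is itself flagged.
#'
#' @param associations Output of [associate_peaks()].
#' @param peaks The peak table; must contain `peak_id`, `point`, `logQ` and
#'   an `occupancy` column (plus any further statistic columns, which are
#'   copied through).
#' @return data.frame with one row per gene: `gene`, `n_peaks`,
#'   `ltr_flag`, and all columns of the selected peak.
#' @export
gene_peak_stats <- function(associations, peaks) {
  stopifnot(all(c("peak_id", "point", "logQ", "occupancy") %in% names(peaks)))
  ga <- associations[associations$feature_type == "gene", , drop = FALSE]
  out <- lapply(split(ga, ga$feature_id), function(a) {
    pk <- peaks[peaks$peak_id %in% a$peak_id, , drop = FALSE]
    ord <- order(pk$logQ, -pk$occupancy, pk$point)
    sel <- pk[ord[1L], , drop = FALSE]
    cbind(data.frame(gene = a$feature_id[1L], n_peaks = nrow(pk),
                     ltr_flag = any(a$ltr_flag), stringsAsFactors = FALSE),
          sel)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Region occupancy in reads per million (RPM)
#'
#' Tags (single-base read positions) are summed over the region across both
#' strands (and across replicates, if several coverage tables are given:
#' counts are summed before scaling), then divided by the library scale
#' factor.
#'
#' @param tag_coverage A bedGraph-style data.frame (`chrom`, `start`, `end`,
#'   `count`; per-base tag counts) or a list of them (strands/replicates to
#'   pool).
#' @param region One-row data.frame or list with `chrom`, `start`, `end`
#'   (0-based half-open).
#' @param library_scale Total tags / 1e6 (pooled across whatever is being
#'   summed); must be positive.
#' @return Non-negative RPM value.
#' @export
occupancy_rpm <- function(tag_coverage, region, library_scale) {
  if (library_scale <= 0) stop("zero or negative library size")
  if (is.data.frame(tag_coverage)) tag_coverage <- list(tag_coverage)
  total <- 0
  for (cov in tag_coverage) {
    cv <- cov[cov$chrom == region$chrom, , drop = FALSE]
    if (nrow(cv) == 0L) next
    ov <- pmin(cv$end, region$end) - pmax(cv$start, region$start)
    total <- total + sum(cv$count[ov > 0] * ov[ov > 0])
  }
  total / library_scale
}

#' Compare occupancy distributions between two groups
#'
#' Group means with 95 percent confidence intervals (t-based or bootstrap)
#' and a two-sided Mann-Whitney U test (exact for small samples).
#'
#' @param group_a,group_b Numeric vectors (non-empty).
#' @param ci `"t"` (default) or `"bootstrap"`.
#' @param n_boot Bootstrap replicates when `ci = "bootstrap"`.
#' @return List with `mean_a`, `mean_b`, `ci_a`, `ci_b`, `U`, `p`.
#' @export
compare_occupancy <- function(group_a, group_b, ci = c("t", "bootstrap"),
                              n_boot = 2000L) {
  ci <- match.arg(ci)
  if (length(group_a) == 0L || length(group_b) == 0L)
    stop("both groups must be non-empty")
  ci_of <- function(x) {
    if (length(x) < 2L) return(c(NA_real_, NA_real_))
    if (ci == "t") {
      se <- stats::sd(x) / sqrt(length(x))
      mean(x) + c(-1, 1) * stats::qt(0.975, length(x) - 1L) * se
    } else {
      means <- replicate(n_boot, mean(sample(x, replace = TRUE)))
      unname(stats::quantile(means, c(0.025, 0.975)))
    }
  }
  mw <- mann_whitney(group_a, group_b)
  list(mean_a = mean(group_a), mean_b = mean(group_b),
       ci_a = ci_of(group_a), ci_b = ci_of(group_b), U = mw$U, p = mw$p)
}

#' Occupancy distributions by di-motif mismatch category
#'
#' Splits per-site occupancies by sorted mismatch category and performs all
#' pairwise Mann-Whitney comparisons with Benjamini-Hochberg correction
#' (no tests when only one category is present).
#'
#' @param occupancy Numeric vector of per-site occupancies (RPM).
#' @param categories Mismatch category label per site (e.g. "0_0", "1_2").
#' @return List with `distributions` (named list of occupancy vectors) and
#'   `tests` (data.frame `cat_a`, `cat_b`, `U`, `p`, `q`).
#' @export
occupancy_vs_mismatch <- function(occupancy, categories) {
  stopifnot(length(occupancy) == length(categories))
  dists <- split(occupancy, categories)
  cats <- names(dists)
  if (length(cats) < 2L)
    return(list(distributions = dists,
                tests = data.frame(cat_a = character(0), cat_b = character(0),
                                   U = numeric(0), p = numeric(0),
                                   q = numeric(0))))
  pairs <- utils::combn(cats, 2L)
  tests <- do.call(rbind, apply(pairs, 2L, function(pr) {
    mw <- mann_whitney(dists[[pr[1]]], dists[[pr[2]]])
    data.frame(cat_a = pr[1], cat_b = pr[2], U = mw$U, p = mw$p,
               stringsAsFactors = FALSE)
  }))
  tests$q <- bh_adjust(tests$p)
  rownames(tests) <- NULL
  list(distributions = dists, tests = tests)
}
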