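# Base index vector (1..5; 5 = N) for one sequence.
base_index <- function(seq) {
  match(strsplit(seq, "")[[1]], c("A", "C", "G", "T", "N"))
}

# Sum over all windows of one strand of prod_j A[j](base_{i+j}); `logA` is
# a 5 x W matrix of log affinities, row 5 the N-policy value. -Inf log
# affinities (true zeros) propagate to window affinity 0.
strand_affinity <- function(idx, logA) {
  W <- ncol(logA)
  n_win <- length(idx) - W + 1L
  if (n_win < 1L) return(0)
  acc <- numeric(n_win)
  for (j in seq_len(W)) acc <- acc + logA[idx[j:(j + n_win - 1L)], j]
  sum(exp(acc))
}

#' Summed promoter affinities for a set of PSAMs
#'
#' N_mg = sum over all windows on both strands of the product of
#' per-position relative affinities. Positions reading N contribute, under
#' the default policy, the background-weighted mean affinity of their PSAM
#' column; with `n_policy = "skip"` any window containing N contributes 0.
#' Promoters shorter than a PSAM get affinity 0 for it, with a warning.
#'
#' @param psams Named list of 4 x W affinity matrices (rows A, C, G, T;
#'   per-position maximum 1).
#' @param promoters Named character vector of promoter sequences.
#' @param n_policy `"background"` (default) or `"skip"`.
#' @param background Base probabilities used by the background N policy.
#' @return Genes x motifs matrix of summed affinities.
#' @export
promoter_affinity <- function(psams, promoters,
                              n_policy = c("background", "skip"),
                              background = c(A = .25, C = .25, G = .25, T = .25)) {
  n_policy <- match.arg(n_policy)
  stopifnot(length(psams) > 0L, !is.null(names(psams)),
            length(promoters) > 0L, !is.null(names(promoters)))
  idx_fwd <- lapply(promoters, base_index)
  idx_rev <- lapply(revcomp(promoters), base_index)
  N <- matrix(0, nrow = length(promoters), ncol = length(psams),
              dimnames = list(names(promoters), names(psams)))
  short_warned <- FALSE
  for (m in names(psams)) {
    A <- psams[[m]]
    stopifnot(nrow(A) == 4L)
    n_val <- if (n_policy == "background") colSums(A * background) else
      rep(0, ncol(A))
    logA <- log(rbind(A, N = n_val))
    for (g in seq_along(promoters)) {
      if (length(idx_fwd[[g]]) < ncol(A)) {
        if (!short_warned) {
          warning("promoter(s) shorter than PSAM width; affinity set to 0")
          short_warned <- TRUE
        }
        next
      }
      N[g, m] <- strand_affinity(idx_fwd[[g]], logA) +
        strand_affinity(idx_rev[[g]], logA)
    }
  }
  N
}

#' Fit motif activities by multivariate least squares
#'
#' Ordinary least squares of a per-gene response (e.g. shrunk log2
#' fold-changes) on the summed promoter affinities of all motifs jointly,
#' with intercept. Collinear (aliased) columns are dropped with a warning;
#' a zero-residual-variance fit (constant response) yields NA p-values with
#' a warning.
#'
#' @param N Genes x motifs affinity matrix from [promoter_affinity()].
#' @param y Per-gene response aligned to `rownames(N)`.
#' @return data.frame with `motif`, `beta`, `t`, `p`, `signed_logp`.
#' @export
fit_activity <- function(N, y) {
  stopifnot(nrow(N) == length(y))
  if (nrow(N) <= ncol(N)) stop("need more genes than motifs")
  df <- data.frame(y = y, N, check.names = FALSE)
  fit <- stats::lm(y ~ ., data = df)
  sm <- suppressWarnings(summary(fit))
  co <- sm$coefficients
  rownames(co) <- gsub("^`|`$", "", rownames(co))
  aliased <- setdiff(colnames(N), rownames(co))
  if (length(aliased) > 0L)
    warning("dropped collinear motif column(s): ",
            paste(aliased, collapse = ", "))
  keep <- intersect(colnames(N), rownames(co))
  beta <- co[keep, "Estimate"]
  tval <- co[keep, "t value"]
  pval <- co[keep, "Pr(>|t|)"]
  if (any(!is.finite(tval)) ||
      sm$sigma < 1e-10 * max(1, stats::sd(y))) {
    warning("zero residual variance; p-values unavailable")
    pval[] <- NA_real_
  }
  out <- data.frame(motif = keep, beta = unname(beta), t = unname(tval),
                    p = unname(pval), stringsAsFactors = FALSE)
  out$signed_logp <- signed_logp(out$beta, out$p)
  rownames(out) <- NULL
  out
}

#' Signed log10 p-value
#'
#' The direction (sign) of the fitted coefficient applied to -log10(p).
#' p = 0 is clamped to the smallest representable double with a warning.
#'
#' @param beta Fitted coefficients.
#' @param p Two-sided p-values in (0, 1] (NA passes through as NA).
#' @return sign(beta) * (-log10(p)).
#' @export
signed_logp <- function(beta, p) {
  if (any(!is.na(p) & p == 0)) {
    warning("p = 0 clamped to smallest representable double")
    p[!is.na(p) & p == 0] <- .Machine$double.xmin
  }
  sign(beta) * (-log10(p))
}

#' Rescale coefficients so the largest absolute value is 1
#'
#' The rescaling family is typically all samples for one motif.
#'
#' @param x Numeric vector of coefficients (not all zero).
#' @return x / max(abs(x)).
#' @export
rescale_coefficients <- function(x) {
  mx <- max(abs(x), na.rm = TRUE)
  if (!is.finite(mx) || mx == 0) stop("all-zero coefficient family")
  x / mx
}

#' Per-sample motif activities from a log2 fold-change matrix
#'
#' Fits [fit_activity()] independently for every sample column, then
#' rescales each motif's coefficients across samples so the largest
#' absolute value is 1.
#'
#' @param N Genes x motifs affinity matrix.
#' @param lfc Genes x samples log2 fold-change matrix (e.g. from
#'   [logfc_matrix()]), rows aligned to `N`.
#' @return data.frame with `motif`, `sample`, `beta`, `t`, `p`,
#'   `signed_logp`, `rescaled_beta`.
#' @export
activity_per_sample <- function(N, lfc) {
  stopifnot(nrow(N) == nrow(lfc))
  fits <- do.call(rbind, lapply(colnames(lfc), function(s) {
    f <- fit_activity(N, lfc[, s])
    f$sample <- s
    f
  }))
  fits$rescaled_beta <- NA_real_
  for (m in unique(fits$motif)) {
    i <- fits$motif == m
    fits$rescaled_beta[i] <- rescale_coefficients(fits$beta[i])
  }
  fits[, c("motif", "sample", "beta", "t", "p", "signed_logp",
           "rescaled_beta")]
}

#' F-test comparing nested activity models
#'
#' Compares the full fit on all motif columns against a reduced fit with
#' some motifs removed, testing whether the removed motifs contribute.
#'
#' @param N Genes x motifs affinity matrix.
#' @param y Per-gene response.
#' @param drop Motif names removed in the reduced model.
#' @return List with `F`, `df1`, `df2`, `p`.
#' @export
activity_reduced_model_test <- function(N, y, drop) {
  stopifnot(all(drop %in% colnames(N)))
  full <- stats::lm(y ~ ., data = data.frame(y = y, N, check.names = FALSE))
  reduced <- stats::lm(y ~ ., data = data.frame(
    y = y, N[, setdiff(colnames(N), drop), drop = FALSE], check.names = FALSE))
  a <- stats::anova(reduced, full)
  list(F = a$F[2L], df1 = a$Df[2L], df2 = a$Res.Df[2L], p = a$`Pr(>F)`[2L])
}
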