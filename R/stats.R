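#' Upper-tail hypergeometric enrichment probability
#'
#' P(X >= k_obs) for X ~ Hypergeometric(N_pop, K_succ, n_draw): the
#' probability of observing at least `k_obs` members of a K-sized attribute
#' class when drawing a set of `n_draw` genes from a population of `N_pop`.
#'
#' @param k_obs Observed successes in the drawn set.
#' @param K_succ Successes in the population.
#' @param n_draw Size of the drawn set.
#' @param N_pop Population size.
#' @return Upper-tail probability.
#' @export
hypergeom_tail <- function(k_obs, K_succ, n_draw, N_pop) {
  stopifnot(K_succ <= N_pop, n_draw <= N_pop,
            k_obs >= 0, k_obs <= min(K_succ, n_draw))
  stats::phyper(k_obs - 1, K_succ, N_pop - K_succ, n_draw,
                lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p Vector of p-values in [0, 1].
#' @return Adjusted p-values (monotone, capped at 1), in input order.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

# Mann-Whitney U statistic of x against pooled midranks.
mwu_stat <- function(rank_sum_x, n_x) rank_sum_x - n_x * (n_x + 1) / 2

#' Mann-Whitney U test (exact with midranks, or normal approximation)
#'
#' Two-sided test of distributional difference between two samples. In
#' `exact` mode the permutation distribution of U over all group
#' relabellings is enumerated with midranks, so ties are handled exactly;
#' `auto` uses enumeration when n_x + n_y <= 20 and otherwise the normal
#' approximation with tie correction and continuity correction omitted.
#'
#' @param x,y Numeric samples, both non-empty.
#' @param mode `"auto"`, `"exact"` or `"normal"`.
#' @return List with elements `U` (statistic of `x`) and `p` (two-sided).
#' @export
mann_whitney <- function(x, y, mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  if (length(x) == 0L || length(y) == 0L) stop("both groups must be non-empty")
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  U <- mwu_stat(sum(r[seq_len(nx)]), nx)
  if (mode == "auto") mode <- if (nx + ny <= 20L) "exact" else "normal"
  if (mode == "exact") {
    # Permutation distribution of U: symmetric about nx * ny / 2 under
    # exchangeability (choosing the x-group of a split is the mirror of
    # choosing the y-group), so the two-sided p-value is the mass at or
    # beyond the observed distance from the centre.
    combs <- utils::combn(nx + ny, nx)
    Us <- apply(combs, 2L, function(idx) mwu_stat(sum(r[idx]), nx))
    centre <- nx * ny / 2
    p <- mean(abs(Us - centre) >= abs(U - centre) - 1e-12)
  } else {
    mu <- nx * ny / 2
    n <- nx + ny
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- nx * ny / 12 * (n + 1 - tie_term)
    if (sigma2 <= 0) return(list(U = U, p = 1))
    z <- (U - mu) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  list(U = U, p = p)
}
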