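# Exact and rank-based group-comparison statistics.

#' Exact r x c Fisher test of independence
#'
#' Two-sided exact test by full enumeration of the fibre of non-negative
#' integer tables sharing the observed row and column margins. Under the
#' multivariate hypergeometric null, the p-value is the total probability of
#' all tables whose probability does not exceed that of the observed table
#' (probability-mass ordering, the conventional two-sided definition; tables
#' tied with the observed probability up to a small relative tolerance are
#' counted in). Enumeration is recursive and margin-constrained, feasible for
#' the small cohort tables this test is meant for.
#'
#' @param tab Matrix (at least 2 x 2) of non-negative integer counts.
#' @return Two-sided p-value. Degenerate tables (any zero row or column
#'   margin) return 1.
#' @export
fisher_exact <- function(tab) {
  tab <- as.matrix(tab)
  if (nrow(tab) < 2L || ncol(tab) < 2L) stop("need at least a 2 x 2 table")
  if (any(tab < 0) || any(tab != round(tab))) stop("counts must be non-negative integers")
  rs <- rowSums(tab); cs <- colSums(tab)
  if (any(rs == 0) || any(cs == 0)) return(1)
  n <- sum(tab)
  lconst <- sum(lgamma(rs + 1)) + sum(lgamma(cs + 1)) - lgamma(n + 1)
  logp_obs <- lconst - sum(lgamma(tab + 1))
  psum <- 0
  tol <- 1e-7
  r <- length(rs); cc <- length(cs)

  # enumerate compositions of `total` into cells bounded by `caps`,
  # accumulating -sum(lgamma(x+1)); at the last row the cells are forced.
  rec_row <- function(row, rem_cols, lacc) {
    if (row == r) {
      lp <- lconst + lacc - sum(lgamma(rem_cols + 1))
      if (lp <= logp_obs + tol) psum <<- psum + exp(lp)
      return(invisible())
    }
    total <- rs[row]
    cell <- function(j, left, rem, lacc2) {
      if (j == cc) {
        if (left > rem[cc]) return(invisible())
        rem2 <- rem; rem2[cc] <- rem2[cc] - left
        rec_row(row + 1L, rem2, lacc2 - lgamma(left + 1))
        return(invisible())
      }
      hi <- min(left, rem[j])
      lo <- max(0L, left - sum(rem[(j + 1L):cc]))
      if (lo > hi) return(invisible())
      for (x in lo:hi) {
        rem2 <- rem; rem2[j] <- rem2[j] - x
        cell(j + 1L, left - x, rem2, lacc2 - lgamma(x + 1))
      }
    }
    cell(1L, total, rem_cols, lacc)
  }
  rec_row(1L, cs, 0)
  min(psum, 1)
}

#' Pairwise Fisher tests between groups with BH correction
#'
#' A 2 x c Fisher exact test for every pair of rows of the contingency table,
#' with Benjamini-Hochberg false-discovery-rate adjustment across the pairs.
#'
#' @param tab Contingency table (rows = groups, columns = outcomes) with at
#'   least 3 rows; row names label the comparisons.
#' @return Data frame `comparison`, `p_raw`, `p_adj`.
#' @export
pairwise_fisher_bh <- function(tab) {
  tab <- as.matrix(tab)
  if (nrow(tab) < 3L) stop("pairwise comparisons need at least 3 groups")
  if (is.null(rownames(tab))) rownames(tab) <- paste0("g", seq_len(nrow(tab)))
  pairs <- utils::combn(nrow(tab), 2L)
  p <- apply(pairs, 2L, function(ij) fisher_exact(tab[ij, , drop = FALSE]))
  lab <- apply(pairs, 2L, function(ij) paste(rownames(tab)[ij], collapse = " vs "))
  data.frame(comparison = lab, p_raw = p,
             p_adj = stats::p.adjust(p, method = "BH"),
             stringsAsFactors = FALSE)
}

#' Kruskal-Wallis rank sum test
#'
#' Tie-corrected H statistic with the chi-squared approximation
#' (df = number of groups - 1), via the canonical base-R implementation.
#'
#' @param groups Named list of numeric vectors (one per group).
#' @return List `H`, `df`, `p`.
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(length(groups) >= 2L, all(lengths(groups) >= 1L))
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  if (length(unique(x)) == 1L) {
    return(list(H = 0, df = length(groups) - 1L, p = 1))
  }
  kt <- stats::kruskal.test(x, g)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p = unname(kt$p.value))
}

#' Pairwise Wilcoxon rank sum tests with BH correction
#'
#' Two-sided rank-sum test for every pair of groups: exact when both samples
#' have at most `exact_max_n` observations and no ties are present, otherwise
#' the tie-corrected normal approximation with continuity correction.
#' Benjamini-Hochberg adjustment across the pairs.
#'
#' @param groups Named list of numeric vectors (one per group).
#' @param exact_max_n Largest per-group size for which the exact null
#'   distribution is enumerated.
#' @return Data frame `comparison`, `p_raw`, `p_adj`.
#' @export
pairwise_wilcoxon_bh <- function(groups, exact_max_n = 25) {
  stopifnot(length(groups) >= 2L)
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  pairs <- utils::combn(length(groups), 2L)
  p <- apply(pairs, 2L, function(ij) {
    a <- groups[[ij[1L]]]; b <- groups[[ij[2L]]]
    if (length(unique(c(a, b))) == 1L) return(1)
    use_exact <- max(length(a), length(b)) <= exact_max_n &&
      !any(duplicated(c(a, b)))
    wt <- suppressWarnings(stats::wilcox.test(a, b, exact = use_exact,
                                              correct = TRUE))
    wt$p.value
  })
  lab <- apply(pairs, 2L, function(ij) paste(names(groups)[ij], collapse = " vs "))
  data.frame(comparison = lab, p_raw = p,
             p_adj = stats::p.adjust(p, method = "BH"),
             stringsAsFactors = FALSE)
}
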