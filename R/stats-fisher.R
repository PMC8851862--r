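# Core downstream statistics: exact two-sided Fisher tests (point-probability
# rule, the convention that reproduces R's p.values), step-up BH FDR,
# upper-tail hypergeometric overlap tests, conserved-set false-positive
# validation, and the species-pair convergence report.

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact p by summing, over the hypergeometric support at fixed margins, all
#' tables whose point probability does not exceed the observed table's.
#' A zero margin yields p = 1 by convention.
#'
#' @param a,b,c,d Non-negative integer cell counts (row-wise).
#' @return List: `odds_ratio` (sample ad/bc), `p`.
#' @export
fisher_two_sided <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  row1 <- a + b; row2 <- c + d; col1 <- a + c; col2 <- b + d
  or <- (a * d) / (b * c)
  if (row1 == 0 || row2 == 0 || col1 == 0 || col2 == 0)
    return(list(odds_ratio = or, p = 1))
  k <- max(0, col1 - row2):min(row1, col1)
  pk <- dhyper(k, row1, row2, col1)
  p0 <- dhyper(a, row1, row2, col1)
  p <- sum(pk[pk <= p0 * (1 + 1e-7)])
  list(odds_ratio = or, p = min(1, p))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment with monotonicity enforcement; output order matches
#' input order.
#'
#' @param p Vector of p-values in [0, 1].
#' @return Adjusted p-values.
#' @export
bh_fdr <- function(p) {
  m <- length(p)
  if (m == 0L) return(numeric(0))
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  ord <- order(p, na.last = TRUE)
  adj <- p[ord] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[ord] <- adj
  out
}

#' Hypergeometric overlap test for two gene lists
#'
#' Tests whether the overlap of two lists drawn from an ortholog universe of
#' size `N` exceeds the random expectation `n1 * n2 / N`.
#'
#' @param n1,n2 List sizes.
#' @param N Universe size (a required input; it is never defaulted).
#' @param observed Observed overlap.
#' @return An `overlap_test`: `n1`, `n2`, `N`, `observed`, `expected`,
#'   `p_hyper` = P(X >= observed).
#' @export
overlap_hypergeometric <- function(n1, n2, N, observed) {
  if (N < max(n1, n2)) stop("universe smaller than a list: N < max(n1, n2)")
  if (observed > min(n1, n2)) stop("observed overlap exceeds min(n1, n2)")
  structure(list(n1 = n1, n2 = n2, N = N, observed = observed,
                 expected = n1 * n2 / N,
                 p_hyper = phyper(observed - 1, n1, N - n1, n2,
                                  lower.tail = FALSE)),
            class = "overlap_test")
}

#' @export
print.overlap_test <- function(x, ...) {
  cat(sprintf("overlap_test: observed %d vs expected %.2f (n1=%d, n2=%d, N=%d), p = %.3g\n",
              x$observed, x$expected, x$n1, x$n2, x$N, x$p_hyper))
  invisible(x)
}

#' Conserved-gene-set false-positive validation
#'
#' Fraction of a conserved (assumed-intact) gene set flagged as lost -- an
#' empirical false-positive ratio for the whole cascade.
#'
#' @param final_calls Character vector of called pseudogene ids.
#' @param conserved_set Character vector of conserved gene ids (non-empty).
#' @return List: `n_flagged`, `n_conserved`, `ratio` (fraction), `percent`.
#' @export
conserved_set_validation <- function(final_calls, conserved_set) {
  if (!length(conserved_set)) stop("conserved set must be non-empty")
  n <- length(intersect(unique(final_calls), unique(conserved_set)))
  ratio <- n / length(unique(conserved_set))
  list(n_flagged = n, n_conserved = length(unique(conserved_set)),
       ratio = ratio, percent = 100 * ratio)
}

#' Convergent-loss report across species pairs
#'
#' For each planned species pair, the overlap (convergent losses) and pooled
#' list size; for each pair of pairs, a two-sided Fisher comparison of the
#' overlap proportions, built as (overlap1, size1 - overlap1, overlap2,
#' size2 - overlap2).
#'
#' @param lists Named list of per-species pseudogene id vectors.
#' @param pair_plan data.frame with columns `species1`, `species2` and
#'   optionally `type` (e.g. homotypic/heterotypic).
#' @return List: `pairs` (overlap counts) and `comparisons` (pairwise Fisher
#'   results).
#' @export
pair_overlap_report <- function(lists, pair_plan) {
  stopifnot(all(c(pair_plan$species1, pair_plan$species2) %in% names(lists)))
  pairs <- do.call(rbind, lapply(seq_len(nrow(pair_plan)), function(i) {
    s1 <- pair_plan$species1[i]; s2 <- pair_plan$species2[i]
    l1 <- unique(lists[[s1]]); l2 <- unique(lists[[s2]])
    data.frame(pair = paste(s1, s2, sep = "-"),
               type = if ("type" %in% names(pair_plan)) pair_plan$type[i] else NA,
               overlap = length(intersect(l1, l2)),
               size = length(l1) + length(l2))
  }))
  comparisons <- NULL
  if (nrow(pairs) >= 2L) {
    idx <- utils::combn(nrow(pairs), 2)
    comparisons <- do.call(rbind, lapply(seq_len(ncol(idx)), function(j) {
      i1 <- idx[1, j]; i2 <- idx[2, j]
      ft <- fisher_two_sided(pairs$overlap[i1], pairs$size[i1] - pairs$overlap[i1],
                             pairs$overlap[i2], pairs$size[i2] - pairs$overlap[i2])
      data.frame(pair1 = pairs$pair[i1], pair2 = pairs$pair[i2],
                 odds_ratio = ft$odds_ratio, p = ft$p)
    }))
  }
  list(pairs = pairs, comparisons = comparisons)
}
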