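# Reciprocal-best-hit orthology between two proteomes: (a, b) is a pair iff
# b is a's unique best-scoring match and a is b's; any tie voids the pair.

.kmer_set <- function(p, k = 4L) {
  n <- nchar(p)
  if (n < k) return(character(0))
  unique(substring(p, 1:(n - k + 1L), k:n))
}

.nw_score <- function(a, b) {
  as.numeric(Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
    substitutionMatrix = blosum62(), gapOpening = 10, gapExtension = 0.5,
    scoreOnly = TRUE))
}

# unique best match of each query in `targets`; NA on tie or no candidates
.best_unique <- function(queries, targets, n_candidates = 5L) {
  tk <- lapply(targets, .kmer_set)
  out <- rep(NA_character_, length(queries))
  names(out) <- names(queries)
  for (qi in seq_along(queries)) {
    qk <- .kmer_set(queries[[qi]])
    shared <- vapply(tk, function(s) length(intersect(qk, s)), 0L)
    cand <- names(sort(shared, decreasing = TRUE))[seq_len(min(n_candidates, length(shared)))]
    cand <- cand[shared[cand] > 0L]
    if (!length(cand)) next
    sc <- vapply(cand, function(tn) .nw_score(queries[[qi]], targets[[tn]]), 0)
    mx <- max(sc)
    best <- cand[sc == mx]
    if (length(best) == 1L) out[qi] <- best
  }
  out
}

#' Reciprocal best hits between two proteomes
#'
#' @param proteome_a,proteome_b Named character vectors of protein sequences.
#' @return data.frame with columns `a`, `b`: the 1:1 ortholog pairs.
#' @export
reciprocal_best_hits <- function(proteome_a, proteome_b) {
  if (!length(proteome_a) || !length(proteome_b))
    stop("both proteomes must be non-empty")
  ab <- .best_unique(proteome_a, proteome_b)
  ba <- .best_unique(proteome_b, proteome_a)
  pairs <- list()
  for (a in names(ab)) {
    b <- ab[[a]]
    if (!is.na(b) && !is.na(ba[[b]]) && ba[[b]] == a)
      pairs[[length(pairs) + 1L]] <- data.frame(a = a, b = b)
  }
  if (!length(pairs)) return(data.frame(a = character(0), b = character(0)))
  do.call(rbind, pairs)
}
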