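# Copy assembly along reference-protein coordinates. Used by the functional
# redundancy filter: hits anywhere in the genome are chained into "copies";
# any copy covering >= 80% of the reference protein signals a functional
# paralog and disqualifies the unitary call.

# Merge colinear runs of hits (one locus, exon-split) into single
# protein-coordinate intervals before copy assembly: hits from adjacent exons
# of one copy often overlap by a few aa at the splice overshoot, which would
# otherwise undercount the copy's true coverage under non-overlapping-subset
# chaining.
merge_colinear_hits <- function(h, max_gap = 20000L, overlap_slack = 8L) {
  if (is.null(h) || !nrow(h)) return(h)
  out <- list()
  for (key in unique(paste(h$chrom, h$strand))) {
    hh <- h[paste(h$chrom, h$strand) == key, , drop = FALSE]
    minus <- hh$strand[1] == "-"
    os <- if (minus) hh$len - hh$tend else hh$tstart
    oe <- if (minus) hh$len - hh$tstart else hh$tend
    ord <- order(os)
    hh <- hh[ord, , drop = FALSE]; os <- os[ord]; oe <- oe[ord]
    cur <- hh[1L, , drop = FALSE]; cur_oe <- oe[1L]
    for (i in seq_len(nrow(hh))[-1L]) {
      colinear <- os[i] - cur_oe <= max_gap &&
        hh$qstart[i] >= cur$qstart - overlap_slack &&
        hh$qstart[i] <= cur$qend + overlap_slack
      if (colinear) {
        cur$qend <- max(cur$qend, hh$qend[i])
        cur$tstart <- min(cur$tstart, hh$tstart[i])
        cur$tend <- max(cur$tend, hh$tend[i])
        cur$score <- cur$score + hh$score[i]
        cur$evalue <- min(cur$evalue, hh$evalue[i])
        cur_oe <- max(cur_oe, oe[i])
      } else {
        out[[length(out) + 1L]] <- cur
        cur <- hh[i, , drop = FALSE]; cur_oe <- oe[i]
      }
    }
    out[[length(out) + 1L]] <- cur
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

# exact maximum-coverage non-overlapping subset (weighted interval
# scheduling, weight = interval length). Intervals: [qstart, qend) in aa.
.max_cov_subset <- function(qstart, qend) {
  n <- length(qstart)
  if (!n) return(integer(0))
  ord <- order(qend, qstart)
  qs <- qstart[ord]; qe <- qend[ord]; w <- qe - qs
  p <- integer(n) # last interval ending <= qs[i]
  for (i in seq_len(n)) {
    p[i] <- 0L
    for (j in seq_len(i - 1L)) if (qe[j] <= qs[i]) p[i] <- j
  }
  opt <- numeric(n + 1L)
  take <- logical(n)
  for (i in seq_len(n)) opt[i + 1L] <- max(opt[i], opt[p[i] + 1L] + w[i])
  sel <- integer(0); i <- n
  while (i >= 1L) {
    if (opt[p[i] + 1L] + w[i] >= opt[i]) { sel <- c(i, sel); i <- p[i] }
    else i <- i - 1L
  }
  ord[sel]
}

#' Chain hits into protein-coordinate copies
#'
#' Assembles hits (protein-coordinate intervals, already E-value filtered)
#' into successive "copies": each copy is the maximum-coverage set of
#' non-overlapping hits, extracted greedily until no hits remain. A copy
#' covering at least `min_cov` of the protein is flagged redundant.
#'
#' @param hits data.frame with `qstart`, `qend` (0-based half-open aa
#'   intervals); extra columns are carried along.
#' @param protein_length Reference protein length (aa).
#' @param min_cov Redundancy threshold on covered fraction (default 0.8).
#' @return data.frame, one row per copy: `copy`, `n_members`,
#'   `covered_aa`, `covered_fraction`, `redundant`, and a `members`
#'   list-column of row indices into `hits`.
#' @export
chain_hits_into_copies <- function(hits, protein_length, min_cov = 0.8) {
  out <- list()
  remaining <- seq_len(if (is.null(hits)) 0L else nrow(hits))
  copy <- 0L
  while (length(remaining)) {
    sel <- .max_cov_subset(hits$qstart[remaining], hits$qend[remaining])
    if (!length(sel)) break
    members <- remaining[sel]
    cov <- sum(hits$qend[members] - hits$qstart[members])
    copy <- copy + 1L
    out[[copy]] <- data.frame(copy = copy, n_members = length(members),
                              covered_aa = cov,
                              covered_fraction = cov / protein_length,
                              redundant = cov / protein_length >= min_cov)
    out[[copy]]$members <- I(list(members))
    remaining <- setdiff(remaining, members)
  }
  if (!length(out)) {
    d <- data.frame(copy = integer(0), n_members = integer(0),
                    covered_aa = integer(0), covered_fraction = numeric(0),
                    redundant = logical(0))
    d$members <- I(list())
    return(d)
  }
  do.call(rbind, out)
}
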