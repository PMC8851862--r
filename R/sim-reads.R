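# Per-base read-support track emulation. Real pipelines confirm each
# disruption against raw reads; here planted assembly-error sites get support
# fractions far below any sensible confirmation threshold and everything else
# is fully supported.

#' Emit a per-base read-support track
#'
#' @param assembly Named character vector of chromosome sequences.
#' @param error_sites data.frame with columns `chrom`, `pos` (0-based) of
#'   planted assembly errors; may be empty.
#' @param depth Mean sequencing depth (>= 1).
#' @param seed Integer seed.
#' @param error_support Mean fraction of reads supporting the assembly base at
#'   an error site (clamped below 0.5 x depth so the site always fails a
#'   confirmation threshold >= 0.5).
#' @return A `pg_support` list: per chromosome, integer vectors `total` and
#'   `support` of length equal to the sequence.
#' @export
emit_read_support <- function(assembly, error_sites = NULL, depth = 30,
                              seed = 1L, error_support = 0.1) {
  if (depth < 1) stop("depth must be >= 1")
  set.seed(as.integer(seed %% .Machine$integer.max))
  out <- lapply(assembly, function(s) {
    L <- nchar(s)
    total <- pmax(1L, stats::rpois(L, depth))
    list(total = total, support = total)
  })
  if (!is.null(error_sites) && nrow(error_sites)) {
    for (i in seq_len(nrow(error_sites))) {
      ch <- error_sites$chrom[i]; p <- error_sites$pos[i] + 1L
      if (!ch %in% names(out) || p < 1L || p > length(out[[ch]]$total)) next
      tot <- out[[ch]]$total[p]
      sup <- stats::rbinom(1L, tot, error_support)
      out[[ch]]$support[p] <- min(sup, floor(0.45 * tot))
    }
  }
  structure(out, class = "pg_support")
}

# supporting/total over a nt interval [start, end) on `chrom`; worst position
# governs. Returns c(support, total) or NULL when the track has no coverage.
support_at <- function(support, chrom, start, end) {
  if (is.null(support) || !chrom %in% names(support)) return(NULL)
  tr <- support[[chrom]]
  idx <- seq.int(max(1L, start + 1L), min(length(tr$total), end))
  if (!length(idx)) return(NULL)
  frac <- tr$support[idx] / tr$total[idx]
  w <- idx[which.min(frac)]
  c(support = tr$support[w], total = tr$total[w])
}
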