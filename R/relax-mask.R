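# Alignment masking in the Gblocks spirit: gap/ambiguity columns removed with
# two flanking codons (6 bp rounded outward to whole codons) on each side,
# low-quality fragments (5-codon windows of mean column conservation < 0.5)
# removed, groups shorter than 150 nt after masking dropped. The pass
# iterates to a fixed point, which makes masking idempotent by construction.

#' Mask a codon alignment
#'
#' @param aln Codon matrix from [build_codon_alignment()].
#' @param gap_flank_nt Flank removed around gap/ambiguity columns, in nt
#'   (rounded outward to whole codons; default 6).
#' @param min_len_nt Minimum surviving length in nt (default 150); shorter
#'   groups are flagged `dropped`.
#' @param min_conservation Mean modal-codon fraction below which a 5-codon
#'   window counts as low quality (default 0.5).
#' @return A `filtered_codon_alignment`: `aln` (retained columns), `retained`
#'   (original codon indices), `mask` (removed columns with reason
#'   `gap_flank` or `low_quality`), `final_len` (nt), `dropped`.
#' @export
mask_alignment <- function(aln, gap_flank_nt = 6L, min_len_nt = 150L,
                           min_conservation = 0.5) {
  stopifnot(is.matrix(aln))
  flank_codons <- as.integer(ceiling(gap_flank_nt / 3))
  orig_idx <- seq_len(ncol(aln))
  cur <- aln
  mask <- data.frame(col = integer(0), reason = character(0))

  repeat {
    n <- ncol(cur)
    if (n == 0L) break
    bad_gap <- vapply(seq_len(n), function(j) {
      col <- cur[, j]
      any(col == "---") || any(!grepl("^[ACGT]{3}$", col))
    }, logical(1))
    gap_mask <- rep(FALSE, n)
    for (j in which(bad_gap))
      gap_mask[max(1L, j - flank_codons):min(n, j + flank_codons)] <- TRUE

    cons <- vapply(seq_len(n), function(j) {
      col <- cur[, j]
      max(table(col)) / length(col)
    }, 0)
    lowq <- rep(FALSE, n)
    if (n >= 5L) {
      for (j in seq_len(n - 4L))
        if (mean(cons[j:(j + 4L)]) < min_conservation) lowq[j:(j + 4L)] <- TRUE
    } else if (mean(cons) < min_conservation) lowq[] <- TRUE

    remove <- gap_mask | lowq
    if (!any(remove)) break
    reason <- ifelse(gap_mask[remove], "gap_flank", "low_quality")
    mask <- rbind(mask, data.frame(col = orig_idx[remove], reason = reason))
    cur <- cur[, !remove, drop = FALSE]
    orig_idx <- orig_idx[!remove]
  }

  final_len <- 3L * ncol(cur)
  structure(list(aln = cur, retained = orig_idx,
                 mask = mask[order(mask$col), , drop = FALSE],
                 final_len = final_len, dropped = final_len < min_len_nt),
            class = "filtered_codon_alignment")
}

#' @export
print.filtered_codon_alignment <- function(x, ...) {
  cat(sprintf("filtered_codon_alignment: %d codon columns (%d nt)%s; %d masked\n",
              ncol(x$aln), x$final_len, if (x$dropped) " [dropped]" else "",
              nrow(x$mask)))
  invisible(x)
}
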