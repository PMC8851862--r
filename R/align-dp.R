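# Spliced protein-to-genome alignment (the gene-prediction stage). The heavy
# DP lives in src/spliced_dp.cpp; this wrapper extracts the locus sequence,
# orients it, runs the DP and rebuilds blocks, introns and raw
# frameshift/stop events in chromosome coordinates.

.dna2idx <- function(s) {
  m <- c(A = 0L, C = 1L, G = 2L, T = 3L)
  v <- m[strsplit(s, "")[[1]]]
  v[is.na(v)] <- -1L
  unname(v)
}

.prot2idx <- function(p) {
  idx <- .aa_char2idx()[utf8ToInt(p) %% 256L + 1L]
  idx[idx < 0L] <- .aa_char2idx()[utf8ToInt("X") + 1L]
  idx
}

.codon_aa_idx <- function() {
  if (is.null(.pg$cai)) {
    gc <- genetic_code()
    c2i <- .aa_char2idx()
    v <- integer(64L)
    base_idx <- stats::setNames(0:3, BASES)
    for (cod in names(gc)) {
      cs <- strsplit(cod, "")[[1]]
      id <- base_idx[cs[1]] * 16L + base_idx[cs[2]] * 4L + base_idx[cs[3]]
      v[id + 1L] <- if (gc[[cod]] == "*") -1L else c2i[utf8ToInt(gc[[cod]]) + 1L]
    }
    .pg$cai <- v
  }
  .pg$cai
}

#' Align a protein to a candidate locus
#'
#' Local alignment with states for codon match, codon-sized indels,
#' 1-2 nt frameshifts (heavy penalty), introns (open cost, canonical GT..AG
#' bonus) and stop-codon traversal (recorded and penalised, never
#' terminating). Ties are broken deterministically (match > frameshift >
#' codon gap > intron, leftmost genome coordinate).
#'
#' @param protein Protein string.
#' @param locus One-row locus data.frame (from [find_candidate_loci()]) or a
#'   list with `chrom`, `start`, `end`, `strand`.
#' @param assembly Named character vector of genome sequences.
#' @param params [align_params()].
#' @return A `spliced_alignment` object: score, coverage, `blocks`, `introns`,
#'   `events` (raw stop/frameshift observations) and per-residue `pairs`.
#' @export
align_protein_to_locus <- function(protein, locus, assembly,
                                   params = align_params()) {
  chrom <- locus$chrom[1]; strand <- locus$strand[1]
  start <- locus$start[1]; end <- locus$end[1]
  seg <- substr(assembly[[chrom]], start + 1L, end)
  if (nchar(seg) < 3L) stop("locus sequence shorter than one codon")
  if (strand == "-") seg <- revcomp(seg)
  m <- nchar(protein)

  r <- spliced_dp_cpp(.prot2idx(protein), .dna2idx(seg), blosum62(),
                      .codon_aa_idx(), params$fs_pen, params$gap_codon,
                      params$intron_open, params$splice_bonus, params$stop_pen,
                      params$min_intron)
  mv <- r$move; iv <- r$i; jv <- r$j; lv <- r$len
  to_chrom <- function(j0, j1) {
    if (strand == "+") c(start + j0, start + j1) else c(end - j1, end - j0)
  }

  segsplit <- strsplit(seg, "")[[1]]
  gc <- genetic_code()
  pchars <- strsplit(protein, "")[[1]]

  blocks <- list(); introns <- list(); events <- list(); pairs <- list()
  b_i0 <- r$i_start; b_j0 <- r$j_start
  flush_block <- function(i1, j1) {
    if (j1 > b_j0 && i1 >= b_i0) {
      g <- to_chrom(b_j0, j1)
      blocks[[length(blocks) + 1L]] <<- data.frame(
        prot_start = b_i0, prot_end = i1, seg_start = b_j0, seg_end = j1,
        start = g[1], end = g[2])
    }
  }
  for (t in seq_along(mv)) {
    m_t <- mv[t]; i_t <- iv[t]; j_t <- jv[t]; l_t <- lv[t]
    j_prev <- j_t - l_t
    if (m_t == 9L) { # intron
      flush_block(i_t, j_prev)
      g <- to_chrom(j_prev, j_t)
      canonical <- l_t >= 4L &&
        paste(segsplit[(j_prev + 1L):(j_prev + 2L)], collapse = "") == "GT" &&
        paste(segsplit[(j_t - 1L):j_t], collapse = "") == "AG"
      introns[[length(introns) + 1L]] <- data.frame(
        seg_start = j_prev, seg_end = j_t, start = g[1], end = g[2],
        canonical = canonical)
      b_i0 <- i_t; b_j0 <- j_t
      next
    }
    if (m_t %in% c(1L, 2L)) {
      codon <- paste(segsplit[(j_prev + 1L):j_t], collapse = "")
      aa <- gc[[codon]]
      g <- to_chrom(j_prev, j_t)
      pairs[[length(pairs) + 1L]] <- data.frame(
        protein_pos = i_t, ref_aa = pchars[i_t], q_aa = aa, codon = codon,
        seg_start = j_prev, seg_end = j_t, start = g[1],
        match = identical(aa, pchars[i_t]))
      if (m_t == 2L) {
        events[[length(events) + 1L]] <- data.frame(
          kind = "premature_stop", protein_pos = i_t, seg_pos = j_prev,
          genome_pos = g[1], size = NA_integer_)
      }
    } else if (m_t %in% c(5L, 6L, 7L, 8L)) {
      size <- abs(l_t - 3L)
      kind <- if (l_t < 3L) "frameshift_del" else "frameshift_ins"
      g <- to_chrom(j_prev, j_t)
      events[[length(events) + 1L]] <- data.frame(
        kind = kind, protein_pos = i_t, seg_pos = j_prev,
        genome_pos = g[1], size = size)
      pairs[[length(pairs) + 1L]] <- data.frame(
        protein_pos = i_t, ref_aa = pchars[i_t], q_aa = NA_character_,
        codon = NA_character_, seg_start = j_prev, seg_end = j_t,
        start = g[1], match = FALSE)
    }
  }
  flush_block(r$i_end, r$j_end)

  nb <- function(x, proto) if (length(x)) do.call(rbind, x) else proto
  aligned_aa <- sum(mv %in% c(1L, 2L, 5L, 6L, 7L, 8L))
  structure(list(
    gene_id = if (!is.null(locus$gene_id)) locus$gene_id[1] else NA_character_,
    chrom = chrom, strand = strand, locus_start = start, locus_end = end,
    score = r$score, coverage = aligned_aa / m, protein_len = m,
    prot_start = r$i_start, prot_end = r$i_end,
    blocks = nb(blocks, data.frame(prot_start = integer(0), prot_end = integer(0),
                                   seg_start = integer(0), seg_end = integer(0),
                                   start = integer(0), end = integer(0))),
    introns = nb(introns, data.frame(seg_start = integer(0), seg_end = integer(0),
                                     start = integer(0), end = integer(0),
                                     canonical = logical(0))),
    events = nb(events, data.frame(kind = character(0), protein_pos = integer(0),
                                   seg_pos = integer(0), genome_pos = integer(0),
                                   size = integer(0))),
    pairs = nb(pairs, data.frame(protein_pos = integer(0), ref_aa = character(0),
                                 q_aa = character(0), codon = character(0),
                                 seg_start = integer(0), seg_end = integer(0),
                                 start = integer(0), match = logical(0))),
    params = params), class = "spliced_alignment")
}

#' @export
print.spliced_alignment <- function(x, ...) {
  cat(sprintf("spliced_alignment %s %s:%d-%d(%s) score %.1f coverage %.2f; %d block(s), %d intron(s), %d event(s)\n",
              x$gene_id, x$chrom, x$locus_start, x$locus_end, x$strand,
              x$score, x$coverage, nrow(x$blocks), nrow(x$introns), nrow(x$events)))
  invisible(x)
}

# aa-level identity of aligned residues whose genomic footprint intersects a
# +/- window nt neighbourhood of segment position `seg_pos`
window_identity <- function(aln, seg_pos, window = 30L) {
  p <- aln$pairs
  if (!nrow(p)) return(NA_real_)
  sel <- p$seg_end > seg_pos - window & p$seg_start < seg_pos + window
  sel <- sel & !(p$seg_start <= seg_pos & p$seg_end > seg_pos)  # exclude the event codon
  if (!any(sel)) return(NA_real_)
  mean(p$match[sel])
}

# nt distance from a segment position to the nearest inferred intron boundary
boundary_distance <- function(aln, seg_pos) {
  if (!nrow(aln$introns)) return(Inf)
  min(abs(c(aln$introns$seg_start, aln$introns$seg_end) - seg_pos))
}
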