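# Disruption calling: raw alignment events -> annotated disruption records ->
# locus classification. One record per in-frame stop within aligned coding
# blocks (the reference terminal stop lies beyond the protein and never
# enters) and per frame-breaking 1-2 nt indel; consecutive indels within one
# codon merge into a single event of net size.

#' Call ORF disruptions from a spliced alignment
#'
#' @param aln A `spliced_alignment`.
#' @param support Optional `pg_support` read-support track; when absent,
#'   read support is reported as unknown (NA) and the downstream filter
#'   treats it per configuration.
#' @param window Identity window half-width in nt (default 30).
#' @param support_pad Extra nt checked on each side of an event's footprint
#'   when reading the support track (default 6): indel placement inside a
#'   repeat is ambiguous by up to a codon or two, so the validity check
#'   covers the neighbourhood, as read-level inspection would.
#' @return data.frame of disruptions: `kind`, `protein_pos`, `genome_pos`,
#'   `size`, `window_identity`, `boundary_distance`, `support`, `total`.
#' @export
call_disruptions <- function(aln, support = NULL, window = 30L,
                             support_pad = 6L) {
  ev <- aln$events
  proto <- data.frame(kind = character(0), protein_pos = integer(0),
                      genome_pos = integer(0), size = integer(0),
                      window_identity = numeric(0), boundary_distance = numeric(0),
                      support = integer(0), total = integer(0))
  if (is.null(ev) || !nrow(ev)) return(proto)

  # merge frame-breaking indels sharing a codon into one net event
  is_fs <- ev$kind %in% c("frameshift_ins", "frameshift_del")
  fs <- ev[is_fs, , drop = FALSE]
  keep <- ev[!is_fs, , drop = FALSE]
  if (nrow(fs)) {
    signed <- ifelse(fs$kind == "frameshift_ins", fs$size, -fs$size)
    agg <- stats::aggregate(signed, by = list(protein_pos = fs$protein_pos), sum)
    merged <- lapply(seq_len(nrow(agg)), function(i) {
      net <- agg$x[i]
      if (net %% 3L == 0L) return(NULL)
      first <- fs[fs$protein_pos == agg$protein_pos[i], , drop = FALSE][1L, ]
      first$kind <- if (net > 0L) "frameshift_ins" else "frameshift_del"
      first$size <- abs(net) %% 3L
      first
    })
    fs <- do.call(rbind, merged[!vapply(merged, is.null, logical(1))])
  }
  ev <- rbind(keep, fs)
  if (is.null(ev) || !nrow(ev)) return(proto)
  ev <- ev[order(ev$protein_pos), , drop = FALSE]

  # nt footprint of each event on the query genome: the full traversed span
  # (stop codon = 3 nt; frameshift insertion = 3 + size nt so the inserted
  # bases are covered; deletion junction = 3 - size nt)
  span <- ifelse(ev$kind == "premature_stop", 3L,
                 ifelse(ev$kind == "frameshift_ins", 3L + ev$size, 3L - ev$size))
  out <- data.frame(kind = ev$kind, protein_pos = ev$protein_pos,
                    genome_pos = ev$genome_pos, size = ev$size,
                    window_identity = vapply(ev$seg_pos, function(j)
                      window_identity(aln, j, window), 0),
                    boundary_distance = vapply(ev$seg_pos, function(j)
                      boundary_distance(aln, j), 0),
                    support = NA_integer_, total = NA_integer_,
                    stringsAsFactors = FALSE)
  if (!is.null(support)) {
    for (i in seq_len(nrow(out))) {
      s <- support_at(support, aln$chrom, out$genome_pos[i] - support_pad,
                      out$genome_pos[i] + span[i] + support_pad)
      if (!is.null(s)) { out$support[i] <- s[["support"]]; out$total[i] <- s[["total"]] }
    }
  }
  out
}

#' Classify a locus from its alignment and disruptions
#'
#' @param aln A `spliced_alignment`.
#' @param disruptions Output of [call_disruptions()].
#' @param coverage_floor Minimum protein coverage for classification
#'   (default 0.5); below it the locus is `unalignable`.
#' @return One of `"putative_pseudogenic"`, `"intact"`, `"unalignable"`.
#' @export
classify_locus <- function(aln, disruptions, coverage_floor = 0.5) {
  if (aln$coverage < coverage_floor) return("unalignable")
  if (nrow(disruptions) >= 1L) "putative_pseudogenic" else "intact"
}

#' Construct a pseudogene call
#'
#' Bundles a putative pseudogenic locus with its disruption list and an
#' (initially empty) ordered filter-decision trail.
#'
#' @param aln A `spliced_alignment`.
#' @param disruptions Output of [call_disruptions()].
#' @param species Species label.
#' @return A `pseudogene_call` object with status `"putative"`.
#' @export
pseudogene_call <- function(aln, disruptions, species = "query") {
  tf <- if (nrow(disruptions)) (min(disruptions$protein_pos) - 1) / aln$protein_len else 1
  structure(list(gene_id = aln$gene_id, species = species,
                 chrom = aln$chrom, strand = aln$strand,
                 locus_start = aln$locus_start, locus_end = aln$locus_end,
                 core_start = if (nrow(aln$blocks)) min(aln$blocks$start) else aln$locus_start,
                 core_end = if (nrow(aln$blocks)) max(aln$blocks$end) else aln$locus_end,
                 protein_len = aln$protein_len, coverage = aln$coverage,
                 disruptions = disruptions, truncated_fraction = tf,
                 status = "putative",
                 filter_trail = data.frame(stage = character(0), rule = character(0),
                                           decision = character(0))),
            class = "pseudogene_call")
}

#' @export
print.pseudogene_call <- function(x, ...) {
  cat(sprintf("pseudogene_call %s [%s] %d disruption(s), status %s\n",
              x$gene_id, x$species, nrow(x$disruptions), x$status))
  invisible(x)
}

trail_add <- function(call, stage, rule, decision) {
  call$filter_trail <- rbind(call$filter_trail,
                             data.frame(stage = stage, rule = rule,
                                        decision = decision))
  call
}
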