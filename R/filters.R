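# The ordered filter cascade. Stage 1 establishes unitary status (gene
# family, annotation class, functional redundancy, synteny); stage 2 removes
# false-positive disruption calls (terminal truncations, boundary/low-identity
# artifacts, read-unsupported sites, annotation-unsupported reference models,
# compensatory frameshift pairs). Every decision is logged to the call's
# trail; every removal carries exactly one primary reason.

#' Filter context
#'
#' Carries everything the cascade rules need: reference annotation flags,
#' the genome-wide hit table (for redundancy chaining), the synteny map, the
#' read-support track, and all thresholds.
#'
#' @param genes Reference gene table (from [generate_reference()] or GFF3).
#' @param hits Genome-wide hit table (from [search_proteome()]).
#' @param synteny Synteny map data.frame (gene_id, ref/query intervals).
#' @param support Optional `pg_support` track.
#' @param family_keywords Gene-family labels excluded as unalignable-by-design
#'   (high-similarity families).
#' @param check_reads Should the read-support rule (b) fire? (In real screens
#'   it can only run for species with raw reads available.)
#' @param copy_cov Redundancy threshold on copy coverage (default 0.8).
#' @param trunc Terminal-truncation threshold (default 0.9).
#' @param window Identity window in nt (default 30).
#' @param min_identity Minimum window identity (default 0.4).
#' @param boundary_nt Distance (nt) within which a disruption counts as
#'   "at the boundary" (default 10).
#' @param read_conf Minimum fraction of reads supporting a disruption.
#' @param min_depth Minimum read depth for confirmation.
#' @return A `filter_context` list.
#' @export
filter_context <- function(genes, hits = NULL, synteny = NULL, support = NULL,
                           family_keywords = c("olfactory", "zinc finger",
                                               "vomeronasal"),
                           check_reads = TRUE, copy_cov = 0.8, trunc = 0.9,
                           window = 30L, min_identity = 0.4, boundary_nt = 10L,
                           read_conf = 0.8, min_depth = 5L) {
  structure(as.list(environment()), class = "filter_context")
}

.gene_row <- function(ctx, gene_id) {
  r <- ctx$genes[ctx$genes$gene_id == gene_id, , drop = FALSE]
  if (!nrow(r)) stop("gene missing from reference annotation: ", gene_id)
  r
}

#' Unitary-status filter (stage 1)
#'
#' Rules, in order: (1) large gene families; (2) predicted or intronless-cDNA
#' reference models; (3) functional redundancy -- any chained copy away from
#' the called locus covering >= `copy_cov` of the protein; (4) conserved
#' genomic position against the synteny map (a gene missing from the map is
#' removed with a distinct sub-reason).
#'
#' @param call A `pseudogene_call` with status `"putative"`.
#' @param ctx A [filter_context()].
#' @return The call, status `"passed"` or `"removed:<reason>"`, trail updated.
#' @export
unitary_status_filter <- function(call, ctx) {
  stopifnot(inherits(call, "pseudogene_call"), call$status == "putative")
  g <- .gene_row(ctx, call$gene_id)

  fam <- !is.na(g$family) &&
    grepl(paste(ctx$family_keywords, collapse = "|"), g$family, ignore.case = TRUE)
  call <- trail_add(call, "unitary", "gene_family", if (fam) "remove" else "pass")
  if (fam) { call$status <- "removed:gene_family"; return(call) }

  pred <- isTRUE(g$predicted) || isTRUE(g$intronless_cdna)
  call <- trail_add(call, "unitary", "predicted_or_intronless",
                    if (pred) "remove" else "pass")
  if (pred) { call$status <- "removed:predicted_or_intronless"; return(call) }

  redundant <- FALSE
  if (!is.null(ctx$hits)) {
    h <- ctx$hits[ctx$hits$gene_id == call$gene_id, , drop = FALSE]
    away <- !(h$chrom == call$chrom &
                h$tstart < call$locus_end & h$tend > call$locus_start)
    h <- h[away, , drop = FALSE]
    if (nrow(h)) {
      h <- merge_colinear_hits(h)
      copies <- chain_hits_into_copies(h, call$protein_len, ctx$copy_cov)
      redundant <- any(copies$redundant)
    }
  }
  call <- trail_add(call, "unitary", "redundancy", if (redundant) "remove" else "pass")
  if (redundant) { call$status <- "removed:redundancy"; return(call) }

  syn_ok <- FALSE; sub <- "missing_from_map"
  if (!is.null(ctx$synteny)) {
    s <- ctx$synteny[ctx$synteny$gene_id == call$gene_id, , drop = FALSE]
    if (nrow(s)) {
      sub <- "position_mismatch"
      ov <- min(call$core_end, s$query_end[1]) - max(call$core_start, s$query_start[1])
      short <- min(call$core_end - call$core_start, s$query_end[1] - s$query_start[1])
      syn_ok <- s$query_chrom[1] == call$chrom && ov > 0.5 * short
    }
  } else syn_ok <- TRUE  # no map supplied: rule disabled
  call <- trail_add(call, "unitary", "synteny",
                    if (syn_ok) "pass" else paste0("remove(", sub, ")"))
  if (!syn_ok) { call$status <- "removed:non_syntenic"; return(call) }

  call$status <- "passed"
  call
}

#' False-positive filter (stage 2)
#'
#' Rule (a) voids individual disruptions that are terminal (a single
#' disruption truncating less than 1 - `trunc` of the protein),
#' boundary-adjacent, or in low-identity windows; rule (b) voids
#' read-unsupported disruptions (unknown support passes with a logged
#' warning); rule (c) removes calls whose reference gene lacks annotation
#' support (TSL not in {1,2} and no CCDS); rule (d) removes calls whose only
#' valid disruptions are exactly two frame-restoring frameshifts. Calls with
#' two or more valid disruptions after (a)-(b) pass the per-disruption rules
#' automatically (the automatable stand-in for manual multi-disruption
#' review, flagged in the trail).
#'
#' @param call A `pseudogene_call` that passed [unitary_status_filter()].
#' @param ctx A [filter_context()].
#' @return The call with final status and trail.
#' @export
false_positive_filter <- function(call, ctx) {
  stopifnot(inherits(call, "pseudogene_call"), call$status == "passed")
  d <- call$disruptions
  valid <- rep(TRUE, nrow(d))
  voided_by <- rep(NA_character_, nrow(d))

  # (a) terminal single disruption
  if (nrow(d) == 1L && call$truncated_fraction > ctx$trunc) {
    valid[1] <- FALSE; voided_by[1] <- "terminal"
  }
  # (a) boundary-adjacent / low-identity
  for (i in seq_len(nrow(d))) {
    if (!valid[i]) next
    if (is.finite(d$boundary_distance[i]) && d$boundary_distance[i] <= ctx$boundary_nt) {
      valid[i] <- FALSE; voided_by[i] <- "boundary"
    } else if (!is.na(d$window_identity[i]) && d$window_identity[i] < ctx$min_identity) {
      valid[i] <- FALSE; voided_by[i] <- "low_identity"
    }
  }
  call <- trail_add(call, "fp", "a_alignment_artifacts",
                    paste0(sum(!valid), "/", nrow(d), " voided"))

  # (b) read support
  if (isTRUE(ctx$check_reads)) {
    for (i in seq_len(nrow(d))) {
      if (!valid[i]) next
      if (is.na(d$total[i])) {
        call <- trail_add(call, "fp", "b_read_support",
                          paste0("disruption ", i, " unknown support: pass (warn)"))
        next
      }
      confirmed <- d$total[i] >= ctx$min_depth &&
        d$support[i] / d$total[i] >= ctx$read_conf
      if (!confirmed) { valid[i] <- FALSE; voided_by[i] <- "read_unsupported" }
    }
    call <- trail_add(call, "fp", "b_read_support",
                      paste0(sum(voided_by %in% "read_unsupported"), " voided"))
  } else {
    call <- trail_add(call, "fp", "b_read_support", "disabled for species")
  }

  if (!any(valid)) {
    reason <- if (any(voided_by %in% "read_unsupported") &&
                  all(voided_by[!is.na(voided_by)] %in% "read_unsupported"))
      "read_unsupported" else "alignment_artifact"
    call <- trail_add(call, "fp", "no_valid_disruption", "remove")
    call$status <- paste0("removed:", reason)
    return(call)
  }
  if (sum(valid) >= 2L)
    call <- trail_add(call, "fp", "multi_disruption_autopass", "pass")

  # (c) annotation support of the reference model
  g <- .gene_row(ctx, call$gene_id)
  annot_ok <- g$tsl %in% c(1L, 2L) || isTRUE(g$ccds)
  call <- trail_add(call, "fp", "c_annotation_support",
                    if (annot_ok) "pass" else "remove")
  if (!annot_ok) { call$status <- "removed:annotation_unsupported"; return(call) }

  # (d) exactly two compensatory frameshifts, nothing else valid
  dv <- d[valid, , drop = FALSE]
  comp <- FALSE
  if (nrow(dv) == 2L && all(dv$kind %in% c("frameshift_ins", "frameshift_del"))) {
    signed <- ifelse(dv$kind == "frameshift_ins", dv$size, -dv$size)
    comp <- sum(signed) %% 3L == 0L
  }
  call <- trail_add(call, "fp", "d_compensatory_pair", if (comp) "remove" else "pass")
  if (comp) { call$status <- "removed:compensatory_pair"; return(call) }

  call$disruptions$valid <- valid
  call$status <- "passed"
  call
}

#' Apply the full filter cascade
#'
#' Runs stage 1 then stage 2 over a list of putative calls and assembles the
#' per-stage count report (counts are non-increasing across stages by
#' construction). The relaxed-selection gate is a separate, later stage.
#'
#' @param calls List of `pseudogene_call`s with status `"putative"`.
#' @param ctx A [filter_context()].
#' @return List: `calls` (all calls, with final stage-2 status) and `report`,
#'   a `cascade_report` with per-stage counts and the removal breakdown.
#' @export
apply_filter_cascade <- function(calls, ctx) {
  n0 <- length(calls)
  calls <- lapply(calls, unitary_status_filter, ctx = ctx)
  passed1 <- vapply(calls, function(x) x$status == "passed", logical(1))
  calls[passed1] <- lapply(calls[passed1], false_positive_filter, ctx = ctx)
  passed2 <- vapply(calls, function(x) x$status == "passed", logical(1))
  status <- vapply(calls, `[[`, "", "status")
  reasons <- table(sub("^removed:", "", status[grepl("^removed:", status)]))
  report <- structure(list(
    counts = c(putative = n0, unitary = sum(passed1), after_fp = sum(passed2),
               after_relax = NA_integer_),
    removal_reasons = reasons), class = "cascade_report")
  list(calls = calls, report = report)
}

#' @export
print.cascade_report <- function(x, ...) {
  cat("cascade_report counts:\n")
  print(x$counts)
  if (length(x$removal_reasons)) { cat("removals:\n"); print(x$removal_reasons) }
  invisible(x)
}
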