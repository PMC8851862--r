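# Query-genome evolution: neutral divergence, planted gene-fate events,
# extra-copy loci, truth table, and the synteny map.

ARTIFACT_KINDS <- c("duplicate_copy", "retrocopy", "family_paralog",
                    "assembly_error", "compensatory_pair")
DISRUPTION_KINDS <- c("premature_stop", "frameshift_ins", "frameshift_del",
                      "compensatory_pair", "assembly_error")

# vectorised substitution draw with transition/transversion bias
.mutate_bases <- function(old, kappa) {
  alts <- list(A = c("G", "C", "T"), C = c("T", "A", "G"),
               G = c("A", "C", "T"), T = c("C", "A", "G"))
  # first alternative is the transition
  w <- c(kappa, 1, 1); w <- w / sum(w)
  pick <- sample.int(3L, length(old), replace = TRUE, prob = w)
  vapply(seq_along(old), function(i) alts[[old[i]]][pick[i]], character(1))
}

# codon-aware substitution pass over one CDS: proposals at `rate`/site with
# kappa bias; stop-creating changes rejected; non-synonymous changes accepted
# with probability `omega`; first and last codons and splice sites untouched.
.evolve_cds <- function(chars, map, n_cod, rate, omega, kappa) {
  if (rate <= 0 || n_cod < 2L) return(chars)
  gc <- genetic_code()
  for (cod in seq(2L, n_cod)) {
    base_i <- (cod - 1L) * 3L
    hit <- which(stats::runif(3) < rate)
    for (p in hit) {
      pos <- map[base_i + p] + 1L
      cur <- chars[map[base_i + 1:3] + 1L]
      alt <- .mutate_bases(chars[pos], kappa)
      newc <- cur; newc[p] <- alt
      new_codon <- paste(newc, collapse = "")
      if (gc[[new_codon]] == "*") next
      syn <- gc[[new_codon]] == gc[[paste(cur, collapse = "")]]
      if (syn || stats::runif(1) < omega) chars[pos] <- alt
    }
  }
  chars
}

.final_coord <- function(p, edits) {
  if (nrow(edits) == 0L) return(p)
  ins <- edits[edits$type == "ins", , drop = FALSE]
  del <- edits[edits$type == "del", , drop = FALSE]
  p + sum(ins$len[ins$pos < p]) - sum(del$len[del$pos + del$len <= p])
}

#' Evolve a query genome with planted gene-fate events
#'
#' Applies genome-wide neutral divergence (synonymous-biased inside intact
#' coding sequence so intactness is preserved), realises every planned event,
#' plants extra gene copies on a separate contig, and emits a machine-readable
#' truth table plus a per-gene synteny map standing in for a whole-genome
#' pairwise alignment.
#'
#' @param reference A [generate_reference()] result.
#' @param config A [sim_config()] carrying the event plan; its seed drives
#'   this step (offset internally so reference and query draws differ).
#' @return A `pg_query` list: `assembly`, `truth` (list of `genes`, `events`,
#'   `copies`, `error_sites` data.frames), `synteny`, `config`.
#' @export
evolve_query <- function(reference, config) {
  stopifnot(inherits(reference, "pg_reference"), inherits(config, "sim_config"))
  set.seed(as.integer((config$seed + 1000003) %% .Machine$integer.max))
  genes <- reference$genes
  plan <- config$event_plan

  bad <- setdiff(vapply(plan, `[[`, "", "gene_id"), genes$gene_id)
  if (length(bad)) stop("event plan references unknown gene(s): ",
                        paste(unique(bad), collapse = ", "))
  # collision check: two point events on one codon of one gene
  keys <- vapply(Filter(function(e) !is.na(e$codon_position), plan),
                 function(e) paste(e$gene_id, e$codon_position), character(1))
  if (anyDuplicated(keys)) stop("event plan collision: two events on one codon")

  chars <- strsplit(reference$assembly[["chr1"]], "")[[1]]
  L <- length(chars)

  plan_by_gene <- split(plan, vapply(plan, `[[`, "", "gene_id"))
  gene_kinds <- lapply(plan_by_gene, function(ps) vapply(ps, `[[`, "", "kind"))

  # ---- constraint class per gene ----
  omega_gene <- stats::setNames(rep(config$omega_intact, nrow(genes)), genes$gene_id)
  for (gid in names(gene_kinds)) {
    ks <- gene_kinds[[gid]]
    if (any(ks %in% DISRUPTION_KINDS)) {
      omega_gene[gid] <- 1
    } else if ("relaxed_evolution" %in% ks) {
      kk <- Filter(function(e) e$kind == "relaxed_evolution", plan_by_gene[[gid]])[[1]]$k
      if (is.na(kk)) kk <- 0.5
      omega_gene[gid] <- config$omega_intact^kk
    }
  }

  # ---- neutral divergence outside CDS (splice dinucleotides protected) ----
  if (config$divergence > 0 && L > 0) {
    cds_pos <- integer(0); protected <- integer(0)
    per_gene_maps <- list()
    for (g in seq_len(nrow(genes))) {
      exg <- reference$exons[reference$exons$gene_id == genes$gene_id[g], , drop = FALSE]
      map <- cds_coord_map(exg)
      per_gene_maps[[genes$gene_id[g]]] <- map
      cds_pos <- c(cds_pos, map)
      exg <- exg[order(exg$rank), , drop = FALSE]
      if (nrow(exg) > 1L) for (e in seq_len(nrow(exg) - 1L)) {
        i0 <- exg$end[e]; i1 <- exg$start[e + 1L]
        protected <- c(protected, i0, i0 + 1L, i1 - 2L, i1 - 1L)
      }
    }
    mutable <- setdiff(seq.int(0L, L - 1L), c(cds_pos, protected))
    hit <- mutable[stats::runif(length(mutable)) < config$divergence]
    if (length(hit)) chars[hit + 1L] <- .mutate_bases(chars[hit + 1L], config$kappa)
    # CDS: codon-aware pass per gene
    for (g in seq_len(nrow(genes))) {
      gid <- genes$gene_id[g]
      chars <- .evolve_cds(chars, per_gene_maps[[gid]], genes$protein_len[g],
                           config$divergence, omega_gene[gid], config$kappa)
    }
  } else {
    per_gene_maps <- lapply(stats::setNames(genes$gene_id, genes$gene_id), function(gid)
      cds_coord_map(reference$exons[reference$exons$gene_id == gid, , drop = FALSE]))
  }

  # ---- planted point events ----
  edits <- data.frame(type = character(0), pos = integer(0), len = integer(0),
                      seq = character(0), stringsAsFactors = FALSE)
  events <- list(); err_pre <- list()
  add_edit <- function(type, pos, len, seq = "") {
    edits[nrow(edits) + 1L, ] <<- list(type, as.integer(pos), as.integer(len), seq)
  }
  for (ev in plan) {
    if (!ev$kind %in% c(DISRUPTION_KINDS, "premature_stop")) next
    gid <- ev$gene_id
    g <- genes[genes$gene_id == gid, ]
    map <- per_gene_maps[[gid]]
    cp <- ev$codon_position
    if (is.na(cp)) stop("event ", ev$kind, " on ", gid, " needs codon_position")
    if (cp < 2L || cp > g$protein_len)
      stop("codon_position out of range for ", gid)
    cstart <- map[(cp - 1L) * 3L + 1L]
    rec <- data.frame(gene_id = gid, kind = ev$kind, codon_position = cp,
                      codon_position2 = NA_integer_, size = ev$size,
                      chrom = "chr1", pos_pre = cstart, pos2_pre = NA_integer_,
                      stringsAsFactors = FALSE)
    if (ev$kind == "premature_stop") {
      chars[cstart + 1:3] <- strsplit(sample(STOP_CODONS, 1L), "")[[1]]
      rec$size <- NA_integer_
    } else if (ev$kind == "frameshift_ins") {
      add_edit("ins", cstart + 1L, ev$size, rand_dna(ev$size))
      rec$pos_pre <- cstart + 1L
    } else if (ev$kind == "frameshift_del") {
      add_edit("del", cstart, ev$size)
    } else if (ev$kind == "assembly_error") {
      add_edit("ins", cstart + 1L, ev$size, rand_dna(ev$size))
      rec$pos_pre <- cstart + 1L
      err_pre[[length(err_pre) + 1L]] <-
        data.frame(gene_id = gid, pos_pre = cstart + 1L, len = ev$size)
    } else if (ev$kind == "compensatory_pair") {
      cp2 <- min(cp + 30L, g$protein_len - 2L)
      if (cp2 <= cp) stop("gene too short for compensatory pair: ", gid)
      c2start <- map[(cp2 - 1L) * 3L + 1L]
      add_edit("ins", cstart + 1L, ev$size, rand_dna(ev$size))
      add_edit("del", c2start, ev$size)
      rec$pos_pre <- cstart + 1L
      rec$codon_position2 <- cp2; rec$pos2_pre <- c2start
    }
    events[[length(events) + 1L]] <- rec
  }

  # ---- apply indel edits (descending position keeps coordinates valid) ----
  if (nrow(edits)) {
    for (i in order(edits$pos, decreasing = TRUE)) {
      e <- edits[i, ]
      if (e$type == "ins") {
        chars <- append(chars, strsplit(e$seq, "")[[1]], after = e$pos)
      } else {
        chars <- chars[-seq(e$pos + 1L, e$pos + e$len)]
      }
    }
  }
  query_chr1 <- paste(chars, collapse = "")

  events <- if (length(events)) do.call(rbind, events) else
    data.frame(gene_id = character(0), kind = character(0),
               codon_position = integer(0), codon_position2 = integer(0),
               size = integer(0), chrom = character(0), pos_pre = integer(0),
               pos2_pre = integer(0), stringsAsFactors = FALSE)
  if (nrow(events)) {
    events$pos <- vapply(events$pos_pre, .final_coord, 0, edits = edits)
    events$pos2 <- ifelse(is.na(events$pos2_pre), NA_integer_,
                          vapply(ifelse(is.na(events$pos2_pre), 0L, events$pos2_pre),
                                 .final_coord, 0, edits = edits))
  } else { events$pos <- integer(0); events$pos2 <- integer(0) }

  error_sites <- if (length(err_pre)) {
    ep <- do.call(rbind, err_pre)
    do.call(rbind, lapply(seq_len(nrow(ep)), function(i) {
      fp <- .final_coord(ep$pos_pre[i], edits[edits$pos != ep$pos_pre[i] |
                                                edits$type != "ins", , drop = FALSE])
      data.frame(gene_id = ep$gene_id[i], chrom = "chr1",
                 pos = seq(fp, fp + ep$len[i] - 1L))
    }))
  } else data.frame(gene_id = character(0), chrom = character(0), pos = integer(0))

  # ---- extra-copy loci on a separate contig ----
  copies <- list(); extra_parts <- character(0); extra_off <- 0L
  spacer <- function() { s <- rand_dna(300L); extra_parts <<- c(extra_parts, s); extra_off <<- extra_off + 300L }
  for (ev in plan) {
    if (!ev$kind %in% c("duplicate_copy", "retrocopy", "family_paralog")) next
    gid <- ev$gene_id
    g <- genes[genes$gene_id == gid, ]
    exg <- reference$exons[reference$exons$gene_id == gid, , drop = FALSE]
    map <- per_gene_maps[[gid]]
    ncov <- max(2L, ceiling(ev$copy_coverage * g$protein_len))
    cov_end_genome <- map[min(length(map), ncov * 3L)] + 1L
    if (ev$kind == "retrocopy") {
      cds <- spliced_cds(reference$assembly, exg)
      seg <- substr(cds, 1L, ncov * 3L)
      seg_map <- seq.int(0L, nchar(seg) - 1L)  # whole segment is CDS
    } else {
      seg <- substr(reference$assembly[["chr1"]], g$start + 1L, cov_end_genome)
      keep <- map < cov_end_genome
      seg_map <- map[keep] - g$start
      seg_map <- seg_map[seq_len(3L * (sum(keep) %/% 3L))]
    }
    segc <- strsplit(seg, "")[[1]]
    rate <- if (ev$kind == "family_paralog") 3 * config$divergence else config$divergence
    om <- if (ev$kind == "family_paralog") 0.6 else config$omega_intact
    rate <- min(rate, 0.3)
    segc <- .evolve_cds(segc, seg_map, length(seg_map) %/% 3L, rate, om, config$kappa)
    # non-CDS part of the copy drifts freely
    noncds <- setdiff(seq.int(0L, length(segc) - 1L), seg_map)
    hit <- noncds[stats::runif(length(noncds)) < rate]
    if (length(hit)) segc[hit + 1L] <- .mutate_bases(segc[hit + 1L], config$kappa)
    spacer()
    cstart <- extra_off
    extra_parts <- c(extra_parts, paste(segc, collapse = ""))
    extra_off <- extra_off + length(segc)
    copies[[length(copies) + 1L]] <-
      data.frame(gene_id = gid, kind = ev$kind, chrom = "chr_extra",
                 start = cstart, end = extra_off, copy_coverage = ev$copy_coverage,
                 stringsAsFactors = FALSE)
  }
  assembly <- c(chr1 = query_chr1)
  if (length(copies)) {
    spacer()
    assembly <- c(assembly, chr_extra = paste(extra_parts, collapse = ""))
  }
  copies <- if (length(copies)) do.call(rbind, copies) else
    data.frame(gene_id = character(0), kind = character(0), chrom = character(0),
               start = integer(0), end = integer(0), copy_coverage = numeric(0))

  # ---- truth table ----
  bad_annot <- genes$predicted | genes$intronless_cdna |
    (genes$tsl > 2L & !genes$ccds) | !is.na(genes$family)
  names(bad_annot) <- genes$gene_id
  fate <- vapply(genes$gene_id, function(gid) {
    ks <- gene_kinds[[gid]]
    if (is.null(ks)) ks <- character(0)
    disrupted <- any(ks %in% DISRUPTION_KINDS)
    if (!disrupted) return("intact")
    artifact <- any(ks %in% ARTIFACT_KINDS) || bad_annot[[gid]]
    if (!artifact) {
      # a lone terminal stop is weak evidence by the cascade's own rule
      ev <- events[events$gene_id == gid, , drop = FALSE]
      g <- genes[genes$gene_id == gid, ]
      if (nrow(ev) == 1L && ev$kind == "premature_stop" &&
          ev$codon_position > 0.9 * g$protein_len) artifact <- TRUE
    }
    if (artifact) "artifact_only" else "lost"
  }, character(1))

  # ---- synteny map ----
  synteny <- if (nrow(genes)) data.frame(
    gene_id = genes$gene_id, ref_chrom = genes$chrom,
    ref_start = genes$start, ref_end = genes$end,
    query_chrom = "chr1",
    query_start = vapply(genes$start, .final_coord, 0, edits = edits),
    query_end = vapply(genes$end, .final_coord, 0, edits = edits),
    strand = "+", stringsAsFactors = FALSE) else
      data.frame(gene_id = character(0), ref_chrom = character(0),
                 ref_start = integer(0), ref_end = integer(0),
                 query_chrom = character(0), query_start = integer(0),
                 query_end = integer(0), strand = character(0))

  events$pos_pre <- NULL; events$pos2_pre <- NULL
  structure(list(assembly = assembly,
                 truth = list(genes = data.frame(gene_id = genes$gene_id,
                                                 fate = unname(fate),
                                                 stringsAsFactors = FALSE),
                              events = events, copies = copies,
                              error_sites = error_sites),
                 synteny = synteny, config = config),
            class = "pg_query")
}

#' @export
print.pg_query <- function(x, ...) {
  tab <- table(x$truth$genes$fate)
  cat("pg_query:", sum(nchar(x$assembly)), "nt;",
      paste(names(tab), tab, collapse = ", "), "\n")
  invisible(x)
}
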