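# Candidate-locus discovery: one translated seed-and-extend search standing in
# for the two external mappers of classic screens. A locus enters the pipeline
# only when it satisfies BOTH an empirical E-value criterion (local similarity)
# and a colinear-chain criterion (multi-hit consistency with one gene
# structure) -- the conjunctive dual-mapper logic without external binaries.

#' Default search/alignment parameters
#'
#' @param flank Flanking nt added to each locus (default 5000).
#' @param evalue_max Empirical E-value cutoff for hits (default 1e-3).
#' @param n_decoys Shuffled-protein decoys per query for the E-value fit.
#' @param seed_k Amino-acid seed length.
#' @param min_seg_score Minimum ungapped segment score kept as a hit.
#' @param min_chain_cov Minimum protein fraction a colinear chain must cover.
#' @param max_intron Maximum genomic gap (nt) bridged inside a chain.
#' @param min_intron Minimum intron length for the spliced aligner.
#' @param fs_pen,gap_codon,intron_open,splice_bonus,stop_pen DP scores.
#' @param coverage_floor Minimum protein coverage for classification.
#' @param seed RNG seed for decoy shuffling.
#' @return Named list of parameters.
#' @export
align_params <- function(flank = 5000L, evalue_max = 1e-3, n_decoys = 200L,
                         seed_k = 5L, min_seg_score = 25, min_chain_cov = 0.25,
                         max_intron = 20000L, min_intron = 30L, fs_pen = -15,
                         gap_codon = -14, intron_open = -10, splice_bonus = 5,
                         stop_pen = -20, coverage_floor = 0.5, seed = 1L) {
  as.list(environment())
}

.aa_char2idx <- function() {
  if (is.null(.pg$c2i)) {
    b <- blosum62()
    v <- rep(-1L, 256L)
    for (i in seq_len(nrow(b))) v[utf8ToInt(rownames(b)[i]) + 1L] <- i - 1L
    .pg$c2i <- v
  }
  .pg$c2i
}

# six-frame translation of an assembly; returns aa strings plus a frame table
translated_frames <- function(assembly) {
  frames <- character(0)
  meta <- list()
  gc <- genetic_code()
  tr <- function(nt) {
    n <- nchar(nt); n3 <- n - n %% 3L
    if (n3 < 3L) return("")
    cod <- substring(nt, seq(1L, n3 - 2L, 3L), seq(3L, n3, 3L))
    aa <- gc[cod]; aa[is.na(aa)] <- "X"
    paste(aa, collapse = "")
  }
  for (ch in names(assembly)) {
    s <- assembly[[ch]]; L <- nchar(s); rc <- revcomp(s)
    for (off in 0:2) {
      frames <- c(frames, tr(substr(s, off + 1L, L)))
      meta[[length(meta) + 1L]] <- data.frame(chrom = ch, strand = "+", offset = off, len = L)
      frames <- c(frames, tr(substr(rc, off + 1L, L)))
      meta[[length(meta) + 1L]] <- data.frame(chrom = ch, strand = "-", offset = off, len = L)
    }
  }
  list(aa = frames, meta = do.call(rbind, meta))
}

.shuffle_protein <- function(p) paste(sample(strsplit(p, "")[[1]]), collapse = "")

# convert frame-local aa intervals to plus-strand nt intervals
.hit_to_nt <- function(h, meta) {
  m <- meta[h$frame, , drop = FALSE]
  plus <- m$strand == "+"
  ts <- ifelse(plus, m$offset + 3L * h$sstart, m$len - (m$offset + 3L * h$send))
  te <- ifelse(plus, m$offset + 3L * h$send, m$len - (m$offset + 3L * h$sstart))
  data.frame(chrom = m$chrom, strand = m$strand, tstart = ts, tend = te,
             qstart = h$qstart, qend = h$qend, score = h$score, len = m$len)
}

#' Search a proteome against a genome assembly
#'
#' Runs the translated seed-and-extend search for every protein (plus shuffled
#' decoys for the empirical extreme-value E-value fit), chains colinear hits,
#' and derives candidate loci. Hits above `evalue_max` are discarded.
#'
#' @param proteome Named character vector of protein sequences.
#' @param assembly Named character vector of genome sequences.
#' @param params [align_params()].
#' @return List: `hits` (all retained hits with E-values, per gene) and
#'   `loci` (candidate-locus table; one row per locus with evidence flags).
#' @export
search_proteome <- function(proteome, assembly, params = align_params()) {
  if (!length(proteome)) return(list(hits = NULL, loci = NULL))
  set.seed(as.integer(params$seed %% .Machine$integer.max))
  fr <- translated_frames(assembly)
  nq <- length(proteome)
  nd <- params$n_decoys
  decoys <- unlist(lapply(proteome, function(p) replicate(nd, .shuffle_protein(p))))
  queries <- c(unname(proteome), decoys)
  want <- c(rep(TRUE, nq), rep(FALSE, length(decoys)))
  res <- scan_proteins_cpp(queries, want, fr$aa, params$seed_k, blosum62(),
                           .aa_char2idx(), params$min_seg_score)
  hits_all <- list(); loci_all <- list()
  for (i in seq_len(nq)) {
    gid <- names(proteome)[i]
    h <- res[[i]]
    d <- vapply(res[nq + ((i - 1L) * nd + 1L):(i * nd)], `[[`, 0, 1L)
    beta <- max(stats::sd(d) * sqrt(6) / pi, 1e-3)
    mu <- mean(d) - 0.57722 * beta
    if (nrow(h)) {
      h <- .hit_to_nt(h, fr$meta)
      h$gene_id <- gid
      h$evalue <- exp(-(h$score - mu) / beta)
      h <- h[h$evalue <= params$evalue_max, , drop = FALSE]
      h <- h[order(h$chrom, h$strand, h$tstart, h$qstart), , drop = FALSE]
    }
    if (nrow(h)) {
      hits_all[[gid]] <- h
      loci_all[[gid]] <- .hits_to_loci(h, nchar(proteome[[i]]), params)
    }
  }
  hits <- if (length(hits_all)) do.call(rbind, c(hits_all, make.row.names = FALSE)) else NULL
  loci <- if (length(loci_all)) do.call(rbind, c(loci_all, make.row.names = FALSE)) else NULL
  list(hits = hits, loci = loci)
}

# greedy chain extraction per (chrom, strand): repeatedly take the best
# colinear chain (max aa coverage, non-overlapping protein intervals) until no
# chain covers min_chain_cov
.hits_to_loci <- function(h, plen, params) {
  out <- list()
  for (key in unique(paste(h$chrom, h$strand))) {
    hh <- h[paste(h$chrom, h$strand) == key, , drop = FALSE]
    # orientation coords: ascending along the gene
    minus <- hh$strand[1] == "-"
    os <- if (minus) hh$len - hh$tend else hh$tstart
    hh <- hh[order(os), , drop = FALSE]
    repeat {
      ch <- .best_chain(hh, params$max_intron)
      if (is.null(ch)) break
      sel <- hh[ch, , drop = FALSE]
      cov <- sum(sel$qend - sel$qstart) / plen
      if (cov >= params$min_chain_cov) {
        out[[length(out) + 1L]] <- data.frame(
          gene_id = sel$gene_id[1], chrom = sel$chrom[1], strand = sel$strand[1],
          start = max(0L, min(sel$tstart) - params$flank),
          end = min(sel$len[1], max(sel$tend) + params$flank),
          flank = params$flank, chain_cov = cov,
          evalue = min(sel$evalue), n_hits = nrow(sel),
          similarity_pass = any(sel$evalue <= params$evalue_max),
          chain_pass = TRUE, stringsAsFactors = FALSE)
      }
      hh <- hh[-ch, , drop = FALSE]
      if (!nrow(hh) || cov < params$min_chain_cov) break
    }
  }
  if (!length(out)) return(NULL)
  loci <- do.call(rbind, out)
  .merge_loci(loci)
}

# chain DP maximising covered aa over colinear compatible hits
.best_chain <- function(hh, max_intron) {
  n <- nrow(hh)
  if (!n) return(NULL)
  minus <- hh$strand[1] == "-"
  os <- if (minus) hh$len - hh$tend else hh$tstart
  oe <- if (minus) hh$len - hh$tstart else hh$tend
  len <- hh$qend - hh$qstart
  best <- len; prev <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)[seq_len(i - 1L) > 0]) {
      ok <- hh$qend[j] <= hh$qstart[i] + 5L && oe[j] <= os[i] + 15L &&
        os[i] - oe[j] <= max_intron
      if (ok && best[j] + len[i] > best[i]) {
        best[i] <- best[j] + len[i]; prev[i] <- j
      }
    }
  }
  i <- which.max(best)
  chain <- integer(0)
  while (!is.na(i)) { chain <- c(i, chain); i <- prev[i] }
  chain
}

# merge loci on one (chrom, strand) overlapping by > 50% of the shorter
.merge_loci <- function(loci) {
  loci <- loci[order(loci$chrom, loci$strand, loci$start), , drop = FALSE]
  keep <- rep(TRUE, nrow(loci))
  i <- 1L
  while (i < nrow(loci)) {
    j <- i + 1L
    while (j <= nrow(loci) && keep[i]) {
      if (!keep[j] || loci$chrom[j] != loci$chrom[i] ||
          loci$strand[j] != loci$strand[i]) { j <- j + 1L; next }
      ov <- min(loci$end[i], loci$end[j]) - max(loci$start[i], loci$start[j])
      short <- min(loci$end[i] - loci$start[i], loci$end[j] - loci$start[j])
      if (ov > 0.5 * short) {
        loci$start[i] <- min(loci$start[i], loci$start[j])
        loci$end[i] <- max(loci$end[i], loci$end[j])
        loci$chain_cov[i] <- max(loci$chain_cov[i], loci$chain_cov[j])
        loci$evalue[i] <- min(loci$evalue[i], loci$evalue[j])
        loci$n_hits[i] <- loci$n_hits[i] + loci$n_hits[j]
        keep[j] <- FALSE
      }
      j <- j + 1L
    }
    i <- i + 1L
  }
  loci[keep, , drop = FALSE]
}

#' Find candidate orthologous loci for one protein
#'
#' Convenience wrapper over [search_proteome()] for a single protein. Only
#' loci with both evidence flags true enter the downstream pipeline.
#'
#' @param protein Single protein string (named, or `gene_id` is used).
#' @param genome Named character vector of genome sequences.
#' @param params [align_params()].
#' @param gene_id Identifier used when `protein` is unnamed.
#' @return Candidate-locus data.frame (possibly empty).
#' @export
find_candidate_loci <- function(protein, genome, params = align_params(),
                                gene_id = "query") {
  if (is.null(names(protein))) names(protein) <- gene_id
  res <- search_proteome(protein, genome, params)
  if (is.null(res$loci))
    return(data.frame(gene_id = character(0), chrom = character(0),
                      strand = character(0), start = integer(0), end = integer(0),
                      flank = integer(0), chain_cov = numeric(0), evalue = numeric(0),
                      n_hits = integer(0), similarity_pass = logical(0),
                      chain_pass = logical(0)))
  res$loci
}
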