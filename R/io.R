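# Format I/O. Internal coordinates are 0-based half-open throughout; the GFF3
# writer/reader pair is the single point where 1-based inclusive conversion
# happens. Sequence I/O goes through Biostrings, GFF3 parsing through
# rtracklayer, trees through ape.

#' Write sequences to FASTA
#' @param x Named character vector of sequences.
#' @param path Output path.
#' @param type `"dna"` or `"aa"`.
#' @export
write_fasta <- function(x, path, type = c("dna", "aa")) {
  type <- match.arg(type)
  set <- if (type == "dna") Biostrings::DNAStringSet(x) else Biostrings::AAStringSet(x)
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' Read sequences from FASTA
#' @param path FASTA path.
#' @param type `"dna"` or `"aa"`.
#' @return Named character vector.
#' @export
read_fasta <- function(path, type = c("dna", "aa")) {
  type <- match.arg(type)
  set <- if (type == "dna") Biostrings::readDNAStringSet(path) else
    Biostrings::readAAStringSet(path)
  out <- as.character(set)
  names(out) <- sub(" .*$", "", names(out))
  out
}

#' Write reference gene models to GFF3
#'
#' Emits gene/mRNA/exon/CDS features, 1-based inclusive, with annotation
#' support flags as gene attributes.
#'
#' @param reference A `pg_reference`.
#' @param path Output path.
#' @export
write_gff3 <- function(reference, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  g <- reference$genes
  for (i in seq_len(nrow(g))) {
    gid <- g$gene_id[i]
    attr_gene <- sprintf("ID=%s;tsl=%d;ccds=%s;predicted=%s;intronless_cdna=%s%s",
                         gid, g$tsl[i], g$ccds[i], g$predicted[i],
                         g$intronless_cdna[i],
                         if (!is.na(g$family[i])) paste0(";family=", g$family[i]) else "")
    writeLines(sprintf("%s\tpgloss\tgene\t%d\t%d\t.\t%s\t.\t%s",
                       g$chrom[i], g$start[i] + 1L, g$end[i], g$strand[i], attr_gene), con)
    writeLines(sprintf("%s\tpgloss\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s.t1;Parent=%s",
                       g$chrom[i], g$start[i] + 1L, g$end[i], g$strand[i], gid, gid), con)
    ex <- reference$exons[reference$exons$gene_id == gid, , drop = FALSE]
    ex <- ex[order(ex$rank), , drop = FALSE]
    phase <- 0L
    for (e in seq_len(nrow(ex))) {
      writeLines(sprintf("%s\tpgloss\texon\t%d\t%d\t.\t%s\t.\tID=%s.e%d;Parent=%s.t1",
                         g$chrom[i], ex$start[e] + 1L, ex$end[e], g$strand[i],
                         gid, e, gid), con)
      writeLines(sprintf("%s\tpgloss\tCDS\t%d\t%d\t.\t%s\t%d\tID=%s.c%d;Parent=%s.t1",
                         g$chrom[i], ex$start[e] + 1L, ex$end[e], g$strand[i],
                         phase, gid, e, gid), con)
      phase <- (3L - ((ex$end[e] - ex$start[e] - phase) %% 3L)) %% 3L
    }
  }
  invisible(path)
}

#' Read reference gene models from GFF3 (+ FASTA)
#'
#' Re-assembles a `pg_reference` from a GFF3 written by [write_gff3()] (or
#' any GFF3 with gene/CDS features and the same attribute names) plus the
#' assembly FASTA; the proteome is derived by conceptual translation.
#'
#' @param gff_path GFF3 path.
#' @param fasta_path Assembly FASTA path.
#' @return A `pg_reference` (config slot NULL).
#' @export
read_gff3_reference <- function(gff_path, fasta_path) {
  lines <- readLines(gff_path, warn = FALSE)
  body <- which(!grepl("^#", lines) & nzchar(lines))
  nfield <- vapply(strsplit(lines[body], "\t", fixed = TRUE), length, 0L)
  if (length(body) && any(nfield != 9L))
    stop("malformed GFF3 at ", gff_path, ":", body[nfield != 9L][1],
         " (expected 9 tab-separated fields)", call. = FALSE)
  gr <- rtracklayer::import(gff_path, format = "gff3")
  assembly <- read_fasta(fasta_path, "dna")
  gg <- gr[gr$type == "gene"]
  getf <- function(x, fld, default) {
    v <- S4Vectors::mcols(x)[[fld]]
    if (is.null(v)) rep(default, length(x)) else ifelse(is.na(v), default, v)
  }
  genes <- data.frame(
    gene_id = getf(gg, "ID", NA_character_),
    chrom = as.character(GenomicRanges::seqnames(gg)),
    strand = as.character(GenomicRanges::strand(gg)),
    start = GenomicRanges::start(gg) - 1L, end = GenomicRanges::end(gg),
    predicted = as.logical(getf(gg, "predicted", "FALSE")),
    intronless_cdna = as.logical(getf(gg, "intronless_cdna", "FALSE")),
    tsl = as.integer(getf(gg, "tsl", "1")),
    ccds = as.logical(getf(gg, "ccds", "TRUE")),
    family = as.character(getf(gg, "family", NA_character_)),
    stringsAsFactors = FALSE)
  cds <- gr[gr$type == "CDS"]
  par <- sub("\\.t1$", "", as.character(unlist(S4Vectors::mcols(cds)$Parent)))
  ord <- order(par, GenomicRanges::start(cds))
  exons <- data.frame(gene_id = par[ord],
                      start = GenomicRanges::start(cds)[ord] - 1L,
                      end = GenomicRanges::end(cds)[ord])
  exons$rank <- stats::ave(seq_len(nrow(exons)), exons$gene_id,
                           FUN = seq_along)
  genes$n_exons <- as.integer(table(exons$gene_id)[genes$gene_id])
  proteome <- vapply(genes$gene_id, function(gid) {
    cdsseq <- spliced_cds(assembly, exons[exons$gene_id == gid, , drop = FALSE],
                          genes$chrom[genes$gene_id == gid])
    sub("\\*$", "", translate_cds(cdsseq))
  }, character(1))
  genes$protein_len <- nchar(proteome)
  structure(list(assembly = assembly, genes = genes, exons = exons,
                 proteome = proteome, config = NULL), class = "pg_reference")
}

#' Write a tab-separated table
#' @param x data.frame. @param path Output path.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a tab-separated table
#' @param path Input path.
#' @return data.frame.
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}

#' Write a read-support track as TSV (chrom, pos, support, total; 0-based)
#' @param support A `pg_support`. @param path Output path.
#' @export
write_support_tsv <- function(support, path) {
  rows <- do.call(rbind, lapply(names(support), function(ch) {
    tr <- support[[ch]]
    data.frame(chrom = ch, pos = seq_along(tr$total) - 1L,
               support = tr$support, total = tr$total)
  }))
  write_tsv(rows, path)
}

#' Read a read-support track TSV
#' @param path Input path.
#' @return A `pg_support`.
#' @export
read_support_tsv <- function(path) {
  d <- read_tsv(path)
  out <- lapply(split(d, d$chrom), function(x) {
    x <- x[order(x$pos), ]
    list(total = x$total, support = x$support)
  })
  structure(out, class = "pg_support")
}

#' Write the truth table of a simulated query
#' @param query A `pg_query`. @param dir Output directory.
#' @export
write_truth <- function(query, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(query$truth$genes, file.path(dir, "truth_genes.tsv"))
  write_tsv(query$truth$events, file.path(dir, "truth_events.tsv"))
  write_tsv(query$truth$copies, file.path(dir, "truth_copies.tsv"))
  write_tsv(query$truth$error_sites, file.path(dir, "truth_error_sites.tsv"))
  write_tsv(query$synteny, file.path(dir, "synteny.tsv"))
  invisible(dir)
}

#' Serialise spliced alignments to a block-structured TSV pair
#' @param alns List of `spliced_alignment`s. @param dir Output directory.
#' @export
write_alignments_tsv <- function(alns, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  take <- function(fld) do.call(rbind, lapply(alns, function(a) {
    d <- a[[fld]]
    if (!nrow(d)) return(NULL)
    cbind(gene_id = a$gene_id, chrom = a$chrom, strand = a$strand, d)
  }))
  hdr <- do.call(rbind, lapply(alns, function(a)
    data.frame(gene_id = a$gene_id, chrom = a$chrom, strand = a$strand,
               locus_start = a$locus_start, locus_end = a$locus_end,
               score = a$score, coverage = a$coverage)))
  write_tsv(hdr, file.path(dir, "alignments.tsv"))
  b <- take("blocks"); if (!is.null(b)) write_tsv(b, file.path(dir, "alignment_blocks.tsv"))
  e <- take("events"); if (!is.null(e)) write_tsv(e, file.path(dir, "alignment_events.tsv"))
  invisible(dir)
}
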