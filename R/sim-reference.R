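# Reference genome/proteome generator.

#' Generate a synthetic reference assembly, gene models, and proteome
#'
#' Builds a single-chromosome assembly of multi-exon protein-coding genes:
#' every gene starts with ATG, carries exactly one terminal stop, has
#' GT..AG introns placed at codon boundaries (phase-0), and no in-frame
#' internal stop codons. Genes are non-overlapping and separated by random
#' intergenic spacers. All coordinates are 0-based half-open on the plus
#' strand; the GFF3 writer converts to 1-based inclusive.
#'
#' @param config A [sim_config()].
#' @return A `pg_reference` list with elements `assembly` (named character
#'   vector of chromosome sequences), `genes` (data.frame incl. annotation
#'   support flags), `exons` (data.frame of coding-exon intervals, terminal
#'   stop included in the last exon), `proteome` (named character vector),
#'   and the `config`.
#' @export
generate_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_genes
  ids <- if (n > 0) sprintf("g%03d", seq_len(n)) else character(0)

  parts <- character(0)
  offset <- 0L
  genes <- vector("list", n)
  exons <- vector("list", n)
  proteome <- character(0)

  rint <- function(rng) if (rng[1] == rng[2]) rng[1] else sample(seq(rng[1], rng[2]), 1L)

  for (g in seq_len(n)) {
    spacer <- rint(config$intergenic_len)
    parts <- c(parts, rand_dna(spacer))
    offset <- offset + spacer

    n_cod <- rint(config$codons_per_gene)            # protein length in aa
    max_ex <- min(config$exons_per_gene[2], (n_cod + 1L) %/% 2L)
    n_ex <- rint(c(min(config$exons_per_gene[1], max_ex), max_ex))
    total_cod <- n_cod + 1L                          # incl. terminal stop

    body <- sample(sense_codons(), n_cod - 1L, replace = TRUE)
    codons <- c("ATG", body, sample(STOP_CODONS, 1L))

    extra <- total_cod - 2L * n_ex
    sizes <- 2L + tabulate(if (extra > 0) sample.int(n_ex, extra, replace = TRUE) else integer(0), n_ex)
    stopifnot(sum(sizes) == total_cod)

    gstart <- offset
    ex <- vector("list", n_ex)
    ci <- 0L
    for (e in seq_len(n_ex)) {
      seg <- paste(codons[(ci + 1L):(ci + sizes[e])], collapse = "")
      ci <- ci + sizes[e]
      estart <- offset
      parts <- c(parts, seg)
      offset <- offset + nchar(seg)
      ex[[e]] <- data.frame(gene_id = ids[g], rank = e,
                            start = estart, end = offset)
      if (e < n_ex) {
        ilen <- rint(config$intron_len)
        intron <- paste0("GT", rand_dna(ilen - 4L), "AG")
        parts <- c(parts, intron)
        offset <- offset + ilen
      }
    }
    gend <- offset
    exons[[g]] <- do.call(rbind, ex)
    prot <- translate_cds(paste(codons[seq_len(n_cod)], collapse = ""))
    proteome[ids[g]] <- prot
    genes[[g]] <- data.frame(gene_id = ids[g], chrom = "chr1", strand = "+",
                             start = gstart, end = gend, n_exons = n_ex,
                             protein_len = n_cod,
                             predicted = FALSE, intronless_cdna = FALSE,
                             tsl = 1L, ccds = TRUE, family = NA_character_,
                             stringsAsFactors = FALSE)
  }
  # trailing spacer so genes never abut the contig end
  parts <- c(parts, rand_dna(rint(config$intergenic_len)))

  genes <- if (n > 0) do.call(rbind, genes) else
    data.frame(gene_id = character(0), chrom = character(0), strand = character(0),
               start = integer(0), end = integer(0), n_exons = integer(0),
               protein_len = integer(0), predicted = logical(0),
               intronless_cdna = logical(0), tsl = integer(0), ccds = logical(0),
               family = character(0), stringsAsFactors = FALSE)
  exons <- if (n > 0) do.call(rbind, exons) else
    data.frame(gene_id = character(0), rank = integer(0),
               start = integer(0), end = integer(0))

  ov <- config$annotation_overrides
  if (!is.null(ov)) {
    for (i in seq_len(nrow(ov))) {
      r <- match(ov$gene_id[i], genes$gene_id)
      if (is.na(r)) stop("annotation override for unknown gene ", ov$gene_id[i])
      for (fld in intersect(names(ov), c("predicted", "intronless_cdna", "tsl", "ccds", "family")))
        if (!is.na(ov[[fld]][i])) genes[[fld]][r] <- ov[[fld]][i]
    }
  }

  structure(list(assembly = c(chr1 = paste(parts, collapse = "")),
                 genes = genes, exons = exons, proteome = proteome,
                 config = config),
            class = "pg_reference")
}

#' @export
print.pg_reference <- function(x, ...) {
  cat("pg_reference:", nrow(x$genes), "genes on",
      length(x$assembly), "chromosome(s),",
      sum(nchar(x$assembly)), "nt\n")
  invisible(x)
}

# spliced CDS of one gene (terminal stop included), from any assembly that
# still matches the given exon coordinates
spliced_cds <- function(assembly, exons_g, chrom = "chr1") {
  seqs <- substring(assembly[[chrom]], exons_g$start + 1L, exons_g$end)
  paste(seqs[order(exons_g$rank)], collapse = "")
}

# genome coordinate of every CDS nucleotide (plus strand), in splice order
cds_coord_map <- function(exons_g) {
  exons_g <- exons_g[order(exons_g$rank), , drop = FALSE]
  unlist(lapply(seq_len(nrow(exons_g)), function(i)
    seq(exons_g$start[i], exons_g$end[i] - 1L)), use.names = FALSE)
}
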