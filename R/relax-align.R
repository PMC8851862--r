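# Ortholog groups and codon-aware multiple alignment. Protein-level
# centre-star progressive alignment back-translated to codons: adequate at
# the divergence this package targets (<= 0.3 substitutions/site), which is
# why a phylogeny-aware aligner is not re-implemented here.

#' Ortholog group for the relaxed-selection stage
#'
#' @param gene_id Group identifier (reference gene).
#' @param cds Named character vector of per-species CDS, disruption codons
#'   already excised; lengths must be multiples of 3.
#' @param tree Species tree (phylo/newick) containing the member taxa.
#' @param foreground Tip label of the species carrying the putative loss.
#' @param min_members Minimum members (default 2).
#' @return An `ortholog_group`.
#' @export
ortholog_group <- function(gene_id, cds, tree, foreground, min_members = 2L) {
  if (length(cds) < min_members)
    stop("ortholog group needs at least ", min_members, " members")
  if (any(nchar(cds) %% 3L != 0L)) stop("CDS lengths must be multiples of 3")
  tree <- .resolve_tree(tree)
  if (!foreground %in% names(cds)) stop("foreground species not in group")
  if (!all(names(cds) %in% tree$tip.label))
    stop("tree does not cover all group members")
  structure(list(gene_id = gene_id, cds = cds, tree = tree,
                 foreground = foreground), class = "ortholog_group")
}

#' Build a codon alignment for an ortholog group
#'
#' Translates each CDS, aligns proteins by centre-star progressive alignment
#' (the longest member anchors), and back-translates so every column is a
#' whole codon.
#'
#' @param group An [ortholog_group()] (or a named CDS vector).
#' @return Character matrix, rows = taxa, columns = codons (`"---"` = gap).
#' @export
build_codon_alignment <- function(group) {
  cds <- if (inherits(group, "ortholog_group")) group$cds else group
  prots <- vapply(cds, function(s) {
    p <- translate_cds(s)
    p <- sub("\\*$", "", p)
    if (grepl("\\*", p)) stop("untranslatable CDS in group (internal stop)")
    p
  }, character(1))
  nm <- names(cds)
  center <- nm[order(-nchar(prots), nm)][1]
  others <- setdiff(nm, center)
  nc <- nchar(prots[[center]])

  # pairwise global alignments to the centre
  pw <- lapply(others, function(o) {
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(prots[[center]]), Biostrings::AAString(prots[[o]]),
      type = "global", substitutionMatrix = blosum62(),
      gapOpening = 10, gapExtension = 0.5)
    list(p = strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]],
         s = strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]])
  })
  names(pw) <- others

  # insertion profile: ins[k+1] = columns inserted after centre residue k
  ins <- integer(nc + 1L)
  for (o in others) {
    pp <- pw[[o]]$p
    k <- 0L; run <- 0L
    for (t in seq_along(pp)) {
      if (pp[t] == "-") run <- run + 1L
      else { ins[k + 1L] <- max(ins[k + 1L], run); run <- 0L; k <- k + 1L }
    }
    ins[k + 1L] <- max(ins[k + 1L], run)
  }
  ncol_total <- nc + sum(ins)
  # global column of centre residue k and of the insertion slots after k
  col_of_center <- cumsum(c(ins[1] + 1L, ins[-1] + 1L))[seq_len(nc)]

  place_row <- function(aa_center, aa_self) {
    # walk a pairwise alignment, emitting the subject into global columns
    row <- rep("-", ncol_total)
    k <- 0L; slot <- 0L
    for (t in seq_along(aa_center)) {
      if (aa_center[t] == "-") {
        slot <- slot + 1L
        base <- if (k == 0L) 0L else col_of_center[k]
        row[base + slot] <- aa_self[t]
      } else {
        k <- k + 1L; slot <- 0L
        if (aa_self[t] != "-") row[col_of_center[k]] <- aa_self[t]
      }
    }
    row
  }

  rows <- matrix("-", nrow = length(nm), ncol = ncol_total,
                 dimnames = list(nm, NULL))
  cc <- strsplit(prots[[center]], "")[[1]]
  rows[center, col_of_center] <- cc
  for (o in others) rows[o, ] <- place_row(pw[[o]]$p, pw[[o]]$s)

  # back-translate each row to codons
  out <- matrix("---", nrow = length(nm), ncol = ncol_total,
                dimnames = list(nm, NULL))
  for (x in nm) {
    cod <- split_codons(substr(cds[[x]], 1L, 3L * nchar(prots[[x]])))
    idx <- which(rows[x, ] != "-")
    stopifnot(length(idx) == length(cod))
    out[x, idx] <- cod
  }
  out
}
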