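# Simulation configuration and event plans.

#' Planned gene-fate event
#'
#' One planted event for [evolve_query()]. Kinds: `premature_stop`,
#' `frameshift_ins`, `frameshift_del` (ORF disruptions), `compensatory_pair`
#' (a +size / -size frameshift pair that restores the frame),
#' `duplicate_copy` / `retrocopy` / `family_paralog` (extra gene copies that
#' create functional redundancy or family confusion), `assembly_error`
#' (a frameshift at a site with low read support), and `relaxed_evolution`
#' (no disruption; the coding sequence evolves under weakened constraint).
#'
#' @param gene_id Reference gene identifier.
#' @param kind Event kind, see above.
#' @param codon_position 1-based codon index on the reference protein (point
#'   events; ignored for copies).
#' @param size Indel size in nt, 1 or 2 (frameshifts only).
#' @param copy_coverage Fraction of the protein covered by a planted copy,
#'   in (0, 1].
#' @param k Selection intensity for `relaxed_evolution` (omega exponent).
#' @return A `planned_event` list.
#' @export
planned_event <- function(gene_id, kind, codon_position = NA_integer_,
                          size = NA_integer_, copy_coverage = NA_real_,
                          k = NA_real_) {
  kinds <- c("premature_stop", "frameshift_ins", "frameshift_del",
             "compensatory_pair", "duplicate_copy", "retrocopy",
             "family_paralog", "assembly_error", "relaxed_evolution")
  if (!kind %in% kinds) stop("unknown event kind: ", kind)
  if (kind %in% c("frameshift_ins", "frameshift_del", "compensatory_pair",
                  "assembly_error")) {
    if (is.na(size)) size <- 1L
    if (!size %in% c(1L, 2L)) stop("frameshift size must be 1 or 2 nt")
  }
  if (kind %in% c("duplicate_copy", "retrocopy", "family_paralog")) {
    if (is.na(copy_coverage)) copy_coverage <- 1
    if (copy_coverage <= 0 || copy_coverage > 1) stop("copy_coverage must be in (0,1]")
  }
  structure(list(gene_id = gene_id, kind = kind,
                 codon_position = as.integer(codon_position),
                 size = as.integer(size), copy_coverage = copy_coverage,
                 k = k),
            class = "planned_event")
}

.check_range <- function(x, name, lower = 1L) {
  if (length(x) == 1L) x <- c(x, x)
  if (length(x) != 2L || any(!is.finite(x)) || x[1] > x[2] || x[1] < lower)
    stop("invalid range for ", name)
  as.integer(x)
}

#' Simulation configuration
#'
#' Describes the synthetic world: gene architecture ranges, genome-wide
#' neutral divergence, and the plan of planted events. Identical
#' (config, seed) pairs reproduce byte-identical artifacts.
#'
#' @param n_genes Number of protein-coding genes.
#' @param exons_per_gene Integer range (min, max) of coding exons per gene.
#' @param codons_per_gene Integer range of protein length in codons (aa).
#' @param intron_len Integer range of intron lengths in nt (minimum 6).
#' @param intergenic_len Integer range of intergenic spacer lengths in nt.
#' @param divergence Expected substitutions/site in [0, 0.3] applied to the
#'   query relative to the reference.
#' @param seed Integer seed; all randomness flows from it.
#' @param event_plan List of [planned_event()]s.
#' @param kappa Transition/transversion rate ratio for substitutions.
#' @param omega_intact Relative acceptance probability of non-synonymous
#'   substitutions in intact coding sequence (the background dN/dS the world
#'   evolves under).
#' @param annotation_overrides Optional data.frame with column `gene_id` and
#'   any of `predicted`, `intronless_cdna`, `tsl`, `ccds`, `family`,
#'   overriding the default healthy annotation flags of the reference.
#' @return A `sim_config` object.
#' @export
sim_config <- function(n_genes, exons_per_gene = c(2L, 6L),
                       codons_per_gene = c(100L, 300L),
                       intron_len = c(60L, 300L),
                       intergenic_len = c(300L, 1000L),
                       divergence = 0.05, seed = 1L, event_plan = list(),
                       kappa = 2, omega_intact = 0.2,
                       annotation_overrides = NULL) {
  if (!is.numeric(n_genes) || n_genes < 0) stop("n_genes must be >= 0")
  exons_per_gene <- .check_range(exons_per_gene, "exons_per_gene")
  codons_per_gene <- .check_range(codons_per_gene, "codons_per_gene", lower = 2L)
  intron_len <- .check_range(intron_len, "intron_len", lower = 6L)
  intergenic_len <- .check_range(intergenic_len, "intergenic_len")
  if (!is.finite(divergence) || divergence < 0 || divergence > 0.3)
    stop("divergence must lie in [0, 0.3]")
  # every exon needs at least 2 codons
  if (codons_per_gene[1] + 1L < exons_per_gene[2] * 2L)
    stop("codons_per_gene too small to hold exons_per_gene exons")
  if (!all(vapply(event_plan, inherits, logical(1), "planned_event")))
    stop("event_plan must be a list of planned_event objects")
  structure(list(n_genes = as.integer(n_genes), exons_per_gene = exons_per_gene,
                 codons_per_gene = codons_per_gene, intron_len = intron_len,
                 intergenic_len = intergenic_len, divergence = divergence,
                 seed = as.integer(seed), event_plan = event_plan,
                 kappa = kappa, omega_intact = omega_intact,
                 annotation_overrides = annotation_overrides),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_genes, "genes, divergence", x$divergence,
      ", seed", x$seed, ",", length(x$event_plan), "planned events\n")
  invisible(x)
}

rand_dna <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")
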