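# The standard synthetic benchmark: a reference proteome plus two query
# species -- a focal species carrying planted losses and artifacts, and a
# clean control species -- with read-support tracks and full truth tables.
# Event positions are chosen away from exon boundaries and from the terminal
# 20% of the protein (except for deliberately terminal artifacts), so that a
# planted loss is a loss by the cascade's own definitions.

# codon positions of gene `gid` that are >= `margin` codons from every exon
# boundary and inside [lo, hi]
.allowed_codons <- function(reference, gid, margin = 10L, lo_frac = 0.1,
                            hi_frac = 0.8) {
  g <- reference$genes[reference$genes$gene_id == gid, ]
  ex <- reference$exons[reference$exons$gene_id == gid, , drop = FALSE]
  ex <- ex[order(ex$rank), , drop = FALSE]
  sizes <- (ex$end - ex$start) / 3L
  bounds <- cumsum(sizes)
  bounds <- bounds[-length(bounds)] # internal boundaries, in codons
  len <- g$protein_len
  lo <- max(3L, ceiling(lo_frac * len))
  hi <- min(len - 2L, floor(hi_frac * len))
  cand <- seq(lo, hi)
  if (length(bounds))
    cand <- cand[vapply(cand, function(p) all(abs(p - bounds) > margin), logical(1))]
  cand
}

#' Build the standard planted-event benchmark
#'
#' Generates the reference, a focal query with `n_lost` genuine losses and
#' `n_artifact` planted artifacts (functional redundancy, family paralogs,
#' assembly errors, compensatory pairs, terminal stops, annotation-class
#' artifacts), a clean control query, and read-support tracks.
#'
#' @param seed Master seed; every stage derives from it.
#' @param n_genes Number of reference genes (default 200).
#' @param divergence Substitutions/site (default 0.05).
#' @param n_lost Planted genuine losses (default 40).
#' @param n_artifact Planted artifact-only genes (default 40).
#' @return List: `reference`, `queries` (named `focal`, `control`),
#'   `supports`, `truth` (the focal truth table).
#' @export
standard_benchmark <- function(seed = 1L, n_genes = 200L, divergence = 0.05,
                               n_lost = 40L, n_artifact = 40L) {
  base <- sim_config(n_genes = n_genes, divergence = divergence, seed = seed)
  reference0 <- generate_reference(base)
  set.seed(as.integer((seed + 500009) %% .Machine$integer.max))

  pickable <- reference0$genes$gene_id[reference0$genes$protein_len >= 120L]
  chosen <- sample(pickable, n_lost + n_artifact)
  lost <- chosen[seq_len(n_lost)]
  artifact <- chosen[n_lost + seq_len(n_artifact)]

  plan <- list(); ov <- list()
  add <- function(e) plan[[length(plan) + 1L]] <<- e
  dis_kinds <- c("premature_stop", "frameshift_ins", "frameshift_del")
  # boundary margin relaxed stepwise for genes whose exon structure leaves
  # few clear codons; sampling spaced positions retries then backs off
  codons_for <- function(gid, hi_frac = 0.8) {
    for (m in c(10L, 6L, 4L)) {
      cand <- .allowed_codons(reference0, gid, margin = m, hi_frac = hi_frac)
      if (length(cand) >= 4L) return(cand)
    }
    cand
  }
  pick1 <- function(cand) cand[sample.int(length(cand), 1L)]
  pick_spaced <- function(cand, nd, gap = 8L) {
    nd <- min(nd, length(cand))
    for (try in 1:50) {
      pos <- sort(sample(cand, nd))
      if (nd == 1L || all(diff(pos) >= gap)) return(pos)
    }
    while (nd > 1L) {
      nd <- nd - 1L
      for (try in 1:50) {
        pos <- sort(sample(cand, nd))
        if (nd == 1L || all(diff(pos) >= gap)) return(pos)
      }
    }
    pick1(cand)
  }

  for (gid in lost) {
    cand <- codons_for(gid)
    nd <- sample(1:3, 1L)
    pos <- pick_spaced(cand, nd)
    nd <- length(pos)
    kinds <- sample(dis_kinds, nd, replace = TRUE)
    # two pure frameshifts can cancel; anchor multi-event losses with a stop
    if (nd == 2L && !"premature_stop" %in% kinds) kinds[1] <- "premature_stop"
    for (i in seq_len(nd))
      add(planned_event(gid, kinds[i], codon_position = pos[i],
                        size = sample(1:2, 1L)))
  }

  art_types <- rep(c("duplicate_copy", "retrocopy", "family_paralog",
                     "assembly_error", "compensatory_pair", "terminal_stop",
                     "predicted", "tsl"), length.out = n_artifact)
  for (i in seq_along(artifact)) {
    gid <- artifact[i]
    g <- reference0$genes[reference0$genes$gene_id == gid, ]
    cand <- codons_for(gid)
    typ <- art_types[i]
    if (typ == "duplicate_copy") {
      add(planned_event(gid, "duplicate_copy",
                        copy_coverage = stats::runif(1, 0.85, 1)))
      add(planned_event(gid, "premature_stop", codon_position = pick1(cand)))
    } else if (typ == "retrocopy") {
      add(planned_event(gid, "retrocopy", copy_coverage = 1))
      add(planned_event(gid, "premature_stop", codon_position = pick1(cand)))
    } else if (typ == "family_paralog") {
      add(planned_event(gid, "family_paralog", copy_coverage = 1))
      add(planned_event(gid, "premature_stop", codon_position = pick1(cand)))
      ov[[length(ov) + 1L]] <- data.frame(gene_id = gid, family = "olfactory receptor")
    } else if (typ == "assembly_error") {
      add(planned_event(gid, "assembly_error", codon_position = pick1(cand),
                        size = 1L))
    } else if (typ == "compensatory_pair") {
      ok <- cand[cand + 30L <= g$protein_len - 5L &
                   vapply(cand, function(p) (p + 30L) %in%
                            .allowed_codons(reference0, gid, hi_frac = 0.95),
                          logical(1))]
      add(planned_event(gid, "compensatory_pair",
                        codon_position = if (length(ok)) pick1(ok) else cand[1],
                        size = 1L))
    } else if (typ == "terminal_stop") {
      pos <- max(ceiling(0.93 * g$protein_len), g$protein_len - 10L)
      add(planned_event(gid, "premature_stop",
                        codon_position = min(pos, g$protein_len - 1L)))
    } else if (typ == "predicted") {
      add(planned_event(gid, "premature_stop", codon_position = pick1(cand)))
      ov[[length(ov) + 1L]] <- data.frame(gene_id = gid, predicted = TRUE)
    } else if (typ == "tsl") {
      add(planned_event(gid, "premature_stop", codon_position = pick1(cand)))
      ov[[length(ov) + 1L]] <- data.frame(gene_id = gid, tsl = 5L, ccds = FALSE)
    }
  }

  overrides <- if (length(ov)) {
    all_cols <- c("gene_id", "predicted", "intronless_cdna", "tsl", "ccds", "family")
    ov <- lapply(ov, function(d) {
      for (cc in setdiff(all_cols, names(d))) d[[cc]] <- NA
      d[all_cols]
    })
    do.call(rbind, ov)
  } else NULL

  focal_cfg <- sim_config(n_genes = n_genes, divergence = divergence,
                          seed = seed, event_plan = plan,
                          annotation_overrides = overrides)
  reference <- generate_reference(focal_cfg)
  focal <- evolve_query(reference, focal_cfg)
  # two clean control lineages (mirroring the rat / guinea-pig roles):
  # more background branches stabilise the background omega estimate
  control_cfg <- sim_config(n_genes = n_genes, divergence = divergence,
                            seed = as.integer((seed + 77) %% .Machine$integer.max))
  control <- evolve_query(reference, control_cfg)
  control2_cfg <- sim_config(n_genes = n_genes, divergence = divergence,
                             seed = as.integer((seed + 104729) %% .Machine$integer.max))
  control2 <- evolve_query(reference, control2_cfg)

  supports <- list(
    focal = emit_read_support(focal$assembly, focal$truth$error_sites,
                              depth = 30, seed = seed + 5L),
    control = emit_read_support(control$assembly, NULL, depth = 30,
                                seed = seed + 6L),
    control2 = emit_read_support(control2$assembly, NULL, depth = 30,
                                 seed = seed + 7L))

  list(reference = reference,
       queries = list(focal = focal, control = control, control2 = control2),
       supports = supports, truth = focal$truth, plan = plan)
}

#' Score a screen against the benchmark truth
#'
#' @param screen A `pg_screen` from [run_gene_loss_screen()].
#' @param truth The focal truth table (from [standard_benchmark()]).
#' @param species Species to score (default `"focal"`).
#' @return List: `sensitivity`, `precision`, `tp`, `fp`, `fn`, plus the
#'   id sets.
#' @export
benchmark_confusion <- function(screen, truth, species = "focal") {
  final <- screen$results[[species]]$final %||% character(0)
  lost <- truth$genes$gene_id[truth$genes$fate == "lost"]
  tp <- intersect(final, lost)
  fp <- setdiff(final, lost)
  fn <- setdiff(lost, final)
  list(sensitivity = length(tp) / length(lost),
       precision = if (length(final)) length(tp) / length(final) else NA_real_,
       tp = length(tp), fp = length(fp), fn = length(fn),
       called = final, missed = fn, spurious = fp)
}
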