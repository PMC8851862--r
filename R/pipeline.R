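# Orchestration: map -> align -> call -> unitary filters -> FP filters ->
# relaxed-selection gate -> downstream statistics, with per-stage logging and
# the Table-1-style cascade report.

.log_stage <- function(log, stage, gene = "", action = "") {
  rec <- sprintf("stage=%s gene=%s action=%s", stage, gene, action)
  c(log, rec)
}

# codons of the query locus aligned to the reference protein, stop and
# frameshift codons excised; multiple of 3 by construction
aligned_cds <- function(aln) {
  p <- aln$pairs
  keep <- !is.na(p$codon) & p$q_aa != "*"
  paste(p$codon[keep], collapse = "")
}

#' Run the gene-loss screen on in-memory objects
#'
#' The programmatic core of the pipeline: takes a reference and one or more
#' query species (simulated or loaded from files) and runs every stage
#' through the relaxed-selection gate.
#'
#' @param reference A `pg_reference`.
#' @param queries Named list (per species) of `pg_query` objects or lists
#'   with `assembly` and optionally `synteny`.
#' @param supports Optional named list of `pg_support` tracks per species.
#' @param check_reads Named logical (per species): run the read-support rule?
#'   Defaults to TRUE where a track exists.
#' @param cfg A [pipeline_config()].
#' @param gate Run the relaxed-selection gate (default TRUE).
#' @param tree Optional species tree (taxa = species names + `"reference"`);
#'   defaults to a star topology, which is all parsimony counting needs.
#' @return A `pg_screen`: per-species `results` (alignments, calls, report,
#'   final gene ids), the structured `log`, and the configuration.
#' @export
run_gene_loss_screen <- function(reference, queries, supports = list(),
                                 check_reads = NULL, cfg = pipeline_config(),
                                 gate = TRUE, tree = NULL) {
  stopifnot(inherits(reference, "pg_reference"), length(queries) >= 1)
  if (is.null(names(queries)) || any(!nzchar(names(queries))))
    stop("queries must be a named list (species names)")
  params <- cfg_align_params(cfg)
  log <- character(0)
  species <- names(queries)
  all_taxa <- c(species, "reference")
  if (is.null(tree))
    tree <- ape::read.tree(text = paste0("(", paste(all_taxa, collapse = ","), ");"))

  per_species <- list()
  for (sp in species) {
    q <- queries[[sp]]
    support <- supports[[sp]]
    cr <- if (!is.null(check_reads)) isTRUE(check_reads[[sp]]) else !is.null(support)
    log <- .log_stage(log, "map", sp, "search_proteome")
    sr <- search_proteome(reference$proteome, q$assembly, params)
    loci <- sr$loci
    if (is.null(loci)) {
      loci <- data.frame(gene_id = character(0), chrom = character(0),
                         strand = character(0), start = integer(0),
                         end = integer(0), chain_cov = numeric(0))
    } else {
      loci <- loci[loci$similarity_pass & loci$chain_pass, , drop = FALSE]
    }

    alns <- list(); calls <- list(); status <- character(0)
    for (gid in unique(loci$gene_id)) {
      lg <- loci[loci$gene_id == gid, , drop = FALSE]
      lg <- lg[order(-lg$chain_cov, lg$chrom, lg$start), , drop = FALSE]
      aln <- align_protein_to_locus(reference$proteome[[gid]], lg[1L, ],
                                    q$assembly, params)
      alns[[gid]] <- aln
      d <- call_disruptions(aln, support, window = cfg$window)
      cls <- classify_locus(aln, d, cfg$coverage_floor)
      status[gid] <- cls
      log <- .log_stage(log, "call", gid, cls)
      if (cls == "putative_pseudogenic")
        calls[[gid]] <- pseudogene_call(aln, d, species = sp)
    }
    ctx <- filter_context(genes = reference$genes, hits = sr$hits,
                          synteny = q$synteny, support = support,
                          check_reads = cr, copy_cov = cfg$copy_cov,
                          trunc = cfg$trunc, window = as.integer(cfg$window),
                          min_identity = cfg$min_identity,
                          boundary_nt = as.integer(cfg$boundary_nt),
                          read_conf = cfg$read_conf,
                          min_depth = as.integer(cfg$min_depth))
    fc <- apply_filter_cascade(unname(calls), ctx)
    names(fc$calls) <- names(calls)
    log <- .log_stage(log, "filter", sp,
                      paste0(fc$report$counts[["after_fp"]], "_surviving"))
    per_species[[sp]] <- list(alignments = alns, locus_status = status,
                              calls = fc$calls, report = fc$report,
                              hits = sr$hits, loci = loci)
  }

  # relaxed-selection gate: ortholog groups keyed by reference gene
  if (gate) {
    for (sp in species) {
      res <- per_species[[sp]]
      surv <- names(res$calls)[vapply(res$calls, function(x)
        x$status == "passed", logical(1))]
      for (gid in surv) {
        cds <- c(stats::setNames(aligned_cds(res$alignments[[gid]]), sp))
        refcds <- spliced_cds(reference$assembly,
                              reference$exons[reference$exons$gene_id == gid, , drop = FALSE])
        cds["reference"] <- substr(refcds, 1L, nchar(refcds) - 3L)
        for (other in setdiff(species, sp)) {
          oa <- per_species[[other]]$alignments[[gid]]
          ost <- per_species[[other]]$locus_status[gid]
          if (!is.null(oa) && !is.na(ost) && ost == "intact")
            cds[other] <- aligned_cds(oa)
        }
        grp <- ortholog_group(gid, cds, tree, foreground = sp)
        aln <- build_codon_alignment(grp)
        filt <- mask_alignment(aln, gap_flank_nt = as.integer(cfg$gap_flank),
                               min_len_nt = as.integer(cfg$min_aln))
        call <- res$calls[[gid]]
        if (filt$dropped) {
          call <- trail_add(call, "relax", "min_alignment_length", "remove")
          call$status <- "removed:short_alignment"
        } else {
          om <- estimate_omega(filt, tree, foreground = sp,
                               outgroup = "reference")
          rr <- relaxation_test(om$omega_fg, om$omega_bg, om$percol,
                                B = as.integer(cfg$bootstrap_B),
                                seed = as.integer(cfg$seed))
          call$relaxation <- rr
          keep <- rr$retained && (is.na(rr$k) || rr$k < cfg$k_threshold)
          call <- trail_add(call, "relax", "omega_fg_gt_bg_and_k_lt_1",
                            if (keep) "retain" else "remove")
          call$status <- if (keep) "retained" else
            paste0("removed:", if (nzchar(rr$reason)) rr$reason else "no_relaxation")
        }
        log <- .log_stage(log, "relax", gid, call$status)
        per_species[[sp]]$calls[[gid]] <- call
      }
      st <- vapply(per_species[[sp]]$calls, `[[`, "", "status")
      per_species[[sp]]$report$counts[["after_relax"]] <- sum(st == "retained")
      per_species[[sp]]$final <- names(st)[st == "retained"]
    }
  } else {
    for (sp in species) {
      st <- vapply(per_species[[sp]]$calls, `[[`, "", "status")
      per_species[[sp]]$final <- names(st)[st == "passed"]
    }
  }
  structure(list(results = per_species, log = log, cfg = cfg,
                 species = species), class = "pg_screen")
}

#' @export
print.pg_screen <- function(x, ...) {
  for (sp in x$species) {
    r <- x$results[[sp]]
    cat(sp, ": ", paste(names(r$report$counts), r$report$counts,
                        sep = "=", collapse = " "), "\n", sep = "")
  }
  invisible(x)
}

#' Run the pipeline from a configuration file
#'
#' File-based orchestration: reads every input named in the configuration,
#' runs [run_gene_loss_screen()], and writes the final pseudogene table,
#' cascade report, filter trails and downstream statistics into the run
#' directory. Stage failures abort with the stage name and offending record.
#'
#' @param cfg A `pipeline_config` or path to a config file.
#' @param stop_after Optional stage name (`"map"`, `"call"`, `"filter"`,
#'   `"relax"`, `"stats"`): run only up to that stage.
#' @return The `pg_screen`, invisibly; side effect: files under `outdir`.
#' @export
run_pipeline <- function(cfg, stop_after = "stats") {
  if (is.character(cfg)) cfg <- parse_config(cfg)
  stages <- c("map", "call", "filter", "relax", "stats")
  stop_after <- match.arg(stop_after, stages)
  need <- function(key) {
    if (is.null(cfg[[key]])) stop("config error: missing key ", key, call. = FALSE)
    cfg[[key]]
  }
  outdir <- cfg$outdir %||% "pgloss_run"
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  reference <- read_gff3_reference(need("reference_gff3"), need("reference_fasta"))
  species <- need("species")
  queries <- list(); supports <- list(); check_reads <- list()
  for (sp in species) {
    fa <- need(paste0("query_fasta.", sp))
    syn_p <- cfg[[paste0("synteny_tsv.", sp)]]
    sup_p <- cfg[[paste0("support_tsv.", sp)]]
    queries[[sp]] <- list(assembly = read_fasta(fa, "dna"),
                          synteny = if (!is.null(syn_p)) read_tsv(syn_p) else NULL)
    if (!is.null(sup_p)) supports[[sp]] <- read_support_tsv(sup_p)
    check_reads[[sp]] <- cfg[[paste0("check_reads.", sp)]] %||% !is.null(sup_p)
  }
  tree <- if (!is.null(cfg$tree_newick)) ape::read.tree(cfg$tree_newick) else NULL

  gate <- stop_after %in% c("relax", "stats")
  screen <- run_gene_loss_screen(reference, queries, supports, check_reads,
                                 cfg = cfg, gate = gate, tree = tree)
  # stage outputs
  for (sp in screen$species) {
    r <- screen$results[[sp]]
    spdir <- file.path(outdir, sp)
    dir.create(spdir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(r$hits)) write_tsv(r$hits, file.path(spdir, "hits.tsv"))
    if (!is.null(r$loci)) write_tsv(r$loci, file.path(spdir, "loci.tsv"))
    if (stop_after == "map") next
    write_alignments_tsv(r$alignments, spdir)
    dis <- do.call(rbind, lapply(r$calls, function(cl) {
      d <- cl$disruptions
      if (!nrow(d)) return(NULL)
      if (is.null(d$valid)) d$valid <- NA # stage-1 removals never reach rule (a)
      cbind(gene_id = cl$gene_id, species = sp, status = cl$status, d)
    }))
    if (!is.null(dis)) write_tsv(dis, file.path(spdir, "disruptions.tsv"))
    if (stop_after == "call") next
    trails <- do.call(rbind, lapply(r$calls, function(cl)
      if (nrow(cl$filter_trail)) cbind(gene_id = cl$gene_id, cl$filter_trail) else NULL))
    if (!is.null(trails)) write_tsv(trails, file.path(spdir, "filter_trail.tsv"))
    cnt <- r$report$counts
    write_tsv(data.frame(stage = names(cnt), count = as.integer(cnt)),
              file.path(spdir, "cascade_report.tsv"))
    final <- data.frame(gene_id = r$final %||% character(0))
    write_tsv(final, file.path(spdir, "final_pseudogenes.tsv"))
  }
  writeLines(screen$log, file.path(outdir, "pipeline.log"))

  if (stop_after == "stats") {
    finals <- lapply(screen$results, function(r) r$final %||% character(0))
    if (length(finals) >= 2L) {
      cmb <- utils::combn(screen$species, 2)
      plan <- data.frame(species1 = cmb[1, ], species2 = cmb[2, ])
      rep <- pair_overlap_report(finals, plan)
      write_tsv(rep$pairs, file.path(outdir, "pair_overlaps.tsv"))
      if (!is.null(rep$comparisons))
        write_tsv(rep$comparisons, file.path(outdir, "pair_comparisons.tsv"))
      if (!is.null(cfg$universe_n)) {
        ot <- overlap_hypergeometric(length(finals[[1]]), length(finals[[2]]),
                                     as.integer(cfg$universe_n),
                                     length(intersect(finals[[1]], finals[[2]])))
        write_tsv(data.frame(n1 = ot$n1, n2 = ot$n2, N = ot$N,
                             observed = ot$observed, expected = ot$expected,
                             p_hyper = ot$p_hyper),
                  file.path(outdir, "convergence_hypergeometric.tsv"))
      }
    }
    if (!is.null(cfg$conserved_tsv)) {
      cons <- read_tsv(cfg$conserved_tsv)$gene_id
      for (sp in screen$species) {
        v <- conserved_set_validation(finals[[sp]], cons)
        write_tsv(data.frame(species = sp, n_flagged = v$n_flagged,
                             n_conserved = v$n_conserved, percent = v$percent),
                  file.path(outdir, paste0("conserved_validation_", sp, ".tsv")))
      }
    }
    if (!is.null(cfg$obo) && !is.null(cfg$gaf) && !is.null(cfg$keyword_tsv)) {
      onto <- parse_obo(cfg$obo)
      gaf <- parse_gaf(cfg$gaf)
      kw <- read_tsv(cfg$keyword_tsv)
      mem <- assign_functional_groups(gaf, onto, kw)
      for (sp in screen$species) {
        bg <- setdiff(reference$genes$gene_id, finals[[sp]])
        ctl <- if (!is.null(cfg$control) && cfg$control %in% screen$species &&
                   cfg$control != sp) finals[[cfg$control]] else NULL
        enr <- efg_test(mem, finals[[sp]], bg, ctl, alpha = cfg$fdr_alpha)
        write_tsv(enr, file.path(outdir, paste0("enrichment_", sp, ".tsv")))
      }
    }
  }
  invisible(screen)
}
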