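# Unitary-status and false-positive filter cascade.

ref_genes_table <- function(n = 3, ...) {
  g <- data.frame(gene_id = sprintf("g%03d", seq_len(n)), chrom = "chr1",
                  strand = "+", start = (seq_len(n) - 1) * 2000L,
                  end = (seq_len(n) - 1) * 2000L + 1500L, n_exons = 3L,
                  protein_len = 100L, predicted = FALSE, intronless_cdna = FALSE,
                  tsl = 1L, ccds = TRUE, family = NA_character_,
                  stringsAsFactors = FALSE)
  ov <- list(...)
  for (nm in names(ov)) g[[nm]][1] <- ov[[nm]]
  g
}

fake_call <- function(gene_id = "g001", disruptions = NULL, protein_len = 100L,
                      locus = c(0L, 1500L)) {
  if (is.null(disruptions))
    disruptions <- data.frame(kind = "premature_stop", protein_pos = 50L,
                              genome_pos = 600L, size = NA_integer_,
                              window_identity = 0.95, boundary_distance = 200,
                              support = NA_integer_, total = NA_integer_)
  aln <- list(gene_id = gene_id, chrom = "chr1", strand = "+",
              locus_start = locus[1], locus_end = locus[2],
              blocks = data.frame(start = locus[1] + 100L, end = locus[2] - 100L),
              protein_len = protein_len, coverage = 0.98)
  pseudogene_call(aln, disruptions, species = "q")
}

default_ctx <- function(genes = ref_genes_table(), ...) {
  syn <- data.frame(gene_id = genes$gene_id, ref_chrom = "chr1",
                    ref_start = genes$start, ref_end = genes$end,
                    query_chrom = "chr1", query_start = genes$start,
                    query_end = genes$end, strand = "+")
  filter_context(genes = genes, hits = NULL, synteny = syn, support = NULL, ...)
}

test_that("unitary filters remove for the right primary reason, in order", {
  ctx_fam <- default_ctx(ref_genes_table(family = "olfactory receptor 12"))
  c1 <- unitary_status_filter(fake_call(), ctx_fam)
  expect_equal(c1$status, "removed:gene_family")

  ctx_pred <- default_ctx(ref_genes_table(predicted = TRUE))
  expect_equal(unitary_status_filter(fake_call(), ctx_pred)$status,
               "removed:predicted_or_intronless")
  ctx_intronless <- default_ctx(ref_genes_table(intronless_cdna = TRUE))
  expect_equal(unitary_status_filter(fake_call(), ctx_intronless)$status,
               "removed:predicted_or_intronless")

  # redundancy: a second chained copy covering 0.85 of the protein
  hits <- data.frame(chrom = c("chr1", "chr9"), strand = "+",
                     tstart = c(100L, 5000L), tend = c(1400L, 6200L),
                     qstart = c(0L, 5L), qend = c(98L, 90L),
                     score = c(500, 400), evalue = 1e-20, len = 10000L,
                     gene_id = "g001")
  ctx_red <- default_ctx(); ctx_red$hits <- hits
  expect_equal(unitary_status_filter(fake_call(), ctx_red)$status,
               "removed:redundancy")
  # ...but a 50% copy passes
  hits2 <- hits; hits2$qend[2] <- 55L
  ctx_red2 <- default_ctx(); ctx_red2$hits <- hits2
  expect_equal(unitary_status_filter(fake_call(), ctx_red2)$status, "passed")

  # synteny: matching map passes, displaced locus or missing gene removes
  expect_equal(unitary_status_filter(fake_call(), default_ctx())$status, "passed")
  ctx_syn <- default_ctx()
  ctx_syn$synteny$query_start <- 90000L; ctx_syn$synteny$query_end <- 91500L
  c2 <- unitary_status_filter(fake_call(), ctx_syn)
  expect_equal(c2$status, "removed:non_syntenic")
  expect_true(any(grepl("position_mismatch", c2$filter_trail$decision)))
  ctx_missing <- default_ctx()
  ctx_missing$synteny <- ctx_missing$synteny[-1, ]
  c3 <- unitary_status_filter(fake_call(), ctx_missing)
  expect_equal(c3$status, "removed:non_syntenic")
  expect_true(any(grepl("missing_from_map", c3$filter_trail$decision)))
})

test_that("rule (a): terminal truncation, boundary, low identity", {
  ctx <- default_ctx()
  # single stop at codon 95 of 100: truncated fraction 0.94 > 0.9 -> removed
  d <- data.frame(kind = "premature_stop", protein_pos = 95L, genome_pos = 600L,
                  size = NA_integer_, window_identity = 0.95,
                  boundary_distance = 200, support = NA_integer_,
                  total = NA_integer_)
  call <- unitary_status_filter(fake_call(disruptions = d), ctx)
  expect_equal(false_positive_filter(call, ctx)$status, "removed:alignment_artifact")

  # low window identity voids the disruption
  d2 <- transform(d, protein_pos = 50L, window_identity = 0.35)
  call2 <- unitary_status_filter(fake_call(disruptions = d2), ctx)
  expect_equal(false_positive_filter(call2, ctx)$status, "removed:alignment_artifact")

  # boundary-adjacent disruption voids
  d3 <- transform(d, protein_pos = 50L, boundary_distance = 5)
  call3 <- unitary_status_filter(fake_call(disruptions = d3), ctx)
  expect_equal(false_positive_filter(call3, ctx)$status, "removed:alignment_artifact")

  # mid-gene, clean disruption survives
  d4 <- transform(d, protein_pos = 50L)
  call4 <- unitary_status_filter(fake_call(disruptions = d4), ctx)
  expect_equal(false_positive_filter(call4, ctx)$status, "passed")
})

test_that("rule (b): read support voids unsupported disruptions; unknown passes", {
  ctx <- default_ctx()
  d <- data.frame(kind = "frameshift_ins", protein_pos = 50L, genome_pos = 600L,
                  size = 1L, window_identity = 0.95, boundary_distance = 200,
                  support = 2L, total = 30L)
  call <- unitary_status_filter(fake_call(disruptions = d), ctx)
  out <- false_positive_filter(call, ctx)
  expect_equal(out$status, "removed:read_unsupported")

  d2 <- transform(d, support = 29L)
  call2 <- unitary_status_filter(fake_call(disruptions = d2), ctx)
  expect_equal(false_positive_filter(call2, ctx)$status, "passed")

  # unknown support: passes with a logged warning
  d3 <- transform(d, support = NA_integer_, total = NA_integer_)
  call3 <- unitary_status_filter(fake_call(disruptions = d3), ctx)
  out3 <- false_positive_filter(call3, ctx)
  expect_equal(out3$status, "passed")
  expect_true(any(grepl("unknown support", out3$filter_trail$decision)))

  # filter disabled per species (no raw reads available)
  ctx_off <- default_ctx(check_reads = FALSE)
  call4 <- unitary_status_filter(fake_call(disruptions = d), ctx_off)
  expect_equal(false_positive_filter(call4, ctx_off)$status, "passed")
})

test_that("rule (c): reference model must have TSL 1/2 or CCDS", {
  ctx_bad <- default_ctx(ref_genes_table(tsl = 4L, ccds = FALSE))
  call <- unitary_status_filter(fake_call(), ctx_bad)
  expect_equal(false_positive_filter(call, ctx_bad)$status,
               "removed:annotation_unsupported")
  ctx_tsl4_ccds <- default_ctx(ref_genes_table(tsl = 4L, ccds = TRUE))
  call2 <- unitary_status_filter(fake_call(), ctx_tsl4_ccds)
  expect_equal(false_positive_filter(call2, ctx_tsl4_ccds)$status, "passed")
})

test_that("rule (d): exactly two frame-restoring frameshifts remove the call", {
  ctx <- default_ctx()
  mk <- function(kinds, sizes, poss = c(30L, 60L)) {
    data.frame(kind = kinds, protein_pos = poss, genome_pos = poss * 10L,
               size = sizes, window_identity = 0.95, boundary_distance = 200,
               support = NA_integer_, total = NA_integer_)
  }
  run <- function(d) {
    call <- unitary_status_filter(fake_call(disruptions = d), ctx)
    false_positive_filter(call, ctx)$status
  }
  expect_equal(run(mk(c("frameshift_ins", "frameshift_del"), c(1L, 1L))),
               "removed:compensatory_pair")
  expect_equal(run(mk(c("frameshift_ins", "frameshift_del"), c(2L, 2L))),
               "removed:compensatory_pair")
  expect_equal(run(mk(c("frameshift_ins", "frameshift_ins"), c(1L, 2L))),
               "removed:compensatory_pair")  # sizes summing to 3
  expect_equal(run(mk(c("frameshift_ins", "frameshift_ins"), c(1L, 1L))),
               "passed")
  # a stop among them breaks the rule
  d3 <- rbind(mk(c("frameshift_ins", "frameshift_del"), c(1L, 1L)),
              data.frame(kind = "premature_stop", protein_pos = 45L,
                         genome_pos = 450L, size = NA_integer_,
                         window_identity = 0.95, boundary_distance = 200,
                         support = NA_integer_, total = NA_integer_))
  expect_equal(run(d3), "passed")
})

test_that("cascade: counts non-increasing, reasons partition removals", {
  genes <- ref_genes_table(6)
  genes$family[2] <- "vomeronasal receptor"
  genes$tsl[3] <- 5L; genes$ccds[3] <- FALSE
  syn <- data.frame(gene_id = genes$gene_id, ref_chrom = "chr1",
                    ref_start = genes$start, ref_end = genes$end,
                    query_chrom = "chr1", query_start = genes$start,
                    query_end = genes$end, strand = "+")
  ctx <- filter_context(genes = genes, hits = NULL, synteny = syn)
  calls <- lapply(genes$gene_id, function(g) {
    fc <- fake_call(gene_id = g)
    fc$locus_start <- genes$start[genes$gene_id == g]
    fc$locus_end <- genes$end[genes$gene_id == g]
    fc$core_start <- fc$locus_start + 100L; fc$core_end <- fc$locus_end - 100L
    fc
  })
  res <- apply_filter_cascade(calls, ctx)
  cnt <- res$report$counts
  expect_true(all(diff(cnt[c("putative", "unitary", "after_fp")]) <= 0))
  removed <- vapply(res$calls, function(x) grepl("^removed:", x$status), logical(1))
  expect_equal(sum(removed) + cnt[["after_fp"]], cnt[["putative"]])
  # every removal has exactly one primary reason
  reasons <- vapply(res$calls[removed], `[[`, "", "status")
  expect_true(all(grepl("^removed:[a-z_]+$", reasons)))
  # empty input
  res0 <- apply_filter_cascade(list(), ctx)
  expect_equal(unname(res0$report$counts[1:3]), c(0L, 0L, 0L))
})

test_that("stage rules are conjunctive: cascade set equals per-rule intersection", {
  # a gene failing several rules is removed exactly once, and the survivors
  # are precisely those passing every rule individually
  genes <- ref_genes_table(4)
  genes$family[1] <- "zinc finger protein"
  genes$predicted[1] <- TRUE            # fails two rules of stage 1
  genes$tsl[2] <- 3L; genes$ccds[2] <- FALSE
  syn <- data.frame(gene_id = genes$gene_id, ref_chrom = "chr1",
                    ref_start = genes$start, ref_end = genes$end,
                    query_chrom = "chr1", query_start = genes$start,
                    query_end = genes$end, strand = "+")
  ctx <- filter_context(genes = genes, hits = NULL, synteny = syn)
  calls <- lapply(genes$gene_id, function(g) {
    fc <- fake_call(gene_id = g)
    fc$locus_start <- genes$start[genes$gene_id == g]
    fc$locus_end <- genes$end[genes$gene_id == g]
    fc$core_start <- fc$locus_start + 100L; fc$core_end <- fc$locus_end - 100L
    fc
  })
  res <- apply_filter_cascade(calls, ctx)
  surviving <- vapply(res$calls, function(x) x$status == "passed", logical(1))
  manual_pass <- !(!is.na(genes$family)) & !genes$predicted &
    (genes$tsl %in% 1:2 | genes$ccds)
  expect_equal(unname(surviving), unname(manual_pass))
})
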