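# Disruption calling and locus classification.

aln_for <- function(world, gid, assembly = world$query$assembly,
                    pa = align_params(n_decoys = 10)) {
  g <- world$ref$genes[world$ref$genes$gene_id == gid, ]
  locus <- list(gene_id = gid, chrom = "chr1", start = max(0, g$start - 100),
                end = g$end + 100, strand = "+")
  align_protein_to_locus(world$ref$proteome[[gid]], locus, assembly, pa)
}

test_that("planted stop and 2 nt insertion are called at their codons", {
  plan <- list(planned_event("g001", "premature_stop", codon_position = 120),
               planned_event("g002", "frameshift_ins", codon_position = 80, size = 2))
  w <- tiny_world(seed = 31, n_genes = 3, divergence = 0,
                  plan = plan)
  d1 <- call_disruptions(aln_for(w, "g001"))
  expect_equal(nrow(d1), 1L)
  expect_equal(d1$kind, "premature_stop")
  expect_equal(d1$protein_pos, 120L)
  d2 <- call_disruptions(aln_for(w, "g002"))
  expect_equal(nrow(d2), 1L)
  expect_equal(d2$kind, "frameshift_ins")
  expect_equal(d2$size, 2L)
  # intact gene: the query's own terminal stop never counts as a disruption
  d3 <- call_disruptions(aln_for(w, "g003"))
  expect_equal(nrow(d3), 0L)
})

test_that("completeness at zero noise: disruption sets equal the truth table", {
  # positions drawn clear of exon boundaries (splice-adjacent events are the
  # aligner's declared ambiguity zone); indel positions may shift by one
  # codon when neighbouring bases repeat (leftmost tie-break)
  base <- tiny_world(seed = 37, n_genes = 2, divergence = 0)
  pos1 <- pgloss:::.allowed_codons(base$ref, "g001")
  pos2 <- pgloss:::.allowed_codons(base$ref, "g002")
  p1 <- pos1[c(1, length(pos1))]
  plan <- list(planned_event("g001", "premature_stop", codon_position = p1[1]),
               planned_event("g001", "frameshift_del", codon_position = p1[2], size = 2),
               planned_event("g002", "frameshift_ins",
                             codon_position = pos2[length(pos2) %/% 2], size = 1))
  w <- tiny_world(seed = 37, n_genes = 2, divergence = 0, plan = plan)
  for (gid in c("g001", "g002")) {
    d <- call_disruptions(aln_for(w, gid))
    truth <- w$query$truth$events[w$query$truth$events$gene_id == gid, ]
    expect_equal(nrow(d), nrow(truth))
    d <- d[order(d$protein_pos), ]; truth <- truth[order(truth$codon_position), ]
    expect_equal(d$kind, truth$kind)
    expect_true(all(abs(d$protein_pos - truth$codon_position) <= 1))
  }
})

test_that("disruption-count pattern: one stop vs one stop plus four indels", {
  # the convergent-loss poster child: disabled by a single premature stop in
  # one lineage and by 1 stop + 4 indels in the other
  base <- tiny_world(seed = 41, n_genes = 1, divergence = 0)
  cand <- pgloss:::.allowed_codons(base$ref, "g001")
  pos <- cand[round(seq(1, length(cand), length.out = 5))]
  stopifnot(all(diff(pos) >= 8))
  plan_a <- list(planned_event("g001", "premature_stop", codon_position = pos[1]))
  plan_b <- list(planned_event("g001", "premature_stop", codon_position = pos[1]),
                 planned_event("g001", "frameshift_ins", codon_position = pos[2], size = 1),
                 planned_event("g001", "frameshift_del", codon_position = pos[3], size = 1),
                 planned_event("g001", "frameshift_ins", codon_position = pos[4], size = 2),
                 planned_event("g001", "frameshift_del", codon_position = pos[5], size = 2))
  wa <- tiny_world(seed = 41, n_genes = 1, divergence = 0, plan = plan_a)
  wb <- tiny_world(seed = 41, n_genes = 1, divergence = 0, plan = plan_b)
  expect_equal(nrow(call_disruptions(aln_for(wa, "g001"))), 1L)
  expect_equal(nrow(call_disruptions(aln_for(wb, "g001"))), 5L)
})

test_that("indels within one codon merge to net size; net-0 disappears", {
  aln <- list(events = data.frame(
    kind = c("frameshift_ins", "frameshift_del", "frameshift_ins", "frameshift_ins"),
    protein_pos = c(40L, 40L, 70L, 70L),
    seg_pos = c(120L, 121L, 210L, 211L),
    genome_pos = c(1120L, 1121L, 1210L, 1211L),
    size = c(1L, 1L, 1L, 1L)),
    pairs = data.frame(), introns = data.frame(seg_start = integer(0), seg_end = integer(0)),
    chrom = "chr1", protein_len = 100L)
  d <- call_disruptions(aln)
  expect_equal(nrow(d), 1L)  # codon 40 cancels; codon 70 nets +2
  expect_equal(d$protein_pos, 70L)
  expect_equal(d$kind, "frameshift_ins")
  expect_equal(d$size, 2L)
})

test_that("classification respects the coverage floor", {
  d0 <- data.frame(); d1 <- data.frame(kind = "premature_stop")
  expect_equal(classify_locus(list(coverage = 0.9), d1), "putative_pseudogenic")
  expect_equal(classify_locus(list(coverage = 0.9), d0), "intact")
  expect_equal(classify_locus(list(coverage = 0.2), d1), "unalignable")
})

test_that("no phantom events on clean genes at divergence 0.1", {
  w <- tiny_world(seed = 43, n_genes = 25, divergence = 0.1)
  phantom <- 0L
  for (gid in w$ref$genes$gene_id)
    if (nrow(call_disruptions(aln_for(w, gid))) > 0) phantom <- phantom + 1L
  expect_lte(phantom / 25, 0.01)
})
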