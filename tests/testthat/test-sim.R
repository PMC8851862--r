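# Synthetic-data module: construction guarantees, determinism, planted-event
# bookkeeping, read-support emulation, codon simulation.

test_that("generate_reference obeys its construction guarantees", {
  cfg <- sim_config(n_genes = 10, codons_per_gene = c(100, 300), seed = 1)
  ref <- generate_reference(cfg)
  expect_equal(nrow(ref$genes), 10L)
  expect_true(all(nchar(ref$proteome) >= 100 & nchar(ref$proteome) <= 300))
  for (g in ref$genes$gene_id) {
    cds <- pgloss:::spliced_cds(ref$assembly, ref$exons[ref$exons$gene_id == g, ])
    p <- translate_cds(cds)
    expect_equal(substr(p, 1, 1), "M")
    expect_equal(substr(p, nchar(p), nchar(p)), "*")
    expect_false(grepl("[*]", substr(p, 1, nchar(p) - 1)))
    expect_equal(substr(p, 1, nchar(p) - 1), unname(ref$proteome[[g]]))
    ex <- ref$exons[ref$exons$gene_id == g, ]
    ex <- ex[order(ex$rank), ]
    if (nrow(ex) > 1) for (e in seq_len(nrow(ex) - 1)) {
      intron <- substr(ref$assembly[["chr1"]], ex$end[e] + 1, ex$start[e + 1])
      expect_equal(substr(intron, 1, 2), "GT")
      expect_equal(substr(intron, nchar(intron) - 1, nchar(intron)), "AG")
    }
  }
  # genes non-overlapping and sorted
  expect_true(all(head(ref$genes$end, -1) <= tail(ref$genes$start, -1)))
})

test_that("identical (config, seed) reproduce byte-identical artifacts", {
  cfg <- sim_config(n_genes = 5, seed = 42, divergence = 0.1,
                    event_plan = list(planned_event("g002", "premature_stop",
                                                    codon_position = 50)))
  r1 <- generate_reference(cfg); r2 <- generate_reference(cfg)
  expect_identical(r1, r2)
  q1 <- evolve_query(r1, cfg); q2 <- evolve_query(r2, cfg)
  expect_identical(q1$assembly, q2$assembly)
  expect_identical(q1$truth, q2$truth)
  d <- withr::local_tempdir()
  write_fasta(r1$assembly, file.path(d, "a1.fa"), "dna")
  write_fasta(r2$assembly, file.path(d, "a2.fa"), "dna")
  write_gff3(r1, file.path(d, "g1.gff3")); write_gff3(r2, file.path(d, "g2.gff3"))
  expect_identical(readLines(file.path(d, "a1.fa")), readLines(file.path(d, "a2.fa")))
  expect_identical(readLines(file.path(d, "g1.gff3")), readLines(file.path(d, "g2.gff3")))
})

test_that("degenerate and invalid configurations are rejected cleanly", {
  cfg0 <- sim_config(n_genes = 0, seed = 1)
  ref0 <- generate_reference(cfg0)
  expect_length(ref0$proteome, 0)
  expect_equal(nrow(ref0$genes), 0L)
  d <- withr::local_tempdir()
  write_gff3(ref0, file.path(d, "empty.gff3"))
  expect_equal(readLines(file.path(d, "empty.gff3")), "##gff-version 3")

  expect_error(sim_config(n_genes = 5, divergence = 0.5), "divergence")
  expect_error(sim_config(n_genes = 5, codons_per_gene = c(300, 100)), "range")
  expect_error(sim_config(n_genes = 5, codons_per_gene = c(4, 6),
                          exons_per_gene = c(4, 8)), "exons")
  expect_error(planned_event("g1", "nonsense_kind"), "unknown event kind")
  expect_error(planned_event("g1", "frameshift_ins", codon_position = 5, size = 3),
               "1 or 2")
})

test_that("evolve_query realises the plan and records exact truth", {
  plan <- list(planned_event("g001", "premature_stop", codon_position = 50),
               planned_event("g002", "frameshift_del", codon_position = 40, size = 1),
               planned_event("g003", "duplicate_copy", copy_coverage = 0.85),
               planned_event("g003", "premature_stop", codon_position = 60),
               planned_event("g004", "compensatory_pair", codon_position = 30, size = 1))
  w <- tiny_world(seed = 3, n_genes = 5, divergence = 0.05, plan = plan)
  q <- w$query
  # truth completeness: every planted event appears exactly once per kind
  planned_kinds <- table(vapply(plan, `[[`, "", "kind"))
  got <- table(c(q$truth$events$kind, q$truth$copies$kind))
  for (k in names(planned_kinds)) expect_equal(unname(got[k]), unname(planned_kinds[k]))
  # planted stop is on the emitted assembly at the recorded coordinate
  ev <- q$truth$events
  stop1 <- ev[ev$gene_id == "g001", ]
  codon <- substr(q$assembly[["chr1"]], stop1$pos + 1, stop1$pos + 3)
  expect_true(codon %in% c("TAA", "TAG", "TGA"))
  # spliced CDS of g001 translates with a stop at codon 50
  exg <- w$ref$exons[w$ref$exons$gene_id == "g001", ]
  # deletion in g002 shifts downstream coordinates by 1 in the synteny map
  syn <- q$synteny
  expect_equal(syn$query_end[syn$gene_id == "g002"] -
                 syn$ref_end[syn$gene_id == "g002"], -1)
  # fates
  fate <- setNames(q$truth$genes$fate, q$truth$genes$gene_id)
  expect_equal(unname(fate[c("g001", "g002", "g003", "g004", "g005")]),
               c("lost", "lost", "artifact_only", "artifact_only", "intact"))
})

test_that("divergence 0 with an empty plan is the identity", {
  w <- tiny_world(seed = 11, n_genes = 3, divergence = 0)
  expect_identical(w$query$assembly[["chr1"]], w$ref$assembly[["chr1"]])
  expect_equal(nrow(w$query$truth$events), 0L)
})

test_that("plan errors are caught", {
  cfg <- sim_config(n_genes = 2, seed = 1, event_plan = list(
    planned_event("g009", "premature_stop", codon_position = 5)))
  ref <- generate_reference(sim_config(n_genes = 2, seed = 1))
  expect_error(evolve_query(ref, cfg), "unknown gene")
  cfg2 <- sim_config(n_genes = 2, seed = 1, event_plan = list(
    planned_event("g001", "premature_stop", codon_position = 50),
    planned_event("g001", "frameshift_ins", codon_position = 50)))
  expect_error(evolve_query(ref, cfg2), "collision")
})

test_that("read-support tracks mark planted error sites and nothing else", {
  assembly <- c(chr1 = paste(rep("ACGT", 250), collapse = ""))
  sup <- emit_read_support(assembly, NULL, depth = 30, seed = 1)
  expect_length(sup$chr1$total, 1000L)
  expect_identical(sup$chr1$support, sup$chr1$total)
  err <- data.frame(gene_id = "g", chrom = "chr1", pos = 499L)
  sup2 <- emit_read_support(assembly, err, depth = 30, seed = 1)
  frac <- sup2$chr1$support / sup2$chr1$total
  expect_lt(frac[500], 0.5)
  expect_equal(sum(frac < 1 - 1e-9), 1L)
  expect_error(emit_read_support(assembly, NULL, depth = 0), "depth")
})

test_that("codon simulator honours the omega_bg^k parameterisation", {
  expect_equal(0.2^0.5, 0.4472136, tolerance = 1e-6)
  tr <- "(a:0.05,b:0.05,c:0.05);"
  sim <- simulate_codon_sequences(tr, omega_bg = 0.2, k = 0.5, kappa = 2,
                                  n_codons = 50, seed = 9, foreground = "a")
  expect_equal(sim$omega_fg, 0.2^0.5)
  expect_true(all(nchar(sim$cds) == 150))
  # no stop codons anywhere
  for (s in sim$cds)
    expect_false(any(pgloss:::split_codons(s) %in% c("TAA", "TAG", "TGA")))
  # determinism
  sim2 <- simulate_codon_sequences(tr, 0.2, 0.5, 2, 50, seed = 9, foreground = "a")
  expect_identical(sim$cds, sim2$cds)
  # foreground marking via newick tag
  sim3 <- simulate_codon_sequences("(a#1:0.1,b:0.1,c:0.1);", 0.2, 1, 2, 10, seed = 2)
  expect_equal(sim3$foreground, "a")
  expect_error(simulate_codon_sequences("(a:0.1,b:0.1);", 0.2, 1, 2, 10, seed = 1),
               "foreground")
  expect_error(simulate_codon_sequences(tr, -1, 1, 2, 10, seed = 1, foreground = "a"),
               "omega_bg")
})
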