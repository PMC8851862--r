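# Spliced aligner and candidate-locus search.

test_that("two-codon example scores s(M,M) + s(K,K) and matches the oracle", {
  pa <- align_params(min_intron = 5)
  aln <- align_protein_to_locus("MK", list(chrom = "c", start = 0, end = 6,
                                           strand = "+"), c(c = "ATGAAA"), pa)
  b62 <- pgloss:::blosum62()
  expect_equal(aln$score, b62["M", "M"] + b62["K", "K"])
  expect_equal(aln$score, oracle_spliced_score("MK", "ATGAAA", pa))
  expect_equal(aln$coverage, 1)
  expect_equal(nrow(aln$events), 0L)
  expect_error(align_protein_to_locus("MK", list(chrom = "c", start = 0, end = 2,
                                                 strand = "+"), c(c = "AT"), pa),
               "shorter than one codon")
})

test_that("planted truth is recovered exactly at zero divergence", {
  w <- tiny_world(seed = 11, n_genes = 2, divergence = 0)
  ref <- w$ref
  g <- ref$genes[1, ]
  pa <- align_params(n_decoys = 10)
  locus <- list(gene_id = g$gene_id, chrom = "chr1",
                start = max(0, g$start - 100), end = g$end + 100, strand = "+")
  aln <- align_protein_to_locus(ref$proteome[[g$gene_id]], locus, ref$assembly, pa)
  expect_equal(aln$coverage, 1)
  expect_equal(nrow(aln$events), 0L)
  expect_equal(nrow(aln$introns), g$n_exons - 1L)
  ex <- ref$exons[ref$exons$gene_id == g$gene_id, ]
  ex <- ex[order(ex$rank), ]
  expect_equal(aln$introns$start, ex$end[-nrow(ex)])
  expect_equal(aln$introns$end, ex$start[-1])
  expect_true(all(aln$introns$canonical))
})

test_that("a planted 1 nt deletion yields exactly one frameshift at its codon", {
  plan <- list(planned_event("g001", "frameshift_del", codon_position = 50, size = 1))
  w <- tiny_world(seed = 13, n_genes = 2, divergence = 0, plan = plan)
  g <- w$ref$genes[1, ]
  pa <- align_params(n_decoys = 10)
  locus <- list(gene_id = "g001", chrom = "chr1", start = max(0, g$start - 100),
                end = g$end + 100, strand = "+")
  aln <- align_protein_to_locus(w$ref$proteome[["g001"]], locus,
                                w$query$assembly, pa)
  expect_equal(nrow(aln$events), 1L)
  expect_equal(aln$events$kind, "frameshift_del")
  expect_equal(aln$events$size, 1L)
  expect_equal(aln$events$protein_pos, 50L)
})

test_that("strand symmetry: reverse complement on the minus strand", {
  w <- tiny_world(seed = 17, n_genes = 1, divergence = 0)
  g <- w$ref$genes[1, ]
  pa <- align_params(n_decoys = 10)
  L <- nchar(w$ref$assembly[["chr1"]])
  flipped <- c(chr1 = revcomp(w$ref$assembly[["chr1"]]))
  plus <- align_protein_to_locus(w$ref$proteome[[1]],
                                 list(chrom = "chr1", start = g$start - 50,
                                      end = g$end + 50, strand = "+"),
                                 w$ref$assembly, pa)
  minus <- align_protein_to_locus(w$ref$proteome[[1]],
                                  list(chrom = "chr1", start = L - (g$end + 50),
                                       end = L - (g$start - 50), strand = "-"),
                                  flipped, pa)
  expect_equal(minus$score, plus$score)
  expect_equal(minus$coverage, plus$coverage)
  # mirrored coordinates: block footprints agree after reflection
  expect_setequal(L - minus$blocks$end, plus$blocks$start)
  expect_setequal(L - minus$blocks$start, plus$blocks$end)
})

test_that("DP equals the independent R oracle on random small instances", {
  pa <- align_params(min_intron = 5)
  set.seed(202)
  for (i in 1:60) {
    inst <- random_dp_instance()
    expect_equal(cpp_spliced_score(inst$protein, inst$dna, pa),
                 oracle_spliced_score(inst$protein, inst$dna, pa),
                 info = paste(inst$protein, inst$dna))
  }
})

test_that("R oracle equals exhaustive path enumeration on very small instances", {
  pa <- align_params(min_intron = 5)
  set.seed(303)
  for (i in 1:15) {
    inst <- random_dp_instance(max_aa = 3, max_nt = 12)
    expect_equal(oracle_spliced_score(inst$protein, inst$dna, pa),
                 oracle_enumerate_score(inst$protein, inst$dna, pa),
                 info = paste(inst$protein, inst$dna))
  }
})

test_that("find_candidate_loci: exact copy, absence, and double copies", {
  w <- tiny_world(seed = 19, n_genes = 1, divergence = 0)
  prot <- w$ref$proteome[1]
  pa <- fast_params()
  loci <- find_candidate_loci(prot, w$ref$assembly, pa)
  expect_equal(nrow(loci), 1L)
  expect_true(loci$similarity_pass && loci$chain_pass)
  expect_lte(loci$evalue, pa$evalue_max)

  junk <- c(chrX = paste(rep("ACGT", 500), collapse = ""))
  expect_equal(nrow(find_candidate_loci(prot, junk, pa)), 0L)

  gene_seq <- substr(w$ref$assembly[["chr1"]], w$ref$genes$start[1] + 1,
                     w$ref$genes$end[1])
  spacer <- strrep("T", 12000)
  double <- c(chr1 = paste0(spacer, gene_seq, spacer, gene_seq, spacer))
  loci2 <- find_candidate_loci(prot, double, pa)
  expect_equal(nrow(loci2), 2L)
})

test_that("recovery invariant: clean genes at divergence 0.1 align fully", {
  w <- tiny_world(seed = 23, n_genes = 6, divergence = 0.1)
  pa <- fast_params()
  sr <- search_proteome(w$ref$proteome, w$query$assembly, pa)
  for (gid in names(w$ref$proteome)) {
    lg <- sr$loci[sr$loci$gene_id == gid, ]
    expect_gte(nrow(lg), 1L)
    aln <- align_protein_to_locus(w$ref$proteome[[gid]], lg[1, ],
                                  w$query$assembly, pa)
    expect_gte(aln$coverage, 0.95)
    expect_equal(nrow(call_disruptions(aln)), 0L)
  }
})
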