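# Independent oracles and small fixture builders shared across the suite.
# The oracles deliberately re-derive results through different code paths
# (plain-R DP, factorial enumeration, path enumeration) from the
# implementations they check.

# ---- plain-R reference DP over the spliced-alignment state space ----------
# Local alignment; same transition set and scores as the C++ aligner, written
# independently as an iterative R dynamic program. Returns the best score.
oracle_spliced_score <- function(protein, dna, params) {
  b62 <- pgloss:::blosum62()
  gc <- Biostrings::GENETIC_CODE
  p <- strsplit(protein, "")[[1]]
  d <- strsplit(dna, "")[[1]]
  m <- length(p); n <- length(d)
  M <- matrix(0, m + 1, n + 1)
  sub_score <- function(a, b) {
    if (!a %in% rownames(b62)) a <- "X"
    if (!b %in% rownames(b62)) b <- "X"
    b62[a, b]
  }
  for (j in 0:n) for (i in 0:m) {
    v <- 0
    if (i >= 1 && j >= 3) {
      codon <- paste(d[(j - 2):j], collapse = "")
      if (!is.na(gc[codon])) {
        aa <- gc[[codon]]
        sc <- if (aa == "*") params$stop_pen else sub_score(p[i], aa)
        v <- max(v, M[i, j - 2] + sc)  # (i-1, j-3) in 0-based cells
      }
    }
    if (i >= 1 && j >= 1) v <- max(v, M[i, j] + params$fs_pen)
    if (i >= 1 && j >= 2) v <- max(v, M[i, j - 1] + params$fs_pen)
    if (i >= 1 && j >= 4) v <- max(v, M[i, j - 3] + params$fs_pen)
    if (i >= 1 && j >= 5) v <- max(v, M[i, j - 4] + params$fs_pen)
    if (i >= 1) v <- max(v, M[i, j + 1] + params$gap_codon)
    if (j >= 3) v <- max(v, M[i + 1, j - 2] + params$gap_codon)
    if (j >= params$min_intron) {
      for (js in 0:(j - params$min_intron)) {
        src <- M[i + 1, js + 1] + params$intron_open
        gt <- js + 2 <= n && d[js + 1] == "G" && d[js + 2] == "T"
        ag <- j >= 2 && d[j - 1] == "A" && d[j] == "G"
        if (gt && ag) src <- src + params$splice_bonus
        v <- max(v, src)
      }
    }
    M[i + 1, j + 1] <- v
  }
  max(M)
}

# exhaustive path enumeration (no memoisation) for very small instances:
# best local alignment score by recursively extending from every start cell
oracle_enumerate_score <- function(protein, dna, params) {
  b62 <- pgloss:::blosum62()
  gc <- Biostrings::GENETIC_CODE
  p <- strsplit(protein, "")[[1]]
  d <- strsplit(dna, "")[[1]]
  m <- length(p); n <- length(d)
  extend <- function(i, j) {
    best <- 0 # a path may end anywhere
    if (i < m && j + 3 <= n) {
      codon <- paste(d[(j + 1):(j + 3)], collapse = "")
      if (!is.na(gc[codon])) {
        aa <- gc[[codon]]
        sc <- if (aa == "*") params$stop_pen else {
          a1 <- if (p[i + 1] %in% rownames(b62)) p[i + 1] else "X"
          b62[a1, aa]
        }
        best <- max(best, sc + extend(i + 1, j + 3))
      }
    }
    for (dl in c(1, 2, 4, 5)) if (i < m && j + dl <= n)
      best <- max(best, params$fs_pen + extend(i + 1, j + dl))
    if (i < m) best <- max(best, params$gap_codon + extend(i + 1, j))
    if (j + 3 <= n) best <- max(best, params$gap_codon + extend(i, j + 3))
    if (j + params$min_intron <= n) {
      for (L in params$min_intron:(n - j)) {
        bonus <- 0
        gt <- d[j + 1] == "G" && (j + 2 <= n) && d[j + 2] == "T"
        ag <- d[j + L - 1] == "A" && d[j + L] == "G"
        if (gt && ag) bonus <- params$splice_bonus
        best <- max(best, params$intron_open + bonus + extend(i, j + L))
      }
    }
    best
  }
  best <- 0
  for (i in 0:m) for (j in 0:n) best <- max(best, extend(i, j))
  best
}

# C++ DP score through the package path
cpp_spliced_score <- function(protein, dna, params) {
  r <- pgloss:::spliced_dp_cpp(pgloss:::.prot2idx(protein),
                               pgloss:::.dna2idx(dna), pgloss:::blosum62(),
                               pgloss:::.codon_aa_idx(), params$fs_pen,
                               params$gap_codon, params$intron_open,
                               params$splice_bonus, params$stop_pen,
                               params$min_intron)
  r$score
}

# random tiny alignment instance: half pure noise, half with a planted
# (mutated, possibly intron-split) coding copy of the protein
random_dp_instance <- function(max_aa = 5L, max_nt = 30L) {
  aas <- setdiff(rownames(pgloss:::blosum62()), c("B", "Z", "X", "*"))
  m <- sample.int(max_aa, 1L)
  protein <- paste(sample(aas, m, replace = TRUE), collapse = "")
  if (runif(1) < 0.5) {
    n <- sample(seq(6L, max_nt), 1L)
    dna <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
  } else {
    rt <- names(Biostrings::GENETIC_CODE)
    gc <- Biostrings::GENETIC_CODE
    cods <- vapply(strsplit(protein, "")[[1]], function(a) {
      hit <- names(gc)[gc == a]
      if (!length(hit)) hit <- rt
      sample(hit, 1L)
    }, "")
    dna <- paste(cods, collapse = "")
    if (runif(1) < 0.4 && nchar(dna) >= 6) { # intron between codons
      at <- 3L * sample.int(m - 1L + (m == 1L), 1L)
      intron <- paste0("GT", paste(sample(c("A", "C", "G", "T"), 3, replace = TRUE),
                                   collapse = ""), "AG")
      dna <- paste0(substr(dna, 1, at), intron, substr(dna, at + 1, nchar(dna)))
    }
    dc <- strsplit(dna, "")[[1]]
    nmut <- rbinom(1, length(dc), 0.1)
    if (nmut > 0) {
      at <- sample(seq_along(dc), nmut)
      dc[at] <- sample(c("A", "C", "G", "T"), nmut, replace = TRUE)
    }
    dna <- paste(dc, collapse = "")
    if (nchar(dna) > max_nt) dna <- substr(dna, 1, max_nt)
    if (nchar(dna) < 6) dna <- paste0(dna, "ACGTAC")
  }
  list(protein = protein, dna = dna)
}

# ---- factorial-enumeration oracles for the statistics module --------------
# two-sided Fisher p for table (a, b, c, d) by enumerating the full support
# with lchoose arithmetic (independent of dhyper)
oracle_fisher_p <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; N <- r1 + r2
  if (r1 == 0 || r2 == 0 || c1 == 0 || c1 == N) return(1)
  ks <- max(0, c1 - r2):min(r1, c1)
  logp <- lchoose(r1, ks) + lchoose(r2, c1 - ks) - lchoose(N, c1)
  pr <- exp(logp)
  obs <- pr[ks == a]
  sum(pr[pr <= obs * (1 + 1e-7)])
}

# upper-tail hypergeometric by enumeration
oracle_hyper_upper <- function(n1, n2, N, obs) {
  ks <- max(0, n1 + n2 - N):min(n1, n2)
  pr <- exp(lchoose(n1, ks) + lchoose(N - n1, n2 - ks) - lchoose(N, n2))
  sum(pr[ks >= obs])
}

# ---- shared fixtures ------------------------------------------------------
balanced16_tree <- function(bl = 0.05) {
  tip <- function(i) sprintf("t%d:%g", i, bl)
  pair <- function(a, b) sprintf("(%s,%s):%g", a, b, bl)
  l1 <- lapply(seq(1, 16, 2), function(i) pair(tip(i), tip(i + 1)))
  l2 <- lapply(seq(1, 8, 2), function(i) pair(l1[[i]], l1[[i + 1]]))
  l3 <- lapply(c(1, 3), function(i) pair(l2[[i]], l2[[i + 1]]))
  ape::read.tree(text = paste0("(", l3[[1]], ",", l3[[2]], ");"))
}

# small simulated world reused by several test files
tiny_world <- function(seed = 7L, n_genes = 4L, divergence = 0.05,
                       plan = list()) {
  cfg <- sim_config(n_genes = n_genes, divergence = divergence, seed = seed,
                    event_plan = plan)
  ref <- generate_reference(cfg)
  list(cfg = cfg, ref = ref, query = evolve_query(ref, cfg))
}

fast_params <- function(...) align_params(n_decoys = 30L, seed = 1L, ...)
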