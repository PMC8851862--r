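# Codon-sequence simulation under a Muse-Gaut-style process with a single
# foreground branch whose omega is omega_bg^k (the selection-intensity
# parameterisation: k < 1 relaxes, k > 1 intensifies constraint).

.resolve_tree <- function(tree) {
  if (inherits(tree, "phylo")) return(tree)
  if (is.character(tree) && length(tree) == 1L) {
    tr <- if (file.exists(tree)) ape::read.tree(tree) else ape::read.tree(text = tree)
    if (is.null(tr)) stop("could not parse newick tree")
    return(tr)
  }
  stop("tree must be a phylo object, a newick string, or a file path")
}

# foreground mark: explicit argument, or tip labels carrying a '#1' or '{FG}'
# suffix in the newick (the suffix is stripped from the returned tree)
resolve_foreground <- function(tree, foreground = NULL) {
  tree <- .resolve_tree(tree)
  tagged <- grepl("(#1|\\{FG\\})$", tree$tip.label)
  if (is.null(foreground)) {
    if (sum(tagged) != 1L)
      stop("tree must carry exactly one foreground mark ('#1' or '{FG}' tip suffix)")
    foreground <- sub("(#1|\\{FG\\})$", "", tree$tip.label[tagged])
  }
  tree$tip.label <- sub("(#1|\\{FG\\})$", "", tree$tip.label)
  if (!foreground %in% tree$tip.label)
    stop("foreground taxon not in tree: ", foreground)
  list(tree = tree, foreground = foreground)
}

# per-codon substitution rate structure for a given omega; rates normalised so
# the mean total rate over a uniform sense-codon distribution is 3 (one
# expected substitution per nt site per unit branch length)
.codon_rates <- function(omega, kappa) {
  nbs <- codon_neighbours(kappa)
  rates <- lapply(nbs, function(d) {
    r <- d$weight * ifelse(d$synonymous, 1, omega)
    list(to = d$to, rate = r, total = sum(r))
  })
  rho <- mean(vapply(rates, `[[`, 0, "total"))
  lapply(rates, function(x) {
    x$rate <- x$rate * 3 / rho; x$total <- x$total * 3 / rho; x
  })
}

.evolve_codon_branch <- function(codons, rates, t) {
  if (t <= 0) return(codons)
  for (i in seq_along(codons)) {
    time <- t
    repeat {
      r <- rates[[codons[i]]]
      wait <- stats::rexp(1L, r$total)
      if (wait > time) break
      time <- time - wait
      codons[i] <- sample(r$to, 1L, prob = r$rate)
    }
  }
  codons
}

#' Simulate codon sequences with one relaxed/intensified foreground branch
#'
#' Evolves an alignment-free set of codon sequences down a tree under a
#' single-nucleotide-step codon process (transition bias `kappa`, no stop
#' codons). Background branches use `omega_bg`; the branch leading to the
#' foreground tip uses `omega_bg^k`.
#'
#' @param tree A `phylo` object, newick string or file; branch lengths in
#'   expected substitutions per nt site. The foreground may be tagged in the
#'   newick with a `#1` (or `{FG}`) tip-label suffix.
#' @param omega_bg Background dN/dS (> 0).
#' @param k Selection intensity; foreground omega is `omega_bg^k`.
#' @param kappa Transition/transversion rate ratio.
#' @param n_codons Number of codons (>= 1).
#' @param seed Integer seed.
#' @param foreground Optional foreground tip label (overrides newick tags).
#' @return List: `cds` named character vector of per-taxon coding sequences,
#'   `tree` (phylo, tags stripped), `foreground`, `omega_fg`, `omega_bg`, `k`.
#' @export
simulate_codon_sequences <- function(tree, omega_bg, k = 1, kappa = 2,
                                     n_codons, seed = 1L, foreground = NULL) {
  if (!is.finite(omega_bg) || omega_bg <= 0) stop("omega_bg must be > 0")
  if (n_codons < 1L) stop("n_codons must be >= 1")
  fg <- resolve_foreground(tree, foreground)
  tree <- fg$tree; foreground <- fg$foreground
  set.seed(as.integer(seed %% .Machine$integer.max))

  omega_fg <- omega_bg^k
  bg_rates <- .codon_rates(omega_bg, kappa)
  fg_rates <- if (identical(omega_fg, omega_bg)) bg_rates else .codon_rates(omega_fg, kappa)

  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  if (is.null(tree$edge.length)) stop("tree needs branch lengths")
  fg_tip <- which(tree$tip.label == foreground)
  fg_edge <- which(tree$edge[, 2] == fg_tip)

  seqs <- vector("list", max(tree$edge))
  seqs[[root]] <- sample(sense_codons(), n_codons, replace = TRUE)
  # preorder edge traversal
  eord <- ape::reorder.phylo(tree, "postorder")$edge
  eord <- eord[rev(seq_len(nrow(eord))), , drop = FALSE]
  elen <- tree$edge.length[match(paste(eord[, 1], eord[, 2]),
                                 paste(tree$edge[, 1], tree$edge[, 2]))]
  for (i in seq_len(nrow(eord))) {
    par <- eord[i, 1]; chl <- eord[i, 2]
    is_fg <- which(tree$edge[, 1] == par & tree$edge[, 2] == chl) == fg_edge
    rates <- if (isTRUE(is_fg)) fg_rates else bg_rates
    seqs[[chl]] <- .evolve_codon_branch(seqs[[par]], rates, elen[i])
  }
  cds <- vapply(seq_len(ntip), function(i) paste(seqs[[i]], collapse = ""), character(1))
  names(cds) <- tree$tip.label
  list(cds = cds, tree = tree, foreground = foreground,
       omega_fg = omega_fg, omega_bg = omega_bg, k = k)
}
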