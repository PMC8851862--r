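# Foreground/background dN/dS from a filtered codon alignment: ancestral
# states by Fitch parsimony (deterministic tie-breaks), pathway counting of
# synonymous/non-synonymous substitutions per branch, kappa-weighted site
# counts, Jukes-Cantor correction, and the selection-intensity gate
# k = ln(omega_fg) / ln(omega_bg) with a codon-bootstrap p.

# 61x61 nucleotide Hamming distances between sense codons (Sankoff costs)
.codon_hamming <- function() {
  if (is.null(.pg$codham)) {
    sc <- sense_codons()
    m <- matrix(0L, length(sc), length(sc), dimnames = list(sc, sc))
    sp <- strsplit(sc, "")
    for (i in seq_along(sc)) for (j in seq_along(sc))
      m[i, j] <- sum(sp[[i]] != sp[[j]])
    .pg$codham <- m
  }
  .pg$codham
}

# ancestral codon states by joint codon-level parsimony; returns a character
# matrix (nodes x codon columns; tips included, ape node numbering)
.ancestral_codons <- function(aln, tree, root_pref = NULL) {
  sc <- sense_codons()
  ntip <- length(tree$tip.label)
  ncod <- ncol(aln)
  tipcod <- matrix(-1L, ntip, ncod)
  for (i in seq_len(ntip)) {
    idx <- match(aln[tree$tip.label[i], ], sc)
    tipcod[i, ] <- ifelse(is.na(idx), -1L, idx - 1L)
  }
  post <- ape::reorder.phylo(tree, "postorder")$edge
  nnode <- ntip + tree$Nnode
  pref <- if (is.null(root_pref)) integer(0) else as.integer(root_pref)
  anc <- sankoff_codon_anc(tipcod, post, .codon_hamming(), nnode, pref)
  matrix(sc[anc + 1L], nnode, ncod)
}

# average synonymous/non-synonymous substitution counts over all mutational
# pathways between two codons, skipping pathways through stop codons
.ng_path_counts <- function(c1, c2) {
  if (is.null(.pg$ngmemo)) .pg$ngmemo <- new.env(parent = emptyenv())
  key <- paste0(c1, c2)
  if (!is.null(.pg$ngmemo[[key]])) return(.pg$ngmemo[[key]])
  gc <- genetic_code()
  d <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  res <- c(N = 0, S = 0)
  if (length(d)) {
    perms <- if (length(d) == 1L) list(d) else
      if (length(d) == 2L) list(d, rev(d)) else
        lapply(list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1)),
               function(p) d[p])
    acc <- c(N = 0, S = 0); nvalid <- 0L
    for (p in perms) {
      cur <- strsplit(c1, "")[[1]]
      tgt <- strsplit(c2, "")[[1]]
      step <- c(N = 0, S = 0); ok <- TRUE
      for (pos in p) {
        nxt <- cur; nxt[pos] <- tgt[pos]
        a <- gc[[paste(cur, collapse = "")]]; b <- gc[[paste(nxt, collapse = "")]]
        if (b == "*") { ok <- FALSE; break }
        if (a == b) step["S"] <- step["S"] + 1 else step["N"] <- step["N"] + 1
        cur <- nxt
      }
      if (ok) { acc <- acc + step; nvalid <- nvalid + 1L }
    }
    res <- if (nvalid > 0L) acc / nvalid else c(N = length(d), S = 0)
  }
  .pg$ngmemo[[key]] <- res
  res
}

.jc_correct <- function(p) {
  if (is.na(p) || p >= 0.75) return(NA_real_)
  -0.75 * log(1 - 4 * p / 3)
}

# omega from accumulated (Nd, Sd, Nsites, Ssites)
.omega_from_counts <- function(cnt) {
  if (cnt[["Ssites"]] <= 0 || cnt[["Nsites"]] <= 0) return(NA_real_)
  if (cnt[["Sd"]] == 0) return(NA_real_)
  dn <- .jc_correct(cnt[["Nd"]] / cnt[["Nsites"]])
  ds <- .jc_correct(cnt[["Sd"]] / cnt[["Ssites"]])
  if (is.na(dn) || is.na(ds) || ds == 0) return(NA_real_)
  dn / ds
}

#' Estimate foreground and background dN/dS
#'
#' Reconstructs ancestral codon states by joint codon-level parsimony,
#' counts synonymous and non-synonymous substitutions per branch (pathway
#' counting, stop-codon paths excluded), accumulates kappa-weighted site
#' counts, and returns Jukes-Cantor-corrected omega for the foreground
#' branch (leading to the foreground tip) and the pooled background (every
#' other branch, internal branches included).
#'
#' @param filt A `filtered_codon_alignment` (or a raw codon matrix).
#' @param tree Species tree covering the alignment rows.
#' @param foreground Foreground tip label.
#' @param kappa Transition/transversion weight used in site counting.
#' @param outgroup Optional tip label (e.g. the reference or a true
#'   outgroup) whose state anchors root-state ties; its branch counts as
#'   background.
#' @return List: `omega_fg`, `omega_bg`, `counts` (per-class totals),
#'   `percol` (per-codon-column contribution arrays, used by the bootstrap),
#'   `n_codons`.
#' @export
estimate_omega <- function(filt, tree, foreground, kappa = 2,
                           outgroup = NULL) {
  aln <- if (inherits(filt, "filtered_codon_alignment")) filt$aln else filt
  taxa <- rownames(aln)
  if (length(taxa) < 2L) stop("need >= 2 sequences")
  tree <- .resolve_tree(tree)
  tree <- ape::keep.tip(tree, taxa)
  if (!foreground %in% tree$tip.label) stop("foreground not in tree")
  ncod <- ncol(aln)
  root_pref <- if (!is.null(outgroup) && outgroup %in% tree$tip.label)
    which(tree$tip.label == outgroup) else NULL
  anc <- .ancestral_codons(aln, tree, root_pref)

  sw <- codon_site_weights(kappa)
  fg_tip <- which(tree$tip.label == foreground)
  percol <- list(fg = matrix(0, ncod, 4, dimnames = list(NULL, c("Nd", "Sd", "Nsites", "Ssites"))),
                 bg = matrix(0, ncod, 4, dimnames = list(NULL, c("Nd", "Sd", "Nsites", "Ssites"))))
  for (e in seq_len(nrow(tree$edge))) {
    par <- tree$edge[e, 1]; chl <- tree$edge[e, 2]
    cls <- if (chl == fg_tip) "fg" else "bg"
    for (c in seq_len(ncod)) {
      pc <- anc[par, c]; cc <- anc[chl, c]
      wN <- sw[pc, "N"]; wS <- sw[pc, "S"]
      tot <- wN + wS
      percol[[cls]][c, "Nsites"] <- percol[[cls]][c, "Nsites"] + 3 * wN / tot
      percol[[cls]][c, "Ssites"] <- percol[[cls]][c, "Ssites"] + 3 * wS / tot
      if (pc != cc) {
        ns <- .ng_path_counts(pc, cc)
        percol[[cls]][c, "Nd"] <- percol[[cls]][c, "Nd"] + ns[["N"]]
        percol[[cls]][c, "Sd"] <- percol[[cls]][c, "Sd"] + ns[["S"]]
      }
    }
  }
  counts <- rbind(fg = colSums(percol$fg), bg = colSums(percol$bg))
  list(omega_fg = .omega_from_counts(counts["fg", ]),
       omega_bg = .omega_from_counts(counts["bg", ]),
       counts = counts, percol = percol, n_codons = ncod)
}

#' Relaxed-selection gate
#'
#' Computes the selection intensity `k = ln(omega_fg) / ln(omega_bg)` (the
#' exponent of the omega_fg = omega_bg^k parameterisation), a nonparametric
#' codon-bootstrap probability of `k >= 1`, and the retention decision:
#' retained iff `omega_fg > omega_bg` and `k < 1`. The p-value is advisory;
#' the gate itself does not require significance. With `omega_bg >= 1` the
#' exponent is undefined and the gate falls back to the omega comparison
#' alone (k flagged NA, logged in `reason`).
#'
#' @param omega_fg,omega_bg Point estimates from [estimate_omega()].
#' @param percol Per-column contribution arrays from [estimate_omega()]
#'   (optional; without them no bootstrap is run).
#' @param B Bootstrap replicates (default 200).
#' @param seed RNG seed for the bootstrap.
#' @return A `relaxation_result`: `omega_fg`, `omega_bg`, `k`, `p_relax`,
#'   `retained`, `reason`.
#' @export
relaxation_test <- function(omega_fg, omega_bg, percol = NULL, B = 200L,
                            seed = 1L) {
  reason <- ""
  if (is.na(omega_fg) || is.na(omega_bg)) {
    return(structure(list(omega_fg = omega_fg, omega_bg = omega_bg,
                          k = NA_real_, p_relax = NA_real_, retained = FALSE,
                          reason = "no_signal"), class = "relaxation_result"))
  }
  if (omega_bg >= 1 || omega_bg <= 0) {
    k <- NA_real_
    retained <- omega_fg > omega_bg
    reason <- "k_undefined_omega_bg_ge_1"
  } else {
    k <- log(omega_fg) / log(omega_bg)
    retained <- omega_fg > omega_bg && k < 1
  }
  p_relax <- NA_real_
  if (!is.null(percol)) {
    set.seed(as.integer(seed %% .Machine$integer.max))
    ncod <- nrow(percol$fg)
    ks <- vapply(seq_len(B), function(b) {
      idx <- sample.int(ncod, ncod, replace = TRUE)
      ofg <- .omega_from_counts(colSums(percol$fg[idx, , drop = FALSE]))
      obg <- .omega_from_counts(colSums(percol$bg[idx, , drop = FALSE]))
      if (is.na(ofg) || is.na(obg) || obg >= 1 || obg <= 0) return(NA_real_)
      log(ofg) / log(obg)
    }, 0)
    if (any(!is.na(ks))) p_relax <- mean(ks >= 1, na.rm = TRUE)
  }
  structure(list(omega_fg = omega_fg, omega_bg = omega_bg, k = k,
                 p_relax = p_relax, retained = retained, reason = reason),
            class = "relaxation_result")
}

#' @export
print.relaxation_result <- function(x, ...) {
  cat(sprintf("relaxation_result: omega_fg=%.3f omega_bg=%.3f k=%.3f p_relax=%s retained=%s %s\n",
              x$omega_fg, x$omega_bg, x$k,
              format(x$p_relax), x$retained, x$reason))
  invisible(x)
}
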