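# Codon-level machinery shared by the simulator, the spliced aligner and the
# dN/dS counting code. The standard genetic code is taken from Biostrings;
# everything here works on plain upper-case character data.

BASES <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")

.pg <- new.env(parent = emptyenv())

# lazy singletons: genetic code lookup, sense codons, BLOSUM62
genetic_code <- function() {
  if (is.null(.pg$gc)) .pg$gc <- Biostrings::GENETIC_CODE
  .pg$gc
}

sense_codons <- function() {
  gc <- genetic_code()
  names(gc)[gc != "*"]
}

blosum62 <- function() {
  if (is.null(.pg$b62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .pg$b62 <- e$BLOSUM62
  }
  .pg$b62
}

#' Translate a coding sequence
#'
#' Conceptual translation of an in-frame nucleotide string. Length must be a
#' multiple of 3; stop codons translate to `*`.
#'
#' @param cds Single character string of A/C/G/T, length a multiple of 3.
#' @return Single amino-acid string (may contain `*`).
#' @export
translate_cds <- function(cds) {
  stopifnot(is.character(cds), length(cds) == 1L)
  n <- nchar(cds)
  if (n == 0L) return("")
  if (n %% 3L != 0L) stop("CDS length not a multiple of 3")
  codons <- substring(cds, seq(1L, n, 3L), seq(3L, n, 3L))
  gc <- genetic_code()
  aa <- gc[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

split_codons <- function(cds) {
  n <- nchar(cds)
  if (n == 0L) return(character(0))
  substring(cds, seq(1L, n, 3L), seq(3L, n, 3L))
}

#' Reverse complement
#' @param x Single DNA string.
#' @return Reverse-complemented string.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

is_transition <- function(a, b) {
  (a == "A" & b == "G") | (a == "G" & b == "A") |
    (a == "C" & b == "T") | (a == "T" & b == "C")
}

# Single-nucleotide codon neighbourhood with kappa-weighted mutation rates.
# Returns, for each sense codon, a data.frame of non-stop neighbours with the
# mutational weight (kappa for transitions, 1 for transversions) and whether
# the change is synonymous. Used by both the codon simulator and the
# site-counting estimator so the two stay on one definition.
codon_neighbours <- function(kappa = 2) {
  gc <- genetic_code()
  out <- vector("list", 64L)
  names(out) <- names(gc)
  for (cod in names(gc)) {
    if (gc[[cod]] == "*") next
    nb <- character(0); w <- numeric(0); syn <- logical(0); pos <- integer(0)
    cs <- strsplit(cod, "")[[1]]
    for (p in 1:3) {
      for (b in BASES[BASES != cs[p]]) {
        alt <- cs; alt[p] <- b
        altc <- paste(alt, collapse = "")
        if (gc[[altc]] == "*") next
        nb <- c(nb, altc)
        w <- c(w, if (is_transition(cs[p], b)) kappa else 1)
        syn <- c(syn, gc[[altc]] == gc[[cod]])
        pos <- c(pos, p)
      }
    }
    out[[cod]] <- data.frame(to = nb, weight = w, synonymous = syn, pos = pos,
                             stringsAsFactors = FALSE)
  }
  out[!vapply(out, is.null, logical(1))]
}

# kappa-weighted synonymous/non-synonymous "site" weights per sense codon
# (mutations to stop codons excluded, matching the simulator's state space).
codon_site_weights <- function(kappa = 2) {
  nbs <- codon_neighbours(kappa)
  t(vapply(nbs, function(d) {
    c(S = sum(d$weight[d$synonymous]), N = sum(d$weight[!d$synonymous]))
  }, c(S = 0, N = 0)))
}
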