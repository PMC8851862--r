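# GO-based functional groups. Minimal OBO/GAF subset parsers (id, name,
# namespace, is_a; GAF columns 2 and 5), is_a ancestor closure, keyword-based
# functional-group assignment, and the enriched-functional-group (EFG) test.

#' Parse a GO ontology (OBO subset)
#'
#' Reads `[Term]` stanzas keeping `id`, `name`, `namespace` and `is_a`
#' parents; obsolete terms are dropped.
#'
#' @param path OBO file path.
#' @return A `go_ontology`: `terms` data.frame and `parents` named list.
#' @export
parse_obo <- function(path) {
  lines <- readLines(path, warn = FALSE)
  terms <- list(); parents <- list()
  cur <- NULL
  flush <- function() {
    if (!is.null(cur) && !isTRUE(cur$obsolete) && !is.null(cur$id)) {
      terms[[length(terms) + 1L]] <<- data.frame(
        id = cur$id, name = cur$name %||% "", namespace = cur$namespace %||% "",
        stringsAsFactors = FALSE)
      parents[[cur$id]] <<- cur$is_a %||% character(0)
    }
  }
  in_term <- FALSE
  for (ln in lines) {
    if (grepl("^\\[", ln)) { flush(); cur <- NULL; in_term <- ln == "[Term]"; if (in_term) cur <- list(); next }
    if (!in_term || is.null(cur)) next
    if (grepl("^id:", ln)) cur$id <- trimws(sub("^id:", "", ln))
    else if (grepl("^name:", ln)) cur$name <- trimws(sub("^name:", "", ln))
    else if (grepl("^namespace:", ln)) cur$namespace <- trimws(sub("^namespace:", "", ln))
    else if (grepl("^is_a:", ln)) {
      p <- trimws(sub("!.*$", "", sub("^is_a:", "", ln)))
      cur$is_a <- c(cur$is_a, p)
    } else if (grepl("^is_obsolete: *true", ln)) cur$obsolete <- TRUE
  }
  flush()
  structure(list(terms = do.call(rbind, terms), parents = parents),
            class = "go_ontology")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Parse gene-to-GO annotations (GAF 2.x subset)
#'
#' Keeps columns 2 (gene id) and 5 (GO id); comment lines (`!`) skipped.
#'
#' @param path GAF file path.
#' @return data.frame with columns `gene`, `go`.
#' @export
parse_gaf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^!", lines) & nzchar(lines)]
  if (!length(lines)) return(data.frame(gene = character(0), go = character(0)))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  data.frame(gene = vapply(parts, `[`, "", 2L),
             go = vapply(parts, `[`, "", 5L), stringsAsFactors = FALSE)
}

# ancestor closure (is_a only, self included), memoised per ontology call
go_ancestors <- function(ontology, ids) {
  memo <- new.env(parent = emptyenv())
  anc <- function(id) {
    if (!is.null(memo[[id]])) return(memo[[id]])
    memo[[id]] <- id # cycle guard
    ps <- ontology$parents[[id]]
    res <- unique(c(id, unlist(lapply(ps, anc), use.names = FALSE)))
    memo[[id]] <- res
    res
  }
  stats::setNames(lapply(ids, anc), ids)
}

#' Assign genes to keyword-defined functional groups
#'
#' A gene joins a group iff any of its GO terms -- including is_a ancestors --
#' has a name matching one of the group's keywords (case-insensitive
#' substring match). GO ids absent from the ontology are skipped with a
#' warning.
#'
#' @param gaf Gene-to-GO data.frame (from [parse_gaf()]).
#' @param ontology A `go_ontology` (from [parse_obo()]).
#' @param keyword_map data.frame with columns `group`, `keyword`.
#' @return Membership data.frame: `gene`, `group` (unique rows).
#' @export
assign_functional_groups <- function(gaf, ontology, keyword_map) {
  stopifnot(nrow(keyword_map) > 0)
  known <- gaf$go %in% ontology$terms$id
  if (any(!known)) {
    warning("skipping ", sum(!known), " annotation(s) with unknown GO id(s): ",
            paste(utils::head(unique(gaf$go[!known]), 3), collapse = ", "))
    gaf <- gaf[known, , drop = FALSE]
  }
  if (!nrow(gaf)) return(data.frame(gene = character(0), group = character(0)))
  anc <- go_ancestors(ontology, unique(gaf$go))
  name_of <- stats::setNames(ontology$terms$name, ontology$terms$id)
  out <- list()
  for (g in unique(gaf$gene)) {
    terms <- unique(unlist(anc[gaf$go[gaf$gene == g]], use.names = FALSE))
    nms <- tolower(name_of[terms])
    for (grp in unique(keyword_map$group)) {
      kws <- tolower(keyword_map$keyword[keyword_map$group == grp])
      hit <- any(vapply(kws, function(k) any(grepl(k, nms, fixed = TRUE)), logical(1)))
      if (hit) out[[length(out) + 1L]] <- data.frame(gene = g, group = grp)
    }
  }
  if (!length(out)) return(data.frame(gene = character(0), group = character(0)))
  unique(do.call(rbind, out))
}

#' Enriched-functional-group (EFG) test
#'
#' For every functional group, a two-sided Fisher test of the proportion of
#' the species' pseudogenes in the group against its non-pseudogene
#' background, and (optionally) against a control species' pseudogene list;
#' BH-FDR over groups per comparison. A group is an EFG when either
#' comparison is significant at `alpha` after FDR -- the disjunctive
#' definition.
#'
#' @param membership Gene/group membership (from
#'   [assign_functional_groups()]).
#' @param pseudogenes Character vector of the species' pseudogene ids.
#' @param background Character vector of the species' non-pseudogene ids.
#' @param control_pseudogenes Optional control-species pseudogene ids.
#' @param alpha FDR threshold (default 0.05).
#' @return data.frame per group: contingency counts, odds ratio, p, fdr_p
#'   for each comparison, and the `efg` flag.
#' @export
efg_test <- function(membership, pseudogenes, background,
                     control_pseudogenes = NULL, alpha = 0.05) {
  groups <- sort(unique(membership$group))
  one <- function(listA, listB, grp) {
    inA <- sum(listA %in% membership$gene[membership$group == grp])
    inB <- sum(listB %in% membership$gene[membership$group == grp])
    ft <- fisher_two_sided(inA, length(listA) - inA, inB, length(listB) - inB)
    c(a = inA, b = length(listA) - inA, c = inB, d = length(listB) - inB,
      odds_ratio = ft$odds_ratio, p = ft$p)
  }
  bgres <- t(vapply(groups, one, numeric(6), listA = pseudogenes, listB = background))
  res <- data.frame(group = groups, bgres)
  res$fdr_p <- bh_fdr(res$p)
  res$efg <- res$fdr_p < alpha
  if (!is.null(control_pseudogenes)) {
    ctl <- t(vapply(groups, one, numeric(6), listA = pseudogenes,
                    listB = control_pseudogenes))
    res$p_control <- ctl[, "p"]
    res$fdr_p_control <- bh_fdr(res$p_control)
    res$efg <- res$efg | res$fdr_p_control < alpha
  }
  res
}
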