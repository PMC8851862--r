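# Pipeline configuration: every threshold named across the modules, with the
# canonical defaults, plus input paths and species roles. Parsed from a flat
# key=value file; unknown keys are rejected.

.pg_threshold_defaults <- function() {
  list(flank = 5000L, evalue = 1e-3, copy_cov = 0.8, trunc = 0.9,
       window = 30L, min_identity = 0.4, gap_flank = 6L, min_aln = 150L,
       k_threshold = 1.0, fdr_alpha = 0.05, seed = 1L,
       coverage_floor = 0.5, boundary_nt = 10L, read_conf = 0.8,
       min_depth = 5L, min_chain_cov = 0.25, n_decoys = 200L,
       min_seg_score = 25, min_intron = 30L, max_intron = 20000L,
       bootstrap_B = 200L)
}

.pg_path_keys <- c("reference_fasta", "reference_gff3", "tree_newick", "obo",
                   "gaf", "keyword_tsv", "conserved_tsv", "outdir")
.pg_role_keys <- c("species", "foreground", "control", "universe_n")
.pg_species_keys <- c("query_fasta", "support_tsv", "synteny_tsv", "check_reads")

#' Pipeline configuration
#'
#' @param ... Named values overriding threshold defaults, paths
#'   (`reference_fasta`, `reference_gff3`, `tree_newick`, `obo`, `gaf`,
#'   `keyword_tsv`, `conserved_tsv`, `outdir`), roles (`species` as character
#'   vector, `foreground`, `control`, `universe_n`) and per-species dotted
#'   keys such as `query_fasta.<species>`. Unknown keys are rejected.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  cfg <- .pg_threshold_defaults()
  extra <- list(...)
  species <- extra$species %||% character(0)
  for (key in names(extra)) {
    base <- sub("\\..*$", "", key)
    sp <- if (grepl("\\.", key)) sub("^[^.]*\\.", "", key) else NA
    ok <- key %in% names(cfg) || key %in% .pg_path_keys || key %in% .pg_role_keys ||
      (base %in% .pg_species_keys && !is.na(sp) && sp %in% species)
    if (!ok) stop("unknown configuration key: ", key, call. = FALSE)
    cfg[[key]] <- extra[[key]]
  }
  # type discipline on numeric thresholds
  for (nm in names(.pg_threshold_defaults()))
    cfg[[nm]] <- as(cfg[[nm]], class(.pg_threshold_defaults()[[nm]]))
  structure(cfg, class = "pipeline_config")
}

#' Parse a flat key=value configuration file
#'
#' Lines `key = value`; `#` starts a comment; `species` is comma-separated.
#' Unknown keys are rejected with a configuration error.
#'
#' @param path Config file path.
#' @return A `pipeline_config`.
#' @export
parse_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([^=]+)=(.*)$", lines))
  bad <- lines[vapply(kv, length, 0L) != 3L]
  if (length(bad)) stop("malformed config line: ", bad[1], call. = FALSE)
  keys <- trimws(vapply(kv, `[`, "", 2L))
  vals <- trimws(vapply(kv, `[`, "", 3L))
  if (anyDuplicated(keys)) stop("duplicate config key: ",
                                keys[duplicated(keys)][1], call. = FALSE)
  args <- stats::setNames(as.list(vals), keys)
  if (!is.null(args$species))
    args$species <- trimws(strsplit(args$species, ",")[[1]])
  num <- names(.pg_threshold_defaults())
  for (nm in intersect(names(args), c(num, "universe_n")))
    args[[nm]] <- as.numeric(args[[nm]])
  for (nm in grep("^check_reads\\.", names(args), value = TRUE))
    args[[nm]] <- toupper(args[[nm]]) %in% c("TRUE", "1", "YES")
  do.call(pipeline_config, args)
}

# translate a pipeline_config into the aligner parameter list
cfg_align_params <- function(cfg) {
  align_params(flank = as.integer(cfg$flank), evalue_max = cfg$evalue,
               n_decoys = as.integer(cfg$n_decoys),
               min_seg_score = cfg$min_seg_score,
               min_chain_cov = cfg$min_chain_cov,
               max_intron = as.integer(cfg$max_intron),
               min_intron = as.integer(cfg$min_intron),
               coverage_floor = cfg$coverage_floor,
               seed = as.integer(cfg$seed))
}
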