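#' Pipeline configuration
#'
#' Returns the full set of tunable parameters used across the pipeline, as a
#' named list. Every threshold used by any stage is a key here, so a single
#' flat key-value file can reconfigure a run. Values passed as `...` override
#' the defaults; unknown keys are an error.
#'
#' Key groups:
#' * `mode_threshold` (bp): genomes whose contigs sum to less than this run
#'   the single-pass phage/plasmid route (default 100000).
#' * k-mer index: `kmer_k`, `kmer_dominance`, `kmer_min_occurrences`;
#'   promotion: `promote_min_hits`, `promote_margin`.
#' * gene calling: `min_orf_len` (nt, default 90), `model_order`,
#'   `model_pseudocount`, start-codon bonuses `start_bonus_atg`,
#'   `start_bonus_gtg`, `start_bonus_ttg` (nats), `max_iter`.
#' * overlap rule: `overlap_min_bp` and `overlap_frac` — an overlap is
#'   "significant" when it exceeds `max(overlap_min_bp, overlap_frac *
#'   shorter feature length)`.
#' * alignment thresholds: `min_score`, `min_identity`, `min_coverage`,
#'   gap penalties `gap_open`, `gap_extend`; `seed_filter` enables an exact
#'   shared-peptide prescreen (`seed_k`) before Smith-Waterman inside the
#'   pipeline's batch steps.
#' * neighbors: `n_neighbors` (default 30), `max_extra_proteins` (default
#'   200), `bbh_neighbors` (how many top neighbors get full BBH tables),
#'   `unduplicated_ratio`.
#' * backfill/repair: `min_gap` (default 1500), `max_join_gap`,
#'   `join_coverage`, `fragment_max_coverage`, `join_segment_slack`.
#' * subsystems: `min_variant_jaccard`; coupling: `close_threshold`.
#'
#' @param ... name = value overrides of any default.
#' @return Named list of parameters.
#' @export
pk_config <- function(...) {
  cfg <- list(
    mode_threshold       = 100000L,
    genetic_code         = 11L,
    # signature k-mer index / promotion
    kmer_k               = 8L,
    kmer_dominance       = 0.9,
    kmer_min_occurrences = 2L,
    promote_min_hits     = 3L,
    promote_margin       = 2L,
    # gene calling
    min_orf_len          = 90L,
    model_order          = 4L,
    model_pseudocount    = 1.0,
    start_bonus_atg      = 0.5,
    start_bonus_gtg      = 0.25,
    start_bonus_ttg      = 0.0,
    max_iter             = 3L,
    # overlap rule
    overlap_min_bp       = 90L,
    overlap_frac         = 0.5,
    # protein alignment
    min_score            = 50,
    min_identity         = 0.3,
    min_coverage         = 0.7,
    gap_open             = 11,
    gap_extend           = 1,
    seed_filter          = TRUE,
    seed_k               = 5L,
    # neighbor estimation
    n_neighbors          = 30L,
    max_extra_proteins   = 200L,
    bbh_neighbors        = 10L,
    unduplicated_ratio   = 0.7,
    universal_roles      = character(0),
    # backfill / frameshift repair
    min_gap              = 1500L,
    max_join_gap         = 300L,
    join_coverage        = 0.8,
    fragment_max_coverage = 0.8,
    join_segment_slack   = 25L,
    # subsystems / coupling
    min_variant_jaccard  = 0.5,
    close_threshold      = 5000L
  )
  ov <- list(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(cfg))
    if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
    cfg[names(ov)] <- ov
  }
  cfg
}

#' Read a flat key = value configuration file
#'
#' Lines of the form `key = value` (or `key<TAB>value`); `#` starts a comment.
#' Values are coerced to the type of the corresponding default.
#'
#' @param path File path.
#' @return A config list as from [pk_config()].
#' @export
pk_read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  cfg <- pk_config()
  for (ln in lines) {
    kv <- strsplit(ln, "[=\t]", fixed = FALSE)[[1]]
    if (length(kv) < 2) stop("malformed config line: ", ln)
    key <- trimws(kv[1]); val <- trimws(paste(kv[-1], collapse = "="))
    if (!key %in% names(cfg)) stop("unknown config key: ", key)
    def <- cfg[[key]]
    cfg[[key]] <- if (is.logical(def)) as.logical(val)
      else if (is.integer(def)) as.integer(val)
      else if (is.numeric(def)) as.numeric(val)
      else if (key == "universal_roles") strsplit(val, ",", fixed = TRUE)[[1]]
      else val
  }
  cfg
}
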