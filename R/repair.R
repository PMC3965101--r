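#' Detect gene fragments caused by sequencing frameshifts
#'
#' Two adjacent same-contig, same-strand CDS features whose translations
#' align to disjoint, collinear segments of one template protein from the
#' neighbor proteomes are proposed for joining. The combined template
#' coverage must reach `join_coverage` (default 0.8) while neither fragment
#' alone reaches `fragment_max_coverage`; the genomic gap between the
#' fragments must not exceed `max_join_gap` (default 300 bp; fragments may
#' slightly overlap). The frame difference between the fragments gives the
#' inferred indel (+1 insertion / -1 deletion, modulo 3).
#'
#' @param features Feature table.
#' @param neighbor_proteins Data frame `id`, `sequence`, `role`.
#' @param config Configuration list.
#' @param exact Alignment prescreen switch.
#' @param extra_fragments Optional additional candidate features to
#'   consider as fragments (e.g. promoted candidates that lost overlap
#'   arbitration against their own sibling fragment).
#' @return Data frame of join proposals: `fragment_1`, `fragment_2` (in
#'   transcription order), `template_id`, `template_role`, `coverage_1`,
#'   `coverage_2`, `combined_coverage`, `shift_offset` (genomic base),
#'   `inferred_indel`, `rationale`; deterministic order.
#' @export
detect_frameshifts <- function(features, neighbor_proteins,
                               config = pk_config(), exact = FALSE,
                               extra_fragments = NULL) {
  empty <- data.frame(fragment_1 = character(0), fragment_2 = character(0),
                      template_id = character(0),
                      template_role = character(0),
                      coverage_1 = numeric(0), coverage_2 = numeric(0),
                      combined_coverage = numeric(0),
                      shift_offset = integer(0), inferred_indel = integer(0),
                      rationale = character(0), stringsAsFactors = FALSE)
  cds <- features[features$type == "CDS", , drop = FALSE]
  if (!is.null(extra_fragments) && nrow(extra_fragments)) {
    extra <- extra_fragments[extra_fragments$type == "CDS" &
                               !extra_fragments$id %in% cds$id, ,
                             drop = FALSE]
    cds <- rbind(cds[, names(empty_features())],
                 extra[, names(empty_features())])
  }
  if (nrow(cds) < 2 || is.null(neighbor_proteins) ||
      nrow(neighbor_proteins) == 0) return(empty)
  cds <- cds[order(cds$contig, cds$start), , drop = FALSE]
  # candidate fragment pairs: same contig and strand, downstream fragment
  # starting within the join window (moderate overlap allowed; unrelated
  # interleaved calls on the other strand do not break a pair)
  cand <- list()
  for (i in seq_len(nrow(cds) - 1L)) {
    for (j in (i + 1L):nrow(cds)) {
      a <- cds[i, ]; b <- cds[j, ]
      if (a$contig != b$contig) break
      if (b$start - a$end > config$max_join_gap) break
      if (a$strand != b$strand) next
      if (b$end <= a$end) next
      cand[[length(cand) + 1L]] <- c(i, j)
    }
  }
  if (length(cand) == 0) return(empty)
  frag_idx <- unique(unlist(cand))
  hits <- sw_score_table(
    stats::setNames(cds$translation[frag_idx], cds$id[frag_idx]),
    stats::setNames(neighbor_proteins$sequence, neighbor_proteins$id),
    exact = exact, config = config)
  hits <- hits[hits$score >= config$min_score &
                 hits$identity >= config$min_identity, , drop = FALSE]
  if (nrow(hits) == 0) return(empty)
  # subject alignment ranges are needed for collinearity: realign survivors
  subj_range <- function(qid, sid) {
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(cds$translation[match(qid, cds$id)]),
      Biostrings::AAString(neighbor_proteins$sequence[
        match(sid, neighbor_proteins$id)]),
      type = "local", substitutionMatrix = pk_blosum62(),
      gapOpening = config$gap_open, gapExtension = config$gap_extend)
    r <- Biostrings::subject(aln)@range
    c(IRanges::start(r), IRanges::end(r))
  }
  out <- list()
  for (pair in cand) {
    a <- cds[pair[1], ]; b <- cds[pair[2], ]
    # transcription order: on the minus strand the downstream-in-genome
    # fragment is N-terminal
    if (a$strand == "+") { f1 <- a; f2 <- b } else { f1 <- b; f2 <- a }
    h1 <- hits[hits$query_id == f1$id, , drop = FALSE]
    h2 <- hits[hits$query_id == f2$id, , drop = FALSE]
    shared <- intersect(h1$subject_id, h2$subject_id)
    if (length(shared) == 0) next
    best <- NULL
    for (sid in sort(shared)) {
      c1 <- h1$subject_coverage[match(sid, h1$subject_id)]
      c2 <- h2$subject_coverage[match(sid, h2$subject_id)]
      if (c1 >= config$fragment_max_coverage ||
          c2 >= config$fragment_max_coverage) next
      if (c1 + c2 < config$join_coverage) next
      r1 <- subj_range(f1$id, sid); r2 <- subj_range(f2$id, sid)
      # collinear and (near-)disjoint on the template
      if (r2[1] < r1[2] - config$join_segment_slack) next
      if (is.null(best) || c1 + c2 > best$combined) {
        best <- list(sid = sid, c1 = c1, c2 = c2, combined = c1 + c2)
      }
    }
    if (is.null(best)) next
    frame_of <- function(f) {
      L <- nchar(f$translation) * 3L + 3L  # region length
      if (f$strand == "+") f$start %% 3L else (-f$end) %% 3L
    }
    df <- (frame_of(f2) - frame_of(f1)) %% 3L
    indel <- if (df == 1L) 1L else if (df == 2L) -1L else 0L
    shift <- as.integer(min(a$end, b$end))
    role <- neighbor_proteins$role[match(best$sid, neighbor_proteins$id)]
    out[[length(out) + 1L]] <- data.frame(
      fragment_1 = f1$id, fragment_2 = f2$id, template_id = best$sid,
      template_role = if (is.na(role)) "" else role,
      coverage_1 = best$c1, coverage_2 = best$c2,
      combined_coverage = best$combined, shift_offset = shift,
      inferred_indel = indel,
      rationale = sprintf(
        "fragments %s+%s cover %.0f%%+%.0f%% of template %s; frame shift of %+d base near %d",
        f1$id, f2$id, 100 * best$c1, 100 * best$c2, best$sid, indel, shift),
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0) return(empty)
  res <- do.call(rbind, out)
  res[order(res$fragment_1, res$fragment_2), , drop = FALSE]
}

#' Apply (or merely record) frameshift join proposals
#'
#' When the user opts in, each join replaces its two fragments with a single
#' compound feature whose region is the two original segments (the assembly
#' sequence is never edited); the function is inherited from the template
#' and the inference is logged with template, offset and inferred indel.
#' Without opt-in, features are unchanged but every proposal is still
#' logged. Conflicting joins sharing a fragment keep the
#' higher-combined-coverage join; the conflict is logged.
#'
#' @param features Feature table.
#' @param joins Proposals from [detect_frameshifts()].
#' @param user_opt_in Apply the joins (`TRUE`) or only record them.
#' @param log Optional `pk_log`.
#' @return List with `features` (updated when opted in) and `applied`
#'   (the proposals actually applied).
#' @export
apply_joins <- function(features, joins, user_opt_in = FALSE,
                        log = pk_log_new(), fragments = NULL) {
  if (is.null(joins) || nrow(joins) == 0)
    return(list(features = features, applied = joins))
  # resolve conflicts: greedy by combined coverage
  joins <- joins[order(-joins$combined_coverage, joins$fragment_1), ,
                 drop = FALSE]
  used <- character(0)
  keep <- logical(nrow(joins))
  for (j in seq_len(nrow(joins))) {
    frags <- c(joins$fragment_1[j], joins$fragment_2[j])
    if (any(frags %in% used)) {
      pk_log_add(log, "frameshift_repair", joins$fragment_1[j],
                 "join_conflict",
                 sprintf("join with %s dropped: a fragment already joined by a higher-coverage proposal",
                         joins$fragment_2[j]))
      next
    }
    used <- c(used, frags)
    keep[j] <- TRUE
  }
  joins <- joins[keep, , drop = FALSE]
  pk_log_add(log, "frameshift_repair",
             joins$fragment_1, "join_proposed", joins$rationale)
  if (!user_opt_in || nrow(joins) == 0)
    return(list(features = features, applied = joins[0, , drop = FALSE]))
  feats <- features
  for (j in seq_len(nrow(joins))) {
    i1 <- match(joins$fragment_1[j], feats$id)
    i2 <- match(joins$fragment_2[j], feats$id)
    lookup <- function(i, id) {
      if (!is.na(i)) return(feats[i, ])
      if (!is.null(fragments)) {
        k <- match(id, fragments$id)
        if (!is.na(k)) return(fragments[k, names(empty_features())])
      }
      NULL
    }
    a <- lookup(i1, joins$fragment_1[j])
    b <- lookup(i2, joins$fragment_2[j])
    if (is.null(a) || is.null(b)) next
    segs <- data.frame(start = c(a$start, b$start), end = c(a$end, b$end))
    segs <- segs[order(segs$start), , drop = FALSE]
    new <- make_features(
      id = sprintf("%s_join", joins$fragment_1[j]),
      contig = a$contig, start = min(segs$start), end = max(segs$end),
      strand = a$strand, fun = joins$template_role[j], status = "retained",
      origin = "join",
      evidence = add_evidence(paste(a$evidence, b$evidence, sep = ","),
                              "blast_neighbor"),
      translation = paste0(a$translation, b$translation),
      kmer_hits = a$kmer_hits + b$kmer_hits,
      score = a$score + b$score,
      parts = list(segs))
    drop <- stats::na.omit(c(i1, i2))
    if (length(drop)) feats <- feats[-drop, , drop = FALSE]
    feats <- rbind(feats, new)
    pk_log_add(log, "frameshift_repair", new$id, "join_applied",
               joins$rationale[j])
  }
  feats <- feats[order(feats$contig, feats$start), , drop = FALSE]
  rownames(feats) <- NULL
  list(features = feats, applied = joins)
}
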