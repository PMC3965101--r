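.pk_matrix_cache <- new.env(parent = emptyenv())
pk_blosum62 <- function() {
  if (is.null(.pk_matrix_cache$BLOSUM62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .pk_matrix_cache$BLOSUM62 <- e$BLOSUM62
  }
  .pk_matrix_cache$BLOSUM62
}

# Maximum attainable score of a protein against itself (sum of diagonal
# substitution scores) -- the local self-alignment optimum, since BLOSUM62
# diagonal entries are all positive.
self_score <- function(sequences) {
  m <- pk_blosum62()
  d <- diag(m)
  vapply(sequences, function(s) {
    aa <- strsplit(s, "", fixed = TRUE)[[1]]
    sum(d[aa], na.rm = TRUE)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Optimal local protein alignment
#'
#' Exact Smith-Waterman alignment with affine gaps (BLOSUM62, gap open 11,
#' gap extend 1 by default), standing in for heuristic BLASTP at desk scale.
#' Identity is matches over alignment columns; coverages are the aligned
#' span over each full sequence length.
#'
#' @param query,subject Protein strings (non-empty).
#' @param gap_open,gap_extend Affine gap penalties (positive costs).
#' @return A one-row data.frame: `query_id`, `subject_id`, `score`,
#'   `identity`, `query_coverage`, `subject_coverage`.
#' @export
align_proteins <- function(query, subject, gap_open = 11, gap_extend = 1) {
  if (!nzchar(query) || !nzchar(subject)) stop("empty sequence")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(query), Biostrings::AAString(subject),
    type = "local", substitutionMatrix = pk_blosum62(),
    gapOpening = gap_open, gapExtension = gap_extend)
  data.frame(
    query_id = "query", subject_id = "subject",
    score = Biostrings::score(aln),
    identity = Biostrings::pid(aln, type = "PID1") / 100,
    query_coverage =
      IRanges::width(Biostrings::pattern(aln)@range) / nchar(query),
    subject_coverage =
      IRanges::width(Biostrings::subject(aln)@range) / nchar(subject),
    stringsAsFactors = FALSE)
}

# Candidate (query, subject) pairs sharing at least one exact amino-acid
# seed of length k. Used as an exact-match prescreen before Smith-Waterman
# in the pipeline's batch steps.
seed_pairs <- function(queries, subjects, k = 5L) {
  qt <- unique(kmer_table(unname(queries), names(queries), k),
               by = c("seq_id", "kmer"))
  st <- unique(kmer_table(unname(subjects), names(subjects), k),
               by = c("seq_id", "kmer"))
  data.table::setnames(qt, "seq_id", "query_id")
  data.table::setnames(st, "seq_id", "subject_id")
  m <- merge(qt[, c("query_id", "kmer")], st[, c("subject_id", "kmer")],
             by = "kmer", allow.cartesian = TRUE)
  unique(m[, c("query_id", "subject_id")])
}

# Batch Smith-Waterman: scores all requested (query, subject) pairs.
# pairs = NULL aligns the full cross product; exact = FALSE restricts the
# cross product to seed-sharing pairs first.
sw_score_table <- function(queries, subjects, pairs = NULL, exact = TRUE,
                           config = pk_config()) {
  empty <- data.table::data.table(query_id = character(0),
                                  subject_id = character(0),
                                  score = numeric(0), identity = numeric(0),
                                  query_coverage = numeric(0),
                                  subject_coverage = numeric(0))
  if (length(queries) == 0 || length(subjects) == 0) return(empty)
  if (is.null(pairs)) {
    if (exact) {
      pairs <- data.table::CJ(query_id = names(queries),
                              subject_id = names(subjects))
    } else {
      pairs <- seed_pairs(queries, subjects, k = config$seed_k)
    }
  }
  if (nrow(pairs) == 0) return(empty)
  out <- vector("list", length(unique(pairs$subject_id)))
  i <- 0L
  for (sid in unique(pairs$subject_id)) {
    qids <- pairs$query_id[pairs$subject_id == sid]
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::AAStringSet(queries[qids]),
      Biostrings::AAString(subjects[[sid]]),
      type = "local", substitutionMatrix = pk_blosum62(),
      gapOpening = config$gap_open, gapExtension = config$gap_extend)
    i <- i + 1L
    out[[i]] <- data.table::data.table(
      query_id = qids, subject_id = sid,
      score = Biostrings::score(aln),
      identity = Biostrings::pid(aln, type = "PID1") / 100,
      query_coverage = IRanges::width(Biostrings::pattern(aln)@range) /
        nchar(queries[qids]),
      subject_coverage = IRanges::width(Biostrings::subject(aln)@range) /
        nchar(subjects[[sid]]))
  }
  data.table::rbindlist(out[seq_len(i)])
}

qualifying <- function(hits, config, coverage = c("query", "subject")) {
  coverage <- match.arg(coverage)
  cov <- if (coverage == "query") hits$query_coverage
         else hits$subject_coverage
  hits[hits$score >= config$min_score & hits$identity >= config$min_identity &
         cov >= config$min_coverage, , drop = FALSE]
}

# Best qualifying hit per query; ties broken by lexicographic subject id.
best_hit_per_query <- function(hits) {
  if (nrow(hits) == 0) return(hits)
  data.table::setorderv(hits, c("query_id", "score", "subject_id"),
                        order = c(1L, -1L, 1L))
  hits[!duplicated(hits$query_id), , drop = FALSE]
}

#' Best-hit classification of two proteomes
#'
#' Aligns two protein sets and classifies every gene as `unique` (no hit
#' passing the score/identity/coverage thresholds), `unidirectional` (its
#' best hit does not reciprocate) or `bidirectional` (reciprocal best hit).
#' Ties for the best hit are broken by lexicographic subject id and logged.
#'
#' @param a_proteins,b_proteins Named character vectors (names are gene
#'   ids; ids must not collide between genomes).
#' @param config Configuration list (uses `min_score`, `min_identity`,
#'   `min_coverage`, gap penalties).
#' @param exact Align all pairs (`TRUE`, default) or only seed-sharing
#'   pairs.
#' @param log Optional `pk_log`.
#' @return List with `pairs` (data.frame `gene_a`, `gene_b`, `score_ab`,
#'   `score_ba`) and `classes` (data.frame `gene_id`, `genome` (`"a"`/`"b"`),
#'   `class`, `best_subject`, `identity`).
#' @export
best_hits <- function(a_proteins, b_proteins, config = pk_config(),
                      exact = TRUE, log = NULL) {
  hits <- sw_score_table(a_proteins, b_proteins, exact = exact,
                         config = config)
  qa <- best_hit_per_query(qualifying(hits, config, "query"))
  # b -> a direction reuses the same alignments with roles swapped
  rev <- data.table::copy(hits)
  data.table::setnames(rev, c("query_id", "subject_id", "query_coverage",
                              "subject_coverage"),
                       c("subject_id", "query_id", "subject_coverage",
                         "query_coverage"))
  qb <- best_hit_per_query(qualifying(rev, config, "query"))
  best_a <- stats::setNames(qa$subject_id, qa$query_id)
  best_b <- stats::setNames(qb$subject_id, qb$query_id)
  score_a <- stats::setNames(qa$score, qa$query_id)
  score_b <- stats::setNames(qb$score, qb$query_id)
  id_a <- stats::setNames(qa$identity, qa$query_id)
  id_b <- stats::setNames(qb$identity, qb$query_id)

  classify <- function(ids, best, other_best) {
    vapply(ids, function(g) {
      bh <- best[g]
      if (is.na(bh)) return("unique")
      if (!is.na(other_best[bh]) && other_best[bh] == g) "bidirectional"
      else "unidirectional"
    }, character(1))
  }
  ca <- classify(names(a_proteins), best_a, best_b)
  cb <- classify(names(b_proteins), best_b, best_a)
  classes <- data.frame(
    gene_id = c(names(a_proteins), names(b_proteins)),
    genome = c(rep("a", length(a_proteins)), rep("b", length(b_proteins))),
    class = c(ca, cb),
    best_subject = c(unname(best_a[names(a_proteins)]),
                     unname(best_b[names(b_proteins)])),
    identity = c(unname(id_a[names(a_proteins)]),
                 unname(id_b[names(b_proteins)])),
    stringsAsFactors = FALSE)
  bi <- names(a_proteins)[ca == "bidirectional"]
  pairs <- data.frame(gene_a = bi, gene_b = unname(best_a[bi]),
                      score_ab = unname(score_a[bi]),
                      score_ba = unname(score_b[unname(best_a[bi])]),
                      stringsAsFactors = FALSE)
  if (!is.null(log) && nrow(pairs)) {
    pk_log_add(log, "best_hits", pairs$gene_a, "bbh",
               sprintf("reciprocal best hit with %s", pairs$gene_b))
  }
  list(pairs = pairs, classes = classes)
}

#' Estimate the closest reference genomes
#'
#' For each reference genome, a similarity score is computed as the sum of
#' best-hit Smith-Waterman scores of the candidate translations against that
#' genome's universal-role proteins plus up to `max_extra` "unduplicated"
#' proteins (genes whose second-best within-genome self hit scores below
#' `unduplicated_ratio` times their self score). The top `n` genomes are
#' returned in descending score order.
#'
#' @param candidate_proteins Named character vector of candidate
#'   translations.
#' @param reference Reference protein data.frame (`id`, `genome_id`,
#'   `sequence`, `role`).
#' @param config Configuration list (`universal_roles`,
#'   `max_extra_proteins`, `n_neighbors`, `unduplicated_ratio`).
#' @param exact Align all pairs or only seed-sharing pairs (default).
#' @return Data frame `genome_id`, `score`, sorted descending; at most
#'   `n_neighbors` rows.
#' @export
find_neighbors <- function(candidate_proteins, reference,
                           config = pk_config(), exact = FALSE) {
  if (is.null(reference) || nrow(reference) == 0) {
    return(data.frame(genome_id = character(0), score = numeric(0),
                      stringsAsFactors = FALSE))
  }
  subjects <- character(0)
  subj_genome <- character(0)
  for (g in sort(unique(reference$genome_id))) {
    rg <- reference[reference$genome_id == g, , drop = FALSE]
    rg <- rg[order(rg$id), , drop = FALSE]
    uni <- rg$role %in% config$universal_roles
    seqs <- stats::setNames(rg$sequence, rg$id)
    ss <- self_score(rg$sequence)
    within <- sw_score_table(seqs, seqs, exact = FALSE, config = config)
    within <- within[within$query_id != within$subject_id, , drop = FALSE]
    second <- stats::setNames(rep(0, nrow(rg)), rg$id)
    if (nrow(within)) {
      mx <- tapply(within$score, within$query_id, max)
      second[names(mx)] <- mx
    }
    undup <- second < config$unduplicated_ratio * ss
    extra <- rg$id[undup & !uni]
    if (length(extra) > config$max_extra_proteins)
      extra <- extra[seq_len(config$max_extra_proteins)]
    pick <- unique(c(rg$id[uni], extra))
    subjects <- c(subjects, stats::setNames(rg$sequence[match(pick, rg$id)],
                                            pick))
    subj_genome <- c(subj_genome, stats::setNames(rep(g, length(pick)),
                                                  pick))
  }
  hits <- sw_score_table(candidate_proteins, subjects, exact = exact,
                         config = config)
  hits <- hits[hits$score >= config$min_score, , drop = FALSE]
  if (nrow(hits) == 0) {
    return(data.frame(genome_id = character(0), score = numeric(0),
                      stringsAsFactors = FALSE))
  }
  hits$genome_id <- subj_genome[hits$subject_id]
  best <- hits[, list(score = max(score)), by = c("query_id", "genome_id")]
  per_genome <- best[, list(score = sum(score)), by = "genome_id"]
  data.table::setorderv(per_genome, c("score", "genome_id"),
                        order = c(-1L, 1L))
  out <- as.data.frame(utils::head(per_genome, config$n_neighbors))
  rownames(out) <- NULL
  out
}

# significant-overlap test of one region against a feature table
.sig_overlap_any <- function(contig, start, end, features, config) {
  if (is.null(features) || nrow(features) == 0) return(FALSE)
  ov <- overlap_bp_vec(contig, start, end, features$contig, features$start,
                       features$end)
  any(significant_overlap(ov, end - start, features$end - features$start,
                          config))
}

#' Rescue unpromoted candidates by similarity to neighbor proteomes
#'
#' An unpromoted gene candidate is accepted when its best Smith-Waterman hit
#' against the proteins of the closest reference genomes passes the
#' score/identity/coverage thresholds and it does not significantly overlap
#' a retained feature.
#'
#' @param candidates Candidate feature table (rows with
#'   `status == "candidate"` are considered).
#' @param neighbor_proteins Data frame of neighbor proteome proteins (`id`,
#'   `sequence`, `role`).
#' @param retained Retained feature table.
#' @param config Configuration list.
#' @param exact Align all pairs or only seed-sharing pairs (default).
#' @param log Optional `pk_log`.
#' @return Accepted features (status `"retained"`, origin
#'   `"neighbor_rescue"`, evidence `blast_neighbor`).
#' @export
rescue_by_neighbor_blast <- function(candidates, neighbor_proteins, retained,
                                     config = pk_config(), exact = FALSE,
                                     log = NULL) {
  un <- candidates[candidates$status == "candidate", , drop = FALSE]
  if (nrow(un) == 0 || is.null(neighbor_proteins) ||
      nrow(neighbor_proteins) == 0) return(empty_features())
  keep <- !vapply(seq_len(nrow(un)), function(i) {
    .sig_overlap_any(un$contig[i], un$start[i], un$end[i], retained, config)
  }, logical(1))
  un <- un[keep, , drop = FALSE]
  if (nrow(un) == 0) return(empty_features())
  hits <- sw_score_table(stats::setNames(un$translation, un$id),
                         stats::setNames(neighbor_proteins$sequence,
                                         neighbor_proteins$id),
                         exact = exact, config = config)
  best <- best_hit_per_query(qualifying(hits, config, "query"))
  acc <- un[un$id %in% best$query_id, , drop = FALSE]
  if (nrow(acc) == 0) return(empty_features())
  keep2 <- arbitrate_overlaps(acc, obstacles = retained, config = config)
  acc <- acc[keep2, , drop = FALSE]
  acc$status <- "retained"
  acc$origin <- "neighbor_rescue"
  acc$evidence <- vapply(acc$evidence, add_evidence, "",
                         tag = "blast_neighbor")
  if (!is.null(log) && nrow(acc)) {
    bh <- best[match(acc$id, best$query_id), ]
    pk_log_add(log, "neighbor_rescue", acc$id, "accepted",
               sprintf("similar to neighbor protein %s (score %.0f, identity %.2f)",
                       bh$subject_id, bh$score, bh$identity))
  }
  acc$start_options <- NULL; acc$frame <- NULL
  acc
}

#' Accept remaining non-overlapping candidates as hypothetical genes
#'
#' Any candidate still unaccepted that does not significantly overlap an
#' existing call is included with an empty function (exported as
#' "hypothetical protein").
#'
#' @inheritParams rescue_by_neighbor_blast
#' @return Accepted features (empty function, evidence `none`).
#' @export
accept_remaining <- function(candidates, retained, config = pk_config(),
                             log = NULL) {
  un <- candidates[candidates$status == "candidate", , drop = FALSE]
  if (nrow(un) == 0) return(empty_features())
  keep <- !vapply(seq_len(nrow(un)), function(i) {
    .sig_overlap_any(un$contig[i], un$start[i], un$end[i], retained, config)
  }, logical(1))
  un <- un[keep, , drop = FALSE]
  if (nrow(un) == 0) return(empty_features())
  keep2 <- arbitrate_overlaps(un, obstacles = retained, config = config)
  un <- un[keep2, , drop = FALSE]
  un$status <- "retained"
  if (!is.null(log) && nrow(un)) {
    pk_log_add(log, "accept_remaining", un$id, "accepted",
               "remaining candidate without significant overlap")
  }
  un$start_options <- NULL; un$frame <- NULL
  un
}

# Gene-free stretches of a genome, as data.frame(contig, start, end).
gene_free_stretches <- function(genome, features) {
  out <- list()
  for (cname in names(genome$contigs)) {
    L <- nchar(genome$contigs[[cname]])
    ff <- features[features$contig == cname, , drop = FALSE]
    if (nrow(ff) == 0) {
      out[[length(out) + 1L]] <- data.frame(contig = cname, start = 0L,
                                            end = L)
      next
    }
    cov <- logical(L)
    for (i in seq_len(nrow(ff))) cov[(ff$start[i] + 1L):ff$end[i]] <- TRUE
    r <- rle(cov)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths
    w <- which(!r$values)
    if (length(w)) {
      out[[length(out) + 1L]] <- data.frame(contig = cname,
                                            start = starts[w],
                                            end = ends[w])
    }
  }
  if (length(out) == 0) {
    return(data.frame(contig = character(0), start = integer(0),
                      end = integer(0)))
  }
  do.call(rbind, out)
}

# Translated (6-frame) search of one DNA stretch against a protein set.
# Returns features (origin as given) for qualifying hits, with the aligned
# segment mapped back to genomic coordinates.
.translated_search <- function(genome, contig, gstart, gend, subjects_df,
                               config, exact = FALSE, origin = "backfill") {
  dna <- substr(genome$contigs[[contig]], gstart + 1L, gend)
  Lg <- nchar(dna)
  frames <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") dna else revcomp(dna)
    for (f in 0:2) {
      n <- ((Lg - f) %/% 3L) * 3L
      if (n < 3 * 10) next
      frames[[paste0(strand, f)]] <- translate_dna(
        substr(s, f + 1L, f + n), as_initiator = FALSE,
        genetic_code = genome$genetic_code)
    }
  }
  if (length(frames) == 0) return(empty_features())
  hits <- sw_score_table(unlist(frames),
                         stats::setNames(subjects_df$sequence,
                                         subjects_df$id),
                         exact = exact, config = config)
  hits <- hits[hits$score >= config$min_score &
                 hits$identity >= config$min_identity &
                 hits$subject_coverage >= config$min_coverage, ,
               drop = FALSE]
  if (nrow(hits) == 0) return(empty_features())
  # aligned pattern ranges are needed to place hits: realign the survivors
  rows <- list()
  for (j in seq_len(nrow(hits))) {
    fr <- hits$query_id[j]
    strand <- substr(fr, 1, 1)
    f <- as.integer(substr(fr, 2, 2))
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(frames[[fr]]),
      Biostrings::AAString(subjects_df$sequence[
        match(hits$subject_id[j], subjects_df$id)]),
      type = "local", substitutionMatrix = pk_blosum62(),
      gapOpening = config$gap_open, gapExtension = config$gap_extend)
    pr <- Biostrings::pattern(aln)@range
    ps <- IRanges::start(pr); pe <- IRanges::end(pr)
    ls <- f + (ps - 1L) * 3L; le <- f + pe * 3L   # local nt, 0-based
    if (strand == "+") { rs <- gstart + ls; re <- gstart + le }
    else { rs <- gstart + (Lg - le); re <- gstart + (Lg - ls) }
    rows[[j]] <- list(contig = contig, start = rs, end = re,
                      strand = strand, score = hits$score[j],
                      subject_id = hits$subject_id[j],
                      translation = substr(frames[[fr]], ps, pe))
  }
  dt <- data.table::rbindlist(rows)
  role <- subjects_df$role[match(dt$subject_id, subjects_df$id)]
  ff <- make_features(id = sprintf("%s.%s.%d", origin, contig,
                                   seq_len(nrow(dt))),
                      contig = dt$contig, start = dt$start, end = dt$end,
                      strand = dt$strand, fun = ifelse(is.na(role), "", role),
                      status = "retained", origin = origin,
                      evidence = "blast_neighbor",
                      translation = dt$translation, score = dt$score)
  ff$subject_id <- dt$subject_id
  ff
}

#' Backfill long gene-free stretches by translated search
#'
#' Every DNA stretch longer than `min_gap` (strictly; default 1500 bp) that
#' contains no gene is translated in all six frames and searched against the
#' neighbor proteomes; qualifying hits become gene candidates with origin
#' `backfill` and the matched protein's function.
#'
#' @param genome A `pk_genome`.
#' @param features Current feature table (defines the gaps).
#' @param neighbor_proteins Data frame `id`, `sequence`, `role`.
#' @param config Configuration list (`min_gap` and alignment thresholds).
#' @param exact Align all pairs or only seed-sharing pairs (default).
#' @param log Optional `pk_log`.
#' @return New backfill features (never overlapping `features`).
#' @export
backfill_gaps <- function(genome, features, neighbor_proteins,
                          config = pk_config(), exact = FALSE, log = NULL) {
  if (is.null(neighbor_proteins) || nrow(neighbor_proteins) == 0)
    return(empty_features())
  gaps <- gene_free_stretches(genome, features)
  gaps <- gaps[gaps$end - gaps$start > config$min_gap, , drop = FALSE]
  if (nrow(gaps) == 0) return(empty_features())
  found <- list()
  for (i in seq_len(nrow(gaps))) {
    ff <- .translated_search(genome, gaps$contig[i], gaps$start[i],
                             gaps$end[i], neighbor_proteins, config,
                             exact = exact, origin = "backfill")
    if (nrow(ff)) found[[length(found) + 1L]] <- ff
  }
  if (length(found) == 0) return(empty_features())
  new <- do.call(rbind, found)
  new$id <- sprintf("backfill.%d", seq_len(nrow(new)))
  keep <- arbitrate_overlaps(new, obstacles = features, config = config)
  new <- new[keep, , drop = FALSE]
  if (!is.null(log) && nrow(new)) {
    pk_log_add(log, "backfill", new$id, "accepted",
               sprintf("translated hit to neighbor protein %s in a gene-free stretch",
                       new$subject_id))
  }
  new$subject_id <- NULL
  new
}

#' Find missed genes in gaps flanked by subsystem BBHs
#'
#' For every remaining gap whose two flanking genes are bidirectional best
#' hits to subsystem genes of one neighbor genome, each neighbor gene lying
#' between those two genes is searched for in the gap by translated
#' alignment; hits become candidates carrying the neighbor gene's function.
#'
#' @param genome A `pk_genome`.
#' @param features Current feature table, resolved so gaps are defined.
#' @param reference Reference proteins with coordinates (`id`, `genome_id`,
#'   `sequence`, `role`, `in_subsystem`, `contig`, `start`, `end`).
#' @param neighbor_ids Neighbor genome ids in rank order.
#' @param bbh_maps Named list (by neighbor genome id) of BBH pair
#'   data.frames (`gene_a` = query feature id, `gene_b` = reference id).
#' @param config Configuration list.
#' @param exact Alignment prescreen switch.
#' @param log Optional `pk_log`.
#' @return New features with origin `neighbor_rescue`.
#' @export
rescue_missed <- function(genome, features, reference, neighbor_ids,
                          bbh_maps, config = pk_config(), exact = FALSE,
                          log = NULL) {
  if (nrow(features) == 0 || length(bbh_maps) == 0)
    return(empty_features())
  in_ss <- if (!is.null(reference$in_subsystem)) reference$in_subsystem
           else rep(TRUE, nrow(reference))
  found <- list()
  for (cname in unique(features$contig)) {
    ff <- features[features$contig == cname, , drop = FALSE]
    ff <- ff[order(ff$start), , drop = FALSE]
    if (nrow(ff) < 2) next
    for (i in seq_len(nrow(ff) - 1L)) {
      gs <- ff$end[i]; ge <- ff$start[i + 1L]
      if (ge - gs < config$min_orf_len) next
      left <- ff$id[i]; right <- ff$id[i + 1L]
      for (N in neighbor_ids) {
        bm <- bbh_maps[[N]]
        if (is.null(bm) || nrow(bm) == 0) next
        b1 <- bm$gene_b[match(left, bm$gene_a)]
        b2 <- bm$gene_b[match(right, bm$gene_a)]
        if (is.na(b1) || is.na(b2)) next
        r1 <- match(b1, reference$id); r2 <- match(b2, reference$id)
        if (!isTRUE(in_ss[r1]) || !isTRUE(in_ss[r2])) next
        if (!identical(reference$contig[r1], reference$contig[r2])) next
        lo <- min(reference$end[r1], reference$end[r2])
        hi <- max(reference$start[r1], reference$start[r2])
        between <- which(reference$genome_id == N &
                           reference$contig == reference$contig[r1] &
                           reference$start >= lo & reference$end <= hi &
                           reference$id != b1 & reference$id != b2)
        if (length(between) == 0) next
        hit <- .translated_search(genome, cname, gs, ge,
                                  reference[between, , drop = FALSE],
                                  config, exact = exact,
                                  origin = "neighbor_rescue")
        if (nrow(hit)) {
          found[[length(found) + 1L]] <- hit
          if (!is.null(log)) {
            pk_log_add(log, "rescue_missed", hit$id, "proposed",
                       sprintf("gap between %s and %s matches neighbor %s gene %s",
                               left, right, N, hit$subject_id))
          }
        }
        break  # the rule requires one neighbor; first ranked neighbor wins
      }
    }
  }
  if (length(found) == 0) return(empty_features())
  new <- do.call(rbind, found)
  new$id <- sprintf("rescue.%d", seq_len(nrow(new)))
  keep <- arbitrate_overlaps(new, obstacles = features, config = config)
  new <- new[keep, , drop = FALSE]
  new$subject_id <- NULL
  new
}

#' Assign functions to unannotated genes by protein similarity
#'
#' Features without a function get the role of their best qualifying
#' Smith-Waterman hit against the neighbor proteomes; features already
#' annotated (by k-mer or otherwise) are untouched.
#'
#' @param features Feature table.
#' @param neighbor_proteins Data frame `id`, `sequence`, `role`.
#' @param config Configuration list.
#' @param exact Alignment prescreen switch.
#' @param log Optional `pk_log`.
#' @return Updated feature table.
#' @export
assign_by_blast <- function(features, neighbor_proteins,
                            config = pk_config(), exact = FALSE,
                            log = NULL) {
  todo <- which(features$type == "CDS" & features$fun == "" &
                  nzchar(features$translation))
  if (length(todo) == 0 || is.null(neighbor_proteins) ||
      nrow(neighbor_proteins) == 0) return(features)
  hits <- sw_score_table(
    stats::setNames(features$translation[todo], features$id[todo]),
    stats::setNames(neighbor_proteins$sequence, neighbor_proteins$id),
    exact = exact, config = config)
  best <- best_hit_per_query(qualifying(hits, config, "query"))
  if (nrow(best) == 0) return(features)
  for (j in seq_len(nrow(best))) {
    i <- match(best$query_id[j], features$id)
    role <- neighbor_proteins$role[match(best$subject_id[j],
                                         neighbor_proteins$id)]
    if (is.na(role) || !nzchar(role)) next
    features$fun[i] <- role
    features$evidence[i] <- add_evidence(features$evidence[i],
                                         "blast_neighbor")
    if (!is.null(log)) {
      pk_log_add(log, "assign_by_blast", features$id[i], "function_assigned",
                 sprintf("best hit %s (score %.0f, identity %.2f) donates '%s'",
                         best$subject_id[j], best$score[j], best$identity[j],
                         role))
    }
  }
  features
}

#' Compute BBH tables of an annotated genome against neighbor genomes
#'
#' @param features Feature table with translations.
#' @param reference Reference proteins (`id`, `genome_id`, `sequence`).
#' @param neighbor_ids Which reference genomes to compare against.
#' @param config Configuration list.
#' @param exact Alignment prescreen switch.
#' @return Named list (by genome id) of [best_hits()] results.
#' @export
compute_bbh_maps <- function(features, reference, neighbor_ids,
                             config = pk_config(), exact = FALSE) {
  qp <- stats::setNames(features$translation, features$id)
  qp <- qp[nzchar(qp)]
  out <- list()
  for (N in neighbor_ids) {
    rg <- reference[reference$genome_id == N, , drop = FALSE]
    out[[N]] <- best_hits(qp, stats::setNames(rg$sequence, rg$id),
                          config = config, exact = exact)
  }
  out
}
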