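STOP_CODONS <- c("TAA", "TAG", "TGA")
START_CODONS <- c("ATG", "GTG", "TTG")

#' Enumerate open reading frames on both strands
#'
#' Finds all maximal stop-to-stop ORFs in all six frames. Each ORF runs from
#' a start codon (ATG/GTG/TTG) to the next in-frame stop codon, stop
#' included; the longest possible start is chosen initially and every
#' alternative in-frame start is recorded in the `start_options` list column
#' (as the genomic coordinate of the boundary that moves: `start` for `+`
#' strand ORFs, `end` for `-` strand ORFs). ORFs shorter than `min_len`
#' nucleotides are dropped. Output order is deterministic: contig, start,
#' strand.
#'
#' @param genome A `pk_genome`.
#' @param min_len Minimum ORF length in nucleotides, stop codon included
#'   (default 90).
#' @return Feature table of candidates with extra columns `frame` (0-2 in
#'   reading space) and `start_options`.
#' @export
enumerate_orfs <- function(genome, min_len = 90L) {
  rows <- list()
  for (cname in names(genome$contigs)) {
    cs <- genome$contigs[[cname]]
    L <- nchar(cs)
    for (strand in c("+", "-")) {
      s <- if (strand == "+") cs else revcomp(cs)
      for (f in 0:2) {
        ncod <- (L - f) %/% 3L
        if (ncod < 2) next
        cod <- substring(s, f + seq(1L, by = 3L, length.out = ncod),
                         f + seq(3L, by = 3L, length.out = ncod))
        is_stop <- cod %in% STOP_CODONS
        is_start <- cod %in% START_CODONS
        stop_idx <- which(is_stop)
        if (length(stop_idx) == 0) next
        start_idx <- which(is_start)
        prev_stop <- 0L
        for (j in stop_idx) {
          ss <- start_idx[start_idx > prev_stop & start_idx < j]
          if (length(ss)) {
            # reading-space nt coords, 0-based half-open, stop included
            rs_all <- f + (ss - 1L) * 3L
            re <- f + j * 3L
            keep <- (re - rs_all) >= min_len
            if (any(keep)) {
              rs_all <- rs_all[keep]
              rs <- rs_all[1]
              if (strand == "+") {
                rows[[length(rows) + 1L]] <- list(
                  contig = cname, start = rs, end = re, strand = strand,
                  frame = f, start_options = list(rs_all))
              } else {
                rows[[length(rows) + 1L]] <- list(
                  contig = cname, start = L - re, end = L - rs,
                  strand = strand, frame = f,
                  start_options = list(L - rs_all))
              }
            }
          }
          prev_stop <- j
        }
      }
    }
  }
  if (length(rows) == 0) {
    out <- empty_features()
    out$frame <- integer(0)
    out$start_options <- list()
    return(out)
  }
  dt <- data.table::rbindlist(rows)
  data.table::setorderv(dt, c("contig", "start", "strand"))
  out <- make_features(id = sprintf("orf.%d", seq_len(nrow(dt))),
                       contig = dt$contig, start = dt$start, end = dt$end,
                       strand = dt$strand)
  out$frame <- dt$frame
  out$start_options <- dt$start_options
  out$translation <- orf_translations(genome, out)
  out
}

orf_translations <- function(genome, orfs) {
  if (nrow(orfs) == 0) return(character(0))
  vapply(seq_len(nrow(orfs)), function(i) {
    translate_region(genome, orfs$contig[i], orfs$start[i], orfs$end[i],
                     orfs$strand[i])
  }, character(1))
}

# ---------------------------------------------------------------------------
# 3-periodic Markov coding model
# ---------------------------------------------------------------------------

# Count (pos, ctx, base) transitions in a set of in-frame sequences.
# periodic = FALSE pools the three codon positions (background model).
.markov_counts <- function(seqs, order, periodic = TRUE) {
  parts <- lapply(seqs, function(s) {
    L <- nchar(s)
    if (L <= order) return(NULL)
    idx <- (order + 1L):L
    data.table::data.table(
      pos = if (periodic) (idx - 1L) %% 3L else 0L,
      ctx = if (order > 0) substring(s, idx - order, idx - 1L)
            else rep("", length(idx)),
      base = substring(s, idx, idx))
  })
  dt <- data.table::rbindlist(parts)
  if (nrow(dt) == 0) {
    return(data.table::data.table(pos = integer(0), ctx = character(0),
                                  base = character(0), n = integer(0)))
  }
  dt <- dt[!grepl("N", paste0(ctx, base)), ]
  dt[, list(n = .N), by = c("pos", "ctx", "base")]
}

#' Train the 3-periodic Markov coding model
#'
#' The coding model holds, for each of the three codon positions, the
#' conditional distribution of the next base given the preceding `order`
#' bases; the background model is a homogeneous chain of the same order
#' trained on non-coding sequence. Both use add-pseudocount smoothing, so a
#' context/base never seen gets probability `pseudocount / (N + 4 *
#' pseudocount)` and a wholly unseen context backs off to the uniform 1/4.
#' Coding training sequences must be supplied in frame (position 1 is codon
#' position 1). Training is count-based, so permuting the training lists
#' leaves the model unchanged.
#'
#' @param coding List/vector of in-frame coding DNA strings.
#' @param noncoding List/vector of non-coding DNA strings (may be empty, in
#'   which case the background is uniform).
#' @param order Markov order (default 4).
#' @param pseudocount Additive smoothing count (default 1).
#' @return Object of class `pk_model`.
#' @export
train_coding_model <- function(coding, noncoding = character(0), order = 4L,
                               pseudocount = 1.0) {
  coding <- as.character(unlist(coding))
  noncoding <- as.character(unlist(noncoding))
  if (length(coding) == 0) stop("insufficient training data")
  total <- sum(nchar(coding))
  if (total < 3 * (order + 1)) stop("insufficient training data")
  cc <- .markov_counts(coding, order, periodic = TRUE)
  bc <- .markov_counts(noncoding, order, periodic = FALSE)
  ct <- cc[, list(N = sum(n)), by = c("pos", "ctx")]
  bt <- bc[, list(N = sum(n)), by = "ctx"]
  data.table::setkeyv(cc, c("pos", "ctx", "base"))
  data.table::setkeyv(ct, c("pos", "ctx"))
  data.table::setkeyv(bc, c("ctx", "base"))
  data.table::setkeyv(bt, "ctx")
  structure(list(order = as.integer(order), pseudocount = pseudocount,
                 coding = cc, coding_totals = ct,
                 background = bc, background_totals = bt,
                 trained_on = total),
            class = "pk_model")
}

#' @export
print.pk_model <- function(x, ...) {
  cat(sprintf("<pk_model> order=%d, trained on %d coding bases\n",
              x$order, x$trained_on))
  invisible(x)
}

#' Conditional probability lookups from a trained model
#'
#' Mostly a testing aid: returns smoothed `P(base | context)` for the coding
#' model at a codon position (`pos` 0-2) or the background (`pos = NULL`).
#'
#' @param model A `pk_model`.
#' @param ctx Context string of length `order`.
#' @param base Single base.
#' @param pos Codon position 0-2, or `NULL` for background.
#' @return Probability.
#' @export
model_prob <- function(model, ctx, base, pos = NULL) {
  pc <- model$pseudocount
  .ctx <- ctx; .base <- base; .pos <- if (is.null(pos)) NULL
                                      else as.integer(pos)
  if (is.null(pos)) {
    n <- model$background[list(.ctx, .base)]$n
    N <- model$background_totals[list(.ctx)]$N
  } else {
    n <- model$coding[list(.pos, .ctx, .base)]$n
    N <- model$coding_totals[list(.pos, .ctx)]$N
  }
  n <- if (length(n) == 0 || is.na(n)) 0 else n
  N <- if (length(N) == 0 || is.na(N)) 0 else N
  (n + pc) / (N + 4 * pc)
}

# Per-contig/strand score precomputation.
#
# For reading-space string s (the contig for "+", its reverse complement for
# "-") builds three cumulative log-odds vectors C[[r]] (r = ORF start mod 3)
# such that the coding score of any in-frame block [a,b) whose frame start
# is congruent to r is C[[r]][b+1] - C[[r]][a+1]. Positions without a full
# preceding context (the first `order` bases) contribute 0, so scores are
# additive over concatenated in-frame blocks.
.strand_cumscores <- function(model, s) {
  L <- nchar(s)
  order <- model$order
  pc <- model$pseudocount
  zero <- list(`0` = numeric(L + 1), `1` = numeric(L + 1),
               `2` = numeric(L + 1))
  if (L <= order) return(zero)
  idx <- (order + 1L):L
  ctx <- if (order > 0) substring(s, idx - order, idx - 1L)
         else rep("", length(idx))
  base <- substring(s, idx, idx)
  ok <- !grepl("N", paste0(ctx, base))
  dt <- data.table::data.table(i = idx - 1L, ctx = ctx, base = base)[ok]
  if (nrow(dt) == 0) return(zero)
  # background log-prob per position
  dt <- model$background[dt, on = c("ctx", "base")]
  dt <- model$background_totals[dt, on = "ctx"]
  dt[is.na(n), n := 0]
  dt[is.na(N), N := 0]
  dt[, lbg := log((n + pc) / (N + 4 * pc))]
  dt[, c("n", "N") := NULL]
  M <- matrix(0, nrow = L, ncol = 3)
  for (p in 0:2) {
    cp <- data.table::copy(dt)
    cp[, pos := p]
    cp <- model$coding[cp, on = c("pos", "ctx", "base")]
    cp <- model$coding_totals[cp, on = c("pos", "ctx")]
    cp[is.na(n), n := 0]
    cp[is.na(N), N := 0]
    M[cp$i + 1L, p + 1L] <- log((cp$n + pc) / (cp$N + 4 * pc)) - cp$lbg
  }
  out <- list()
  i <- seq_len(L) - 1L
  for (r in 0:2) {
    V <- M[cbind(seq_len(L), ((i %% 3L) - r) %% 3L + 1L)]
    out[[as.character(r)]] <- c(0, cumsum(V))
  }
  out
}

# Cache of cumulative scores for a genome under one model.
genome_cumscores <- function(model, genome) {
  out <- list()
  for (cname in names(genome$contigs)) {
    cs <- genome$contigs[[cname]]
    out[[cname]] <- list(
      "+" = .strand_cumscores(model, cs),
      "-" = .strand_cumscores(model, revcomp(cs)))
  }
  out
}

# Reading-space interval of a genomic region.
.reading_interval <- function(start, end, strand, L) {
  if (strand == "+") c(start, end) else c(L - end, L - start)
}

#' Score ORF candidates under a trained model
#'
#' The score of an ORF is the summed per-base log-odds (coding vs
#' background) over its region, reading the minus strand on the reverse
#' complement. Scores are additive over concatenated in-frame blocks because
#' each base's context is taken from the surrounding contig sequence.
#'
#' @param model A `pk_model`.
#' @param genome A `pk_genome`.
#' @param orfs Candidate feature table ([enumerate_orfs()]).
#' @param cums Optional precomputed [genome_cumscores()] cache.
#' @return Numeric vector of log-odds scores (nats).
#' @export
score_orfs <- function(model, genome, orfs, cums = NULL) {
  if (is.null(model)) stop("untrained model")
  if (nrow(orfs) == 0) return(numeric(0))
  if (is.null(cums)) cums <- genome_cumscores(model, genome)
  vapply(seq_len(nrow(orfs)), function(i) {
    L <- nchar(genome$contigs[[orfs$contig[i]]])
    ri <- .reading_interval(orfs$start[i], orfs$end[i], orfs$strand[i], L)
    C <- cums[[orfs$contig[i]]][[orfs$strand[i]]][[as.character(ri[1] %% 3L)]]
    C[ri[2] + 1L] - C[ri[1] + 1L]
  }, numeric(1))
}

start_codon_bonus <- function(codon, config) {
  switch(codon, ATG = config$start_bonus_atg, GTG = config$start_bonus_gtg,
         TTG = config$start_bonus_ttg, 0)
}

# Re-pick each ORF's start among its recorded options, maximizing model
# score plus a fixed start-codon bonus (ATG > GTG > TTG). Updates region,
# translation and score columns.
pick_starts <- function(model, genome, orfs, config = pk_config(),
                        cums = NULL) {
  if (nrow(orfs) == 0) return(orfs)
  if (is.null(cums)) cums <- genome_cumscores(model, genome)
  for (i in seq_len(nrow(orfs))) {
    opts <- orfs$start_options[[i]]
    if (length(opts) < 1) next
    cname <- orfs$contig[i]; strand <- orfs$strand[i]
    L <- nchar(genome$contigs[[cname]])
    best_j <- 1L; best_val <- -Inf
    for (j in seq_along(opts)) {
      if (strand == "+") { st <- opts[j]; en <- orfs$end[i] }
      else { st <- orfs$start[i]; en <- opts[j] }
      ri <- .reading_interval(st, en, strand, L)
      C <- cums[[cname]][[strand]][[as.character(ri[1] %% 3L)]]
      sc <- C[ri[2] + 1L] - C[ri[1] + 1L]
      codon <- if (strand == "+") substr(genome$contigs[[cname]], st + 1L,
                                         st + 3L)
               else revcomp(substr(genome$contigs[[cname]], en - 2L, en))
      val <- sc + start_codon_bonus(codon, config)
      if (val > best_val + 1e-12) { best_val <- val; best_j <- j }
    }
    if (strand == "+") {
      if (opts[best_j] != orfs$start[i]) {
        orfs$start[i] <- opts[best_j]
        orfs$translation[i] <- translate_region(genome, cname, orfs$start[i],
                                                orfs$end[i], strand)
      }
    } else {
      if (opts[best_j] != orfs$end[i]) {
        orfs$end[i] <- opts[best_j]
        orfs$translation[i] <- translate_region(genome, cname, orfs$start[i],
                                                orfs$end[i], strand)
      }
    }
    ri <- .reading_interval(orfs$start[i], orfs$end[i], strand, L)
    C <- cums[[cname]][[strand]][[as.character(ri[1] %% 3L)]]
    orfs$score[i] <- C[ri[2] + 1L] - C[ri[1] + 1L]
  }
  orfs
}

# Trim a promoted candidate's start to the latest recorded start option
# that still precedes its first signature k-mer hit (aa position h on the
# current translation). Signature evidence anchors the gene body, so starts
# chosen this way are robust to the stop-free composition bias that makes
# pure model scores favor the longest in-frame extension.
anchor_start <- function(cands, i, h, genome) {
  opts <- cands$start_options[[i]]
  if (length(opts) < 2 || is.na(h)) return(cands)
  if (cands$strand[i] == "+") {
    off <- (opts - min(opts)) / 3L
    cur_off <- (cands$start[i] - min(opts)) / 3L
  } else {
    off <- (max(opts) - opts) / 3L
    cur_off <- (max(opts) - cands$end[i]) / 3L
  }
  allowed <- which(off <= cur_off + h - 1L)
  if (length(allowed) == 0) return(cands)
  j <- allowed[which.max(off[allowed])]
  if (cands$strand[i] == "+") {
    if (opts[j] == cands$start[i]) return(cands)
    cands$start[i] <- opts[j]
  } else {
    if (opts[j] == cands$end[i]) return(cands)
    cands$end[i] <- opts[j]
  }
  cands$translation[i] <- translate_region(genome, cands$contig[i],
                                           cands$start[i], cands$end[i],
                                           cands$strand[i])
  cands
}

# Greedy overlap arbitration: features ordered by (kmer_hits desc, score
# desc, start asc) are kept unless they significantly overlap an already
# kept feature or an obstacle. Returns indices of kept rows.
arbitrate_overlaps <- function(features, obstacles = NULL,
                               config = pk_config(),
                               order_by = c("kmer_hits", "score")) {
  n <- nrow(features)
  if (n == 0) return(integer(0))
  ord <- order(-features$kmer_hits,
               if ("score" %in% order_by) -features$score else
                 -(features$end - features$start),
               features$contig, features$start)
  lens <- features$end - features$start
  kept <- integer(0)
  kc <- character(0); ks <- integer(0); ke <- integer(0); kl <- integer(0)
  if (!is.null(obstacles) && nrow(obstacles) > 0) {
    kc <- obstacles$contig; ks <- obstacles$start; ke <- obstacles$end
    kl <- obstacles$end - obstacles$start
  }
  for (i in ord) {
    ov <- overlap_bp_vec(features$contig[i], features$start[i],
                         features$end[i], kc, ks, ke)
    if (!any(significant_overlap(ov, lens[i], kl, config))) {
      kept <- c(kept, i)
      kc <- c(kc, features$contig[i]); ks <- c(ks, features$start[i])
      ke <- c(ke, features$end[i]); kl <- c(kl, lens[i])
    }
  }
  sort(kept)
}

# Non-coding complement of a feature set, as DNA strings (plus strand).
noncoding_regions <- function(genome, features, min_chunk = 30L,
                              max_total = 200000L) {
  out <- character(0)
  total <- 0L
  for (cname in names(genome$contigs)) {
    L <- nchar(genome$contigs[[cname]])
    ff <- features[features$contig == cname, , drop = FALSE]
    cov <- logical(L)
    if (nrow(ff)) {
      for (i in seq_len(nrow(ff))) {
        cov[(ff$start[i] + 1L):ff$end[i]] <- TRUE
      }
    }
    r <- rle(cov)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(!r$values & r$lengths >= min_chunk)) {
      out <- c(out, substr(genome$contigs[[cname]], starts[j], ends[j]))
      total <- total + r$lengths[j]
      if (total > max_total) return(out)
    }
  }
  out
}

coding_training_seqs <- function(genome, features) {
  vapply(seq_len(nrow(features)), function(i) {
    region_dna(genome, features$contig[i], features$start[i],
               features$end[i], features$strand[i])
  }, character(1))
}

#' Iterative gene calling with k-mer validation
#'
#' Implements the retrain-and-validate loop: enumerate ORF candidates, scan
#' their translations against the signature k-mer index, promote candidates
#' with sufficient evidence, retain promoted candidates that do not
#' significantly overlap a previously called gene, retrain the coding model
#' on the retained set, re-pick start codons by model score, and repeat.
#' The loop stops when an iteration promotes no new candidate or after
#' `max_iter` iterations. The promoted set is monotone non-decreasing across
#' iterations, and every promotion/rejection is logged.
#'
#' @param genome A `pk_genome` (prokaryote mode).
#' @param index A `pk_kmer_index`.
#' @param config Configuration list.
#' @param max_iter Maximum number of iterations (default from config, 3).
#' @param rna_features Optional externally supplied RNA features treated as
#'   immovable obstacles for the overlap rule.
#' @param log Optional `pk_log` to append to.
#' @return List with `features` (retained, status `"retained"`),
#'   `candidates` (all ORFs after start refinement, promotion status
#'   recorded), `model`, `iterations`, `promoted_history` (per-iteration
#'   promoted id sets, for monotonicity checks), `log`.
#' @export
call_genes_iterative <- function(genome, index, config = pk_config(),
                                 max_iter = config$max_iter,
                                 rna_features = NULL, log = pk_log_new()) {
  cands <- enumerate_orfs(genome, min_len = config$min_orf_len)
  model <- NULL
  iterations <- 0L
  if (nrow(cands) == 0) {
    return(list(features = empty_features(), candidates = cands,
                model = NULL, iterations = 0L,
                promoted_history = list(), log = log))
  }
  retained_idx <- integer(0)
  promoted_history <- list()
  for (iter in seq_len(max_iter)) {
    iterations <- iter
    todo <- which(cands$status == "candidate")
    newly <- integer(0)
    if (length(todo)) {
      tr <- stats::setNames(cands$translation[todo], cands$id[todo])
      sc <- scan_kmers_batch(index, tr)
      if (nrow(sc)) {
        for (cid in unique(sc$candidate_id)) {
          rows <- sc[sc$candidate_id == cid, ]
          asg <- assign_function_from_scan(rows, index,
                                           min_hits = config$promote_min_hits,
                                           margin = config$promote_margin)
          i <- match(cid, cands$id)
          cands$kmer_hits[i] <- max(cands$kmer_hits[i], asg$hits)
          if (asg$promoted) {
            cands$status[i] <- "promoted"
            cands$fun[i] <- asg$fun
            cands$evidence[i] <- add_evidence(cands$evidence[i], "kmer")
            h <- min(unlist(rows$positions[rows$role_id %in% asg$role_ids]))
            cands <- anchor_start(cands, i, h, genome)
            newly <- c(newly, i)
            pk_log_add(log, "gene_calling", cid, "promoted",
                       sprintf("iteration %d: %d signature k-mer hits for '%s'",
                               iter, asg$hits, asg$fun))
          }
        }
      }
    }
    promoted_history[[iter]] <-
      cands$id[cands$status %in% c("promoted", "retained")]
    if (length(newly) == 0) break
    promoted <- which(cands$status %in% c("promoted", "retained"))
    keep <- arbitrate_overlaps(cands[promoted, , drop = FALSE],
                               obstacles = rna_features, config = config)
    rejected <- setdiff(seq_along(promoted), keep)
    if (length(rejected)) {
      pk_log_add(log, "gene_calling", cands$id[promoted[rejected]],
                 "overlap_rejected",
                 sprintf("iteration %d: significantly overlaps a previously called gene", iter))
    }
    retained_idx <- promoted[keep]
    ret <- cands[retained_idx, , drop = FALSE]
    model <- tryCatch(
      train_coding_model(coding_training_seqs(genome, ret),
                         noncoding_regions(genome, ret),
                         order = config$model_order,
                         pseudocount = config$model_pseudocount),
      error = function(e) NULL)
    if (!is.null(model)) {
      cums <- genome_cumscores(model, genome)
      free <- cands$status == "candidate"  # promoted starts stay anchored
      cands[free, ] <- pick_starts(model, genome,
                                   cands[free, , drop = FALSE],
                                   config = config, cums = cums)
      cands$score <- score_orfs(model, genome, cands, cums = cums)
    }
  }
  feats <- cands[retained_idx, , drop = FALSE]
  if (nrow(feats)) feats$status <- "retained"
  feats$start_options <- NULL; feats$frame <- NULL
  list(features = feats, candidates = cands, model = model,
       iterations = iterations, promoted_history = promoted_history,
       log = log)
}

#' Single-pass gene calling for phage/plasmid submissions
#'
#' Runs one enumerate-and-scan pass and accepts *all* candidate genes,
#' promoted or not, subject only to the overlap rule (arbitration prefers
#' k-mer-supported, then longer, then leftmost candidates). Functions are
#' assigned where k-mer evidence exists.
#'
#' @inheritParams call_genes_iterative
#' @return List as [call_genes_iterative()] (with `model = NULL`,
#'   `iterations = 1`).
#' @export
call_genes_single_pass <- function(genome, index, config = pk_config(),
                                   rna_features = NULL,
                                   log = pk_log_new()) {
  if (!identical(genome$mode, "phage_plasmid")) stop("wrong mode")
  cands <- enumerate_orfs(genome, min_len = config$min_orf_len)
  if (nrow(cands) == 0) {
    return(list(features = empty_features(), candidates = cands,
                model = NULL, iterations = 1L, log = log))
  }
  tr <- stats::setNames(cands$translation, cands$id)
  sc <- scan_kmers_batch(index, tr)
  if (nrow(sc)) {
    for (cid in unique(sc$candidate_id)) {
      rows <- sc[sc$candidate_id == cid, ]
      asg <- assign_function_from_scan(rows, index,
                                       min_hits = config$promote_min_hits,
                                       margin = config$promote_margin)
      i <- match(cid, cands$id)
      cands$kmer_hits[i] <- asg$hits
      if (asg$promoted) {
        cands$status[i] <- "promoted"
        cands$fun[i] <- asg$fun
        cands$evidence[i] <- add_evidence(cands$evidence[i], "kmer")
        h <- min(unlist(rows$positions[rows$role_id %in% asg$role_ids]))
        cands <- anchor_start(cands, i, h, genome)
        pk_log_add(log, "gene_calling", cid, "promoted",
                   sprintf("single pass: %d signature k-mer hits for '%s'",
                           asg$hits, asg$fun))
      }
    }
  }
  keep <- arbitrate_overlaps(cands, obstacles = rna_features,
                             config = config, order_by = "kmer_hits")
  rejected <- setdiff(seq_len(nrow(cands)), keep)
  if (length(rejected)) {
    pk_log_add(log, "gene_calling", cands$id[rejected], "overlap_rejected",
               "single pass: significantly overlaps an accepted candidate")
  }
  feats <- cands[keep, , drop = FALSE]
  feats$status <- "retained"
  pk_log_add(log, "gene_calling", feats$id, "accepted",
             "single pass: all non-overlapping candidates accepted")
  feats$start_options <- NULL; feats$frame <- NULL
  list(features = feats, candidates = cands, model = NULL, iterations = 1L,
       log = log)
}

#' Serialize a coding model to JSON
#' @param model A `pk_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  obj <- list(order = model$order, pseudocount = model$pseudocount,
              trained_on = model$trained_on,
              coding = as.data.frame(model$coding),
              background = as.data.frame(model$background))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
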