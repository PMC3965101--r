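#' Extract overlapping amino-acid k-mers from a protein
#'
#' Returns the `n - k + 1` overlapping windows in sequence order. Windows
#' containing the ambiguity residue `X` (or a stop `*`) are skipped, since
#' they can never act as signatures.
#'
#' @param sequence Protein string.
#' @param k Window size (default 8).
#' @return Character vector of k-mers (possibly empty).
#' @export
extract_kmers <- function(sequence, k = 8L) {
  if (k < 1) stop("k must be >= 1")
  n <- nchar(sequence)
  if (n < k) return(character(0))
  w <- substring(sequence, 1:(n - k + 1L), k:n)
  w[!grepl("[X*]", w)]
}

# kmers of many sequences as a data.table(seq_id, kmer, pos)
kmer_table <- function(sequences, ids, k) {
  stopifnot(length(sequences) == length(ids))
  n <- nchar(sequences)
  keep <- n >= k
  if (!any(keep)) {
    return(data.table::data.table(seq_id = character(0), kmer = character(0),
                                  pos = integer(0)))
  }
  sequences <- sequences[keep]; ids <- ids[keep]; n <- n[keep]
  nw <- n - k + 1L
  seq_id <- rep(ids, nw)
  pos <- unlist(lapply(nw, seq_len), use.names = FALSE)
  kmer <- substring(rep(sequences, nw), pos, pos + k - 1L)
  dt <- data.table::data.table(seq_id = seq_id, kmer = kmer, pos = pos)
  dt[!grepl("[X*]", kmer)]
}

#' Build a signature k-mer index from role-annotated reference proteins
#'
#' An amino-acid k-mer is a *signature* of a functional role when its
#' occurrences in the reference collection are dominated by proteins of that
#' role. A k-mer is stored iff its majority-role occurrence count divided by
#' its total count is at least `dominance_threshold` and its total count is
#' at least `min_occurrences`; ties for the majority role discard the k-mer.
#' The index maps each stored k-mer to exactly one role.
#'
#' @param reference Data frame with columns `id`, `genome_id`, `sequence`,
#'   `role` (role text), and optionally `in_subsystem` (logical).
#' @param k k-mer size (default 8).
#' @param dominance_threshold Minimum majority fraction (default 0.9).
#' @param min_occurrences Minimum total occurrences (default 2).
#' @return An object of class `pk_kmer_index` with elements `k`,
#'   `dominance_threshold`, `min_occurrences`, `roles` (data.frame `id`,
#'   `text`, `in_subsystem`) and `kmers` (data.table keyed by `kmer` with
#'   `role_id`, `count`, `genome_count`).
#' @export
build_kmer_index <- function(reference, k = 8L, dominance_threshold = 0.9,
                             min_occurrences = 2L) {
  if (is.null(reference) || nrow(reference) == 0) stop("empty reference")
  if (any(is.na(reference$role) | reference$role == ""))
    stop("every reference protein must carry a role")
  # Dense role ids from 0, keyed by sorted role text so the index is
  # independent of input order.
  role_text <- sort(unique(reference$role))
  roles <- data.frame(id = seq_along(role_text) - 1L, text = role_text,
                      stringsAsFactors = FALSE)
  if (!is.null(reference$in_subsystem)) {
    ss <- tapply(reference$in_subsystem, reference$role, any)
    roles$in_subsystem <- as.logical(ss[roles$text])
  } else roles$in_subsystem <- TRUE
  role_id <- stats::setNames(roles$id, roles$text)

  kt <- kmer_table(reference$sequence, reference$id, k)
  prot <- data.table::data.table(seq_id = reference$id,
                                 role_id = role_id[reference$role],
                                 genome_id = reference$genome_id)
  kt <- merge(kt, prot, by = "seq_id", allow.cartesian = TRUE)
  # per (kmer, role): occurrences and distinct genomes
  count <- genome_id <- n_role <- total <- top <- tie <- NULL  # NSE notes
  per <- kt[, list(count = .N,
                   genome_count = data.table::uniqueN(genome_id)),
            by = c("kmer", "role_id")]
  per[, total := sum(count), by = "kmer"]
  per[, top := max(count), by = "kmer"]
  per[, tie := sum(count == top) > 1L, by = "kmer"]
  sig <- per[count == top & tie == FALSE & total >= min_occurrences &
               count / total >= dominance_threshold]
  kmers <- sig[, c("kmer", "role_id", "count", "genome_count")]
  data.table::setkeyv(kmers, "kmer")
  structure(list(k = as.integer(k),
                 dominance_threshold = dominance_threshold,
                 min_occurrences = as.integer(min_occurrences),
                 roles = roles, kmers = kmers),
            class = "pk_kmer_index")
}

#' @export
print.pk_kmer_index <- function(x, ...) {
  cat(sprintf("<pk_kmer_index> k=%d, %d signature k-mers, %d roles\n",
              x$k, nrow(x$kmers), nrow(x$roles)))
  invisible(x)
}

#' Scan a candidate translation against a signature k-mer index
#'
#' Counts exact occurrences of stored signature k-mers in the translation,
#' per functional role. `best_role` is filled only when the promotion rule
#' (see [promote_candidate()]) is satisfied.
#'
#' @param index A `pk_kmer_index`.
#' @param translation Protein string.
#' @param candidate_id Identifier carried into the result.
#' @param min_hits,margin Promotion parameters, see [promote_candidate()].
#' @return List with `candidate_id`, `counts` (named integer vector by role
#'   id), `positions` (list of 1-based window offsets per role id),
#'   `best_role` (role id or `NA`), and `promoted`.
#' @export
scan_kmers <- function(index, translation, candidate_id = "candidate",
                       min_hits = 3L, margin = 2L) {
  dt <- scan_kmers_batch(index, stats::setNames(translation, candidate_id))
  counts <- stats::setNames(dt$hits, as.character(dt$role_id))
  positions <- stats::setNames(dt$positions, as.character(dt$role_id))
  res <- list(candidate_id = candidate_id, counts = counts,
              positions = positions, best_role = NA_integer_,
              promoted = FALSE)
  pr <- promote_candidate(res, min_hits = min_hits, margin = margin)
  res$best_role <- pr$role
  res$promoted <- pr$promoted
  res
}

# Batch scan: named translations -> data.table(candidate_id, role_id, hits,
# positions (list of integer vectors), len (translation length)).
scan_kmers_batch <- function(index, translations) {
  kt <- kmer_table(unname(translations), names(translations), index$k)
  hits <- NULL
  if (nrow(kt) == 0) {
    return(data.table::data.table(candidate_id = character(0),
                                  role_id = integer(0), hits = integer(0),
                                  positions = list(), len = integer(0)))
  }
  m <- index$kmers[kt, on = "kmer", nomatch = NULL]
  if (nrow(m) == 0) {
    return(data.table::data.table(candidate_id = character(0),
                                  role_id = integer(0), hits = integer(0),
                                  positions = list(), len = integer(0)))
  }
  out <- m[, list(hits = .N, positions = list(sort(pos))),
           by = c("seq_id", "role_id")]
  data.table::setnames(out, "seq_id", "candidate_id")
  lens <- nchar(translations)
  out$len <- unname(lens[out$candidate_id])
  data.table::setorderv(out, c("candidate_id", "role_id"))
  out
}

#' Apply the promotion rule to a k-mer scan result
#'
#' A candidate is promoted to protein-encoding gene status when its top role
#' has at least `min_hits` signature k-mer hits and leads the runner-up by at
#' least `margin` hits.
#'
#' @param result Scan result from [scan_kmers()] (or a named counts vector).
#' @param min_hits Minimum hits for the top role (default 3).
#' @param margin Minimum lead over the runner-up (default 2).
#' @return List with `role` (role id or `NA`) and `promoted` (logical).
#' @export
promote_candidate <- function(result, min_hits = 3L, margin = 2L) {
  counts <- if (is.list(result)) result$counts else result
  if (length(counts) == 0) return(list(role = NA_integer_, promoted = FALSE))
  counts <- sort(counts, decreasing = TRUE)
  top <- counts[1]
  runner <- if (length(counts) > 1) counts[2] else 0L
  if (top >= min_hits && (top - runner) >= margin) {
    list(role = as.integer(names(counts)[1]), promoted = TRUE)
  } else list(role = NA_integer_, promoted = FALSE)
}

# Decide the emitted function for a scanned candidate, including the fusion
# rule: when two roles each reach min_hits with all their hits confined to
# opposite halves of the translation, both role texts are joined with " / "
# in N- to C-terminal order. Returns list(fun, role_ids, promoted, hits).
assign_function_from_scan <- function(scan_dt_rows, index, min_hits = 3L,
                                      margin = 2L) {
  if (nrow(scan_dt_rows) == 0)
    return(list(fun = "", role_ids = integer(0), promoted = FALSE,
                hits = 0L))
  counts <- stats::setNames(scan_dt_rows$hits,
                            as.character(scan_dt_rows$role_id))
  len <- scan_dt_rows$len[1]
  k <- index$k
  # fusion: the two strongest roles each satisfy min_hits and their hit
  # windows occupy disjoint, ordered stretches of the translation
  strong <- scan_dt_rows[scan_dt_rows$hits >= min_hits, , drop = FALSE]
  if (nrow(strong) >= 2 && !is.na(len)) {
    strong <- strong[order(-strong$hits), , drop = FALSE]
    a <- strong[1, ]; b <- strong[2, ]
    sa <- c(min(a$positions[[1]]), max(a$positions[[1]]) + k - 1L)
    sb <- c(min(b$positions[[1]]), max(b$positions[[1]]) + k - 1L)
    if (a$role_id != b$role_id && (sa[2] < sb[1] || sb[2] < sa[1])) {
      if (sb[1] < sa[1]) { tmp <- a; a <- b; b <- tmp }
      texts <- index$roles$text[match(c(a$role_id, b$role_id),
                                      index$roles$id)]
      return(list(fun = paste(texts, collapse = " / "),
                  role_ids = c(a$role_id, b$role_id), promoted = TRUE,
                  hits = a$hits + b$hits))
    }
  }
  pr <- promote_candidate(counts, min_hits = min_hits, margin = margin)
  if (pr$promoted) {
    list(fun = index$roles$text[match(pr$role, index$roles$id)],
         role_ids = pr$role, promoted = TRUE, hits = max(counts))
  } else {
    list(fun = "", role_ids = integer(0), promoted = FALSE,
         hits = if (length(counts)) max(counts) else 0L)
  }
}

#' Serialize a signature k-mer index to (gzipped) TSV
#'
#' Header comment lines record `k` and the build thresholds and enumerate the
#' role table; data lines are `kmer, role_id, count, genome_count`.
#'
#' @param index A `pk_kmer_index`.
#' @param path Output path; a `.gz` suffix gzip-compresses.
#' @return `path`, invisibly.
#' @export
write_kmer_index <- function(index, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("#k\t%d", index$k),
    sprintf("#dominance_threshold\t%s", format(index$dominance_threshold)),
    sprintf("#min_occurrences\t%d", index$min_occurrences),
    sprintf("#role\t%d\t%s\t%d", index$roles$id, index$roles$text,
            as.integer(index$roles$in_subsystem)),
    "#kmer\trole_id\tcount\tgenome_count"
  ), con)
  if (nrow(index$kmers)) {
    writeLines(sprintf("%s\t%d\t%d\t%d", index$kmers$kmer,
                       index$kmers$role_id, index$kmers$count,
                       index$kmers$genome_count), con)
  }
  invisible(path)
}

#' Read a signature k-mer index written by [write_kmer_index()]
#' @param path Index file path.
#' @return A `pk_kmer_index`.
#' @export
read_kmer_index <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "r") else file(path, "r")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  getv <- function(key) {
    ln <- hdr[startsWith(hdr, paste0("#", key, "\t"))]
    if (length(ln) != 1) stop("corrupt index header: missing ", key)
    strsplit(ln, "\t", fixed = TRUE)[[1]][2]
  }
  role_lines <- hdr[startsWith(hdr, "#role\t")]
  rl <- strsplit(role_lines, "\t", fixed = TRUE)
  roles <- data.frame(id = as.integer(vapply(rl, `[`, "", 2)),
                      text = vapply(rl, `[`, "", 3),
                      in_subsystem = as.integer(vapply(rl, `[`, "", 4)) == 1L,
                      stringsAsFactors = FALSE)
  if (length(body)) {
    bl <- strsplit(body, "\t", fixed = TRUE)
    if (any(lengths(bl) != 4)) stop("corrupt index body")
    kmers <- data.table::data.table(
      kmer = vapply(bl, `[`, "", 1),
      role_id = as.integer(vapply(bl, `[`, "", 2)),
      count = as.integer(vapply(bl, `[`, "", 3)),
      genome_count = as.integer(vapply(bl, `[`, "", 4)))
  } else {
    kmers <- data.table::data.table(kmer = character(0),
                                    role_id = integer(0), count = integer(0),
                                    genome_count = integer(0))
  }
  data.table::setkeyv(kmers, "kmer")
  structure(list(k = as.integer(getv("k")),
                 dominance_threshold = as.numeric(getv("dominance_threshold")),
                 min_occurrences = as.integer(getv("min_occurrences")),
                 roles = roles, kmers = kmers),
            class = "pk_kmer_index")
}

role_text <- function(index, role_id) {
  index$roles$text[match(role_id, index$roles$id)]
}

#' Split a (possibly fused) function string into role texts
#'
#' Fusion gene products carry several roles joined with `" / "`.
#' @param fun Character vector of function strings.
#' @return List of character vectors of role texts.
#' @export
split_roles <- function(fun) {
  out <- strsplit(fun, " / ", fixed = TRUE)
  lapply(out, function(x) x[nzchar(x)])
}
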