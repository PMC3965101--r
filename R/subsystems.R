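#' Read a subsystem collection from TSV
#'
#' The format is a three/four-column TSV: `subsystem`, `record`
#' (`role` or `variant`), `key`, `value`. For `role` records the key is the
#' 0-based role index and the value the role text; for `variant` records the
#' key is the variant code and the value a comma-separated list of role
#' indices. The codes `"0"` (not active) and `"-1"` (absent) are reserved.
#'
#' @param path TSV file.
#' @return Named list of subsystems, each `list(name, roles, variants)`
#'   where `variants` maps codes to character vectors of role texts.
#' @export
read_subsystems <- function(path) {
  dt <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "#")
  needed <- c("subsystem", "record", "key", "value")
  if (!all(needed %in% names(dt))) stop("corrupt subsystem TSV: need columns ",
                                        paste(needed, collapse = ", "))
  out <- list()
  for (nm in unique(dt$subsystem)) {
    rows <- dt[dt$subsystem == nm, , drop = FALSE]
    rr <- rows[rows$record == "role", , drop = FALSE]
    roles <- rr$value[order(as.integer(rr$key))]
    vr <- rows[rows$record == "variant", , drop = FALSE]
    variants <- list()
    for (j in seq_len(nrow(vr))) {
      idx <- as.integer(strsplit(vr$value[j], ",", fixed = TRUE)[[1]])
      variants[[as.character(vr$key[j])]] <- roles[idx + 1L]
    }
    out[[nm]] <- list(name = nm, roles = roles, variants = variants)
  }
  validate_subsystems(out)
}

validate_subsystems <- function(collection) {
  nms <- vapply(collection, `[[`, "", "name")
  if (anyDuplicated(nms)) stop("duplicate subsystem names in collection")
  for (ss in collection) {
    for (v in ss$variants) {
      if (!all(v %in% ss$roles)) stop("variant roles outside subsystem '",
                                      ss$name, "'")
    }
  }
  collection
}

#' Write a subsystem collection to TSV
#' @param collection List of subsystems (see [read_subsystems()]).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_subsystems <- function(collection, path) {
  rows <- list()
  for (ss in collection) {
    rows[[length(rows) + 1L]] <- data.frame(
      subsystem = ss$name, record = "role",
      key = as.character(seq_along(ss$roles) - 1L), value = ss$roles,
      stringsAsFactors = FALSE)
    if (length(ss$variants)) {
      rows[[length(rows) + 1L]] <- data.frame(
        subsystem = ss$name, record = "variant", key = names(ss$variants),
        value = vapply(ss$variants, function(v) {
          paste(match(v, ss$roles) - 1L, collapse = ",")
        }, ""), stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Project subsystems onto an annotated genome
#'
#' For each subsystem, features are mapped to its roles by exact role-text
#' match (fusion functions are split on `" / "` first); subsystems with no
#' matched role are omitted. Each projection then gets its most likely
#' variant via [estimate_variant()] and a completeness fraction (found roles
#' of the assigned variant / variant size).
#'
#' @param features Feature table with `fun` role texts.
#' @param collection Subsystem collection (list, see [read_subsystems()]).
#' @param config Configuration list (`min_variant_jaccard`).
#' @param log Optional `pk_log`.
#' @return List of projections: `list(subsystem, variant, roles (named list
#'   role -> feature ids), completeness)`.
#' @export
project_subsystems <- function(features, collection, config = pk_config(),
                               log = NULL) {
  validate_subsystems(collection)
  roles_per_feature <- split_roles(features$fun)
  out <- list()
  for (ss in collection) {
    role_map <- list()
    for (role in ss$roles) {
      hit <- which(vapply(roles_per_feature, function(r) role %in% r,
                          logical(1)))
      if (length(hit)) role_map[[role]] <- features$id[hit]
    }
    if (length(role_map) == 0) next
    variant <- estimate_variant(names(role_map), ss,
                                min_jaccard = config$min_variant_jaccard,
                                log = log)
    vroles <- if (variant %in% names(ss$variants)) ss$variants[[variant]]
              else ss$roles
    completeness <- length(intersect(names(role_map), vroles)) /
      max(1L, length(vroles))
    out[[ss$name]] <- list(subsystem = ss$name, variant = variant,
                           roles = role_map, completeness = completeness)
    if (!is.null(log)) {
      pk_log_add(log, "subsystems", ss$name, "projected",
                 sprintf("variant '%s', %d/%d roles found", variant,
                         length(role_map), length(ss$roles)))
    }
  }
  out
}

#' Estimate the most likely variant of a projected subsystem
#'
#' Chooses the variant code maximizing the Jaccard similarity between the
#' found roles and the variant's role set. Ties prefer the variant with the
#' fewest roles, then the lexicographically smaller code. A best Jaccard
#' below `min_jaccard` yields code `"0"` (not active). For subsystems
#' without declared variants the code is `"1"` when at least half the roles
#' are found, else `"0"`.
#'
#' @param found_roles Character vector of role texts found in the genome.
#' @param subsystem One subsystem (`list(name, roles, variants)`).
#' @param min_jaccard Activity threshold (default 0.5).
#' @param log Optional `pk_log` (tie-breaks are logged).
#' @return Variant code string.
#' @export
estimate_variant <- function(found_roles, subsystem, min_jaccard = 0.5,
                             log = NULL) {
  found <- unique(found_roles)
  vars <- subsystem$variants
  vars <- vars[!names(vars) %in% c("0", "-1")]
  if (length(vars) == 0) {
    return(if (length(intersect(found, subsystem$roles)) >=
               length(subsystem$roles) / 2) "1" else "0")
  }
  jac <- vapply(vars, function(v) {
    length(intersect(found, v)) / length(union(found, v))
  }, numeric(1))
  sizes <- lengths(vars)
  ord <- order(-jac, sizes, names(vars))
  best <- ord[1]
  if (length(ord) > 1) {
    second <- ord[2]
    if (!is.null(log) && jac[second] == jac[best]) {
      pk_log_add(log, "subsystems", subsystem$name, "variant_tie",
                 sprintf("variants '%s' and '%s' tie at Jaccard %.2f; '%s' chosen",
                         names(vars)[best], names(vars)[second], jac[best],
                         names(vars)[best]))
    }
  }
  if (jac[best] < min_jaccard) "0" else names(vars)[best]
}

# gap between two regions on one contig (0 when overlapping)
region_gap <- function(start_a, end_a, start_b, end_b) {
  pmax(0L, pmax(start_a, start_b) - pmin(end_a, end_b))
}

#' Pairs of close bidirectional best hits (functional coupling)
#'
#' A PCBBH is a quadruple (a1, a2; b1, b2) where a1-b1 and a2-b2 are BBH
#' pairs between the query genome and one reference genome, a1 and a2 lie
#' within `close_threshold` bases of each other on one query contig
#' (boundary gap, 0 when overlapping) and b1, b2 likewise in the reference.
#' The coupling score of a query gene pair is the number of distinct
#' reference genomes contributing a PCBBH for it.
#'
#' @param features Annotated query feature table.
#' @param reference Reference proteins with coordinates (`id`, `genome_id`,
#'   `contig`, `start`, `end`).
#' @param bbh_maps Named list (by reference genome id) of BBH pair
#'   data.frames (`gene_a`, `gene_b`).
#' @param close_threshold Maximum gap in bases (default 5000).
#' @return List with `pcbbh` (data.frame `genome_id`, `gene_a1`, `gene_a2`,
#'   `gene_b1`, `gene_b2`, `d_a`, `d_b`) and `coupling` (data.frame
#'   `gene_a1`, `gene_a2`, `score`).
#' @export
compute_pcbbh <- function(features, reference, bbh_maps,
                          close_threshold = 5000L) {
  empty <- list(pcbbh = data.frame(genome_id = character(0),
                                   gene_a1 = character(0),
                                   gene_a2 = character(0),
                                   gene_b1 = character(0),
                                   gene_b2 = character(0),
                                   d_a = integer(0), d_b = integer(0),
                                   stringsAsFactors = FALSE),
                coupling = data.frame(gene_a1 = character(0),
                                      gene_a2 = character(0),
                                      score = integer(0),
                                      stringsAsFactors = FALSE))
  if (nrow(features) < 2 || length(bbh_maps) == 0) return(empty)
  ff <- features[order(features$contig, features$start), , drop = FALSE]
  # close query pairs
  qpairs <- list()
  for (cname in unique(ff$contig)) {
    fc <- ff[ff$contig == cname, , drop = FALSE]
    n <- nrow(fc)
    if (n < 2) next
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        d <- region_gap(fc$start[i], fc$end[i], fc$start[j], fc$end[j])
        if (fc$start[j] - fc$end[i] > close_threshold) break
        if (d <= close_threshold) {
          qpairs[[length(qpairs) + 1L]] <- data.frame(
            gene_a1 = fc$id[i], gene_a2 = fc$id[j], d_a = d,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(qpairs) == 0) return(empty)
  qp <- do.call(rbind, qpairs)
  out <- list()
  for (N in names(bbh_maps)) {
    bm <- bbh_maps[[N]]
    if (is.null(bm) || nrow(bm) == 0) next
    b1 <- bm$gene_b[match(qp$gene_a1, bm$gene_a)]
    b2 <- bm$gene_b[match(qp$gene_a2, bm$gene_a)]
    ok <- !is.na(b1) & !is.na(b2)
    if (!any(ok)) next
    r1 <- match(b1[ok], reference$id); r2 <- match(b2[ok], reference$id)
    same_contig <- reference$contig[r1] == reference$contig[r2] &
      reference$genome_id[r1] == N & reference$genome_id[r2] == N
    d_b <- region_gap(reference$start[r1], reference$end[r1],
                      reference$start[r2], reference$end[r2])
    close_b <- same_contig & d_b <= close_threshold
    if (!any(close_b)) next
    w <- which(ok)[close_b]
    out[[N]] <- data.frame(genome_id = N, gene_a1 = qp$gene_a1[w],
                           gene_a2 = qp$gene_a2[w],
                           gene_b1 = b1[w], gene_b2 = b2[w],
                           d_a = qp$d_a[w], d_b = d_b[close_b],
                           stringsAsFactors = FALSE)
  }
  if (length(out) == 0) return(empty)
  pcbbh <- do.call(rbind, out)
  rownames(pcbbh) <- NULL
  cp <- stats::aggregate(genome_id ~ gene_a1 + gene_a2, data = pcbbh,
                         FUN = function(x) length(unique(x)))
  names(cp)[3] <- "score"
  cp <- cp[order(cp$gene_a1, cp$gene_a2), , drop = FALSE]
  rownames(cp) <- NULL
  list(pcbbh = pcbbh, coupling = cp)
}
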