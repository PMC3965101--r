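#' Context-based re-annotation via conserved gene triples
#'
#' For each CDS lacking a subsystem-based role whose two immediate flanking
#' features on the same contig both have subsystem-based roles: if the
#' triple (left, self, right) are bidirectional best hits to a contiguous
#' gene triple in one neighbor genome, the middle gene's function is
#' replaced by the neighbor middle gene's subsystem role. Flanking is
#' strand-blind (nearest retained CDS on each side); when several neighbors
#' satisfy the rule with conflicting roles the highest-ranked neighbor wins
#' and the conflict is logged. Features that already carry a
#' subsystem-based role are never changed.
#'
#' @param features Feature table, any order.
#' @param reference Reference proteins with coordinates and roles (`id`,
#'   `genome_id`, `role`, `in_subsystem`, `contig`, `start`).
#' @param neighbor_ids Neighbor genome ids in rank order.
#' @param bbh_maps Named list (by genome id) of BBH pair data.frames
#'   (`gene_a` query feature id, `gene_b` reference protein id).
#' @param subsystem_roles Character vector of role texts counted as
#'   subsystem-based.
#' @param log Optional `pk_log`.
#' @return Updated feature table.
#' @export
context_reannotate <- function(features, reference, neighbor_ids, bbh_maps,
                               subsystem_roles, log = NULL) {
  if (nrow(features) < 3 || length(bbh_maps) == 0) return(features)
  is_ss_role <- function(fun) {
    vapply(split_roles(fun),
           function(r) any(r %in% subsystem_roles), logical(1))
  }
  # neighbor gene order along each reference contig
  ref_rank <- stats::ave(reference$start,
                         paste(reference$genome_id, reference$contig),
                         FUN = rank)
  names(ref_rank) <- reference$id
  ord <- order(features$contig, features$start)
  for (ii in seq_along(ord)[-c(1, length(ord))]) {
    i <- ord[ii]; l <- ord[ii - 1L]; r <- ord[ii + 1L]
    if (features$type[i] != "CDS") next
    if (features$contig[l] != features$contig[i] ||
        features$contig[r] != features$contig[i]) next
    if (is_ss_role(features$fun[i])) next
    if (!is_ss_role(features$fun[l]) || !is_ss_role(features$fun[r])) next
    for (N in neighbor_ids) {
      bm <- bbh_maps[[N]]
      if (is.null(bm) || nrow(bm) == 0) next
      bl <- bm$gene_b[match(features$id[l], bm$gene_a)]
      bi <- bm$gene_b[match(features$id[i], bm$gene_a)]
      br <- bm$gene_b[match(features$id[r], bm$gene_a)]
      if (is.na(bl) || is.na(bi) || is.na(br)) next
      ctg <- reference$contig[match(c(bl, bi, br), reference$id)]
      if (length(unique(ctg)) != 1) next
      rk <- ref_rank[c(bl, bi, br)]
      if (max(rk) - min(rk) != 2 || rk[2] == max(rk) || rk[2] == min(rk))
        next  # middle gene must sit between its flanks, immediately adjacent
      ri <- match(bi, reference$id)
      role <- reference$role[ri]
      in_ss <- if (!is.null(reference$in_subsystem))
        isTRUE(reference$in_subsystem[ri]) else role %in% subsystem_roles
      if (!in_ss || is.na(role) || !nzchar(role)) next
      if (!is.null(log)) {
        if (nzchar(features$fun[i]) && features$fun[i] != role) {
          pk_log_add(log, "context_reannotate", features$id[i],
                     "function_replaced",
                     sprintf("'%s' replaced by '%s' from neighbor %s (conserved triple %s-%s-%s)",
                             features$fun[i], role, N, bl, bi, br))
        } else {
          pk_log_add(log, "context_reannotate", features$id[i],
                     "function_assigned",
                     sprintf("'%s' from neighbor %s (conserved triple)",
                             role, N))
        }
      }
      features$fun[i] <- role
      features$evidence[i] <- add_evidence(features$evidence[i],
                                           "context_bbh")
      break  # highest-ranked satisfying neighbor wins
    }
  }
  features
}

#' Final cleanup of unsupported gene candidates
#'
#' A feature with no annotation evidence (no `kmer`, `blast_neighbor` or
#' `context_bbh` tag) is removed when it is embedded within another feature
#' (entirely contained, either strand), significantly overlaps another
#' feature, or is shorter than 90 nt (strictly). Supported features are
#' never removed here. The operation is idempotent.
#'
#' @param features Feature table.
#' @param config Configuration list.
#' @param log Optional `pk_log`.
#' @return Retained features.
#' @export
final_filter <- function(features, config = pk_config(), log = NULL) {
  if (nrow(features) == 0) return(features)
  supported <- is_supported(features)
  lens <- features$end - features$start
  remove <- logical(nrow(features))
  reason <- character(nrow(features))
  for (i in which(!supported)) {
    if (lens[i] < config$overlap_min_bp) {
      remove[i] <- TRUE
      reason[i] <- sprintf("unsupported and shorter than %d nt",
                           config$overlap_min_bp)
      next
    }
    others <- setdiff(seq_len(nrow(features)), i)
    same <- others[features$contig[others] == features$contig[i]]
    if (length(same) == 0) next
    embedded <- any(features$start[same] <= features$start[i] &
                      features$end[same] >= features$end[i])
    if (embedded) {
      remove[i] <- TRUE
      reason[i] <- "unsupported and embedded within another feature"
      next
    }
    ov <- overlap_bp_vec(features$contig[i], features$start[i],
                         features$end[i], features$contig[same],
                         features$start[same], features$end[same])
    if (any(significant_overlap(ov, lens[i], lens[same], config))) {
      remove[i] <- TRUE
      reason[i] <- "unsupported and significantly overlapping another feature"
    }
  }
  if (!is.null(log) && any(remove)) {
    pk_log_add(log, "final_filter", features$id[remove], "removed",
               reason[remove])
  }
  features[!remove, , drop = FALSE]
}
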