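#' Annotate a genome against a reference protein collection
#'
#' Runs the full annotation pipeline. For prokaryotic submissions the stage
#' order is: neighbor estimation from ab initio candidates; the iterative
#' k-mer-validated gene-calling loop; rescue of unpromoted candidates by
#' similarity to the closest neighbor proteomes; acceptance of remaining
#' non-overlapping candidates; frameshift detection (joins applied only
#' with `fix_frameshifts = TRUE`); backfilling of gene-free stretches longer
#' than 1500 bp; similarity-based function assignment; context
#' re-annotation via conserved BBH triples; missed-gene rescue in gaps
#' flanked by subsystem BBHs; final cleanup; subsystem projection with
#' variant estimation; and functional coupling (PCBBH). Submissions under
#' 100 kb total run the phage/plasmid route instead: a single calling pass
#' accepting all candidates, then the pipeline continues from frameshift
#' detection onward.
#'
#' @param genome A `pk_genome`, or a path to a FASTA/GenBank file.
#' @param reference A list with `proteins` (data.frame: `id`, `genome_id`,
#'   `sequence`, `role`, optional `in_subsystem`, `contig`, `start`, `end`,
#'   `strand`) and optional `subsystems`, or a directory path readable by
#'   [read_reference()].
#' @param subsystems Optional subsystem collection (overrides the
#'   reference's).
#' @param index Optional prebuilt `pk_kmer_index` (otherwise built from the
#'   reference).
#' @param mode `"auto"`, `"prokaryote"` or `"phage_plasmid"`.
#' @param fix_frameshifts Apply frameshift joins (default FALSE: proposals
#'   are only logged).
#' @param rna_features Optional externally computed RNA features: a feature
#'   table or a GFF3 path. Merged as immovable features; no RNA detection
#'   is performed.
#' @param out_dir Optional output directory; when given, GFF3, GenBank,
#'   FASTA (nucleotide and protein), feature/subsystem/coupling TSVs and
#'   the annotation log are written there.
#' @param seed Integer seed (the pipeline is deterministic; the seed guards
#'   any downstream randomness).
#' @param config Configuration list, see [pk_config()].
#' @return Object of class `pk_result`: `genome`, `features`, `candidates`,
#'   `model`, `iterations`, `neighbors`, `bbh_maps`, `joins`,
#'   `applied_joins`, `projections`, `pcbbh`, `coupling`, `log`, `index`,
#'   `config`.
#' @export
annotate <- function(genome, reference, subsystems = NULL, index = NULL,
                     mode = "auto", fix_frameshifts = FALSE,
                     rna_features = NULL, out_dir = NULL, seed = 1L,
                     config = pk_config()) {
  set.seed(seed)
  log <- pk_log_new()
  if (is.character(genome)) {
    genome <- if (grepl("\\.(gb|gbk|gbff|genbank)$", genome,
                        ignore.case = TRUE))
      read_genome_genbank(genome, mode = mode, config = config)
    else read_genome_fasta(genome, mode = mode, config = config)
  } else if (!identical(mode, "auto")) {
    genome$mode <- select_mode(genome, mode, config = config)
  }
  if (is.character(reference)) reference <- read_reference(reference)
  ref <- reference$proteins
  if (is.null(subsystems)) subsystems <- reference$subsystems
  if (is.null(index)) {
    index <- build_kmer_index(ref, k = config$kmer_k,
                              dominance_threshold = config$kmer_dominance,
                              min_occurrences = config$kmer_min_occurrences)
  }
  if (is.character(rna_features)) rna_features <- read_gff3_features(rna_features)
  pk_log_add(log, "setup", genome$id, "mode_selected",
             sprintf("%d bp over %d contig(s): %s route", genome_length(genome),
                     length(genome$contigs), genome$mode))

  phage <- identical(genome$mode, "phage_plasmid")
  call <- if (phage) {
    call_genes_single_pass(genome, index, config = config,
                           rna_features = rna_features, log = log)
  } else {
    call_genes_iterative(genome, index, config = config,
                         rna_features = rna_features, log = log)
  }
  features <- call$features

  # closest reference genomes, estimated from the ab initio candidates
  cand_prot <- stats::setNames(call$candidates$translation,
                               call$candidates$id)
  neighbors <- find_neighbors(cand_prot, ref, config = config,
                              exact = !config$seed_filter)
  pk_log_add(log, "neighbors", neighbors$genome_id, "ranked",
             sprintf("similarity score %.0f", neighbors$score))
  neighbor_proteins <- ref[ref$genome_id %in% neighbors$genome_id, ,
                           drop = FALSE]

  if (!phage) {
    rescued <- rescue_by_neighbor_blast(call$candidates, neighbor_proteins,
                                        features, config = config,
                                        exact = !config$seed_filter,
                                        log = log)
    if (nrow(rescued)) {
      call$candidates$status[call$candidates$id %in% rescued$id] <- "retained"
      features <- rbind(features, rescued)
    }
    remaining <- accept_remaining(call$candidates, features,
                                  config = config, log = log)
    if (nrow(remaining)) features <- rbind(features, remaining)
  }
  if (!is.null(rna_features) && nrow(rna_features))
    features <- rbind(features, rna_features)
  features <- features[order(features$contig, features$start,
                             features$id), , drop = FALSE]

  # frameshift detection and (optional) repair; promoted candidates that
  # lost overlap arbitration are still visible as fragments here, since a
  # frameshifted gene's two fragment ORFs frequently overlap each other
  lost <- call$candidates[call$candidates$status == "promoted" &
                            !call$candidates$id %in% features$id, ,
                          drop = FALSE]
  joins <- detect_frameshifts(features, neighbor_proteins, config = config,
                              exact = !config$seed_filter,
                              extra_fragments = lost)
  rep_res <- apply_joins(features, joins, user_opt_in = fix_frameshifts,
                         log = log, fragments = lost)
  features <- rep_res$features

  # backfill long gene-free stretches
  bf <- backfill_gaps(genome, features, neighbor_proteins, config = config,
                      exact = !config$seed_filter, log = log)
  if (nrow(bf)) features <- rbind(features, bf)

  # similarity-based function assignment
  features <- assign_by_blast(features, neighbor_proteins, config = config,
                              exact = !config$seed_filter, log = log)

  # BBH tables against the top-ranked neighbors
  bbh_ids <- utils::head(neighbors$genome_id, config$bbh_neighbors)
  bbh_full <- compute_bbh_maps(features, ref, bbh_ids, config = config,
                               exact = !config$seed_filter)
  bbh_maps <- lapply(bbh_full, `[[`, "pairs")

  subsystem_roles <- if (!is.null(subsystems)) {
    unique(unlist(lapply(subsystems, `[[`, "roles")))
  } else unique(ref$role[ref$in_subsystem %||% rep(TRUE, nrow(ref))])

  features <- context_reannotate(features, ref, bbh_ids, bbh_maps,
                                 subsystem_roles, log = log)

  missed <- rescue_missed(genome, features, ref, bbh_ids, bbh_maps,
                          config = config, exact = !config$seed_filter,
                          log = log)
  if (nrow(missed)) {
    features <- rbind(features, missed)
    features <- features[order(features$contig, features$start,
                               features$id), , drop = FALSE]
  }

  features <- final_filter(features, config = config, log = log)
  rownames(features) <- NULL

  projections <- if (!is.null(subsystems)) {
    project_subsystems(features, subsystems, config = config, log = log)
  } else list()

  pc <- compute_pcbbh(features, ref, bbh_maps,
                      close_threshold = config$close_threshold)

  res <- structure(list(genome = genome, features = features,
                        candidates = call$candidates, model = call$model,
                        iterations = call$iterations,
                        neighbors = neighbors, bbh_maps = bbh_maps,
                        joins = joins, applied_joins = rep_res$applied,
                        projections = projections, pcbbh = pc$pcbbh,
                        coupling = pc$coupling, log = log, index = index,
                        config = config),
                   class = "pk_result")
  if (!is.null(out_dir)) export_annotation(res, out_dir)
  res
}

#' @export
print.pk_result <- function(x, ...) {
  cat(sprintf("<pk_result> %s (%s): %d features, %d subsystems projected, %d coupled gene pairs\n",
              x$genome$id, x$genome$mode, nrow(x$features),
              length(x$projections), nrow(x$coupling)))
  invisible(x)
}

#' Export an annotation result bundle
#'
#' Writes `genome.gff3`, `genome.gbk`, `genome.fna`, `proteins.faa`,
#' `features.tsv`, `subsystems.tsv`, `coupling.tsv` and `log.txt` into
#' `out_dir`.
#'
#' @param result A `pk_result` from [annotate()].
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
export_annotation <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  notes <- NULL
  if (nrow(result$applied_joins)) {
    notes <- stats::setNames(result$applied_joins$rationale,
                             paste0(result$applied_joins$fragment_1,
                                    "_join"))
  }
  write_gff3(result$genome, result$features,
             file.path(out_dir, "genome.gff3"), notes = notes)
  write_genbank(result$genome, result$features,
                file.path(out_dir, "genome.gbk"), notes = notes)
  write_genome_fasta(result$genome, file.path(out_dir, "genome.fna"))
  write_proteins_fasta(result$features, file.path(out_dir, "proteins.faa"))
  write_feature_tsv(result$features, file.path(out_dir, "features.tsv"),
                    projections = result$projections)
  ss <- data.frame(
    subsystem = vapply(result$projections, `[[`, "", "subsystem"),
    variant = vapply(result$projections, `[[`, "", "variant"),
    completeness = vapply(result$projections, `[[`, 0, "completeness"),
    roles_found = vapply(result$projections,
                         function(p) length(p$roles), 0L),
    stringsAsFactors = FALSE)
  utils::write.table(ss, file.path(out_dir, "subsystems.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_coupling_tsv(result$coupling, file.path(out_dir, "coupling.tsv"))
  utils::write.table(as.data.frame(result$log),
                     file.path(out_dir, "log.txt"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(out_dir)
}

#' Compare annotated target genomes against a reference genome
#'
#' For each target (at most nine), every target gene is classified as
#' `unique`, `unidirectional` or `bidirectional` best hit against the
#' reference proteome — the data table behind a multi-genome
#' insertion/deletion circle plot.
#'
#' @param reference A `pk_result` (or feature table with translations) for
#'   the reference genome.
#' @param targets List of up to nine `pk_result`s/feature tables.
#' @param config Configuration list.
#' @param exact Alignment prescreen switch.
#' @return Named list (by target index or name) of `classes` data.frames
#'   (target-side rows only, with coordinates merged in).
#' @export
genome_compare <- function(reference, targets, config = pk_config(),
                           exact = TRUE) {
  if (length(targets) > 9) stop("at most nine target genomes are supported")
  feats_of <- function(x) if (inherits(x, "pk_result")) x$features else x
  rf <- feats_of(reference)
  rp <- stats::setNames(rf$translation, rf$id)
  rp <- rp[nzchar(rp)]
  out <- list()
  nms <- names(targets) %||% as.character(seq_along(targets))
  for (i in seq_along(targets)) {
    tf <- feats_of(targets[[i]])
    tp <- stats::setNames(tf$translation, tf$id)
    tp <- tp[nzchar(tp)]
    bh <- best_hits(tp, rp, config = config, exact = exact)
    cls <- bh$classes[bh$classes$genome == "a", , drop = FALSE]
    m <- match(cls$gene_id, tf$id)
    cls$contig <- tf$contig[m]
    cls$start <- tf$start[m]; cls$end <- tf$end[m]
    cls$strand <- tf$strand[m]
    out[[nms[i]]] <- cls
  }
  out
}
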