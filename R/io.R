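feature_segments <- function(features, i) {
  p <- features$parts[[i]]
  if (is.null(p)) data.frame(start = features$start[i],
                             end = features$end[i])
  else p[order(p$start), , drop = FALSE]
}

gff3_escape <- function(x) {
  x <- gsub("%", "%25", x, fixed = TRUE)
  x <- gsub(";", "%3B", x, fixed = TRUE)
  x <- gsub("=", "%3D", x, fixed = TRUE)
  x <- gsub(",", "%2C", x, fixed = TRUE)
  x <- gsub("&", "%26", x, fixed = TRUE)
  x
}

gff3_unescape <- function(x) {
  for (p in list(c("%3B", ";"), c("%3D", "="), c("%2C", ","),
                 c("%26", "&"), c("%25", "%"))) {
    x <- gsub(p[1], p[2], x, fixed = TRUE)
  }
  x
}

#' Write annotated features as GFF3
#'
#' Internal 0-based half-open coordinates are converted to GFF3's 1-based
#' inclusive convention. Joined (frameshift-repaired) features emit one CDS
#' line per segment sharing a single `ID`, with the CDS phase computed per
#' segment. Output is byte-deterministic.
#'
#' @param genome A `pk_genome`.
#' @param features Feature table.
#' @param path Output path.
#' @param notes Optional named character vector (feature id -> note).
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genome, features, path, notes = NULL) {
  lines <- c("##gff-version 3",
             sprintf("##sequence-region %s 1 %d", names(genome$contigs),
                     nchar(genome$contigs)))
  if (nrow(features)) {
    features <- features[order(features$contig, features$start,
                               features$id), , drop = FALSE]
    for (i in seq_len(nrow(features))) {
      segs <- feature_segments(features, i)
      # phase per segment in transcription order
      ord <- if (features$strand[i] == "+") seq_len(nrow(segs))
             else rev(seq_len(nrow(segs)))
      phase <- integer(nrow(segs))
      done <- 0L
      for (j in ord) {
        phase[j] <- (3L - done %% 3L) %% 3L
        done <- done + (segs$end[j] - segs$start[j])
      }
      product <- if (nzchar(features$fun[i])) features$fun[i]
                 else if (features$type[i] == "CDS") "hypothetical protein"
                 else ""
      attrs <- sprintf("ID=%s;product=%s;status=%s;origin=%s;evidence=%s",
                       gff3_escape(features$id[i]), gff3_escape(product),
                       features$status[i], features$origin[i],
                       gff3_escape(features$evidence[i]))
      note <- notes[features$id[i]]
      if (!is.null(note) && !is.na(note))
        attrs <- paste0(attrs, ";Note=", gff3_escape(unname(note)))
      lines <- c(lines, sprintf(
        "%s\tprokann\t%s\t%d\t%d\t%s\t%s\t%s\t%s",
        features$contig[i], features$type[i], segs$start + 1L, segs$end,
        if (is.na(features$score[i]) || features$score[i] == 0) "."
        else sprintf("%.2f", features$score[i]),
        features$strand[i],
        if (features$type[i] == "CDS") as.character(phase) else ".",
        attrs))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read features from a GFF3 file
#'
#' Reads CDS/tRNA/rRNA (and other) feature lines back into the internal
#' feature table, merging lines that share an `ID` into multi-segment
#' features. Used both for round-tripping and for merging externally
#' computed RNA features into a run.
#'
#' @param path GFF3 file.
#' @return Feature table.
#' @export
read_gff3_features <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0) return(empty_features())
  fld <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fld) != 9)) stop("malformed GFF3 line")
  df <- data.frame(contig = vapply(fld, `[`, "", 1),
                   type = vapply(fld, `[`, "", 3),
                   start = as.integer(vapply(fld, `[`, "", 4)) - 1L,
                   end = as.integer(vapply(fld, `[`, "", 5)),
                   score = vapply(fld, `[`, "", 6),
                   strand = vapply(fld, `[`, "", 7),
                   attrs = vapply(fld, `[`, "", 9),
                   stringsAsFactors = FALSE)
  getattr <- function(attrs, key) {
    m <- regmatches(attrs, regexec(paste0("(?:^|;)", key, "=([^;]*)"),
                                   attrs))
    vapply(m, function(x) if (length(x) == 2) gff3_unescape(x[2]) else "",
           "")
  }
  df$id <- getattr(df$attrs, "ID")
  df$product <- getattr(df$attrs, "product")
  df$status <- getattr(df$attrs, "status")
  df$origin <- getattr(df$attrs, "origin")
  df$evidence <- getattr(df$attrs, "evidence")
  out <- list()
  for (fid in unique(df$id)) {
    rows <- df[df$id == fid, , drop = FALSE]
    fun <- rows$product[1]
    if (identical(fun, "hypothetical protein")) fun <- ""
    ft <- make_features(
      id = fid, contig = rows$contig[1], start = min(rows$start),
      end = max(rows$end), strand = rows$strand[1], type = rows$type[1],
      fun = fun,
      status = if (nzchar(rows$status[1])) rows$status[1] else "retained",
      origin = if (nzchar(rows$origin[1])) rows$origin[1] else "external_rna",
      evidence = if (nzchar(rows$evidence[1])) rows$evidence[1] else "none",
      score = suppressWarnings(as.numeric(rows$score[1])))
    if (nrow(rows) > 1) {
      ft$parts <- list(data.frame(start = sort(rows$start),
                                  end = sort(rows$end)))
    }
    if (is.na(ft$score)) ft$score <- 0
    out[[length(out) + 1L]] <- ft
  }
  res <- do.call(rbind, out)
  res <- res[order(res$contig, res$start, res$id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Write the genome sequence as FASTA
#' @param genome A `pk_genome`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome$contigs),
                              path)
  invisible(path)
}

#' Write CDS translations as protein FASTA
#' @param features Feature table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_proteins_fasta <- function(features, path) {
  cds <- features[features$type == "CDS" & nzchar(features$translation), ,
                  drop = FALSE]
  desc <- ifelse(nzchar(cds$fun), cds$fun, "hypothetical protein")
  seqs <- Biostrings::AAStringSet(stats::setNames(
    cds$translation, paste(cds$id, desc)))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

# GenBank location string for one feature (1-based inclusive).
.gbk_location <- function(features, i) {
  segs <- feature_segments(features, i)
  locs <- sprintf("%d..%d", segs$start + 1L, segs$end)
  loc <- if (length(locs) > 1) sprintf("join(%s)",
                                       paste(locs, collapse = ","))
         else locs
  if (features$strand[i] == "-") sprintf("complement(%s)", loc) else loc
}

.gbk_wrap_qualifier <- function(key, value) {
  txt <- sprintf("/%s=\"%s\"", key, value)
  out <- character(0)
  width <- 58L
  while (nchar(txt) > width) {
    out <- c(out, substr(txt, 1, width))
    txt <- substr(txt, width + 1L, nchar(txt))
  }
  c(out, txt)
}

#' Write annotated contigs as a GenBank flat file
#'
#' One record per contig; joined features use `join()` locations and carry
#' the frameshift rationale in a `/note`. The LOCUS date is fixed so
#' identical runs produce byte-identical files.
#'
#' @param genome A `pk_genome`.
#' @param features Feature table.
#' @param path Output path.
#' @param notes Optional named character vector (feature id -> note).
#' @return `path`, invisibly.
#' @export
write_genbank <- function(genome, features, path, notes = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  for (cname in names(genome$contigs)) {
    s <- genome$contigs[[cname]]
    L <- nchar(s)
    writeLines(sprintf(
      "LOCUS       %-16s %d bp    DNA     linear   BCT 01-JAN-2000",
      cname, L), con)
    writeLines(sprintf("DEFINITION  %s contig %s.", genome$name, cname),
               con)
    writeLines("FEATURES             Location/Qualifiers", con)
    writeLines(sprintf("     source          1..%d", L), con)
    ff <- features[features$contig == cname, , drop = FALSE]
    if (nrow(ff)) {
      ff <- ff[order(ff$start, ff$id), , drop = FALSE]
      for (i in seq_len(nrow(ff))) {
        key <- switch(ff$type[i], CDS = "CDS", tRNA = "tRNA",
                      rRNA = "rRNA", "misc_feature")
        writeLines(sprintf("     %-15s %s", key, .gbk_location(ff, i)),
                   con)
        quals <- c(.gbk_wrap_qualifier("locus_tag", ff$id[i]),
                   .gbk_wrap_qualifier("product",
                                       if (nzchar(ff$fun[i])) ff$fun[i]
                                       else "hypothetical protein"))
        note <- notes[ff$id[i]]
        if (!is.null(note) && !is.na(note))
          quals <- c(quals, .gbk_wrap_qualifier("note", unname(note)))
        if (ff$type[i] == "CDS" && nzchar(ff$translation[i]))
          quals <- c(quals, .gbk_wrap_qualifier("translation",
                                                ff$translation[i]))
        writeLines(paste0("                     ", quals), con)
      }
    }
    writeLines("ORIGIN", con)
    pos <- seq(1L, L, by = 60L)
    for (p in pos) {
      chunk <- substr(s, p, min(p + 59L, L))
      groups <- substring(chunk,
                          seq(1L, nchar(chunk), by = 10L),
                          pmin(seq(10L, nchar(chunk) + 9L, by = 10L),
                               nchar(chunk)))
      writeLines(sprintf("%9d %s", p, tolower(paste(groups,
                                                    collapse = " "))), con)
    }
    writeLines("//", con)
  }
  invisible(path)
}

#' Write the tab-delimited feature dump
#'
#' Columns: `feature_id`, `contig`, `start`, `end` (1-based inclusive),
#' `strand`, `type`, `function`, `evidence`, `subsystem`, `variant`.
#'
#' @param features Feature table.
#' @param path Output path.
#' @param projections Subsystem projections (from [project_subsystems()])
#'   used to fill the subsystem/variant columns.
#' @return `path`, invisibly.
#' @export
write_feature_tsv <- function(features, path, projections = NULL) {
  ss <- stats::setNames(rep("", nrow(features)), features$id)
  vv <- stats::setNames(rep("", nrow(features)), features$id)
  for (pr in projections) {
    for (ids in pr$roles) {
      for (fid in ids) {
        if (!fid %in% names(ss)) next
        ss[fid] <- if (nzchar(ss[fid])) paste(ss[fid], pr$subsystem,
                                              sep = ";")
                   else pr$subsystem
        vv[fid] <- if (nzchar(vv[fid])) paste(vv[fid], pr$variant,
                                              sep = ";")
                   else pr$variant
      }
    }
  }
  features <- features[order(features$contig, features$start,
                             features$id), , drop = FALSE]
  df <- data.frame(feature_id = features$id, contig = features$contig,
                   start = features$start + 1L, end = features$end,
                   strand = features$strand, type = features$type,
                   `function` = features$fun, evidence = features$evidence,
                   subsystem = unname(ss[features$id]),
                   variant = unname(vv[features$id]),
                   stringsAsFactors = FALSE, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a feature TSV written by [write_feature_tsv()]
#' @param path TSV path.
#' @return Feature table (span coordinates; segment structure and
#'   translations are not part of the TSV dump).
#' @export
read_feature_tsv <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          quote = "", check.names = FALSE)
  make_features(id = df$feature_id, contig = df$contig,
                start = df$start - 1L, end = df$end, strand = df$strand,
                type = df$type, fun = df$`function`, status = "retained",
                evidence = df$evidence)
}

#' Write the functional-coupling table
#' @param coupling Coupling data.frame from [compute_pcbbh()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_coupling_tsv <- function(coupling, path) {
  utils::write.table(coupling, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a proteome-comparison table (insertions/deletions view)
#'
#' The data table behind a circle-plot comparison: each target gene with
#' its coordinates, best-hit class against the reference (`unique`,
#' `unidirectional`, `bidirectional`), best subject and identity.
#'
#' @param classes `classes` data.frame from [best_hits()] (target side).
#' @param features Target feature table (for coordinates).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_comparison_tsv <- function(classes, features, path) {
  m <- match(classes$gene_id, features$id)
  df <- data.frame(gene_id = classes$gene_id,
                   contig = features$contig[m],
                   start = features$start[m] + 1L, end = features$end[m],
                   strand = features$strand[m], class = classes$class,
                   best_subject = ifelse(is.na(classes$best_subject), "",
                                         classes$best_subject),
                   identity = ifelse(is.na(classes$identity), "",
                                     sprintf("%.3f", classes$identity)),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
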