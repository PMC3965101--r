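#' @importFrom Biostrings DNAStringSet AAStringSet readDNAStringSet
#'   writeXStringSet reverseComplement getGeneticCode
#' @import data.table
NULL

#' Construct a genome object
#'
#' A genome is a set of named contigs (DNA over A,C,G,T,N) plus a genetic
#' code and a pipeline mode. Mode is `"phage_plasmid"` when the summed contig
#' length is below `mode_threshold` (default 100000 bp), `"prokaryote"`
#' otherwise; an explicit `mode` overrides the automatic choice.
#'
#' Internally all coordinates are 0-based half-open `[start, end)`; exporters
#' convert to the 1-based inclusive convention of GFF3/GenBank.
#'
#' @param contigs Named character vector of contig sequences.
#' @param id,name Genome identifier and display name.
#' @param genetic_code NCBI translation table number (default 11).
#' @param mode `"auto"`, `"prokaryote"` or `"phage_plasmid"`.
#' @param config Configuration list, see [pk_config()].
#' @return An object of class `pk_genome`.
#' @export
pk_genome <- function(contigs, id = "genome", name = id,
                      genetic_code = 11L, mode = "auto",
                      config = pk_config()) {
  if (length(contigs) == 0) stop("no contigs")
  if (is.null(names(contigs)) || anyDuplicated(names(contigs)))
    stop("contigs must have unique names")
  nm <- names(contigs)
  contigs <- toupper(as.character(contigs))
  names(contigs) <- nm
  if (any(nchar(contigs) < 1)) stop("empty contig")
  if (any(grepl("[^ACGTN]", contigs))) stop("contig contains non-ACGTN characters")
  g <- structure(list(id = id, name = name, contigs = contigs,
                      genetic_code = as.integer(genetic_code),
                      mode = "auto"),
                 class = "pk_genome")
  g$mode <- select_mode(g, if (identical(mode, "auto")) NULL else mode,
                        config = config)
  g
}

#' @export
print.pk_genome <- function(x, ...) {
  cat(sprintf("<pk_genome> %s: %d contig(s), %d bp, mode=%s, code=%d\n",
              x$id, length(x$contigs), genome_length(x), x$mode,
              x$genetic_code))
  invisible(x)
}

#' Total genome length in bases
#' @param genome A `pk_genome`.
#' @return Integer, sum of contig lengths.
#' @export
genome_length <- function(genome) sum(nchar(genome$contigs))

#' Select the pipeline mode for a genome
#'
#' Submissions shorter than `mode_threshold` bases over all contigs run the
#' single-pass phage/plasmid route; the comparison is a strict less-than, so
#' a genome of exactly the threshold length is treated as prokaryotic. A user
#' override always wins.
#'
#' @param genome A `pk_genome`.
#' @param override `NULL`, `"prokaryote"` or `"phage_plasmid"`.
#' @param config Configuration list.
#' @return `"prokaryote"` or `"phage_plasmid"`.
#' @export
select_mode <- function(genome, override = NULL, config = pk_config()) {
  if (length(genome$contigs) == 0) stop("no contigs")
  if (!is.null(override)) {
    if (!override %in% c("prokaryote", "phage_plasmid"))
      stop("invalid mode override: ", override)
    return(override)
  }
  if (genome_length(genome) < config$mode_threshold) "phage_plasmid"
  else "prokaryote"
}

#' Read a genome from a (possibly multi-contig) FASTA file
#'
#' @param path FASTA file; any line wrapping; `N` allowed.
#' @inheritParams pk_genome
#' @return A `pk_genome`.
#' @export
read_genome_fasta <- function(path, id = NULL, mode = "auto",
                              genetic_code = 11L, config = pk_config()) {
  ss <- readDNAStringSet(path)
  if (length(ss) == 0) stop("no contigs")
  contigs <- as.character(ss)
  names(contigs) <- sub("\\s.*$", "", names(ss))
  if (is.null(id)) id <- tools::file_path_sans_ext(basename(path))
  pk_genome(contigs, id = id, mode = mode, genetic_code = genetic_code,
            config = config)
}

#' Read genome sequence from a GenBank flat file
#'
#' Only LOCUS names and ORIGIN sequence blocks are used; feature annotations
#' in the input are ignored.
#'
#' @param path GenBank flat file, possibly multi-record.
#' @inheritParams pk_genome
#' @return A `pk_genome`.
#' @export
read_genome_genbank <- function(path, id = NULL, mode = "auto",
                                genetic_code = 11L, config = pk_config()) {
  lines <- readLines(path, warn = FALSE)
  locus_i <- grep("^LOCUS", lines)
  if (length(locus_i) == 0) stop("no LOCUS records in ", path)
  ends <- c(locus_i[-1] - 1L, length(lines))
  contigs <- character(0)
  for (r in seq_along(locus_i)) {
    block <- lines[locus_i[r]:ends[r]]
    cname <- strsplit(trimws(sub("^LOCUS\\s+", "", block[1])), "\\s+")[[1]][1]
    oi <- grep("^ORIGIN", block)
    if (length(oi) == 0) stop("record without ORIGIN block: ", cname)
    seq_lines <- block[(oi[1] + 1):length(block)]
    seq_lines <- seq_lines[!grepl("^//", seq_lines)]
    s <- toupper(gsub("[^a-zA-Z]", "", paste(seq_lines, collapse = "")))
    contigs[cname] <- s
  }
  if (is.null(id)) id <- tools::file_path_sans_ext(basename(path))
  pk_genome(contigs, id = id, mode = mode, genetic_code = genetic_code,
            config = config)
}

#' Reverse complement of DNA strings
#' @param x Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(reverseComplement(DNAStringSet(x)))
}

# Translation table cache: named vector codon -> AA for a genetic code.
.pk_code_cache <- new.env(parent = emptyenv())
pk_codon_table <- function(genetic_code = 11L) {
  key <- as.character(genetic_code)
  if (is.null(.pk_code_cache[[key]])) {
    .pk_code_cache[[key]] <- getGeneticCode(key)
  }
  .pk_code_cache[[key]]
}

#' Translate in-frame DNA sequences to protein
#'
#' Translation uses the genome's genetic code (default table 11). The first
#' codon is rendered `M` when it is one of the initiators ATG/GTG/TTG;
#' internal stops are rendered `*` and are tolerated (they are a frameshift
#' signal consumed by the repair stage, not an error); a single trailing stop
#' is trimmed. Codons containing `N` translate to `X`.
#'
#' @param dna Character vector of DNA sequences, each with length divisible
#'   by 3.
#' @param genetic_code NCBI translation table number.
#' @param as_initiator Treat position 1 as an initiator codon (default TRUE).
#' @return Character vector of protein sequences.
#' @export
translate_dna <- function(dna, genetic_code = 11L, as_initiator = TRUE) {
  if (length(dna) == 0) return(character(0))
  if (any(nchar(dna) %% 3 != 0)) stop("frame error")
  tab <- pk_codon_table(genetic_code)
  vapply(dna, function(s) {
    n <- nchar(s)
    if (n == 0) return("")
    codons <- substring(s, seq(1L, n - 2L, by = 3L), seq(3L, n, by = 3L))
    aa <- unname(tab[codons])
    aa[is.na(aa)] <- "X"
    if (as_initiator && codons[1] %in% c("ATG", "GTG", "TTG")) aa[1] <- "M"
    if (length(aa) > 0 && aa[length(aa)] == "*") aa <- aa[-length(aa)]
    paste(aa, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Extract the DNA of a (possibly multi-segment) region
#'
#' Segments are given in genomic order; on the minus strand they are
#' reverse-complemented and concatenated in transcription order.
#'
#' @param genome A `pk_genome`.
#' @param contig_id Contig name.
#' @param starts,ends Integer vectors (0-based half-open), one per segment.
#' @param strand `"+"` or `"-"`.
#' @return A single DNA string.
#' @export
region_dna <- function(genome, contig_id, starts, ends, strand = "+") {
  s <- genome$contigs[[contig_id]]
  if (is.null(s)) stop("unknown contig: ", contig_id)
  L <- nchar(s)
  if (any(starts < 0) || any(ends > L) || any(starts >= ends))
    stop("invalid region on ", contig_id)
  o <- order(starts)
  segs <- substring(s, starts[o] + 1L, ends[o])
  if (strand == "+") paste(segs, collapse = "")
  else revcomp(paste(segs, collapse = ""))  # revcomp reverses segment order
}

#' Translate a region of a genome
#'
#' @inheritParams region_dna
#' @param genetic_code Overrides the genome's code when given.
#' @return Protein string (trailing stop trimmed, internal stops as `*`).
#' @export
translate_region <- function(genome, contig_id, starts, ends, strand = "+",
                             genetic_code = NULL) {
  dna <- region_dna(genome, contig_id, starts, ends, strand)
  if (nchar(dna) %% 3 != 0) stop("frame error")
  translate_dna(dna, genetic_code %||% genome$genetic_code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Overlap between two regions in bases
#'
#' Strand-blind; 0 when the regions are on different contigs or disjoint.
#' Coordinates are 0-based half-open, so `[0,300)` and `[300,600)` are
#' adjacent, not overlapping.
#'
#' @param contig_a,start_a,end_a First region.
#' @param contig_b,start_b,end_b Second region.
#' @return Integer number of overlapping bases.
#' @export
overlap_bp <- function(contig_a, start_a, end_a, contig_b, start_b, end_b) {
  if (!identical(contig_a, contig_b)) return(0L)
  as.integer(max(0L, min(end_a, end_b) - max(start_a, start_b)))
}

# Vectorised overlap of one region against columns of a feature table.
overlap_bp_vec <- function(contig, start, end, contigs, starts, ends) {
  ov <- pmin(ends, end) - pmax(starts, start)
  ov[contigs != contig] <- 0L
  pmax(ov, 0L)
}

#' Is an overlap "significant" under the pipeline's overlap rule?
#'
#' An overlap is significant when it exceeds
#' `max(overlap_min_bp, overlap_frac * shorter feature length)`
#' (defaults 90 bp and 50%).
#'
#' @param ov Overlap in bases.
#' @param len_a,len_b Lengths of the two features.
#' @param config Configuration list.
#' @return Logical.
#' @export
significant_overlap <- function(ov, len_a, len_b, config = pk_config()) {
  ov > pmax(config$overlap_min_bp, config$overlap_frac * pmin(len_a, len_b))
}

# ---------------------------------------------------------------------------
# Feature tables
#
# Features are plain data.frames, one row per feature:
#   id, contig, start, end (0-based half-open span), strand, type,
#   fun (functional role text, "" when unassigned), status, origin,
#   evidence (comma-joined tags of kmer/blast_neighbor/context_bbh/none),
#   translation, kmer_hits, score, parts (list column; NULL for simple
#   features, else data.frame(start, end) for multi-segment joins).
# ---------------------------------------------------------------------------

#' An empty feature table
#' @return Zero-row feature data.frame with the canonical columns.
#' @export
empty_features <- function() {
  df <- data.frame(id = character(0), contig = character(0),
                   start = integer(0), end = integer(0),
                   strand = character(0), type = character(0),
                   fun = character(0), status = character(0),
                   origin = character(0), evidence = character(0),
                   translation = character(0), kmer_hits = integer(0),
                   score = numeric(0), stringsAsFactors = FALSE)
  df$parts <- list()
  df
}

#' Build a feature table row-wise
#'
#' Missing columns get defaults (`status="candidate"`, `origin="ab_initio"`,
#' `evidence="none"`, etc.). Used heavily by tests and the synthetic module.
#'
#' @param id,contig,start,end,strand,type,fun,status,origin,evidence,translation,kmer_hits,score
#'   Column vectors, recycled to a common length.
#' @param parts Optional list of segment data.frames.
#' @return Feature data.frame.
#' @export
make_features <- function(id, contig, start, end, strand, type = "CDS",
                          fun = "", status = "candidate",
                          origin = "ab_initio", evidence = "none",
                          translation = "", kmer_hits = 0L, score = 0,
                          parts = NULL) {
  n <- length(id)
  df <- data.frame(id = id, contig = rep_len(contig, n),
                   start = as.integer(rep_len(start, n)),
                   end = as.integer(rep_len(end, n)),
                   strand = rep_len(strand, n),
                   type = rep_len(type, n), fun = rep_len(fun, n),
                   status = rep_len(status, n),
                   origin = rep_len(origin, n),
                   evidence = rep_len(evidence, n),
                   translation = rep_len(translation, n),
                   kmer_hits = as.integer(rep_len(kmer_hits, n)),
                   score = as.numeric(rep_len(score, n)),
                   stringsAsFactors = FALSE)
  df$parts <- if (is.null(parts)) vector("list", n) else parts
  df
}

feature_lengths <- function(features) {
  vapply(seq_len(nrow(features)), function(i) {
    p <- features$parts[[i]]
    if (is.null(p)) features$end[i] - features$start[i]
    else as.integer(sum(p$end - p$start))
  }, integer(1))
}

has_evidence <- function(features, tag) {
  vapply(strsplit(features$evidence, ",", fixed = TRUE),
         function(tags) tag %in% tags, logical(1))
}

add_evidence <- function(evidence, tag) {
  tags <- strsplit(evidence, ",", fixed = TRUE)[[1]]
  tags <- setdiff(tags, "none")
  paste(unique(c(tags, tag)), collapse = ",")
}

#' Is any feature supported by annotation evidence?
#'
#' Supported means carrying at least one of the `kmer`, `blast_neighbor` or
#' `context_bbh` evidence tags; non-CDS features (externally supplied RNAs)
#' are always supported.
#'
#' @param features Feature table.
#' @return Logical vector.
#' @export
is_supported <- function(features) {
  has_evidence(features, "kmer") | has_evidence(features, "blast_neighbor") |
    has_evidence(features, "context_bbh") | features$type != "CDS"
}

# ---------------------------------------------------------------------------
# Annotation log: an append-only record of every inference.
# ---------------------------------------------------------------------------

#' Create an annotation log
#'
#' The log is an append-only environment accumulating one entry per
#' inference: which stage acted on which feature, what it did and why.
#'
#' @return An object of class `pk_log`.
#' @export
pk_log_new <- function() {
  e <- new.env(parent = emptyenv())
  e$stage <- character(0); e$feature_id <- character(0)
  e$action <- character(0); e$rationale <- character(0)
  class(e) <- "pk_log"
  e
}

#' Append entries to an annotation log
#' @param log A `pk_log`.
#' @param stage,feature_id,action,rationale Entry fields (recycled).
#' @return The log, invisibly.
#' @export
pk_log_add <- function(log, stage, feature_id, action, rationale = "") {
  n <- max(length(stage), length(feature_id), length(action),
           length(rationale))
  if (n == 0) return(invisible(log))
  log$stage <- c(log$stage, rep_len(stage, n))
  log$feature_id <- c(log$feature_id, rep_len(feature_id, n))
  log$action <- c(log$action, rep_len(action, n))
  log$rationale <- c(log$rationale, rep_len(rationale, n))
  invisible(log)
}

#' @export
as.data.frame.pk_log <- function(x, ...) {
  data.frame(stage = x$stage, feature_id = x$feature_id, action = x$action,
             rationale = x$rationale, stringsAsFactors = FALSE)
}

#' @export
print.pk_log <- function(x, ...) {
  cat(sprintf("<pk_log> %d entries\n", length(x$stage)))
  invisible(x)
}
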