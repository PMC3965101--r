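NONSTOP_CODONS <- setdiff(
  as.vector(outer(as.vector(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                                  paste0)),
                  c("A", "C", "G", "T"), paste0)),
  c("TAA", "TAG", "TGA"))

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N", "P",
          "Q", "R", "S", "T", "V", "W", "Y")

.random_gene_dna <- function(ncodons) {
  body <- sample(NONSTOP_CODONS, ncodons - 2L, replace = TRUE)
  paste(c("ATG", body, "TAA"), collapse = "")
}

.mutate_protein <- function(protein, rate) {
  aa <- strsplit(protein, "", fixed = TRUE)[[1]]
  n <- length(aa)
  if (n < 3) return(protein)
  hit <- which(stats::runif(n) < rate)
  hit <- hit[hit > 1L]  # keep the initiator M
  for (i in hit) aa[i] <- sample(setdiff(AA20, aa[i]), 1L)
  paste(aa, collapse = "")
}

#' Generate a synthetic reference world
#'
#' Builds a collection of protein families sharing functional roles, spread
#' over several reference genomes, plus a subsystem collection — the raw
#' material the annotation pipeline consumes. Each family descends from a
#' random ancestor gene; members are derived by per-site substitutions tuned
#' so the mean pairwise within-family protein identity matches
#' `within_family_identity`. A further `n_novel_families` families are
#' generated but excluded from the emitted reference, so simulated genomes
#' can carry genes unknown to the annotator. Reference genes get coordinates
#' on one contig per reference genome (family order, forward strand), which
#' drives the gene-context and functional-coupling machinery. Identical
#' parameters and seed reproduce the world bit for bit.
#'
#' @param n_roles Number of distinct functional roles (default 40).
#' @param n_families Number of reference families (>= `n_roles`; default
#'   `n_roles`, one family per role).
#' @param proteins_per_family Members per family, assigned to reference
#'   genomes round-robin (default 6).
#' @param n_reference_genomes Number of reference genomes (default 6).
#' @param protein_length Codon-length range genes are drawn from
#'   (default `c(100, 300)`).
#' @param within_family_identity Target mean pairwise protein identity
#'   within a family (default 0.9).
#' @param n_novel_families Families held out of the reference (default 10%
#'   of `n_families`, at least 2).
#' @param subsystem_size Roles per subsystem (default 4); about 60% of
#'   roles are organized into subsystems, each declaring two variants (the
#'   full role set, and its first half).
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @return Object of class `pk_world`: `proteins` (reference data.frame),
#'   `subsystems`, `families`, `novel_families`, `params`.
#' @export
generate_world <- function(n_roles = 40L, n_families = n_roles,
                           proteins_per_family = 6L,
                           n_reference_genomes = 6L,
                           protein_length = c(100L, 300L),
                           within_family_identity = 0.9,
                           n_novel_families = max(2L, round(0.1 * n_families)),
                           subsystem_size = 4L, seed = 1L) {
  if (n_families < n_roles) stop("inconsistent params: families < roles")
  set.seed(seed)
  role_texts <- sprintf("Synthetic role %03d (EC 9.9.9.%d)", seq_len(n_roles),
                        seq_len(n_roles))
  fam_role <- role_texts[((seq_len(n_families) - 1L) %% n_roles) + 1L]
  novel_role <- sprintf("Novel role %03d", seq_len(n_novel_families))

  make_family <- function(role) {
    ncod <- sample(protein_length[1]:protein_length[2], 1L)
    dna <- .random_gene_dna(ncod)
    list(dna = dna, protein = translate_dna(dna), role = role)
  }
  families <- lapply(fam_role, make_family)
  novel_families <- lapply(novel_role, make_family)

  # subsystems over ~60% of roles, in blocks
  n_ss <- max(1L, floor(n_roles * 0.6 / subsystem_size))
  subsystems <- list()
  ss_roles <- character(0)
  for (s in seq_len(n_ss)) {
    idx <- ((s - 1L) * subsystem_size + 1L):(s * subsystem_size)
    roles <- role_texts[idx]
    nm <- sprintf("Synthetic subsystem %02d", s)
    subsystems[[nm]] <- list(
      name = nm, roles = roles,
      variants = list("1" = roles,
                      "2" = roles[seq_len(ceiling(subsystem_size / 2))]))
    ss_roles <- c(ss_roles, roles)
  }

  rate <- 1 - sqrt(within_family_identity)
  rows <- list()
  for (fi in seq_along(families)) {
    fam <- families[[fi]]
    for (m in seq_len(proteins_per_family)) {
      g <- ((m - 1L) %% n_reference_genomes) + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        id = sprintf("G%d.f%03d", g, fi),
        genome_id = sprintf("G%d", g),
        sequence = .mutate_protein(fam$protein, rate),
        role = fam$role, in_subsystem = fam$role %in% ss_roles,
        family = fi, stringsAsFactors = FALSE)
    }
  }
  proteins <- do.call(rbind, rows)
  proteins <- proteins[!duplicated(proteins$id), , drop = FALSE]
  # coordinates: per genome, genes in family order with fixed spacing
  proteins <- proteins[order(proteins$genome_id, proteins$family), ,
                       drop = FALSE]
  proteins$contig <- paste0(proteins$genome_id, "_c1")
  proteins$strand <- "+"
  proteins$start <- NA_integer_; proteins$end <- NA_integer_
  for (g in unique(proteins$genome_id)) {
    w <- which(proteins$genome_id == g)
    lens <- nchar(proteins$sequence[w]) * 3L + 3L
    starts <- cumsum(c(0L, utils::head(lens + 150L, -1L)))
    proteins$start[w] <- starts
    proteins$end[w] <- starts + lens
  }
  rownames(proteins) <- NULL
  structure(list(proteins = proteins, subsystems = subsystems,
                 families = families, novel_families = novel_families,
                 params = list(n_roles = n_roles, n_families = n_families,
                               proteins_per_family = proteins_per_family,
                               n_reference_genomes = n_reference_genomes,
                               protein_length = protein_length,
                               within_family_identity = within_family_identity,
                               n_novel_families = n_novel_families,
                               subsystem_size = subsystem_size,
                               seed = seed)),
            class = "pk_world")
}

#' @export
print.pk_world <- function(x, ...) {
  cat(sprintf("<pk_world> %d roles, %d families (+%d novel), %d genomes, %d proteins, %d subsystems\n",
              x$params$n_roles, x$params$n_families,
              x$params$n_novel_families, x$params$n_reference_genomes,
              nrow(x$proteins), length(x$subsystems)))
  invisible(x)
}

#' Write a world's reference files to a directory
#'
#' Emits exactly the formats the pipeline consumes: `proteins.faa` (protein
#' FASTA), `roles.tsv` (protein id, genome id, role, in_subsystem flag and
#' reference coordinates) and `subsystems.tsv`.
#'
#' @param world A `pk_world`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- world$proteins
  Biostrings::writeXStringSet(
    Biostrings::AAStringSet(stats::setNames(p$sequence, p$id)),
    file.path(dir, "proteins.faa"))
  utils::write.table(
    p[, c("id", "genome_id", "role", "in_subsystem", "contig", "start",
          "end", "strand")],
    file.path(dir, "roles.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  write_subsystems(world$subsystems, file.path(dir, "subsystems.tsv"))
  invisible(dir)
}

#' Read a reference collection from a directory
#'
#' Expects `proteins.faa` and `roles.tsv` as written by [write_world()];
#' `subsystems.tsv` is read when present.
#'
#' @param dir Directory path.
#' @return List with `proteins` (data.frame) and `subsystems` (possibly
#'   `NULL`).
#' @export
read_reference <- function(dir) {
  faa <- Biostrings::readAAStringSet(file.path(dir, "proteins.faa"))
  roles <- utils::read.delim(file.path(dir, "roles.tsv"), sep = "\t",
                             stringsAsFactors = FALSE, quote = "")
  proteins <- data.frame(id = sub("\\s.*$", "", names(faa)),
                         sequence = as.character(faa),
                         stringsAsFactors = FALSE)
  proteins <- merge(proteins, roles, by = "id", sort = TRUE)
  sspath <- file.path(dir, "subsystems.tsv")
  subsystems <- if (file.exists(sspath)) read_subsystems(sspath) else NULL
  list(proteins = proteins, subsystems = subsystems)
}

#' Simulate a genome from a synthetic world, with exact truth
#'
#' Genes are drawn from the world's families (reverse-complemented with
#' probability 0.5), point-mutated at `mutation_rate` per base (start and
#' stop codons are preserved and substitutions creating in-frame stops are
#' redrawn, so every implanted gene stays a single ORF), and separated by
#' random intergenic spacers of geometric length (mean `intergenic_mean`,
#' minimum 1). A fraction `frameshift_rate` of genes receives a single
#' random +/-1 indel in its middle; `novel_gene_fraction` of genes come
#' from families absent from the reference. The returned truth table holds
#' the exact post-injection coordinates of every implanted gene.
#'
#' @param world A `pk_world`.
#' @param n_genes Number of genes to implant (default 200).
#' @param mutation_rate Per-base substitution probability (default 0.005).
#' @param frameshift_rate Per-gene frameshift injection probability.
#' @param novel_gene_fraction Fraction of genes from held-out families.
#' @param intergenic_mean Mean spacer length in bases (default 120).
#' @param seed Integer seed.
#' @param families Optional explicit vector of reference family indices to
#'   implant in order (overrides `n_genes`/`novel_gene_fraction`).
#' @param genome_id,contig_id Identifiers for the emitted genome.
#' @param max_genome_len Guard against implausibly large requests.
#' @return List with `genome` (a `pk_genome`) and `truth` (data.frame:
#'   `gene_id`, `contig`, `start`, `end`, `strand`, `role`, `family`,
#'   `identity`, `frameshift`, `novel`).
#' @export
simulate_genome <- function(world, n_genes = 200L, mutation_rate = 0.005,
                            frameshift_rate = 0, novel_gene_fraction = 0,
                            intergenic_mean = 120L, seed = 1L,
                            families = NULL, genome_id = "synthetic",
                            contig_id = "chr1", max_genome_len = 20e6) {
  set.seed(seed)
  if (is.null(families)) {
    n_novel <- round(n_genes * novel_gene_fraction)
    fam <- c(sample(seq_along(world$families), n_genes - n_novel,
                    replace = TRUE),
             -sample(seq_along(world$novel_families),
                     n_novel, replace = TRUE))
    fam <- sample(fam)  # shuffle novel genes among the rest
  } else fam <- families
  avg <- mean(vapply(world$families, function(f) nchar(f$dna), numeric(1)))
  if (length(fam) * (avg + intergenic_mean) > max_genome_len)
    stop("requested gene count exceeds plausible contig capacity")

  spacer <- function() {
    n <- 1L + stats::rgeom(1L, 1 / max(2, intergenic_mean))
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
  }
  mutate_gene <- function(dna) {
    L <- nchar(dna)
    bases <- strsplit(dna, "", fixed = TRUE)[[1]]
    eligible <- which(stats::runif(L) < mutation_rate)
    eligible <- eligible[eligible > 3L & eligible <= L - 3L]
    for (i in eligible) {
      cod0 <- (i - 1L) %/% 3L
      repeat {
        b <- sample(setdiff(c("A", "C", "G", "T"), bases[i]), 1L)
        codon <- paste(replace(bases[(cod0 * 3L + 1L):(cod0 * 3L + 3L)],
                               i - cod0 * 3L, b), collapse = "")
        if (!codon %in% STOP_CODONS) { bases[i] <- b; break }
      }
    }
    list(dna = paste(bases, collapse = ""), n_mut = length(eligible))
  }
  inject_frameshift <- function(dna) {
    L <- nchar(dna)
    pos <- sample(floor(L * 0.35):ceiling(L * 0.65), 1L)
    if (stats::runif(1) < 0.5) {
      list(dna = paste0(substr(dna, 1, pos - 1L), substr(dna, pos + 1L, L)),
           indel = -1L)
    } else {
      list(dna = paste0(substr(dna, 1, pos),
                        sample(c("A", "C", "G", "T"), 1L),
                        substr(dna, pos + 1L, L)),
           indel = 1L)
    }
  }

  pieces <- character(0)
  cur <- 0L
  truth <- list()
  push <- function(s) {
    pieces[[length(pieces) + 1L]] <<- s
    cur <<- cur + nchar(s)
  }
  push(spacer())
  for (gi in seq_along(fam)) {
    f <- fam[gi]
    fobj <- if (f > 0) world$families[[f]] else world$novel_families[[-f]]
    mg <- mutate_gene(fobj$dna)
    dna <- mg$dna
    shifted <- FALSE
    if (stats::runif(1) < frameshift_rate) {
      dna <- inject_frameshift(dna)$dna
      shifted <- TRUE
    }
    strand <- if (stats::runif(1) < 0.5) "+" else "-"
    placed <- if (strand == "+") dna else revcomp(dna)
    start <- cur
    push(placed)
    truth[[gi]] <- data.frame(
      gene_id = sprintf("g%d", gi), contig = contig_id, start = start,
      end = cur, strand = strand, role = fobj$role, family = f,
      identity = 1 - mg$n_mut / nchar(fobj$dna),
      frameshift = shifted, novel = f < 0, stringsAsFactors = FALSE)
    push(spacer())
  }
  contig <- paste(pieces, collapse = "")
  genome <- pk_genome(stats::setNames(contig, contig_id), id = genome_id,
                      mode = "auto")
  list(genome = genome, truth = do.call(rbind, truth))
}

#' Score predicted features against a simulation truth table
#'
#' A truth gene is recovered when a predicted CDS on the same contig and
#' strand overlaps it reciprocally by at least `min_reciprocal` of both
#' lengths. Function exactness compares the truth role against the
#' predicted function after fusion splitting, over recovered non-novel
#' genes. Frameshift detection recall is the fraction of injected
#' frameshift genes covered by a join proposal (its `shift_offset` falls
#' inside the truth gene).
#'
#' @param truth Truth table from [simulate_genome()].
#' @param features Predicted feature table.
#' @param joins Optional join proposals from [detect_frameshifts()].
#' @param min_reciprocal Reciprocal overlap threshold (default 0.9).
#' @return List of metrics: `gene_recall` (all truth genes),
#'   `gene_recall_intact` (excluding frameshift-injected genes),
#'   `gene_precision`, `function_exactness`, `frameshift_recall` (`NA`
#'   when nothing was injected), plus counts.
#' @export
evaluate_annotation <- function(truth, features, joins = NULL,
                                min_reciprocal = 0.9) {
  cds <- features[features$type == "CDS", , drop = FALSE]
  if (nrow(cds) > 0 && nrow(truth) > 0 &&
      !any(cds$contig %in% truth$contig))
    stop("mismatched contig ids")
  lens_p <- cds$end - cds$start
  matched <- logical(nrow(truth))
  match_idx <- rep(NA_integer_, nrow(truth))
  used <- logical(nrow(cds))
  for (i in seq_len(nrow(truth))) {
    lt <- truth$end[i] - truth$start[i]
    ov <- overlap_bp_vec(truth$contig[i], truth$start[i], truth$end[i],
                         cds$contig, cds$start, cds$end)
    ok <- which(ov >= min_reciprocal * lt & ov >= min_reciprocal * lens_p &
                  cds$strand == truth$strand[i] & !used)
    if (length(ok)) {
      j <- ok[which.max(ov[ok])]
      matched[i] <- TRUE
      match_idx[i] <- j
      used[j] <- TRUE
    }
  }
  intact <- !truth$frameshift
  nonnovel <- matched & !truth$novel
  fn_ok <- vapply(which(nonnovel), function(i) {
    truth$role[i] %in% split_roles(cds$fun[match_idx[i]])[[1]]
  }, logical(1))
  fs <- which(truth$frameshift)
  fs_detected <- if (length(fs) && !is.null(joins) && nrow(joins) > 0) {
    vapply(fs, function(i) {
      any(joins$shift_offset >= truth$start[i] - 50L &
            joins$shift_offset <= truth$end[i] + 50L)
    }, logical(1))
  } else logical(0)
  list(
    gene_recall = if (nrow(truth)) mean(matched) else NA_real_,
    gene_recall_intact = if (any(intact)) mean(matched[intact]) else NA_real_,
    gene_precision = if (nrow(cds)) sum(matched) / nrow(cds) else NA_real_,
    function_exactness = if (length(fn_ok)) mean(fn_ok) else NA_real_,
    frameshift_recall = if (length(fs)) mean(fs_detected) else NA_real_,
    n_truth = nrow(truth), n_predicted = nrow(cds),
    n_matched = sum(matched))
}
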