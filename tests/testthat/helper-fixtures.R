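# Shared fixtures and independent oracles. Everything here is generated in
# code; nothing is read from disk.

AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
                 "P", "Q", "R", "S", "T", "V", "W", "Y")

random_protein <- function(n) {
  paste(sample(AA_ALPHABET, n, replace = TRUE), collapse = "")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Independent affine-gap Smith-Waterman (Gotoh), quadratic DP. Gap of
# length L costs open + extend * L. Returns the optimal local score.
sw_oracle <- function(a, b, open = 11, extend = 1, mat = NULL) {
  if (is.null(mat)) mat <- prokann:::pk_blosum62()
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  M <- matrix(0, n + 1, m + 1)
  Ix <- matrix(-Inf, n + 1, m + 1)
  Iy <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) {
    s <- mat[A[i - 1], B]
    for (j in 2:(m + 1)) {
      Ix[i, j] <- max(M[i - 1, j] - open - extend, Ix[i - 1, j] - extend)
      Iy[i, j] <- max(M[i, j - 1] - open - extend, Iy[i, j - 1] - extend)
      M[i, j] <- max(0, M[i - 1, j - 1] + s[j - 1],
                     Ix[i - 1, j - 1] + s[j - 1],
                     Iy[i - 1, j - 1] + s[j - 1])
    }
    best <- max(best, max(M[i, ]))
  }
  best
}

# Naive all-substrings signature counter: per-role occurrence counts of the
# index's stored k-mers in a translation, by direct window lookup.
naive_kmer_counts <- function(index, translation) {
  n <- nchar(translation)
  k <- index$k
  if (n < k) return(integer(0))
  w <- substring(translation, 1:(n - k + 1L), k:n)
  w <- w[!grepl("[X*]", w)]
  hit <- match(w, index$kmers$kmer)
  hit <- hit[!is.na(hit)]
  if (length(hit) == 0) return(integer(0))
  tab <- table(index$kmers$role_id[hit])
  stats::setNames(as.integer(tab), names(tab))
}

# Independent ORF scanner: tries every position as a start codon and walks
# codon by codon to the next in-frame stop. Returns data.frame of maximal
# ORFs (longest start per stop) on both strands, plus all starts per stop.
orf_oracle <- function(contig, min_len) {
  L <- nchar(contig)
  scan_strand <- function(s, strand) {
    res <- list()
    starts_by_stop <- list()
    for (p in 0:(L - 3)) {
      cod <- substr(s, p + 1, p + 3)
      if (!cod %in% c("ATG", "GTG", "TTG")) next
      # preceding in-frame codon must be a stop or the contig edge region
      q <- p + 3
      repeat {
        if (q + 3 > L) { q <- NA; break }
        cq <- substr(s, q + 1, q + 3)
        if (cq %in% c("TAA", "TAG", "TGA")) break
        q <- q + 3
      }
      if (is.na(q)) next
      # only starts not preceded in-frame by an earlier non-stop run from
      # another start matter for maximality; collect all, reduce later
      key <- as.character(q)
      starts_by_stop[[key]] <- c(starts_by_stop[[key]], p)
    }
    for (key in names(starts_by_stop)) {
      q <- as.integer(key)
      ss <- sort(starts_by_stop[[key]])
      # drop starts separated from the stop by an intervening in-frame stop
      # (cannot happen by construction of the walk) and apply min_len
      ss <- ss[(q + 3 - ss) >= min_len]
      if (length(ss) == 0) next
      rs <- ss[1]; re <- q + 3
      if (strand == "+") {
        res[[length(res) + 1]] <- data.frame(
          start = rs, end = re, strand = strand,
          options = I(list(ss)), stringsAsFactors = FALSE)
      } else {
        res[[length(res) + 1]] <- data.frame(
          start = L - re, end = L - rs, strand = strand,
          options = I(list(L - ss)), stringsAsFactors = FALSE)
      }
    }
    if (length(res) == 0) return(NULL)
    do.call(rbind, res)
  }
  out <- rbind(scan_strand(contig, "+"),
               scan_strand(prokann::revcomp(contig), "-"))
  if (is.null(out)) return(out)
  out[order(out$start, out$strand), , drop = FALSE]
}

# A small deterministic world for pipeline-level tests.
mini_world <- function(seed = 11L) {
  generate_world(n_roles = 12L, n_families = 12L, proteins_per_family = 4L,
                 n_reference_genomes = 4L, protein_length = c(80L, 160L),
                 seed = seed)
}

# Hand-crafted frameshift fixture: a template gene split into two fragment
# ORFs separated by `spacer_nt` extra bases (so the inferred indel is
# controlled), plus the intact template protein as the neighbor reference.
# Returns list(features, template, contig, gene_start).
fs_fixture <- function(seed = 5L, n1 = 100L, n2 = 100L, spacer_nt = 1L,
                       gap_extra = 0L) {
  set.seed(seed)
  codons1 <- sample(prokann:::NONSTOP_CODONS, n1 - 1L, replace = TRUE)
  codons2 <- sample(prokann:::NONSTOP_CODONS, n2, replace = TRUE)
  h1 <- paste(c("ATG", codons1), collapse = "")
  h2 <- paste(c("ATG", codons2), collapse = "")
  template <- paste0(translate_dna(h1), translate_dna(paste0(h2, "TAA")))
  lead <- random_dna(60L)
  mid <- if (spacer_nt > 0) random_dna(spacer_nt) else ""
  gap_fill <- if (gap_extra > 0) random_dna(gap_extra) else ""
  contig <- paste0(lead, h1, "TAA", mid, gap_fill, h2, "TAA",
                   random_dna(60L))
  s1 <- nchar(lead)
  e1 <- s1 + nchar(h1) + 3L
  s2 <- e1 + spacer_nt + gap_extra
  e2 <- s2 + nchar(h2) + 3L
  g <- pk_genome(stats::setNames(contig, "ctg"), id = "fsfix")
  feats <- make_features(
    id = c("fragA", "fragB"), contig = "ctg", start = c(s1, s2),
    end = c(e1, e2), strand = "+", status = "retained",
    translation = c(translate_region(g, "ctg", s1, e1, "+"),
                    translate_region(g, "ctg", s2, e2, "+")))
  list(features = feats, template = template, genome = g,
       bounds = c(s1, e1, s2, e2))
}

neighbor_df <- function(ids, sequences, roles = "") {
  data.frame(id = ids, sequence = sequences,
             role = rep_len(roles, length(ids)), stringsAsFactors = FALSE)
}
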