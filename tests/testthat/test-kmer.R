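toy_reference <- function() {
  # three roles; role A has a shared conserved core in two genomes, role B
  # is a single protein, role C shares one k-mer with A to exercise
  # dominance accounting
  data.frame(
    id = c("a1", "a2", "a3", "b1", "c1"),
    genome_id = c("G1", "G2", "G1", "G1", "G2"),
    sequence = c("MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ",
                 "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ",
                 "MKTAYIAKQRQISFVKSHFSRQWWWWWWWWWW",
                 "MDDDDDDDDDDDDDDDDDDDD",
                 "MPPPPPPPPPPPPPPPPPPPP"),
    role = c("Role A", "Role A", "Role A", "Role B", "Role C"),
    stringsAsFactors = FALSE)
}

test_that("k-mer windows are enumerated in order and X windows skipped", {
  expect_equal(extract_kmers("MKTAYIAKQR", 8),
               c("MKTAYIAK", "KTAYIAKQ", "TAYIAKQR"))
  expect_equal(extract_kmers("MKTAYIAK", 8), "MKTAYIAK")
  expect_equal(extract_kmers("MKTAYI", 8), character(0))
  expect_equal(extract_kmers("MKTXYIAKQR", 8), character(0))
  expect_error(extract_kmers("MKTAYIAK", 0))
  # brute-force window check on a random protein with X sprinkled in
  set.seed(4)
  p <- random_protein(60)
  substr(p, 20, 20) <- "X"
  w <- extract_kmers(p, 8)
  for (km in w) expect_true(grepl(km, p, fixed = TRUE))
  expect_false(any(grepl("X", w)))
})

test_that("index stores only dominant, sufficiently frequent k-mers", {
  ref <- toy_reference()
  idx <- build_kmer_index(ref, k = 8, dominance_threshold = 0.9,
                          min_occurrences = 2)
  # counting oracle over the toy collection
  role_of <- stats::setNames(ref$role, ref$id)
  occ <- list()
  for (i in seq_len(nrow(ref))) {
    for (km in extract_kmers(ref$sequence[i], 8)) {
      occ[[km]] <- c(occ[[km]], ref$role[i])
    }
  }
  for (km in names(occ)) {
    tab <- sort(table(occ[[km]]), decreasing = TRUE)
    expected_stored <- sum(tab) >= 2 &&
      tab[1] / sum(tab) >= 0.9 &&
      (length(tab) == 1 || tab[1] > tab[2])
    stored <- km %in% idx$kmers$kmer
    expect_identical(stored, expected_stored)
    if (stored) {
      role_id <- idx$kmers$role_id[match(km, idx$kmers$kmer)]
      expect_equal(idx$roles$text[match(role_id, idx$roles$id)],
                   names(tab)[1])
    }
  }
  # a k-mer occurring once only is never stored at min_occurrences = 2
  singleton <- names(occ)[lengths(occ) == 1]
  expect_false(any(singleton %in% idx$kmers$kmer))
  expect_error(build_kmer_index(ref[0, ]), "empty reference")
})

test_that("ties for the majority role discard the k-mer", {
  ref <- data.frame(
    id = c("x1", "x2", "y1", "y2"), genome_id = c("G1", "G1", "G2", "G2"),
    sequence = rep("MSHAREDKMER", 4),
    role = c("Role X", "Role X", "Role Y", "Role Y"),
    stringsAsFactors = FALSE)
  idx <- build_kmer_index(ref, k = 8)
  expect_equal(nrow(idx$kmers), 0L)
})

test_that("index construction is order-independent", {
  ref <- toy_reference()
  set.seed(8)
  idx1 <- build_kmer_index(ref)
  idx2 <- build_kmer_index(ref[sample(nrow(ref)), ])
  expect_equal(idx1$roles, idx2$roles)
  expect_equal(as.data.frame(idx1$kmers), as.data.frame(idx2$kmers))
})

test_that("scan matches a naive all-substrings counter on random proteins", {
  w <- mini_world(seed = 3)
  idx <- build_kmer_index(w$proteins)
  set.seed(17)
  for (i in 1:40) {
    p <- if (i %% 2 == 0) random_protein(sample(30:1000, 1))
         else {
           # half the cases: real family material so hits are plentiful
           base <- w$proteins$sequence[sample(nrow(w$proteins), 1)]
           paste0(base, random_protein(20))
         }
    sc <- scan_kmers(idx, p, "q")
    oracle <- naive_kmer_counts(idx, p)
    if (length(oracle) == 0) {
      expect_length(sc$counts, 0)
    } else {
      expect_equal(sc$counts[order(names(sc$counts))],
                   oracle[order(names(oracle))])
    }
  }
  # empty / hit-free translation
  sc0 <- scan_kmers(idx, "MWWWWWWWAAA", "none")
  expect_equal(length(sc0$counts), 0L)
  expect_true(is.na(sc0$best_role))
})

test_that("a reference protein scans back to its own role", {
  w <- mini_world(seed = 3)
  idx <- build_kmer_index(w$proteins)
  p <- w$proteins[7, ]
  sc <- scan_kmers(idx, p$sequence, p$id)
  expect_true(sc$promoted)
  expect_equal(idx$roles$text[match(sc$best_role, idx$roles$id)], p$role)
})

test_that("promotion needs min_hits and a margin over the runner-up", {
  expect_true(promote_candidate(c(`0` = 5L))$promoted)
  expect_equal(promote_candidate(c(`0` = 5L))$role, 0L)
  expect_false(promote_candidate(c(`0` = 3L, `1` = 2L))$promoted)
  expect_true(promote_candidate(c(`0` = 4L, `1` = 2L))$promoted)
  expect_false(promote_candidate(c(`0` = 2L))$promoted)
  expect_false(promote_candidate(integer(0))$promoted)
  # monotonicity: adding hits for the top role never un-promotes
  set.seed(12)
  for (i in 1:30) {
    counts <- stats::setNames(sample(0:8, 3, TRUE), c("0", "1", "2"))
    pr <- promote_candidate(counts)
    if (pr$promoted) {
      counts[as.character(pr$role)] <- counts[as.character(pr$role)] + 5L
      pr2 <- promote_candidate(counts)
      expect_true(pr2$promoted)
      expect_equal(pr2$role, pr$role)
    }
  }
})

test_that("fusion candidates with two roles in disjoint halves get joined functions", {
  w <- mini_world(seed = 3)
  idx <- build_kmer_index(w$proteins)
  p1 <- w$proteins$sequence[1]
  p2 <- w$proteins$sequence[match(unique(w$proteins$role)[5],
                                  w$proteins$role)]
  fusion <- paste0(p1, p2)
  dt <- prokann:::scan_kmers_batch(idx, c(fus = fusion))
  asg <- prokann:::assign_function_from_scan(dt, idx)
  expect_true(asg$promoted)
  expect_true(grepl(" / ", asg$fun, fixed = TRUE))
  parts <- split_roles(asg$fun)[[1]]
  expect_length(parts, 2)
  expect_true(w$proteins$role[1] %in% parts)
})

test_that("index round-trips through gzipped TSV entry for entry", {
  w <- mini_world(seed = 3)
  idx <- build_kmer_index(w$proteins)
  path <- file.path(withr::local_tempdir(), "index.tsv.gz")
  write_kmer_index(idx, path)
  idx2 <- read_kmer_index(path)
  expect_equal(idx2$k, idx$k)
  expect_equal(idx2$dominance_threshold, idx$dominance_threshold)
  expect_equal(idx2$min_occurrences, idx$min_occurrences)
  expect_equal(idx2$roles, idx$roles)
  expect_equal(as.data.frame(idx2$kmers), as.data.frame(idx$kmers))
})
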