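test_that("ORF enumeration handles the single-gene contig and the length floor", {
  g <- pk_genome(c(c1 = "ATGAAATAA"))
  orfs <- enumerate_orfs(g, min_len = 9)
  expect_equal(nrow(orfs), 1L)
  expect_equal(orfs$start, 0L)
  expect_equal(orfs$end, 9L)
  expect_equal(orfs$strand, "+")
  expect_equal(orfs$translation, "MK")
  expect_equal(nrow(enumerate_orfs(g, min_len = 90)), 0L)
})

test_that("ORF enumeration equals an independent positional scanner on random sequence", {
  set.seed(23)
  for (rep in 1:3) {
    contig <- random_dna(10000)
    g <- pk_genome(c(chr = contig))
    orfs <- enumerate_orfs(g, min_len = 90)
    oracle <- orf_oracle(contig, min_len = 90)
    key <- function(df) paste(df$start, df$end, df$strand)
    expect_setequal(key(orfs), key(oracle))
    m <- match(key(orfs), key(oracle))
    for (i in seq_len(nrow(orfs))) {
      expect_setequal(orfs$start_options[[i]], oracle$options[[m[i]]])
    }
  }
})

test_that("ORF regions are start-to-stop and translations match their regions", {
  set.seed(61)
  g <- pk_genome(c(chr = random_dna(6000)))
  orfs <- enumerate_orfs(g, min_len = 90)
  for (i in seq_len(nrow(orfs))) {
    dna <- prokann::region_dna(g, orfs$contig[i], orfs$start[i],
                               orfs$end[i], orfs$strand[i])
    expect_true(substr(dna, 1, 3) %in% c("ATG", "GTG", "TTG"))
    expect_true(substr(dna, nchar(dna) - 2, nchar(dna)) %in%
                  c("TAA", "TAG", "TGA"))
    expect_false(grepl("*", orfs$translation[i], fixed = TRUE))
  }
})

test_that("training recovers deterministic codon statistics in closed form", {
  m <- train_coding_model(strrep("ATG", 60), character(0), order = 2,
                          pseudocount = 1e-9)
  # after context TG the next base (codon position 0) is always A
  expect_equal(model_prob(m, "TG", "A", pos = 0), 1, tolerance = 1e-6)
  expect_equal(model_prob(m, "TG", "C", pos = 0), 0, tolerance = 1e-6)
  # unseen context backs off to uniform
  expect_equal(model_prob(m, "CC", "A", pos = 1), 0.25, tolerance = 1e-6)
  expect_error(train_coding_model(character(0)), "insufficient")
  expect_error(train_coding_model("ATGGCA", character(0), order = 4),
               "insufficient")
})

test_that("identical phase-symmetric coding and noncoding training gives zero log-odds", {
  seqs <- c(strrep("A", 60), strrep("C", 60), strrep("G", 60),
            strrep("T", 60))
  m <- train_coding_model(seqs, seqs, order = 2, pseudocount = 1e-9)
  for (ctx in c("AA", "CC", "GT", "TT")) {
    for (b in c("A", "C", "G", "T")) {
      for (p in 0:2) {
        expect_equal(model_prob(m, ctx, b, pos = p),
                     model_prob(m, ctx, b, pos = NULL), tolerance = 1e-5)
      }
    }
  }
})

test_that("training is invariant to permutation of the training list", {
  set.seed(41)
  coding <- replicate(8, paste(sample(prokann:::NONSTOP_CODONS, 50, TRUE),
                               collapse = ""))
  nc <- replicate(4, random_dna(150))
  m1 <- train_coding_model(coding, nc, order = 3)
  m2 <- train_coding_model(rev(coding), sample(nc), order = 3)
  expect_equal(as.data.frame(m1$coding), as.data.frame(m2$coding))
  expect_equal(as.data.frame(m1$background), as.data.frame(m2$background))
})

test_that("smoothed conditional probabilities sum to one over the four bases", {
  set.seed(43)
  m <- train_coding_model(replicate(5, random_dna(300)),
                          replicate(3, random_dna(200)), order = 2)
  for (ctx in c("AC", "GG", "TA", "ZZ")) {
    for (p in 0:2) {
      tot <- sum(vapply(c("A", "C", "G", "T"),
                        function(b) model_prob(m, ctx, b, pos = p), 0))
      expect_equal(tot, 1, tolerance = 1e-9)
    }
  }
})

test_that("scores are additive over concatenated in-frame blocks", {
  set.seed(47)
  coding <- replicate(10, paste(sample(prokann:::NONSTOP_CODONS, 80, TRUE),
                                collapse = ""))
  m <- train_coding_model(coding, replicate(5, random_dna(200)), order = 4)
  contig <- random_dna(3000)
  g <- pk_genome(c(chr = contig))
  for (rep in 1:10) {
    s <- sample(seq(12, 2000, by = 3), 1)
    mdl <- s + sample(seq(90, 300, by = 3), 1)
    e <- mdl + sample(seq(90, 300, by = 3), 1)
    orf <- function(a, b) make_features("x", "chr", a, b, "+")
    sc <- function(a, b) score_orfs(m, g, orf(a, b))
    expect_equal(sc(s, e), sc(s, mdl) + sc(mdl, e), tolerance = 1e-9)
  }
})

test_that("minus-strand scores equal plus-strand scores on the reverse complement", {
  set.seed(53)
  coding <- replicate(8, paste(sample(prokann:::NONSTOP_CODONS, 70, TRUE),
                               collapse = ""))
  m <- train_coding_model(coding, replicate(4, random_dna(150)), order = 3)
  contig <- random_dna(1200)
  g1 <- pk_genome(c(chr = contig))
  g2 <- pk_genome(c(chr = revcomp(contig)))
  L <- nchar(contig)
  for (rep in 1:8) {
    s <- sample(seq(30, 900, by = 3), 1)
    e <- s + sample(seq(90, 240, by = 3), 1)
    sc1 <- score_orfs(m, g1, make_features("x", "chr", s, e, "-"))
    sc2 <- score_orfs(m, g2, make_features("x", "chr", L - e, L - s, "+"))
    expect_equal(sc1, sc2, tolerance = 1e-9)
  }
})

test_that("ORFs drawn from the coding distribution score positive in expectation", {
  set.seed(59)
  gene <- function() paste(c("ATG", sample(prokann:::NONSTOP_CODONS, 60,
                                           replace = TRUE,
                                           prob = rep(c(3, 1), c(20, 41))),
                            "TAA"), collapse = "")
  m <- train_coding_model(replicate(60, gene()),
                          replicate(30, random_dna(200)), order = 4)
  scores <- numeric(200)
  for (i in seq_len(200)) {
    dna <- gene()
    contig <- paste0(random_dna(30), dna, random_dna(30))
    g <- pk_genome(c(chr = contig))
    scores[i] <- score_orfs(m, g, make_features("x", "chr", 30,
                                                30 + nchar(dna), "+"))
  }
  expect_gt(mean(scores), 0)
  expect_gt(mean(scores > 0), 0.75)
})

test_that("iterative calling converges and the promoted set is monotone", {
  w <- mini_world(seed = 11)
  idx <- build_kmer_index(w$proteins)
  sim <- simulate_genome(w, n_genes = 25, mutation_rate = 0.005, seed = 19)
  res <- call_genes_iterative(sim$genome, idx)
  expect_lte(res$iterations, 3)
  expect_gte(nrow(res$features), 20)
  hist <- res$promoted_history
  if (length(hist) > 1) {
    for (i in 2:length(hist)) {
      expect_true(all(hist[[i - 1]] %in% hist[[i]]))
    }
  }
  # no retained pair violates the overlap rule
  ff <- res$features
  cfg <- pk_config()
  for (i in seq_len(nrow(ff) - 1)) {
    for (j in (i + 1):nrow(ff)) {
      ov <- overlap_bp(ff$contig[i], ff$start[i], ff$end[i],
                       ff$contig[j], ff$start[j], ff$end[j])
      expect_false(significant_overlap(ov, ff$end[i] - ff$start[i],
                                       ff$end[j] - ff$start[j], cfg))
    }
  }
})

test_that("a genome without k-mer evidence exits after one empty iteration", {
  w <- mini_world(seed = 11)
  idx <- build_kmer_index(w$proteins)
  set.seed(71)
  g <- pk_genome(c(chr = random_dna(8000)))
  res <- call_genes_iterative(g, idx)
  expect_equal(res$iterations, 1L)
  expect_equal(nrow(res$features), 0L)
})

test_that("single-pass phage calling accepts candidates without evidence", {
  w <- mini_world(seed = 11)
  idx <- build_kmer_index(w$proteins)
  sim <- simulate_genome(w, n_genes = 30, mutation_rate = 0.005, seed = 29)
  expect_equal(sim$genome$mode, "phage_plasmid")
  res <- call_genes_single_pass(sim$genome, idx)
  # every retained candidate equals the arbitration of the full candidate set
  keep <- prokann:::arbitrate_overlaps(res$candidates,
                                       config = pk_config(),
                                       order_by = "kmer_hits")
  expect_equal(sort(res$features$id), sort(res$candidates$id[keep]))
  expect_gt(sum(res$features$kmer_hits == 0), 0)  # evidence-free retained
  # prokaryote-mode genome is rejected
  gp <- sim$genome
  gp$mode <- "prokaryote"
  expect_error(call_genes_single_pass(gp, idx), "wrong mode")
  # the iterative caller on the same sequence retains only promoted ones
  it <- call_genes_iterative(sim$genome, idx)
  expect_true(all(it$features$kmer_hits > 0))
  expect_true(all(prokann::is_supported(it$features)))
})
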