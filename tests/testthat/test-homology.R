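test_that("local alignment matches an independent Gotoh DP oracle", {
  a <- align_proteins("HEAGAWGHEE", "PAWHEAE")
  expect_equal(a$score, sw_oracle("HEAGAWGHEE", "PAWHEAE"))
  expect_error(align_proteins("", "PAW"), "empty sequence")
  set.seed(101)
  for (i in 1:20) {
    p <- random_protein(sample(15:120, 1))
    q <- random_protein(sample(15:120, 1))
    expect_equal(align_proteins(p, q)$score, sw_oracle(p, q))
    expect_equal(align_proteins(p, q)$score, align_proteins(q, p)$score)
  }
})

test_that("self-alignment has identity one and the maximal score", {
  set.seed(103)
  for (i in 1:10) {
    p <- random_protein(sample(20:100, 1))
    a <- align_proteins(p, p)
    expect_equal(a$identity, 1.0)
    expect_equal(a$query_coverage, 1.0)
    expect_equal(a$score, prokann:::self_score(p))
    q <- random_protein(50)
    expect_lte(align_proteins(p, q)$score, a$score)
  }
})

test_that("best-hit classes match a brute-force all-vs-all oracle", {
  set.seed(107)
  base <- replicate(3, random_protein(60))
  mut <- function(p, k) {
    aa <- strsplit(p, "")[[1]]
    idx <- sample(length(aa), k)
    for (i in idx) aa[i] <- sample(setdiff(AA_ALPHABET, aa[i]), 1)
    paste(aa, collapse = "")
  }
  # a1<->b1 reciprocal; a2 hits b1 one-way; a3 and b2 unrelated
  a_prot <- c(a1 = base[1], a2 = mut(base[1], 25), a3 = random_protein(55))
  b_prot <- c(b1 = mut(base[1], 3), b2 = random_protein(58))
  cfg <- pk_config()
  bh <- best_hits(a_prot, b_prot, config = cfg)

  # brute-force oracle with the independent DP
  ids_a <- names(a_prot); ids_b <- names(b_prot)
  S <- matrix(0, length(ids_a), length(ids_b),
              dimnames = list(ids_a, ids_b))
  oracle_hit_ok <- function(p, q, cov_len) {
    al <- align_proteins(p, q)
    al$score >= cfg$min_score && al$identity >= cfg$min_identity
  }
  qual_a <- matrix(FALSE, length(ids_a), length(ids_b),
                   dimnames = dimnames(S))
  qual_b <- qual_a
  for (i in ids_a) for (j in ids_b) {
    al <- align_proteins(a_prot[[i]], b_prot[[j]])
    S[i, j] <- sw_oracle(a_prot[[i]], b_prot[[j]])
    ok <- al$score >= cfg$min_score & al$identity >= cfg$min_identity
    qual_a[i, j] <- ok && al$query_coverage >= cfg$min_coverage
    qual_b[i, j] <- ok && al$subject_coverage >= cfg$min_coverage
  }
  best_a <- sapply(ids_a, function(i) {
    cand <- ids_b[qual_a[i, ]]
    if (!length(cand)) return(NA_character_)
    cand[order(-S[i, cand], cand)][1]
  })
  best_b <- sapply(ids_b, function(j) {
    cand <- ids_a[qual_b[, j]]
    if (!length(cand)) return(NA_character_)
    cand[order(-S[cand, j], cand)][1]
  })
  oracle_class_a <- sapply(ids_a, function(i) {
    if (is.na(best_a[i])) "unique"
    else if (!is.na(best_b[best_a[i]]) && best_b[best_a[i]] == i)
      "bidirectional" else "unidirectional"
  })
  got <- bh$classes[bh$classes$genome == "a", ]
  expect_equal(stats::setNames(got$class, got$gene_id), oracle_class_a)
  expect_equal(nrow(bh$pairs), sum(oracle_class_a == "bidirectional"))
  expect_setequal(unique(bh$classes$class),
                  c("bidirectional", "unidirectional", "unique"))
})

test_that("identical proteomes are all bidirectional; empty subjects are unique", {
  set.seed(109)
  prot <- stats::setNames(replicate(5, random_protein(70)),
                          paste0("pA", 1:5))
  prot_b <- stats::setNames(unname(prot), paste0("pB", 1:5))
  bh <- best_hits(prot, prot_b)
  expect_equal(nrow(bh$pairs), 5L)
  expect_true(all(bh$classes$class == "bidirectional"))
  bh2 <- best_hits(stats::setNames(prot[1], "solo"),
                   stats::setNames(character(0), character(0)))
  expect_equal(bh2$classes$class, "unique")
  expect_equal(nrow(bh2$pairs), 0L)
})

test_that("neighbor estimation ranks the source genome first", {
  w <- mini_world(seed = 13)
  cand <- stats::setNames(
    w$proteins$sequence[w$proteins$genome_id == "G2"],
    paste0("q", seq_len(sum(w$proteins$genome_id == "G2"))))
  nb <- find_neighbors(cand, w$proteins)
  expect_equal(nb$genome_id[1], "G2")
  expect_lte(nrow(nb), pk_config()$n_neighbors)
  # permutation invariance over reference row order
  set.seed(113)
  nb2 <- find_neighbors(cand, w$proteins[sample(nrow(w$proteins)), ])
  expect_equal(nb, nb2)
  # empty reference
  expect_equal(nrow(find_neighbors(cand, w$proteins[0, ])), 0L)
})

test_that("neighbor rescue honors thresholds and the overlap rule", {
  w <- mini_world(seed = 13)
  p <- w$proteins$sequence[1]
  gene <- w$families[[w$proteins$family[1]]]$dna
  contig <- paste0(random_dna(100), gene, random_dna(100))
  g <- pk_genome(c(chr = contig), id = "t")
  cands <- make_features(id = "cand1", contig = "chr", start = 100,
                         end = 100 + nchar(gene), strand = "+",
                         translation = translate_region(
                           g, "chr", 100, 100 + nchar(gene), "+"))
  np <- neighbor_df("n1", p, "some role")
  acc <- rescue_by_neighbor_blast(cands, np, empty_features())
  expect_equal(acc$id, "cand1")
  expect_equal(acc$origin, "neighbor_rescue")
  expect_true(is_supported(acc))
  # same candidate overlapping a retained gene by ~95% is rejected
  retained <- make_features(id = "kept", contig = "chr", start = 90,
                            end = 100 + nchar(gene), strand = "+",
                            status = "retained")
  expect_equal(nrow(rescue_by_neighbor_blast(cands, np, retained)), 0L)
  # no neighbors -> no acceptances
  expect_equal(nrow(rescue_by_neighbor_blast(cands, np[0, ],
                                             empty_features())), 0L)
})

test_that("remaining candidates are accepted only without significant overlap", {
  cands <- make_features(id = c("free", "embedded"), contig = "chr",
                         start = c(1000, 210), end = c(1300, 330),
                         strand = "+",
                         translation = c(strrep("K", 99), strrep("K", 39)))
  retained <- make_features(id = "big", contig = "chr", start = 200,
                            end = 800, strand = "+", status = "retained")
  acc <- accept_remaining(cands, retained)
  expect_equal(acc$id, "free")
  expect_equal(acc$fun, "")
  expect_false(is_supported(acc))
  # zero leftovers is the identity
  expect_equal(nrow(accept_remaining(cands[0, ], retained)), 0L)
})

test_that("backfilling only examines stretches strictly longer than 1500 bp", {
  w <- mini_world(seed = 13)
  fam <- w$families[[3]]
  gene <- fam$dna
  member <- w$proteins[w$proteins$family == 3, ][1, ]
  np <- neighbor_df(member$id, member$sequence, member$role)
  mk <- function(gap_dna) {
    contig <- paste0("ATG", strrep("GCA", 40), "TAA", gap_dna,
                     "ATG", strrep("GCA", 40), "TAA")
    g <- pk_genome(c(chr = contig), id = "bf")
    flank_len <- 3 + 120 + 3
    ff <- make_features(id = c("L", "R"), contig = "chr",
                        start = c(0, flank_len + nchar(gap_dna)),
                        end = c(flank_len,
                                2 * flank_len + nchar(gap_dna)),
                        strand = "+", status = "retained")
    list(genome = g, features = ff)
  }
  set.seed(127)
  # exactly 1500 bp of gap: not examined
  gap1500 <- paste0(random_dna(750 - nchar(gene) %/% 2), gene,
                    random_dna(1500 - 750 - (nchar(gene) - nchar(gene) %/% 2)))
  expect_equal(nchar(gap1500), 1500L)
  f1 <- mk(gap1500)
  expect_equal(nrow(backfill_gaps(f1$genome, f1$features, np)), 0L)
  # 2000 bp stretch containing the gene: one backfill candidate covering it
  lead <- random_dna(300)
  gap2000 <- paste0(lead, gene, random_dna(2000 - 300 - nchar(gene)))
  f2 <- mk(gap2000)
  bf <- backfill_gaps(f2$genome, f2$features, np)
  expect_equal(nrow(bf), 1L)
  expect_equal(bf$origin, "backfill")
  expect_equal(bf$fun, member$role)
  gene_start <- 126 + 300
  ov <- overlap_bp("chr", bf$start, bf$end, "chr", gene_start,
                   gene_start + nchar(gene))
  expect_gt(ov / nchar(gene), 0.9)
  # random 2000 bp stretch: nothing
  f3 <- mk(random_dna(2000))
  expect_equal(nrow(backfill_gaps(f3$genome, f3$features, np)), 0L)
})

test_that("similarity-based assignment fills only unannotated functions", {
  w <- mini_world(seed = 13)
  m <- w$proteins[1, ]
  ff <- make_features(id = c("u1", "kdone"), contig = "chr",
                      start = c(0, 1000), end = c(900, 1900), strand = "+",
                      status = "retained",
                      fun = c("", "Existing role"),
                      evidence = c("none", "kmer"),
                      translation = c(m$sequence, m$sequence))
  np <- neighbor_df(m$id, m$sequence, m$role)
  out <- assign_by_blast(ff, np)
  expect_equal(out$fun[1], m$role)
  expect_true(is_supported(out[1, ]))
  expect_equal(out$fun[2], "Existing role")  # untouched
  # below-threshold best hit leaves the function empty
  ff$translation[1] <- random_protein(60)
  out2 <- assign_by_blast(ff, np)
  expect_equal(out2$fun[1], "")
})
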