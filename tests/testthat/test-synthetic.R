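test_that("world generation is bit-deterministic and validates parameters", {
  w1 <- generate_world(n_roles = 8, n_families = 8, proteins_per_family = 3,
                       n_reference_genomes = 3, seed = 42)
  w2 <- generate_world(n_roles = 8, n_families = 8, proteins_per_family = 3,
                       n_reference_genomes = 3, seed = 42)
  expect_identical(w1$proteins, w2$proteins)
  expect_identical(w1$subsystems, w2$subsystems)
  expect_identical(vapply(w1$families, `[[`, "", "dna"),
                   vapply(w2$families, `[[`, "", "dna"))
  expect_error(generate_world(n_roles = 10, n_families = 5),
               "inconsistent params")
  # a one-role world is valid input for the k-mer index
  w3 <- generate_world(n_roles = 1, n_families = 1, seed = 3)
  idx <- build_kmer_index(w3$proteins)
  expect_gt(nrow(idx$kmers), 0)
})

test_that("within-family identity tracks the requested target", {
  w <- generate_world(n_roles = 10, proteins_per_family = 4,
                      within_family_identity = 0.9, seed = 7)
  pid <- c()
  for (f in unique(w$proteins$family)) {
    mem <- w$proteins$sequence[w$proteins$family == f]
    for (i in seq_along(mem)) for (j in seq_len(i - 1)) {
      a <- strsplit(mem[i], "")[[1]]; b <- strsplit(mem[j], "")[[1]]
      pid <- c(pid, mean(a == b))
    }
  }
  expect_lt(abs(mean(pid) - 0.9), 0.03)
})

test_that("simulated genomes have exact truth coordinates and determinism", {
  w <- mini_world(seed = 19)
  s1 <- simulate_genome(w, n_genes = 20, mutation_rate = 0.01, seed = 5)
  s2 <- simulate_genome(w, n_genes = 20, mutation_rate = 0.01, seed = 5)
  expect_identical(s1$genome$contigs, s2$genome$contigs)
  expect_identical(s1$truth, s2$truth)
  # every truth gene is a translatable ORF at its stated coordinates
  for (i in seq_len(nrow(s1$truth))) {
    tr <- s1$truth[i, ]
    if (tr$frameshift) next
    dna <- region_dna(s1$genome, tr$contig, tr$start, tr$end, tr$strand)
    expect_true(substr(dna, 1, 3) %in% c("ATG", "GTG", "TTG"))
    expect_true(substr(dna, nchar(dna) - 2, nchar(dna)) %in%
                  c("TAA", "TAG", "TGA"))
    expect_false(grepl("\\*", translate_dna(dna)))
  }
  expect_error(simulate_genome(w, n_genes = 1e6), "capacity")
})

test_that("frameshift injection flags truth rows and shifts gene length by one", {
  w <- mini_world(seed = 19)
  s <- simulate_genome(w, n_genes = 30, mutation_rate = 0, seed = 9,
                       frameshift_rate = 1)
  expect_true(all(s$truth$frameshift))
  for (i in seq_len(nrow(s$truth))) {
    fam <- s$truth$family[i]
    expected <- nchar(w$families[[fam]]$dna)
    expect_equal(abs((s$truth$end[i] - s$truth$start[i]) - expected), 1)
  }
  s0 <- simulate_genome(w, n_genes = 30, mutation_rate = 0, seed = 9,
                        frameshift_rate = 0)
  expect_false(any(s0$truth$frameshift))
})

test_that("novel genes come from families absent from the reference", {
  w <- mini_world(seed = 19)
  s <- simulate_genome(w, n_genes = 30, novel_gene_fraction = 0.2, seed = 13)
  expect_equal(sum(s$truth$novel), 6)
  expect_true(all(s$truth$family[s$truth$novel] < 0))
  expect_false(any(s$truth$role[s$truth$novel] %in% w$proteins$role))
})

test_that("the generated genome round-trips through FASTA bit-exactly", {
  w <- mini_world(seed = 19)
  s <- simulate_genome(w, n_genes = 10, seed = 21)
  path <- file.path(withr::local_tempdir(), "g.fna")
  write_genome_fasta(s$genome, path)
  back <- read_genome_fasta(path)
  expect_identical(back$contigs, s$genome$contigs)
})

test_that("evaluation scores perfect and half predictions exactly", {
  w <- mini_world(seed = 19)
  s <- simulate_genome(w, n_genes = 20, mutation_rate = 0, seed = 25)
  truth <- s$truth
  perfect <- make_features(id = truth$gene_id, contig = truth$contig,
                           start = truth$start, end = truth$end,
                           strand = truth$strand, status = "retained",
                           fun = truth$role)
  ev <- evaluate_annotation(truth, perfect)
  expect_equal(ev$gene_recall, 1)
  expect_equal(ev$gene_precision, 1)
  expect_equal(ev$function_exactness, 1)
  half <- perfect[seq_len(10), ]
  ev2 <- evaluate_annotation(truth, half)
  expect_equal(ev2$gene_recall, 0.5)
  expect_equal(ev2$gene_precision, 1)
  # fusion functions are split before comparison
  fused <- perfect
  fused$fun <- paste(truth$role, "Another role", sep = " / ")
  expect_equal(evaluate_annotation(truth, fused)$function_exactness, 1)
  # mismatched contigs are an error
  wrong <- perfect
  wrong$contig <- "other"
  expect_error(evaluate_annotation(truth, wrong), "mismatched contig")
})

test_that("a mutation-free, fully-referenced simulation annotates with recall 1", {
  w <- mini_world(seed = 19)
  s <- simulate_genome(w, n_genes = 25, mutation_rate = 0,
                       novel_gene_fraction = 0, seed = 31)
  res <- annotate(s$genome, list(proteins = w$proteins,
                                 subsystems = w$subsystems), seed = 1)
  ev <- evaluate_annotation(s$truth, res$features)
  expect_equal(ev$gene_recall, 1)
  expect_equal(ev$function_exactness, 1)
})

test_that("rescue recovers a gene deleted between two conserved subsystem genes", {
  w <- mini_world(seed = 19)
  # implant families 1,2,3 in order; reference genome G1 carries them in the
  # same order with subsystem membership
  s <- simulate_genome(w, families = c(1, 2, 3), mutation_rate = 0,
                       seed = 35, intergenic_mean = 60)
  tr <- s$truth
  g <- s$genome
  ref <- w$proteins
  # features: the flanking genes only (middle gene "deleted" from the calls)
  flank <- tr[c(1, 3), ]
  ff <- make_features(id = c("q1", "q3"), contig = flank$contig,
                      start = flank$start, end = flank$end,
                      strand = flank$strand, status = "retained",
                      fun = flank$role,
                      translation = vapply(seq_len(2), function(i)
                        translate_region(g, flank$contig[i], flank$start[i],
                                         flank$end[i], flank$strand[i]),
                        ""))
  r1 <- ref$id[ref$genome_id == "G1" & ref$family == 1]
  r2 <- ref$id[ref$genome_id == "G1" & ref$family == 2]
  r3 <- ref$id[ref$genome_id == "G1" & ref$family == 3]
  ref$in_subsystem[ref$id %in% c(r1, r2, r3)] <- TRUE
  bbh <- list(G1 = data.frame(gene_a = c("q1", "q3"),
                              gene_b = c(r1, r3), stringsAsFactors = FALSE))
  found <- rescue_missed(g, ff, ref, "G1", bbh)
  expect_equal(nrow(found), 1L)
  expect_equal(found$fun, tr$role[2])
  ov <- overlap_bp(found$contig, found$start, found$end,
                   tr$contig[2], tr$start[2], tr$end[2])
  expect_gt(ov / (tr$end[2] - tr$start[2]), 0.8)
  # flanks BBH to different neighbors: no proposal
  bbh2 <- list(G1 = bbh$G1[1, ], G2 = data.frame(gene_a = "q3",
                                                 gene_b = sub("^G1", "G2", r3),
                                                 stringsAsFactors = FALSE))
  expect_equal(nrow(rescue_missed(g, ff, ref, c("G1", "G2"), bbh2)), 0L)
  # no gaps: nothing proposed
  ffall <- make_features(id = c("q1", "q2", "q3"), contig = tr$contig,
                         start = tr$start, end = tr$end, strand = tr$strand,
                         status = "retained", fun = tr$role)
  expect_equal(nrow(rescue_missed(g, ffall, ref, "G1", bbh)), 0L)
})
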