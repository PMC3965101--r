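phe_subsystem <- function() {
  list(name = "tRNA aminoacylation Phe",
       roles = c("Phenylalanyl-tRNA synthetase alpha chain (EC 6.1.1.20)",
                 "Phenylalanyl-tRNA synthetase beta chain (EC 6.1.1.20)"),
       variants = list())
}

test_that("projection maps features to roles by exact text, splitting fusions", {
  ss <- phe_subsystem()
  ff <- make_features(
    id = c("pegA", "pegB", "pegC"), contig = "chr",
    start = c(0, 2000, 4000), end = c(1000, 3000, 5000), strand = "+",
    status = "retained",
    fun = c(ss$roles[1], ss$roles[2], "Unrelated role"))
  pr <- project_subsystems(ff, list(ss))
  expect_length(pr, 1L)
  p <- pr[[1]]
  expect_equal(p$subsystem, "tRNA aminoacylation Phe")
  expect_equal(sort(names(p$roles)), sort(ss$roles))
  expect_equal(p$roles[[ss$roles[1]]], "pegA")
  expect_equal(p$variant, "1")
  expect_equal(p$completeness, 1)
  # a fusion product fills both roles
  ff2 <- make_features(id = "fus", contig = "chr", start = 0, end = 3000,
                       strand = "+", status = "retained",
                       fun = paste(ss$roles, collapse = " / "))
  pr2 <- project_subsystems(ff2, list(ss))
  expect_equal(sort(names(pr2[[1]]$roles)), sort(ss$roles))
  # no matching roles: projection omitted entirely
  pr3 <- project_subsystems(ff2[0, ], list(ss))
  expect_length(pr3, 0L)
  # duplicate subsystem names are rejected
  expect_error(project_subsystems(ff, list(ss, ss)), "duplicate")
})

test_that("variant estimation maximizes Jaccard with documented tie-breaks", {
  ss <- list(name = "S", roles = c("r1", "r2", "r3"),
             variants = list("1" = c("r1", "r2", "r3"),
                             "2" = c("r1", "r2")))
  expect_equal(estimate_variant(c("r1", "r2", "r3"), ss), "1")
  expect_equal(estimate_variant(c("r1", "r2"), ss), "2")
  # tie between equal-Jaccard variants: fewer roles wins
  ss2 <- list(name = "S2", roles = c("r1", "r2", "r3"),
              variants = list("a" = c("r1", "r2"), "b" = c("r1", "r3")))
  expect_equal(estimate_variant("r1", ss2), "a")  # equal sizes: smaller code
  ss3 <- list(name = "S3", roles = c("r1", "r2", "r3"),
              variants = list("big" = c("r1", "r2", "r3"),
                              "sml" = c("r1")))
  expect_equal(estimate_variant("r1", ss3), "sml")  # Jaccard 1 beats 1/3
  # all below the activity floor -> "0"
  ss4 <- list(name = "S4", roles = paste0("r", 1:6),
              variants = list("1" = paste0("r", 1:6)))
  expect_equal(estimate_variant("r1", ss4), "0")
  # no declared variants: half-the-roles rule
  ss5 <- list(name = "S5", roles = c("r1", "r2"), variants = list())
  expect_equal(estimate_variant("r1", ss5), "1")
  expect_equal(estimate_variant(character(0), ss5), "0")
  # invariant to feature/role ordering
  expect_equal(estimate_variant(c("r3", "r1", "r2"), ss),
               estimate_variant(c("r1", "r2", "r3"), ss))
})

test_that("subsystem collections round-trip through TSV", {
  w <- mini_world(seed = 17)
  path <- file.path(withr::local_tempdir(), "ss.tsv")
  write_subsystems(w$subsystems, path)
  back <- read_subsystems(path)
  expect_equal(names(back), names(w$subsystems))
  for (nm in names(back)) {
    expect_equal(back[[nm]]$roles, w$subsystems[[nm]]$roles)
    expect_equal(back[[nm]]$variants, w$subsystems[[nm]]$variants)
  }
})

# PCBBH fixture: a 3-gene operon conserved in n reference genomes.
operon_fixture <- function(n_ref = 4, ref_spacing = 200) {
  ff <- make_features(id = c("g1", "g2", "g3"), contig = "chr",
                      start = c(0, 1200, 2400),
                      end = c(1000, 2200, 3400), strand = "+",
                      status = "retained")
  refs <- list(); maps <- list()
  for (k in seq_len(n_ref)) {
    gid <- sprintf("N%d", k)
    refs[[k]] <- data.frame(
      id = sprintf("%s_b%d", gid, 1:3), genome_id = gid,
      contig = paste0(gid, "_c1"),
      start = (0:2) * (1000 + ref_spacing),
      end = (0:2) * (1000 + ref_spacing) + 1000,
      stringsAsFactors = FALSE)
    maps[[gid]] <- data.frame(gene_a = c("g1", "g2", "g3"),
                              gene_b = sprintf("%s_b%d", gid, 1:3),
                              stringsAsFactors = FALSE)
  }
  list(features = ff, reference = do.call(rbind, refs), bbh_maps = maps)
}

test_that("conserved operons couple adjacent genes once per reference genome", {
  fx <- operon_fixture(n_ref = 4)
  pc <- compute_pcbbh(fx$features, fx$reference, fx$bbh_maps)
  cp <- pc$coupling
  expect_equal(cp$score[cp$gene_a1 == "g1" & cp$gene_a2 == "g2"], 4L)
  expect_equal(cp$score[cp$gene_a1 == "g2" & cp$gene_a2 == "g3"], 4L)
  expect_true(all(cp$score <= 4L))  # bounded by the number of genomes
  expect_true(all(pc$pcbbh$d_a <= 5000 & pc$pcbbh$d_b <= 5000))
})

test_that("gene pairs beyond the closeness threshold are not coupled", {
  fx <- operon_fixture(n_ref = 1)
  fx$features$start[2] <- fx$features$end[1] + 6000
  fx$features$end[2] <- fx$features$start[2] + 1000
  pc <- compute_pcbbh(fx$features, fx$reference, fx$bbh_maps,
                      close_threshold = 5000)
  expect_false(any(pc$coupling$gene_a1 == "g1" &
                     pc$coupling$gene_a2 == "g2"))
  # neighbor-side distance also enforced
  fx2 <- operon_fixture(n_ref = 1, ref_spacing = 7000)
  pc2 <- compute_pcbbh(fx2$features, fx2$reference, fx2$bbh_maps)
  expect_equal(nrow(pc2$pcbbh), 0L)
})

test_that("a single identical reference genome couples every close pair once", {
  fx <- operon_fixture(n_ref = 1)
  pc <- compute_pcbbh(fx$features, fx$reference, fx$bbh_maps)
  expect_true(all(pc$coupling$score == 1L))
  expect_equal(nrow(pc$coupling), 3L)  # g1-g2, g1-g3, g2-g3 all within 5 kb
})
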