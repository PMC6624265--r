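# hand-built NMI methylation object with exact per-stage means
mk_nm <- function(stage_means, rep2_means = stage_means, adult = c(0.6, 0.6),
                  depth = 1000) {
  samples <- c(paste0("soma_", c(4, 7, 24, 36), "_r1"),
               paste0("soma_", c(4, 7, 24, 36), "_r2"),
               "brain_adult_r1", "liver_adult_r1")
  vals <- c(stage_means, rep2_means, adult)
  meth <- matrix(vals, 1, dimnames = list("nmi_0001", samples))
  cM <- round(meth * depth)
  cU <- depth - cM
  list(candidates = data.frame(chrom = "chr1", start = 0L, end = 100L,
                               name = "nmi_0001", score = 0, strand = ".",
                               gene_ids = "gA", n_genes = 1L,
                               stringsAsFactors = FALSE),
       meth = meth, counts_M = cM, counts_U = cU, uncovered = FALSE)
}

test_that("NMI peak merging unifies overlapping and book-ended peaks", {
  p1 <- region_set("chr1", c(0, 50), c(100, 150))
  merged <- build_nmi_set(list(p1))
  expect_equal(nrow(merged), 1)
  expect_equal(c(merged$start, merged$end), c(0L, 150L))

  booked <- build_nmi_set(list(region_set("chr1", 0, 100),
                               region_set("chr1", 100, 200)))
  expect_equal(nrow(booked), 1)
  expect_equal(c(booked$start, booked$end), c(0L, 200L))
  expect_error(build_nmi_set(list()), "peak file")
})

test_that("NMI-TSS linking requires a 1 bp overlap, no flank", {
  nmis <- region_set("chr1", c(100, 400), c(200, 500),
                     name = c("n1", "n2"))
  tss <- region_set("chr1", c(150, 200, 420, 430), c(151, 201, 421, 431),
                    name = c("inside", "just_outside", "gA", "gB"))
  linked <- link_nmis_to_tss(nmis, tss)
  expect_equal(nrow(linked), 2)
  expect_equal(linked$gene_ids[1], "inside")   # 200 is outside [100,200)
  expect_equal(linked$gene_ids[2], "gA,gB")
  expect_equal(linked$n_genes, c(1L, 2L))
})

test_that("NMI methylation means agree with genomic binning", {
  cand <- data.frame(chrom = "chr1", start = 0L, end = 100L, name = "n1",
                     score = 0, strand = ".", gene_ids = "g", n_genes = 1L,
                     stringsAsFactors = FALSE)
  tab <- data.frame(chrom = "chr1", pos = c(10L, 20L),
                    count_M = c(0L, 5L), count_U = c(10L, 5L))
  nm <- nmi_methylation(cand, list(s1 = tab))
  expect_equal(unname(nm$meth[1, 1]), 5 / 20)
  expect_equal(unname(nm$meth[1, 1]),
               bin_methylation(tab, 100)$meth[1])
  zero <- nmi_methylation(cand, list(s1 = tab[0, ]))
  expect_true(zero$uncovered)
})

test_that("screen gates encode the five criteria", {
  # canonical gaining promoter: r ~ 0.97, all gates pass
  nm <- mk_nm(c(0.01, 0.05, 0.20, 0.30))
  scr <- screen_candidates(nm)
  expect_equal(scr$pearson_r, cor(c(0.01, 0.05, 0.20, 0.30), 1:4),
               tolerance = 1e-6)
  expect_gt(scr$pearson_r, 0.5)
  expect_true(scr$gates_pass)

  # decreasing trajectory fails on the correlation sign
  dec <- screen_candidates(mk_nm(c(0.30, 0.20, 0.05, 0.01)))
  expect_lt(dec$pearson_r, 0)
  expect_false(dec$gates_pass)

  # constant trajectory is degenerate, never passes
  con <- screen_candidates(mk_nm(c(0.20, 0.20, 0.20, 0.20)))
  expect_true(is.na(con$pearson_r))
  expect_false(con$gates_pass)

  # each threshold gate binds in each replicate
  expect_false(screen_candidates(
    mk_nm(c(0.01, 0.05, 0.20, 0.30),
          rep2_means = c(0.03, 0.05, 0.20, 0.30)))$gate_4hpf)
  expect_false(screen_candidates(
    mk_nm(c(0.01, 0.05, 0.20, 0.30),
          rep2_means = c(0.01, 0.05, 0.20, 0.10)))$gate_36hpf)
  expect_false(screen_candidates(
    mk_nm(c(0.01, 0.05, 0.20, 0.30), adult = c(0.30, 0.60)))$gate_brain)
  expect_error(screen_candidates(
    within(mk_nm(c(0.01, 0.05, 0.2, 0.3)), {
      meth <- meth[, -1, drop = FALSE]
      counts_M <- counts_M[, -1, drop = FALSE]
      counts_U <- counts_U[, -1, drop = FALSE]
    })), "missing sample")
})

test_that("Fisher exact matches enumeration, with degenerate margins", {
  expect_equal(fisher_exact_2x2(c(10, 0, 0, 10))$p, 2 / choose(20, 10))
  expect_equal(fisher_exact_2x2(c(5, 5, 5, 5))$p, 1)
  expect_true(fisher_exact_2x2(c(0, 0, 3, 4))$degenerate)
  expect_equal(fisher_exact_2x2(c(0, 0, 3, 4))$p, 1)

  # exhaustive agreement with the independent enumeration (and fisher.test)
  set.seed(31)
  for (i in 1:60) {
    tab <- as.vector(stats::rmultinom(1, sample(4:20, 1), rep(0.25, 4)))
    got <- fisher_exact_2x2(tab)$p
    expect_equal(got, oracle_fisher(tab[1], tab[2], tab[3], tab[4]),
                 tolerance = 1e-12)
    if (all(rowSums(matrix(tab, 2, byrow = TRUE)) > 0) &&
        all(colSums(matrix(tab, 2, byrow = TRUE)) > 0))
      expect_equal(got,
                   stats::fisher.test(matrix(tab, 2, byrow = TRUE))$p.value,
                   tolerance = 1e-9)
  }
})

test_that("stage Fisher test pools early and late counts per replicate", {
  nm <- mk_nm(c(0.01, 0.05, 0.20, 0.30), depth = 500)
  ft <- fisher_stage_test(nm, "nmi_0001", 1)
  expect_equal(unname(ft$table["early", "M"]), round(0.01 * 500) +
                 round(0.05 * 500))
  expect_equal(unname(ft$table["late", "M"]), round(0.2 * 500) +
                 round(0.3 * 500))
  expect_lt(ft$p, 1e-10)
  expect_error(fisher_stage_test(nm, "nope", 1), "unknown candidate")
})

test_that("BH adjustment is the exact step-up", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(8)
  for (i in 1:20) {
    p <- runif(sample(1:50, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, stats::p.adjust(p, "BH"))
    expect_equal(adj, oracle_bh(p))
    expect_true(all(adj >= p))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("target finalisation reports both tiers", {
  m <- fixture("model")
  meth <- fixture("meth")
  cand <- link_nmis_to_tss(m$regions$nmis, m$regions$tss)
  nm <- nmi_methylation(cand, meth$tables)
  scr <- screen_candidates(nm)
  targets <- finalize_targets(scr, nm)

  truth_genes <- m$truth$regions$name[m$truth$regions$class ==
                                        "promoter_target"]
  expect_setequal(targets$name[targets$is_target], truth_genes)
  expect_equal(sum(targets$gates_pass & !targets$is_target), 0)
  expect_true(all(targets$padj_rep1[targets$is_target] < 0.01))
  expect_true(all(targets$tier[targets$is_target] == "significant"))

  none <- finalize_targets(scr[0, ], nm)
  expect_equal(nrow(none), 0)
})

test_that("orthologue projection reports unmapped and one-to-many genes", {
  targets <- data.frame(gene_ids = c("g1", "g2,g3"),
                        stringsAsFactors = FALSE)
  ortho <- data.frame(gene_id = c("g1", "g2", "g2"),
                      mouse_gene = c("m1", "m2a", "m2b"),
                      stringsAsFactors = FALSE)
  foreign <- data.frame(gene = c("m1", "m2a"), sperm = c(0.02, 0.05),
                        oocyte = c(0.8, 0.7), stringsAsFactors = FALSE)
  pr <- project_orthologues(targets, ortho, foreign)
  expect_true("g1" %in% rownames(pr$matrix))
  expect_equal(pr$unmapped, "g3")
  expect_equal(pr$one_to_many, "g2")
  empty <- project_orthologues(targets, ortho[0, ], foreign)
  expect_equal(nrow(empty$matrix), 0)
  expect_setequal(empty$unmapped, c("g1", "g2", "g3"))
})
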