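dmc_at <- function(pos, d = 0.5)
  data.frame(chrom = rep("chr1", length(pos)), pos = as.integer(pos),
             d = rep(d, length(pos)), p = rep(1e-6, length(pos)),
             is_dmc = rep(TRUE, length(pos)), stringsAsFactors = FALSE)

test_that("stitching merges runs of nearby DMCs", {
  one <- stitch_dmrs(dmc_at(c(100, 130, 160, 200, 240)))
  expect_equal(nrow(one), 1)
  expect_equal(one$start, 99L)
  expect_equal(one$end, 240L)
  expect_equal(one$n_dmc, 5L)

  two <- stitch_dmrs(dmc_at(c(100, 130, 200)))
  expect_equal(two$n_dmc, c(2L, 1L))
  expect_equal(two$start, c(99L, 199L))

  expect_equal(nrow(stitch_dmrs(dmc_at(integer()))), 0)
  # chromosome boundaries never merge
  d <- dmc_at(c(100, 120))
  d$chrom <- c("chr1", "chr2")
  expect_equal(nrow(stitch_dmrs(d)), 2)
})

# dense toy locus where every CpG is differential
toy_locus <- function(pos, mu_pgc, mu_soma, cov = 50L) {
  mk <- function(mu) data.frame(chrom = "chr1", pos = as.integer(pos),
                                count_M = as.integer(round(cov * mu)),
                                count_U = as.integer(cov - round(cov * mu)),
                                stringsAsFactors = FALSE)
  list(pgc = list(mk(mu_pgc), mk(mu_pgc)),
       soma = list(mk(mu_soma), mk(mu_soma)))
}

test_that("filters drop candidates exactly as the rules state", {
  pos <- seq(100, 400, by = 20)

  # 4 DMCs: dropped by the minimum-DMC rule
  tl <- toy_locus(pos[1:4], 0.1, 0.9)
  res <- call_dmrs(tl$pgc, tl$soma, region_set())
  expect_equal(nrow(res$dmrs), 0)

  # 5 DMCs spanning >= 50 bp: emitted and classified
  tl5 <- toy_locus(pos[1:5], 0.1, 0.9)
  res5 <- call_dmrs(tl5$pgc, tl5$soma, region_set())
  expect_equal(nrow(res5$dmrs), 1)
  expect_equal(res5$dmrs$class, "hypo_in_PGC")
  expect_equal(res5$dmrs$span, res5$dmrs$end - res5$dmrs$start)

  # 5 DMCs packed into < 50 bp: dropped by the span rule
  tight <- toy_locus(seq(100, 140, by = 10), 0.1, 0.9)
  res_t <- call_dmrs(tight$pgc, tight$soma, region_set())
  expect_equal(nrow(res_t$dmrs), 0)

  # any repeat overlap excludes the candidate
  res_r <- call_dmrs(tl5$pgc, tl5$soma, region_set("chr1", 170, 175))
  expect_equal(nrow(res_r$dmrs), 0)

  # low-coverage CpGs beyond 25% exclude the candidate
  tl_low <- toy_locus(pos[1:9], 0.1, 0.9)
  for (r in 1:2) {
    tl_low$pgc[[r]]$count_M[1:3] <- 0L
    tl_low$pgc[[r]]$count_U[1:3] <- 1L   # pooled coverage 2 < 5
  }
  res_l <- call_dmrs(tl_low$pgc, tl_low$soma, region_set())
  expect_equal(nrow(res_l$dmrs), 0)
})

test_that("classification needs a 0.1 difference in both replicates", {
  pos <- seq(100, 300, by = 20)
  tl <- toy_locus(pos, 0.65, 0.5, cov = 400L)
  # replicate 2 of PGC pulled down to a +0.08 difference
  tl$pgc[[2]]$count_M <- as.integer(round(400 * 0.58))
  tl$pgc[[2]]$count_U <- 400L - tl$pgc[[2]]$count_M
  res <- call_dmrs(tl$pgc, tl$soma, region_set(), alpha_dmc = 0.05)
  expect_equal(nrow(res$dmrs), 1)
  expect_equal(res$dmrs$class, "unclassified")
  expect_gt(res$dmrs$delta_rep1, 0.1)
  expect_lt(res$dmrs$delta_rep2, 0.1)

  # sign consistency of emitted classes on the simulation
  m <- fixture("model")
  meth <- fixture("meth")
  res24 <- call_dmrs(meth_group(meth, "PGC", "24"),
                     meth_group(meth, "soma", "24"), m$regions$repeats)
  hyper <- res24$dmrs[res24$dmrs$class == "hyper_in_PGC", ]
  hypo <- res24$dmrs[res24$dmrs$class == "hypo_in_PGC", ]
  expect_true(all(hyper$delta_rep1 >= 0.1 & hyper$delta_rep2 >= 0.1))
  expect_true(all(hypo$delta_rep1 <= -0.1 & hypo$delta_rep2 <= -0.1))
})

test_that("the DMC-to-DMR path matches the brute-force reference", {
  for (seed in 1:40) {
    inst <- random_dmr_instance(seed + 500)
    got <- call_dmrs(inst$pgc, inst$soma, inst$repeats)
    want <- oracle_dmr_path(inst$pgc, inst$soma, inst$repeats)
    expect_equal(nrow(got$dmrs), nrow(want),
                 info = paste("instance", seed))
    if (nrow(want)) {
      expect_equal(got$dmrs$start, want$start, info = paste("inst", seed))
      expect_equal(got$dmrs$end, want$end, info = paste("inst", seed))
      expect_equal(got$dmrs$n_dmc, want$n_dmc, info = paste("inst", seed))
      expect_equal(got$dmrs$class, want$class, info = paste("inst", seed))
    }
  }
})
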