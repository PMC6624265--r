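# hand-built 8-sample PSI table
mk_psi <- function(psi_rows, qual = "SOUND") {
  samples <- expand.grid(replicate = 1:2, stage = c(7, 24),
                         tissue = c("PGC", "soma"),
                         stringsAsFactors = FALSE)[, 3:1]
  samples$sample_id <- paste0(samples$tissue, "_", samples$stage, "_r",
                              samples$replicate)
  psi <- matrix(unlist(psi_rows), length(psi_rows), 8, byrow = TRUE,
                dimnames = list(names(psi_rows), samples$sample_id))
  q <- matrix(qual, nrow(psi), 8, dimnames = dimnames(psi))
  list(psi = psi, qual = q, samples = samples)
}
# column order: PGC_7_r1 PGC_7_r2 PGC_24_r1 PGC_24_r2 soma_7_r1 ... soma_24_r2

test_that("coverage filtering requires VLOW in all eight samples", {
  tab <- mk_psi(list(ok = rep(50, 8), dropped = rep(50, 8),
                     low = rep(50, 8)))
  tab$qual["dropped", 3] <- "N"
  tab$qual["low", ] <- "VLOW"
  kept <- filter_psi_coverage(tab)
  expect_setequal(kept, c("ok", "low"))
  short <- tab
  short$psi <- short$psi[, 1:7]
  expect_error(filter_psi_coverage(short), "8 design samples")

  # brute-force row scan agrees on the simulated table
  psi <- fixture("psi")
  kept_sim <- filter_psi_coverage(psi)
  brute <- rownames(psi$qual)[apply(psi$qual, 1, function(q)
    all(match(q, c("N", "VLOW", "LOW", "OK", "SOUND")) >= 2))]
  expect_setequal(kept_sim, brute)
})

test_that("the dPSI rules decide differential exons", {
  tab <- mk_psi(list(
    too_weak = c(66, 56, 50, 50, 50, 50, 50, 50),   # dPSI +16, +6: mean 11
    clear = c(70, 64, 50, 50, 50, 50, 50, 50),      # dPSI +20, +14: mean 17
    flip = c(80, 20, 50, 50, 50, 50, 50, 50)))      # dPSI +30, -30
  res <- differential_exons(tab, "tissue@7")
  expect_equal(res$differential[match(c("too_weak", "clear", "flip"),
                                      res$event_id)],
               c(FALSE, TRUE, FALSE))
  expect_equal(res$mean_dpsi[match("clear", res$event_id)], 17)

  # a pair below the per-pair floor fails even with a large mean
  weak_pair <- mk_psi(list(e = c(90, 54, 50, 50, 50, 50, 50, 50)))
  expect_false(differential_exons(weak_pair, "tissue@7")$differential)

  # monotonicity: raising either threshold never adds events
  psi <- fixture("psi")
  base <- differential_exons(psi, "tissue@7")
  stricter <- differential_exons(psi, "tissue@7", min_avg_dpsi = 25)
  expect_true(all(stricter$event_id[stricter$differential] %in%
                    base$event_id[base$differential]))
  stricter2 <- differential_exons(psi, "tissue@7", min_pair_dpsi = 12)
  expect_true(all(stricter2$event_id[stricter2$differential] %in%
                    base$event_id[base$differential]))
})

test_that("rule decisions agree with the brute-force evaluator", {
  psi <- fixture("psi")
  covered <- filter_psi_coverage(psi)
  s <- psi$samples
  combos <- list(c("tissue@7", "PGC_7", "soma_7"),
                 c("tissue@24", "PGC_24", "soma_24"),
                 c("dev@PGC", "PGC_7", "PGC_24"),
                 c("dev@soma", "soma_7", "soma_24"))
  for (cmb in combos) {
    got <- differential_exons(psi, cmb[1], events = covered)
    want <- oracle_diff_exons(psi$psi[covered, , drop = FALSE],
                              paste0(cmb[2], "_r", 1:2),
                              paste0(cmb[3], "_r", 1:2))
    expect_equal(got$differential, unname(want), info = cmb[1])
  }
})

test_that("developmental overlap uses the Fisher engine on the universe", {
  uni <- sprintf("e%02d", 1:30)
  same <- developmental_overlap_test(uni[1:10], uni[1:10], uni)
  expect_equal(same$overlap, 10)
  expect_lt(same$p, 0.05)
  none <- developmental_overlap_test(character(), uni[1:10], uni)
  expect_equal(none$overlap, 0)
  expect_equal(none$p, 1)
  expect_error(developmental_overlap_test(uni[1:2], uni[1:2], character()),
               "empty universe")
  expect_error(developmental_overlap_test("zz", uni[1:3], uni), "subsets")

  # planted stage-offset exons overlap between the tissues by design
  psi <- fixture("psi")
  covered <- filter_psi_coverage(psi)
  dp <- differential_exons(psi, "dev@PGC", events = covered)
  ds <- differential_exons(psi, "dev@soma", events = covered)
  ov <- developmental_overlap_test(dp$event_id[dp$differential],
                                   ds$event_id[ds$differential], covered)
  expect_lt(ov$p, 1e-6)
})

test_that("tissue marker exons satisfy all three criteria", {
  tab <- mk_psi(list(
    marker = c(66, 62, 70, 66, 50, 50, 50, 50),   # dPSI +14, +18
    gate_i = c(62, 58, 72, 68, 50, 50, 50, 50),   # dPSI +10... stage-7 ok
    weak = c(58, 56, 59, 57, 50, 50, 50, 50)))    # dPSI +7, +8
  res <- tissue_marker_exons(tab)
  expect_true(res$marker[match("marker", res$event_id)])
  expect_false(res$marker[match("weak", res$event_id)])
  expect_equal(res$dpsi_7[match("marker", res$event_id)], 14)
  expect_equal(res$dpsi_24[match("marker", res$event_id)], 18)

  # planted tissue-offset events recovered, stage-offset and background not
  m <- fixture("model")
  psi <- fixture("psi")
  covered <- filter_psi_coverage(psi)
  mk <- tissue_marker_exons(psi, events = covered)
  truth <- m$truth$exons
  tis <- intersect(truth$event_id[truth$type == "tissue"], covered)
  got <- mk$event_id[mk$marker]
  expect_gte(length(intersect(got, tis)) / length(tis), 0.8)
  expect_equal(setdiff(got, truth$event_id), character())
})
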