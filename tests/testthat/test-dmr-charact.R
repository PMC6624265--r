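test_that("matched controls preserve lengths and avoid exclusions", {
  m <- fixture("model")
  tr <- m$truth$regions
  sel <- tr$class == "hypo4_dmr"
  dmrs <- region_set(tr$chrom[sel], tr$start[sel], tr$end[sel])
  excl <- rbind(m$regions$repeats[, 1:6],
                region_set(tr$chrom, tr$start, tr$end))
  ctrl <- sample_matched_controls(dmrs, m$chrom_sizes, excl, seed = 5)
  expect_equal(sort(ctrl$end - ctrl$start), sort(dmrs$end - dmrs$start))
  expect_equal(region_overlap_fraction(ctrl, excl)$n_overlap, 0)
  ctrl2 <- sample_matched_controls(dmrs, m$chrom_sizes, excl, seed = 5)
  expect_identical(ctrl, ctrl2)
  expect_error(sample_matched_controls(region_set("chr1", 0, 900),
                                       c(chr1 = 1000),
                                       region_set("chr1", 0, 999),
                                       max_tries = 20),
               "could not place")
})

test_that("signal enrichment statistics behave at the boundaries", {
  track <- data.frame(chrom = "chr1", start = seq(0, 900, 100),
                      end = seq(100, 1000, 100), value = 1:10)
  regions <- region_set("chr1", c(0, 300), c(200, 500),
                        name = c("a", "b"))
  self <- region_signal_enrichment(track, regions, regions)
  expect_equal(self$t, 0)
  expect_equal(self$p, 1)

  const <- track
  const$value <- 7
  res <- region_signal_enrichment(const, regions,
                                  region_set("chr1", c(600, 800),
                                             c(700, 900)))
  expect_equal(res$t, 0)
  expect_equal(res$p, 1)

  # length-weighted mean over partial bins
  part <- region_set("chr1", 50, 150)
  expect_equal(pgcmethylome:::region_track_means(track, part),
               (1 * 50 + 2 * 50) / 100)

  # planted enrichment is detected against matched controls
  mdl <- fixture("model")
  tracks <- fixture("tracks")
  tr <- mdl$truth$regions
  sel <- tr$class %in% c("hypo4_dmr", "hyper24_dmr")
  dmrs <- region_set(tr$chrom[sel], tr$start[sel], tr$end[sel])
  excl <- rbind(mdl$regions$repeats[, 1:6],
                region_set(tr$chrom, tr$start, tr$end))
  ctrl <- sample_matched_controls(dmrs, mdl$chrom_sizes, excl, seed = 2)
  enr <- region_signal_enrichment(tracks$H3K27ac, dmrs, ctrl)
  expect_lt(enr$p, 0.001)
  expect_gt(mean(enr$region_means), mean(enr$control_means))
})

test_that("signal profiles have the stated geometry", {
  track <- data.frame(chrom = "chr1", start = seq(0, 19900, 100),
                      end = seq(100, 20000, 100), value = 3)
  regions <- region_set("chr1", c(9000, 100), c(9600, 200),
                        name = c("mid", "edge"))
  expect_warning(pr <- profile_signal(track, regions, flank = 3000,
                                      bin = 300),
                 "edge")
  expect_equal(ncol(pr$profile), 20)
  expect_equal(nrow(pr$profile), 1)
  expect_equal(rownames(pr$profile), "mid")
  expect_equal(pr$excluded, 1L)   # regions are kept in sorted order
  expect_true(all(pr$profile == 3))           # flat for a constant track
  expect_error(profile_signal(track, regions, flank = 1000, bin = 300),
               "divisible")

  # 5hmC separates late-hyper from early-hypo regions
  mdl <- fixture("model")
  tr <- mdl$truth$regions
  pick <- function(cls) {
    sel <- tr$class == cls
    region_set(tr$chrom[sel], tr$start[sel], tr$end[sel],
               name = tr$name[sel])
  }
  cmp <- compare_profiles(fixture("tracks")$hmC5, pick("hyper24_dmr"),
                          pick("hypo4_dmr"), chrom_sizes = mdl$chrom_sizes)
  expect_lt(cmp$p, 0.01)
})

test_that("region overlap fractions count intervals once", {
  a <- region_set(c("chr1", "chr1"), c(0, 200), c(100, 300))
  b <- region_set("chr1", 90, 110)
  r <- region_overlap_fraction(a, b)
  expect_equal(r$fraction, 0.5)
  expect_equal(r$n_overlap, 1L)
  expect_equal(region_overlap_fraction(a, a)$fraction, 1)
  dis <- region_set("chr2", 0, 50)
  expect_equal(region_overlap_fraction(a, dis)$fraction, 0)
  # min_bp raises the bar
  expect_equal(region_overlap_fraction(a, b, min_bp = 20)$fraction, 0)
})
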