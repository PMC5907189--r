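mk_cx <- function(...) {
  rows <- list(...)
  tibble::tibble(
    chrom = vapply(rows, `[[`, "", 1),
    pos = vapply(rows, function(r) as.numeric(r[[2]]), 0),
    strand = vapply(rows, `[[`, "", 3),
    meth = vapply(rows, function(r) as.numeric(r[[4]]), 0),
    unmeth = vapply(rows, function(r) as.numeric(r[[5]]), 0),
    context = "CG", tricontext = "CGN",
    depth = vapply(rows, function(r) as.numeric(r[[4]]) + as.numeric(r[[5]]), 0),
    is_cpg = TRUE
  )
}

test_that("strand merging pools the C and its complementary G position", {
  sites <- tibble::tibble(chrom = "chr1", pos = c(100, 300))
  cx <- mk_cx(list("chr1", 100, "+", 3, 1),
              list("chr1", 101, "-", 2, 2),
              list("chr1", 300, "+", 4, 0))
  calls <- merge_strands(cx, sites)
  expect_equal(calls$meth, c(5, 4))
  expect_equal(calls$depth, c(8, 4))
  expect_equal(calls$level, c(5 / 8, 1.0))
  # conservation
  expect_equal(sum(calls$meth), sum(cx$meth))
  expect_equal(sum(calls$unmeth), sum(cx$unmeth))
})

test_that("uncovered sites are kept at depth zero with undefined level", {
  sites <- tibble::tibble(chrom = "chr1", pos = c(10, 20))
  calls <- merge_strands(mk_cx(list("chr1", 10, "+", 1, 1)), sites)
  expect_equal(calls$depth, c(2, 0))
  expect_true(is.na(calls$level[2]))
})

test_that("CpG records at non-CpG positions warn and are excluded", {
  sites <- tibble::tibble(chrom = "chr1", pos = 100)
  cx <- mk_cx(list("chr1", 100, "+", 3, 1), list("chr1", 555, "+", 9, 0))
  expect_warning(calls <- merge_strands(cx, sites), "mismatch")
  expect_equal(sum(calls$meth), 3)
  expect_equal(nrow(attr(calls, "excluded")), 1)
})

test_that("strand merging conserves counts on simulated data", {
  st <- tiny_study()
  sites <- enumerate_cpg_sites(st$genome)
  calls <- merge_strands(st$cx, sites)
  expect_equal(sum(calls$meth), sum(st$cx$meth))
  expect_equal(sum(calls$unmeth), sum(st$cx$unmeth))
})

test_that("on-target filtering and read rate follow half-open overlap", {
  target <- regions("chr1", 50, 150)
  calls <- merge_strands(mk_cx(list("chr1", 100, "+", 1, 0),
                               list("chr1", 150, "+", 1, 0)),
                         tibble::tibble(chrom = "chr1", pos = c(100, 150)))
  kept <- on_target_sites(calls, target)
  expect_equal(kept$pos, 100)
  reads <- regions("chr1", c(40, 100, 150, 400), c(141, 201, 251, 501))
  # read starting exactly at target end has zero overlap -> off-target
  expect_equal(on_target_read_rate(reads, target), 0.5)
  expect_equal(on_target_read_rate(regions("chr1", 60, 80), target), 1.0)
  expect_true(is.na(on_target_read_rate(reads[0, ], target)))
})

test_that("read rate matches a per-read overlap oracle on simulated reads", {
  st <- tiny_study()
  target <- regions("chr1", c(1000, 50000), c(20000, 90000))
  rate <- on_target_read_rate(st$reads, target)
  oracle <- mean(vapply(seq_len(nrow(st$reads)), function(i) {
    any(st$reads$start[i] < target$end & target$start < st$reads$end[i])
  }, TRUE))
  expect_equal(rate, oracle)
})

test_that("depth profile counts uncovered sites and is non-increasing", {
  sites <- tibble::tibble(chrom = "chr1", pos = c(10, 20, 30))
  cx <- mk_cx(list("chr1", 10, "+", 1, 0),
              list("chr1", 20, "+", 3, 2),
              list("chr1", 30, "+", 6, 4))
  calls <- merge_strands(cx, sites)
  dp <- depth_profile(calls, regions("chr1", 0, 100), thresholds = c(1, 5, 10))
  expect_equal(dp$coverage$pct_sites, c(100, 200 / 3, 100 / 3))
  expect_equal(dp$mean_depth, mean(c(1, 5, 10)))
  # all-uncovered target
  dp0 <- depth_profile(calls, regions("chr1", 500, 600), thresholds = c(1, 5))
  expect_equal(dp0$n_sites, 0)
  # empty calls at every site
  empty_calls <- merge_strands(mk_cx(list("chr1", 10, "+", 0, 0)), sites)
  dp1 <- depth_profile(empty_calls, regions("chr1", 0, 100))
  expect_equal(dp1$coverage$pct_sites[1], 0)
  expect_equal(dp1$mean_depth, 0)
})

test_that("class methylation averages per-site levels with sample SD", {
  sites <- tibble::tibble(chrom = "chr1", pos = c(10, 20, 30))
  cx <- mk_cx(list("chr1", 10, "+", 2, 8),    # 0.2
              list("chr1", 20, "+", 4, 6),    # 0.4
              list("chr1", 30, "+", 1, 1))    # depth 2: filtered at min 5
  calls <- merge_strands(cx, sites)
  cls <- list(X = regions("chr1", 0, 100), EMPTY = regions("chr1", 500, 600))
  cm <- class_methylation(calls, cls, min_depth = 5)
  x <- cm[cm$region_class == "X", ]
  expect_equal(x$n_sites, 2)
  expect_equal(x$mean_level, 0.30)
  expect_equal(x$sd_level, sd(c(0.2, 0.4)))
  expect_true(is.na(cm$mean_level[cm$region_class == "EMPTY"]))
  # single qualifying site: mean defined, sd undefined
  one <- class_methylation(calls, list(Y = regions("chr1", 5, 15)),
                           min_depth = 5)
  expect_equal(one$mean_level, 0.2)
  expect_true(is.na(one$sd_level))
  # weighted pooling differs when depths differ
  cmw <- class_methylation(calls, cls, min_depth = 5, weighted = TRUE)
  expect_equal(cmw$mean_level[1], (2 + 4) / 20)
})

test_that("class means match an independent two-pass recomputation", {
  st <- tiny_study()
  sites <- enumerate_cpg_sites(st$genome)
  calls <- merge_strands(st$cx, sites)
  cls <- st$truth_classes["SHORE"]
  target <- st$capture
  cm <- class_methylation(calls, cls, target = target, min_depth = 5)
  # oracle: plain vector arithmetic over explicitly selected sites
  inside <- sites_in_regions(calls, cls$SHORE) &
    sites_in_regions(calls, target) & calls$depth >= 5
  expect_equal(cm$n_sites, sum(inside))
  expect_equal(cm$mean_level, mean(calls$level[inside]))
  expect_equal(cm$sd_level, sd(calls$level[inside]))
})
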