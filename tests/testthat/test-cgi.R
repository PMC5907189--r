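test_that("no-CG sequences yield no islands", {
  expect_equal(nrow(find_cgis(c(chr1 = strrep("AT", 500)))), 0)
  expect_equal(nrow(find_cgis(c(chr1 = "A"))), 0)
})

test_that("a CGCG run forms one CG-bounded island with the expected peak", {
  calls <- find_cgis(c(chr1 = "CGCG"))
  expect_equal(nrow(calls), 1)
  expect_equal(calls$start, 0)
  expect_equal(calls$end, 4)
  expect_equal(calls$peak_score, 17 - 1 + 17)
  expect_equal(calls$cg_count, 2)
})

test_that("island coordinates stop at the rightmost score maximum", {
  # CG at 0, then 20 non-CG steps: the single CG is its own minimal island
  s <- paste0("CG", strrep("A", 20), "T")
  calls <- find_cgis(c(chr1 = s))
  expect_equal(nrow(calls), 1)
  expect_equal(c(calls$start, calls$end), c(0, 2))
  # a CG in the still-open tail of a segment, below the peak, is not reported
  s2 <- paste0("CGCG", strrep("A", 30), "CG")
  calls2 <- find_cgis(c(chr1 = s2))
  expect_equal(calls2$start, 0)
  expect_equal(calls2$end, 4)
  expect_equal(calls2$peak_score, 33)
  # once the segment has closed, a later CG opens a fresh minimal island
  s3 <- paste0("CGCG", strrep("A", 40), "CG")
  calls3 <- find_cgis(c(chr1 = s3))
  expect_equal(calls3$start, c(0, 44))
  expect_equal(calls3$end, c(4, 46))
})

test_that("N bases break CGs, incur the penalty, and bad letters error", {
  with_n <- find_cgis(c(chr1 = "CNGCG"))
  expect_equal(nrow(with_n), 1)
  expect_equal(c(with_n$start, with_n$end), c(3, 5))
  expect_error(find_cgis(c(chr1 = "ACGX")), "disallowed")
})

test_that("detector matches the positional-walk oracle on random sequences", {
  withr::local_seed(11)
  for (rep in 1:60) {
    # CG-enriched so multi-CG segments and clamp resets are exercised
    s <- random_dna(2000, gc = runif(1, 0.4, 0.7))
    got <- find_cgis(c(chr1 = s))
    exp <- cgi_oracle(s)
    expect_equal(as.data.frame(got[, c("start", "end", "peak_score")]),
                 exp, ignore_attr = TRUE)
    # every island is CG-bounded
    if (nrow(got) > 0) {
      expect_true(all(substr(rep(s, nrow(got)), got$start + 1,
                             got$start + 2) == "CG"))
      expect_true(all(substr(rep(s, nrow(got)), got$end - 1, got$end) == "CG"))
      expect_true(all(got$cg_count >= 1))
      expect_true(all(diff(got$start) > 0))
    }
  }
})

test_that("identical input produces identical calls", {
  s <- c(chr1 = random_dna(3000, gc = 0.6))
  expect_identical(find_cgis(s), find_cgis(s))
})

test_that("shores and shelves follow the 2 kb geometry with precedence", {
  cl <- c(chr1 = 1e6)
  cgis <- regions("chr1", 10000, 10800)
  ss <- derive_shores_shelves(cgis, cl)
  expect_equal(as.data.frame(ss$shores[, c("start", "end")]),
               data.frame(start = c(8000, 10800), end = c(10000, 12800)))
  expect_equal(as.data.frame(ss$shelves[, c("start", "end")]),
               data.frame(start = c(6000, 12800), end = c(8000, 14800)))
})

test_that("flanks clip at chromosome boundaries", {
  ss <- derive_shores_shelves(regions("chr1", 500, 700), c(chr1 = 1e6))
  expect_equal(as.data.frame(ss$shores[1, c("start", "end")]),
               data.frame(start = 0, end = 500))
  expect_equal(nrow(ss$shelves), 1)  # no room left of the shore
  expect_error(derive_shores_shelves(regions("chr1", 500, 700), c(chr1 = 600)),
               "beyond")
})

test_that("adjacent islands share shore bases once, with no shelf between", {
  cl <- c(chr1 = 1e6)
  cgis <- regions("chr1", c(10000, 11800), c(10800, 12600))
  ss <- derive_shores_shelves(cgis, cl)
  # per-base class map oracle over the local window
  win <- 4000:20000
  base_class <- rep("none", length(win))
  claim <- function(cls, set) {
    for (i in seq_len(nrow(set))) {
      sel <- win >= set$start[i] & win < set$end[i]
      base_class[sel & base_class == "none"] <<- cls
    }
  }
  # oracle: raw windows with precedence CGI > shore > shelf
  claim("cgi", cgis)
  claim("shore", regions("chr1", c(8000, 10800, 9800, 12600),
                         c(10000, 12800, 11800, 14600)))
  claim("shelf", regions("chr1", c(6000, 12800, 7800, 14600),
                         c(8000, 14800, 9800, 16600)))
  sites <- tibble::tibble(chrom = "chr1", pos = win)
  expect_identical(sites_in_regions(sites, ss$shores), base_class == "shore")
  expect_identical(sites_in_regions(sites, ss$shelves), base_class == "shelf")
  # pairwise disjoint
  expect_equal(nrow(intersect_regions(ss$shores, ss$shelves)), 0)
  expect_equal(nrow(intersect_regions(ss$shores, cgis)), 0)
  expect_equal(nrow(intersect_regions(ss$shelves, cgis)), 0)
  # no shelf bases between the two islands
  between <- intersect_regions(ss$shelves, regions("chr1", 10800, 11800))
  expect_equal(nrow(between), 0)
})
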