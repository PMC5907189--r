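test_that("region validation rejects malformed intervals and identifies them", {
  expect_error(regions("chr1", 10, 10), "row")
  expect_error(regions("chr1", 20, 10), "start < end")
  expect_error(regions("", 0, 10), "row")
  expect_error(as_regions(data.frame(chrom = "chr1", start = 0)), "lacks")
  ok <- regions("chr1", 0, 10, genome = "asmA")
  expect_identical(region_genome(ok), "asmA")
})

test_that("merge coalesces overlapping and book-ended intervals", {
  expect_equal(merge_regions(regions("chr1", c(0, 5), c(10, 20))),
               regions("chr1", 0, 20), ignore_attr = TRUE)
  expect_equal(merge_regions(regions("chr1", c(0, 10), c(10, 20))),
               regions("chr1", 0, 20), ignore_attr = TRUE)
  # idempotent
  x <- regions("chr1", c(0, 5, 100), c(10, 20, 200))
  expect_identical(merge_regions(merge_regions(x)), merge_regions(x))
})

test_that("intersect and subtract follow half-open semantics", {
  a <- regions("chr1", 0, 10)
  b <- regions("chr1", 5, 20)
  expect_equal(intersect_regions(a, b), regions("chr1", 5, 10),
               ignore_attr = TRUE)
  expect_equal(intersect_regions(a, empty <- regions("chr1", 0, 1)[0, ]),
               regions("chr1", 0, 1)[0, ], ignore_attr = TRUE)
  expect_equal(subtract_regions(regions("chr1", 0, 20), regions("chr1", 5, 10)),
               regions("chr1", c(0, 10), c(5, 20)), ignore_attr = TRUE)
  expect_equal(nrow(subtract_regions(a, a)), 0)
})

test_that("set operations refuse mixed genomes", {
  a <- regions("chr1", 0, 10, genome = "asmA")
  b <- regions("chr1", 5, 20, genome = "asmB")
  expect_error(intersect_regions(a, b), "genome mismatch")
  expect_error(subtract_regions(a, b), "genome mismatch")
  expect_error(overlap_fraction(a, b), "genome mismatch")
})

test_that("overlap_fraction computes clipped covered fraction", {
  set <- regions("chr1", c(500, 1500), c(1000, 1800))
  expect_equal(overlap_fraction(regions("chr1", 0, 2000), set), 0.40)
  expect_equal(overlap_fraction(regions("chr1", 600, 700), set), 1.0)
  expect_equal(overlap_fraction(regions("chr1", 3000, 4000), set), 0.0)
  # vectorised over query rows
  q <- regions("chr1", c(0, 600, 3000), c(2000, 700, 4000))
  expect_equal(overlap_fraction(q, set), c(0.40, 1.0, 0.0))
})

test_that("set algebra agrees base-for-base with the boolean-array oracle", {
  withr::local_seed(7)
  lens <- c(chr1 = 8000, chr2 = 5000, chr3 = 10000)
  for (rep in 1:50) {
    a <- as_regions(random_region_set(sample(1:40, 1), lens))
    b <- as_regions(random_region_set(sample(1:40, 1), lens))
    expect_same_bases(merge_regions(a),
                      bool_to_regions(oracle_bases(a, lens)))
    expect_same_bases(intersect_regions(a, b), oracle_op(a, b, lens, "intersect"))
    expect_same_bases(subtract_regions(a, b), oracle_op(a, b, lens, "subtract"))
    expect_same_bases(union_regions(a, b), oracle_op(a, b, lens, "union"))
  }
})

test_that("inclusion-exclusion holds for total covered length", {
  withr::local_seed(8)
  lens <- c(chr1 = 6000, chr2 = 6000)
  for (rep in 1:20) {
    a <- as_regions(random_region_set(20, lens))
    b <- as_regions(random_region_set(20, lens))
    expect_equal(region_total_length(union_regions(a, b)) +
                   region_total_length(intersect_regions(a, b)),
                 region_total_length(a) + region_total_length(b))
  }
})

test_that("site membership uses the half-open convention", {
  set <- regions("chr1", 50, 150)
  sites <- tibble::tibble(chrom = "chr1", pos = c(49, 50, 149, 150))
  expect_identical(sites_in_regions(sites, set), c(FALSE, TRUE, TRUE, FALSE))
})
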