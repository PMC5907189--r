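mk_aln <- function(...) {
  rows <- list(...)
  tibble::tibble(
    query_id = vapply(rows, `[[`, "", 1),
    subject = "chr1",
    identity = vapply(rows, function(r) as.numeric(r[[2]]), 0),
    aln_length = 120L, mismatches = 0L, gap_opens = 0L,
    qstart = 1L, qend = 120L, sstart = 1L, send = 120L,
    evalue = vapply(rows, function(r) as.numeric(r[[3]]), 0),
    bitscore = vapply(rows, function(r) as.numeric(r[[4]]), 0),
    chrom = "chr1",
    start = vapply(rows, function(r) as.numeric(r[[5]]), 0),
    end = vapply(rows, function(r) as.numeric(r[[5]]) + 120, 0),
    minus_strand = FALSE
  )
}

test_that("identity/e-value thresholds are inclusive and independent", {
  aln <- mk_aln(
    list("p1", 85.0, 1e-10, 100, 0),     # both exactly at threshold: passes
    list("p2", 84.9, 1e-30, 100, 1000),  # identity fails alone
    list("p3", 99.0, 1e-5, 100, 2000),   # e-value fails alone
    list("p4", 92.0, 1e-30, 150, 3000)
  )
  pass <- filter_alignments(aln, mode = "all")
  expect_setequal(pass$query_id, c("p1", "p4"))
  expect_setequal(attr(pass, "dropped_probes"), c("p2", "p3"))
  # brute-force row-wise predicate agrees
  expect_identical(sort(pass$query_id),
                   sort(aln$query_id[aln$identity >= 85 & aln$evalue <= 1e-10]))
})

test_that("best-hit selection ranks bitscore, then evalue, then identity", {
  aln <- mk_aln(
    list("p1", 90, 1e-20, 100, 0),
    list("p1", 95, 1e-30, 200, 5000),   # highest bitscore wins
    list("p2", 90, 1e-20, 100, 0),
    list("p2", 91, 1e-25, 100, 5000),   # tie bitscore -> lower evalue
    list("p3", 90, 1e-20, 100, 5000),
    list("p3", 92, 1e-20, 100, 0)       # tie bitscore+evalue -> higher identity
  )
  best <- filter_alignments(aln, mode = "best")
  expect_equal(nrow(best), 3)
  expect_equal(best$start[best$query_id == "p1"], 5000)
  expect_equal(best$start[best$query_id == "p2"], 5000)
  expect_equal(best$identity[best$query_id == "p3"], 92)
})

test_that("HPR merges subject intervals and mode=all keeps multiple loci", {
  aln <- mk_aln(list("p1", 95, 1e-20, 100, 100),
                list("p2", 95, 1e-20, 100, 200))
  hpr <- build_hpr(filter_alignments(aln, mode = "best"))
  expect_equal(as.data.frame(hpr), data.frame(chrom = "chr1", start = 100,
                                              end = 320), ignore_attr = TRUE)
  expect_equal(region_total_length(hpr), 220)
  two_loci <- mk_aln(list("p1", 95, 1e-20, 100, 100),
                     list("p1", 90, 1e-15, 90, 10000))
  expect_equal(nrow(build_hpr(filter_alignments(two_loci, mode = "all"))), 2)
  expect_equal(nrow(build_hpr(filter_alignments(two_loci, mode = "best"))), 1)
})

test_that("promoter coverage gate is strictly more-than", {
  prom <- tibble::tibble(gene = c("g60", "g6005", "g100"), chrom = "chr1",
                         start = c(0, 10000, 20000),
                         end = c(2000, 12000, 22000))
  probes <- regions("chr1",
                    c(0, 10000, 20000),
                    c(1200, 11201, 22000))  # 0.600, 0.6005, 1.0
  cov <- promoter_probe_coverage(as_regions(prom), probes)
  expect_equal(cov$covered_fraction, c(0.600, 0.6005, 1.0))
  expect_setequal(covered_gene_symbols(as_regions(prom), probes),
                  c("g6005", "g100"))
})

test_that("OPR keeps only symbols present in the target annotation", {
  target <- gene_models(tibble::tibble(
    gene = c("A", "B", "C"), transcript_id = c("a", "b", "c"),
    chrom = "chr1", strand = "+",
    start = c(10000, 20000, 30000), end = c(14000, 24000, 34000)
  ))
  opr <- build_opr(c("A", "C", "D", "E"), target)
  expect_equal(region_total_length(opr), 4000)  # two 2 kb promoters
  expect_setequal(attr(opr, "matched_symbols"), c("A", "C"))
  expect_setequal(attr(opr, "unmatched_symbols"), c("D", "E"))
  expect_equal(nrow(build_opr(character(), target)), 0)
  # case folding is opt-in
  expect_equal(region_total_length(build_opr("a", target)), 0)
  expect_equal(region_total_length(build_opr("a", target,
                                             ignore_case = TRUE)), 2000)
})

test_that("assembly absorbs contained OPRs and adds disjoint ones", {
  hpr <- regions("chr1", 1000, 5000)
  inside <- regions("chr1", 2000, 3000)
  td <- assemble_target(hpr, inside)
  expect_equal(td$stats$redefined_length, 4000)
  expect_equal(td$stats$opr_added_bases, 0)
  disjoint <- regions("chr1", 10000, 12000)
  td2 <- assemble_target(hpr, disjoint)
  expect_equal(td2$stats$redefined_length, 6000)
  expect_equal(td2$stats$opr_added_bases, 2000)
})

test_that("OPR-added CG sites equal the census of opr minus hpr", {
  withr::local_seed(3)
  seqs <- c(chr1 = random_dna(20000, gc = 0.5))
  sites <- enumerate_cpg_sites(seqs)
  hpr <- as_regions(random_region_set(10, c(chr1 = 20000), 2000))
  opr <- as_regions(random_region_set(10, c(chr1 = 20000), 2000))
  td <- assemble_target(hpr, opr, cpg_sites = sites)
  oracle <- sum(sites_in_regions(sites, subtract_regions(opr, hpr)))
  expect_equal(td$stats$opr_added_cg_sites, oracle)
  expect_equal(td$stats$target_cg_sites,
               sum(sites_in_regions(sites, union_regions(hpr, opr))))
})

test_that("raising the identity threshold never grows the HPR", {
  st <- tiny_study()
  lens <- vapply(seq(80, 95, by = 1), function(idv) {
    p <- pipeline_params(hpr_min_identity = idv)
    region_total_length(build_hpr(filter_alignments(st$alignments, p,
                                                    mode = "all")))
  }, 0)
  expect_true(all(diff(lens) <= 0))
})

test_that("probe mapping rate counts probes with at least one passing hit", {
  st <- tiny_study()
  td <- redefine_target(st$alignments, st$probes)
  truth_rate <- length(unique(st$alignment_truth$query_id[
    st$alignment_truth$pass])) / nrow(st$probes)
  expect_equal(td$stats$probe_mapping_rate, truth_rate)
})
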