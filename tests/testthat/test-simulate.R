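test_that("the same seed reproduces the study byte-for-byte", {
  cfg <- tiny_cfg(seed = 9)
  a <- simulate_study(cfg)
  b <- simulate_study(cfg)
  expect_identical(as.character(a$genome), as.character(b$genome))
  expect_identical(a$alignments, b$alignments)
  expect_identical(a$cx, b$cx)
  expect_identical(a$reads, b$reads)
  c <- simulate_study(tiny_cfg(seed = 10))
  expect_false(identical(as.character(a$genome), as.character(c$genome)))
})

test_that("zero islands yields an empty truth set and no CGI/shore classes", {
  st <- simulate_study(tiny_cfg(seed = 5, n_islands = 0))
  expect_equal(nrow(st$islands), 0)
  expect_equal(nrow(st$truth_classes$CGI), 0)
  expect_equal(nrow(st$truth_classes$SHORE), 0)
  expect_false(any(st$site_truth$class %in% c("CGI", "SHORE", "SHELF")))
})

test_that("the detector recovers planted island bases", {
  st <- tiny_study()
  calls <- find_cgis(st$genome)
  covered <- intersect_regions(st$islands, calls)
  recall <- region_total_length(covered) / region_total_length(st$islands)
  expect_gt(recall, 0.9)
})

test_that("planted alignment labels straddle both filter boundaries", {
  st <- default_study()
  tr <- st$alignment_truth
  expect_gt(sum(tr$pass), 0)
  expect_gt(sum(!tr$pass), 0)
  expect_gt(sum(tr$identity == 85), 0)          # exact identity boundary
  expect_gt(sum(tr$evalue == 1e-10), 0)         # exact e-value boundary
  expect_gt(sum(!tr$pass & tr$identity >= 85), 0)  # fails on e-value alone
  expect_gt(sum(!tr$pass & tr$evalue <= 1e-10), 0) # fails on identity alone
})

test_that("generator promoter truth matches gene_promoters output", {
  st <- tiny_study()
  p_src <- gene_promoters(st$annotation$source, upstream = 2000)
  truth <- st$annotation$genes
  joined <- merge(p_src, truth[, c("gene", "source_tss")], by = "gene")
  expect_equal(joined$tss, joined$source_tss)
  p_tgt <- gene_promoters(st$annotation$target, upstream = 2000)
  tkey <- truth[, c("target_symbol", "target_tss")]
  names(tkey) <- c("gene", "truth_tss")
  joined_t <- merge(p_tgt, tkey, by = "gene")
  expect_equal(nrow(joined_t), nrow(truth))
  expect_equal(joined_t$tss, joined_t$truth_tss)
})

test_that("symbol sharing controls the OPR downstream", {
  none <- simulate_study(tiny_cfg(seed = 21, shared_symbol_fraction = 0))
  src_prom <- gene_promoters(none$annotation$source)
  covered <- covered_gene_symbols(src_prom, none$probes)
  opr <- build_opr(covered, none$annotation$target)
  expect_equal(nrow(opr), 0)
  all_shared <- simulate_study(tiny_cfg(seed = 21, shared_symbol_fraction = 1))
  covered2 <- covered_gene_symbols(gene_promoters(all_shared$annotation$source),
                                   all_shared$probes)
  opr2 <- build_opr(covered2, all_shared$annotation$target)
  expect_equal(length(attr(opr2, "unmatched_symbols")), 0)
  expect_gt(nrow(opr2), 0)
})

test_that("zero sequencing depth propagates to NA class levels", {
  st <- simulate_study(tiny_cfg(seed = 3, depth_mean = 0, offtarget_depth = 0))
  expect_true(all(st$cx$depth == 0))
  calls <- merge_strands(st$cx, enumerate_cpg_sites(st$genome))
  cm <- class_methylation(calls, st$truth_classes, min_depth = 5)
  expect_true(all(is.na(cm$mean_level)))
})

test_that("written study files parse back to the in-memory objects", {
  dir <- withr::local_tempdir()
  st <- simulate_study(tiny_cfg(seed = 13), dir = dir)
  g <- read_genome_fasta(st$files$fasta)
  expect_identical(as.character(g), as.character(st$genome))
  aln <- read_blast8(st$files$blast8)
  expect_equal(nrow(aln), nrow(st$alignments))
  expect_equal(aln$identity, st$alignments$identity)
  expect_equal(aln$evalue, st$alignments$evalue)
  expect_equal(aln$start, st$alignments$start)
  cx <- read_cytosine_report(st$files$cx_report)
  expect_equal(nrow(cx), nrow(st$cx))
  expect_equal(sum(cx$meth), sum(st$cx$meth))
  m <- read_gtf(st$files$target_gtf)
  expect_setequal(unique(m$transcripts$gene),
                  unique(st$annotation$genes$target_symbol))
  probes <- read_bed(st$files$probes_bed)
  expect_equal(nrow(probes), nrow(st$probes))
})
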