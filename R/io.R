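#' Read a genome FASTA
#'
#' Sequences are uppercased (soft-masked lowercase bases are treated as normal
#' sequence) and duplicate headers are rejected. Header text after the first
#' whitespace is dropped, as is conventional for sequence names.
#'
#' @param path Path to a FASTA file.
#' @return A named [Biostrings::DNAStringSet].
#' @export
read_genome_fasta <- function(path) {
  if (!file.exists(path)) abort(paste0("FASTA not found: ", path))
  dss <- Biostrings::readDNAStringSet(path)
  nm <- sub("\\s.*$", "", names(dss))
  if (anyDuplicated(nm)) {
    abort(paste0("duplicate FASTA header(s): ",
                 paste(unique(nm[duplicated(nm)]), collapse = ", ")))
  }
  if (any(Biostrings::width(dss) == 0)) {
    abort(paste0("empty sequence for header(s): ",
                 paste(nm[Biostrings::width(dss) == 0], collapse = ", ")))
  }
  seqs <- toupper(as.character(dss))
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- nm
  out
}

#' Chromosome lengths of a genome
#'
#' @param genome A [Biostrings::DNAStringSet] or named character vector of
#'   sequences, or an already-named numeric vector of lengths (returned as is).
#' @return Named numeric vector of sequence lengths (bp).
#' @export
chrom_lengths <- function(genome) {
  if (is.numeric(genome)) {
    if (is.null(names(genome))) abort("lengths must be named by chromosome")
    return(genome)
  }
  if (methods::is(genome, "DNAStringSet")) {
    return(setNames(as.numeric(Biostrings::width(genome)), names(genome)))
  }
  if (is.character(genome)) {
    if (is.null(names(genome))) abort("character genome must be named")
    return(setNames(nchar(genome), names(genome)))
  }
  abort("cannot derive chromosome lengths from this object")
}

as_genome_seqs <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) {
    setNames(as.character(genome), names(genome))
  } else if (is.character(genome)) {
    if (is.null(names(genome))) abort("character genome must be named")
    toupper(genome)
  } else {
    abort("genome must be a DNAStringSet or named character vector")
  }
}

#' Read / write BED intervals
#'
#' BED3/BED6, tab-separated, 0-based half-open — the package's native interval
#' convention, so no coordinate shift is applied. Lines starting with `#`,
#' `track` or `browser` are skipped (and counted). `write_bed()` emits BED3
#' plus any of `name`, `score`, `strand` present, with `.` placeholders where
#' a later column is present but an earlier one is not.
#'
#' @param path File path.
#' @param genome Optional genome identifier to attach (see [regions()]).
#' @return `read_bed()`: a region tibble. `write_bed()`: `path`, invisibly.
#' @export
read_bed <- function(path, genome = NULL) {
  if (!file.exists(path)) abort(paste0("BED not found: ", path))
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(lines)
  lines <- lines[keep]
  if (length(lines) == 0) return(empty_regions(genome))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(parts)
  if (any(ncols < 3)) {
    abort(paste0("BED line ", which(keep)[which(ncols < 3)[1]],
                 ": fewer than 3 columns"))
  }
  nmax <- min(max(ncols), 6)
  x <- tibble(
    chrom = vapply(parts, `[`, "", 1),
    start = suppressWarnings(as.numeric(vapply(parts, `[`, "", 2))),
    end = suppressWarnings(as.numeric(vapply(parts, `[`, "", 3)))
  )
  if (anyNA(x$start) | anyNA(x$end)) {
    bad <- which(is.na(x$start) | is.na(x$end))[1]
    abort(paste0("BED line ", which(keep)[bad], ": non-numeric start/end"))
  }
  if (nmax >= 4) x$name <- vapply(parts, function(p) if (length(p) >= 4) p[4] else ".", "")
  if (nmax >= 5) x$score <- suppressWarnings(as.numeric(vapply(parts, function(p) if (length(p) >= 5) p[5] else "0", "")))
  if (nmax >= 6) x$strand <- vapply(parts, function(p) if (length(p) >= 6) p[6] else "*", "")
  as_regions(x, genome = genome)
}

#' @param x Region tibble to write.
#' @rdname read_bed
#' @export
write_bed <- function(x, path) {
  x <- as_regions(x, genome = region_genome(x))
  cols <- c("chrom", "start", "end")
  opt <- intersect(c("name", "score", "strand"), names(x))
  if (length(opt) > 0) {
    upto <- max(match(opt, c("name", "score", "strand")))
    full <- c("name", "score", "strand")[seq_len(upto)]
    for (cn in setdiff(full, names(x))) {
      x[[cn]] <- if (cn == "score") 0 else "."
    }
    cols <- c(cols, full)
  }
  out <- x[, cols]
  out$start <- format_bp(out$start)
  out$end <- format_bp(out$end)
  readr::write_tsv(out, path, col_names = FALSE, na = ".")
  invisible(path)
}

format_bp <- function(v) format(v, scientific = FALSE, trim = TRUE)

#' Read blast8 tabular alignments
#'
#' The 12-column tab-separated format produced by `blat -out=blast8` (and
#' `blastn -outfmt 6`): query, subject, percent identity, alignment length,
#' mismatches, gap opens, qstart, qend, sstart, send (1-based inclusive),
#' e-value, bit score. `#` comment lines are skipped and counted. Subject
#' coordinates are normalised to 0-based half-open `start`/`end` columns with
#' `minus_strand = TRUE` when `sstart > send`; the set algebra downstream
#' ignores the flag because capture is strand-agnostic.
#'
#' @param path File path.
#' @return Tibble of alignment records with normalised `chrom`, `start`,
#'   `end`, `minus_strand` columns alongside the raw fields.
#' @export
read_blast8 <- function(path) {
  if (!file.exists(path)) abort(paste0("blast8 not found: ", path))
  lines <- readLines(path)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  body <- lines[keep]
  if (length(body) == 0) {
    return(tibble(query_id = character(), subject = character(),
                  identity = numeric(), aln_length = integer(),
                  mismatches = integer(), gap_opens = integer(),
                  qstart = integer(), qend = integer(),
                  sstart = integer(), send = integer(),
                  evalue = numeric(), bitscore = numeric(),
                  chrom = character(), start = numeric(), end = numeric(),
                  minus_strand = logical()))
  }
  parts <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 12)
  if (length(bad) > 0) {
    abort(paste0("blast8 line ", which(keep)[bad[1]],
                 ": expected 12 tab-separated columns, got ",
                 lengths(parts)[bad[1]]))
  }
  col <- function(i) vapply(parts, `[`, "", i)
  num <- function(i, what) {
    v <- suppressWarnings(as.numeric(col(i)))
    if (anyNA(v)) {
      abort(paste0("blast8 line ", which(keep)[which(is.na(v))[1]],
                   ": non-numeric ", what))
    }
    v
  }
  x <- tibble(
    query_id = col(1), subject = col(2),
    identity = num(3, "identity"), aln_length = as.integer(num(4, "length")),
    mismatches = as.integer(num(5, "mismatches")),
    gap_opens = as.integer(num(6, "gap opens")),
    qstart = as.integer(num(7, "qstart")), qend = as.integer(num(8, "qend")),
    sstart = as.integer(num(9, "sstart")), send = as.integer(num(10, "send")),
    evalue = num(11, "evalue"), bitscore = num(12, "bitscore")
  )
  bad <- which(x$identity < 0 | x$identity > 100 | x$evalue < 0 |
                 x$aln_length < 1)
  if (length(bad) > 0) {
    abort(paste0("blast8 line ", which(keep)[bad[1]],
                 ": identity/evalue/length out of range"))
  }
  x$minus_strand <- x$sstart > x$send
  x$chrom <- x$subject
  x$start <- as.numeric(ifelse(x$minus_strand, x$send, x$sstart)) - 1
  x$end <- as.numeric(ifelse(x$minus_strand, x$sstart, x$send))
  x
}

#' Read gene models from a GTF file
#'
#' Transcripts are grouped by gene symbol (`gene_name` attribute when present,
#' falling back to `gene_id`). Transcript spans are derived from exon extent,
#' and all 1-based closed GTF coordinates are converted to 0-based half-open.
#'
#' @param path Path to a GTF (or GFF) file readable by
#'   [rtracklayer::import()].
#' @return A `gene_models` object: list of tibbles `transcripts`
#'   (gene, transcript_id, chrom, strand, start, end), `exons` and `cds`.
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) abort(paste0("GTF not found: ", path))
  gr <- rtracklayer::import(path)
  mc <- S4Vectors::mcols(gr)
  type <- as.character(mc$type)
  sel <- type %in% c("exon", "CDS")
  gr <- gr[sel]
  mc <- S4Vectors::mcols(gr)
  if (length(gr) == 0) abort("GTF contains no exon or CDS features")
  tx <- as.character(mc$transcript_id)
  if (is.null(mc$transcript_id) || anyNA(tx) || any(tx == "")) {
    abort("exon/CDS feature without transcript_id attribute")
  }
  gene_id <- if (!is.null(mc$gene_id)) as.character(mc$gene_id) else NA_character_
  gene_name <- if (!is.null(mc$gene_name)) as.character(mc$gene_name) else rep(NA_character_, length(gr))
  symbol <- ifelse(is.na(gene_name) | gene_name == "", gene_id, gene_name)
  if (anyNA(symbol)) abort("feature with neither gene_name nor gene_id")
  strand <- as.character(GenomicRanges::strand(gr))
  if (any(strand == "*")) abort("exon/CDS feature with unknown strand")
  feats <- tibble(
    gene = symbol,
    transcript_id = tx,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = strand,
    start = GenomicRanges::start(gr) - 1,
    end = GenomicRanges::end(gr),
    type = as.character(S4Vectors::mcols(gr)$type)
  )
  gene_models_from_features(feats)
}

gene_models_from_features <- function(feats) {
  exons <- feats %>% filter(.data$type == "exon") %>% select(-"type")
  cds <- feats %>% filter(.data$type == "CDS") %>% select(-"type")
  if (nrow(exons) == 0) abort("annotation has no exon features")
  transcripts <- exons %>%
    group_by(.data$gene, .data$transcript_id, .data$chrom, .data$strand) %>%
    summarise(start = min(.data$start), end = max(.data$end),
              n_exons = dplyr::n(), .groups = "drop") %>%
    arrange(.data$chrom, .data$start)
  multi <- transcripts %>%
    group_by(.data$gene) %>%
    summarise(n_chrom = dplyr::n_distinct(.data$chrom), .groups = "drop") %>%
    filter(.data$n_chrom > 1)
  out <- structure(
    list(transcripts = transcripts, exons = as_tibble(exons),
         cds = as_tibble(cds)),
    class = "gene_models"
  )
  attr(out, "multi_locus_genes") <- multi$gene
  if (nrow(multi) > 0) {
    inform(paste0(nrow(multi), " gene symbol(s) span multiple chromosomes: ",
                  paste(head(multi$gene, 5), collapse = ", ")))
  }
  out
}

#' Build gene models from tidy feature tables
#'
#' In-memory counterpart of [read_gtf()], mainly used by the synthetic-study
#' generator and tests.
#'
#' @param exons,cds Tibbles with columns `gene`, `transcript_id`, `chrom`,
#'   `strand`, `start`, `end` (0-based half-open).
#' @return A `gene_models` object.
#' @export
gene_models <- function(exons, cds = NULL) {
  if (is.null(cds)) cds <- exons[0, ]
  feats <- bind_rows(mutate(as_tibble(exons), type = "exon"),
                     mutate(as_tibble(cds), type = "CDS"))
  gene_models_from_features(feats)
}

#' @export
print.gene_models <- function(x, ...) {
  cat("<gene_models> ", dplyr::n_distinct(x$transcripts$gene), " genes, ",
      nrow(x$transcripts), " transcripts, ", nrow(x$exons), " exons, ",
      nrow(x$cds), " CDS segments\n", sep = "")
  invisible(x)
}

#' Read a Bismark-style cytosine report
#'
#' Seven tab-separated columns: chromosome, 1-based position, strand (+/-),
#' methylated count, unmethylated count, context (CG/CHG/CHH), trinucleotide.
#' Positions are converted to 0-based; a `depth` column and an `is_cpg` flag
#' (context `CG` or `CpG`) are added. Zero-depth rows are retained — depth
#' filtering happens at summarisation time.
#'
#' @param path File path.
#' @return Tibble with columns `chrom`, `pos` (0-based), `strand`, `meth`,
#'   `unmeth`, `context`, `tricontext`, `depth`, `is_cpg`.
#' @export
read_cytosine_report <- function(path) {
  if (!file.exists(path)) abort(paste0("cytosine report not found: ", path))
  x <- readr::read_tsv(
    path,
    col_names = c("chrom", "pos", "strand", "meth", "unmeth", "context",
                  "tricontext"),
    col_types = readr::cols(
      chrom = readr::col_character(), pos = readr::col_double(),
      strand = readr::col_character(), meth = readr::col_double(),
      unmeth = readr::col_double(), context = readr::col_character(),
      tricontext = readr::col_character()
    ),
    comment = "#", progress = FALSE, lazy = FALSE
  )
  pr <- readr::problems(x)
  if (nrow(pr) > 0) {
    abort(paste0("cytosine report line ", pr$row[1], ": ", pr$expected[1],
                 " but got '", pr$actual[1], "'"))
  }
  bad <- which(!(x$strand %in% c("+", "-")))
  if (length(bad) > 0) {
    abort(paste0("cytosine report line ", bad[1], ": bad strand '",
                 x$strand[bad[1]], "'"))
  }
  bad <- which(x$meth < 0 | x$unmeth < 0 | is.na(x$meth) | is.na(x$unmeth))
  if (length(bad) > 0) {
    abort(paste0("cytosine report line ", bad[1], ": negative/missing counts"))
  }
  x %>%
    mutate(pos = .data$pos - 1,
           depth = .data$meth + .data$unmeth,
           is_cpg = .data$context %in% c("CG", "CpG"))
}

# TSV with '#' metadata header lines (version, seed, parameter echo); used by
# the pipeline so outputs are self-describing yet byte-reproducible.
write_tsv_with_header <- function(x, path, meta = character()) {
  hdr <- c(paste0("# methlift ", as.character(packageVersion("methlift"))),
           paste0("# ", meta))
  writeLines(hdr, path)
  readr::write_tsv(x, path, append = TRUE, col_names = TRUE)
  invisible(path)
}
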