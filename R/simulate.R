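#' Synthetic methyl-capture study configuration
#'
#' Defines the conditions of the simulated cross-species capture experiment:
#' a CpG-depleted background genome with dense planted CpG islands hosted
#' inside gene introns, a source/target annotation pair sharing a fraction of
#' gene symbols, a probe panel tiling islands (with shore/shelf flanks),
#' promoters, exons and scattered DMR-like intergenic targets, blast8-style
#' probe alignments whose identities straddle the 85% / 1e-10 filter, 101-bp
#' de-duplicated read intervals, and a beta-binomial cytosine report with a
#' planted monotone methylation gradient (CGI 0.10 < promoter 0.20 <
#' shore 0.40 < shelf 0.60 < exon 0.75 < intergenic 0.80) at ~30x
#' strand-merged capture depth.
#'
#' Region classes are pairwise disjoint by construction (islands live inside
#' large introns, DMR targets in clear intergenic space) so that every CpG
#' site has an unambiguous planted class; real genomes violate this (promoter
#' CpG islands are common).
#'
#' @param seed Integer seed; the whole fixture bundle is reproducible from it.
#' @param n_chroms,chrom_length Genome shape (default 2 x 2.5 Mb).
#' @param background_gc Background GC fraction (default 0.40; background CpG
#'   density is then (GC/2)^2 = 4% per bp).
#' @param n_genes Total genes across chromosomes.
#' @param gene_span Genomic span of each gene, bp.
#' @param max_tx_per_gene Transcripts are drawn uniformly from 1..this.
#' @param n_islands Number of planted islands (each hosted by one gene).
#' @param island_length,island_cg_density Island geometry: length in bp and
#'   the per-dinucleotide-slot probability of an exact CG.
#' @param n_dmr_targets,dmr_length Intergenic probe-target segments.
#' @param shared_symbol_fraction Fraction of gene symbols shared between the
#'   source and target annotations.
#' @param probe_length Capture probe length, bp (120).
#' @param promoter_cover_range Range of the per-promoter fraction tiled by
#'   probes (panels cover promoters only partially).
#' @param p_conserved Probability a probe locus is conserved (primary
#'   alignment identity drawn from `conserved_identity`, else
#'   `diverged_identity`).
#' @param conserved_identity,diverged_identity Identity ranges (percent).
#' @param p_boundary_identity,p_boundary_evalue Probability of planting an
#'   exact boundary value (identity 85.0, e-value 1e-10) on a record.
#' @param p_lost Probability a diverged probe yields no primary alignment.
#' @param class_means Named planted methylation means per region class.
#' @param dispersion Beta overdispersion rho in `[0, 1)`; per-site true
#'   levels are Beta with the class mean and `a + b = (1 - rho) / rho`
#'   (0 means every site sits exactly at the class mean).
#' @param depth_mean Mean strand-merged depth over captured sites (per-strand
#'   depths are independent Poisson halves).
#' @param offtarget_depth Mean strand-merged depth outside captured regions.
#' @param read_length Read length, bp (101).
#' @param n_reads Number of de-duplicated read intervals to emit.
#' @param read_on_target Fraction of reads drawn from captured regions (the
#'   remainder is uniform, so the measured on-target rate is slightly
#'   higher).
#' @param promoter_upstream,shore_width,shelf_width Region geometry, bp.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(seed = 1,
                         n_chroms = 2, chrom_length = 2.5e6,
                         background_gc = 0.40,
                         n_genes = 120, gene_span = 20000,
                         max_tx_per_gene = 3,
                         n_islands = 60, island_length = 800,
                         island_cg_density = 0.5,
                         n_dmr_targets = 120, dmr_length = 1000,
                         shared_symbol_fraction = 0.8,
                         probe_length = 120,
                         promoter_cover_range = c(0.3, 1.0),
                         p_conserved = 0.6,
                         conserved_identity = c(88, 99.5),
                         diverged_identity = c(72, 84.5),
                         p_boundary_identity = 0.05,
                         p_boundary_evalue = 0.05,
                         p_lost = 0.3,
                         class_means = c(CGI = 0.10, PROMOTER = 0.20,
                                         SHORE = 0.40, SHELF = 0.60,
                                         EXON = 0.75, INTERGENIC = 0.80),
                         dispersion = 0.05,
                         depth_mean = 30, offtarget_depth = 1,
                         read_length = 101, n_reads = 20000,
                         read_on_target = 0.85,
                         promoter_upstream = 2000,
                         shore_width = 2000, shelf_width = 2000) {
  stopifnot(all(class_means >= 0 & class_means <= 1),
            depth_mean >= 0, dispersion >= 0, dispersion < 1,
            n_islands <= n_genes || n_genes == 0,
            island_length %% 2 == 0)
  structure(as.list(environment()), class = "synth_config")
}

chrom_names <- function(config) paste0("chr", seq_len(config$n_chroms))

# Deterministic layout: gene slots on a jittered grid, islands hosted in the
# central intron, DMR targets rejected-sampled into free space.
sim_layout <- function(config) {
  set.seed(config$seed + 1L)
  cn <- chrom_names(config)
  per <- rep(config$n_genes %/% config$n_chroms, config$n_chroms)
  if (config$n_genes %% config$n_chroms > 0) {
    per[seq_len(config$n_genes %% config$n_chroms)] <-
      per[seq_len(config$n_genes %% config$n_chroms)] + 1
  }
  gap <- 2000
  margin <- 10000
  slot <- config$gene_span + 2 * config$promoter_upstream + 2 * gap
  genes <- purrr::map2(cn, per, function(ch, n) {
    if (n == 0) return(NULL)
    usable <- config$chrom_length - 2 * margin
    if (n * slot > usable) {
      abort("chromosome too short for the requested number of genes")
    }
    free <- usable - n * slot
    gaps <- as.vector(rmultinom(1, free, rep(1, n + 1)))
    slot_start <- margin + cumsum(gaps)[seq_len(n)] + (seq_len(n) - 1) * slot
    start <- slot_start + gap + config$promoter_upstream
    tibble(chrom = ch, start = start, end = start + config$gene_span,
           strand = sample(c("+", "-"), n, replace = TRUE))
  })
  genes <- bind_rows(genes)
  if (nrow(genes) > 0) {
    genes$gene <- sprintf("GENE%04d", seq_len(nrow(genes)))
    host <- rep(FALSE, nrow(genes))
    if (config$n_islands > 0) {
      host[sample(nrow(genes), config$n_islands)] <- TRUE
    }
    genes$hosts_island <- host
    off <- round((config$gene_span - config$island_length) / 2)
    flank <- config$shore_width + config$shelf_width
    exon1_end <- round(0.02 * config$gene_span)
    exon2_start <- round(0.90 * config$gene_span)
    if (config$n_islands > 0 &&
        (off - flank <= exon1_end ||
         off + config$island_length + flank >= exon2_start)) {
      abort("gene_span too small to host an island with its shore/shelf flanks clear of exons")
    }
    genes$island_start <- ifelse(host, genes$start + off, NA_real_)
    genes$island_end <- ifelse(host, genes$island_start + config$island_length,
                               NA_real_)
  } else if (config$n_islands > 0) {
    # no genes: islands straight onto the grid
    isl <- purrr::map(cn, function(ch) {
      n <- config$n_islands %/% config$n_chroms +
        as.integer(match(ch, cn) <= config$n_islands %% config$n_chroms)
      if (n == 0) return(NULL)
      pitch <- (config$chrom_length - 2 * margin) / n
      start <- round(margin + pitch * (seq_len(n) - 1) + pitch / 2)
      tibble(chrom = ch, start = start, end = start + config$island_length)
    })
    genes <- tibble(chrom = character(), start = numeric(), end = numeric(),
                    strand = character(), gene = character(),
                    hosts_island = logical(), island_start = numeric(),
                    island_end = numeric())
    attr(genes, "free_islands") <- bind_rows(isl)
  }
  islands <- if (nrow(genes) > 0) {
    genes %>%
      filter(.data$hosts_island) %>%
      transmute(chrom = .data$chrom, start = .data$island_start,
                end = .data$island_end) %>%
      arrange(.data$chrom, .data$start)
  } else {
    fi <- attr(genes, "free_islands")
    if (is.null(fi)) tibble(chrom = character(), start = numeric(),
                            end = numeric()) else fi
  }
  # DMR-like intergenic probe targets, kept clear of gene slots and islands
  occupied <- bind_rows(
    if (nrow(genes) > 0) {
      tibble(chrom = genes$chrom,
             start = genes$start - config$promoter_upstream - 500,
             end = genes$end + config$promoter_upstream + 500)
    },
    if (nrow(islands) > 0) {
      tibble(chrom = islands$chrom,
             start = islands$start - config$shore_width -
               config$shelf_width - 500,
             end = islands$end + config$shore_width +
               config$shelf_width + 500)
    }
  )
  if (nrow(occupied) == 0) {
    occupied <- tibble(chrom = character(), start = numeric(),
                       end = numeric())
  }
  dmrs <- list()
  if (config$n_dmr_targets > 0) {
    occ_ch <- occupied$chrom
    occ_s <- pmax(0, occupied$start)
    occ_e <- occupied$end
    for (k in seq_len(config$n_dmr_targets)) {
      placed <- FALSE
      for (try in 1:200) {
        ch <- sample(cn, 1)
        s <- floor(runif(1, 1000, config$chrom_length - config$dmr_length - 1000))
        cs <- s - 500
        ce <- s + config$dmr_length + 500
        sel <- occ_ch == ch
        if (!any(sel & occ_s < ce & cs < occ_e)) {
          dmrs[[k]] <- tibble(chrom = ch, start = s,
                              end = s + config$dmr_length)
          occ_ch <- c(occ_ch, ch); occ_s <- c(occ_s, cs); occ_e <- c(occ_e, ce)
          placed <- TRUE
          break
        }
      }
      if (!placed) abort("could not place DMR target after 200 tries; genome too crowded")
    }
  }
  dmrs <- if (length(dmrs) > 0) {
    arrange(bind_rows(dmrs), .data$chrom, .data$start)
  } else {
    tibble(chrom = character(), start = numeric(), end = numeric())
  }
  list(genes = genes, islands = islands, dmrs = dmrs)
}

#' Generate the synthetic genome
#'
#' I.i.d. background bases at `background_gc` with dense CG-rich islands
#' overwritten at the planted coordinates.
#'
#' @param config A [synth_config()].
#' @param layout Internal layout (computed from `config` when omitted).
#' @return List with `genome` (a [Biostrings::DNAStringSet]) and `islands`
#'   (truth region tibble).
#' @export
sim_genome <- function(config, layout = NULL) {
  if (is.null(layout)) layout <- sim_layout(config)
  set.seed(config$seed + 2L)
  gc <- config$background_gc
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seqs <- vapply(chrom_names(config), function(ch) {
    v <- sample(names(probs), config$chrom_length, replace = TRUE,
                prob = probs)
    isl <- layout$islands[layout$islands$chrom == ch, ]
    if (nrow(isl) > 0) {
      for (i in seq_len(nrow(isl))) {
        len <- isl$end[i] - isl$start[i]
        v[(isl$start[i] + 1):isl$end[i]] <- island_sequence(len, config)
      }
    }
    paste(v, collapse = "")
  }, "")
  genome <- Biostrings::DNAStringSet(seqs)
  names(genome) <- chrom_names(config)
  list(genome = genome, islands = layout$islands)
}

island_sequence <- function(len, config) {
  n_slot <- len %/% 2
  is_cg <- runif(n_slot) < config$island_cg_density
  first <- ifelse(is_cg, "C", sample(c("A", "C", "G", "T"), n_slot,
                                     replace = TRUE))
  second <- ifelse(is_cg, "G", sample(c("A", "C", "G", "T"), n_slot,
                                      replace = TRUE))
  as.vector(rbind(first, second))
}

#' Generate source and target annotations
#'
#' Each gene gets 1..`max_tx_per_gene` transcripts; the longest spans the
#' whole gene. The target annotation reuses the gene loci with the TSS
#' jittered by up to 200 bp and shares `shared_symbol_fraction` of the gene
#' symbols (the rest become species-specific `LOC` identifiers), which is
#' what makes orthologous-promoter matching non-trivial.
#'
#' @inheritParams sim_genome
#' @return List with `source` and `target` (`gene_models`), the matching
#'   feature tibbles `source_feats` / `target_feats` (GTF-writable), and a
#'   `genes` truth tibble.
#' @export
sim_annotation <- function(config, layout = NULL) {
  if (is.null(layout)) layout <- sim_layout(config)
  set.seed(config$seed + 3L)
  genes <- layout$genes
  if (nrow(genes) == 0) {
    abort("annotation requires n_genes > 0")
  }
  n <- nrow(genes)
  shared <- rep(FALSE, n)
  shared[sample(n, round(config$shared_symbol_fraction * n))] <- TRUE
  tss_jitter <- sample(-200:200, n, replace = TRUE)
  n_tx <- sample(config$max_tx_per_gene, n, replace = TRUE)

  build_feats <- function(which) {
    purrr::map(seq_len(n), function(i) {
      g <- genes[i, ]
      span <- g$end - g$start
      exlen <- round(0.02 * span)
      sym <- if (which == "source" || shared[i]) g$gene else
        sprintf("LOC%05d", 90000 + i)
      s0 <- g$start
      e0 <- g$end
      if (which == "target") {
        if (g$strand == "+") s0 <- s0 + tss_jitter[i] else e0 <- e0 + tss_jitter[i]
      }
      # terminal exons anchored at the (possibly jittered) transcript ends so
      # that the TSS is exon-derived; middle exon fixed inside the span
      anchor <- tibble(
        start = c(s0, g$start + round(0.90 * span), e0 - exlen),
        end = c(s0 + exlen, g$start + round(0.92 * span), e0)
      )
      txs <- purrr::map(seq_len(n_tx[i]), function(k) {
        if (k == 1) {
          ts <- s0; te <- e0
        } else if (g$strand == "+") {
          ts <- s0 + 500 + (k - 1) * 1500; te <- e0
        } else {
          ts <- s0; te <- e0 - 500 - (k - 1) * 1500
        }
        ex <- tibble(start = pmax(anchor$start, ts),
                     end = pmin(anchor$end, te)) %>%
          filter(.data$start < .data$end)
        if (nrow(ex) == 0) return(NULL)
        tid <- sprintf("%s.t%d", sym, k)
        exon_rows <- tibble(gene = sym, transcript_id = tid,
                            chrom = g$chrom, strand = g$strand,
                            start = ex$start, end = ex$end, type = "exon")
        cds_rows <- if (k == 1) {
          tibble(gene = sym, transcript_id = tid, chrom = g$chrom,
                 strand = g$strand,
                 start = ex$start + 100, end = ex$end - 100,
                 type = "CDS") %>%
            filter(.data$start < .data$end)
        } else {
          NULL
        }
        bind_rows(exon_rows, cds_rows)
      })
      bind_rows(txs)
    }) %>% bind_rows()
  }
  source_feats <- build_feats("source")
  target_feats <- build_feats("target")
  truth <- genes %>%
    mutate(shared_symbol = shared,
           target_symbol = ifelse(shared, .data$gene,
                                  sprintf("LOC%05d", 90000 + seq_len(n))),
           source_tss = ifelse(.data$strand == "+", .data$start, .data$end),
           target_tss = ifelse(.data$strand == "+",
                               .data$start + tss_jitter,
                               .data$end + tss_jitter))
  list(
    source = gene_models_from_features(source_feats),
    target = gene_models_from_features(target_feats),
    source_feats = source_feats,
    target_feats = target_feats,
    genes = truth
  )
}

#' Generate the probe panel and its blast8 alignments
#'
#' Probes tile the island windows (island plus shore and shelf flanks), a
#' random fraction of each source promoter, the exons and the DMR targets.
#' Every probe locus is conserved with probability `p_conserved`; conserved
#' loci get a high-identity primary alignment at (roughly) their own
#' coordinates, diverged loci a sub-threshold one (or none), and 0-2
#' paralog-like secondary hits are added elsewhere. Identities and e-values
#' straddle the 85% / 1e-10 filter, with occasional exact boundary values,
#' and each record carries an independent truth label for whether it passes.
#'
#' @inheritParams sim_genome
#' @param annotation Output of [sim_annotation()].
#' @return List with `probes` (region tibble with `name`), `alignments`
#'   (blast8-shaped tibble), `truth` (per-record `query_id`, `pass`), and
#'   `capture` (padded captureable regions used for depth planting).
#' @export
sim_probes_alignments <- function(config, layout = NULL, annotation = NULL) {
  if (is.null(layout)) layout <- sim_layout(config)
  if (is.null(annotation)) annotation <- sim_annotation(config, layout)
  set.seed(config$seed + 4L)
  pl <- config$probe_length
  tile <- function(x, frac = NULL) {
    if (nrow(x) == 0) return(NULL)
    purrr::pmap(list(x$chrom, x$start, x$end,
                     if (is.null(frac)) rep(1, nrow(x)) else frac),
                function(ch, s, e, f) {
      len <- max(pl, floor((e - s) * f))
      starts <- seq(s, s + len - 1, by = pl)
      starts <- starts[starts + pl <= e | starts == s]
      tibble(chrom = ch, start = starts, end = starts + pl)
    }) %>% bind_rows()
  }
  flank <- config$shore_width + config$shelf_width
  island_windows <- if (nrow(layout$islands) > 0) {
    tibble(chrom = layout$islands$chrom,
           start = layout$islands$start - flank,
           end = layout$islands$end + flank)
  } else {
    tibble(chrom = character(), start = numeric(), end = numeric())
  }
  src_prom <- gene_promoters(annotation$source,
                             upstream = config$promoter_upstream)
  cover <- runif(nrow(src_prom), config$promoter_cover_range[1],
                 config$promoter_cover_range[2])
  # tile from the TSS-proximal end of each promoter
  prom_tiles <- purrr::pmap(list(src_prom$chrom, src_prom$start,
                                 src_prom$end, src_prom$strand, cover),
                            function(ch, s, e, st, f) {
    len <- max(pl, floor((e - s) * f))
    if (st == "+") {
      starts <- seq(e - len, e - pl, by = pl)
    } else {
      starts <- seq(s, s + len - pl, by = pl)
    }
    tibble(chrom = ch, start = starts, end = starts + pl)
  }) %>% bind_rows()
  exons <- annotation$source$exons %>%
    distinct(.data$chrom, .data$start, .data$end)
  probes <- bind_rows(tile(island_windows), prom_tiles, tile(exons),
                      tile(layout$dmrs)) %>%
    distinct(.data$chrom, .data$start, .data$end) %>%
    arrange(.data$chrom, .data$start)
  probes$name <- sprintf("probe%06d", seq_len(nrow(probes)))
  probes$promoter_cover <- NULL
  attr(probes, "promoter_cover_fraction") <-
    tibble(gene = src_prom$gene, planned_fraction = cover)

  np <- nrow(probes)
  conserved <- runif(np) < config$p_conserved
  lost <- !conserved & runif(np) < config$p_lost
  mk_evalue <- function(identity) {
    ev <- 10^(-((identity - 75) + runif(length(identity), -1, 1)))
    exact <- runif(length(identity)) < config$p_boundary_evalue
    ev[exact] <- 1e-10
    pmin(ev, 10)
  }
  primary_id <- ifelse(conserved,
                       runif(np, config$conserved_identity[1],
                             config$conserved_identity[2]),
                       runif(np, config$diverged_identity[1],
                             config$diverged_identity[2]))
  exact_id <- runif(np) < config$p_boundary_identity
  primary_id[exact_id] <- 85.0
  shift <- sample(-5:5, np, replace = TRUE)
  aln_len <- pl - sample(0:10, np, replace = TRUE)
  primary <- tibble(
    query_id = probes$name,
    subject = probes$chrom,
    identity = round(primary_id, 2),
    aln_length = aln_len,
    start = probes$start + shift,
    end = probes$start + shift + aln_len,
    evalue = signif(mk_evalue(round(primary_id, 2)), 3),
    bitscore = round(aln_len * primary_id / 100 * 1.9, 1)
  )[!lost, ]
  n_extra <- sample(0:2, np, replace = TRUE, prob = c(0.6, 0.3, 0.1))
  idx <- rep(seq_len(np), n_extra)
  ne <- length(idx)
  extra <- NULL
  if (ne > 0) {
    eid <- runif(ne, 70, 88)
    elen <- sample(40:pl, ne, replace = TRUE)
    ech <- sample(chrom_names(config), ne, replace = TRUE)
    es <- floor(runif(ne, 0, config$chrom_length - pl - 1))
    extra <- tibble(
      query_id = probes$name[idx],
      subject = ech,
      identity = round(eid, 2),
      aln_length = elen,
      start = es,
      end = es + elen,
      evalue = signif(mk_evalue(round(eid, 2)), 3),
      bitscore = round(elen * eid / 100 * 1.9, 1)
    )
  }
  aln <- bind_rows(primary, extra) %>% arrange(.data$query_id, desc(.data$bitscore))
  aln$minus_strand <- runif(nrow(aln)) < 0.3
  aln <- aln %>%
    mutate(chrom = .data$subject,
           mismatches = as.integer(round(.data$aln_length *
                                           (1 - .data$identity / 100))),
           gap_opens = 0L,
           qstart = 1L, qend = .data$aln_length,
           sstart = as.integer(ifelse(.data$minus_strand, .data$end,
                                      .data$start + 1)),
           send = as.integer(ifelse(.data$minus_strand, .data$start + 1,
                                    .data$end))) %>%
    select("query_id", "subject", "identity", "aln_length", "mismatches",
           "gap_opens", "qstart", "qend", "sstart", "send", "evalue",
           "bitscore", "chrom", "start", "end", "minus_strand")
  truth <- tibble(
    query_id = aln$query_id,
    identity = aln$identity,
    evalue = aln$evalue,
    pass = aln$identity >= 85 & aln$evalue <= 1e-10
  )
  # hybridization model: only loci homologous enough (>= 80% identity) are
  # pulled down; designed loci whose sequence diverged further capture nothing
  capturable <- aln %>% filter(.data$identity >= 80) %>%
    select("chrom", "start", "end")
  capture <- merge_regions(as_regions(capturable))
  capture <- merge_regions(mutate(capture,
                                  start = pmax(0, .data$start - 100),
                                  end = pmin(config$chrom_length,
                                             .data$end + 100)))
  list(probes = probes, alignments = aln, truth = truth, capture = capture)
}

#' Generate de-duplicated read intervals
#'
#' `read_on_target` of the reads start inside captured regions (chosen
#' proportionally to region length); the rest are uniform over the genome.
#'
#' @inheritParams sim_genome
#' @param capture Region tibble of captureable loci
#'   (from [sim_probes_alignments()]).
#' @return Region tibble of `n_reads` read intervals with `name`.
#' @export
sim_reads <- function(config, capture, layout = NULL) {
  set.seed(config$seed + 5L)
  n <- config$n_reads
  rl <- config$read_length
  if (n == 0) return(empty_regions())
  on <- if (nrow(capture) > 0) runif(n) < config$read_on_target else
    rep(FALSE, n)
  w <- capture$end - capture$start
  pick <- sample(nrow(capture), sum(on), replace = TRUE, prob = w)
  s_on <- floor(capture$start[pick] +
                  runif(sum(on)) * pmax(1, w[pick] - 1) - rl / 2)
  ch_on <- capture$chrom[pick]
  ch_off <- sample(chrom_names(config), sum(!on), replace = TRUE)
  s_off <- floor(runif(sum(!on), 0, config$chrom_length - rl))
  out <- tibble(
    chrom = c(ch_on, ch_off),
    start = pmax(0, c(s_on, s_off))
  ) %>%
    mutate(end = pmin(config$chrom_length, .data$start + rl))
  out <- out[sample(nrow(out)), ]
  out$name <- sprintf("read%06d", seq_len(nrow(out)))
  as_regions(arrange(out, .data$chrom, .data$start))
}

#' Generate the cytosine report with a planted class gradient
#'
#' Every CpG site is assigned one truth class by the precedence
#' CGI > shore > shelf > promoter > exon > intergenic (a generator-side
#' convention only — the analysis never uses it), given a true level drawn
#' from a Beta distribution with the class mean and the configured
#' overdispersion, and covered by independent per-strand Poisson depths
#' (mean `depth_mean / 2` per strand inside captured regions,
#' `offtarget_depth / 2` outside). Methylated counts are Binomial(depth,
#' level) per strand, sharing the site's true level.
#'
#' @inheritParams sim_genome
#' @param genome_bundle Output of [sim_genome()] (or a list with `genome`).
#' @param class_map Named list of region tibbles (CGI, SHORE, SHELF,
#'   PROMOTER, EXON at minimum); everything else is intergenic.
#' @param capture Captureable regions for depth planting.
#' @return List with `cx` (cytosine-report tibble as from
#'   [read_cytosine_report()]) and `site_truth` (`chrom`, `pos`, `class`,
#'   `level`, `in_capture`).
#' @export
sim_cytosine_report <- function(config, genome_bundle, class_map, capture) {
  set.seed(config$seed + 6L)
  genome <- genome_bundle$genome
  sites <- enumerate_cpg_sites(genome)
  n <- nrow(sites)
  cls <- rep("INTERGENIC", n)
  for (nm in rev(c("CGI", "SHORE", "SHELF", "PROMOTER", "EXON"))) {
    if (!is.null(class_map[[nm]]) && nrow(class_map[[nm]]) > 0) {
      cls[sites_in_regions(sites, class_map[[nm]])] <- nm
    }
  }
  # precedence: assign in reverse so higher-precedence classes overwrite
  m <- config$class_means[cls]
  if (anyNA(m)) abort("class_means must name every class present")
  level <- if (config$dispersion == 0) {
    as.numeric(m)
  } else {
    theta <- (1 - config$dispersion) / config$dispersion
    rbeta(n, m * theta, (1 - m) * theta)
  }
  in_capture <- sites_in_regions(sites, capture)
  lam <- ifelse(in_capture, config$depth_mean / 2, config$offtarget_depth / 2)
  d_plus <- rpois(n, lam)
  d_minus <- rpois(n, lam)
  meth_plus <- rbinom(n, d_plus, level)
  meth_minus <- rbinom(n, d_minus, level)
  seqs <- as_genome_seqs(genome)
  nxt <- substr_vec(seqs, sites$chrom, sites$pos + 3)   # base after the G
  prv <- substr_vec(seqs, sites$chrom, sites$pos)       # base before the C
  tri_plus <- paste0("CG", nxt)
  tri_minus <- paste0("CG", chartr("ACGTN", "TGCAN", prv))
  cx <- bind_rows(
    tibble(chrom = sites$chrom, pos = sites$pos, strand = "+",
           meth = as.numeric(meth_plus),
           unmeth = as.numeric(d_plus - meth_plus),
           context = "CG", tricontext = tri_plus),
    tibble(chrom = sites$chrom, pos = sites$pos + 1, strand = "-",
           meth = as.numeric(meth_minus),
           unmeth = as.numeric(d_minus - meth_minus),
           context = "CG", tricontext = tri_minus)
  ) %>%
    arrange(.data$chrom, .data$pos, .data$strand) %>%
    mutate(depth = .data$meth + .data$unmeth, is_cpg = TRUE)
  site_truth <- tibble(chrom = sites$chrom, pos = sites$pos, class = cls,
                       level = level, in_capture = in_capture)
  list(cx = cx, site_truth = site_truth)
}

# 1-based single-base lookup across chromosomes; "N" outside bounds
substr_vec <- function(seqs, chrom, pos1) {
  out <- rep("N", length(chrom))
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    p <- pos1[sel]
    ok <- p >= 1 & p <= nchar(seqs[[ch]])
    v <- rep("N", sum(sel))
    v[ok] <- substring(seqs[[ch]], p[ok], p[ok])
    out[sel] <- v
  }
  out
}

#' Simulate a complete methyl-capture study
#'
#' Orchestrates the generators into a coherent fixture bundle: genome with
#' planted islands, source/target annotations, probe panel, blast8
#' alignments with pass/fail truth, read intervals, a cytosine report with
#' the planted class gradient, and the truth-geometry region class map
#' (planted islands run through [derive_shores_shelves()] and
#' [build_region_map()] with the target annotation). Everything is
#' reproducible from `config$seed`; with `dir` given, all inputs are also
#' written as plain-text files (FASTA, 2x GTF, BED, blast8 TSV, cytosine
#' report, truth tables).
#'
#' @param config A [synth_config()].
#' @param dir Optional output directory for the file bundle.
#' @return List with elements `config`, `genome`, `islands`, `annotation`,
#'   `probes`, `alignments`, `alignment_truth`, `capture`, `reads`, `cx`,
#'   `site_truth`, `truth_classes`, `chrom_lengths` and (with `dir`)
#'   `files`.
#' @export
simulate_study <- function(config = synth_config(), dir = NULL) {
  layout <- sim_layout(config)
  gb <- sim_genome(config, layout)
  ann <- sim_annotation(config, layout)
  pa <- sim_probes_alignments(config, layout, ann)
  reads <- sim_reads(config, pa$capture, layout)
  cl <- chrom_lengths(gb$genome)
  ss <- derive_shores_shelves(gb$islands, cl,
                              shore_width = config$shore_width,
                              shelf_width = config$shelf_width)
  target_prom <- gene_promoters(ann$target,
                                upstream = config$promoter_upstream,
                                chrom_lengths = cl)
  truth_classes <- build_region_map(gb$islands, ss$shores, ss$shelves,
                                    target_prom, ann$target, cl)
  cxb <- sim_cytosine_report(config, gb, truth_classes, pa$capture)
  out <- list(config = config, genome = gb$genome, islands = gb$islands,
              annotation = ann, probes = pa$probes,
              alignments = pa$alignments, alignment_truth = pa$truth,
              capture = pa$capture, reads = reads, cx = cxb$cx,
              site_truth = cxb$site_truth, truth_classes = truth_classes,
              chrom_lengths = cl)
  if (!is.null(dir)) {
    out$files <- write_study_files(out, dir)
  }
  out
}

write_study_files <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "truth"), showWarnings = FALSE)
  p <- function(...) file.path(dir, ...)
  files <- list(
    fasta = p("genome.fa"),
    source_gtf = p("source.gtf"),
    target_gtf = p("target.gtf"),
    probes_bed = p("probes.bed"),
    blast8 = p("alignments.blast8.tsv"),
    cx_report = p("calls.CX_report.txt"),
    reads_bed = p("reads.dedup.bed"),
    truth_islands = p("truth", "islands.bed"),
    truth_genes = p("truth", "genes.tsv"),
    truth_alignments = p("truth", "alignment_labels.tsv"),
    truth_class_means = p("truth", "class_means.tsv")
  )
  Biostrings::writeXStringSet(study$genome, files$fasta, width = 70)
  write_gtf(study$annotation$source_feats, files$source_gtf)
  write_gtf(study$annotation$target_feats, files$target_gtf)
  write_bed(study$probes[, c("chrom", "start", "end", "name")],
            files$probes_bed)
  write_blast8(study$alignments, files$blast8)
  write_cytosine_report(study$cx, files$cx_report)
  write_bed(study$reads, files$reads_bed)
  write_bed(study$islands, files$truth_islands)
  readr::write_tsv(study$annotation$genes, files$truth_genes)
  readr::write_tsv(study$alignment_truth, files$truth_alignments)
  means <- tibble(region_class = names(study$config$class_means),
                  planted_mean = as.numeric(study$config$class_means))
  readr::write_tsv(means, files$truth_class_means)
  files
}

write_gtf <- function(feats, path) {
  lines <- sprintf(
    '%s\tmethlift_sim\t%s\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s"; gene_name "%s";',
    feats$chrom, feats$type, as.integer(feats$start + 1),
    as.integer(feats$end), feats$strand, feats$gene, feats$transcript_id,
    feats$gene
  )
  writeLines(lines, path)
  invisible(path)
}

write_blast8 <- function(aln, path) {
  lines <- sprintf("%s\t%s\t%.2f\t%d\t%d\t%d\t%d\t%d\t%d\t%d\t%s\t%.1f",
                   aln$query_id, aln$subject, aln$identity, aln$aln_length,
                   aln$mismatches, aln$gap_opens, aln$qstart, aln$qend,
                   aln$sstart, aln$send,
                   formatC(aln$evalue, format = "e", digits = 2),
                   aln$bitscore)
  writeLines(lines, path)
  invisible(path)
}

write_cytosine_report <- function(cx, path) {
  lines <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s",
                   cx$chrom, as.integer(cx$pos + 1), cx$strand,
                   as.integer(cx$meth), as.integer(cx$unmeth), cx$context,
                   cx$tricontext)
  writeLines(lines, path)
  invisible(path)
}
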