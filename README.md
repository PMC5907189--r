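# methlift

Reusing a methyl-capture sequencing (MC-seq) panel designed on one genome —
typically the human SureSelect-style kit — on a related species requires
*redefining* the capture target on the other genome before any methylome
analysis makes sense. methlift implements that redefinition and the
downstream methylome summarisation for researchers running human-panel
MC-seq on non-human primates (or any pair of closely related genomes):

* **HPR (homologous probe region)** — probe-to-target alignments in blast8
  format are filtered at `identity ≥ 85%` and `e-value ≤ 1e-10` (best hit
  per probe by bit score), and the passing subject intervals are merged.
* **OPR (orthologous promoter region)** — gene symbols whose source-genome
  promoter is covered by probes strictly more than 60% are matched into the
  target annotation, and their promoters are recomputed as the 2 kb
  upstream of the target TSS (TSS = start of the longest transcript per
  symbol).
* **Redefined target** = HPR ∪ OPR, with a per-region-class CpG census.
* **Region taxonomy** — CpG islands from a clamped running-score detector
  (+17 per CG, −1 otherwise, peak ≥ 17; the classic EMBOSS-style defaults),
  2 kb shores and shelves with CGI > shore > shelf precedence, promoters,
  exon/CDS, intergenic.
* **Methylome summary** — Bismark-style cytosine reports are strand-merged
  into CpG-site calls (counts at the C and at the complementary G pool
  together), filtered to the target, and summarised as mean depth,
  cumulative coverage per depth threshold, on-target read rate, and
  per-class mean ± SD methylation at calling depth ≥ 5×.
* **Synthetic study generator** — a deterministic 5 Mb two-species fixture
  with planted islands, shared/unshared gene symbols, alignments straddling
  the filter thresholds, and a beta-binomial methylome with the planted
  gradient CGI 0.10 < promoter 0.20 < shore 0.40 < shelf 0.60 < exon 0.75 <
  intergenic 0.80 at ~30× depth.

Everything is tibble-first: readers return tibbles (regions are
`chrom`/`start`/`end`, 0-based half-open), results have broom-style
`tidy()`/`glance()` methods and ggplot2 `autoplot()`s.

## Worked example

```r
library(methlift)

st  <- simulate_study(synth_config(seed = 1))     # or read your own files
cpg <- enumerate_cpg_sites(st$genome)

td <- redefine_target(st$alignments, st$probes,
                      gene_promoters(st$annotation$source),
                      st$annotation$target,
                      chrom_lengths = st$chrom_lengths, cpg_sites = cpg)
td
#> <target_definition>
#>   HPR           534550 bp (4198 intervals)
#>   OPR            92000 bp (46 intervals; adds 47962 bp)
#>   redefined     582512 bp (3899 intervals)
#>   probe mapping rate 61.7% (4739 / 7683 probes)
#>   CG sites: 29376 in target (OPR adds 1891)

ms <- summarize_methylome(st$cx, cpg, td$redefined, st$truth_classes,
                          reads = st$reads)
glance(ms)
#> # A tibble: 1 × 4
#>   n_target_sites mean_depth pct_sites_depth_ge5 on_target_rate
#>            <int>      <dbl>               <dbl>          <dbl>
#> 1          29376       29.5                98.3          0.544

tidy(ms)      # per-class n, mean, sd, 95% interval
autoplot(ms)  # the per-class bar chart
```

Reading the numbers: 61.7% of the panel's probes align usefully to the
target genome; the redefined target spans 0.58 Mb and 29,376 CpG sites, of
which 98.3% are callable at ≥ 5× with a mean strand-merged depth of 29.5×;
54.4% of de-duplicated reads fall on target; and the per-class means
recover the planted hypomethylated-island-to-hypermethylated-intergenic
gradient.

For file-based runs the same stages are wired end to end:

```r
run_pipeline(fasta = "genome.fa", target_gtf = "target.gtf",
             blast8 = "aln.blast8.tsv", probes_bed = "probes.bed",
             source_gtf = "source.gtf", cx_report = "calls.CX_report.txt",
             reads_bed = "reads.dedup.bed", out_dir = "out/")
```

which writes BEDs for every region set, census and methylation TSVs, and a
JSON run summary; reruns are byte-identical. A thin CLI wrapping these
functions ships in `inst/scripts/methlift`
(`methlift simulate|cgi|hpr|opr|run-all ...`).

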