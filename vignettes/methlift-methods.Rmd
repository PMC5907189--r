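---
title: "Cross-species methyl-capture target redefinition: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-species methyl-capture target redefinition: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methlift)
```

## The problem

Methyl-capture sequencing (MC-seq) enriches bisulfite libraries for a fixed
panel of capture probes designed on one genome — in practice, the human
genome. Applying such a kit to a related species (e.g. an Old World monkey)
raises two questions that methlift answers computationally:

1. **Where do the probes actually capture on the other genome?** Probes only
   pull down fragments whose sequence is close enough to hybridise, so the
   effective target must be *redefined* on the new genome.
2. **Given that redefined target, what does the methylome look like?**
   Per-CpG methylation calls must be filtered to the target, summarised by
   depth, and averaged within the standard regulatory region classes.

## The redefined target: HPR + OPR

**Homologous probe region (HPR).** Probe sequences are aligned to the target
genome with a local aligner producing 12-column blast8 records. A record
enters the HPR when `identity >= 85%` and `e-value <= 1e-10`; both
boundaries are inclusive, a deliberate reading of thresholds that are
themselves chosen values (`pipeline_params()` exposes both). Among multiple
hits for one probe the default is best-hit selection — highest bit score,
ties broken by lowest e-value, then highest identity, then smallest
coordinate — because keeping every passing paralogous hit inflates the
target with loci the probe may never efficiently capture; `mode = "all"` is
available for sensitivity analysis. Passing subject intervals are merged
strand-agnostically: capture chemistry does not distinguish strands.

**Orthologous promoter region (OPR).** Capture panels tile promoters only
partially, and homology search misses promoters whose sequence diverged.
The OPR compensates: every source-genome gene symbol whose promoter is
covered by probes *strictly more than 60%* of its length is looked up in the
target annotation by exact symbol match, and the promoter is *recomputed* on
the target genome as the 2 kb upstream of the target TSS. The strictness of
the 60% gate matters at the boundary (a promoter covered exactly 60.00% is
excluded) and is tested explicitly.

**Redefined target** = merged union of HPR and OPR. Because it is unstated
whether OPR promoters should be trimmed by the HPR before counting what the
OPR "adds", the assembly reports both the raw OPR CG count and the count in
OPR minus HPR.

## Region taxonomy

* **CpG islands** are predicted from sequence with a clamped running score:
  +17 at each CG dinucleotide, −1 otherwise, floored at zero. A candidate
  segment opens when the score rises from zero and closes when it returns to
  zero; the island spans from the segment's first CG to the CG at which the
  score peaked (rightmost on ties, a fixed tie-break), and is reported when
  the peak reaches 17. These are the published defaults of the classic
  EMBOSS running-score predictor; all three constants are configurable via
  `cgi_params()`. `N` bases never form a CG and incur the ordinary penalty —
  conservative around assembly gaps. Note a structural property of this
  scoring: any isolated CG reaches the default peak threshold on its own, so
  CpG-poor background yields many minimal two-base islands. That mirrors the
  permissiveness of the emulated tool and is why the simulation study below
  plants dense islands and evaluates methylation classes on the designed
  geometry.
* **Shores** are the 2 kb windows flanking each island; **shelves** the
  2 kb windows beyond each shore. Although shelves are sometimes described
  open-endedly ("2 kb or more"), the fixed 2 kb width of the 450K-array
  convention is used — an unbounded shelf is unusable in practice. Windows
  are clipped at chromosome ends and trimmed by precedence
  CGI > shore > shelf, so the three classes are pairwise disjoint and
  inter-island flanks are counted once.
* **Promoters** are 2 kb upstream of the TSS. The TSS is the start site of
  the *longest transcript* per gene symbol, where "longest" means largest
  genomic span (`end − start`), not summed exon length — the TSS is a
  genomic-coordinate concept. Ties break on the lexicographically smallest
  transcript id for determinism.
* **Exon / CDS** are merged unions over all transcripts; introns are
  excluded from the intragenic classes. **Intergenic** is the genome minus
  merged gene spans and promoters. Classes are intentionally non-exclusive
  across groups (a base can be both CGI and promoter) because per-class
  summaries are reported independently.

All coordinates are 0-based half-open internally (BED native); GTF and
blast8 coordinates are converted on read. Book-ended intervals merge, since
regions here represent covered spans, not features.

## Methylome summarisation

Per-cytosine calls (Bismark-style cytosine reports) are strand-merged: the
plus-strand C at position *p* and the minus-strand C at *p + 1* pool their
counts into one CpG-site call, conserving totals. Depth statistics count
uncovered sites at depth zero, so cumulative coverage is non-increasing in
the threshold by construction. Methylation levels are summarised per region
class over sites with strand-merged depth ≥ 5 (the conventional calling
depth; the 30–40× figures are acquisition goals, not per-site filters), as
the *unweighted mean of per-site levels* with the sample standard deviation
(n − 1). Depth-weighted pooling of counts is available behind
`weighted = TRUE` for comparison. Interval estimates are the normal
approximation mean ± 1.96 sd/√n over sites; a per-sample bootstrap is out
of scope because the package summarises one methylome at a time.

A read counts as on-target when it overlaps the redefined target by at
least 1 bp (no minimum is standard; the knob is exposed).

## The synthetic study

`synth_config()` / `simulate_study()` generate a complete, deterministic
study at desk scale — the package's defaults are the study conditions used
throughout the tests and the acceptance script:

* **Genome**: 2 chromosomes × 2.5 Mb (5 Mb total) of i.i.d. background at
  40% GC, giving a background CpG density of 4% per bp; 60 planted islands
  of 800 bp with CG placed at half of all dinucleotide slots.
* **Annotation**: 120 genes of 20 kb with 1–3 transcripts; the target
  annotation reuses the loci with the TSS jittered ±200 bp and shares 80%
  of gene symbols (the rest become species-specific identifiers), which is
  what makes symbol matching non-trivial.
* **Geometry**: islands are hosted inside large central introns, and
  DMR-like intergenic probe targets sit clear of genes and island flanks.
  This makes the six classes *pairwise disjoint*, so each CpG site has an
  unambiguous planted class and class-mean recovery is well-posed. Real
  genomes violate this deliberately simplified geometry — promoter CpG
  islands are the norm, not the exception — so passing recovery tests shows
  estimator correctness, not that real class averages are uncontaminated.
* **Probes**: 120 bp tiles over island windows (island ± shore ± shelf),
  a random 30–100% of each promoter (panels cover promoters partially),
  exons, and the DMR targets — the region mix such panels are designed
  against.
* **Alignments**: each probe locus is conserved with probability 0.6;
  conserved primaries draw identity from U(88, 99.5), diverged from
  U(72, 84.5), with 5% atoms at exactly 85.0 and exactly 1e-10 so both
  filter boundaries are exercised; e-values follow
  10^−((identity − 75) + U(−1, 1)), and 0–2 paralog-like secondary hits are
  added. The resulting probe mapping rate (~62%) and on-target read rate
  (~54%) sit in the regime reported for cross-species use of human capture
  panels on Old World monkey genomes.
* **Methylome**: each site's true level is Beta-distributed around its
  class mean (CGI 0.10 < promoter 0.20 < shore 0.40 < shelf 0.60 <
  exon 0.75 < intergenic 0.80 — the canonical gradual hypermethylation away
  from islands) with overdispersion ρ = 0.05; per-strand depths are
  independent Poisson halves of a 30× capture depth (1× off-target), so
  strand-merging conservation is a non-trivial check. Truth classes are
  assigned by the precedence CGI > shore > shelf > promoter > exon >
  intergenic — a generator-side convention only.
* **Reads**: 20 000 de-duplicated 101-bp intervals, 85% drawn from
  captured loci (hybridisation-capable loci, identity ≥ 80%), the rest
  uniform.

What the generator does **not** emulate: sequence-context capture bias,
bisulfite conversion failure, PCR duplicates (inputs are assumed
de-duplicated), mappability, paralog collapse, and overlapping real-genome
class geometry. Results on synthetic fixtures therefore validate the
algebra, the filters and the estimators — not kit performance on any real
genome.

## Numerical and testing choices

* Set algebra is delegated to IRanges/GenomicRanges behind tibble-first
  wrappers; tests compare every operation base-for-base against an
  independent boolean-array oracle on random instances.
* The island scan uses the closed form `y = S − min(0, cummin(S))` of the
  clamped recursion, verified against an exhaustive positional-walk oracle
  on random sequences.
* The class map used for the methylation study (tests and acceptance
  script) is built from the *planted* island geometry via the same
  shore/shelf and taxonomy code paths; the detector itself is validated
  separately against its oracle and for ≥90% recall of planted island
  bases. The full file-based pipeline (`run_pipeline()`) runs the detector
  end-to-end and is checked for byte-identical reruns.
* Problem sizes in the test-suite: 5 Mb genomes (~212k CpG sites) for the
  study-level checks, 300 kb for unit-level fixtures — sizes chosen so the
  whole suite exercises every stage at meaningful scale while remaining
  quick to run.

## Known limitations

* Gene symbols are matched as strings (optionally case-folded); no ortholog
  database resolves renames, one-to-many orthology or multi-locus symbols
  (the latter are detected and reported).
* Exact output parity with the original EMBOSS island predictor on
  clamp-reset edge cases is not asserted — only the scoring scheme as
  documented here.
* The probe mapping rate counts probes with ≥1 passing alignment over the
  panel size; if the alignment file omits probes with no hits and no panel
  BED is given, the denominator falls back to the probes seen in the file
  and the rate is optimistic.
* Methylation summaries describe one sample at a time; differential
  analysis and DMR calling are out of scope.

## A worked run

```{r, eval = FALSE}
st <- simulate_study(synth_config(seed = 1))
cpg <- enumerate_cpg_sites(st$genome)
td <- redefine_target(st$alignments, st$probes,
                      gene_promoters(st$annotation$source),
                      st$annotation$target,
                      chrom_lengths = st$chrom_lengths, cpg_sites = cpg)
glance(td)
ms <- summarize_methylome(st$cx, cpg, td$redefined, st$truth_classes,
                          reads = st$reads)
tidy(ms)
autoplot(ms)
```

`scripts/acceptance.R` wraps exactly this computation and writes the
resulting quantities as JSON.
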