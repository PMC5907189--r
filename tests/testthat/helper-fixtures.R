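# Shared fixtures, memoised so expensive simulations run once per session.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

tiny_cfg <- function(seed = 42, ...) {
  args <- list(seed = seed, n_chroms = 1, chrom_length = 3e5, n_genes = 8,
               n_islands = 5, n_dmr_targets = 4, n_reads = 1500)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(synth_config, args)
}

tiny_study <- function() memo("tiny_study", simulate_study(tiny_cfg()))

# the default study conditions (5 Mb, planted gradient, ~30x)
default_study <- function() {
  memo("default_study", simulate_study(synth_config(seed = 101)))
}

default_cpg_sites <- function() {
  memo("default_cpg", enumerate_cpg_sites(default_study()$genome))
}
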