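# Small programmatic fixtures shared across test files.

make_track <- function(n = 12, positions = seq(100, by = 100, length.out = 12),
                       chrom = "chr1", seed = 1) {
  set.seed(seed)
  p <- length(positions)
  probe_track(rep(chrom, p), positions, matrix(runif(n * p), n))
}

make_design <- function(n = 30, seed = 1, ...) {
  set.seed(seed)
  design_spec(rnorm(n), ...)
}
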