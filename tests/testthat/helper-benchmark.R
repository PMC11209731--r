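# The end-to-end benchmark protocol is expensive; run it once and share the
# result between the recoverability and mutation-robustness tests.
.benchmark_cache <- new.env(parent = emptyenv())

acceptance_benchmark <- function() {
  if (is.null(.benchmark_cache$bench)) {
    .benchmark_cache$bench <- benchmark_protocol(seeds = 1:5,
                                                 include_mutation = TRUE)
  }
  .benchmark_cache$bench
}
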