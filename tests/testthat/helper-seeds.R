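# draw a reproducible sample without touching the caller's RNG stream
with_seed_sample <- function(seed, x, size) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  sample(x, size)
}
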