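# Seed plumbing. Every randomised function takes `seed = NULL`; a non-NULL
# seed is applied locally and the caller's RNG state restored afterwards, so
# seeded calls are pure. Multi-stage procedures split one run seed into
# sub-seeds with `sub_seeds()` (documented stream-splitting: the run seed
# seeds a draw of 31-bit child seeds, one per stage/replicate).

with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

sub_seeds <- function(seed, k) {
  if (is.null(seed)) return(rep(list(NULL), k))
  as.list(with_seed(seed, sample.int(.Machine$integer.max - 1L, k)))
}
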