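## Seeded functions must not disturb the caller's RNG stream: save the
## global .Random.seed on entry and restore it on exit.
.save_rng <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv())
  else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

.local_seed <- function(seed, envir = parent.frame()) {
  old <- .save_rng()
  do.call(on.exit, list(bquote(.restore_rng(.(old))), add = TRUE),
          envir = envir)
  set.seed(seed)
}
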