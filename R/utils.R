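# Seed plumbing: a master seed spawns independent child seeds so that
# replicate-level results are reproducible and order-independent.
childSeeds <- function(seed, n) {
  old <- .saveRNG()
  on.exit(.restoreRNG(old))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

.saveRNG <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.restoreRNG <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# Evaluate expr under a local, seeded RNG stream without disturbing the
# caller's RNG state.
withSeed <- function(seed, expr) {
  old <- .saveRNG()
  on.exit(.restoreRNG(old))
  set.seed(seed)
  expr
}

.assertNetwork <- function(x) {
  if (!methods::is(x, "HeterogeneousNetwork")) {
    stop("expected a HeterogeneousNetwork object", call. = FALSE)
  }
  methods::validObject(x)
  invisible(x)
}

relChange <- function(new, old) {
  denom <- max(norm(old, "F"), .Machine$double.eps)
  norm(new - old, "F") / denom
}
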