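# Internal helpers shared across modules.

# Evaluate expr with a temporary RNG state seeded by `seed`; the caller's
# RNG state is restored afterwards so library calls never perturb user code.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# One master seed fans out into fixed, named per-stage sub-seeds so that,
# e.g., changing the noise realisation does not move the cell placement.
stage_seeds <- function(master_seed) {
  with_seed(master_seed, {
    s <- sample.int(.Machine$integer.max - 1L, 8L)
  })
  names(s) <- c("placement", "field", "distractor", "render",
                "shuffle", "permutation", "scaling", "spare")
  s
}

# Binary disk footprint of the given radius (2r+1 x 2r+1 logical matrix,
# centre included; dx^2 + dy^2 <= r^2).  Shared by the filters and their
# brute-force oracles so that the footprint definition is single-sourced.
disk_footprint <- function(radius) {
  stopifnot(radius >= 1)
  d <- seq(-radius, radius)
  outer(d, d, function(a, b) a * a + b * b <= radius * radius)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# md5 of an in-memory object via its canonical JSON rendering
config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA), f)
  unname(tools::md5sum(f))
}
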