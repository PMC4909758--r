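#' @keywords internal
"_PACKAGE"

# Round half away from zero (voxel tie rule). base::round() rounds half to
# even, which would put the world point exactly between two voxel centres
# into either voxel depending on parity.
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG
# stream. All randomness in the package funnels through this.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
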