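#' @importFrom rlang %||%
NULL

# evaluate `code` under a local RNG state seeded with `seed`, restoring the
# caller's RNG afterwards so package functions never disturb the global stream
with_seed <- function(seed, code) {
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
  force(code)
}

# mmHg -> kPa
MMHG_TO_KPA <- 0.133322
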