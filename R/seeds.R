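#' Derive a reproducible sub-seed from a master seed and a stage label
#'
#' Expands one global seed into independent per-stage integer seeds by
#' hashing the stage label (FNV-1a, 32 bit) and folding it into the master
#' seed.  Adding detectors or stages to a run therefore never perturbs the
#' random stream of earlier stages.
#'
#' @param seed Integer master seed.
#' @param ... Character or numeric labels identifying the stage (e.g.
#'   `"uniformity"`, detector id).  Coerced to character and concatenated.
#' @return A single integer in `[0, 2^31 - 2]`, suitable for `set.seed()`.
#' @export
#' @examples
#' derive_seed(1, "grid", 3)
derive_seed <- function(seed, ...) {
  label <- paste(vapply(list(...), function(x) paste(format(x), collapse = ","),
                        character(1)), collapse = "/")
  bytes <- utf8ToInt(label)
  h <- 2166136261
  for (b in bytes) {
    # xor on the low byte (labels are ASCII), keeping h a double: R's
    # bitwXor cannot take values above 2^31
    h <- (h %/% 256) * 256 + bitwXor(h %% 256, b %% 256)
    # 32-bit FNV prime multiply in exact double arithmetic (split 16/16
    # bits so intermediates stay below 2^53)
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- (((hi * 16777619) %% 65536) * 65536 + lo * 16777619) %% 4294967296
  }
  as.integer((as.numeric(seed) + h) %% 2147483647)
}

# Run `expr` under a temporary RNG state seeded from (seed, ...).
with_stage_seed <- function(seed, ..., expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(derive_seed(seed, ...))
  expr
}
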