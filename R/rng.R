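# Deterministic sub-seed derivation.  Every randomised stage (splitting, CV
# fold draws, permutation importance, final refits) draws its own seed from
# (parent seed, stage label), so a single top-level seed reproduces the whole
# run on any machine and no stage depends on hidden global RNG state.

# 31-bit polynomial string hash; arithmetic stays below 2^53 so it is exact
# in doubles.
hash31 <- function(seed, label) {
  h <- seed %% 2147483647
  for (b in utf8ToInt(label)) h <- (h * 31 + b) %% 2147483647
  as.integer(h)
}

#' Derive a stage-specific random seed
#'
#' Hashes a parent seed together with one or more stage labels into a
#' reproducible 31-bit seed. All randomised operations in the package draw
#' their seeds through this function, so identical inputs always yield
#' identical results regardless of the caller's RNG state.
#'
#' @param seed Integer parent seed.
#' @param ... Stage labels (coerced to character) identifying the consumer.
#' @return A single integer in `[0, 2^31 - 2]`.
#' @examples
#' derive_seed(1, "split")
#' derive_seed(1, "cv", 3)
#' @export
derive_seed <- function(seed, ...) {
  hash31(seed, paste(vapply(list(...), as.character, ""), collapse = "/"))
}

# Evaluate `code` under `seed` without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
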