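#' @keywords internal
"_PACKAGE"

#' @useDynLib microsuccession, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Derive a reproducible child seed from a base seed and a string key
#'
#' Stochastic steps (rarefaction of a sample, the null stream of a sample
#' pair, each stage of the simulator) draw their RNG state from a child seed
#' computed from the run seed plus a stable textual key. Results are therefore
#' independent of iteration order: rarefying sample "S7" gives the same counts
#' whether it is processed first or last.
#'
#' @param seed integer base seed.
#' @param ... character/numeric components identifying the consumer
#'   (e.g. `"rarefy"`, a sample id, a canonical pair id).
#' @return An integer in `[1, 2^31 - 2]` suitable for [set.seed()].
#' @export
derive_seed <- function(seed, ...) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  key <- paste(c(format(as.integer(seed)), vapply(list(...), paste,
                                                 character(1), collapse = "|")),
               collapse = "/")
  m <- 2147483629  # largest prime < 2^31
  h <- 0
  for (v in utf8ToInt(key)) h <- (h * 131 + v) %% m
  as.integer(h %% (m - 1L) + 1)
}

# run `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards
with_seed <- function(seed, code) {
  force(seed)  # the seed expression may itself consume the caller's stream
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# canonical id for an unordered sample pair
pair_id <- function(a, b) paste(sort(c(a, b)), collapse = "::")

`%||%` <- function(x, y) if (is.null(x)) y else x
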