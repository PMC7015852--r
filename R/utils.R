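#' @keywords internal
"_PACKAGE"

#' @importFrom stats density median quantile rbinom rexp rpois runif sd setNames
#' @importFrom utils head read.delim write.table combn
NULL

# Deterministic 31-bit sub-seed for a named stage, derived from one master seed.
# Keeps every source of randomness on a single user-visible seed while giving
# each pipeline stage an independent stream.
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 131 + ch) %% 2147483647
  as.integer((as.numeric(seed) %% 2147483647 * 48271 + h) %% 2147483647)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

wgd_log <- function(..., verbose = getOption("wgdlens.verbose", TRUE)) {
  if (isTRUE(verbose)) message("[wgdlens] ", ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
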