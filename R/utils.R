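# Internal helpers shared across modules.

#' @importFrom stats quantile rnbinom runif p.adjust phyper setNames
#' @importFrom utils read.delim write.table combn head
NULL

# Derive a reproducible sub-seed from a master seed and a stream counter,
# kept below 2^31 so it is always a valid R integer seed.
split_seed <- function(seed, counter) {
  as.integer((as.double(seed) * 48271 + counter * 16807) %% 2147483647L)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
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

# Stable ordering key for windows: by chromosome name, then start.
window_order <- function(chrom, start) order(chrom, start, method = "radix")

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ <- function(...) stop(sprintf(...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x == floor(x)
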