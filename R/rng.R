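# Random-number channels. Natural-history channels (other_death, emergence,
# tumour_attr, uptake, attrs) are drawn independently of policy-side channels
# (visits, routine, screening, surveillance, melanoma_death, detection), which
# is what makes common-random-numbers policy comparison possible.
.mel_channels <- c(
  other_death = 1L, emergence = 2L, tumour_attr = 3L, uptake = 4L,
  attrs = 5L, visits = 6L, routine = 7L, screening = 8L,
  surveillance = 9L, melanoma_death = 10L, detection = 11L
)

.mel_block_size <- 128L

# Mix (root, id, channel, block) into a 31-bit seed. Exact in double
# arithmetic: all intermediates stay far below 2^53.
.mix_seed <- function(root, id, channel, block) {
  p <- 2147483647
  x <- (root %% p) + 1
  x <- (x * 48271) %% p
  x <- (x + id * 69621 + 1) %% p
  x <- (x * 16807 + channel * 30269) %% p
  x <- (x * 40692 + block * 10007 + 1) %% p
  as.integer(x)
}

#' Per-individual, per-channel random stream
#'
#' Creates a reproducible stream of uniform deviates for one simulated
#' individual. Draws depend only on `(root_seed, id, channel, draw index)`,
#' so cohorts are invariant to execution order, a cohort split into halves
#' reproduces the single run exactly, and natural-history channels are
#' untouched when only the screening policy changes.
#'
#' @param root_seed Integer root seed for the whole cohort.
#' @param id Positive integer individual identifier.
#' @return An object of class `mel_stream`.
#' @export
random_stream <- function(root_seed, id) {
  stopifnot(is.numeric(root_seed), length(root_seed) == 1L,
            is.numeric(id), length(id) == 1L, id >= 1)
  env <- new.env(parent = emptyenv())
  env$root <- as.numeric(root_seed)
  env$id <- as.numeric(id)
  nch <- length(.mel_channels)
  env$cache <- vector("list", nch)
  env$cursor <- rep.int(.mel_block_size + 1L, nch)
  env$block <- integer(nch)
  class(env) <- "mel_stream"
  env
}

.stream_refill <- function(stream, ch) {
  seed <- .mix_seed(stream$root, stream$id, ch, stream$block[ch])
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv(), inherits = FALSE) else NULL
  set.seed(seed)
  stream$cache[[ch]] <- stats::runif(.mel_block_size)
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  stream$block[ch] <- stream$block[ch] + 1L
  stream$cursor[ch] <- 1L
  invisible(stream)
}

#' Draw uniform deviates from a stream channel
#'
#' @param stream A `mel_stream` from [random_stream()].
#' @param channel Channel name, one of
#'   `names(melscreen:::.mel_channels)`.
#' @param n Number of deviates.
#' @return Numeric vector of `n` U(0,1) draws.
#' @export
stream_uniform <- function(stream, channel, n = 1L) {
  ch <- .mel_channels[[channel]]
  n <- as.integer(n)
  if (n == 0L) return(numeric(0))
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    if (stream$cursor[ch] > .mel_block_size) .stream_refill(stream, ch)
    take <- min(n - got, .mel_block_size - stream$cursor[ch] + 1L)
    idx <- stream$cursor[ch]
    out[(got + 1L):(got + take)] <- stream$cache[[ch]][idx:(idx + take - 1L)]
    stream$cursor[ch] <- idx + take
    got <- got + take
  }
  out
}
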