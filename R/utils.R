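#' Derive a stage-specific sub-seed from a global seed
#'
#' One global seed drives the whole study; each simulation stage mixes its
#' name into the stream so stages can be rerun independently without
#' correlated draws.
#'
#' @param seed Integer global seed.
#' @param stage Character stage label.
#' @return An integer in [0, 2^31 - 2].
#' @export
sub_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 31 + ch) %% 2147483647
  as.integer((h + (abs(seed) %% 1e6) * 10007 + 17) %% 2147483647)
}

# log(sum(exp(x))) without overflow
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# log(exp(a) - exp(b)) for a >= b; returns -Inf when the difference
# underflows (caller clamps)
logdiffexp <- function(a, b) {
  if (b >= a) return(-Inf)
  a + log1p(-exp(b - a))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_cfg <- function(...) stop(sprintf(...), call. = FALSE)
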