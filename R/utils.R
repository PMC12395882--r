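#' @importFrom rlang %||% abort warn .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter arrange select group_by summarise ungroup
#'   bind_rows left_join n
#' @importFrom purrr map map_dbl map_int map_chr map2 imap pmap
#' @importFrom stats rnorm runif rbinom qt sd median uniroot plogis
NULL

# numerically stable log(1 + exp(x))
softplus <- function(x) {
  pmax(x, 0) + log1p(exp(-abs(x)))
}

sigmoid <- function(x) plogis(x)

stopifnot_scalar_int <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x)) {
    abort(sprintf("`%s` must be a single integer", name))
  }
  as.integer(x)
}

# Derive a stream-specific 32-bit seed from a master seed so that stages
# (split, folds, synthesis, training) draw from independent streams.
derive_seed <- function(seed, stream) {
  seed <- stopifnot_scalar_int(seed, "seed")
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.double(seed) * 48271 + h) %% 2147483647)
}

# largest-remainder apportionment of n items over proportions p (sums to n)
largest_remainder <- function(n, p) {
  stopifnot(abs(sum(p) - 1) < 1e-8)
  raw <- n * p
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    ord <- order(raw - base, decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  as.integer(base)
}
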