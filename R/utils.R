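#' Derive a child seed from a master seed
#'
#' Deterministically mixes a master seed with any number of integer keys
#' (e.g. stage id, resample size, iteration) into a new seed in
#' \[1, 2^31 - 2\]. Used throughout the package so that every (size,
#' iteration) cell of a sweep has its own reproducible random stream,
#' independent of loop order.
#'
#' @param seed Master seed (integer).
#' @param ... Integer keys identifying the sub-stream.
#' @return An integer seed.
#' @export
#' @examples
#' derive_seed(1, 25, 3)
derive_seed <- function(seed, ...) {
  keys <- c(seed, ...)
  m <- 2147483647 # 2^31 - 1, keeps products exact in doubles
  x <- 0
  for (k in keys) {
    x <- (x * 69069 + (abs(as.numeric(k)) %% m) + 1) %% m
  }
  as.integer(x %% (m - 2) + 1)
}

#' Logarithmically spaced resample size bins
#'
#' @param min_size Smallest resample size (default 25).
#' @param max_size Largest resample size, usually the full sample size
#'   (default 1000).
#' @param n_bins Number of bins before rounding/deduplication (default 10).
#' @return Increasing integer vector of sizes.
#' @export
#' @examples
#' resample_sizes() # 25 ... 1000, 10 bins
resample_sizes <- function(min_size = 25, max_size = 1000, n_bins = 10) {
  stopifnot(min_size >= 4, max_size >= min_size, n_bins >= 1)
  sizes <- round(exp(seq(log(min_size), log(max_size), length.out = n_bins)))
  unique(as.integer(sizes))
}

# djb2-style string hash, used to stamp output CSVs with a config fingerprint
config_hash <- function(config) {
  s <- paste(deparse(config[order(names(config))]), collapse = "")
  h <- 5381
  for (v in utf8ToInt(s)) h <- (h * 33 + v) %% 2147483648
  sprintf("%08x", as.integer(h))
}
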