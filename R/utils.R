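`%||%` <- function(x, y) if (is.null(x)) y else x

# Clamp p-values away from 0/1 before quantile inversion.
clamp_p <- function(p, lo = 1e-15, hi = 1) pmin(pmax(p, lo), hi)

# Run `expr` under `seed` without disturbing the caller's RNG stream;
# seed = NULL draws from the current stream.
with_seed_opt <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(seed, expr)
}

assert_prob <- function(p, what = "p-value") {
  bad <- !is.finite(p) | p < 0 | p > 1
  if (any(bad)) {
    stop(sprintf("%s outside [0,1] at position(s) %s",
                 what, paste(utils::head(which(bad), 5L), collapse = ", ")),
         call. = FALSE)
  }
  invisible(p)
}

# Canonical key for a gene set (used for deduplication and ordering).
set_key <- function(genes) paste(sort(unique(genes)), collapse = ";")
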