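#' @keywords internal
"_PACKAGE"

#' @importFrom stats coef cor median na.omit p.adjust phyper prcomp predict
#'   pt quantile rnorm runif sd setNames var
#' @importFrom utils read.csv write.csv head
NULL

# Evaluate `code` under a fixed RNG state without disturbing the caller's
# stream. All randomized operations in the package go through this.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), code, .rng_kind = "Mersenne-Twister")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# stable order: descending by value, ties broken by original position
order_desc_stable <- function(x) order(-x, seq_along(x))

# pooled leave-one-out / generic R^2 on observed vs predicted
r_squared <- function(y, yhat) {
  sst <- sum((y - mean(y))^2)
  if (sst == 0) stop("R^2 undefined: response has zero variance")
  1 - sum((y - yhat)^2) / sst
}

abort_if <- function(cond, msg, ...) {
  if (cond) stop(sprintf(msg, ...), call. = FALSE)
}
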