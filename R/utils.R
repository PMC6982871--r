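# Internal numeric helpers shared across modules.

#' Round half away from zero
#'
#' Commercial rounding at the final per-class allocation step: 14.5 rounds to
#' 15, unlike base [round()] which rounds half to even.
#'
#' @param x Numeric vector.
#' @return Integer-valued numeric vector.
#' @keywords internal
round_half_up <- function(x) {
  floor(x + 0.5)
}

#' Largest-remainder apportionment of an integer total
#'
#' Splits `total` into `k` non-negative integer shares proportional to
#' `weights` (equal by default). Base shares are the floors of the exact
#' quotas; leftover units go to the largest fractional remainders, ties broken
#' toward the LATER index. The tie rule is what puts the odd unit on the last
#' model/class of a group (24/24/25 rather than 25/24/24).
#'
#' @param total Non-negative integer to apportion.
#' @param k Number of shares.
#' @param weights Optional positive weights, length `k`.
#' @return Integer vector of length `k` summing to `total`.
#' @keywords internal
largest_remainder <- function(total, k, weights = rep(1, k)) {
  stopifnot(total >= 0, k >= 1, length(weights) == k, all(weights >= 0))
  quotas <- total * weights / sum(weights)
  shares <- floor(quotas)
  rem <- quotas - shares
  extra <- round(total - sum(shares))
  if (extra > 0) {
    ord <- order(rem, seq_len(k), decreasing = TRUE) # later index wins ties
    shares[ord[seq_len(extra)]] <- shares[ord[seq_len(extra)]] + 1
  }
  as.integer(shares)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards. All seeded entry points funnel through here
# so seeded determinism never leaks into (or from) user RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (had) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    })
    set.seed(seed)
  }
  expr
}

# Derive a child seed from a base seed and a stream label, kept below 2^31.
derive_seed <- function(seed, stream) {
  (as.numeric(seed) * 1000003 + as.numeric(stream) * 7919) %% 2147483647
}

`%||%` <- function(a, b) if (is.null(a)) b else a
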