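`%||%` <- function(x, y) if (is.null(x)) y else x

#' Round half away from zero
#'
#' Commercial ("half-up") rounding, used for all displayed percentages.
#' `base::round()` rounds half to even, which would print 8.5% as 8%.
#'
#' @param x numeric vector
#' @param digits number of decimal places to keep
#' @return rounded numeric vector
#' @examples
#' round_half_up(c(0.5, 1.5, 2.5))
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# exact percentage (display rounding applied only at print time)
pct_exact <- function(num, den) 100 * num / den

# scalar logical check
is_flag <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == as.integer(x)
}

is_prob <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x <= 1

# Deterministic allocation of `total` units over `n` bins: every bin gets
# `min_each`, the remainder is dealt one unit at a time, round-robin from the
# first bin, never exceeding `cap` (scalar or per-bin). Errors when the totals
# are infeasible; used by the fixture builder, where infeasibility means the
# requested marginal counts are mutually inconsistent.
distribute_counts <- function(total, n, min_each = 0L, cap = Inf, what = "units") {
  if (n == 0L) {
    if (total != 0L) {
      stop(sprintf("specification error: %d %s to place but no bins", total, what),
           call. = FALSE)
    }
    return(integer(0))
  }
  cap <- rep_len(cap, n)
  out <- rep(as.integer(min_each), n)
  if (any(out > cap)) {
    stop(sprintf("specification error: minimum per-bin count exceeds capacity for %s", what),
         call. = FALSE)
  }
  rem <- total - sum(out)
  if (rem < 0) {
    stop(sprintf("specification error: %d %s cannot cover a minimum of %d",
                 total, what, sum(out)), call. = FALSE)
  }
  i <- 1L
  guard <- 0L
  while (rem > 0L) {
    if (out[i] < cap[i]) {
      out[i] <- out[i] + 1L
      rem <- rem - 1L
      guard <- 0L
    } else {
      guard <- guard + 1L
      if (guard > n) {
        stop(sprintf("specification error: capacity exhausted while placing %s", what),
             call. = FALSE)
      }
    }
    i <- if (i == n) 1L else i + 1L
  }
  out
}

# Deterministic capacity-greedy allocation: each unit goes to the bin with the
# most remaining room (ties -> lowest index). Keeps per-trial outcome totals
# balanced when the fixture builder spreads extra outcomes over a trial group.
distribute_greedy <- function(extra, room, what = "units") {
  out <- integer(length(room))
  while (extra > 0L) {
    free <- room - out
    j <- which.max(free)
    if (length(j) == 0L || free[j] <= 0L) {
      stop(sprintf("specification error: no remaining capacity for %s", what),
           call. = FALSE)
    }
    out[j] <- out[j] + 1L
    extra <- extra - 1L
  }
  out
}
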