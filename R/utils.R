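#' @useDynLib maskdoor, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif rpois rbinom quantile uniroot qnorm qt sd optim
#' @importFrom utils head
NULL

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed`, restoring the previous
#' RNG state afterwards so callers' random streams are not disturbed.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    set.seed(seed)
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
  }
  force(code)
}

## round-half-away-from-zero; base round() is banker's rounding
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

stopifnot_scalar_prob <- function(x, name, open = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("`%s` must be a single number", name), call. = FALSE)
  }
  if (open && (x <= 0 || x >= 1)) {
    stop(sprintf("`%s` must lie in (0, 1)", name), call. = FALSE)
  }
  if (!open && (x < 0 || x > 1)) {
    stop(sprintf("`%s` must lie in [0, 1]", name), call. = FALSE)
  }
  invisible(x)
}

#' Size of the trigger-mask space
#'
#' The trigger search space for a 48-hour, 17-channel grid contains one mask
#' per subset of the 816 cells. The exact count 2^816 does not fit in a
#' double, so it is returned as a decimal string (computed by repeated exact
#' doubling) together with its base-2 logarithm.
#'
#' @param n_rows,n_cols grid dimensions; defaults 48 and 17.
#' @return list with `log2` (816 by default) and `count` (exact decimal
#'   string).
#' @export
#' @examples
#' trigger_space_size()$log2
trigger_space_size <- function(n_rows = 48L, n_cols = 17L) {
  bits <- as.integer(n_rows) * as.integer(n_cols)
  # exact 2^bits via schoolbook doubling on decimal digits
  digits <- 1L
  for (i in seq_len(bits)) {
    digits <- digits * 2L
    carry <- 0L
    for (j in seq_along(digits)) {
      v <- digits[j] + carry
      digits[j] <- v %% 10L
      carry <- v %/% 10L
    }
    while (carry > 0L) {
      digits <- c(digits, carry %% 10L)
      carry <- carry %/% 10L
    }
  }
  list(log2 = bits, count = paste(rev(digits), collapse = ""))
}
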