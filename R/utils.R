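# internal helpers shared across modules

# Evaluate `code` under a fixed RNG seed without clobbering the caller's
# random state. All generators take explicit seeds; no global state leaks.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

abort_invalid <- function(msg, ...) {
  stop(sprintf(msg, ...), call. = FALSE)
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_null = FALSE) {
  if (is.null(x)) {
    if (allow_null) return(invisible(x))
    abort_invalid("`%s` must be supplied", name)
  }
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort_invalid("`%s` must be a single finite number", name)
  }
  if (x < lower || x > upper) {
    abort_invalid("`%s` = %g violates bound [%g, %g]", name, x, lower, upper)
  }
  invisible(x)
}

# nearest integer, half away from zero (used for all linking-number rounding)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' @importFrom tibble tibble as_tibble
#' @importFrom rlang .data
#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
#' @importFrom stats approx coef cor kmeans optim pt qt runif rnorm rpois
#'   rbinom sd t.test setNames
NULL
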