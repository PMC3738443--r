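#' @keywords internal
"_PACKAGE"

#' @importFrom rlang abort warn inform .data :=
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom tidyr pivot_longer pivot_wider
#' @importFrom purrr map map_dbl map_chr map2 imap list_rbind
#' @importFrom stats lm coef pnorm qnorm plogis qlogis pt rnorm runif rbeta
#'   p.adjust fisher.test ks.test complete.cases var sd setNames median cor
#' @importFrom utils head modifyList
NULL

stop_format <- function(msg, ...) {
  abort(msg, class = "methylewas_format_error", ...)
}

stop_invalid <- function(msg, ...) {
  abort(msg, class = "methylewas_validation_error", ...)
}

# logit helpers guarded away from 0/1 so batch shifts stay finite
.logit_eps <- 1e-4

logit_clamped <- function(p) qlogis(pmin(pmax(p, .logit_eps), 1 - .logit_eps))

clip01 <- function(x) pmin(pmax(x, 0), 1)

# truncated-normal draws on [0,1] via inverse-CDF; vectorised over mean
rtruncnorm01 <- function(n, mean, sd) {
  if (sd <= 0) return(rep_len(mean, n))
  lo <- pnorm((0 - mean) / sd)
  hi <- pnorm((1 - mean) / sd)
  u <- runif(n, lo, hi)
  mean + sd * qnorm(pmin(pmax(u, 1e-12), 1 - 1e-12))
}

# run code under a temporary RNG state seeded with `seed`
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop_invalid("`seed` must be a single integer")
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
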