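#' @useDynLib nradjust, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats aggregate binomial chisq.test coef cor.test glm glm.fit
#'   isoreg ks.test lm.fit median optimize plogis pnorm predict qbinom qnorm
#'   quantile rbeta rbinom rgamma rlnorm rnorm runif sd setNames var
#' @importFrom utils head modifyList read.csv write.csv
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

logit <- function(p) log(p / (1 - p))

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Derive a reproducible sub-stream seed for a named pipeline stage
#'
#' All randomness in the package flows from one root seed; each stage draws
#' from its own sub-stream so that re-running a single stage reproduces its
#' output regardless of what ran before.
#'
#' @param seed integer root seed.
#' @param stage character stage label.
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
substream_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% 2147483629
  as.integer((abs(seed) * 48271 + h) %% 2147483629)
}

# type-1 (inverted ECDF) sample quantile: smallest x with ECDF(x) >= p
quantile_type1 <- function(x, p) {
  unname(quantile(x, probs = p, type = 1, names = FALSE))
}

stop_field <- function(field, msg) {
  stop(sprintf("invalid parameter '%s': %s", field, msg), call. = FALSE)
}

check_prob <- function(x, field) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0) || any(x > 1))
    stop_field(field, "must be a probability in [0, 1]")
  invisible(x)
}

check_nonneg <- function(x, field) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0))
    stop_field(field, "must be non-negative")
  invisible(x)
}

format_pval <- function(p, digits = 3) {
  ifelse(p < 0.001, "<0.001", formatC(round(p, digits), format = "f", digits = digits))
}
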