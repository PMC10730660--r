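#' @importFrom rlang .data abort warn inform %||%
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange bind_rows group_by ungroup
#'   summarise across left_join n distinct pull if_else rename count
#' @importFrom stats qbeta rbeta rbinom rlnorm fisher.test chisq.test
#'   wilcox.test p.adjust setNames quantile sd
#' @importFrom utils head
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

# Round half away from zero, as printed tables do (base round() is half-even).
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Render a rate as a "1:N" ratio string
#'
#' Affected-birth rates and allele frequencies are conventionally printed as
#' "1:N" with N the nearest integer to 1/rate (ties round half-up).
#'
#' @param rate Numeric vector of rates in (0, 1].
#' @return Character vector; `NA` where `rate` is 0 or missing.
#' @examples
#' ratio_string(269 / 35728)
#' @export
ratio_string <- function(rate) {
  out <- rep(NA_character_, length(rate))
  ok <- !is.na(rate) & rate > 0
  out[ok] <- paste0("1:", format(round_half_up(1 / rate[ok]), scientific = FALSE, trim = TRUE))
  out
}

# nearest-integer denominator for a positive rate
ratio_n <- function(rate) {
  ifelse(!is.na(rate) & rate > 0, round_half_up(1 / rate), NA_real_)
}

check_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    abort(paste0("`", name, "` must be TRUE or FALSE."))
  }
  x
}

check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper) {
    abort(paste0("`", name, "` must be a single number in [", lower, ", ", upper, "]."))
  }
  x
}
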