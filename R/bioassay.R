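#' Specific growth rate (SGR)
#'
#' The standard aquaculture growth statistic for a feeding trial:
#' \deqn{SGR(\%) = 100 \cdot \frac{\ln L_t - \ln L_0}{t}}
#' with `l0` and `lt` the initial and final body lengths and `t` the trial
#' duration in days. The statistic is invariant to length units and
#' antisymmetric under swapping the two lengths (shrinkage gives a negative
#' rate). Vectorized over all arguments.
#'
#' @param l0 initial length (> 0).
#' @param lt final length (> 0).
#' @param t duration in days (> 0).
#' @return SGR in percent per day.
#' @examples
#' specific_growth_rate(10, 20, 30)  # 100 * ln 2 / 30 ~ 2.31 %/day
#' @export
specific_growth_rate <- function(l0, lt, t) {
  if (any(l0 <= 0) || any(lt <= 0)) {
    stop("lengths must be positive", call. = FALSE)
  }
  if (any(t <= 0)) stop("duration must be positive", call. = FALSE)
  100 * (log(lt) - log(l0)) / t
}

#' Per-group growth summaries
#'
#' Mean, standard error (sd with n-1 denominator over the square root of n)
#' and group size of per-animal SGR values, as plotted with error bars in
#' feeding-trial figures. The per-animal table is the intended input to any
#' external significance test.
#'
#' @param data data.frame with a grouping column and an SGR column, or a
#'   named list of numeric vectors.
#' @param group,value column names when `data` is a data.frame.
#' @return data.frame of group, n, mean_sgr, se.
#' @export
summarize_growth <- function(data, group = "group", value = "sgr") {
  if (is.data.frame(data)) {
    split_vals <- split(data[[value]], data[[group]])
  } else {
    split_vals <- data
  }
  small <- names(split_vals)[lengths(split_vals) < 2L]
  if (length(small)) {
    stop("group(s) with fewer than 2 values: ",
         paste(small, collapse = ", "), call. = FALSE)
  }
  out <- data.frame(
    group = names(split_vals),
    n = lengths(split_vals),
    mean_sgr = vapply(split_vals, mean, numeric(1L)),
    se = vapply(split_vals, function(v) stats::sd(v) / sqrt(length(v)),
                numeric(1L)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}
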