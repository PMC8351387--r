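#' Fold-change of an isolate readout against the parental mean
#'
#' @param isolate_mean Mean readout of the isolate (concentration or
#'   fluorescence intensity).
#' @param parental_mean Mean readout of the parental strain, same units;
#'   must be positive.
#' @return List with `ratio` and `log2fc`.
#' @examples
#' fold_change(134, 42)   # ~3.2-fold
#' fold_change(426, 42)   # ~10-fold
#' @export
fold_change <- function(isolate_mean, parental_mean) {
  if (!all(parental_mean > 0))
    stop("parental_mean must be positive", call. = FALSE)
  ratio <- isolate_mean / parental_mean
  list(ratio = ratio, log2fc = log2(ratio))
}

#' Growth-curve container
#'
#' @param times Sampling times in hours, strictly increasing.
#' @param ods OD600 values, positive (the estimator works on log2(OD)).
#' @return Object of class `growth_curve`.
#' @export
growth_curve <- function(times, ods) {
  stopifnot(length(times) == length(ods), length(times) >= 2)
  if (any(diff(times) <= 0)) stop("times must be strictly increasing", call. = FALSE)
  if (any(ods <= 0)) stop("ods must be positive", call. = FALSE)
  structure(list(times = as.numeric(times), ods = as.numeric(ods)),
            class = "growth_curve")
}

#' Maximum specific growth rate from log2-transformed OD values
#'
#' Slides a window of exactly `min_points` consecutive samples along the
#' curve, fits a least-squares line to log2(OD) versus time in each window,
#' and returns the maximum slope. The unit is doublings per hour (log2 OD
#' per hour). At least 5 points per fit is the monoculture convention;
#' conditioned-media curves conventionally use 6 to 8.
#'
#' @param curve A [growth_curve()] (or a list with `times` and `ods`).
#' @param min_points Window length; the curve must be at least this long.
#' @return List with `rate` (max slope, h^-1 in log2 units), `window`
#'   (indices of the winning window), and `intercept` of the winning fit.
#' @examples
#' tm <- 0:9
#' growth_rate(growth_curve(tm, 0.01 * 2^tm))$rate   # exactly 1
#' @export
growth_rate <- function(curve, min_points = 5L) {
  t <- curve$times; y <- log2(curve$ods)
  n <- length(t)
  if (min_points < 2) stop("min_points must be at least 2", call. = FALSE)
  if (n < min_points)
    stop("growth curve has ", n, " points; at least ", min_points,
         " are required", call. = FALSE)
  best <- list(rate = -Inf, window = NULL, intercept = NA_real_)
  for (s in 1:(n - min_points + 1)) {
    idx <- s:(s + min_points - 1)
    ft <- t[idx]; fy <- y[idx]
    mt <- mean(ft); my <- mean(fy)
    slope <- sum((ft - mt) * (fy - my)) / sum((ft - mt)^2)
    if (slope > best$rate)
      best <- list(rate = slope, window = idx, intercept = my - slope * mt)
  }
  best
}

#' Generations elapsed between inoculation and transfer
#'
#' Computed as `log10(A_f / A_i) / 0.3`, with `A_f` the OD600 before the
#' transfer and `A_i` the inoculated OD600. The divisor is the literal 0.3
#' of the field formula (a rounding of log10(2) = 0.30103, so the count is
#' a close approximation of true doublings).
#'
#' @param A_f Final OD600 (before transfer), positive.
#' @param A_i Initial (inoculated) OD600, positive.
#' @return Generation count.
#' @examples
#' generations(2, 1)    # ~1.003
#' generations(10, 1)   # 10/3
#' @export
generations <- function(A_f, A_i) {
  if (any(A_f <= 0) || any(A_i <= 0))
    stop("OD values must be positive", call. = FALSE)
  log10(A_f / A_i) / 0.3
}

#' Aggregation percentage from the settling drop in optical density
#'
#' `(1 - A_t / A_0) * 100`: the percentage decrease of the suspension OD600
#' as cells aggregate and settle. Negative values (OD increased) are
#' reported as-is.
#'
#' @param A_0 OD600 at the start, positive.
#' @param A_t OD600 at the readout time.
#' @return Aggregation percentage.
#' @examples
#' aggregation_percent(1, 0.25)   # 75
#' @export
aggregation_percent <- function(A_0, A_t) {
  if (any(A_0 <= 0)) stop("A_0 must be positive", call. = FALSE)
  (1 - A_t / A_0) * 100
}

#' Background-subtracted biofilm readout (mean and SD)
#'
#' Subtracts the mean of the blank (medium-only) wells from each replicate
#' A570 reading and returns the sample mean and standard deviation (n - 1).
#'
#' @param values A570 readings of the stained wells (>= 1 value).
#' @param blanks A570 readings of empty control wells (>= 1 value).
#' @return List with `mean` and `sd` (NA when a single replicate).
#' @examples
#' biofilm_readout(c(0.5, 0.7), 0.1)
#' @export
biofilm_readout <- function(values, blanks) {
  if (!length(values) || !length(blanks))
    stop("values and blanks must be non-empty", call. = FALSE)
  corrected <- values - mean(blanks)
  list(mean = mean(corrected),
       sd = if (length(corrected) > 1) sd(corrected) else NA_real_)
}

#' Unpaired two-tailed t-test between two groups
#'
#' Classical Student (equal-variance) test by default; Welch's correction
#' behind a flag. Two identical zero-variance groups are degenerate for the
#' t statistic and are reported as t = 0, p = 1 by convention.
#'
#' @param group_a,group_b Numeric vectors, each with >= 2 values.
#' @param welch Use Welch's unequal-variance form.
#' @return List with `t`, `df` and two-tailed `p`.
#' @examples
#' two_group_test(c(1, 2, 3), c(4, 5, 6))
#' @export
two_group_test <- function(group_a, group_b, welch = FALSE) {
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("each group needs at least 2 values", call. = FALSE)
  if (sd(group_a) == 0 && sd(group_b) == 0 &&
      mean(group_a) == mean(group_b)) {
    return(list(t = 0, df = length(group_a) + length(group_b) - 2, p = 1))
  }
  ht <- t.test(group_a, group_b, var.equal = !welch, paired = FALSE,
               alternative = "two.sided")
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = min(1, ht$p.value))
}
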