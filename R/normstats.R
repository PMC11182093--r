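# Normative-comparison statistics: eccentricity-matched z-scores against
# healthy-control tables, two-sample Wilcoxon rank-sum with exact
# enumeration for small samples, and ICC(A,1) intrarater reliability
# with its F-based 95% confidence interval.

#' Validate a normative table
#'
#' A normative table holds healthy-control summary statistics indexed by
#' measure, eccentricity and meridian, the source of z-scores for
#' patient values.
#'
#' @param x Data.frame with columns `measure`, `eccentricity_mm`,
#'   `meridian`, `mean`, `sd`, `n`.
#' @return The validated data.frame with class `normative_table`.
#' @export
normative_table <- function(x) {
  need <- c("measure", "eccentricity_mm", "meridian", "mean", "sd", "n")
  if (!all(need %in% names(x)))
    stop("normative table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(x$sd)) || any(x$sd <= 0))
    stop("normative SDs must be positive", call. = FALSE)
  if (any(x$n < 2)) stop("normative n must be >= 2", call. = FALSE)
  key <- paste(x$measure, x$eccentricity_mm, x$meridian)
  if (anyDuplicated(key))
    stop("duplicate (measure, eccentricity, meridian) keys", call. = FALSE)
  class(x) <- c("normative_table", "data.frame")
  x
}

#' Read / write normative tables as CSV
#' @param path CSV file path.
#' @return `read_normative_table()` returns a `normative_table`.
#' @export
read_normative_table <- function(path) {
  normative_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_normative_table
#' @param table A `normative_table`.
#' @export
write_normative_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' z-score of a measurement against normative data
#'
#' Converts a patient measurement to the number of healthy-control SDs
#' from the healthy mean at the matching eccentricity and meridian:
#' `z = (value - mean) / sd`. The matching normative row is the nearest
#' eccentricity within `tolerance_mm` on the requested meridian (no
#' interpolation). A value is flagged abnormal when `z < -2` (strictly).
#'
#' @param value Measured value (same units as the table's `mean`).
#' @param table A [normative_table()].
#' @param measure Measure label (e.g. `"cone_density"`, `"rt"`).
#' @param eccentricity_mm Eccentricity of the measurement, mm.
#' @param meridian Meridian label.
#' @param tolerance_mm Maximum eccentricity mismatch accepted.
#' @return A `zscore_result`: `value`, `normal_mean`, `normal_sd`, `z`,
#'   `abnormal`, and the matched row's eccentricity.
#' @examples
#' tab <- normative_table(data.frame(measure = "cone_density",
#'   eccentricity_mm = 1, meridian = "nasal", mean = 10, sd = 2, n = 10))
#' zscore(5, tab, "cone_density", 1, "nasal")$z
#' @export
zscore <- function(value, table, measure, eccentricity_mm, meridian,
                   tolerance_mm = 0.15) {
  stopifnot(inherits(table, "normative_table"))
  rows <- table[table$measure == measure & table$meridian == meridian, ,
                drop = FALSE]
  if (!nrow(rows))
    stop(sprintf("no normative rows for measure '%s' on meridian '%s'; %s",
                 measure, meridian, available_keys(table)), call. = FALSE)
  d <- abs(rows$eccentricity_mm - eccentricity_mm)
  j <- which.min(d)
  if (d[j] > tolerance_mm)
    stop(sprintf(
      "no normative row within %.2f mm of eccentricity %.2f mm; %s",
      tolerance_mm, eccentricity_mm, available_keys(table)), call. = FALSE)
  z <- (value - rows$mean[j]) / rows$sd[j]
  structure(list(value = value, normal_mean = rows$mean[j],
                 normal_sd = rows$sd[j], z = z, abnormal = z < -2,
                 matched_eccentricity_mm = rows$eccentricity_mm[j]),
            class = "zscore_result")
}

available_keys <- function(table) {
  paste0("available: ",
         paste(unique(paste0(table$measure, "@", table$eccentricity_mm,
                             "mm/", table$meridian))[1:min(12, nrow(table))],
               collapse = ", "))
}

#' @export
print.zscore_result <- function(x, ...) {
  cat(sprintf("z = %.3f (value %.4g vs normal %.4g +/- %.4g)%s\n", x$z,
              x$value, x$normal_mean, x$normal_sd,
              if (x$abnormal) "  [abnormal: z < -2]" else ""))
  invisible(x)
}

#' Two-sample Wilcoxon rank-sum test
#'
#' Rank-sum statistic with midranks for ties. In exact mode the
#' two-sided p-value is computed by full enumeration of all
#' `choose(n + m, n)` assignments of the pooled (mid)ranks; in
#' approximate mode a continuity-corrected normal approximation with the
#' tie correction is used. The two-sided exact p is the total null
#' probability of rank sums at least as far from their mean as the one
#' observed.
#'
#' @param x,y Numeric samples.
#' @param mode `"exact"` (requires `n + m <= 22`) or `"normal_approx"`.
#' @return List with `statistic` (rank sum of `x`, midranks), `p`
#'   (two sided), `mode`, `degenerate` (TRUE when all pooled values are
#'   identical, in which case `p = 1`).
#' @examples
#' wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6), mode = "exact")$p  # 0.1
#' @export
wilcoxon_rank_sum <- function(x, y, mode = c("exact", "normal_approx")) {
  mode <- match.arg(mode)
  if (!length(x) || !length(y))
    stop("both samples must be nonempty", call. = FALSE)
  n <- length(x); m <- length(y); N <- n + m
  pooled <- c(x, y)
  if (diff(range(pooled)) == 0)
    return(list(statistic = n * (N + 1) / 2, p = 1, mode = mode,
                degenerate = TRUE))
  r <- rank(pooled)                    # midranks
  W <- sum(r[seq_len(n)])
  mu <- n * (N + 1) / 2
  if (mode == "exact") {
    if (N > 22)
      stop("exact enumeration limited to n + m <= 22; use normal_approx",
           call. = FALSE)
    cmb <- utils::combn(N, n)
    sums <- colSums(matrix(r[cmb], nrow = n))
    p <- mean(abs(sums - mu) >= abs(W - mu) - 1e-9)
  } else {
    # normal approximation with tie correction and continuity correction
    ties <- table(r)
    sig2 <- n * m / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sig2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  list(statistic = W, p = p, mode = mode, degenerate = FALSE)
}

#' Intraclass correlation ICC(A,1)
#'
#' Single-rater absolute-agreement ICC from a two-way (subjects x
#' sessions) random-effects ANOVA:
#' `ICC(A,1) = (MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))`
#' with `MSR`, `MSC`, `MSE` the subject, session and error mean squares,
#' `n` subjects and `k` sessions. The 95% confidence interval follows
#' the standard F-distribution method for absolute-agreement
#' single-rater ICCs.
#'
#' @param ratings Numeric matrix, subjects in rows, sessions in columns,
#'   no missing cells.
#' @param conf_level Confidence level (default 0.95).
#' @return An `icc_result`: `icc`, `ci_low`, `ci_high`, `model`,
#'   mean squares, `n`, `k`.
#' @examples
#' ratings <- cbind(c(9, 6, 8, 7), c(9.5, 6.1, 8.2, 7.1))
#' icc_a1(ratings)$icc
#' @export
icc_a1 <- function(ratings, conf_level = 0.95) {
  ratings <- as.matrix(ratings)
  if (any(is.na(ratings))) stop("no missing cells allowed", call. = FALSE)
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 2 || k < 2)
    stop("need >= 2 subjects and >= 2 sessions", call. = FALSE)
  grand <- mean(ratings)
  rowm <- rowMeans(ratings); colm <- colMeans(ratings)
  ssr <- k * sum((rowm - grand)^2)
  ssc <- n * sum((colm - grand)^2)
  sst <- sum((ratings - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + (k / n) * (msc - mse)
  if (abs(denom) < 1e-300 || msr <= 0) {
    warning("zero between-subject variance: ICC undefined, reported as 0")
    return(structure(list(icc = 0, ci_low = NA_real_, ci_high = NA_real_,
                          model = "two-way, absolute agreement, single rater",
                          msr = msr, msc = msc, mse = mse, n = n, k = k),
                     class = "icc_result"))
  }
  icc <- (msr - mse) / denom
  alpha <- 1 - conf_level
  a <- (k * icc) / (n * (1 - icc))
  b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  f_l <- stats::qf(1 - alpha / 2, n - 1, v)
  f_u <- stats::qf(1 - alpha / 2, v, n - 1)
  ci_low <- n * (msr - f_l * mse) /
    (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
  ci_high <- n * (f_u * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f_u * msr)
  structure(list(icc = icc, ci_low = min(ci_low, icc),
                 ci_high = max(ci_high, icc),
                 model = "two-way, absolute agreement, single rater",
                 msr = msr, msc = msc, mse = mse, n = n, k = k),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC(A,1) = %.3f [%.3f-%.3f] (%s; %d subjects x %d sessions)\n",
              x$icc, x$ci_low, x$ci_high, x$model, x$n, x$k))
  invisible(x)
}
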