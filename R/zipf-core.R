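#' Build the Zipf curve of an expression profile
#'
#' A Zipf curve summarises a profile \eqn{X = (X_1, \dots, X_n)} of
#' non-negative expression measures by its \eqn{m} distinct positive values
#' \eqn{z_1 > z_2 > \dots > z_m}, their frequencies \eqn{f_1, \dots, f_m}, and
#' the rank of each distinct value,
#' \deqn{r_i = \sum_{j=1}^n I(X_j \ge z_i) = \sum_{j \le i} f_j,}
#' i.e. the number of measures at least as large as \eqn{z_i}.  The scatter of
#' \eqn{\log r_i} against \eqn{\log z_i} is the Zipf plot; for a power-law
#' (Pareto) upper tail with index \eqn{\kappa} it is linear with slope
#' \eqn{1 - \kappa < 0}.
#'
#' Zeros do not appear as curve points (their logarithm is undefined); they are
#' counted in \code{n_zero} and in the total \code{n_total}.
#'
#' @param counts numeric vector of non-negative expression measures (raw
#'   integer counts or normalized fractional values).
#' @param sample_id optional label carried through for messages and tables.
#' @return An object of class \code{"zipf_curve"}: a list with components
#'   \code{values} (distinct positive values, strictly decreasing),
#'   \code{freqs} (their frequencies), \code{ranks} (cumulative ranks
#'   \eqn{r_i}), \code{n_total}, \code{n_zero} and \code{sample_id}.
#' @examples
#' zc <- zipf_curve(c(10, 10, 5, 1, 0))
#' zc$values # 10 5 1
#' zc$ranks  # 2 3 4
#' @seealso [fit_tail()], [log_survival()], [plot.zipf_curve()]
#' @export
zipf_curve <- function(counts, sample_id = NULL) {
  if (!is.numeric(counts) || length(counts) == 0L)
    stop("'counts' must be a non-empty numeric vector")
  if (anyNA(counts)) stop("'counts' contains missing values")
  if (any(counts < 0)) stop("'counts' contains negative values")
  pos <- counts[counts > 0]
  if (length(pos) == 0L)
    stop("no positive measures: cannot build a Zipf curve from an all-zero profile",
         if (!is.null(sample_id)) paste0(" (sample '", sample_id, "')") else "")
  # exact double comparison; avoids the value -> character round trip of table()
  s <- sort(pos, decreasing = TRUE)
  values <- unique(s)
  freqs <- tabulate(match(s, values))
  structure(list(
    values = values,
    freqs = freqs,
    ranks = cumsum(freqs),
    n_total = length(counts),
    n_zero = length(counts) - length(pos),
    sample_id = sample_id
  ), class = "zipf_curve")
}

#' @export
print.zipf_curve <- function(x, ...) {
  cat("Zipf curve",
      if (!is.null(x$sample_id)) paste0("of sample '", x$sample_id, "'") else "",
      "\n")
  cat(sprintf("  %d distinct positive values over %d genes (%d zeros, %.1f%%)\n",
              length(x$values), x$n_total, x$n_zero, 100 * x$n_zero / x$n_total))
  cat(sprintf("  value range [%g, %g], max rank %d\n",
              min(x$values), max(x$values), max(x$ranks)))
  invisible(x)
}

#' Zipf plot coordinates on the log-survival scale
#'
#' Replaces the log rank by the log of the empirical survival function,
#' \eqn{\log S(z_i) = \log r_i - \log n}, a downward shift of \eqn{\log n}
#' that makes curves from profiles of different sizes directly comparable.
#'
#' @param curve a [zipf_curve()] object.
#' @return A two-column matrix with columns \code{log_value} and
#'   \code{log_survival} (natural logarithms).
#' @export
log_survival <- function(curve) {
  stopifnot(inherits(curve, "zipf_curve"))
  cbind(log_value = log(curve$values),
        log_survival = log(curve$ranks) - log(curve$n_total))
}

#' Fit a least-squares line to the upper tail of a Zipf curve
#'
#' Selects the distinct-value points of the Zipf plot whose log rank falls
#' below \code{rank_cutoff_log} (the highest-expressed genes; the default 6
#' keeps points of rank \eqn{\le \lfloor e^6 \rfloor = 403}) and fits ordinary
#' least squares of \eqn{\log r_i} on \eqn{\log z_i}.  Under a power-law tail
#' with index \eqn{\kappa}, the slope estimates \eqn{1 - \kappa}, so
#' \eqn{\hat\kappa = 1 - \mathrm{slope}}.
#'
#' Tail membership is by rank cutoff, not by a lower value threshold
#' \eqn{x_{\min}}; each distinct value contributes one unweighted point,
#' matching the plotted object.
#'
#' @param curve a [zipf_curve()] object.
#' @param rank_cutoff_log tail points are those with
#'   \code{log(rank) < rank_cutoff_log} (natural log; default 6).
#' @param min_tail_points minimum number of qualifying points required
#'   (default 10).
#' @return An object of class \code{"zipf_tail_fit"}: list with \code{slope},
#'   \code{intercept}, \code{kappa} (\code{= 1 - slope}), \code{r_squared},
#'   \code{n_points}, \code{rank_cutoff_log}, \code{log_value},
#'   \code{log_rank} (the fitted points) and \code{sample_id}.
#' @examples
#' set.seed(1)
#' x <- rpareto(2000, kappa = 2.7, x_min = 1)
#' fit_tail(zipf_curve(x))
#' @export
fit_tail <- function(curve, rank_cutoff_log = 6, min_tail_points = 10) {
  stopifnot(inherits(curve, "zipf_curve"))
  keep <- log(curve$ranks) < rank_cutoff_log
  n_points <- sum(keep)
  if (n_points < min_tail_points)
    stop(sprintf(
      "only %d distinct tail points with log(rank) < %g%s; need at least %d",
      n_points, rank_cutoff_log,
      if (!is.null(curve$sample_id))
        paste0(" in sample '", curve$sample_id, "'") else "",
      min_tail_points))
  lz <- log(curve$values[keep])
  lr <- log(curve$ranks[keep])
  fit <- stats::lm.fit(cbind(1, lz), lr)
  slope <- unname(fit$coefficients[2L])
  intercept <- unname(fit$coefficients[1L])
  tss <- sum((lr - mean(lr))^2)
  r_squared <- if (tss > 0) 1 - sum(fit$residuals^2) / tss else NA_real_
  structure(list(
    slope = slope,
    intercept = intercept,
    kappa = 1 - slope,
    r_squared = r_squared,
    n_points = n_points,
    rank_cutoff_log = rank_cutoff_log,
    log_value = lz,
    log_rank = lr,
    sample_id = curve$sample_id
  ), class = "zipf_tail_fit")
}

#' @export
print.zipf_tail_fit <- function(x, ...) {
  cat("Zipf tail fit",
      if (!is.null(x$sample_id)) paste0("(sample '", x$sample_id, "')") else "",
      "\n")
  cat(sprintf("  slope %.4f (kappa = %.4f), intercept %.4f\n",
              x$slope, x$kappa, x$intercept))
  cat(sprintf("  %d tail points with log(rank) < %g, R-squared %.4f\n",
              x$n_points, x$rank_cutoff_log, x$r_squared))
  invisible(x)
}

#' @export
coef.zipf_tail_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' Plot a Zipf curve and (optionally) its fitted tail line
#'
#' @param x a [zipf_curve()] object.
#' @param fit optional [fit_tail()] result to overlay.
#' @param survival if \code{TRUE}, plot log survival instead of log rank on
#'   the y-axis.
#' @param ... further arguments passed to [graphics::plot()].
#' @export
plot.zipf_curve <- function(x, fit = NULL, survival = FALSE, ...) {
  lz <- log(x$values)
  ly <- if (survival) log(x$ranks) - log(x$n_total) else log(x$ranks)
  graphics::plot(lz, ly, xlab = "log value",
                 ylab = if (survival) "log survival" else "log rank", ...)
  if (!is.null(fit)) {
    off <- if (survival) -log(x$n_total) else 0
    graphics::abline(fit$intercept + off, fit$slope, lty = 2)
  }
  invisible(x)
}

#' Export Zipf-plot coordinates as delimited text
#'
#' Writes a two-column tab-separated table (\code{log_value}, \code{log_rank})
#' for external plotting.
#'
#' @param curve a [zipf_curve()] object.
#' @param path output file path.
#' @export
write_zipf_points <- function(curve, path) {
  stopifnot(inherits(curve, "zipf_curve"))
  df <- data.frame(log_value = log(curve$values), log_rank = log(curve$ranks))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
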