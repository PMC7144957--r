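#' Power-transform exponent from two tail slopes
#'
#' The non-linear normalizing parameter \eqn{\gamma} makes the Zipf-plot tail
#' slope of the transformed target \eqn{Y^\gamma} equal that of the reference
#' \eqn{X}: raising a profile to the power \eqn{a} multiplies its Zipf slope
#' by \eqn{1/a}, so \eqn{\gamma = \mathrm{slope}_Y / \mathrm{slope}_X}.  With
#' the published example slopes \eqn{-1.734} (reference) and \eqn{-1.730}
#' (target) this gives \eqn{\hat\gamma = (-1.730)/(-1.734) = 0.9977}.
#'
#' @param fit_x tail fit of the reference profile ([fit_tail()]).
#' @param fit_y tail fit of the target profile.
#' @return the positive scalar \eqn{\hat\gamma}.
#' @export
estimate_gamma <- function(fit_x, fit_y) {
  stopifnot(inherits(fit_x, "zipf_tail_fit"), inherits(fit_y, "zipf_tail_fit"))
  if (fit_x$slope >= 0 || fit_y$slope >= 0)
    stop(sprintf(
      "tail slopes must be strictly negative (heavy-tailed decreasing); got %.4f and %.4f",
      fit_x$slope, fit_y$slope))
  fit_y$slope / fit_x$slope
}

#' Pool the tail points of two Zipf curves
#'
#' Stacks the qualifying tail points (log rank below the cutoff) of a
#' reference curve (group 0) and a target curve (group 1) into one table,
#' optionally power-transforming the target's log values by \code{gamma}.
#'
#' @inheritParams estimate_log_sigma
#' @return data.frame with columns \code{log_value}, \code{log_rank},
#'   \code{group}.
#' @keywords internal
pooled_tail_points <- function(curve_x, curve_y, rank_cutoff_log = 6,
                               min_tail_points = 10, gamma = 1) {
  fx <- fit_tail(curve_x, rank_cutoff_log, min_tail_points)
  fy <- fit_tail(curve_y, rank_cutoff_log, min_tail_points)
  data.frame(
    log_value = c(fx$log_value, gamma * fy$log_value),
    log_rank = c(fx$log_rank, fy$log_rank),
    group = rep(c(0L, 1L), c(fx$n_points, fy$n_points))
  )
}

#' Estimate the log rescaling factor by a pooled tail regression
#'
#' Pools the Zipf-plot tail points of the reference profile \eqn{X} (group
#' indicator \eqn{G = 0}) and the target profile \eqn{Y} (\eqn{G = 1}) and
#' fits the shared-slope linear model
#' \deqn{Z = \alpha + \beta R + c\, G,}
#' where \eqn{Z} are log values and \eqn{R} log ranks.  The coefficient
#' \eqn{c} of \eqn{G} is the horizontal distance the target's Zipf plot must
#' move to overlay the reference's, i.e. \eqn{\log\sigma}: dividing \eqn{Y}
#' by \eqn{\sigma = e^{c}} aligns the two tails.
#'
#' When \code{gamma != 1} the target's log values enter the design already
#' power-transformed (\eqn{\gamma \log z^y}); the coefficient of \eqn{G} then
#' estimates \eqn{\gamma \log\sigma}, and the returned value is divided by
#' \eqn{\gamma} so that it is always \eqn{\log\sigma} of the transform
#' \eqn{Y' = (Y/\sigma)^\gamma}.
#'
#' @param curve_x reference [zipf_curve()].
#' @param curve_y target [zipf_curve()].
#' @param rank_cutoff_log tail cutoff on the natural-log rank scale
#'   (default 6).
#' @param min_tail_points minimum qualifying points per profile (default 10).
#' @param gamma power-transform exponent applied to the target's tail
#'   (default 1, pure rescaling).
#' @return the scalar \eqn{\log\hat\sigma}.
#' @export
estimate_log_sigma <- function(curve_x, curve_y, rank_cutoff_log = 6,
                               min_tail_points = 10, gamma = 1) {
  stopifnot(gamma > 0)
  pts <- pooled_tail_points(curve_x, curve_y, rank_cutoff_log,
                            min_tail_points, gamma)
  fit <- stats::lm.fit(cbind(1, pts$log_rank, pts$group), pts$log_value)
  unname(fit$coefficients[3L]) / gamma
}

#' Apply the two-parameter normalization to a profile
#'
#' Transforms each measure \eqn{y} to \eqn{y' = (y/\sigma)^\gamma}.  Zeros map
#' exactly to zero; the transform is strictly increasing on positive values,
#' so within-profile gene ranking is preserved.  Output values are real, not
#' re-rounded to integers.
#'
#' @param counts numeric vector of non-negative measures.
#' @param sigma positive linear rescaling factor.
#' @param gamma positive power-transform exponent.
#' @return numeric vector of the same length, names preserved.
#' @examples
#' normalize_profile(c(0, 4), sigma = 4, gamma = 0.5) # 0 1
#' @export
normalize_profile <- function(counts, sigma = 1, gamma = 1) {
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0)
    stop("'sigma' must be a single positive number")
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma <= 0)
    stop("'gamma' must be a single positive number")
  out <- (counts / sigma)^gamma
  out[counts == 0] <- 0
  out
}

#' Choose the reference profile of a count matrix
#'
#' @param counts gene-by-sample matrix of non-negative measures.
#' @param strategy \code{"fewest_zeros"} picks the sample with the minimum
#'   number of zero entries (ties broken by column order); any other string is
#'   taken as a sample (column) name.
#' @return the reference sample id (column name).
#' @export
select_reference <- function(counts, strategy = "fewest_zeros") {
  counts <- as_count_matrix(counts)
  if (identical(strategy, "fewest_zeros")) {
    nz <- colSums(counts == 0)
    return(colnames(counts)[which.min(nz)])
  }
  if (!strategy %in% colnames(counts))
    stop(sprintf("reference sample '%s' not found among the %d columns",
                 strategy, ncol(counts)))
  strategy
}

# coerce to a numeric matrix with sample names, validating non-negativity
as_count_matrix <- function(counts) {
  if (is.data.frame(counts)) counts <- as.matrix(counts)
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("'counts' must be a numeric gene-by-sample matrix")
  if (ncol(counts) < 1L) stop("'counts' has no samples")
  if (anyNA(counts)) stop("'counts' contains missing values")
  if (any(counts < 0)) stop("'counts' contains negative values")
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("S", seq_len(ncol(counts)))
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("g", seq_len(nrow(counts)))
  counts
}

#' Zipf-plot based normalization of a count matrix
#'
#' Normalizes every profile (column) of a gene-by-sample count matrix against
#' a reference profile so that the upper tails of their Zipf plots coincide.
#' Each target \eqn{Y} is transformed as \eqn{Y' = (Y/\sigma)^\gamma}.
#'
#' Under \code{scheme = "linear"} only the rescaling factor \eqn{\sigma} is
#' estimated (\eqn{\gamma = 1}), by the pooled tail regression of
#' [estimate_log_sigma()].  Under \code{scheme = "full"} the exponent
#' \eqn{\gamma} is first estimated from the ratio of the two fitted tail
#' slopes ([estimate_gamma()]), and \eqn{\sigma} is then estimated on the
#' already power-transformed target tail so that the pair is jointly
#' consistent with the transform (set \code{sigma_on_raw_tails = TRUE} to
#' estimate \eqn{\sigma} from the untransformed tails instead).
#'
#' With \code{refine = TRUE} each pair \eqn{(\sigma, \gamma)} is further
#' refined by a deterministic grid search minimizing the two-sample
#' Kolmogorov-Smirnov distance between the reference and the normalized
#' target (see [refine_params()]); under the linear scheme the grid varies
#' \eqn{\sigma} only.
#'
#' @param counts gene-by-sample matrix (or data.frame) of non-negative
#'   measures; raw integer counts in the intended use.
#' @param reference \code{"fewest_zeros"} or a sample name
#'   (see [select_reference()]).
#' @param scheme \code{"linear"} (rescaling only) or \code{"full"}
#'   (rescaling + power transform).
#' @param rank_cutoff_log,min_tail_points tail selection, as in [fit_tail()].
#' @param refine logical; run the Kolmogorov-Smirnov grid refinement.
#' @param grid a [grid_spec()] controlling the refinement grid (centres are
#'   set per sample from the regression estimates).
#' @param sigma_on_raw_tails logical; see Details.
#' @return An object of class \code{"zipf_norm"}: list with components
#'   \code{normalized} (the normalized matrix; reference column unchanged),
#'   \code{params} (data.frame: \code{sample_id}, \code{sigma}, \code{gamma},
#'   \code{method}, \code{reference_id}, \code{estimator}, and when refined
#'   \code{ks_initial}, \code{ks_refined}), \code{tail_fits} (per-sample
#'   [fit_tail()] results), \code{reference}, \code{scheme} and \code{call}.
#' @examples
#' sim <- simulate_zipf_counts(n_genes = 5000, n_samples = 3,
#'                             sigma = c(1, 0.5, 2), seed = 1,
#'                             rounding = "continuous")
#' fit <- zipf_normalize(sim$counts)
#' coef(fit)
#' @seealso [normalized_counts()], [summary.zipf_norm()], [baseline_factor()]
#' @export
zipf_normalize <- function(counts, reference = "fewest_zeros",
                           scheme = c("linear", "full"),
                           rank_cutoff_log = 6, min_tail_points = 10,
                           refine = FALSE, grid = grid_spec(),
                           sigma_on_raw_tails = FALSE) {
  scheme <- match.arg(scheme)
  counts <- as_count_matrix(counts)
  ref_id <- select_reference(counts, reference)
  ids <- colnames(counts)

  curves <- lapply(ids, function(id) zipf_curve(counts[, id], sample_id = id))
  names(curves) <- ids
  fits <- lapply(curves, function(cv)
    fit_tail(cv, rank_cutoff_log, min_tail_points))

  method <- if (scheme == "linear") "ZN-linear" else "ZN-full"
  estimator <- if (refine) "ks_refined" else "ols"
  ref_curve <- curves[[ref_id]]
  ref_fit <- fits[[ref_id]]
  ref_pos <- counts[, ref_id][counts[, ref_id] > 0]

  sigma <- gamma <- ks0 <- ks1 <- stats::setNames(numeric(length(ids)), ids)
  normalized <- counts
  for (id in ids) {
    if (id == ref_id) {
      sigma[id] <- 1; gamma[id] <- 1
      ks0[id] <- ks1[id] <- 0
      next
    }
    g <- if (scheme == "full") estimate_gamma(ref_fit, fits[[id]]) else 1
    ls <- estimate_log_sigma(ref_curve, curves[[id]],
                             rank_cutoff_log, min_tail_points,
                             gamma = if (sigma_on_raw_tails) 1 else g)
    s <- exp(ls)
    if (refine) {
      y_pos <- counts[, id][counts[, id] > 0]
      gr <- grid
      gr$center <- c(sigma = s, gamma = g)
      if (scheme == "linear") {          # keep gamma pinned at 1
        gr$gamma_steps <- 1L
        gr$gamma_halfwidth <- 0
      }
      rf <- refine_params(ref_pos, y_pos, gr)
      ks0[id] <- rf$ks_initial$distance
      ks1[id] <- rf$ks_optimum$distance
      s <- rf$sigma
      g <- rf$gamma
    }
    sigma[id] <- s
    gamma[id] <- g
    normalized[, id] <- normalize_profile(counts[, id], s, g)
  }

  params <- data.frame(
    sample_id = ids,
    sigma = unname(sigma),
    gamma = unname(gamma),
    method = method,
    reference_id = ref_id,
    estimator = estimator,
    r_squared = vapply(fits, function(f) f$r_squared, numeric(1)),
    row.names = NULL
  )
  if (refine) {
    params$ks_initial <- unname(ks0)
    params$ks_refined <- unname(ks1)
  }
  structure(list(
    normalized = normalized,
    params = params,
    tail_fits = fits,
    reference = ref_id,
    scheme = scheme,
    rank_cutoff_log = rank_cutoff_log,
    refine = refine,
    call = match.call()
  ), class = "zipf_norm")
}

#' Extract the normalized matrix
#'
#' @param object a [zipf_normalize()] fit.
#' @return the gene-by-sample matrix of normalized (real-valued) measures.
#' @export
normalized_counts <- function(object) {
  stopifnot(inherits(object, "zipf_norm"))
  object$normalized
}

#' @export
print.zipf_norm <- function(x, ...) {
  cat(sprintf("Zipf-plot normalization (%s scheme%s)\n", x$scheme,
              if (x$refine) ", KS-refined" else ""))
  cat(sprintf("  %d genes x %d samples; reference '%s'\n",
              nrow(x$normalized), ncol(x$normalized), x$reference))
  cat("  sigma: "); print(summary(x$params$sigma))
  if (x$scheme == "full") {
    cat("  gamma: "); print(summary(x$params$gamma))
  }
  invisible(x)
}

#' Per-sample normalizing parameters
#'
#' @param object a [zipf_normalize()] fit.
#' @param ... unused.
#' @return matrix with one row per sample and columns \code{sigma},
#'   \code{gamma}.
#' @export
coef.zipf_norm <- function(object, ...) {
  m <- cbind(sigma = object$params$sigma, gamma = object$params$gamma)
  rownames(m) <- object$params$sample_id
  m
}

#' Summarise a normalization fit
#'
#' Produces the distribution summary of the estimated rescaling factors
#' (min, quartiles, mean, max, SD) together with the fraction of samples
#' scaled up (\eqn{\sigma < 1}: division increases the measures) and left
#' unchanged (\eqn{\sigma = 1}), plus the tail-slope summary.
#'
#' @param object a [zipf_normalize()] fit.
#' @param ... unused.
#' @export
summary.zipf_norm <- function(object, ...) {
  slopes <- vapply(object$tail_fits, function(f) f$slope, numeric(1))
  structure(list(
    factor_summary = summarize_factors(object$params),
    slopes = slopes,
    scheme = object$scheme,
    reference = object$reference,
    dim = dim(object$normalized)
  ), class = "summary.zipf_norm")
}

#' @export
print.summary.zipf_norm <- function(x, ...) {
  cat(sprintf("Zipf-plot normalization (%s scheme), %d genes x %d samples, reference '%s'\n",
              x$scheme, x$dim[1], x$dim[2], x$reference))
  cat("\nNormalizing parameters (sigma):\n")
  print(x$factor_summary, digits = 4)
  cat("\nZipf tail slopes:\n")
  print(summary(x$slopes))
  invisible(x)
}

#' Zipf plots before and after normalization
#'
#' Overlays the Zipf curves of all samples for the raw (left) and normalized
#' (right) matrices; well-normalized profiles collapse onto a common curve.
#'
#' @param x a [zipf_normalize()] fit.
#' @param raw optional raw matrix to draw the "before" panel (defaults to
#'   reconstructing it from the stored parameters).
#' @param ... passed to [graphics::plot()].
#' @export
plot.zipf_norm <- function(x, raw = NULL, ...) {
  if (is.null(raw)) {
    raw <- x$normalized
    for (j in seq_len(ncol(raw))) {
      p <- x$params[j, ]
      pos <- raw[, j] > 0
      raw[pos, j] <- raw[pos, j]^(1 / p$gamma) * p$sigma
    }
  }
  op <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(op))
  for (mat in list(raw = raw, normalized = x$normalized)) {
    first <- TRUE
    for (j in seq_len(ncol(mat))) {
      cv <- zipf_curve(mat[, j])
      if (first) {
        graphics::plot(log(cv$values), log(cv$ranks), type = "l",
                       xlab = "log value", ylab = "log rank", ...)
        first <- FALSE
      } else graphics::lines(log(cv$values), log(cv$ranks), col = j)
    }
  }
  invisible(x)
}
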