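#' Pairwise baseline normalizing factor
#'
#' Simplified pairwise formulations of five popular linear normalizers,
#' computed for one target profile against one reference profile.  Each
#' returns a rescaling factor \eqn{\sigma} (with \eqn{\gamma = 1}); the
#' normalized target is \code{target / sigma}.
#'
#' \describe{
#'   \item{TC}{total count ratio, \eqn{\sigma = \sum y / \sum x}.}
#'   \item{MED}{ratio of medians after the zero policy.}
#'   \item{UQ}{ratio of upper quartiles (level \code{quartile_level}) after
#'     the zero policy.}
#'   \item{TMM}{trimmed mean of M-values: over genes surviving the zero
#'     policy, \eqn{M_g = \log(y_g / x_g)}; the lowest and highest
#'     \code{trim_fraction} of the M-values are dropped and
#'     \eqn{\sigma = \exp(\bar M)} of the rest.}
#'   \item{RLE}{relative log expression, \eqn{\sigma = \exp(\mathrm{median}\,
#'     M_g)} after the zero policy.}
#' }
#'
#' These are deliberately the plain pairwise versions (no reference-free
#' geometric means, no expression-level trimming or precision weights), so
#' they will not in general reproduce edgeR's \code{calcNormFactors} or
#' DESeq2's \code{estimateSizeFactors}.
#'
#' The default zero policy \code{"auto_cascade"} first drops genes that are
#' zero in \emph{both} profiles; if the resulting statistic is invalid (zero
#' median or quartile, non-finite trimmed mean or median of M), it refilters
#' dropping genes zero in \emph{either} profile and recomputes.  The path
#' taken is recorded in the \code{zero_path} column.  TC uses all genes.
#'
#' @param method one of \code{"tc"}, \code{"med"}, \code{"uq"}, \code{"tmm"},
#'   \code{"rle"} (case-insensitive).
#' @param target,reference numeric vectors of non-negative measures over the
#'   same gene index.
#' @param trim_fraction fraction of M-values trimmed from each end for TMM
#'   (default 0.30).
#' @param quartile_level quantile level for UQ (default 0.75; linear
#'   interpolation between order statistics).
#' @param zero_policy \code{"auto_cascade"}, \code{"both_zero_only"} or
#'   \code{"either_zero"}.
#' @param target_id,reference_id optional labels for the returned table and
#'   error messages.
#' @return one-row data.frame: \code{sample_id}, \code{sigma}, \code{gamma}
#'   (always 1), \code{method}, \code{reference_id}, \code{estimator}
#'   (\code{"baseline"}), \code{zero_path} (\code{"none"},
#'   \code{"both_zero"} or \code{"either_zero"}).
#' @examples
#' x <- c(10, 0, 4, 8, 0)
#' baseline_factor("tc", 2 * x, x)$sigma # 2
#' @export
baseline_factor <- function(method, target, reference,
                            trim_fraction = 0.30, quartile_level = 0.75,
                            zero_policy = c("auto_cascade", "both_zero_only",
                                            "either_zero"),
                            target_id = "target", reference_id = "reference") {
  method <- toupper(match.arg(tolower(method),
                              c("tc", "med", "uq", "tmm", "rle")))
  zero_policy <- match.arg(zero_policy)
  stopifnot(length(target) == length(reference),
            all(target >= 0), all(reference >= 0),
            trim_fraction >= 0, trim_fraction < 0.5)

  if (method == "TC") {
    if (sum(reference) == 0) stop("TC: reference profile sums to zero")
    sigma <- sum(target) / sum(reference)
    return(baseline_row(target_id, sigma, method, reference_id, "none"))
  }

  stat <- function(keep) {
    y <- target[keep]; x <- reference[keep]
    if (length(y) == 0L) return(NA_real_)
    switch(method,
      MED = {
        my <- stats::median(y); mx <- stats::median(x)
        if (my <= 0 || mx <= 0) NA_real_ else my / mx
      },
      UQ = {
        qy <- unname(stats::quantile(y, quartile_level))
        qx <- unname(stats::quantile(x, quartile_level))
        if (qy <= 0 || qx <= 0) NA_real_ else qy / qx
      },
      TMM = {
        m <- sort(log(y / x))
        k <- floor(length(m) * trim_fraction)
        kept <- m[(k + 1):(length(m) - k)]
        v <- exp(mean(kept))
        if (is.finite(v) && v > 0) v else NA_real_
      },
      RLE = {
        v <- exp(stats::median(log(y / x)))
        if (is.finite(v) && v > 0) v else NA_real_
      })
  }

  paths <- switch(zero_policy,
    auto_cascade = c("both_zero", "either_zero"),
    both_zero_only = "both_zero",
    either_zero = "either_zero")
  for (p in paths) {
    keep <- if (p == "both_zero") !(target == 0 & reference == 0)
            else target > 0 & reference > 0
    sigma <- stat(keep)
    if (!is.na(sigma))
      return(baseline_row(target_id, sigma, method, reference_id, p))
  }
  stop(sprintf(
    "%s: no valid normalizing factor for sample '%s' (zero policy exhausted)",
    method, target_id))
}

baseline_row <- function(sample_id, sigma, method, reference_id, zero_path) {
  data.frame(sample_id = sample_id, sigma = sigma, gamma = 1,
             method = method, reference_id = reference_id,
             estimator = "baseline", zero_path = zero_path,
             row.names = NULL)
}

#' Baseline-normalize a whole count matrix
#'
#' Applies [baseline_factor()] to every column against a reference column and
#' rescales; the reference column is unchanged (\eqn{\sigma = 1}).
#'
#' @param counts gene-by-sample matrix of non-negative measures.
#' @param method baseline method, as in [baseline_factor()].
#' @param reference \code{"fewest_zeros"} or a sample name.
#' @param ... passed on to [baseline_factor()].
#' @return an object of class \code{"zipf_norm"} (normalized matrix + params
#'   table), so the same summary and evaluation tooling applies.
#' @export
baseline_normalize <- function(counts, method, reference = "fewest_zeros",
                               ...) {
  counts <- as_count_matrix(counts)
  ref_id <- select_reference(counts, reference)
  ids <- colnames(counts)
  rows <- vector("list", length(ids))
  normalized <- counts
  for (j in seq_along(ids)) {
    id <- ids[j]
    if (id == ref_id) {
      rows[[j]] <- baseline_row(id, 1, toupper(method), ref_id, "none")
    } else {
      rows[[j]] <- baseline_factor(method, counts[, id], counts[, ref_id],
                                   target_id = id, reference_id = ref_id, ...)
      normalized[, id] <- counts[, id] / rows[[j]]$sigma
    }
  }
  structure(list(
    normalized = normalized,
    params = do.call(rbind, rows),
    tail_fits = NULL,
    reference = ref_id,
    scheme = "baseline",
    refine = FALSE,
    call = match.call()
  ), class = "zipf_norm")
}

#' Summary table of normalizing factors
#'
#' Distribution summary of the estimated \eqn{\sigma} per method: Min,
#' 1st Qu., Median, Mean, 3rd Qu., Max, SD, plus \code{Scal Up} (the fraction
#' of samples with \eqn{\sigma < 1}; dividing by \eqn{\sigma < 1} scales
#' expressions up) and \code{No Chng} (the fraction with \eqn{\sigma}
#' exactly 1; tied quantiles in zero-inflated integer data produce exact
#' ties).
#'
#' @param params data.frame with at least \code{sigma} and \code{method}
#'   columns (one row per normalized sample), e.g. the \code{params}
#'   component of a [zipf_normalize()] or [baseline_normalize()] fit, or
#'   several such tables row-bound together.
#' @param exclude_reference drop rows where \code{sample_id} equals
#'   \code{reference_id} before summarising (default \code{TRUE}; the
#'   reference is not itself normalized).
#' @return matrix with one row per method and columns \code{Min.},
#'   \code{1st Qu.}, \code{Median}, \code{Mean}, \code{3rd Qu.}, \code{Max.},
#'   \code{SD}, \code{Scal Up}, \code{No Chng}.
#' @export
summarize_factors <- function(params, exclude_reference = TRUE) {
  stopifnot(is.data.frame(params), nrow(params) > 0,
            all(c("sigma", "method") %in% names(params)))
  if (exclude_reference && all(c("sample_id", "reference_id") %in% names(params)))
    params <- params[params$sample_id != params$reference_id, , drop = FALSE]
  if (nrow(params) == 0) stop("no non-reference samples to summarise")
  methods <- unique(params$method)
  out <- t(vapply(methods, function(m) {
    s <- params$sigma[params$method == m]
    q <- unname(stats::quantile(s, c(0, 0.25, 0.5, 0.75, 1)))
    c(`Min.` = q[1], `1st Qu.` = q[2], Median = q[3], Mean = mean(s),
      `3rd Qu.` = q[4], `Max.` = q[5], SD = stats::sd(s),
      `Scal Up` = mean(s < 1), `No Chng` = mean(s == 1))
  }, numeric(9)))
  rownames(out) <- methods
  out
}
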