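#' Per-gene coefficients of variation across normalized samples
#'
#' For each gene, the coefficient of variation CV = sd / mean of its
#' normalized values across all samples (sample standard deviation, n - 1
#' denominator; zeros included in the computation).  Genes with
#' \code{zero_exclusion_fraction} or more of their values equal to zero are
#' marked ineligible for invariant selection — most of them are weakly
#' expressed and dominated by measurement error — and get \code{NA} CV.
#'
#' @param normalized gene-by-sample matrix of normalized measures (at least
#'   two samples).
#' @param zero_exclusion_fraction a gene is ineligible when its zero fraction
#'   is at least this value (default 0.5).
#' @return An object of class \code{"invariant_report"}: list with
#'   \code{gene_cv} (named vector, \code{NA} where ineligible),
#'   \code{eligible} (named logical), and empty selection slots to be filled
#'   by [select_invariants()].
#' @export
gene_cv <- function(normalized, zero_exclusion_fraction = 0.5) {
  normalized <- as_count_matrix(normalized)
  if (ncol(normalized) < 2L) stop("need at least two samples to compute CVs")
  zero_frac <- rowMeans(normalized == 0)
  eligible <- zero_frac < zero_exclusion_fraction
  mu <- rowMeans(normalized)
  if (any(eligible & mu == 0))
    stop("eligible gene with zero mean: inconsistent input")
  # sample sd, n-1 denominator
  n <- ncol(normalized)
  sdev <- sqrt(rowSums((normalized - mu)^2) / (n - 1))
  cv <- ifelse(eligible, sdev / mu, NA_real_)
  names(cv) <- rownames(normalized)
  structure(list(
    gene_cv = cv,
    eligible = stats::setNames(eligible, rownames(normalized)),
    invariant_ids = NULL,
    cutoff_cv = NA_real_,
    n_selected = 0L
  ), class = "invariant_report")
}

#' @export
print.invariant_report <- function(x, ...) {
  cat(sprintf("Invariant report: %d genes, %d eligible (< 50%% zeros)\n",
              length(x$eligible), sum(x$eligible)))
  if (x$n_selected > 0L)
    cat(sprintf("  %d invariants selected, cutoff CV = %.4f\n",
                x$n_selected, x$cutoff_cv))
  invisible(x)
}

#' Select the invariant gene set
#'
#' Invariants are the \code{n} eligible genes with the smallest CV —
#' strongly, stably expressed genes whose spread after normalization
#' indicates how well a method aligned the samples.  Ties at the selection
#' boundary are broken by gene-index order.  The cutoff CV is the largest CV
#' among the selected genes.
#'
#' @param report an [gene_cv()] report.
#' @param n number of invariants (default 1000).
#' @return the report with \code{invariant_ids}, \code{cutoff_cv} and
#'   \code{n_selected} filled in.
#' @export
select_invariants <- function(report, n = 1000) {
  stopifnot(inherits(report, "invariant_report"))
  elig <- which(report$eligible)
  if (length(elig) < n)
    stop(sprintf("only %d eligible genes; cannot select %d invariants",
                 length(elig), n))
  ord <- elig[order(report$gene_cv[elig], elig)][seq_len(n)]
  report$invariant_ids <- names(report$eligible)[sort(ord)]
  report$cutoff_cv <- max(report$gene_cv[ord])
  report$n_selected <- as.integer(n)
  report
}

#' Agreement matrix between normalization methods
#'
#' Compares invariant selections across methods in one square matrix:
#' the diagonal holds each method's cutoff CV; the lower triangle the number
#' of invariants identified by both methods; the upper triangle the Spearman
#' rank correlation (average ranks for ties) between the two methods' CV
#' vectors over genes eligible under both.
#'
#' @param reports named list of completed [select_invariants()] reports that
#'   share the gene index and \code{n_selected}.
#' @return square numeric matrix with method names as dimnames.
#' @export
agreement <- function(reports) {
  stopifnot(is.list(reports), length(reports) >= 1,
            !is.null(names(reports)))
  k <- length(reports)
  gidx <- names(reports[[1]]$eligible)
  for (r in reports) {
    stopifnot(inherits(r, "invariant_report"))
    if (!identical(names(r$eligible), gidx))
      stop("reports do not share the same gene index")
    if (r$n_selected == 0L)
      stop("all reports must have invariants selected")
  }
  out <- matrix(NA_real_, k, k, dimnames = list(names(reports), names(reports)))
  for (i in seq_len(k)) {
    out[i, i] <- reports[[i]]$cutoff_cv
    for (j in seq_len(k)) {
      if (j >= i) next
      out[i, j] <- length(intersect(reports[[i]]$invariant_ids,
                                    reports[[j]]$invariant_ids))
      both <- reports[[i]]$eligible & reports[[j]]$eligible
      out[j, i] <- stats::cor(reports[[i]]$gene_cv[both],
                              reports[[j]]$gene_cv[both],
                              method = "spearman")
    }
  }
  out
}

#' MA-plot data for a pair of profiles
#'
#' Per-gene log ratio \eqn{M = \log X - \log Y} against average log
#' expression \eqn{A = (\log X + \log Y)/2}, over genes positive in both
#' profiles (logs are undefined at zero).
#'
#' @param x,y numeric vectors over the same gene index (\code{x} the
#'   reference, \code{y} the target or its normalized version).
#' @param gene_ids optional gene labels (defaults to names of \code{x} or
#'   indices).
#' @return data.frame with columns \code{gene_id}, \code{m}, \code{a}.
#' @export
ma_data <- function(x, y, gene_ids = NULL) {
  stopifnot(length(x) == length(y))
  if (is.null(gene_ids))
    gene_ids <- if (!is.null(names(x))) names(x) else as.character(seq_along(x))
  keep <- x > 0 & y > 0
  if (!any(keep)) stop("no genes positive in both profiles")
  data.frame(gene_id = gene_ids[keep],
             m = log(x[keep]) - log(y[keep]),
             a = (log(x[keep]) + log(y[keep])) / 2,
             row.names = NULL)
}

#' Loess smooth of MA-plot data
#'
#' Thin diagnostic wrapper around [stats::loess()] for the trend of M
#' against A (spans 0.2 and 0.1 are typical choices).
#'
#' @param ma a [ma_data()] data.frame.
#' @param span loess smoothing span (default 0.2).
#' @param n number of evaluation points across the A range.
#' @return data.frame with columns \code{a} and \code{m_smooth}.
#' @export
ma_smooth <- function(ma, span = 0.2, n = 200) {
  fit <- stats::loess(m ~ a, data = ma, span = span,
                      family = "gaussian", degree = 2)
  a <- seq(min(ma$a), max(ma$a), length.out = n)
  data.frame(a = a, m_smooth = stats::predict(fit, data.frame(a = a)))
}
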