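#' Random draws from a Pareto (power-law) distribution
#'
#' Density \eqn{f(x) = (\kappa - 1)\, x_{\min}^{\kappa - 1} x^{-\kappa}} for
#' \eqn{x \ge x_{\min}}, by inversion.
#'
#' @param n number of draws.
#' @param kappa tail index, \eqn{\kappa > 1}; smaller is heavier.
#' @param x_min positive lower bound.
#' @export
rpareto <- function(n, kappa, x_min = 1) {
  stopifnot(kappa > 1, x_min > 0)
  x_min * stats::runif(n)^(-1 / (kappa - 1))
}

#' Simulate zero-inflated power-law-tailed count profiles
#'
#' Generates a gene-by-sample matrix emulating deeply zero-inflated bulk
#' RNA-seq profiles: each gene draws one latent base measure — zero with
#' probability \code{zero_fraction}; otherwise, with probability
#' \code{small_count_mass}, a small count (Poisson mean 3 truncated at
#' \eqn{\ge 1}, mimicking the heavy spike of counts \eqn{\le 10}); otherwise
#' a Pareto(\code{kappa}, \code{x_min}) draw forming the power-law upper
#' tail.  Sample \eqn{j} then observes the distorted measure
#' \eqn{\sigma_j \cdot \mathrm{base}^{1/\gamma_j}}, rounded to a count via
#' \code{floor(x + 0.5)} when \code{rounding = "counts"} or kept continuous
#' for distortion-recovery experiments unconfounded by rounding.
#'
#' The defaults (85\% zeros, \eqn{\kappa = 2.7} so the Zipf tail slope is
#' about \eqn{-1.7}) match the regime of deeply sequenced lymphoblastoid
#' cell-line profiles.  Because all samples share one latent base profile,
#' columns are exact monotone transforms of each other: the generator
#' isolates the between-sample distortion that normalization must undo.
#'
#' @param n_genes,n_samples matrix dimensions.
#' @param zero_fraction probability a gene's base measure is zero
#'   (default 0.85).
#' @param kappa power-law tail index (default 2.7).
#' @param x_min lower bound of the Pareto component (default 10, above the
#'   small-count range).
#' @param small_count_mass probability a positive gene is a small count
#'   rather than a tail draw (default 0.3).
#' @param sigma,gamma per-sample distortion parameters, recycled to
#'   \code{n_samples} (defaults: no distortion).
#' @param seed optional integer seed for exact reproducibility.
#' @param rounding \code{"counts"} (integer) or \code{"continuous"}.
#' @return list with \code{counts} (matrix, genes \code{g1..} by samples
#'   \code{S1..}) and \code{params} (data.frame \code{sample_id},
#'   \code{sigma}, \code{gamma} — the true distortions).
#' @examples
#' sim <- simulate_zipf_counts(2000, 2, sigma = c(1, 2), seed = 7)
#' colSums(sim$counts == 0) / 2000
#' @export
simulate_zipf_counts <- function(n_genes, n_samples,
                                 zero_fraction = 0.85, kappa = 2.7,
                                 x_min = 10, small_count_mass = 0.3,
                                 sigma = 1, gamma = 1, seed = NULL,
                                 rounding = c("counts", "continuous")) {
  rounding <- match.arg(rounding)
  stopifnot(n_genes >= 1, n_samples >= 1,
            zero_fraction >= 0, zero_fraction < 1,
            kappa > 1, x_min > 0,
            small_count_mass >= 0, small_count_mass <= 1,
            all(sigma > 0), all(gamma > 0))
  sigma <- rep_len(sigma, n_samples)
  gamma <- rep_len(gamma, n_samples)
  if (!is.null(seed)) set.seed(seed)

  u <- stats::runif(n_genes)
  base <- numeric(n_genes)
  small <- u >= zero_fraction & u < zero_fraction + (1 - zero_fraction) * small_count_mass
  tail <- u >= zero_fraction + (1 - zero_fraction) * small_count_mass
  base[small] <- stats::qpois(stats::runif(sum(small),
                                           stats::dpois(0, 3), 1), 3)
  base[tail] <- rpareto(sum(tail), kappa, x_min)

  counts <- matrix(0, n_genes, n_samples,
                   dimnames = list(paste0("g", seq_len(n_genes)),
                                   paste0("S", seq_len(n_samples))))
  for (j in seq_len(n_samples)) {
    obs <- sigma[j] * base^(1 / gamma[j])
    obs[base == 0] <- 0
    if (rounding == "counts") obs <- floor(obs + 0.5)
    counts[, j] <- obs
  }
  list(counts = counts,
       params = data.frame(sample_id = colnames(counts),
                           sigma = sigma, gamma = gamma))
}

#' Read a gene-by-sample count matrix
#'
#' Delimited text (TSV/CSV: header row of sample ids, first column gene
#' ids) or MatrixMarket (\code{.mtx} with sidecar label files
#' \code{<path>.rows} and \code{<path>.cols}, one label per line).
#'
#' @param path input file.
#' @param format \code{"auto"} (by extension), \code{"tsv"}, \code{"csv"} or
#'   \code{"mtx"}.
#' @return numeric matrix with gene row names and sample column names.
#' @export
read_counts <- function(path, format = c("auto", "tsv", "csv", "mtx")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, csv = "csv", mtx = "mtx",
                     tsv = , txt = , tab = "tsv",
                     stop(sprintf("cannot infer format from extension '%s'", ext)))
  }
  if (format == "mtx") {
    m <- as.matrix(Matrix::readMM(path))
    rows <- readLines(paste0(path, ".rows"))
    cols <- readLines(paste0(path, ".cols"))
    if (length(rows) != nrow(m) || length(cols) != ncol(m))
      stop("sidecar label files do not match the matrix dimensions")
    dimnames(m) <- list(rows, cols)
  } else {
    sep <- if (format == "csv") "," else "\t"
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            check.names = FALSE, colClasses = NA,
                            stringsAsFactors = FALSE)
    if (ncol(df) < 2) stop("expected a gene-id column plus at least one sample")
    ids <- as.character(df[[1]])
    if (anyDuplicated(ids))
      stop(sprintf("duplicate gene ids in '%s' (e.g. '%s')", path,
                   ids[duplicated(ids)][1]))
    m <- as.matrix(df[, -1, drop = FALSE])
    if (anyNA(m)) stop(sprintf("missing values in '%s'", path))
    if (!is.numeric(m)) stop(sprintf("non-numeric count entries in '%s'", path))
    rownames(m) <- ids
  }
  storage.mode(m) <- "double"
  if (anyNA(m)) stop(sprintf("missing values in '%s'", path))
  if (any(m < 0)) stop(sprintf("negative counts in '%s'", path))
  m
}

#' Write a gene-by-sample count matrix
#'
#' Inverse of [read_counts()]: TSV/CSV with a leading \code{gene_id} column,
#' or MatrixMarket plus \code{<path>.rows} / \code{<path>.cols} sidecars.
#'
#' @param counts numeric matrix with dimnames.
#' @param path output file.
#' @param format \code{"auto"}, \code{"tsv"}, \code{"csv"} or \code{"mtx"}.
#' @export
write_counts <- function(counts, path, format = c("auto", "tsv", "csv", "mtx")) {
  format <- match.arg(format)
  counts <- as_count_matrix(counts)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, csv = "csv", mtx = "mtx",
                     tsv = , txt = , tab = "tsv",
                     stop(sprintf("cannot infer format from extension '%s'", ext)))
  }
  if (format == "mtx") {
    Matrix::writeMM(methods::as(methods::as(Matrix::Matrix(counts),
                                            "CsparseMatrix"), "generalMatrix"),
                    path)
    writeLines(rownames(counts), paste0(path, ".rows"))
    writeLines(colnames(counts), paste0(path, ".cols"))
  } else {
    sep <- if (format == "csv") "," else "\t"
    df <- data.frame(gene_id = rownames(counts), counts,
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Drop genes that are zero in every sample
#'
#' @param counts gene-by-sample matrix.
#' @return list with \code{counts} (survivors, original order preserved) and
#'   \code{n_removed}.
#' @export
filter_all_zero_genes <- function(counts) {
  counts <- as_count_matrix(counts)
  keep <- rowSums(counts > 0) > 0
  list(counts = counts[keep, , drop = FALSE],
       n_removed = sum(!keep))
}
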