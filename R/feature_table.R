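#' Construct a feature table
#'
#' The central container of the pipeline: a features x samples matrix of
#' non-negative abundances. The same container serves OTU count tables,
#' gene-family/EC count tables and percent-scale relative-abundance tables;
#' the `units` tag records which interpretation applies and is enforced.
#'
#' @param counts Numeric matrix, features in rows, samples in columns, with
#'   unique rownames (feature ids) and colnames (sample ids).
#' @param units One of `"counts"` (non-negative integers), `"proportions"`
#'   (every sample column sums to 100, percent scale) or `"normalized"`
#'   (arbitrary non-negative values, e.g. quantile-normalized abundances).
#' @return An object of class `feature_table`: a list with elements
#'   `counts` (the matrix) and `units`.
#' @examples
#' m <- matrix(c(6, 2, 2, 2), 2, 2,
#'             dimnames = list(c("otu1", "otu2"), c("s1", "s2")))
#' ft <- feature_table(m)
#' feature_ids(ft)
#' @export
feature_table <- function(counts, units = c("counts", "proportions", "normalized")) {
  units <- match.arg(units)
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("`counts` must be a numeric matrix", call. = FALSE)
  # R drops zero-length dimnames to NULL; only non-empty dims need names
  if ((nrow(counts) > 0 && is.null(rownames(counts))) ||
      (ncol(counts) > 0 && is.null(colnames(counts))))
    stop("`counts` must have feature rownames and sample colnames", call. = FALSE)
  x <- structure(list(counts = counts, units = units), class = "feature_table")
  validate_feature_table(x)
  x
}

#' Validate a feature table's invariants
#'
#' Checks id uniqueness, non-negativity, integrality of count tables and the
#' percent-sum invariant of proportion tables. Called by every constructor
#' and reader; exported so user code can re-check after manual surgery.
#'
#' @param x A `feature_table`.
#' @return `x`, invisibly, or an error describing the violated invariant.
#' @export
validate_feature_table <- function(x) {
  stopifnot(inherits(x, "feature_table"))
  m <- x$counts
  if (anyDuplicated(rownames(m)))
    stop("duplicate feature ids: ",
         paste(unique(rownames(m)[duplicated(rownames(m))]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(colnames(m)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(m)[duplicated(colnames(m))]), collapse = ", "),
         call. = FALSE)
  if (anyNA(m)) stop("feature table contains missing values", call. = FALSE)
  if (any(m < 0)) stop("feature table contains negative values", call. = FALSE)
  if (x$units == "counts" && nrow(m) > 0 && ncol(m) > 0 &&
      any(abs(m - round(m)) > 1e-9))
    stop("a table tagged 'counts' must contain only integers", call. = FALSE)
  if (x$units == "proportions" && nrow(m) > 0 && ncol(m) > 0) {
    cs <- colSums(m)
    if (any(abs(cs - 100) > 1e-9))
      stop("a table tagged 'proportions' must have sample sums of 100 (percent scale); ",
           "worst deviation ", format(max(abs(cs - 100))), call. = FALSE)
  }
  invisible(x)
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table: %d features x %d samples [%s]\n",
              nrow(x$counts), ncol(x$counts), x$units))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$counts)

#' Feature and sample identifiers
#'
#' @param x A `feature_table`.
#' @return Character vector of ids, in table order.
#' @export
feature_ids <- function(x) rownames(x$counts)

#' @rdname feature_ids
#' @export
sample_ids <- function(x) colnames(x$counts)

#' Drop low-count features
#'
#' Keeps features whose total count across all samples is at least
#' `min_total` (boundary inclusive: a feature with exactly `min_total` reads
#' is kept). The sample set is unchanged; an empty result is allowed.
#' The study default removes OTUs with fewer than 10 sequences overall.
#'
#' @param x A counts `feature_table`.
#' @param min_total Minimum total count, inclusive.
#' @return Filtered `feature_table`.
#' @export
filter_min_count <- function(x, min_total = 10) {
  stopifnot(inherits(x, "feature_table"))
  if (min_total < 0) stop("`min_total` must be >= 0", call. = FALSE)
  keep <- rowSums(x$counts) >= min_total
  feature_table(x$counts[keep, , drop = FALSE], units = x$units)
}

#' Convert counts to percent-scale relative abundance
#'
#' Rescales every sample column to sum to 100. Idempotent on a table already
#' tagged `proportions`.
#'
#' @param x A `feature_table` with no all-zero sample.
#' @return A `feature_table` tagged `proportions`.
#' @export
relative_abundance <- function(x) {
  stopifnot(inherits(x, "feature_table"))
  cs <- colSums(x$counts)
  if (any(cs == 0))
    stop("all-zero sample(s): ", paste(colnames(x$counts)[cs == 0], collapse = ", "),
         call. = FALSE)
  feature_table(sweep(x$counts, 2, cs / 100, "/"), units = "proportions")
}
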