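#' Rarefy a count table to even depth
#'
#' Subsamples each sample column without replacement to exactly `depth`
#' reads (a single draw per sample, not an average over draws). Samples with
#' fewer than `depth` total reads are dropped with a warning. Per-feature
#' counts after rarefaction follow the (multivariate) hypergeometric
#' distribution, so expected counts are `depth * x / total`.
#'
#' @param x A counts `feature_table`.
#' @param depth Target reads per sample (> 0). The study rarefied at the
#'   minimum per-sample total after OTU filtering.
#' @param seed Optional integer seed for reproducibility.
#' @return A counts `feature_table` whose columns each sum to exactly `depth`.
#' @export
rarefy_table <- function(x, depth, seed = NULL) {
  stopifnot(inherits(x, "feature_table"))
  if (x$units != "counts") stop("rarefaction requires a counts table", call. = FALSE)
  if (depth <= 0) stop("`depth` must be > 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  totals <- colSums(x$counts)
  keep <- totals >= depth
  if (!all(keep))
    warning(sum(!keep), " sample(s) below depth ", depth, " dropped: ",
            paste(colnames(x$counts)[!keep], collapse = ", "), call. = FALSE)
  m <- x$counts[, keep, drop = FALSE]
  out <- m
  nf <- nrow(m)
  for (j in seq_len(ncol(m))) {
    if (sum(m[, j]) == depth) next  # already at depth: column unchanged
    pool <- rep.int(seq_len(nf), m[, j])
    drawn <- sample(pool, depth, replace = FALSE)
    out[, j] <- tabulate(drawn, nbins = nf)
  }
  feature_table(out, units = "counts")
}

#' Construct a sample dissimilarity matrix
#'
#' @param d Symmetric numeric matrix with zero diagonal and matching
#'   row/column sample ids.
#' @return An object of class `dist_matrix`.
#' @export
dist_matrix <- function(d) {
  if (!isSymmetric(unname(d), tol = 1e-12))
    stop("dissimilarity matrix must be symmetric", call. = FALSE)
  if (any(abs(diag(d)) > 1e-12)) stop("diagonal must be zero", call. = FALSE)
  if (any(d < 0)) stop("dissimilarities must be >= 0", call. = FALSE)
  if (is.null(rownames(d))) stop("matrix needs sample ids as dimnames", call. = FALSE)
  structure(list(sample_ids = rownames(d), d = d), class = "dist_matrix")
}

#' @export
print.dist_matrix <- function(x, ...) {
  cat(sprintf("dist_matrix: %d samples\n", length(x$sample_ids)))
  invisible(x)
}

#' Bray-Curtis dissimilarity between samples
#'
#' `d(u, v) = sum |u_f - v_f| / sum (u_f + v_f)` over features; 0 for
#' identical columns, 1 for disjoint supports. Computed with
#' \pkg{vegan}'s `vegdist`. Jaccard (abundance-based, as in vegan) is
#' offered as an alternative since the study names the ordination package
#' but not the metric.
#'
#' @param x A `feature_table` with at least two samples, none all-zero.
#' @param method `"bray"` (default) or `"jaccard"`.
#' @return A `dist_matrix`.
#' @export
bray_curtis <- function(x, method = c("bray", "jaccard")) {
  method <- match.arg(method)
  stopifnot(inherits(x, "feature_table"))
  if (ncol(x$counts) < 2) stop("need >= 2 samples", call. = FALSE)
  cs <- colSums(x$counts)
  if (any(cs == 0))
    stop("all-zero sample(s): ", paste(colnames(x$counts)[cs == 0], collapse = ", "),
         call. = FALSE)
  d <- as.matrix(vegan::vegdist(t(x$counts), method = method))
  dist_matrix(d)
}

# Kruskal stress-1 and disparities for a configuration.
# d: input dissimilarities (lower-triangle vector), ord: order(d) computed
# once (stable, so tied dissimilarities keep input order: primary tie
# approach); delta: configuration distances in the same pair order.
.stress1 <- function(delta, ord) {
  iso <- stats::isoreg(delta[ord])     # PAVA on distances sorted by dissimilarity
  dhat <- numeric(length(delta))
  dhat[ord] <- iso$yf
  s2 <- sum(delta^2)
  if (s2 == 0) return(list(stress = 0, dhat = dhat))
  list(stress = sqrt(sum((delta - dhat)^2) / s2), dhat = dhat)
}

# One Guttman transform toward the disparities dhat.
.guttman <- function(X, dhat, delta) {
  n <- nrow(X)
  ratio <- ifelse(delta > 0, dhat / delta, 0)
  B <- matrix(0, n, n)
  B[lower.tri(B)] <- -ratio
  B <- B + t(B)
  diag(B) <- -rowSums(B)
  (B %*% X) / n
}

.nmds_run <- function(dmat, X, max_iter, tol) {
  n <- nrow(X)
  dvec <- dmat[lower.tri(dmat)]
  ord <- order(dvec)
  delta <- as.vector(stats::dist(X))
  st <- .stress1(delta, ord)
  trace <- st$stress
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    if (st$stress < 1e-12) { converged <- TRUE; break }
    Xg <- .guttman(X, st$dhat, delta)
    # line search: accept the first step that lowers stress-1, so the
    # recorded stress sequence is non-increasing by construction
    improved <- FALSE
    alpha <- 1
    for (h in 1:8) {
      Xc <- X + alpha * (Xg - X)
      delta_c <- as.vector(stats::dist(Xc))
      st_c <- .stress1(delta_c, ord)
      if (st_c$stress < st$stress) {
        rel <- (st$stress - st_c$stress) / st$stress
        X <- Xc; delta <- delta_c; st <- st_c
        trace <- c(trace, st$stress)
        improved <- TRUE
        if (rel < tol) converged <- TRUE
        break
      }
      alpha <- alpha / 2
    }
    if (!improved) { converged <- TRUE; break }  # local minimum
    if (converged) break
  }
  list(X = X, stress = st$stress, trace = trace, converged = converged)
}

#' Non-metric multidimensional scaling (Kruskal stress-1)
#'
#' Places samples in a `k`-dimensional configuration so that the rank order
#' of configuration distances matches the rank order of the input
#' dissimilarities. Minimises Kruskal stress-1,
#' `sqrt(sum((delta - dhat)^2) / sum(delta^2))`, where `delta` are
#' configuration distances and `dhat` their monotone (isotonic,
#' pool-adjacent-violators, primary tie approach) regression on the
#' dissimilarity ranks. Optimisation alternates a Guttman transform with a
#' halving line search that only ever accepts stress-decreasing steps, so
#' the per-iteration stress trace is non-increasing. The first start is the
#' metric-MDS (principal coordinates) configuration; the remaining starts
#' are random. The best (lowest-stress, ties to the lowest restart index)
#' solution is returned, centered and rotated to its principal axes.
#'
#' @param dm A `dist_matrix`.
#' @param k Number of ordination axes (default 2; must be < number of samples).
#' @param n_restarts Number of starts including the metric-MDS start.
#' @param max_iter Iteration cap per start.
#' @param tol Relative stress-change convergence tolerance.
#' @param seed Optional integer seed for the random starts.
#' @return An object of class `ordination`: `sample_ids`, `points`
#'   (samples x k, centered, principal-axis rotated), `stress`,
#'   `stress_trace` (per accepted iteration, best start), `converged`,
#'   `n_restarts_used`.
#' @export
nmds <- function(dm, k = 2, n_restarts = 20, max_iter = 1000, tol = 1e-6,
                 seed = NULL) {
  stopifnot(inherits(dm, "dist_matrix"))
  n <- length(dm$sample_ids)
  if (k >= n) stop("`k` must be < number of samples", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  dmat <- dm$d
  scale0 <- mean(dmat[lower.tri(dmat)])
  best <- NULL
  for (r in seq_len(n_restarts)) {
    X0 <- if (r == 1) {
      suppressWarnings(stats::cmdscale(stats::as.dist(dmat), k = k))
    } else {
      matrix(stats::rnorm(n * k, sd = scale0), n, k)
    }
    if (ncol(X0) < k)  # degenerate PCoA (e.g. collinear points): pad axes
      X0 <- cbind(X0, matrix(stats::rnorm(n * (k - ncol(X0)), sd = 1e-4 * scale0),
                             n, k - ncol(X0)))
    run <- .nmds_run(dmat, X0, max_iter, tol)
    if (is.null(best) || run$stress < best$stress) best <- run
  }
  X <- scale(best$X, center = TRUE, scale = FALSE)
  if (n > 1) {
    sv <- svd(X)
    X <- X %*% sv$v
    # deterministic axis signs: largest-|loading| coordinate positive
    for (j in seq_len(ncol(X))) {
      i <- which.max(abs(X[, j]))
      if (X[i, j] < 0) X[, j] <- -X[, j]
    }
    X <- scale(X, center = TRUE, scale = FALSE)
  }
  dimnames(X) <- list(dm$sample_ids, paste0("axis", seq_len(k)))
  structure(list(sample_ids = dm$sample_ids, points = X, stress = best$stress,
                 stress_trace = best$trace, converged = best$converged,
                 n_restarts_used = n_restarts),
            class = "ordination")
}

#' @export
print.ordination <- function(x, ...) {
  cat(sprintf("ordination: %d samples, %d axes, stress = %.5f (%s)\n",
              nrow(x$points), ncol(x$points), x$stress,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' Fit an environmental variable as a direction in ordination space
#'
#' Regresses the centered variable on the ordination coordinates by least
#' squares; the fitted coefficient vector (normalised to unit length) is the
#' direction of steepest increase and the regression R-squared measures how
#' strongly the variable is structured along the ordination. Significance is
#' assessed by permuting the variable's values across samples:
#' `p = (1 + #{permuted r2 >= observed}) / (1 + n_permutations)`, so the
#' smallest attainable p is `1/(n_permutations + 1)`. Samples with a missing
#' value are excluded from this variable's fit only.
#'
#' @param ord An `ordination`.
#' @param values Named numeric vector (names = sample ids) or a vector in
#'   ordination sample order; may contain `NA`.
#' @param n_permutations Number of permutations (study default 999).
#' @param seed Optional integer seed.
#' @param variable Variable name carried into the result.
#' @return An object of class `envfit_result`: `variable`, `direction`
#'   (unit vector, length k), `r_squared`, `p_value`, `n_permutations`,
#'   `n_used` (samples with data).
#' @export
envfit_vector <- function(ord, values, n_permutations = 999, seed = NULL,
                          variable = deparse(substitute(values))) {
  stopifnot(inherits(ord, "ordination"))
  if (!is.null(names(values))) {
    values <- values[ord$sample_ids]
  } else if (length(values) != length(ord$sample_ids)) {
    stop("`values` must be named or match the ordination sample count", call. = FALSE)
  }
  ok <- !is.na(values)
  if (sum(ok) < 3) stop("need >= 3 non-missing samples", call. = FALSE)
  y <- values[ok]
  if (stats::sd(y) == 0) stop("variable is constant", call. = FALSE)
  X <- scale(ord$points[ok, , drop = FALSE], center = TRUE, scale = FALSE)
  yc <- y - mean(y)
  qrX <- qr(X)
  Q <- qr.Q(qrX)
  r2_of <- function(v) {
    vc <- v - mean(v)
    sum(crossprod(Q, vc)^2) / sum(vc^2)
  }
  r2 <- r2_of(y)
  b <- qr.coef(qrX, yc)
  b[is.na(b)] <- 0
  direction <- b / sqrt(sum(b^2))
  if (!is.null(seed)) set.seed(seed)
  perm <- replicate(n_permutations, r2_of(sample(y)))
  p <- (1 + sum(perm >= r2)) / (1 + n_permutations)
  structure(list(variable = variable, direction = direction, r_squared = r2,
                 p_value = p, n_permutations = n_permutations,
                 n_used = sum(ok)),
            class = "envfit_result")
}

#' @export
print.envfit_result <- function(x, ...) {
  cat(sprintf("envfit: %s  r2 = %.4f  p = %.4g  (%d permutations, n = %d)\n",
              x$variable, x$r_squared, x$p_value, x$n_permutations, x$n_used))
  invisible(x)
}

#' Abundance-weighted species scores
#'
#' Places selected features in ordination space at the weighted average of
#' the sample coordinates, weights being the feature's relative abundance in
#' each sample. Used to overlay dominant taxa (e.g. the oil-responding
#' OTUs) on a sample ordination.
#'
#' @param x A `feature_table` sharing samples with the ordination.
#' @param ord An `ordination`.
#' @param features Character vector of feature ids (default: all).
#' @return Matrix of coordinates, features x axes.
#' @export
species_scores <- function(x, ord, features = feature_ids(x)) {
  stopifnot(inherits(x, "feature_table"), inherits(ord, "ordination"))
  if (!all(ord$sample_ids %in% sample_ids(x)))
    stop("table and ordination must share samples", call. = FALSE)
  missing_f <- setdiff(features, feature_ids(x))
  if (length(missing_f))
    stop("features not in table: ", paste(missing_f, collapse = ", "), call. = FALSE)
  m <- x$counts[features, ord$sample_ids, drop = FALSE]
  rel <- sweep(m, 2, colSums(x$counts[, ord$sample_ids, drop = FALSE]), "/")
  tot <- rowSums(rel)
  if (any(tot == 0))
    stop("all-zero feature(s): ",
         paste(features[tot == 0], collapse = ", "), call. = FALSE)
  w <- sweep(rel, 1, tot, "/")
  out <- w %*% ord$points
  rownames(out) <- features
  out
}
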