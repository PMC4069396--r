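#' Filter alignment hits on quality cutoffs
#'
#' Keeps hits with `evalue <= evalue_max`, `pct_identity >= identity_min`
#' and `aln_length >= length_min`; all boundaries inclusive on the stated
#' side. Defaults are the study's annotation cutoffs (e-value 1e-5,
#' identity 60%, alignment length 15).
#'
#' @param hits Hit data frame from [read_hit_table()].
#' @param evalue_max,identity_min,length_min Cutoffs.
#' @return The surviving rows of `hits`.
#' @export
filter_hits <- function(hits, evalue_max = 1e-5, identity_min = 60,
                        length_min = 15) {
  hits[hits$evalue <= evalue_max & hits$pct_identity >= identity_min &
         hits$aln_length >= length_min, , drop = FALSE]
}

#' Assign each query to its best hit and count gene families per sample
#'
#' For each query within a sample, hits below `bitscore_min` bits are
#' discarded and the single highest-bit-score hit is kept (the study's
#' best-hit rule at >= 40 bits); a tie on bit score resolves to the
#' lexicographically smallest subject id, making the assignment independent
#' of input row order. Assigned queries are counted per
#' (gene family, sample).
#'
#' @param hits_by_sample Named list of hit data frames, one per sample
#'   (names are sample ids); query ids must be unique within a sample in
#'   the sense that all rows of one query id belong to that query.
#' @param bitscore_min Minimum bit score, inclusive.
#' @return A counts `feature_table`, gene families x samples. Samples whose
#'   queries all fail the cutoff still appear as all-zero columns.
#' @export
assign_best_hits <- function(hits_by_sample, bitscore_min = 40) {
  if (is.null(names(hits_by_sample)) || any(!nzchar(names(hits_by_sample))))
    stop("`hits_by_sample` must be a named list (names = sample ids)", call. = FALSE)
  per_sample <- lapply(hits_by_sample, function(h) {
    h <- h[h$bit_score >= bitscore_min, , drop = FALSE]
    if (nrow(h) == 0) return(character(0))
    o <- order(h$query_id, -h$bit_score, h$subject_id, method = "radix")
    h <- h[o, , drop = FALSE]
    h$subject_id[!duplicated(h$query_id)]
  })
  families <- sort(unique(unlist(per_sample)))
  m <- matrix(0L, nrow = length(families), ncol = length(per_sample),
              dimnames = list(families, names(hits_by_sample)))
  for (j in seq_along(per_sample)) {
    tab <- table(per_sample[[j]])
    m[names(tab), j] <- as.integer(tab)
  }
  feature_table(m, units = "counts")
}

#' Aggregate a function table up a classification hierarchy
#'
#' Sums counts of functions within their level-1/2/3 category; total count
#' per sample is conserved. `level = "function"` is the identity.
#'
#' @param x A `feature_table` of function counts.
#' @param map Hierarchy map data frame from [read_hierarchy_map()].
#' @param level `"level1"`, `"level2"`, `"level3"` or `"function"`.
#' @return Aggregated `feature_table`.
#' @export
aggregate_hierarchy <- function(x, map, level = c("level1", "level2", "level3",
                                                  "function")) {
  level <- match.arg(level)
  stopifnot(inherits(x, "feature_table"))
  if (level == "function") return(x)
  idx <- match(feature_ids(x), map$function_id)
  if (anyNA(idx))
    stop("unmapped function(s): ",
         paste(feature_ids(x)[is.na(idx)], collapse = ", "), call. = FALSE)
  cat_of <- map[[level]][idx]
  agg <- rowsum(x$counts, group = cat_of)
  feature_table(agg[order(rownames(agg)), , drop = FALSE], units = x$units)
}

#' Two-group Welch comparison of functional proportions
#'
#' Per feature, an unequal-variance (Welch) two-sided t-test of percent
#' proportions between two sample groups, with a confidence interval for the
#' difference and the study's effect-size filter: a feature passes when the
#' absolute difference between group mean proportions is at least
#' `effect_threshold` percentage points (the study excluded effects
#' < 1.00). Benjamini-Hochberg q-values are computed over the features
#' passing the effect filter only; raw p-values are reported for all. A
#' feature with zero variance in both groups and equal means yields
#' `p = 1`, `diff = 0` rather than an error.
#'
#' @param x A `feature_table` tagged `proportions` (see
#'   [relative_abundance()]).
#' @param group_a,group_b Disjoint character vectors of sample ids, each of
#'   length >= 2. Group A minus group B is the reported difference.
#' @param confidence Confidence level of the interval (study value 0.95).
#' @param effect_threshold Minimum |difference| in percentage points.
#' @return A `data.frame`, one row per feature: `feature_id`,
#'   `mean_prop_a`, `mean_prop_b`, `diff_proportions`, `ci_low`, `ci_high`,
#'   `t_statistic`, `df`, `p_value`, `passed_effect_filter`, `q_value`
#'   (NA for features failing the effect filter).
#' @export
compare_groups_welch <- function(x, group_a, group_b, confidence = 0.95,
                                 effect_threshold = 1.00) {
  stopifnot(inherits(x, "feature_table"))
  if (x$units != "proportions")
    stop("table must be percent proportions; see relative_abundance()", call. = FALSE)
  if (length(intersect(group_a, group_b)))
    stop("groups must be disjoint", call. = FALSE)
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("both groups need >= 2 samples", call. = FALSE)
  missing_s <- setdiff(c(group_a, group_b), sample_ids(x))
  if (length(missing_s))
    stop("samples not in table: ", paste(missing_s, collapse = ", "), call. = FALSE)
  A <- x$counts[, group_a, drop = FALSE]
  B <- x$counts[, group_b, drop = FALSE]
  n <- nrow(x$counts)
  res <- data.frame(
    feature_id = feature_ids(x),
    mean_prop_a = rowMeans(A), mean_prop_b = rowMeans(B),
    diff_proportions = rowMeans(A) - rowMeans(B),
    ci_low = NA_real_, ci_high = NA_real_,
    t_statistic = NA_real_, df = NA_real_, p_value = NA_real_,
    stringsAsFactors = FALSE, row.names = NULL
  )
  for (i in seq_len(n)) {
    a <- A[i, ]; b <- B[i, ]
    if (stats::var(a) == 0 && stats::var(b) == 0) {
      d <- mean(a) - mean(b)
      if (d == 0) {
        res[i, c("ci_low", "ci_high")] <- 0
        res$t_statistic[i] <- 0
        res$df[i] <- length(a) + length(b) - 2
        res$p_value[i] <- 1
      } else {
        # degenerate separation: zero within-group spread, nonzero shift
        res$ci_low[i] <- d; res$ci_high[i] <- d
        res$t_statistic[i] <- sign(d) * Inf
        res$df[i] <- length(a) + length(b) - 2
        res$p_value[i] <- .Machine$double.xmin
      }
    } else {
      tt <- stats::t.test(a, b, var.equal = FALSE, conf.level = confidence)
      res$ci_low[i] <- tt$conf.int[1]; res$ci_high[i] <- tt$conf.int[2]
      res$t_statistic[i] <- unname(tt$statistic)
      res$df[i] <- unname(tt$parameter)
      res$p_value[i] <- tt$p.value
    }
  }
  res$passed_effect_filter <- abs(res$diff_proportions) >= effect_threshold
  res$q_value <- NA_real_
  if (any(res$passed_effect_filter))
    res$q_value[res$passed_effect_filter] <-
      stats::p.adjust(res$p_value[res$passed_effect_filter], method = "BH")
  res
}

#' Build a bipartite sample-function network
#'
#' Emits an edge (sample, function, weight = count) for every cell of the
#' count table at least `min_count`; the study omitted edges where a
#' function was observed fewer than 20 times in a sample, so a count of
#' exactly 20 keeps its edge.
#'
#' @param x A counts `feature_table`.
#' @param min_count Edge threshold, inclusive.
#' @return An object of class `sample_function_network`: `edges` (data frame
#'   `sample_id`, `function_id`, `weight`), `samples`, `functions` (node
#'   sets; all table samples/functions, including isolated nodes).
#' @export
build_network <- function(x, min_count = 20) {
  stopifnot(inherits(x, "feature_table"))
  keep <- which(x$counts >= min_count, arr.ind = TRUE)
  edges <- data.frame(
    sample_id = colnames(x$counts)[keep[, "col"]],
    function_id = rownames(x$counts)[keep[, "row"]],
    weight = x$counts[keep],
    stringsAsFactors = FALSE
  )
  edges <- edges[order(edges$sample_id, edges$function_id), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(edges = edges, samples = colnames(x$counts),
                 functions = rownames(x$counts)),
            class = "sample_function_network")
}

#' @export
print.sample_function_network <- function(x, ...) {
  cat(sprintf("sample-function network: %d samples, %d functions, %d edges\n",
              length(x$samples), length(x$functions), nrow(x$edges)))
  invisible(x)
}

#' Aggregate gene families into hydrocarbon-degradation classes
#'
#' Sums gene-family counts within hydrocarbon substrate classes (BTEX, PAH,
#' alkanes, ...) for heatmap-style export. Families absent from the map go
#' to an `"unclassified"` row (with a message), so sample totals are
#' conserved.
#'
#' @param x A `feature_table` of gene-family counts.
#' @param category_map Named character vector: `family id -> class`, or a
#'   data frame with columns `function_id` and `category`.
#' @return Aggregated `feature_table`, classes x samples.
#' @export
hydrocarbon_category_profile <- function(x, category_map) {
  stopifnot(inherits(x, "feature_table"))
  if (is.data.frame(category_map))
    category_map <- stats::setNames(category_map$category, category_map$function_id)
  cls <- unname(category_map[feature_ids(x)])
  n_un <- sum(is.na(cls))
  if (n_un > 0) {
    message(n_un, " gene familie(s) not in category map; assigned 'unclassified'")
    cls[is.na(cls)] <- "unclassified"
  }
  agg <- rowsum(x$counts, group = cls)
  feature_table(agg[order(rownames(agg)), , drop = FALSE], units = x$units)
}
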