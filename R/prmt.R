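#' Default currency metabolites excluded from the transformation matrix
#'
#' Ubiquitous cofactors and solvent species that participate in so many
#' reactions that their turnover scores are uninformative. Nitrogen species
#' are deliberately not on this list.
#'
#' @return Character vector of metabolite ids.
#' @export
prmt_currency_metabolites <- function() {
  c("H2O", "H+", "ATP", "ADP", "Orthophosphate",
    "NAD+", "NADH", "NADP+", "NADPH", "CoA")
}

#' Build the environmental transformation matrix (ETM)
#'
#' Converts a reaction database into a metabolites x ECs weight matrix. For
#' an EC `e` catalysing the reaction set `R_e`, the weight of metabolite `m`
#' is the average over `R_e` of its signed stoichiometry: `+v` where `m` is
#' a substrate with coefficient `v`, `-v` where a product, 0 otherwise. The
#' per-EC average (rather than the sum) keeps promiscuous ECs from
#' dominating; `weighting = "sum"` restores the plain sum. Reactions written
#' reversibly (`<=>`) are scored in the written direction by default
#' (`reversible = "as_written"`); `reversible = "drop"` excludes them.
#' Currency metabolites produce no row.
#'
#' @param reactions List of [reaction()] objects.
#' @param currency_exclusions Metabolite ids to drop;
#'   default [prmt_currency_metabolites()].
#' @param weighting `"average"` (default) or `"sum"` over an EC's reactions.
#' @param reversible `"as_written"` (default) or `"drop"`.
#' @return An object of class `etm`: `metabolite_ids`, `ec_ids`, `W`
#'   (metabolites x ECs).
#' @export
build_etm <- function(reactions,
                      currency_exclusions = prmt_currency_metabolites(),
                      weighting = c("average", "sum"),
                      reversible = c("as_written", "drop")) {
  weighting <- match.arg(weighting)
  reversible <- match.arg(reversible)
  if (length(reactions) == 0) stop("empty reaction list", call. = FALSE)
  if (reversible == "drop")
    reactions <- Filter(function(r) !isTRUE(r$reversible), reactions)
  if (length(reactions) == 0) stop("no reactions left after dropping reversible ones",
                                   call. = FALSE)
  ecs <- sort(unique(unlist(lapply(reactions, `[[`, "ec_numbers"))))
  mets <- sort(unique(unlist(lapply(reactions, function(r)
    c(r$substrates$metabolite, r$products$metabolite)))))
  mets <- setdiff(mets, currency_exclusions)
  W <- matrix(0, length(mets), length(ecs), dimnames = list(mets, ecs))
  n_rxn <- stats::setNames(numeric(length(ecs)), ecs)
  for (r in reactions) {
    s <- stats::setNames(r$substrates$coef, r$substrates$metabolite)
    p <- stats::setNames(-r$products$coef, r$products$metabolite)
    signed <- c(s, p)
    signed <- signed[names(signed) %in% mets]
    for (e in unique(r$ec_numbers)) {
      n_rxn[e] <- n_rxn[e] + 1
      if (length(signed))
        W[names(signed), e] <- W[names(signed), e] + signed
    }
  }
  if (weighting == "average")
    W <- sweep(W, 2, pmax(n_rxn, 1), "/")
  structure(list(metabolite_ids = mets, ec_ids = ecs, W = W), class = "etm")
}

#' @export
print.etm <- function(x, ...) {
  cat(sprintf("environmental transformation matrix: %d metabolites x %d ECs\n",
              length(x$metabolite_ids), length(x$ec_ids)))
  invisible(x)
}

#' Quantile-normalize and log2-transform EC abundances
#'
#' Forces every sample column onto a common empirical distribution (each
#' rank is replaced by the mean of the sorted values at that rank across
#' samples; ties receive the mean of their rank positions' reference
#' values), then applies `log2(x + 1)`. After normalization the sorted
#' value multisets of all columns are identical. The pseudocount handles
#' zero counts.
#'
#' @param x A `feature_table` of EC abundances with >= 2 samples.
#' @return An object of class `normalized_abundance`: `ec_ids`,
#'   `sample_ids`, `A` (log2 scale matrix).
#' @export
normalize_ec_abundance <- function(x) {
  stopifnot(inherits(x, "feature_table"))
  if (ncol(x$counts) < 2)
    stop("quantile normalization needs >= 2 samples", call. = FALSE)
  qn <- limma::normalizeQuantiles(x$counts, ties = TRUE)
  A <- log2(qn + 1)
  dimnames(A) <- dimnames(x$counts)
  structure(list(ec_ids = rownames(A), sample_ids = colnames(A), A = A),
            class = "normalized_abundance")
}

#' Predicted relative metabolic turnover scores
#'
#' Multiplies per-sample deviations of normalized EC abundance from the
#' mean-of-samples reference by the ETM:
#' `S[m, j] = sum_e W[m, e] * (A[e, j] - mean_j' A[e, j'])`. Positive scores
#' predict relative consumption of the metabolite in that sample, negative
#' scores relative accumulation; with the mean reference every metabolite's
#' scores sum to zero across samples. ECs absent from the ETM are dropped
#' with a warning; a fully disjoint EC set is an error.
#'
#' @param A A `normalized_abundance` (see [normalize_ec_abundance()]).
#' @param etm An `etm` (see [build_etm()]).
#' @return An object of class `prmt_scores`: `metabolite_ids`, `sample_ids`,
#'   `S` (metabolites x samples), `reference = "mean of samples"`.
#' @export
prmt_scores <- function(A, etm) {
  stopifnot(inherits(A, "normalized_abundance"), inherits(etm, "etm"))
  common <- intersect(A$ec_ids, etm$ec_ids)
  if (length(common) == 0)
    stop("no EC shared between abundance table and ETM", call. = FALSE)
  dropped <- setdiff(A$ec_ids, etm$ec_ids)
  if (length(dropped))
    warning(length(dropped), " EC(s) absent from ETM dropped: ",
            paste(utils::head(dropped, 5), collapse = ", "),
            if (length(dropped) > 5) ", ..." else "", call. = FALSE)
  M <- A$A[common, , drop = FALSE]
  dev <- M - rowMeans(M)
  S <- etm$W[, common, drop = FALSE] %*% dev
  structure(list(metabolite_ids = rownames(S), sample_ids = colnames(S),
                 S = S, reference = "mean of samples"),
            class = "prmt_scores")
}

#' @export
print.prmt_scores <- function(x, ...) {
  cat(sprintf("PRMT scores: %d metabolites x %d samples (reference: %s)\n",
              length(x$metabolite_ids), length(x$sample_ids), x$reference))
  invisible(x)
}

# rank-sum statistic of group A within the pooled vector
.rank_sum <- function(v, idx_a) sum(rank(v)[idx_a])

#' Compare PRMT scores between two sample groups by permutation rank tests
#'
#' Per metabolite, the default (unpaired) test uses the Wilcoxon rank-sum
#' statistic of group A with a group-label permutation p-value:
#' `p = (1 + #{|W_perm - E0| >= |W_obs - E0|}) / (1 + n_permutations)`
#' where `E0 = nA (nA + nB + 1) / 2` is the null expectation (two-sided).
#' The paired mode uses the signed-rank statistic with sign-flip
#' permutations for samples paired by position in `group_a`/`group_b`.
#' The add-one estimator bounds p below by `1/(n_permutations + 1)`; scores
#' identical across both groups give p = 1.
#'
#' @param scores A `prmt_scores`.
#' @param group_a,group_b Disjoint sample-id vectors; unpaired mode needs
#'   >= 2 per group, paired mode equal lengths.
#' @param n_permutations Number of permutations (study value 1000).
#' @param seed Optional integer seed.
#' @param paired Use the signed-rank paired mode?
#' @return A `data.frame`: `metabolite`, `statistic`, `mean_a`, `mean_b`,
#'   `p_value`.
#' @export
compare_prmt_groups <- function(scores, group_a, group_b,
                                n_permutations = 1000, seed = NULL,
                                paired = FALSE) {
  stopifnot(inherits(scores, "prmt_scores"))
  if (length(intersect(group_a, group_b))) stop("groups must be disjoint", call. = FALSE)
  missing_s <- setdiff(c(group_a, group_b), scores$sample_ids)
  if (length(missing_s))
    stop("samples not in scores: ", paste(missing_s, collapse = ", "), call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  S <- scores$S
  if (paired) {
    if (length(group_a) != length(group_b))
      stop("paired mode needs equal group sizes", call. = FALSE)
    D <- S[, group_a, drop = FALSE] - S[, group_b, drop = FALSE]
    m <- ncol(D)
    signs <- matrix(sample(c(-1, 1), m * n_permutations, replace = TRUE),
                    n_permutations, m)
    stat_p <- apply(D, 1, function(d) {
      nz <- d != 0
      if (!any(nz)) return(c(0, 1))
      r <- rank(abs(d[nz]))
      e0 <- sum(r) / 2
      v_obs <- sum(r[d[nz] > 0])
      flips <- signs[, nz, drop = FALSE]
      v_perm <- as.vector((flips > 0) %*% r)
      p <- (1 + sum(abs(v_perm - e0) >= abs(v_obs - e0))) / (1 + n_permutations)
      c(v_obs, p)
    })
  } else {
    if (length(group_a) < 2 || length(group_b) < 2)
      stop("unpaired mode needs >= 2 samples per group", call. = FALSE)
    na <- length(group_a); nb <- length(group_b)
    pooled <- S[, c(group_a, group_b), drop = FALSE]
    e0 <- na * (na + nb + 1) / 2
    # one shared permutation set across metabolites
    perm_idx <- replicate(n_permutations, sample.int(na + nb, na))
    stat_p <- apply(pooled, 1, function(v) {
      r <- rank(v)
      w_obs <- sum(r[seq_len(na)])
      w_perm <- colSums(matrix(r[perm_idx], nrow = na))
      p <- (1 + sum(abs(w_perm - e0) >= abs(w_obs - e0))) / (1 + n_permutations)
      c(w_obs, p)
    })
  }
  data.frame(
    metabolite = scores$metabolite_ids,
    statistic = stat_p[1, ],
    mean_a = rowMeans(S[, group_a, drop = FALSE]),
    mean_b = rowMeans(S[, group_b, drop = FALSE]),
    p_value = stat_p[2, ],
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Label metabolites as relatively consumed or accumulated in group A
#'
#' Positive PRMT scores mean consumption, so a metabolite whose mean score
#' is higher in group A than in group B is labelled `consumption_up` in
#' group A, lower `accumulation_up`; a zero difference is flagged
#' `ambiguous`. Swapping the groups flips every non-ambiguous label.
#'
#' @param comparison Result of [compare_prmt_groups()] computed on `scores`
#'   with the same groups.
#' @return A `data.frame`: `metabolite`, `direction`
#'   (`consumption_up` / `accumulation_up` / `ambiguous`), `p_value`.
#' @export
annotate_metabolite_directions <- function(comparison) {
  d <- comparison$mean_a - comparison$mean_b
  direction <- ifelse(d > 0, "consumption_up",
                      ifelse(d < 0, "accumulation_up", "ambiguous"))
  data.frame(metabolite = comparison$metabolite, direction = direction,
             p_value = comparison$p_value,
             stringsAsFactors = FALSE, row.names = NULL)
}
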