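# shared fixture builders; everything is generated in code, no data files

tiny_ft <- function(m = NULL, units = "counts") {
  if (is.null(m))
    m <- matrix(c(6, 2, 1, 2, 2, 0), nrow = 3, byrow = TRUE,
                dimnames = list(c("f1", "f2", "f3"), c("s1", "s2")))
  feature_table(m, units = units)
}

# distance matrix from a point configuration, with sample ids
config_dm <- function(pts) {
  d <- as.matrix(dist(pts))
  ids <- paste0("s", seq_len(nrow(pts)))
  dimnames(d) <- list(ids, ids)
  dist_matrix(d)
}

# independent Welch oracle: textbook formulas, no call to t.test
welch_oracle <- function(a, b, conf = 0.95) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  se <- sqrt(va + vb)
  t <- (mean(a) - mean(b)) / se
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  p <- 2 * pt(-abs(t), df)
  ci <- (mean(a) - mean(b)) + c(-1, 1) * qt(1 - (1 - conf) / 2, df) * se
  list(t = t, df = df, p = p, ci = ci)
}

# minimal outfmt-6 hit data frame builder
hit_row <- function(query, subject, identity = 90, len = 100,
                    evalue = 1e-20, bits = 80) {
  data.frame(query_id = query, subject_id = subject,
             pct_identity = identity, aln_length = len,
             mismatches = 0, gap_opens = 0, q_start = 1, q_end = len,
             s_start = 1, s_end = len, evalue = evalue, bit_score = bits,
             stringsAsFactors = FALSE)
}

# one-reaction helper for ETM tests
rxn <- function(id, ec, sub, sub_coef, prod, prod_coef, reversible = FALSE) {
  reaction(id, ec,
           data.frame(metabolite = sub, coef = sub_coef),
           data.frame(metabolite = prod, coef = prod_coef),
           reversible = reversible)
}

# small, fast study configuration for recovery tests
small_study <- function(seed, n_otus = 150, depth_range = c(4000, 6000), ...) {
  study_config(seed = seed, n_otus = n_otus, depth_range = depth_range, ...)
}
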