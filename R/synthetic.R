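#' Derive a reproducible per-stage seed from a master seed
#'
#' Hashes (master seed, stage name) into a 32-bit-safe integer so that every
#' pipeline stage can be reproduced in isolation from the run manifest.
#'
#' @param master Integer master seed.
#' @param stage Stage name string.
#' @return Integer seed in `[0, 2^31 - 2]`.
#' @export
stage_seed <- function(master, stage) {
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% 2147483647
  as.integer((abs(as.numeric(master)) %% 1048576 * 2039 + h) %% 2147483647)
}

#' Configuration of a synthetic contaminated-sediment study
#'
#' Defines the shape of the simulated study: 64 sediment samples on a
#' contamination gradient of which the 19 nearest the wellhead exceed the
#' EPA aquatic-life benchmark (EPA-BM); TPH spanning 18 to 65 643 ug/kg;
#' responder OTUs reaching 18% relative abundance in the most contaminated
#' samples but <0.01% elsewhere; a metagenome subset of seven exceed and
#' seven non-exceed samples with gene families enriched under contamination;
#' and a toy nitrogen-cycle reaction network in which denitrification
#' enzymes are enriched in exceed samples.
#'
#' @param n_samples Number of sediment samples.
#' @param n_exceed Number of near-well samples exceeding the EPA-BM.
#' @param n_metagenome_per_group Samples per group in the metagenome subset.
#' @param n_otus Total OTUs in the simulated community.
#' @param n_responder_otus Number of TPH-responding OTUs.
#' @param responder_max_fraction Relative abundance the leading responder
#'   reaches at maximum TPH (additional responders reach successive halves).
#' @param tph_range Min/max TPH in ug/kg.
#' @param depth_range Min/max sequencing depth (reads per sample).
#' @param n_background_families Background (non-planted) gene families.
#' @param base_family_count Mean reads per gene family per sample.
#' @param enriched_family_ids Gene families enriched in exceed samples;
#'   `NULL` selects the denitrification (nar/nap/nir/nor/nos) and BTEX
#'   degradation families.
#' @param enrichment_fold Fold enrichment of those families in exceed
#'   samples (> 0; 1 = null study).
#' @param seed Master seed.
#' @return An object of class `study_config` (a validated list).
#' @export
study_config <- function(n_samples = 64, n_exceed = 19,
                         n_metagenome_per_group = 7,
                         n_otus = 400, n_responder_otus = 3,
                         responder_max_fraction = 0.18,
                         tph_range = c(18, 65643),
                         depth_range = c(122804, 200000),
                         n_background_families = 30,
                         base_family_count = 60,
                         enriched_family_ids = NULL,
                         enrichment_fold = 4,
                         seed = 1) {
  cfg <- list(n_samples = n_samples, n_exceed = n_exceed,
              n_metagenome_per_group = n_metagenome_per_group,
              n_otus = n_otus, n_responder_otus = n_responder_otus,
              responder_max_fraction = responder_max_fraction,
              tph_range = tph_range, depth_range = depth_range,
              n_background_families = n_background_families,
              base_family_count = base_family_count,
              enriched_family_ids = enriched_family_ids,
              enrichment_fold = enrichment_fold, seed = seed)
  if (n_exceed >= n_samples) stop("n_exceed must be < n_samples", call. = FALSE)
  if (responder_max_fraction <= 0 || responder_max_fraction >= 1)
    stop("responder_max_fraction must be in (0, 1)", call. = FALSE)
  if (any(tph_range <= 0) || tph_range[1] >= tph_range[2])
    stop("tph_range must be positive and ordered", call. = FALSE)
  if (enrichment_fold <= 0) stop("enrichment_fold must be > 0", call. = FALSE)
  if (2 * n_metagenome_per_group > n_samples ||
      n_metagenome_per_group > n_exceed)
    stop("metagenome subset larger than available groups", call. = FALSE)
  structure(cfg, class = "study_config")
}

#' Simulate gradient metadata for a contaminated-sediment study
#'
#' The `n_exceed` contaminated samples sit at log-uniform distances within
#' 0.3-5 km of the wellhead and carry the EPA-BM exceed flag; the remaining
#' samples sit at 5-256 km. log10(TPH) decays exponentially with distance
#' (e-folding 4 km) plus noise, clamped to the configured range, so
#' contamination is concentrated near the well and distant samples sit at
#' background TPH. Ammonia and nitrate (hence DIN) rise with TPH so that
#' inorganic nitrogen co-varies with contamination, as observed in heavily
#' impacted sediments.
#'
#' @param cfg A [study_config()].
#' @param seed Seed; defaults to a stage seed derived from `cfg$seed`.
#' @return Metadata `data.frame` in the schema of [read_metadata()].
#' @export
generate_metadata <- function(cfg, seed = stage_seed(cfg$seed, "metadata")) {
  stopifnot(inherits(cfg, "study_config"))
  set.seed(seed)
  n <- cfg$n_samples
  dist_km <- c(sort(exp(stats::runif(cfg$n_exceed, log(0.3), log(5)))),
               sort(exp(stats::runif(n - cfg$n_exceed, log(5), log(256)))))
  lo <- log10(cfg$tph_range[1]); hi <- log10(cfg$tph_range[2])
  ltph <- lo + (hi - lo) * exp(-dist_km / 4) + stats::rnorm(n, 0, 0.2)
  ltph <- pmin(pmax(ltph, lo), hi)
  tph <- round(10^ltph, 1)
  rel <- tph / cfg$tph_range[2]
  nh3 <- round(0.02 * exp(stats::rnorm(n, 0, 0.4)) + 0.35 * rel, 5)
  no3 <- round(0.01 * exp(stats::rnorm(n, 0, 0.4)) + 0.10 * rel, 5)
  data.frame(
    sample_id = sprintf("BP%03d", seq_len(n) + 300),
    tph = tph,
    din = nh3 + no3,
    nh3_n = nh3,
    no3_n = no3,
    total_n = round(0.0008 + 0.004 * rel + stats::runif(n, 0, 2e-4), 6),
    exceeds_epa_bm = seq_len(n) <= cfg$n_exceed,
    distance_km = round(dist_km, 2),
    depth_m = round(stats::runif(n, 1400, 1650)),
    stringsAsFactors = FALSE
  )
}

# saturating responder response: Hill form with h = 2, half-saturation
# 1000 ug/kg, so the response is ~0 at background TPH (18 -> 3e-4 of max)
# and essentially saturated at the contaminated end (65 643 -> 0.9998 of max)
.responder_fraction <- function(tph, fmax, K = 1000) {
  fmax * tph^2 / (tph^2 + K^2)
}

#' Simulate an OTU count table with TPH-responding taxa
#'
#' The background community follows a log-normal rank-abundance curve fixed
#' per study. Responder OTUs' expected relative abundance follows a
#' saturating function of TPH, so the leading responder reaches
#' `responder_max_fraction` at maximum TPH but stays below 0.01% at
#' background TPH (additional responders reach successive halves of the
#' maximum). Per-sample counts are multinomial at a depth drawn uniformly
#' from `depth_range`.
#'
#' @param cfg A [study_config()].
#' @param metadata Output of [generate_metadata()].
#' @param seed Seed; defaults to a stage seed derived from `cfg$seed`.
#' @return List: `table` (counts `feature_table`) and `ground_truth`
#'   (list with `responder_otus`, `gradient_variable`, `gradient_values`).
#' @export
generate_otu_table <- function(cfg, metadata,
                               seed = stage_seed(cfg$seed, "otu")) {
  stopifnot(inherits(cfg, "study_config"))
  set.seed(seed)
  n_resp <- cfg$n_responder_otus
  fmax <- cfg$responder_max_fraction * 0.5^(seq_len(n_resp) - 1)
  if (sum(fmax) >= 1 || cfg$responder_max_fraction * n_resp >= 1)
    stop("responders over-allocate the community", call. = FALSE)
  n_base <- cfg$n_otus - n_resp
  base_abund <- sort(stats::rlnorm(n_base, 0, 1.5), decreasing = TRUE)
  base_p <- base_abund / sum(base_abund)
  otu_ids <- c(sprintf("OTU_resp%02d", seq_len(n_resp)),
               sprintf("OTU_%04d", seq_len(n_base)))
  n <- nrow(metadata)
  counts <- matrix(0L, cfg$n_otus, n, dimnames = list(otu_ids, metadata$sample_id))
  depths <- if (cfg$depth_range[1] == cfg$depth_range[2]) {
    rep(cfg$depth_range[1], n)
  } else {
    sample(seq(cfg$depth_range[1], cfg$depth_range[2]), n, replace = TRUE)
  }
  for (j in seq_len(n)) {
    f <- .responder_fraction(metadata$tph[j], fmax)
    p <- c(f, base_p * (1 - sum(f)))
    counts[, j] <- as.integer(stats::rmultinom(1, depths[j], p))
  }
  list(
    table = feature_table(counts, units = "counts"),
    ground_truth = list(
      responder_otus = otu_ids[seq_len(n_resp)],
      gradient_variable = "tph",
      gradient_values = stats::setNames(metadata$tph, metadata$sample_id)
    )
  )
}

#' Toy nitrogen-cycle reaction database
#'
#' A small fixture (synthetic, not a KEGG extract) covering fixation
#' (nif), nitrification (amo, hao, nxr) and denitrification
#' (nar/nap, nir, nor, nos), with real nitrogen-cycle EC labels and toy
#' stoichiometry. It is the reaction input of the PRMT recovery
#' experiments.
#'
#' @return List of [reaction()] objects.
#' @export
nitrogen_cycle_reactions <- function() {
  mk <- function(id, ec, eq, reversible = FALSE) {
    sides <- strsplit(eq, if (reversible) " <=> " else " => ", fixed = TRUE)[[1]]
    reaction(id, ec, .parse_equation_side(sides[1], id),
             .parse_equation_side(sides[2], id), reversible)
  }
  list(
    mk("R_nif", "1.18.6.1", "N2 + 3 H2 => 2 NH3"),
    mk("R_amo", "1.14.99.39", "NH3 + O2 + QH2 => NH2OH + H2O + Q"),
    mk("R_hao", "1.7.2.6", "NH2OH + H2O => NO2- + 5 H+"),
    mk("R_nxr", "1.7.99.-", "NO2- + H2O => NO3- + 2 H+"),
    mk("R_nar", "1.7.5.1", "NO3- + QH2 => NO2- + Q + H2O"),
    mk("R_nap", "1.9.6.1", "NO3- + 2 Cytochrome-c => NO2- + H2O"),
    mk("R_nir", "1.7.2.1", "NO2- + 2 H+ => NO + H2O"),
    mk("R_nor", "1.7.2.5", "2 NO + QH2 => N2O + H2O + Q"),
    mk("R_nos", "1.7.2.4", "N2O + QH2 => N2 + H2O + Q")
  )
}

# gene-family catalogue: planted nitrogen-cycle and hydrocarbon families
# plus anonymous background families with generic ECs
.gene_family_catalog <- function(n_background) {
  named <- data.frame(
    family = c("nifH", "amoA", "hao", "nxrA", "narG", "napA", "nirS",
               "norB", "nosZ",
               "todC1", "xylM", "bssA",
               "nahAc", "phnAc",
               "alkB", "bmoX", "ladA"),
    ec = c("1.18.6.1", "1.14.99.39", "1.7.2.6", "1.7.99.-", "1.7.5.1",
           "1.9.6.1", "1.7.2.1", "1.7.2.5", "1.7.2.4",
           "1.14.12.11", "1.14.15.1", "4.1.99.11",
           "1.14.12.12", "1.14.12.22",
           "1.14.15.3", "1.14.13.230", "1.13.11.77"),
    category = c(rep("nitrogen cycle", 9), rep("BTEX", 3), rep("PAH", 2),
                 rep("alkanes", 3)),
    stringsAsFactors = FALSE
  )
  bg <- data.frame(
    family = sprintf("bg%03d", seq_len(n_background)),
    ec = sprintf("2.7.1.%d", seq_len(n_background)),
    category = "other",
    stringsAsFactors = FALSE
  )
  rbind(named, bg)
}

#' Gene families enriched by default in exceed samples
#'
#' The denitrification marker families (narG, napA, nirS, norB, nosZ) and
#' the BTEX degradation families (todC1, xylM, bssA).
#'
#' @return Character vector of family ids.
#' @export
default_enriched_families <- function() {
  c("narG", "napA", "nirS", "norB", "nosZ", "todC1", "xylM", "bssA")
}

# vectorized hit-table forgery for one sample: one passing true hit per
# counted read, plus same-query low-bit decoys, high-bit decoys that fail a
# quality filter, and decoy-only queries below the bit cutoff
.make_hits <- function(sample_id, family_counts, families) {
  n_true <- sum(family_counts)
  if (n_true == 0) {
    return(data.frame(query_id = character(0), subject_id = character(0),
                      pct_identity = numeric(0), aln_length = numeric(0),
                      mismatches = numeric(0), gap_opens = numeric(0),
                      q_start = numeric(0), q_end = numeric(0),
                      s_start = numeric(0), s_end = numeric(0),
                      evalue = numeric(0), bit_score = numeric(0),
                      stringsAsFactors = FALSE))
  }
  qid <- sprintf("%s_q%06d", sample_id, seq_len(n_true))
  subj <- rep(names(family_counts), family_counts)
  bit_true <- round(pmax(41, stats::rnorm(n_true, 80, 10)), 1)
  row_tpl <- function(q, s, ident, len, ev, bit) data.frame(
    query_id = q, subject_id = s,
    pct_identity = ident, aln_length = len,
    mismatches = round(len * (100 - ident) / 100), gap_opens = 0,
    q_start = 1, q_end = len, s_start = 1, s_end = len,
    evalue = ev, bit_score = bit, stringsAsFactors = FALSE
  )
  true_hits <- row_tpl(qid, subj,
                       round(stats::runif(n_true, 60, 100), 1),
                       sample(15:150, n_true, replace = TRUE),
                       signif(10^-stats::runif(n_true, 10, 40), 3), bit_true)
  # low-bit competing decoys (pass filters, strictly below the true bit)
  i1 <- which(stats::runif(n_true) < 0.3)
  d1 <- row_tpl(qid[i1], sample(families, length(i1), replace = TRUE),
                round(stats::runif(length(i1), 60, 100), 1),
                sample(15:150, length(i1), replace = TRUE),
                signif(10^-stats::runif(length(i1), 6, 20), 3),
                round(bit_true[i1] - stats::runif(length(i1), 2, 30), 1))
  # high-bit decoys that fail exactly one quality filter
  i2 <- which(stats::runif(n_true) < 0.2)
  fail_mode <- sample(1:3, length(i2), replace = TRUE)
  d2 <- row_tpl(qid[i2], sample(families, length(i2), replace = TRUE),
                ifelse(fail_mode == 1, round(stats::runif(length(i2), 20, 59.5), 1),
                       round(stats::runif(length(i2), 60, 100), 1)),
                ifelse(fail_mode == 2, sample(1:14, length(i2), replace = TRUE),
                       sample(15:150, length(i2), replace = TRUE)),
                ifelse(fail_mode == 3, signif(10^-stats::runif(length(i2), 1, 4), 3),
                       signif(10^-stats::runif(length(i2), 6, 20), 3)),
                round(bit_true[i2] + stats::runif(length(i2), 1, 20), 1))
  # decoy-only queries: pass quality filters but sit below the bit cutoff
  n_d3 <- max(1, round(0.05 * n_true))
  d3 <- row_tpl(sprintf("%s_decoy%05d", sample_id, seq_len(n_d3)),
                sample(families, n_d3, replace = TRUE),
                round(stats::runif(n_d3, 60, 100), 1),
                sample(15:150, n_d3, replace = TRUE),
                signif(10^-stats::runif(n_d3, 6, 20), 3),
                round(stats::runif(n_d3, 20, 39.5), 1))
  hits <- rbind(true_hits, d1, d2, d3)
  hits[order(hits$query_id, -hits$bit_score), , drop = FALSE]
}

#' Simulate the metagenome layer: hit tables, EC table, reaction DB
#'
#' Selects a metagenome subset (`n_metagenome_per_group` exceed and
#' non-exceed samples), draws Poisson gene-family counts with the enriched
#' families multiplied by `enrichment_fold` in exceed samples, and forges
#' per-sample tabular alignment hit files that reproduce those counts
#' exactly under the quality-filter + best-hit rules: each counted read has
#' one passing hit, decoy hits below the bit cutoff, competing lower-bit
#' hits and high-scoring hits that fail the e-value/identity/length filters.
#' Also returns the toy nitrogen-cycle reaction database and the ground
#' truth (enriched families; expected metabolite directions: nitrate
#' consumption and dinitrogen accumulation in exceed samples).
#'
#' @param cfg A [study_config()].
#' @param metadata Output of [generate_metadata()].
#' @param hit_tables Generate the per-sample hit data frames? (They are the
#'   slowest part; the EC/family tables are always generated.)
#' @param seed Seed; defaults to a stage seed derived from `cfg$seed`.
#' @return List: `family_table` and `ec_table` (counts `feature_table`s over
#'   the metagenome subset), `hits_by_sample` (named list or `NULL`),
#'   `reactions`, `family_catalog`, `groups` (list `exceed`, `non_exceed`),
#'   `ground_truth`.
#' @export
generate_functional_data <- function(cfg, metadata, hit_tables = TRUE,
                                     seed = stage_seed(cfg$seed, "func")) {
  stopifnot(inherits(cfg, "study_config"))
  set.seed(seed)
  catalog <- .gene_family_catalog(cfg$n_background_families)
  enriched <- cfg$enriched_family_ids
  if (is.null(enriched)) enriched <- default_enriched_families()
  if (!all(enriched %in% catalog$family))
    stop("enriched families not in catalogue: ",
         paste(setdiff(enriched, catalog$family), collapse = ", "), call. = FALSE)
  ex_pool <- metadata$sample_id[metadata$exceeds_epa_bm]
  nx_pool <- metadata$sample_id[!metadata$exceeds_epa_bm]
  grp_ex <- sort(sample(ex_pool, cfg$n_metagenome_per_group))
  grp_nx <- sort(sample(nx_pool, cfg$n_metagenome_per_group))
  samples <- c(grp_ex, grp_nx)
  lambda0 <- cfg$base_family_count *
    exp(stats::rnorm(nrow(catalog), 0, 0.4))
  names(lambda0) <- catalog$family
  counts <- matrix(0L, nrow(catalog), length(samples),
                   dimnames = list(catalog$family, samples))
  for (j in seq_along(samples)) {
    lam <- lambda0
    if (samples[j] %in% grp_ex)
      lam[enriched] <- lam[enriched] * cfg$enrichment_fold
    counts[, j] <- stats::rpois(length(lam), lam)
  }
  # drop families never observed so emitted tables match best-hit output
  counts <- counts[rowSums(counts) > 0, , drop = FALSE]
  catalog <- catalog[catalog$family %in% rownames(counts), , drop = FALSE]
  family_table <- feature_table(counts, units = "counts")
  ec_counts <- rowsum(counts, group = catalog$ec[match(rownames(counts),
                                                       catalog$family)])
  ec_table <- feature_table(ec_counts[order(rownames(ec_counts)), , drop = FALSE],
                            units = "counts")
  hits <- NULL
  if (hit_tables) {
    hits <- lapply(samples, function(s)
      .make_hits(s, counts[, s], catalog$family))
    names(hits) <- samples
  }
  list(
    family_table = family_table,
    ec_table = ec_table,
    hits_by_sample = hits,
    reactions = nitrogen_cycle_reactions(),
    family_catalog = catalog,
    groups = list(exceed = grp_ex, non_exceed = grp_nx),
    ground_truth = list(
      enriched_families = enriched,
      metabolite_directions = data.frame(
        metabolite = c("NO3-", "N2"),
        direction = c("consumption_up", "accumulation_up"),
        stringsAsFactors = FALSE
      )
    )
  )
}
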