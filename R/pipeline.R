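#' Full-pipeline run configuration
#'
#' Collects every stage parameter with the study's published values as
#' defaults: OTU filter at 10 total sequences, rarefaction depth 122 804,
#' two ordination axes with 999 envfit permutations, hit filters at e-value
#' 1e-5 / identity 60% / length 15 / bit score 40, Welch confidence 0.95
#' with a 1.00 percentage-point effect filter, network edge threshold 20,
#' and 1000 PRMT permutations. `depth = NULL` applies the study's
#' rarefaction rule instead of a fixed number: the minimum per-sample total
#' after OTU filtering.
#'
#' @param out_dir Run directory (created if needed).
#' @param study A [study_config()] describing the simulated inputs.
#' @param min_count,depth,k,env_permutations Community-stage parameters.
#' @param bitscore_min,evalue_max,identity_min,length_min,confidence,effect_threshold,network_min
#'   Functional-stage parameters.
#' @param prmt_permutations PRMT-stage permutations.
#' @param seed Master seed; per-stage seeds are derived with [stage_seed()].
#' @return An object of class `run_config` (a validated list).
#' @export
run_config <- function(out_dir, study = study_config(seed = seed),
                       min_count = 10, depth = 122804, k = 2,
                       env_permutations = 999,
                       bitscore_min = 40, evalue_max = 1e-5,
                       identity_min = 60, length_min = 15,
                       confidence = 0.95, effect_threshold = 1.00,
                       network_min = 20, prmt_permutations = 1000,
                       seed = 1) {
  cfg <- list(out_dir = out_dir, study = study, min_count = min_count,
              depth = depth, k = k, env_permutations = env_permutations,
              bitscore_min = bitscore_min, evalue_max = evalue_max,
              identity_min = identity_min, length_min = length_min,
              confidence = confidence, effect_threshold = effect_threshold,
              network_min = network_min,
              prmt_permutations = prmt_permutations, seed = seed)
  stopifnot(min_count >= 0, is.null(depth) || depth > 0, k >= 1,
            env_permutations >= 1, bitscore_min >= 0, evalue_max > 0,
            identity_min >= 0, identity_min <= 100, length_min >= 1,
            confidence > 0, confidence < 1, effect_threshold >= 0,
            network_min >= 0, prmt_permutations >= 1)
  structure(cfg, class = "run_config")
}

.stage <- function(name, expr) {
  t0 <- Sys.time()
  res <- tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  message(sprintf("[sedimeta] stage %-10s %6.2fs", name,
                  as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  res
}

#' Run the full pipeline: simulate, community, functional, PRMT
#'
#' Executes the stages in dependency order inside `config$out_dir`:
#' `inputs/` (simulated OTU table, metadata, hit tables, EC table, reaction
#' DB, ground truth), `community/` (ordination coordinates, envfit table,
#' run log), `func/` (Welch comparison, network edge list, category
#' profile), `prmt/` (ETM, score matrix, comparison, direction report), plus
#' `manifest.json`. Every stage reads its inputs back from the files the
#' previous stage wrote, so the run directory is a complete, self-contained
#' record; identical master seeds give byte-identical directories. Stage
#' timings are logged to the console, not written to disk.
#'
#' @param config A [run_config()].
#' @return The manifest, invisibly (also written as `manifest.json`).
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  for (d in file.path(out, c("inputs", "inputs/hits", "community", "func", "prmt")))
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
  seeds <- sapply(c("metadata", "otu", "func", "rarefy", "nmds", "envfit", "prmt"),
                  function(s) stage_seed(config$seed, s))

  ## --- simulate ---------------------------------------------------------
  sim <- .stage("simulate", {
    meta <- generate_metadata(config$study, seed = seeds[["metadata"]])
    otu <- generate_otu_table(config$study, meta, seed = seeds[["otu"]])
    fun <- generate_functional_data(config$study, meta, seed = seeds[["func"]])
    write_metadata(meta, file.path(out, "inputs", "metadata.tsv"))
    write_feature_table(otu$table, file.path(out, "inputs", "otu_table.tsv"),
                        id_column = "otu_id")
    write_feature_table(fun$ec_table, file.path(out, "inputs", "ec_table.tsv"),
                        id_column = "ec")
    write_reaction_db(fun$reactions, file.path(out, "inputs", "reactions.txt"))
    for (s in names(fun$hits_by_sample))
      write_hit_table(fun$hits_by_sample[[s]],
                      file.path(out, "inputs", "hits", paste0(s, ".tsv")))
    jsonlite::write_json(
      list(responder_otus = otu$ground_truth$responder_otus,
           enriched_families = fun$ground_truth$enriched_families,
           metabolite_directions = fun$ground_truth$metabolite_directions,
           groups = fun$groups),
      file.path(out, "inputs", "ground_truth.json"), auto_unbox = TRUE,
      pretty = TRUE)
    list(meta = meta, groups = fun$groups, catalog = fun$family_catalog)
  })
  meta <- read_metadata(file.path(out, "inputs", "metadata.tsv"))

  ## --- community --------------------------------------------------------
  comm <- .stage("community", {
    otu <- read_feature_table(file.path(out, "inputs", "otu_table.tsv"))
    otu <- filter_min_count(otu, config$min_count)
    depth <- config$depth
    if (is.null(depth)) depth <- min(colSums(otu$counts))
    rar <- rarefy_table(otu, depth, seed = seeds[["rarefy"]])
    if (ncol(rar$counts) < 3)
      stop("fewer than 3 samples survive rarefaction at depth ", depth)
    ord <- nmds(bray_curtis(rar), k = config$k, seed = seeds[["nmds"]])
    env_vars <- c("tph", "din", "nh3_n", "no3_n")
    ef <- do.call(rbind, lapply(env_vars, function(v) {
      vals <- stats::setNames(meta[[v]], meta$sample_id)
      r <- envfit_vector(ord, vals, n_permutations = config$env_permutations,
                         seed = seeds[["envfit"]], variable = v)
      data.frame(variable = v, r_squared = r$r_squared, p_value = r$p_value,
                 n_permutations = r$n_permutations, stringsAsFactors = FALSE)
    }))
    utils::write.table(
      data.frame(sample_id = ord$sample_ids, ord$points, check.names = FALSE),
      file.path(out, "community", "ordination.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(ef, file.path(out, "community", "envfit.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(stress = ord$stress, converged = ord$converged,
           n_features = nrow(rar$counts), n_samples = ncol(rar$counts),
           depth = depth),
      file.path(out, "community", "run_log.json"), auto_unbox = TRUE,
      pretty = TRUE, digits = NA)
    list(ord = ord, envfit = ef)
  })

  ## --- functional -------------------------------------------------------
  fun <- .stage("func", {
    hit_files <- list.files(file.path(out, "inputs", "hits"),
                            full.names = TRUE, pattern = "\\.tsv$")
    hits <- lapply(hit_files, function(f)
      filter_hits(read_hit_table(f), evalue_max = config$evalue_max,
                  identity_min = config$identity_min,
                  length_min = config$length_min))
    names(hits) <- sub("\\.tsv$", "", basename(hit_files))
    fam <- assign_best_hits(hits, bitscore_min = config$bitscore_min)
    grp_ex <- sim$groups$exceed
    grp_nx <- sim$groups$non_exceed
    cmp <- compare_groups_welch(relative_abundance(fam), grp_ex, grp_nx,
                                confidence = config$confidence,
                                effect_threshold = config$effect_threshold)
    net <- build_network(fam, min_count = config$network_min)
    hc <- hydrocarbon_category_profile(
      fam, data.frame(function_id = sim$catalog$family,
                      category = sim$catalog$category,
                      stringsAsFactors = FALSE))
    write_feature_table(fam, file.path(out, "func", "family_table.tsv"),
                        id_column = "family")
    utils::write.table(cmp, file.path(out, "func", "welch_comparison.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(net$edges, file.path(out, "func", "network_edges.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_feature_table(hc, file.path(out, "func", "hydrocarbon_categories.tsv"),
                        id_column = "category")
    list(comparison = cmp)
  })

  ## --- prmt -------------------------------------------------------------
  prmt <- .stage("prmt", {
    ec <- read_feature_table(file.path(out, "inputs", "ec_table.tsv"))
    reactions <- read_reaction_db(file.path(out, "inputs", "reactions.txt"))
    etm <- build_etm(reactions)
    norm <- normalize_ec_abundance(ec)
    sc <- suppressWarnings(prmt_scores(norm, etm))
    cmp <- compare_prmt_groups(sc, sim$groups$exceed, sim$groups$non_exceed,
                               n_permutations = config$prmt_permutations,
                               seed = seeds[["prmt"]])
    dirs <- annotate_metabolite_directions(cmp)
    write_signed_matrix <- function(m, path, id_column) {
      df <- data.frame(rownames(m), m, check.names = FALSE)
      names(df)[1] <- id_column
      utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    }
    write_signed_matrix(etm$W, file.path(out, "prmt", "etm.tsv"), "metabolite")
    write_signed_matrix(sc$S, file.path(out, "prmt", "scores.tsv"), "metabolite")
    utils::write.table(cmp, file.path(out, "prmt", "comparison.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(dirs, file.path(out, "prmt", "directions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(comparison = cmp, directions = dirs)
  })

  ## --- manifest ---------------------------------------------------------
  input_files <- list.files(file.path(out, "inputs"), recursive = TRUE,
                            full.names = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("sedimeta")),
    master_seed = config$seed,
    stage_seeds = as.list(seeds),
    parameters = unclass(config)[setdiff(names(config), c("out_dir", "study"))],
    study = unclass(config$study),
    input_checksums = as.list(stats::setNames(
      unname(tools::md5sum(input_files)),
      sub(paste0("^", out, "/?"), "", input_files)))
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
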