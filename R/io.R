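#' Read a feature table from TSV
#'
#' Expects a tab-separated file whose first column holds feature ids and whose
#' header row holds sample ids. Row and column order are preserved as in the
#' file; all type invariants are enforced on read.
#'
#' @param path File path.
#' @param units Units tag for the table; see [feature_table()].
#' @return A `feature_table`.
#' @export
read_feature_table <- function(path, units = c("counts", "proportions", "normalized")) {
  units <- match.arg(units)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("feature table needs an id column and >=1 sample column",
                         call. = FALSE)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop("duplicate feature ids in ", path, call. = FALSE)
  if (anyDuplicated(names(df)[-1]))
    stop("duplicate sample ids in header of ", path, call. = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric values in feature table ", path, call. = FALSE)
  rownames(m) <- ids
  feature_table(m, units = units)
}

#' Write a feature table to TSV
#'
#' Inverse of [read_feature_table()]; `read(write(x))` reproduces `x`.
#'
#' @param x A `feature_table`.
#' @param path Output path.
#' @param id_column Header name of the feature-id column.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(x, path, id_column = "feature_id") {
  stopifnot(inherits(x, "feature_table"))
  df <- data.frame(rownames(x$counts), x$counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# canonical metadata schema: column -> parser
.metadata_columns <- c(
  sample_id = "character", tph = "numeric", din = "numeric",
  nh3_n = "numeric", no3_n = "numeric", total_n = "numeric",
  exceeds_epa_bm = "logical", distance_km = "numeric", depth_m = "numeric"
)

#' Read per-sample environmental metadata
#'
#' TSV with named columns. Recognised columns: `sample_id`, `tph`
#' (total petroleum hydrocarbons, ug/kg), `din`, `nh3_n`, `no3_n` (mg/l),
#' `total_n` (fraction), `exceeds_epa_bm` (0/1/true/false, required),
#' `distance_km`, `depth_m`. Missing values are encoded `NA`. Unknown columns
#' raise a warning and are ignored; a missing or unparseable
#' `exceeds_epa_bm` is an error because the group label drives every
#' two-group comparison downstream.
#'
#' @param path File path.
#' @return A `data.frame`, one row per sample, with the recognised columns.
#' @export
read_metadata <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE, na.strings = "NA",
                          colClasses = "character")
  if (nrow(df) == 0) stop("metadata file ", path, " has no rows", call. = FALSE)
  unknown <- setdiff(names(df), names(.metadata_columns))
  if (length(unknown))
    warning("ignoring unknown metadata column(s): ", paste(unknown, collapse = ", "),
            call. = FALSE)
  df <- df[, intersect(names(df), names(.metadata_columns)), drop = FALSE]
  if (!"sample_id" %in% names(df)) stop("metadata lacks sample_id column", call. = FALSE)
  if (!"exceeds_epa_bm" %in% names(df))
    stop("metadata lacks required exceeds_epa_bm column", call. = FALSE)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in metadata", call. = FALSE)
  out <- data.frame(sample_id = df$sample_id, stringsAsFactors = FALSE)
  for (col in setdiff(names(df), c("sample_id", "exceeds_epa_bm"))) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- !is.na(df[[col]]) & is.na(v)
    if (any(bad)) stop("non-numeric value in metadata column ", col, call. = FALSE)
    if (any(v < 0, na.rm = TRUE))
      stop("negative concentration in metadata column ", col, call. = FALSE)
    out[[col]] <- v
  }
  raw <- tolower(df$exceeds_epa_bm)
  if (anyNA(raw)) stop("exceeds_epa_bm must never be missing", call. = FALSE)
  if (!all(raw %in% c("0", "1", "true", "false")))
    stop("exceeds_epa_bm must be one of 0/1/true/false", call. = FALSE)
  out$exceeds_epa_bm <- raw %in% c("1", "true")
  out
}

#' Write per-sample metadata to TSV
#'
#' @param meta Metadata data frame as returned by [read_metadata()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(meta, path) {
  m <- meta
  m$exceeds_epa_bm <- as.integer(m$exceeds_epa_bm)
  utils::write.table(m, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

.hit_columns <- c("query_id", "subject_id", "pct_identity", "aln_length",
                  "mismatches", "gap_opens", "q_start", "q_end",
                  "s_start", "s_end", "evalue", "bit_score")

#' Read a tabular alignment hit file (BLAST/USEARCH outfmt-6 dialect)
#'
#' Twelve tab-separated columns per line, no header: query, subject,
#' percent identity, alignment length, mismatches, gap opens, query start/end,
#' subject start/end, e-value, bit score. Columns 5-10 are parsed but unused
#' downstream. An empty file yields an empty table without error; a line with
#' the wrong column count is an error naming the line.
#'
#' @param path File path.
#' @return A `data.frame` with columns named as in the outfmt-6 convention
#'   (`query_id`, `subject_id`, `pct_identity`, `aln_length`, ..., `evalue`,
#'   `bit_score`), validated record by record.
#' @export
read_hit_table <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  empty <- data.frame(matrix(nrow = 0, ncol = 12,
                             dimnames = list(NULL, .hit_columns)))
  if (length(lines) == 0) {
    for (col in c("query_id", "subject_id")) empty[[col]] <- character(0)
    return(empty)
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nfld <- lengths(parts)
  if (any(nfld != 12))
    stop("hit table ", path, ": expected 12 tab-separated columns, got ",
         nfld[which(nfld != 12)[1]], " on line ", which(nfld != 12)[1],
         call. = FALSE)
  m <- matrix(unlist(parts), ncol = 12, byrow = TRUE)
  hits <- data.frame(
    query_id = m[, 1], subject_id = m[, 2],
    pct_identity = as.numeric(m[, 3]), aln_length = as.numeric(m[, 4]),
    mismatches = as.numeric(m[, 5]), gap_opens = as.numeric(m[, 6]),
    q_start = as.numeric(m[, 7]), q_end = as.numeric(m[, 8]),
    s_start = as.numeric(m[, 9]), s_end = as.numeric(m[, 10]),
    evalue = as.numeric(m[, 11]), bit_score = as.numeric(m[, 12]),
    stringsAsFactors = FALSE
  )
  bad <- which(!is.finite(hits$bit_score) | is.na(hits$evalue) | hits$evalue < 0 |
                 is.na(hits$aln_length) | hits$aln_length < 1 |
                 is.na(hits$pct_identity) |
                 hits$pct_identity < 0 | hits$pct_identity > 100)
  if (length(bad))
    stop("hit table ", path, ": invalid record on line ", bad[1], call. = FALSE)
  hits
}

#' Write a hit table in outfmt-6 layout
#'
#' @param hits Data frame as returned by [read_hit_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hit_table <- function(hits, path) {
  utils::write.table(hits[, .hit_columns], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

.ec_pattern <- "^[0-9]+\\.[0-9]+\\.[0-9]+\\.([0-9]+|-)$"

#' Construct a reaction record
#'
#' @param reaction_id Identifier string.
#' @param ec_numbers Character vector of EC numbers (`d.d.d.d` or `d.d.d.-`).
#' @param substrates,products Data frames with columns `metabolite` and
#'   `coef` (stoichiometric coefficient, > 0); left/right side of the
#'   equation as written.
#' @param reversible Logical: written with `<=>`?
#' @return An object of class `reaction`.
#' @export
reaction <- function(reaction_id, ec_numbers, substrates, products,
                     reversible = FALSE) {
  if (length(ec_numbers) == 0) stop("reaction ", reaction_id, " has no EC", call. = FALSE)
  if (!all(grepl(.ec_pattern, ec_numbers)))
    stop("malformed EC number in reaction ", reaction_id, ": ",
         paste(ec_numbers[!grepl(.ec_pattern, ec_numbers)], collapse = ", "),
         call. = FALSE)
  for (side in list(substrates, products)) {
    if (nrow(side) == 0) stop("reaction ", reaction_id, " has an empty side", call. = FALSE)
    if (anyDuplicated(side$metabolite))
      stop("metabolite repeated on one side of reaction ", reaction_id, call. = FALSE)
    if (any(side$coef <= 0)) stop("non-positive coefficient in ", reaction_id, call. = FALSE)
  }
  structure(list(reaction_id = reaction_id, ec_numbers = ec_numbers,
                 substrates = substrates, products = products,
                 reversible = reversible),
            class = "reaction")
}

.parse_equation_side <- function(side, rid) {
  terms <- strsplit(side, " + ", fixed = TRUE)[[1]]
  terms <- trimws(terms)
  terms <- terms[nzchar(terms)]
  if (length(terms) == 0) stop("empty equation side in reaction ", rid, call. = FALSE)
  coef <- rep(1, length(terms))
  met <- terms
  has_coef <- grepl("^[0-9]+(\\.[0-9]+)? ", terms)
  coef[has_coef] <- as.numeric(sub(" .*$", "", terms[has_coef]))
  met[has_coef] <- sub("^[0-9]+(\\.[0-9]+)? +", "", terms[has_coef])
  data.frame(metabolite = met, coef = coef, stringsAsFactors = FALSE)
}

#' Read a reaction database
#'
#' Plain-text stanza format, one reaction per stanza, stanzas separated by
#' `//` lines:
#' ```
#' ID R00001
#' EC 1.7.5.1; 1.9.6.1
#' EQ NO3- + QH2 => NO2- + Q + H2O
#' //
#' ```
#' The equation separator is `=>` (written direction) or `<=>` (reversible);
#' a term may carry a leading numeric stoichiometric coefficient (`2 H+`),
#' omitted coefficients default to 1. The left side is read as consumed
#' (substrates), the right as produced, exactly as written.
#'
#' @param path File path.
#' @return A list of [reaction()] objects.
#' @export
read_reaction_db <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop("no reactions found in ", path, call. = FALSE)
  breaks <- c(0, which(lines == "//"))
  if (lines[length(lines)] != "//") breaks <- c(breaks, length(lines) + 1)
  out <- list()
  for (i in seq_len(length(breaks) - 1)) {
    stanza <- lines[seq(breaks[i] + 1, breaks[i + 1] - 1)]
    stanza <- stanza[stanza != "//"]
    if (length(stanza) == 0) next
    get1 <- function(tag) {
      hit <- grep(paste0("^", tag, "\\s"), stanza, value = TRUE)
      if (length(hit) == 0) return(NULL)
      trimws(sub(paste0("^", tag, "\\s+"), "", hit[1]))
    }
    rid <- get1("ID")
    if (is.null(rid)) stop("reaction stanza without ID line in ", path, call. = FALSE)
    ec_line <- get1("EC")
    if (is.null(ec_line)) stop("reaction ", rid, " has no EC line", call. = FALSE)
    ecs <- trimws(strsplit(ec_line, ";", fixed = TRUE)[[1]])
    eq <- get1("EQ")
    if (is.null(eq)) stop("reaction ", rid, " has no EQ line", call. = FALSE)
    reversible <- grepl("<=>", eq, fixed = TRUE)
    sides <- if (reversible) strsplit(eq, "<=>", fixed = TRUE)[[1]]
             else strsplit(eq, "=>", fixed = TRUE)[[1]]
    if (length(sides) != 2)
      stop("reaction ", rid, ": equation needs one '=>' or '<=>' separator",
           call. = FALSE)
    out[[length(out) + 1]] <- reaction(
      rid, ecs,
      substrates = .parse_equation_side(trimws(sides[1]), rid),
      products = .parse_equation_side(trimws(sides[2]), rid),
      reversible = reversible
    )
  }
  if (length(out) == 0) stop("no reactions found in ", path, call. = FALSE)
  out
}

#' Write a reaction database
#'
#' @param reactions List of [reaction()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reaction_db <- function(reactions, path) {
  fmt_side <- function(side) {
    paste(ifelse(side$coef == 1, side$metabolite,
                 paste(side$coef, side$metabolite)),
          collapse = " + ")
  }
  txt <- vapply(reactions, function(r) {
    sep <- if (isTRUE(r$reversible)) "<=>" else "=>"
    paste0("ID ", r$reaction_id, "\n",
           "EC ", paste(r$ec_numbers, collapse = "; "), "\n",
           "EQ ", fmt_side(r$substrates), " ", sep, " ", fmt_side(r$products),
           "\n//")
  }, character(1))
  writeLines(txt, path)
  invisible(path)
}

#' Read a gene-function hierarchy map
#'
#' Four-column TSV with header: `function_id`, `level1`, `level2`, `level3`.
#' The map must be total over the functions queried downstream;
#' [aggregate_hierarchy()] raises an error for unmapped functions.
#'
#' @param path File path.
#' @return A `data.frame` with the four columns.
#' @export
read_hierarchy_map <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE, colClasses = "character")
  need <- c("function_id", "level1", "level2", "level3")
  if (!all(need %in% names(df)))
    stop("hierarchy map must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(df$function_id))
    stop("duplicate function_id in hierarchy map", call. = FALSE)
  df[, need]
}
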