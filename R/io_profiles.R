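#' Construct an abundance table
#'
#' Lightweight container for a features x samples relative-abundance matrix.
#' Feature identifiers are full taxonomy (or pathway) strings kept as row
#' names; sample identifiers are column names.
#'
#' @param values Numeric matrix, features in rows, samples in columns, with
#'   row and column names set.
#' @param level Either `"SGB"` (species-level genome bins) or `"pathway"`.
#' @return An object of class `abundance_table`.
#' @export
abundance_table <- function(values, level = c("SGB", "pathway")) {
  level <- match.arg(level)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("values must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("values must carry feature (row) and sample (column) names")
  }
  if (anyDuplicated(rownames(values))) {
    stop("duplicate feature IDs: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  }
  if (anyDuplicated(colnames(values))) stop("duplicate sample IDs")
  if (any(values < 0)) stop("negative abundance values")
  structure(list(values = values, level = level), class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("abundance_table: %d %s features x %d samples\n",
              nrow(x$values), x$level, ncol(x$values)))
  invisible(x)
}

#' @export
dim.abundance_table <- function(x) dim(x$values)

#' Feature identifiers of an abundance table
#' @param tab An `abundance_table`.
#' @return Character vector of feature IDs.
#' @export
feature_ids <- function(tab) rownames(tab$values)

#' Sample identifiers of an abundance table
#' @param tab An `abundance_table`.
#' @return Character vector of sample IDs.
#' @export
sample_ids <- function(tab) colnames(tab$values)

#' Read a merged MetaPhlAn/HUMAnN-style abundance table
#'
#' Parses a merged profile TSV (first column = clade or pathway label,
#' remaining columns numeric per-sample abundances, optional leading `#`
#' comment lines). For `level = "SGB"` only rows whose taxonomy string
#' terminates in a `t__` (SGB) rank are kept, dropping the redundant higher
#' ranks of the lineage; unclassified SGB groups are retained. Percentages
#' are detected from column totals and rescaled to proportions.
#'
#' @param path Path to the TSV file.
#' @param level `"SGB"` or `"pathway"`.
#' @return An [abundance_table()].
#' @export
read_merged_profile <- function(path, level = c("SGB", "pathway")) {
  level <- match.arg(level)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  skip <- 0L
  while (skip < length(lines) && startsWith(lines[skip + 1L], "#")) {
    skip <- skip + 1L
  }
  df <- tryCatch(
    utils::read.delim(path, skip = skip, header = TRUE,
                      check.names = FALSE, stringsAsFactors = FALSE),
    error = function(e) stop("malformed profile header at line ", skip + 1L,
                             ": ", conditionMessage(e))
  )
  if (ncol(df) < 2L) stop("malformed profile header at line ", skip + 1L,
                          ": need a label column plus sample columns")
  feats <- as.character(df[[1L]])
  vals <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(vals)) {
    bad <- which(!vapply(df[-1L], is.numeric, logical(1)))[1L]
    stop("non-numeric sample column '", colnames(df)[bad + 1L],
         "' (data begin at line ", skip + 2L, ")")
  }
  if (anyDuplicated(feats)) {
    stop("duplicate feature row(s): ",
         paste(unique(feats[duplicated(feats)]), collapse = ", "))
  }
  if (any(vals < 0)) stop("negative abundance value in ", path)
  rownames(vals) <- feats
  if (level == "SGB") {
    terminal <- sub(".*\\|", "", feats)
    keep <- grepl("^t__", terminal)
    vals <- vals[keep, , drop = FALSE]
    if (nrow(vals) == 0L) stop("no t__ (SGB-level) rows found in ", path)
  }
  # percentage dialect: rescale when columns total ~100 rather than ~1
  tot <- stats::median(colSums(vals))
  if (tot > 1.5) vals <- vals / 100
  abundance_table(vals, level = level)
}

#' Read per-sample metadata
#'
#' Expects a TSV with one row per sample and the columns `sample_id`,
#' `patient_id`, `visit` (0-3), `days_since_first_infusion`, `pfs12`
#' (`">=12"`/`"<12"`), `therapy` (`"mono"`/`"combo"`), `colitis`,
#' `other_irae`, `ppi`, `antibiotics`, `prior_targeted` (each `"no"`/`"yes"`),
#' `center`, `age`, `sex` (`"F"`/`"M"`), `bmi`.
#'
#' @param path Path to the metadata TSV.
#' @return A `data.frame`, one row per sample.
#' @export
read_metadata <- function(path) {
  md <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  validate_metadata(md)
  md
}

required_metadata_fields <- c(
  "sample_id", "patient_id", "visit", "days_since_first_infusion", "pfs12",
  "therapy", "colitis", "other_irae", "ppi", "antibiotics", "prior_targeted",
  "center", "age", "sex", "bmi")

validate_metadata <- function(md) {
  miss <- setdiff(required_metadata_fields, colnames(md))
  if (length(miss)) stop("metadata missing field(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(md$sample_id)) stop("duplicate sample_id in metadata")
  if (!all(md$visit %in% 0:3)) stop("visit must be an integer in 0..3")
  invisible(md)
}

#' Read per-patient survival records
#'
#' @param path TSV with columns `patient_id`, `time` (months), `event`
#'   (1 = event, 0 = censored), plus any covariate columns.
#' @return A `data.frame`.
#' @export
read_survival <- function(path) {
  sv <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  need <- c("patient_id", "time", "event")
  miss <- setdiff(need, colnames(sv))
  if (length(miss)) stop("survival table missing: ", paste(miss, collapse = ", "))
  if (any(sv$time <= 0)) stop("survival times must be positive")
  if (!all(sv$event %in% c(0, 1))) stop("event must be 0/1")
  sv
}

#' Prevalence filter
#'
#' Keeps features present (abundance strictly greater than zero) in at least
#' `baseline_min` of the baseline (visit 0) samples AND at least
#' `longitudinal_min` of the post-baseline samples. Both thresholds are
#' inclusive. The filtered table is not renormalized; follow with
#' [renormalize()] to re-close the compositions.
#'
#' @param tab An [abundance_table()].
#' @param meta Metadata `data.frame` covering the table's samples (columns
#'   `sample_id`, `visit`).
#' @param baseline_min Minimum baseline prevalence (default 0.20).
#' @param longitudinal_min Minimum post-baseline prevalence (default 0.10).
#' @return Filtered `abundance_table`.
#' @export
prevalence_filter <- function(tab, meta, baseline_min = 0.20,
                              longitudinal_min = 0.10) {
  stopifnot(inherits(tab, "abundance_table"))
  m <- meta[match(sample_ids(tab), meta$sample_id), ]
  if (any(is.na(m$sample_id))) {
    stop("metadata missing for sample(s): ",
         paste(setdiff(sample_ids(tab), meta$sample_id), collapse = ", "))
  }
  base <- m$visit == 0
  long <- m$visit > 0
  if (!any(base)) stop("no baseline (visit 0) samples; cannot apply filter")
  if (!any(long)) stop("no longitudinal (visit > 0) samples; cannot apply filter")
  pres <- tab$values > 0
  prev_b <- rowMeans(pres[, base, drop = FALSE])
  prev_l <- rowMeans(pres[, long, drop = FALSE])
  keep <- prev_b >= baseline_min & prev_l >= longitudinal_min
  abundance_table(tab$values[keep, , drop = FALSE], level = tab$level)
}

#' Renormalize an abundance table
#'
#' Closes each sample column to sum 1. Within-sample ratios of retained
#' features are unchanged (subcompositional coherence of the closure).
#'
#' @param tab An [abundance_table()].
#' @return Renormalized `abundance_table`.
#' @export
renormalize <- function(tab) {
  stopifnot(inherits(tab, "abundance_table"))
  cs <- colSums(tab$values)
  if (any(cs <= 0)) {
    stop("all-zero sample column(s): ",
         paste(sample_ids(tab)[cs <= 0], collapse = ", "))
  }
  abundance_table(sweep(tab$values, 2, cs, "/"), level = tab$level)
}

#' Write a tabular result to TSV
#'
#' Writes with a header, tab separation and full double precision so that
#' numeric round trips are lossless to at least 1e-12.
#'
#' @param table A `data.frame` (or matrix) of results.
#' @param path Output file path.
#' @return Invisibly, the path written.
#' @export
write_results <- function(table, path) {
  df <- as.data.frame(table)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) formatC(v, digits = 17, format = "g"))
  tryCatch(
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE),
    error = function(e) stop("cannot write ", path, ": ", conditionMessage(e))
  )
  invisible(path)
}
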