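#' Weighted-sum (frequency-centered) coding of a categorical variable
#'
#' Codes a k-level factor into k-1 columns. Level j (j < k) is coded 1 in
#' column j and 0 elsewhere; the reference (last) level is coded
#' `-n_j / n_k` in column j, where `n_j` and `n_k` are observed level counts.
#' Every column then has observation-weighted mean zero, so with this coding
#' the model intercept is the observation-weighted grand mean rather than a
#' reference-cell mean. With balanced binary levels it reduces to the classic
#' sum-to-zero (+1/-1) contrasts.
#'
#' @param levels Character or factor vector of observed levels; every level
#'   must occur at least once.
#' @return N x (k-1) numeric coding matrix; columns named after the
#'   non-reference levels.
#' @export
encode_weighted_sum <- function(levels) {
  f <- if (is.factor(levels)) droplevels(levels) else factor(levels)
  k <- nlevels(f)
  if (k < 2L) stop("weighted-sum coding needs at least 2 observed levels")
  counts <- table(f)
  lev <- levels(f)
  out <- matrix(0, length(f), k - 1L,
                dimnames = list(NULL, lev[-k]))
  for (j in seq_len(k - 1L)) {
    out[f == lev[j], j] <- 1
    out[f == lev[k], j] <- -counts[[j]] / counts[[k]]
  }
  out
}

focal_term_names <- c(
  "(Intercept)", "visit", "pfs12", "visit:pfs12",
  "combo", "visit:combo", "pfs12:combo", "visit:pfs12:combo",
  "colitis", "visit:colitis", "pfs12:colitis", "visit:pfs12:colitis",
  "ppi", "visit:ppi", "pfs12:ppi", "visit:pfs12:ppi")

#' Build the longitudinal interaction design matrix
#'
#' Constructs the Q x N covariate matrix for the logistic-normal regression.
#' The focal block has exactly 16 rows: the full expansion of
#' visit (X, integer 0-3) x PFS12 (Z) x each of three dummy-coded treatment
#' moderators (combination therapy W1, colitis W2, PPI use W3):
#' `{1, X, Z, XZ, W1, XW1, ZW1, XZW1, W2, XW2, ZW2, XZW2, W3, XW3, ZW3, XZW3}`.
#' Peripheral categorical covariates (prior targeted therapy, center, other
#' irAEs, antibiotics, sex, patient identifier) are weighted-sum coded and
#' continuous covariates (age, BMI, days since first infusion) mean-centered,
#' so all peripheral rows have mean zero and the focal block alone determines
#' marginal case-control contrasts.
#'
#' The patient identifier enters as a weighted-sum-coded fixed factor to
#' absorb repeated-measures correlation. This makes patient-constant focal
#' variables (Z, W2, W3) collinear with the patient block; the Bayesian ridge
#' prior regularizes the fit, and a message reports the numerical rank.
#'
#' @param meta Metadata `data.frame` (see [read_metadata()] for fields).
#' @param include_patient Include the patient-identifier factor (default TRUE).
#' @return List with `X` (Q x N matrix, columns in `meta` row order) and
#'   `spec` (term bookkeeping: `term_names`, `focal` indices, observed focal
#'   frequencies used by reference grids, numerical rank).
#' @export
build_design <- function(meta, include_patient = TRUE) {
  validate_metadata(meta)
  for (fld in required_metadata_fields) {
    bad <- is.na(meta[[fld]])
    if (any(bad)) {
      stop("missing '", fld, "' for sample(s): ",
           paste(meta$sample_id[bad], collapse = ", "))
    }
  }
  N <- nrow(meta)
  X <- as.numeric(meta$visit)
  Z <- as.numeric(meta$pfs12 == ">=12")
  W1 <- as.numeric(meta$therapy == "combo")
  W2 <- as.numeric(meta$colitis == "yes")
  W3 <- as.numeric(meta$ppi == "yes")

  focal <- rbind(1, X, Z, X * Z,
                 W1, X * W1, Z * W1, X * Z * W1,
                 W2, X * W2, Z * W2, X * Z * W2,
                 W3, X * W3, Z * W3, X * Z * W3)
  rownames(focal) <- focal_term_names

  periph <- list()
  add_ws <- function(name, v) {
    cm <- encode_weighted_sum(v)
    colnames(cm) <- paste0(name, ".", colnames(cm))
    t(cm)
  }
  for (nm in c("prior_targeted", "center", "other_irae", "antibiotics", "sex")) {
    v <- meta[[nm]]
    if (length(unique(v)) > 1L) periph[[nm]] <- add_ws(nm, v)
  }
  if (include_patient && length(unique(meta$patient_id)) > 1L) {
    periph[["patient_id"]] <- add_ws("patient", as.character(meta$patient_id))
  }
  for (nm in c("age", "bmi", "days_since_first_infusion")) {
    v <- as.numeric(meta[[nm]])
    periph[[nm]] <- matrix(v - mean(v), nrow = 1,
                           dimnames = list(nm, NULL))
  }
  Xmat <- do.call(rbind, c(list(focal), unname(periph)))
  colnames(Xmat) <- meta$sample_id

  rk <- qr(t(Xmat))$rank
  if (rk < nrow(Xmat)) {
    message("design matrix numerically rank-deficient (rank ", rk, " of ",
            nrow(Xmat), " rows); the coefficient prior regularizes the fit")
  }
  spec <- list(
    term_names = rownames(Xmat),
    focal = seq_len(16L),
    freqs = c(pfs12 = mean(Z), combo = mean(W1),
              colitis = mean(W2), ppi = mean(W3)),
    n = N, rank = rk)
  list(X = Xmat, spec = spec)
}

#' Look up the row index of a model term
#'
#' Accepts either the descriptive term name (a row name of the design matrix)
#' or the positional aliases `"beta0"` ... `"beta15"` for the focal block.
#'
#' @param spec The `spec` element returned by [build_design()].
#' @param name Term label.
#' @return Integer row index.
#' @export
term_index <- function(spec, name) {
  if (grepl("^beta[0-9]+$", name)) {
    i <- as.integer(sub("beta", "", name)) + 1L
    if (i >= 1L && i <= 16L) return(i)
    stop("focal aliases run beta0..beta15; got ", name)
  }
  i <- match(name, spec$term_names)
  if (is.na(i)) stop("unknown term: ", name)
  i
}
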