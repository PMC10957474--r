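#' Define a balance between two feature sets
#'
#' @param plus Character vector of feature IDs forming the numerator set.
#' @param minus Character vector forming the denominator set.
#' @param name Optional label.
#' @return Object of class `balance_def`.
#' @export
balance_def <- function(plus, minus, name = "balance") {
  if (!length(plus) || !length(minus)) stop("both feature sets must be nonempty")
  if (length(intersect(plus, minus))) {
    stop("feature sets overlap: ", paste(intersect(plus, minus), collapse = ", "))
  }
  structure(list(plus = unique(plus), minus = unique(minus), name = name),
            class = "balance_def")
}

#' Per-sample balance scores
#'
#' The balance between feature sets `I+` and `I-` is the log ratio of their
#' geometric means, computed as
#' `B = mean(log x_i, i in I+) - mean(log x_j, j in I-)`
#' per sample (the sqrt normalization constant of the original definition is
#' omitted as a harmless monotone rescaling). Scores are invariant to
#' renormalization of the sample and to subsetting the table to any superset
#' of the member features.
#'
#' @param tab An [abundance_table()] with strictly positive member
#'   abundances (apply [zero_replace()] first if needed).
#' @param def A [balance_def()].
#' @param drop_missing If `TRUE`, member features absent from the table are
#'   dropped from their geometric mean with a warning (mirrors validation
#'   cohorts lacking some taxa); if `FALSE` (default), absence is an error.
#' @return Named numeric vector of per-sample balance values (log units).
#' @export
balance_score <- function(tab, def, drop_missing = FALSE) {
  stopifnot(inherits(tab, "abundance_table"), inherits(def, "balance_def"))
  have <- feature_ids(tab)
  miss <- setdiff(c(def$plus, def$minus), have)
  plus <- def$plus; minus <- def$minus
  if (length(miss)) {
    if (!drop_missing) {
      stop("balance member feature(s) missing from table: ",
           paste(miss, collapse = ", "))
    }
    warning("dropping absent balance member(s): ", paste(miss, collapse = ", "))
    plus <- setdiff(plus, miss); minus <- setdiff(minus, miss)
    if (!length(plus) || !length(minus)) {
      stop("a balance side lost all its members")
    }
  }
  v <- tab$values
  if (any(v[c(plus, minus), ] <= 0)) {
    stop("balance members must be strictly positive; zero-replace the table first")
  }
  lp <- log(v[plus, , drop = FALSE])
  lm <- log(v[minus, , drop = FALSE])
  colMeans(lp) - colMeans(lm)
}

#' Median stratification of balance scores
#'
#' Labels each sample `High` when its score is strictly above the median and
#' `Low` otherwise (ties at the median go to `Low`).
#'
#' @param scores Numeric vector of balance scores.
#' @return Factor with levels `Low`, `High`, same names as `scores`.
#' @export
median_stratify <- function(scores) {
  med <- stats::median(scores)
  factor(ifelse(scores > med, "High", "Low"), levels = c("Low", "High"))
}

#' Rank (Mann-Whitney) AUC
#'
#' Area under the ROC curve computed from ranks with the midrank convention
#' for ties: `U / (n1 * n0)` where `U` is the Mann-Whitney statistic of the
#' positive class.
#'
#' @param scores Numeric classifier scores.
#' @param labels Binary labels (logical, 0/1, or two-level factor; the
#'   second level / `TRUE` / `1` is the positive class).
#' @return AUC in `[0, 1]`.
#' @export
auc_rank <- function(scores, labels) {
  y <- as_binary_label(labels)
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores)  # midranks for ties
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

as_binary_label <- function(labels) {
  if (is.factor(labels)) {
    if (nlevels(labels) != 2L) stop("labels must have exactly two levels")
    return(as.integer(labels == levels(labels)[2L]))
  }
  if (is.logical(labels)) return(as.integer(labels))
  u <- sort(unique(labels))
  if (!all(labels %in% c(0, 1))) stop("labels must be binary")
  as.integer(labels == 1)
}

#' Repeated stratified cross-validated AUC of a balance score
#'
#' Per repeat: a class-stratified `folds`-fold split; on each fold a
#' univariate logistic regression of the label on the balance score is fit
#' on the training folds and scored on the held-out fold; held-out
#' predictions are pooled across folds into one AUC per repeat. Degenerate
#' folds (a training split with a single class) trigger a re-draw within the
#' repeat, with a message.
#'
#' @param scores Numeric balance scores.
#' @param labels Binary outcome labels.
#' @param repeats Number of repeated splits (default 100).
#' @param folds Number of folds (default 5).
#' @param seed Root seed; per-repeat streams derive from it.
#' @return List with `mean`, `sd` and the per-repeat AUC vector.
#' @export
cv_auc <- function(scores, labels, repeats = 100L, folds = 5L, seed = 1L) {
  y <- as_binary_label(labels)
  n <- length(y)
  stopifnot(length(scores) == n)
  if (min(table(y)) < folds) {
    stop("minority class smaller than fold count; cannot stratify")
  }
  set.seed(as.integer(seed))
  rep_seeds <- sample.int(.Machine$integer.max, repeats)
  aucs <- vapply(seq_len(repeats), function(r) {
    set.seed(rep_seeds[r])
    for (attempt in 1:10) {
      fold <- integer(n)
      for (cls in c(0L, 1L)) {
        idx <- sample(which(y == cls))
        fold[idx] <- rep_len(seq_len(folds), length(idx))
      }
      pred <- rep(NA_real_, n)
      ok <- TRUE
      for (f in seq_len(folds)) {
        tr <- fold != f
        if (length(unique(y[tr])) < 2L) { ok <- FALSE; break }
        fit <- suppressWarnings(
          stats::glm(y[tr] ~ scores[tr], family = stats::binomial()))
        pred[!tr] <- stats::coef(fit)[1] + stats::coef(fit)[2] * scores[!tr]
      }
      if (ok) return(auc_rank(pred, y))
      message("degenerate fold split; re-drawing within repeat ", r)
    }
    stop("could not obtain a non-degenerate stratified split")
  }, numeric(1))
  list(mean = mean(aucs), sd = stats::sd(aucs), aucs = aucs)
}

#' Training-data AUC of a balance in an external cohort
#'
#' Fits `glm(label ~ balance, family = binomial)` on all samples and reports
#' the AUC on those same samples (no held-out split), as appropriate for a
#' small independent validation cohort. Member features absent from the
#' cohort can be dropped from the geometric means.
#'
#' @param tab An [abundance_table()] for the cohort (zero-replaced).
#' @param def A [balance_def()].
#' @param labels Binary outcome labels, aligned with the table's samples.
#' @param drop_missing Passed to [balance_score()] (default `TRUE`: external
#'   cohorts often lack some member taxa).
#' @return List with `auc`, the fitted `glm`, and the score vector.
#' @export
external_eval <- function(tab, def, labels, drop_missing = TRUE) {
  b <- balance_score(tab, def, drop_missing = drop_missing)
  y <- as_binary_label(labels)
  fit <- suppressWarnings(stats::glm(y ~ b, family = stats::binomial()))
  pred <- stats::fitted(fit)
  list(auc = auc_rank(pred, y), fit = fit, scores = b)
}
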