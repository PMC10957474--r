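#' The seven post hoc contrasts of the longitudinal model
#'
#' Each contrast compares a case arm against a control arm defined by fixing
#' some of the focal variables (Z = PFS12 status, W1 = combination therapy,
#' W2 = colitis, W3 = PPI use) and averaging over the rest with observed
#' frequency weights. `NA` marks an averaged-over variable.
#'
#' @return Named list of contrast definitions (`case` / `ctrl` settings).
#' @export
lnm_contrasts <- function() {
  arm <- function(Z = NA, W1 = NA, W2 = NA, W3 = NA)
    list(Z = Z, W1 = W1, W2 = W2, W3 = W3)
  list(
    pfs12          = list(case = arm(Z = 1), ctrl = arm(Z = 0)),
    colitis        = list(case = arm(W2 = 1), ctrl = arm(W2 = 0)),
    pfs12_colitis  = list(case = arm(Z = 1, W2 = 1), ctrl = arm(Z = 1, W2 = 0)),
    therapy_colitis = list(case = arm(W1 = 1, W2 = 1), ctrl = arm(W1 = 0, W2 = 1)),
    pfs12_mono     = list(case = arm(Z = 1, W1 = 0, W2 = 0, W3 = 0),
                          ctrl = arm(Z = 0, W1 = 0, W2 = 0, W3 = 0)),
    pfs12_combo    = list(case = arm(Z = 1, W1 = 1, W2 = 0, W3 = 0),
                          ctrl = arm(Z = 0, W1 = 1, W2 = 0, W3 = 0)),
    pfs12_ppi      = list(case = arm(Z = 1, W1 = 0, W2 = 0, W3 = 1),
                          ctrl = arm(Z = 0, W1 = 0, W2 = 0, W3 = 1))
  )
}

# focal coefficient weights of an arm: marginal mean over the reference grid.
# The model is linear in Z/W, so averaging over a variable with frequency
# weights equals substituting its observed frequency.
arm_weights <- function(Z, W1, W2, W3) {
  int <- numeric(16)
  slp <- numeric(16)
  m <- c(1, Z, W1, Z * W1, W2, Z * W2, W3, Z * W3)
  int[c(1, 3, 5, 7, 9, 11, 13, 15)] <- m
  slp[c(2, 4, 6, 8, 10, 12, 14, 16)] <- m
  list(int = int, slope = slp)
}

#' Build the reference-grid pair for a contrast
#'
#' Resolves a named contrast into the case/control focal coefficient weights.
#' Averaged-over variables are replaced by their observed sample frequencies
#' (proportional marginal-mean weighting) or, with `weights = "equal"`, by
#' 0.5. Peripheral covariates contribute nothing to the marginal means by
#' construction (weighted-sum/mean-centered coding), so only the 16 focal
#' coefficients enter.
#'
#' @param meta Metadata `data.frame` (source of observed frequencies), or a
#'   named numeric vector `c(pfs12=, combo=, colitis=, ppi=)`.
#' @param contrast Name from [lnm_contrasts()] (or an equivalent definition).
#' @param weights `"observed"` (default) or `"equal"` averaging weights.
#' @return List of class `reference_grid` with per-arm intercept and slope
#'   weight vectors over the 16 focal terms, plus the resolved settings.
#' @export
build_reference_grid <- function(meta, contrast, weights = c("observed", "equal")) {
  weights <- match.arg(weights)
  if (is.character(contrast)) {
    defs <- lnm_contrasts()
    if (!contrast %in% names(defs)) {
      stop("unknown contrast '", contrast, "'; available: ",
           paste(names(defs), collapse = ", "))
    }
    def <- defs[[contrast]]
    cname <- contrast
  } else {
    def <- contrast
    cname <- "custom"
  }
  if (is.data.frame(meta)) {
    freqs <- c(pfs12 = mean(meta$pfs12 == ">=12"),
               combo = mean(meta$therapy == "combo"),
               colitis = mean(meta$colitis == "yes"),
               ppi = mean(meta$ppi == "yes"))
    # fixed arms must be populated in the data
    for (a in def) {
      chk <- c(Z = "pfs12", W1 = "combo", W2 = "colitis", W3 = "ppi")
      for (v in names(chk)) {
        if (!is.na(a[[v]])) {
          p <- freqs[[chk[[v]]]]
          obs <- if (a[[v]] == 1) p > 0 else p < 1
          if (!obs) stop("empty stratum: ", chk[[v]], " = ", a[[v]])
        }
      }
    }
  } else freqs <- meta
  if (weights == "equal") freqs[] <- 0.5
  resolve <- function(a) {
    list(Z = if (is.na(a$Z)) freqs[["pfs12"]] else a$Z,
         W1 = if (is.na(a$W1)) freqs[["combo"]] else a$W1,
         W2 = if (is.na(a$W2)) freqs[["colitis"]] else a$W2,
         W3 = if (is.na(a$W3)) freqs[["ppi"]] else a$W3)
  }
  ca <- resolve(def$case); co <- resolve(def$ctrl)
  structure(list(name = cname,
                 case = c(arm_weights(ca$Z, ca$W1, ca$W2, ca$W3),
                          settings = list(ca)),
                 ctrl = c(arm_weights(co$Z, co$W1, co$W2, co$W3),
                          settings = list(co)),
                 freqs = freqs),
            class = "reference_grid")
}

#' Bayesian-confidence-level significance of a scalar posterior
#'
#' A draw set is significant at level `p` when its equal-tailed `p`-level
#' credible interval `[q_{(1-p)/2}, q_{(1+p)/2}]` excludes zero. Quantiles
#' use linear interpolation of order statistics; at `p = 1` the interval is
#' the full range of the draws.
#'
#' @param x Numeric vector of posterior draws.
#' @param level Credible level in (0, 1].
#' @return Logical flag.
#' @export
bcl_significant <- function(x, level) {
  ci <- bcl_interval(x, level)
  ci[1] > 0 || ci[2] < 0
}

bcl_interval <- function(x, level) {
  if (level >= 1) return(range(x))
  stats::quantile(x, c((1 - level) / 2, (1 + level) / 2),
                  names = FALSE, type = 7)
}

default_bcl_levels <- c(0.5, 0.6, 0.7, 0.8, 0.9, 0.95, 0.99, 1)

#' Posterior case-control contrast across study visits
#'
#' For every feature and posterior draw, computes the marginal-mean
#' difference between the case and control arms of a reference grid:
#' an intercept difference, a slope difference, and the per-visit difference
#' `Delta(t) = Delta_intercept + t * Delta_slope` for visits `t = 0..3`
#' (the average gap between the two arms' linear trajectories at each visit).
#' Per-arm slope draws are retained for dynamics classification.
#'
#' @param draws Posterior coefficient draws in clr coordinates
#'   ([draws_to_clr()]).
#' @param grid A [build_reference_grid()] pair.
#' @param features Optional subset of feature IDs (default: all rows).
#' @param levels Credible levels for BCL flags.
#' @return Object of class `contrast_result`: draw arrays (`delta`:
#'   D x visits x S; `slope_case`, `slope_ctrl`: D x S) and a `summary`
#'   data.frame (feature, visit, posterior mean, CI bounds and significance
#'   flag per level, slope summaries).
#' @export
contrast_posterior <- function(draws, grid, features = NULL,
                               levels = default_bcl_levels) {
  stopifnot(inherits(draws, "lnm_draws"), inherits(grid, "reference_grid"))
  if (draws$system != "clr") {
    stop("contrasts require clr-system draws; use draws_to_clr() first")
  }
  L <- draws$Lambda
  fid <- dimnames(L)[[1L]]
  if (is.null(fid)) fid <- paste0("feature_", seq_len(dim(L)[1L]))
  if (!is.null(features)) {
    idx <- match(features, fid)
    if (anyNA(idx)) stop("feature(s) absent from draws: ",
                         paste(features[is.na(idx)], collapse = ", "))
    L <- L[idx, , , drop = FALSE]
    fid <- features
  }
  D <- dim(L)[1L]; S <- dim(L)[3L]
  w_int <- grid$case$int - grid$ctrl$int
  w_slp <- grid$case$slope - grid$ctrl$slope
  visits <- 0:3
  d_int <- matrix(NA_real_, D, S)
  d_slp <- matrix(NA_real_, D, S)
  s_case <- matrix(NA_real_, D, S)
  s_ctrl <- matrix(NA_real_, D, S)
  for (s in seq_len(S)) {
    focal <- L[, 1:16, s, drop = FALSE]
    dim(focal) <- c(D, 16L)
    d_int[, s] <- focal %*% w_int
    d_slp[, s] <- focal %*% w_slp
    s_case[, s] <- focal %*% grid$case$slope
    s_ctrl[, s] <- focal %*% grid$ctrl$slope
  }
  delta <- array(NA_real_, c(D, length(visits), S),
                 dimnames = list(fid, paste0("T", visits), NULL))
  for (k in seq_along(visits)) {
    delta[, k, ] <- d_int + visits[k] * d_slp
  }
  sm <- do.call(rbind, lapply(seq_len(D), function(d) {
    do.call(rbind, lapply(seq_along(visits), function(k) {
      x <- delta[d, k, ]
      row <- data.frame(feature = fid[d], visit = visits[k],
                        mean = mean(x), stringsAsFactors = FALSE)
      for (p in levels) {
        ci <- bcl_interval(x, p)
        tag <- formatC(100 * p, format = "d")
        row[[paste0("lo", tag)]] <- ci[1]
        row[[paste0("hi", tag)]] <- ci[2]
        row[[paste0("sig", tag)]] <- ci[1] > 0 || ci[2] < 0
      }
      row
    }))
  }))
  rownames(sm) <- NULL
  structure(list(name = grid$name, features = fid, visits = visits,
                 delta = delta, slope_case = s_case, slope_ctrl = s_ctrl,
                 slope_diff = d_slp, intercept_diff = d_int,
                 levels = levels, summary = sm),
            class = "contrast_result")
}

#' @export
print.contrast_result <- function(x, ...) {
  cat(sprintf("contrast_result '%s': %d features x visits %s (%d draws)\n",
              x$name, length(x$features),
              paste(x$visits, collapse = ","), dim(x$delta)[3L]))
  invisible(x)
}

#' Differential ranking of features at a visit
#'
#' Orders features by the posterior mean case-control difference `Delta(t)`
#' at the requested visit, largest first; ties break by feature ID. Because
#' differences of clr coordinates are invariant to the compositional
#' reference, the ranking agrees with what any alr reference would give.
#'
#' @param res A [contrast_posterior()] result.
#' @param visit Study visit 0-3.
#' @return `data.frame` sorted by decreasing posterior mean, carrying the CI
#'   bounds and BCL flags for every level.
#' @export
differential_ranking <- function(res, visit) {
  stopifnot(inherits(res, "contrast_result"), visit %in% res$visits)
  sm <- res$summary[res$summary$visit == visit, ]
  sm <- sm[order(-sm$mean, sm$feature), ]
  sm$rank <- seq_len(nrow(sm))
  rownames(sm) <- NULL
  sm
}

#' Count features flagged at each BCL level
#'
#' @param res A [contrast_posterior()] result.
#' @param visit Visit to count at (default: flagged at any visit).
#' @return Named integer vector over the result's BCL levels; counts are
#'   non-increasing in the level.
#' @export
bcl_flag_counts <- function(res, visit = NULL) {
  sm <- res$summary
  if (!is.null(visit)) sm <- sm[sm$visit == visit, ]
  sapply(res$levels, function(p) {
    col <- paste0("sig", formatC(100 * p, format = "d"))
    flag <- tapply(sm[[col]], sm$feature, any)
    sum(flag)
  }) |> stats::setNames(paste0(100 * res$levels, "%"))
}

#' Classify the longitudinal dynamics of each feature
#'
#' Applies a rule set, in order of precedence, to the per-visit significance
#' pattern of `Delta(t)` and the per-arm slope intervals at the given BCL
#' level:
#' \describe{
#'   \item{stable-difference}{significant with one sign at every visit}
#'   \item{baseline-only}{significant at T0 only}
#'   \item{emergent}{null at T0, significant at some later visit with a
#'     constant sign}
#'   \item{crossing}{significant with opposite signs at T0 and T3}
#'   \item{case-flat / control-flat}{the named arm's slope interval covers
#'     zero while the other arm's does not}
#'   \item{none}{otherwise}
#' }
#'
#' @param res A [contrast_posterior()] result.
#' @param level BCL level for all interval checks (default 0.9).
#' @return `data.frame` with `feature`, `category` and the supporting flags.
#' @export
classify_dynamics <- function(res, level = 0.9) {
  stopifnot(inherits(res, "contrast_result"))
  nT <- length(res$visits)
  out <- lapply(seq_along(res$features), function(d) {
    sig <- logical(nT); sgn <- integer(nT)
    for (k in seq_len(nT)) {
      ci <- bcl_interval(res$delta[d, k, ], level)
      sig[k] <- ci[1] > 0 || ci[2] < 0
      sgn[k] <- if (ci[1] > 0) 1L else if (ci[2] < 0) -1L else 0L
    }
    ci_case <- bcl_interval(res$slope_case[d, ], level)
    ci_ctrl <- bcl_interval(res$slope_ctrl[d, ], level)
    case_moves <- ci_case[1] > 0 || ci_case[2] < 0
    ctrl_moves <- ci_ctrl[1] > 0 || ci_ctrl[2] < 0
    cat_ <- if (all(sig) && length(unique(sgn)) == 1L) "stable-difference"
    else if (sig[1] && !any(sig[-1])) "baseline-only"
    else if (!sig[1] && any(sig[-1]) &&
             length(unique(sgn[sig])) == 1L) "emergent"
    else if (sig[1] && sig[nT] && sgn[1] != sgn[nT]) "crossing"
    else if (!case_moves && ctrl_moves) "case-flat"
    else if (case_moves && !ctrl_moves) "control-flat"
    else "none"
    data.frame(feature = res$features[d], category = cat_,
               sig_T0 = sig[1], sig_T3 = sig[nT],
               sign_T0 = sgn[1], sign_T3 = sgn[nT],
               case_slope_moves = case_moves,
               ctrl_slope_moves = ctrl_moves,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
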