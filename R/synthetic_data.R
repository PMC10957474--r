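#' Configuration for synthetic cohort generation
#'
#' Defaults emulate the design of a multicenter longitudinal melanoma
#' immunotherapy cohort: 175 patients sampled at up to four visits with
#' dropout calibrated to per-visit sample counts of 62/77/38/30 (PFS >= 12
#' months) and 74/69/34/24 (PFS < 12 months), and covariate frequencies
#' matching the cohort table (combination therapy 58/175, colitis 33/175,
#' PPI 47/175, antibiotics 25/175, prior targeted therapy 41/175, PFS12
#' 83/175). Abundances are generated from the logistic-normal model itself:
#' a planted clr-scale coefficient matrix with `n_diff` features carrying a
#' slope-difference effect of `delta` clr units per visit between outcome
#' groups, residual covariance `sigma^2 I`. `D = 60` features is the default
#' desk-scale stand-in for the hundreds retained after prevalence filtering
#' in a full cohort.
#'
#' @param n_patients Number of patients (default 175).
#' @param D Number of features (default 60).
#' @param n_diff Number of planted differential features (default 10, capped
#'   at `D/2`; half shifted up in cases, half down).
#' @param delta Planted slope-difference effect size, clr units per visit
#'   (default 0.8).
#' @param sigma Residual standard deviation per alr coordinate (default 1).
#' @param visit_probs 2 x 4 matrix of per-visit sampling probabilities, rows
#'   `>=12` and `<12` (default: calibrated to the counts above).
#' @param freqs Named covariate frequencies.
#' @param zero_inflation Probability of a structural zero per entry
#'   (default 0: the observation layer is the exact logistic-normal).
#' @param depth Sequencing depth for an optional multinomial count layer
#'   (default `NA`: proportions observed directly).
#' @param surv_median_months Baseline median overall survival for the
#'   survival generator (default 34).
#' @param surv_beta Log hazard ratio of the high-risk stratum (default
#'   `log(2)`).
#' @param surv_horizon Administrative censoring horizon in months
#'   (default 84).
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_patients = 175L, D = 60L,
                       n_diff = min(10L, D %/% 2L),
                       delta = 0.8, sigma = 1,
                       visit_probs = NULL,
                       freqs = c(pfs12 = 83 / 175, combo = 58 / 175,
                                 colitis = 33 / 175, ppi = 47 / 175,
                                 antibiotics = 25 / 175,
                                 prior_targeted = 41 / 175,
                                 other_irae = 0.55, female = 75 / 175),
                       zero_inflation = 0, depth = NA,
                       surv_median_months = 34, surv_beta = log(2),
                       surv_horizon = 84) {
  if (is.null(visit_probs)) {
    visit_probs <- rbind(">=12" = c(62, 77, 38, 30) / 83,
                         "<12" = c(74, 69, 34, 24) / 92)
  }
  stopifnot(D >= 3L, n_diff <= D, all(visit_probs >= 0 & visit_probs <= 1),
            all(freqs >= 0 & freqs <= 1), zero_inflation >= 0,
            zero_inflation < 1)
  structure(list(n_patients = as.integer(n_patients), D = as.integer(D),
                 n_diff = as.integer(n_diff), delta = delta, sigma = sigma,
                 visit_probs = visit_probs, freqs = freqs,
                 zero_inflation = zero_inflation, depth = depth,
                 surv_median_months = surv_median_months,
                 surv_beta = surv_beta, surv_horizon = surv_horizon),
            class = "sim_config")
}

sgb_feature_ids <- function(D) {
  sprintf(paste0("k__Bacteria|p__Firmicutes|c__Clostridia|o__Eubacteriales|",
                 "f__Lachnospiraceae|g__Genus%03d|s__Species%03d|t__SGB%05d"),
          seq_len(D), seq_len(D), seq_len(D))
}

#' Simulate patient and sample metadata
#'
#' Draws patient-level covariates at the configured frequencies and a
#' longitudinal sampling pattern: each patient contributes a sample at visit
#' `t` with the per-visit probability of their outcome group (patients
#' drawing no visits are re-drawn, so everyone contributes at least one
#' sample). Days since first infusion follow the 3-week infusion cycle with
#' a few days of jitter.
#'
#' @param cfg A [sim_config()].
#' @param seed Integer seed.
#' @return List with `meta` (per-sample metadata `data.frame`) and
#'   `patients` (per-patient `data.frame`).
#' @export
simulate_metadata <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(as.integer(seed))
  n <- cfg$n_patients
  f <- cfg$freqs
  centers <- c("PRIMM-UK", "PRIMM-NL", "Manchester", "Leeds", "Barcelona")
  pat <- data.frame(
    patient_id = sprintf("P%03d", seq_len(n)),
    pfs12 = ifelse(stats::runif(n) < f[["pfs12"]], ">=12", "<12"),
    therapy = ifelse(stats::runif(n) < f[["combo"]], "combo", "mono"),
    colitis = ifelse(stats::runif(n) < f[["colitis"]], "yes", "no"),
    ppi = ifelse(stats::runif(n) < f[["ppi"]], "yes", "no"),
    antibiotics = ifelse(stats::runif(n) < f[["antibiotics"]], "yes", "no"),
    prior_targeted = ifelse(stats::runif(n) < f[["prior_targeted"]], "yes", "no"),
    other_irae = ifelse(stats::runif(n) < f[["other_irae"]], "yes", "no"),
    center = sample(centers, n, replace = TRUE,
                    prob = c(54, 74, 17, 19, 11) / 175),
    sex = ifelse(stats::runif(n) < f[["female"]], "F", "M"),
    age = round(pmin(94, pmax(19, stats::rnorm(n, 62, 14)))),
    bmi = round(pmin(45, pmax(16, stats::rnorm(n, 26, 4.5))), 1),
    stringsAsFactors = FALSE)
  rows <- lapply(seq_len(n), function(i) {
    p <- cfg$visit_probs[pat$pfs12[i], ]
    repeat {
      present <- stats::runif(4) < p
      if (any(present)) break
    }
    visits <- which(present) - 1L
    data.frame(
      sample_id = sprintf("%s_T%d", pat$patient_id[i], visits),
      patient_id = pat$patient_id[i],
      visit = visits,
      days_since_first_infusion = 21L * visits +
        sample(-3:3, length(visits), replace = TRUE),
      stringsAsFactors = FALSE)
  })
  meta <- do.call(rbind, rows)
  meta <- cbind(meta, pat[match(meta$patient_id, pat$patient_id),
                          setdiff(colnames(pat), "patient_id")])
  rownames(meta) <- NULL
  validate_metadata(meta)
  list(meta = meta, patients = pat)
}

#' Simulate abundance profiles from a planted logistic-normal model
#'
#' Builds the full interaction design matrix for the given metadata, plants
#' a clr-scale coefficient matrix whose focal block carries slope-difference
#' effects (the visit-by-PFS12 interaction) of `+delta` for the first half
#' and `-delta` for the second half of the `n_diff` differential features
#' (columns re-centered so clr columns sum to zero), adds small random
#' peripheral coefficients, draws alr coordinates from
#' `eta ~ N(Lambda X, sigma^2 I)` and maps them to compositions via the
#' softmax. Optional multinomial resampling at a configured depth and
#' structural zeros give count-like observation noise.
#'
#' @param meta Sample metadata from [simulate_metadata()].
#' @param cfg A [sim_config()].
#' @param seed Integer seed.
#' @return List with `tab` (an [abundance_table()]) and `truth`
#'   (planted clr coefficient matrix, residual sd, planted feature IDs and
#'   signs, the planted balance definition, the design, the alr reference).
#' @export
simulate_abundances <- function(meta, cfg, seed = 1L) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(as.integer(seed))
  D <- cfg$D
  fid <- sgb_feature_ids(D)
  des <- build_design(meta)
  Q <- nrow(des$X); N <- ncol(des$X)

  Lambda_clr <- matrix(0, D, Q, dimnames = list(fid, des$spec$term_names))
  sign_vec <- integer(0)
  if (cfg$n_diff > 0L) {
    planted <- seq_len(cfg$n_diff)
    sign_vec <- rep(c(1, -1), length.out = cfg$n_diff)
    j <- term_index(des$spec, "visit:pfs12")
    Lambda_clr[planted, j] <- sign_vec * cfg$delta
    Lambda_clr[, j] <- Lambda_clr[, j] - mean(Lambda_clr[, j])
  }
  if (Q > 16L) {
    periph <- matrix(stats::rnorm(D * (Q - 16L), 0, 0.05), D, Q - 16L)
    periph <- sweep(periph, 2, colMeans(periph))
    Lambda_clr[, 17:Q] <- periph
  }
  ref <- D
  Lambda_alr <- sweep(Lambda_clr[-ref, , drop = FALSE], 2, Lambda_clr[ref, ])
  eta <- Lambda_alr %*% des$X +
    matrix(stats::rnorm((D - 1L) * N, 0, cfg$sigma), D - 1L, N)
  vals <- alr_inv(eta, ref = ref)
  dimnames(vals) <- list(fid, meta$sample_id)
  if (is.finite(cfg$depth)) {
    vals <- apply(vals, 2, function(p)
      stats::rmultinom(1, size = cfg$depth, prob = p) / cfg$depth)
    dimnames(vals) <- list(fid, meta$sample_id)
  }
  if (cfg$zero_inflation > 0) {
    drop <- matrix(stats::runif(D * N) < cfg$zero_inflation, D, N)
    # never zero out an entire sample
    keep_col <- colSums(!drop) == 0
    drop[, keep_col] <- FALSE
    vals[drop] <- 0
    vals <- sweep(vals, 2, colSums(vals), "/")
  }
  tab <- abundance_table(vals, level = "SGB")
  plus <- fid[seq_len(cfg$n_diff)][sign_vec > 0]
  minus <- fid[seq_len(cfg$n_diff)][sign_vec < 0]
  truth <- list(Lambda_clr = Lambda_clr, sigma = cfg$sigma,
                planted = fid[seq_len(cfg$n_diff)], signs = sign_vec,
                balance = if (length(plus) && length(minus))
                  balance_def(plus, minus, "planted") else NULL,
                delta = cfg$delta, ref = ref, design = des)
  list(tab = tab, truth = truth)
}

#' Simulate survival records
#'
#' Exponential event times with the hazard of the high-risk stratum scaled
#' by `exp(beta)`, administratively censored at the configured horizon.
#'
#' @param patients Patient table from [simulate_metadata()].
#' @param cfg A [sim_config()].
#' @param group Binary high-risk indicator per patient (default: PFS < 12
#'   months).
#' @param beta Log hazard ratio (default `cfg$surv_beta`).
#' @param seed Integer seed.
#' @return `data.frame` with `patient_id`, `time`, `event`, `group` and the
#'   patient covariates.
#' @export
simulate_survival <- function(patients, cfg, group = NULL, beta = NULL,
                              seed = 1L) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(as.integer(seed))
  if (is.null(group)) group <- as.integer(patients$pfs12 == "<12")
  if (is.null(beta)) beta <- cfg$surv_beta
  n <- nrow(patients)
  base_rate <- log(2) / cfg$surv_median_months
  t_raw <- stats::rexp(n, rate = base_rate * exp(beta * group))
  out <- data.frame(patient_id = patients$patient_id,
                    time = pmin(t_raw, cfg$surv_horizon),
                    event = as.integer(t_raw <= cfg$surv_horizon),
                    group = group,
                    stringsAsFactors = FALSE)
  cbind(out, patients[, setdiff(colnames(patients), "patient_id")])
}

#' Simulate a complete cohort
#'
#' Metadata, abundance profiles and survival records from one root seed
#' (sub-seeds are derived deterministically).
#'
#' @param cfg A [sim_config()].
#' @param seed Integer root seed.
#' @return List of class `sim_output` with `meta`, `patients`, `tab`,
#'   `truth`, `survival` and the config and seed.
#' @export
simulate_cohort <- function(cfg = sim_config(), seed = 1L) {
  set.seed(as.integer(seed))
  seeds <- sample.int(2^31 - 1, 3)
  md <- simulate_metadata(cfg, seed = seeds[1])
  ab <- simulate_abundances(md$meta, cfg, seed = seeds[2])
  sv <- simulate_survival(md$patients, cfg, seed = seeds[3])
  structure(list(meta = md$meta, patients = md$patients, tab = ab$tab,
                 truth = ab$truth, survival = sv, config = cfg, seed = seed),
            class = "sim_output")
}

#' Write a simulated cohort to disk
#'
#' Emits a MetaPhlAn-style merged abundance TSV (taxonomy strings in the
#' first column, one leading `#` comment line), metadata and survival TSVs,
#' and the truth bundle as JSON. Numeric values are written at full double
#' precision so [read_merged_profile()] round-trips bit-identically.
#'
#' @param sim A [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths.
#' @export
write_fixture <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_output"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(abundance = file.path(dir, "abundance.tsv"),
             metadata = file.path(dir, "metadata.tsv"),
             survival = file.path(dir, "survival.tsv"),
             truth = file.path(dir, "truth.json"))
  vals <- sim$tab$values
  ab <- data.frame(clade_name = rownames(vals),
                   as.data.frame(vals, check.names = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  con <- file(paths["abundance"], "w")
  writeLines("#synthetic merged abundance table", con)
  close(con)
  num <- vapply(ab, is.numeric, logical(1))
  ab[num] <- lapply(ab[num], function(v) formatC(v, digits = 17, format = "g"))
  suppressWarnings(utils::write.table(ab, paths["abundance"], sep = "\t",
                                      quote = FALSE, row.names = FALSE,
                                      append = TRUE))
  write_results(sim$meta, paths["metadata"])
  write_results(sim$survival, paths["survival"])
  truth <- sim$truth
  truth$design <- NULL
  truth$Lambda_clr_focal <- truth$Lambda_clr[, 1:16]
  truth$Lambda_clr <- NULL
  truth$balance <- if (!is.null(truth$balance))
    list(plus = truth$balance$plus, minus = truth$balance$minus)
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(paths)
}
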