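#' Read a pipeline run configuration
#'
#' Configurations are plain named lists; this helper loads one from a YAML
#' (requires the `yaml` package) or JSON file. Flags passed directly to the
#' `run_*` functions override file values.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` config file.
#' @return Named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the yaml package is required to read YAML configs")
    }
    return(yaml::read_yaml(path))
  }
  jsonlite::read_json(path, simplifyVector = TRUE)
}

cfg_get <- function(cfg, name, default) {
  if (!is.null(cfg[[name]])) cfg[[name]] else default
}

resolve_table <- function(x, level = "SGB") {
  if (inherits(x, "abundance_table")) return(x)
  if (is.character(x)) return(read_merged_profile(x, level = level))
  stop("abundance input must be a path or an abundance_table")
}

resolve_meta <- function(x) {
  if (is.data.frame(x)) { validate_metadata(x); return(x) }
  if (is.character(x)) return(read_metadata(x))
  stop("metadata input must be a path or a data.frame")
}

#' Run the longitudinal differential-abundance pipeline
#'
#' Orchestrates: prevalence filtering and renormalization, zero replacement,
#' alr transform, interaction design matrix, conjugate logistic-normal fit,
#' posterior sampling, clr conversion, and the requested post hoc contrasts
#' with per-visit differential rankings and dynamics labels. Writes one TSV
#' per contrast plus a `manifest.json` recording the seed, prior dimensions
#' and feature/sample counts at every stage, so a run is reproducible from
#' its manifest.
#'
#' @param cfg Named list (or path to a YAML/JSON file, see
#'   [read_run_config()]) with entries: `abundance` (path or table),
#'   `metadata` (path or data.frame), and optionally `level`,
#'   `baseline_min`, `longitudinal_min`, `epsilon`, `S`, `seed`,
#'   `contrasts` (names from [lnm_contrasts()]), `bcl_levels`, `out_dir`.
#' @return Invisibly, a list with the posterior draws, per-contrast results
#'   and the manifest; files are written when `out_dir` is set.
#' @export
run_longitudinal <- function(cfg) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  stage <- function(nm, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", nm, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  tab <- stage("read", resolve_table(cfg$abundance, cfg_get(cfg, "level", "SGB")))
  meta <- stage("read", resolve_meta(cfg$metadata))
  meta <- meta[match(sample_ids(tab), meta$sample_id), ]
  n_in <- nrow(tab$values)
  tab <- stage("prevalence_filter",
               prevalence_filter(tab, meta,
                                 cfg_get(cfg, "baseline_min", 0.20),
                                 cfg_get(cfg, "longitudinal_min", 0.10)))
  tab <- stage("renormalize", renormalize(tab))
  eps <- cfg_get(cfg, "epsilon", 1e-6)
  vals <- stage("zero_replace", zero_replace(tab$values, epsilon = eps))
  D <- nrow(vals)
  eta <- stage("alr", alr(vals))
  des <- stage("design", build_design(meta))
  prior <- stage("prior", lnm_prior(D, nrow(des$X)))
  post <- stage("fit", fit_conjugate(eta, des, prior))
  S <- cfg_get(cfg, "S", 2000L)
  seed <- cfg_get(cfg, "seed", 1L)
  draws <- stage("sample", sample_posterior(post, S = S, seed = seed))
  draws <- stage("clr", draws_to_clr(draws, feature_names = feature_ids(tab)))
  contrast_names <- cfg_get(cfg, "contrasts", "pfs12")
  levels <- cfg_get(cfg, "bcl_levels", default_bcl_levels)
  out_dir <- cfg$out_dir
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE,
                                    showWarnings = FALSE)
  results <- list()
  for (cn in contrast_names) {
    grid <- stage(paste0("contrast:", cn), build_reference_grid(meta, cn))
    res <- stage(paste0("contrast:", cn),
                 contrast_posterior(draws, grid, levels = levels))
    dyn <- classify_dynamics(res, level = 0.9)
    tabout <- merge(res$summary, dyn[, c("feature", "category")],
                    by = "feature", sort = FALSE)
    tabout <- tabout[order(tabout$feature, tabout$visit), ]
    if (!is.null(out_dir)) {
      write_results(tabout, file.path(out_dir, paste0("contrast_", cn, ".tsv")))
      write_results(differential_ranking(res, visit = 3),
                    file.path(out_dir, paste0("ranking_", cn, "_T3.tsv")))
    }
    results[[cn]] <- list(result = res, dynamics = dyn)
  }
  manifest <- list(
    package = "lnmdyn",
    version = as.character(utils::packageVersion("lnmdyn")),
    seed = seed, S = S, epsilon = eps,
    features_input = n_in, features_retained = D,
    samples = ncol(vals), Q = nrow(des$X), design_rank = des$spec$rank,
    prior = list(nu = prior$nu, Gamma = "identity", Theta = "zero",
                 Xi = paste0((prior$nu - D), " * identity")),
    contrasts = contrast_names)
  if (!is.null(out_dir)) {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(list(draws = draws, contrasts = results, meta = meta,
                 tab = tab, manifest = manifest))
}

#' Run the balance biomarker analysis
#'
#' Computes per-visit balance scores, their case-control Wilcoxon p-values,
#' the repeated cross-validated AUC per visit, and (when survival records
#' are supplied) Cox models for the median-stratified and continuous
#' baseline balance, with Kaplan-Meier curves by stratum.
#'
#' @param cfg Named list (or config file path) with: `abundance`,
#'   `metadata`, `balance` (a [balance_def()], or a list/JSON file with
#'   `plus` and `minus` ID vectors), and optionally `survival` (path or
#'   data.frame), `epsilon`, `repeats`, `folds`, `seed`, `cox_covariates`,
#'   `out_dir`.
#' @return Invisibly, a list with per-visit scores, Wilcoxon p-values,
#'   CV-AUC summaries and any survival results.
#' @export
run_balance <- function(cfg) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  tab <- resolve_table(cfg$abundance, cfg_get(cfg, "level", "SGB"))
  meta <- resolve_meta(cfg$metadata)
  meta <- meta[match(sample_ids(tab), meta$sample_id), ]
  bd <- cfg$balance
  if (is.null(bd)) stop("config must provide a balance definition")
  if (is.character(bd)) bd <- jsonlite::read_json(bd, simplifyVector = TRUE)
  if (!inherits(bd, "balance_def")) {
    bd <- balance_def(bd$plus, bd$minus, cfg_get(bd, "name", "balance"))
  }
  vals <- zero_replace(renormalize(tab)$values,
                       epsilon = cfg_get(cfg, "epsilon", 1e-6))
  ztab <- abundance_table(vals, level = tab$level)
  scores <- balance_score(ztab, bd,
                          drop_missing = cfg_get(cfg, "drop_missing", FALSE))
  seed <- cfg_get(cfg, "seed", 1L)
  label <- meta$pfs12 == ">=12"
  per_visit <- lapply(0:3, function(v) {
    sel <- meta$visit == v
    if (!any(sel) || length(unique(label[sel])) < 2L) return(NULL)
    wt <- wilcoxon_rank_sum(scores[sel][label[sel]], scores[sel][!label[sel]])
    cv <- cv_auc(scores[sel], label[sel],
                 repeats = cfg_get(cfg, "repeats", 100L),
                 folds = cfg_get(cfg, "folds", 5L),
                 seed = seed + v)
    list(visit = v, n = sum(sel), wilcoxon_p = wt$p,
         auc_mean = cv$mean, auc_sd = cv$sd)
  })
  per_visit <- per_visit[!vapply(per_visit, is.null, logical(1))]
  metrics <- do.call(rbind, lapply(per_visit, as.data.frame))
  surv_res <- NULL
  if (!is.null(cfg$survival)) {
    sv <- if (is.data.frame(cfg$survival)) cfg$survival else
      read_survival(cfg$survival)
    base <- meta$visit == 0
    b0 <- scores[base]
    names(b0) <- meta$patient_id[base]
    sv <- sv[sv$patient_id %in% names(b0), ]
    sv$balance <- b0[sv$patient_id]
    sv$stratum <- median_stratify(sv$balance)
    covs <- cfg_get(cfg, "cox_covariates", character(0))
    strat_fit <- cox_fit(sv, c("stratum", covs))
    cont_fit <- cox_fit(sv, c("balance", covs))
    surv_res <- list(km = km_estimate(sv, group = sv$stratum),
                     cox_stratified = strat_fit,
                     cox_continuous = cont_fit)
  }
  out_dir <- cfg$out_dir
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_results(data.frame(sample_id = names(scores), balance = scores),
                  file.path(out_dir, "balance_scores.tsv"))
    write_results(metrics, file.path(out_dir, "balance_metrics.tsv"))
    if (!is.null(surv_res)) {
      write_results(surv_res$cox_stratified,
                    file.path(out_dir, "cox_stratified.tsv"))
      write_results(surv_res$cox_continuous,
                    file.path(out_dir, "cox_continuous.tsv"))
      write_results(surv_res$km$curve, file.path(out_dir, "km_curve.tsv"))
    }
  }
  invisible(list(scores = scores, metrics = metrics, survival = surv_res,
                 balance = bd))
}

#' Simulate a cohort and write it as a fixture directory
#'
#' @param cfg Named list with optional [sim_config()] fields, `seed` and
#'   `out_dir`.
#' @return Invisibly, the [simulate_cohort()] output; files written when
#'   `out_dir` is set.
#' @export
run_simulate <- function(cfg = list()) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  seed <- cfg_get(cfg, "seed", 1L)
  cfg_args <- cfg[intersect(names(cfg), names(formals(sim_config)))]
  sc <- do.call(sim_config, cfg_args)
  sim <- simulate_cohort(sc, seed = seed)
  if (!is.null(cfg$out_dir)) write_fixture(sim, cfg$out_dir)
  invisible(sim)
}
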