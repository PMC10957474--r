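# shared in-code fixtures for the test suite

# minimal metadata frame; vectors recycle across n samples
make_meta <- function(n = 8, visit = rep(0:3, length.out = n),
                      patient = paste0("P", rep(seq_len(ceiling(n / 4)),
                                                each = 4)[seq_len(n)]),
                      pfs12 = rep(c(">=12", "<12"), length.out = n),
                      therapy = "mono", colitis = "no", ppi = "no") {
  data.frame(
    sample_id = paste0("S", seq_len(n)),
    patient_id = rep(patient, length.out = n),
    visit = visit,
    days_since_first_infusion = 21 * visit,
    pfs12 = rep(pfs12, length.out = n),
    therapy = rep(therapy, length.out = n),
    colitis = rep(colitis, length.out = n),
    other_irae = rep(c("no", "yes"), length.out = n),
    ppi = rep(ppi, length.out = n),
    antibiotics = "no",
    prior_targeted = rep(c("yes", "no"), length.out = n),
    center = rep(c("A", "B"), length.out = n),
    age = seq(40, 70, length.out = n),
    sex = rep(c("F", "M"), length.out = n),
    bmi = seq(20, 30, length.out = n),
    stringsAsFactors = FALSE)
}

# small positive abundance matrix closed to proportions
make_tab <- function(D = 5, n = 8, seed = 1) {
  set.seed(seed)
  v <- matrix(stats::rexp(D * n), D, n,
              dimnames = list(paste0("f", seq_len(D)), paste0("S", seq_len(n))))
  abundance_table(sweep(v, 2, colSums(v), "/"), level = "SGB")
}

# synthetic posterior draw set in clr coordinates: D features, 16+ terms,
# draws generated N(mean_mat, sd) then column-centered per draw
make_clr_draws <- function(mean_focal, S = 400, sd = 0.05, Q = 16, seed = 1,
                           center = TRUE) {
  set.seed(seed)
  D <- nrow(mean_focal)
  L <- array(0, c(D, Q, S), dimnames = list(rownames(mean_focal), NULL, NULL))
  for (s in seq_len(S)) {
    M <- matrix(rnorm(D * Q, 0, sd), D, Q)
    M[, seq_len(ncol(mean_focal))] <- M[, seq_len(ncol(mean_focal))] +
      mean_focal
    L[, , s] <- if (center) sweep(M, 2, colMeans(M)) else M
  }
  structure(list(Lambda = L, Sigma = NULL, system = "clr", ref = D,
                 term_names = NULL, spec = NULL, seed = seed),
            class = "lnm_draws")
}
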