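# Independent oracles and fixture builders used across the suite.

# brute-force U-statistic AUC: enumerate all positive-negative pairs
brute_auc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  mean(outer(pos, neg, ">") + 0.5 * outer(pos, neg, "=="))
}

# delete-one jackknife covariance of a vector of correlated AUCs
jackknife_auc_cov <- function(score_mat, labels) {
  n <- nrow(score_mat)
  k <- ncol(score_mat)
  loo <- t(vapply(seq_len(n), function(i) {
    vapply(seq_len(k), function(j)
      brute_auc(score_mat[-i, j], labels[-i]), numeric(1))
  }, numeric(k)))
  ctr <- sweep(loo, 2, colMeans(loo))
  ((n - 1) / n) * crossprod(ctr)
}

# random small score/label instance with heavy ties (integer scores)
random_tied_instance <- function(n_max = 30) {
  n <- sample(4:n_max, 1)
  repeat {
    y <- runif(n) < 0.4
    if (sum(y) >= 1 && sum(!y) >= 1) break
  }
  list(s = sample(0:6, n, replace = TRUE) + sample(c(0, 0.5), n, replace = TRUE),
       y = y)
}

# one patient's rows in the long cohort schema
make_patient <- function(id, minutes, pulse, sbp, dbp = NA_real_,
                         died = FALSE, eof = FALSE, icu = FALSE, units = 0,
                         hyst = FALSE, diagnosis = "other",
                         context = "tertiary", ebl = 1000,
                         age = 30, parity = 2) {
  k <- length(minutes)
  data.frame(patient_id = rep(id, k), entry_context = rep(context, k),
             ebl_ml = rep(ebl, k), diagnosis = rep(diagnosis, k),
             minutes_from_entry = minutes,
             pulse = rep_len(pulse, k), sbp = rep_len(sbp, k),
             dbp = rep_len(dbp, k),
             died = rep(died, k), end_organ_failure = rep(eof, k),
             icu_admission = rep(icu, k), transfusion_units = rep(units, k),
             emergency_hysterectomy = rep(hyst, k),
             age_years = rep(age, k), parity = rep(parity, k),
             stringsAsFactors = FALSE)
}

make_cohort <- function(...) {
  df <- do.call(rbind, list(...))
  class(df) <- c("shock_cohort", "data.frame")
  df
}

# drop class and bookkeeping attributes for content comparison
plain_df <- function(d) {
  d <- as.data.frame(d)
  attributes(d) <- attributes(d)[c("names", "row.names")]
  class(d) <- "data.frame"
  rownames(d) <- NULL
  d
}

fixture_path <- function(file) {
  system.file("extdata", file, package = "shockindex", mustWork = TRUE)
}
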