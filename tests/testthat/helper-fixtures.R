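# Shared fixtures, built in code at test time.

# A small, fully explicit cohort data frame (3 patients).
toy_cohort_df <- function() {
  data.frame(
    patient_id = c("P1", "P2", "P3"),
    screen_dim_major = c(20, 15, 12),
    screen_dim_minor = c(10, 12, 8),
    diag_dim_major = c(30, 18, 13),
    diag_dim_minor = c(15, 14, 9),
    interval_days = c(540, 365, 200),
    age_years = c(55, 62, 68),
    grade = c(2, 3, 1),
    histological_size_mm = c(18, 25, 9),
    npi = c(3.4, 5.1, 2.2),
    nodal_stage = c(1, 2, 1),
    mitotic_score = c(2, 3, 1),
    ki67_percent = c(12, 34, 5),
    er_status = c("positive", "negative", "positive"),
    pr_status = c("positive", "negative", "positive"),
    her2_status = c("negative", "positive", NA),
    lvi = c("negative", "definite", "probable"),
    subtype = c("luminal A", "TNBC", "luminal B"),
    bcss_months = c(110, 48, 130),
    event = c(0L, 1L, 0L),
    stringsAsFactors = FALSE
  )
}

toy_cohort <- function() as_cohort(toy_cohort_df(), provenance = "toy")

# Feature matrix where exactly three features determine the label
# (deterministic linear rule), plus pure-noise features.
make_selection_fixture <- function(n = 200, seed = 1, n_noise = 4) {
  invigor:::with_seed(seed, {
    x <- matrix(stats::rnorm(n * (3 + n_noise)), n, 3 + n_noise,
                dimnames = list(NULL, c(paste0("inf", 1:3),
                                        paste0("noise", seq_len(n_noise)))))
    lab <- factor(ifelse(x[, 1] + 0.8 * x[, 2] + 0.6 * x[, 3] > 0,
                         "fast", "slow"),
                  levels = c("slow", "fast"))
    list(x = x, labels = lab)
  })
}

# Null fixture: labels drawn independently of every feature.
make_null_fixture <- function(n = 200, seed = 1, n_features = 7) {
  invigor:::with_seed(seed, {
    x <- matrix(stats::rnorm(n * n_features), n, n_features,
                dimnames = list(NULL, paste0("f", seq_len(n_features))))
    lab <- factor(ifelse(stats::rbinom(n, 1, 0.5) == 1, "fast", "slow"),
                  levels = c("slow", "fast"))
    list(x = x, labels = lab)
  })
}

# Exhaustive cutpoint oracle: evaluate survival::survdiff at every
# admissible midpoint and return the maximising threshold and chi-square.
cutpoint_oracle <- function(rates, time, event, min_group_frac = 0.10) {
  n <- length(rates)
  srt <- sort(unique(rates))
  mids <- (srt[-1] + srt[-length(srt)]) / 2
  min_count <- ceiling(min_group_frac * n)
  keep <- vapply(mids, function(th) {
    nb <- sum(rates <= th); nb >= min_count && (n - nb) >= min_count
  }, logical(1))
  mids <- mids[keep]
  chis <- vapply(mids, function(th) {
    g <- rates > th
    survival::survdiff(survival::Surv(time, event) ~ g)$chisq
  }, numeric(1))
  best <- which.max(chis)
  list(threshold = mids[best], chi_square = chis[best],
       candidates = data.frame(threshold = mids, chi_square = chis))
}
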