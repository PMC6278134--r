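# Shared fixtures: tiny hand-built populations and instance sets, all
# constructed in code at test time.

# assemble an ehr_population directly from per-patient pieces
make_population <- function(patients, diagnoses, exams) {
  pop <- list(
    patients = data.table::as.data.table(patients),
    diagnoses = data.table::as.data.table(diagnoses),
    exams = data.table::as.data.table(exams)
  )
  pop$diagnoses$date <- as.Date(pop$diagnoses$date)
  pop$exams$date <- as.Date(pop$exams$date)
  data.table::setkey(pop$diagnoses, patient_id, date)
  class(pop) <- "ehr_population"
  pop
}

# a small matched-cohort scenario: one stroke case born 1950 plus a pool of
# stroke-free candidates sharing (or not) its birth year and gender
cohort_scenario <- function(n_candidates = 5, candidate_birth = 1950,
                            candidate_gender = 1) {
  idx <- as.Date("2010-06-15")
  pats <- data.frame(
    patient_id = c("CASE", sprintf("CTL%02d", seq_len(n_candidates))),
    gender = c(1, rep(candidate_gender, n_candidates)),
    birth_year = c(1950, rep(candidate_birth, n_candidates))
  )
  d <- rbind(
    data.frame(patient_id = "CASE",
               date = c("2005-03-01", "2010-06-15"),
               icd10_code = c("I10", "I639")),
    do.call(rbind, lapply(pats$patient_id[-1], function(id)
      data.frame(patient_id = id, date = c("2005-01-10", "2012-01-10"),
                 icd10_code = c("E11", "J069"))))
  )
  e <- rbind(
    data.frame(patient_id = "CASE", date = "2006-04-01",
               metric = "Hb", value = 14.5),
    do.call(rbind, lapply(pats$patient_id[-1], function(id)
      data.frame(patient_id = id, date = c("2006-02-01", "2012-02-01"),
                 metric = "Hb", value = c(14.0, 13.8))))
  )
  make_population(pats, d, e)
}

# scaler stats straight from the catalog reference distributions
reference_stats <- function() {
  cat20 <- metric_catalog()
  out <- list(
    metrics = data.frame(metric = cat20$metric, mean = cat20$mean_m,
                         sd = cat20$sd_m, stringsAsFactors = FALSE),
    gender_means = rbind(
      data.frame(metric = cat20$metric, gender = 0, mean = cat20$mean_f),
      data.frame(metric = cat20$metric, gender = 1, mean = cat20$mean_m)
    )
  )
  class(out) <- "scaler_stats"
  out
}

# a small trained embedder over the default background vocabulary
default_embedder <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- train_autoencoder(
        code_vocabulary(names(default_background_codes())), dim = 32,
        seed = 1)
    cache
  }
})

# random instance_set of exam-like sequences; optional mean shift on a
# block of entries of the positives
random_exam_set <- function(n, seed, prev = 0.3, shift = 0,
                            len = 20L, dim = 28L) {
  set.seed(seed)
  y <- stats::rbinom(n, 1, prev)
  x <- array(stats::rnorm(n * len * dim), c(n, len, dim))
  if (shift != 0)
    for (i in which(y == 1))
      x[i, (len - 5):len, 9:13] <- x[i, (len - 5):len, 9:13] + shift
  out <- list(x = x, mask = matrix(1, n, len), y = y,
              anchor = as.Date("2010-01-01") + seq_len(n),
              patient_id = sprintf("R%04d", seq_len(n)))
  class(out) <- "instance_set"
  out
}

# small random prediction batches for loss fuzzing
random_batch <- function(n, seed) {
  set.seed(seed)
  p <- stats::runif(n, 0.02, 0.98)
  prediction_batch(cbind(1 - p, p), stats::rbinom(n, 1, 0.4))
}
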