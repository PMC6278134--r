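#' Truncate a raw ICD-10 code to four characters
#'
#' Raw EHR codes may carry a fifth character, optionally spelled with a dot
#' ("E11.6"). Truncation removes any dot and keeps at most the first four
#' characters; because ICD-10 codes form a prefix hierarchy, the truncated
#' code is the parent category. The operation is idempotent.
#'
#' @param raw_code character vector of raw code strings.
#' @return character vector of codes of length at most 4.
#' @export
#' @examples
#' truncate_code(c("G4730", "I63", "I63.9"))
truncate_code <- function(raw_code) {
  if (length(raw_code) == 0) return(character(0))
  if (any(is.na(raw_code) | !nzchar(raw_code)))
    stop("truncate_code: empty code")
  if (any(!grepl("^[A-Za-z][A-Za-z0-9.]*$", raw_code)))
    stop("truncate_code: not an ICD-10-shaped code: ",
         paste(utils::head(raw_code[!grepl("^[A-Za-z][A-Za-z0-9.]*$", raw_code)], 3),
               collapse = ", "))
  substr(gsub(".", "", raw_code, fixed = TRUE), 1, 4)
}

#' Categorize the day gap between consecutive records
#'
#' The number of days since the previous record is bucketed into six
#' categories: 0 for an unknown gap or the first record and for gaps under a
#' week, 1 for [7, 30) days, 2 for [30, 90), 3 for [90, 180), 4 for
#' [180, 365], and 5 beyond a year. Note the closed upper edge of category
#' 4: a gap of exactly 365 days is category 4, 366 days is category 5.
#'
#' @param n integer day counts; `NA` is the unknown-gap marker.
#' @return integer categories in 0..5.
#' @export
#' @examples
#' gap_category(c(NA, 3, 45, 365, 366))
gap_category <- function(n) {
  if (length(n) == 0) return(integer(0))
  if (any(!is.na(n) & n < 0)) stop("gap_category: negative day count")
  out <- integer(length(n))
  out[is.na(n)] <- 0L
  k <- which(!is.na(n))
  v <- n[k]
  out[k] <- ifelse(v < 7, 0L,
            ifelse(v < 30, 1L,
            ifelse(v < 90, 2L,
            ifelse(v < 180, 3L,
            ifelse(v <= 365, 4L, 5L)))))
  out
}

#' One-hot encode a gap category
#'
#' @param n_c integer categories in 0..5 (vectorized).
#' @return a `length(n_c)` x 6 matrix of 0/1 with exactly one 1 per row.
#' @export
one_hot_gap <- function(n_c) {
  if (any(is.na(n_c) | n_c < 0 | n_c > 5 | n_c != floor(n_c)))
    stop("one_hot_gap: category out of range 0..5")
  m <- matrix(0, length(n_c), 6)
  m[cbind(seq_along(n_c), n_c + 1L)] <- 1
  m
}

#' Summarize a patient's exams by age
#'
#' Exam histories are irregular: panels repeat within a year, metrics are
#' missing, and a metric can appear twice in one panel. The summarization
#' keeps, for each (age, metric) pair, only the newest recorded value, where
#' age is the exam year minus birth year. Within a single date the
#' later-listed measurement wins. The date of the kept measurement is
#' retained so downstream instances can compute day gaps and anchor dates.
#'
#' @param patient a `patient_record`.
#' @return data.frame `age`, `metric`, `value`, `date` (the date of the
#'   kept measurement), at most one row per (age, metric), ordered by age.
#' @export
summarize_exams_by_age <- function(patient) {
  ex <- patient$exams
  if (!nrow(ex)) {
    return(data.frame(age = integer(), metric = character(),
                      value = numeric(), date = as.Date(character())))
  }
  age <- as.integer(format(as.Date(ex$date), "%Y")) - patient$birth_year
  tab <- data.frame(age = age, metric = ex$metric, value = ex$value,
                    date = as.Date(ex$date), listed = seq_len(nrow(ex)),
                    stringsAsFactors = FALSE)
  # newest date wins; within a date, the later-listed measurement wins
  tab <- tab[order(tab$age, tab$metric, tab$date, tab$listed), , drop = FALSE]
  last <- !duplicated(tab[, c("age", "metric")], fromLast = TRUE)
  out <- tab[last, c("age", "metric", "value", "date"), drop = FALSE]
  out <- out[order(out$age, out$metric), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Training-split scaler and imputation statistics
#'
#' Per-metric mean and standard deviation, and per-gender per-metric
#' imputation means, all computed from the observed (pre-imputation)
#' age-summarized values of training-split patients only. Validation and
#' test data are always standardized with these statistics, never their own.
#'
#' @param population an `ehr_population`.
#' @param train_ids patient ids of the training split.
#' @return A `scaler_stats`: list with `metrics` (data.frame `metric`,
#'   `mean`, `sd`) and `gender_means` (data.frame `metric`, `gender`,
#'   `mean`).
#' @export
fit_scaler <- function(population, train_ids) {
  cat20 <- metric_catalog()$metric
  obs <- vector("list", length(train_ids))
  for (i in seq_along(train_ids)) {
    rec <- as_patient_record(population, train_ids[i])
    s <- summarize_exams_by_age(rec)
    if (nrow(s)) obs[[i]] <- data.frame(metric = s$metric, value = s$value,
                                        gender = rec$gender)
  }
  obs <- do.call(rbind, obs[!vapply(obs, is.null, TRUE)])
  if (is.null(obs) || !nrow(obs)) stop("fit_scaler: no exam values in the training split")
  agg <- stats::aggregate(value ~ metric, obs, function(v) c(mean(v), stats::sd(v)))
  met <- data.frame(metric = agg$metric, mean = agg$value[, 1], sd = agg$value[, 2],
                    stringsAsFactors = FALSE)
  missing_m <- setdiff(cat20, met$metric)
  if (length(missing_m))
    stop("fit_scaler: metric(s) never observed in the training split: ",
         paste(missing_m, collapse = ", "))
  if (any(!is.finite(met$sd) | met$sd <= 0))
    stop("fit_scaler: zero-variance metric(s): ",
         paste(met$metric[!is.finite(met$sd) | met$sd <= 0], collapse = ", "))
  gm <- stats::aggregate(value ~ metric + gender, obs, mean)
  names(gm)[names(gm) == "value"] <- "mean"
  for (g in 0:1) {
    miss <- setdiff(cat20, gm$metric[gm$gender == g])
    if (length(miss))
      stop("fit_scaler: no training observations for gender ", g,
           " on metric(s): ", paste(miss, collapse = ", "))
  }
  res <- list(metrics = met[match(cat20, met$metric), ],
              gender_means = gm)
  class(res) <- "scaler_stats"
  res
}

#' Impute an age-summarized exam table
#'
#' Three strategies for the metric values a patient never had measured at a
#' given age:
#' * `roll_forward`: a missing value takes the last recorded value at an
#'   earlier age (LOCF across the patient's own history);
#' * `roll_forward_gender_mean` (default, the best-performing strategy):
#'   roll forward first, then fill any still-missing value with the
#'   training-split mean for the patient's gender;
#' * `indicator`: missing values become 0 and a 0/1 presence flag per
#'   metric is appended (flags later extend the exam feature vector).
#'
#' @param summary_table output of [summarize_exams_by_age()].
#' @param gender the patient's gender code (0/1), used for gender means.
#' @param strategy one of `"indicator"`, `"roll_forward"`,
#'   `"roll_forward_gender_mean"`.
#' @param stats a `scaler_stats`; required by `roll_forward_gender_mean`.
#' @return data.frame with one row per (age present in the input) x (all 20
#'   metrics): `age`, `metric`, `value`, `date` (per-age anchor date),
#'   `present` (1 if observed at that age).
#' @export
impute_exams <- function(summary_table, gender,
                         strategy = c("roll_forward_gender_mean",
                                      "roll_forward", "indicator"),
                         stats = NULL) {
  strategy <- match.arg(strategy)
  cat20 <- metric_catalog()$metric
  ages <- sort(unique(summary_table$age))
  if (!length(ages)) {
    return(data.frame(age = integer(), metric = character(), value = numeric(),
                      date = as.Date(character()), present = integer()))
  }
  full <- expand.grid(metric = cat20, age = ages, stringsAsFactors = FALSE)
  full <- full[, c("age", "metric")]
  key_full <- paste(full$age, full$metric, sep = "\r")
  key_obs <- paste(summary_table$age, summary_table$metric, sep = "\r")
  mi <- match(key_full, key_obs)
  full$value <- summary_table$value[mi]
  full$present <- as.integer(!is.na(mi))
  # per-age anchor date: newest kept measurement date at that age
  age_date <- stats::aggregate(date ~ age, summary_table, max)
  full$date <- age_date$date[match(full$age, age_date$age)]

  if (strategy == "indicator") {
    full$value[is.na(full$value)] <- 0
  } else {
    # roll forward within each metric across ascending ages
    full <- full[order(full$metric, full$age), , drop = FALSE]
    for (m in unique(full$metric)) {
      k <- which(full$metric == m)
      v <- full$value[k]
      filled <- v
      last <- NA_real_
      for (j in seq_along(v)) {
        if (!is.na(v[j])) last <- v[j] else filled[j] <- last
      }
      full$value[k] <- filled
    }
    if (strategy == "roll_forward_gender_mean") {
      if (is.null(stats)) stop("impute_exams: gender-mean strategy needs scaler stats")
      gm <- stats$gender_means
      gm <- gm[gm$gender == gender, ]
      still <- which(is.na(full$value))
      if (length(still)) {
        mm <- gm$mean[match(full$metric[still], gm$metric)]
        if (anyNA(mm))
          stop("impute_exams: no gender mean for metric(s): ",
               paste(unique(full$metric[still][is.na(mm)]), collapse = ", "))
        full$value[still] <- mm
      }
    }
  }
  full <- full[order(full$age, full$metric), , drop = FALSE]
  rownames(full) <- NULL
  full
}

#' Standardize exam values with training-split statistics
#'
#' z = (x - mean) / sd, with mean and sd from [fit_scaler()]. Values
#' imputed as absent under the indicator strategy (0 with flag 0) are left
#' untouched.
#'
#' @param table output of [impute_exams()].
#' @param stats a `scaler_stats`.
#' @param skip_absent if `TRUE`, rows with `present == 0` keep their filled
#'   value (used by the indicator strategy where 0 marks absence).
#' @return the table with `value` standardized.
#' @export
standardize_exams <- function(table, stats, skip_absent = FALSE) {
  if (!nrow(table)) return(table)
  mi <- match(table$metric, stats$metrics$metric)
  if (anyNA(mi)) stop("standardize_exams: metric not in scaler stats")
  z <- (table$value - stats$metrics$mean[mi]) / stats$metrics$sd[mi]
  if (skip_absent) {
    keep <- table$present == 0
    z[keep] <- table$value[keep]
  }
  table$value <- z
  table
}

# embedded diagnosis rows for one patient: g, age, one-hot gap, 32-dim code
# embedding; codes must already be truncated
diagnosis_rows <- function(gender, birth_year, dates, codes, embedder) {
  n <- length(dates)
  emb <- embed_codes(codes, embedder)            # n x 32
  age <- as.integer(format(dates, "%Y")) - birth_year
  gaps <- c(NA, as.integer(diff(dates)))
  oh <- one_hot_gap(gap_category(gaps))
  cbind(gender, age, oh, emb, deparse.level = 0)
}

#' Build diagnosis-sequence instances for one patient
#'
#' One instance is emitted per anchor position i over the patient's usable
#' diagnoses (for cases: non-stroke diagnoses dated strictly before the
#' index date; for controls: all diagnoses). Instance i holds rows h..i with
#' h = max(1, i - 34), so at most 35 rows. Each row is the 40-long vector
#' (gender, age at diagnosis, 6 one-hot gap categories, 32-dim code
#' embedding); the gap of the patient's first diagnosis is the unknown
#' marker (category 0). The label is 1 iff a stroke diagnosis falls within
#' (anchor, anchor + 365 days].
#'
#' @param patient a `patient_record`.
#' @param embedder a trained [train_autoencoder()] model.
#' @param index_date the case's first stroke date, or `NULL` for controls.
#' @param window label horizon in days.
#' @param max_len row cap per instance.
#' @return list of instances: each `list(x = matrix rows x 40, y = 0/1,
#'   anchor = Date)`, or an empty list if no usable diagnosis exists.
#' @export
build_diagnosis_instances <- function(patient, embedder, index_date = NULL,
                                      window = 365L, max_len = 35L) {
  d <- patient$diagnoses
  if (!nrow(d)) return(list())
  codes <- truncate_code(d$icd10_code)
  dates <- as.Date(d$date)
  keep <- !is_stroke_code(codes)
  if (!is.null(index_date)) keep <- keep & dates < as.Date(index_date)
  codes <- codes[keep]; dates <- dates[keep]
  if (!length(codes)) return(list())
  rows <- diagnosis_rows(patient$gender, patient$birth_year, dates, codes,
                         embedder)
  lapply(seq_along(dates), function(i) {
    h <- max(1L, i - (max_len - 1L))
    y <- if (is.null(index_date)) 0L else {
      as.integer(as.Date(index_date) > dates[i] &
                   as.Date(index_date) <= dates[i] + window)
    }
    list(x = rows[h:i, , drop = FALSE], y = y, anchor = dates[i])
  })
}

#' Build exam-sequence instances for one patient
#'
#' The patient's exams are age-summarized, imputed, and standardized; one
#' instance is emitted per age with data, holding the rows of the first
#' through j-th ages (capped at the 20 most recent). Each row is the
#' 28-long vector (gender, age at exam, 6 one-hot gap categories, 20
#' standardized metric values); under the indicator strategy the 20
#' presence flags extend rows to 48. Day gaps run between the retained
#' per-age anchor dates. The instance anchor is the newest exam date in it;
#' for cases, instances anchored on/after the stroke date are not emitted.
#'
#' @param patient a `patient_record`.
#' @param stats a `scaler_stats`.
#' @param index_date the case's first stroke date, or `NULL` for controls.
#' @param strategy imputation strategy, see [impute_exams()].
#' @param window label horizon in days.
#' @param max_len row cap per instance.
#' @return list of instances (`x`, `y`, `anchor`), possibly empty; an empty
#'   exam history yields an empty list with a warning.
#' @export
build_exam_instances <- function(patient, stats, index_date = NULL,
                                 strategy = "roll_forward_gender_mean",
                                 window = 365L, max_len = 20L) {
  s <- summarize_exams_by_age(patient)
  if (!nrow(s)) {
    warning("patient ", patient$patient_id, " has no exam history; skipped")
    return(list())
  }
  imp <- impute_exams(s, patient$gender, strategy, stats)
  imp <- standardize_exams(imp, stats, skip_absent = (strategy == "indicator"))
  cat20 <- metric_catalog()$metric
  ages <- sort(unique(imp$age))
  anchor_dates <- imp$date[match(ages, imp$age)]
  # value matrix: one row per age, metrics in catalog order
  vm <- matrix(imp$value[order(match(imp$age, ages), match(imp$metric, cat20))],
               nrow = length(ages), ncol = length(cat20), byrow = TRUE)
  gaps <- c(NA, as.integer(diff(anchor_dates)))
  oh <- one_hot_gap(gap_category(gaps))
  rows <- cbind(patient$gender, ages, oh, vm, deparse.level = 0)
  if (strategy == "indicator") {
    pm <- matrix(imp$present[order(match(imp$age, ages), match(imp$metric, cat20))],
                 nrow = length(ages), ncol = length(cat20), byrow = TRUE)
    rows <- cbind(rows, pm, deparse.level = 0)
  }
  out <- lapply(seq_along(ages), function(j) {
    if (!is.null(index_date) && anchor_dates[j] >= as.Date(index_date))
      return(NULL)
    h <- max(1L, j - (max_len - 1L))
    y <- if (is.null(index_date)) 0L else {
      as.integer(as.Date(index_date) > anchor_dates[j] &
                   as.Date(index_date) <= anchor_dates[j] + window)
    }
    list(x = rows[h:j, , drop = FALSE], y = y, anchor = anchor_dates[j])
  })
  out[!vapply(out, is.null, TRUE)]
}

#' Stack instance lists into a padded array set
#'
#' Instances are pre-padded with all-zero rows to a fixed sequence length;
#' a 0/1 mask marks the real rows. This fixed-shape layout is the contract
#' of the neural predictors.
#'
#' @param instances list of instances from the builders.
#' @param len fixed sequence length (35 for diagnoses, 20 for exams).
#' @param ids optional per-instance patient ids.
#' @return An `instance_set`: list with `x` (n x len x dim array),
#'   `mask` (n x len), `y` (n), `anchor` (Date, n), `patient_id`.
#' @export
stack_instances <- function(instances, len, ids = NULL) {
  n <- length(instances)
  if (n == 0) stop("stack_instances: no instances")
  dim_x <- ncol(instances[[1]]$x)
  x <- array(0, c(n, len, dim_x))
  mask <- matrix(0, n, len)
  y <- integer(n)
  anchor <- as.Date(rep(NA, n))
  for (i in seq_len(n)) {
    xi <- instances[[i]]$x
    r <- nrow(xi)
    if (r > len) stop("stack_instances: instance longer than len")
    x[i, (len - r + 1):len, ] <- xi   # pre-padding
    mask[i, (len - r + 1):len] <- 1
    y[i] <- instances[[i]]$y
    anchor[i] <- instances[[i]]$anchor
  }
  out <- list(x = x, mask = mask, y = y, anchor = anchor,
              patient_id = if (is.null(ids)) rep(NA_character_, n) else ids)
  class(out) <- "instance_set"
  out
}

#' @export
print.instance_set <- function(x, ...) {
  cat("instance_set:", length(x$y), "instances,",
      dim(x$x)[2], "x", dim(x$x)[3], "padded rows;",
      sum(x$y), "positive\n")
  invisible(x)
}

# subset an instance_set by index
subset_instances <- function(set, idx) {
  out <- list(x = set$x[idx, , , drop = FALSE], mask = set$mask[idx, , drop = FALSE],
              y = set$y[idx], anchor = set$anchor[idx],
              patient_id = set$patient_id[idx])
  class(out) <- "instance_set"
  out
}

#' Featurize a whole cohort into per-split instance sets
#'
#' Runs the full encoding path for every case and control in the cohort:
#' diagnosis instances through the code embedder, exam instances through
#' summarize / impute / standardize with training-split statistics, grouped
#' by split. Paired-input (dual) instances join each patient's diagnosis
#' and exam instance lists by nearest anchor dates: for every exam anchor
#' the newest diagnosis instance anchored on or before it (and at least one
#' exists) is paired with it, keeping the exam instance's label.
#'
#' @param population the injected `ehr_population`.
#' @param cohort_table data.frame from [read_cohort()] / [write_cohort()]
#'   layout (case_id, control_id_1, control_id_2, index_date, split).
#' @param embedder trained autoencoder.
#' @param stats `scaler_stats` fitted on the training split.
#' @param strategy imputation strategy.
#' @param window label horizon in days.
#' @return list with one element per split (`train`, `validation`, `test`),
#'   each holding `diagnosis`, `exam`, and `dual` instance sets (`dual` has
#'   `x_d`, `x_e`, masks, shared `y`).
#' @export
featurize_cohort <- function(population, cohort_table, embedder, stats,
                             strategy = "roll_forward_gender_mean",
                             window = 365L) {
  splits <- c("train", "validation", "test")
  members <- data.frame(
    patient_id = c(cohort_table$case_id, cohort_table$control_id_1,
                   cohort_table$control_id_2),
    index_date = c(as.character(cohort_table$index_date),
                   rep(NA_character_, 2 * nrow(cohort_table))),
    split = rep(cohort_table$split, 3),
    stringsAsFactors = FALSE
  )
  out <- list()
  for (sp in splits) {
    ms <- members[members$split == sp, , drop = FALSE]
    di <- list(); ei <- list(); d_ids <- character(0); e_ids <- character(0)
    dual_d <- list(); dual_e <- list(); dual_ids <- character(0)
    for (k in seq_len(nrow(ms))) {
      rec <- as_patient_record(population, ms$patient_id[k])
      idx <- if (is.na(ms$index_date[k])) NULL else as.Date(ms$index_date[k])
      dd <- build_diagnosis_instances(rec, embedder, idx, window = window)
      ee <- suppressWarnings(
        build_exam_instances(rec, stats, idx, strategy = strategy, window = window))
      if (length(dd)) { di <- c(di, dd); d_ids <- c(d_ids, rep(rec$patient_id, length(dd))) }
      if (length(ee)) { ei <- c(ei, ee); e_ids <- c(e_ids, rep(rec$patient_id, length(ee))) }
      if (length(dd) && length(ee)) {
        d_anchors <- as.Date(vapply(dd, function(z) as.character(z$anchor), ""))
        for (z in ee) {
          j <- which(d_anchors <= z$anchor)
          if (!length(j)) next
          j <- j[which.max(d_anchors[j])]
          dual_d <- c(dual_d, dd[j])
          dual_e <- c(dual_e, list(z))
          dual_ids <- c(dual_ids, rec$patient_id)
        }
      }
    }
    dim_e <- if (strategy == "indicator") 48L else 28L
    dset <- if (length(di)) stack_instances(di, 35L, d_ids) else NULL
    eset <- if (length(ei)) stack_instances(ei, 20L, e_ids) else NULL
    dual <- NULL
    if (length(dual_d)) {
      sd_ <- stack_instances(dual_d, 35L, dual_ids)
      se_ <- stack_instances(dual_e, 20L, dual_ids)
      dual <- list(x_d = sd_$x, mask_d = sd_$mask, x_e = se_$x,
                   mask_e = se_$mask, y = se_$y, patient_id = dual_ids,
                   anchor = se_$anchor)
      class(dual) <- "dual_instance_set"
    }
    out[[sp]] <- list(diagnosis = dset, exam = eset, dual = dual)
  }
  out
}
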