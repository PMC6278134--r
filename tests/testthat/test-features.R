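test_that("code truncation strips dots, caps at 4 characters, and is idempotent", {
  expect_equal(truncate_code("G4730"), "G473")
  expect_equal(truncate_code("I63"), "I63")
  expect_equal(truncate_code("I63.9"), "I639")
  expect_equal(truncate_code("E11.65"), "E116")
  v <- c("G4730", "I63", "I63.9", "A00", "M545")
  expect_equal(truncate_code(truncate_code(v)), truncate_code(v))
  expect_error(truncate_code(""), "empty")
  expect_error(truncate_code("63A"), "ICD-10")
})

test_that("gap categorization matches a brute-force lookup over 0..1000 days", {
  # independent oracle: explicit interval table evaluated per day count
  oracle <- function(n) {
    if (is.na(n)) return(0L)
    bounds <- list(c(0, 6, 0L), c(7, 29, 1L), c(30, 89, 2L), c(90, 179, 3L),
                   c(180, 365, 4L), c(366, Inf, 5L))
    for (b in bounds) if (n >= b[1] && n <= b[2]) return(as.integer(b[3]))
  }
  n <- 0:1000
  expect_equal(gap_category(n), vapply(n, oracle, 0L))
  expect_equal(gap_category(NA), 0L)
  expect_equal(gap_category(c(45, 365, 366)), c(2L, 4L, 5L))
  expect_error(gap_category(-1), "negative")
})

test_that("one-hot gap encoding places a single 1 at the category", {
  expect_equal(one_hot_gap(2)[1, ], c(0, 0, 1, 0, 0, 0))
  expect_equal(one_hot_gap(0)[1, ], c(1, 0, 0, 0, 0, 0))
  m <- one_hot_gap(0:5)
  expect_equal(rowSums(m), rep(1, 6))
  expect_equal(m, diag(6), ignore_attr = TRUE)
  expect_error(one_hot_gap(6), "range")
})

test_that("age summarization keeps the newest value per (age, metric)", {
  pat <- patient_record("S1", 1, 1950, exams = data.frame(
    date = c("2010-03-01", "2010-11-01", "2011-05-01"),
    metric = c("Hb", "Hb", "Hb"),
    value = c(14.0, 13.1, 15.2)
  ))
  s <- summarize_exams_by_age(pat)
  expect_equal(nrow(s), 2)
  expect_equal(s$value[s$age == 60], 13.1)   # Nov beats Mar at age 60
  expect_equal(s$value[s$age == 61], 15.2)

  # duplicate metric on one date: the later-listed measurement wins
  pat2 <- patient_record("S2", 0, 1940, exams = data.frame(
    date = c("2005-06-01", "2005-06-01"),
    metric = c("WBC", "WBC"), value = c(6.1, 7.3)
  ))
  expect_equal(summarize_exams_by_age(pat2)$value, 7.3)

  # single value passes through unchanged
  pat3 <- patient_record("S3", 0, 1940, exams = data.frame(
    date = "2005-06-01", metric = "ALP", value = 200
  ))
  expect_equal(summarize_exams_by_age(pat3)$value, 200)
})

test_that("imputation strategies fill gaps as documented", {
  stats <- reference_stats()
  # Hb observed at age 60 only; GGT never observed
  tab <- data.frame(age = c(60L, 61L), metric = c("Hb", "WBC"),
                    value = c(14.2, 6.0),
                    date = as.Date(c("2010-06-01", "2011-06-01")))

  rf <- impute_exams(tab, gender = 1, strategy = "roll_forward")
  expect_equal(rf$value[rf$age == 61 & rf$metric == "Hb"], 14.2)  # carried
  expect_true(is.na(rf$value[rf$age == 60 & rf$metric == "GGT"])) # nothing to carry

  gm <- impute_exams(tab, gender = 1, strategy = "roll_forward_gender_mean",
                     stats = stats)
  expect_equal(gm$value[gm$age == 61 & gm$metric == "Hb"], 14.2)
  expect_equal(gm$value[gm$age == 60 & gm$metric == "GGT"],
               stats$gender_means$mean[stats$gender_means$metric == "GGT" &
                                         stats$gender_means$gender == 1])
  expect_false(anyNA(gm$value))

  ind <- impute_exams(tab, gender = 1, strategy = "indicator")
  expect_equal(ind$value[ind$age == 60 & ind$metric == "GGT"], 0)
  expect_equal(ind$present[ind$age == 60 & ind$metric == "Hb"], 1L)
  expect_equal(ind$present[ind$age == 60 & ind$metric == "GGT"], 0L)

  # a fully observed table is unchanged under every strategy
  full <- expand.grid(age = 60L, metric = metric_catalog()$metric,
                      stringsAsFactors = FALSE)
  full$value <- seq_len(nrow(full))
  full$date <- as.Date("2010-06-01")
  for (st in c("roll_forward", "roll_forward_gender_mean", "indicator")) {
    out <- impute_exams(full, 1, st, stats)
    expect_equal(out$value[order(out$metric)], full$value[order(full$metric)])
  }
})

test_that("the scaler is fitted on the training split and standardizes to z-scores", {
  cfg <- generator_config(n_patients = 120, seed = 44)
  pop <- generate_population(cfg)
  ids <- pop$patients$patient_id
  stats <- fit_scaler(pop, ids)
  expect_true(all(stats$metrics$sd > 0))
  expect_setequal(stats$metrics$metric, metric_catalog()$metric)

  # standardizing the train data itself recenters each metric near 0
  val <- lapply(ids[1:40], function(id) {
    rec <- as_patient_record(pop, id)
    s <- summarize_exams_by_age(rec)
    standardize_exams(impute_exams(s, rec$gender, "roll_forward_gender_mean",
                                   stats), stats)
  })
  val <- do.call(rbind, val)
  for (m in c("Hb", "LDL-C"))
    expect_lt(abs(mean(val$value[val$metric == m])), 0.2)

  # a value equal to the train mean maps to exactly 0
  one <- data.frame(age = 50L, metric = "Hb",
                    value = stats$metrics$mean[stats$metrics$metric == "Hb"],
                    date = as.Date("2000-01-01"), present = 1L)
  expect_equal(standardize_exams(one, stats)$value, 0)

  # zero-variance metrics are a fitting error
  pop2 <- pop
  pop2$exams$value[pop2$exams$metric == "Hb"] <- 12
  expect_error(fit_scaler(pop2, ids), "zero-variance|Hb")
})

test_that("diagnosis instances window to 35 rows with 40-long vectors", {
  emb <- default_embedder()
  codes <- rep(names(default_background_codes()), length.out = 60)
  pat <- patient_record("D1", 1, 1945, diagnoses = data.frame(
    date = as.Date("2000-01-01") + cumsum(rep(20, 60)), icd10_code = codes))
  inst <- build_diagnosis_instances(pat, emb)
  expect_length(inst, 60)
  expect_equal(nrow(inst[[60]]$x), 35)    # h = max(1, 60 - 34) = 26
  expect_equal(nrow(inst[[1]]$x), 1)
  expect_true(all(vapply(inst, function(z) ncol(z$x), 0L) == 40))
  # control patient: all labels 0
  expect_true(all(vapply(inst, `[[`, 0L, "y") == 0))
  # first row of the first instance has the unknown-gap category (one-hot 0)
  expect_equal(inst[[1]]$x[1, 3:8], c(1, 0, 0, 0, 0, 0))
  # embedding block stays inside the tanh range
  expect_true(all(abs(inst[[60]]$x[, 9:40]) < 1))
})

test_that("case labels flag strokes within the 365-day horizon only", {
  emb <- default_embedder()
  idx <- as.Date("2012-01-01")
  pat <- patient_record("C1", 1, 1945, diagnoses = data.frame(
    date = c(idx - 400, idx - 100, idx),
    icd10_code = c("I10", "E11", "I639")))
  inst <- build_diagnosis_instances(pat, emb, index_date = idx)
  # the stroke code itself and anything on/after the index date are excluded
  expect_length(inst, 2)
  expect_equal(vapply(inst, `[[`, 0L, "y"), c(0L, 1L))

  # label switches 0 -> 1 exactly once over anchors, never after the stroke
  pat2 <- patient_record("C2", 0, 1940, diagnoses = data.frame(
    date = idx - c(900, 700, 500, 300, 120, 30, 0),
    icd10_code = c(rep("I10", 6), "I639")))
  inst2 <- build_diagnosis_instances(pat2, emb, index_date = idx)
  y <- vapply(inst2, `[[`, 0L, "y")
  expect_equal(y, c(0L, 0L, 0L, 1L, 1L, 1L))
  expect_true(all(diff(y) >= 0))
  expect_true(all(as.numeric(vapply(inst2, `[[`, as.numeric(idx), "anchor")) < as.numeric(idx)))
})

test_that("unknown codes raise an encoding error naming the code", {
  emb <- default_embedder()
  pat <- patient_record("U1", 1, 1950, diagnoses = data.frame(
    date = as.Date("2010-01-01"), icd10_code = "Z999"))
  expect_error(build_diagnosis_instances(pat, emb), "Z999")
  expect_error(embed_codes("Z999", emb), "Z999")
})

test_that("exam instances cap at the 20 most recent ages and pad correctly", {
  stats <- reference_stats()
  pat <- patient_record("E1", 1, 1930, exams = data.frame(
    date = as.Date("1990-06-01") + round(365.25 * (0:24)),
    metric = "Hb", value = rnorm(25, 15, 1)))
  inst <- build_exam_instances(pat, stats)
  expect_length(inst, 25)
  expect_equal(nrow(inst[[25]]$x), 20)
  expect_equal(nrow(inst[[1]]$x), 1)
  expect_true(all(vapply(inst, function(z) ncol(z$x), 0L) == 28))
  # single-exam instance carries the first-record gap category
  expect_equal(inst[[1]]$x[1, 3:8], c(1, 0, 0, 0, 0, 0))

  # indicator strategy widens rows to 48
  inst48 <- build_exam_instances(pat, stats, strategy = "indicator")
  expect_equal(ncol(inst48[[1]]$x), 48)

  # case anchoring: instances on/after the stroke date are not emitted
  idx <- as.Date("2000-06-15")
  inst_case <- build_exam_instances(pat, stats, index_date = idx)
  expect_true(all(as.numeric(vapply(inst_case, `[[`, as.numeric(idx), "anchor")) < as.numeric(idx)))
  y <- vapply(inst_case, `[[`, 0L, "y")
  expect_equal(sum(y), 1)   # only the anchor within 365 d of the stroke

  # empty exam history: skipped with a warning
  pat0 <- patient_record("E0", 1, 1950)
  expect_warning(out <- build_exam_instances(pat0, stats), "no exam history")
  expect_length(out, 0)
})

test_that("stacked instance sets pre-pad with zeros and keep masks aligned", {
  emb <- default_embedder()
  pat <- patient_record("P1", 1, 1945, diagnoses = data.frame(
    date = as.Date("2005-01-01") + c(0, 40, 80), icd10_code = c("I10", "E11", "J069")))
  set <- stack_instances(build_diagnosis_instances(pat, emb), 35L)
  expect_equal(dim(set$x), c(3, 35, 40))
  expect_equal(rowSums(set$mask), c(1, 2, 3))
  # padding rows are all zero
  expect_true(all(set$x[1, 1:34, ] == 0))
  expect_true(all(set$x[3, 33:35, 1] == 1))  # gender bit on real rows
})

test_that("featurizing a small cohort produces consistent per-split sets", {
  cfg <- generator_config(n_patients = 500, seed = 66)
  pop <- inject_stroke_events(generate_population(cfg), cfg)
  m <- match_controls(select_cases(pop), pop, seed = 66)
  expect_gt(nrow(m$cases), 5)
  sp <- split_cohort(m, seed = 66)
  tab <- data.frame(case_id = m$cases$patient_id,
                    control_id_1 = m$cases$control_1,
                    control_id_2 = m$cases$control_2,
                    index_date = m$cases$index_date,
                    split = sp$split[match(m$cases$patient_id, sp$patient_id)])
  emb <- train_autoencoder(code_vocabulary(pop$diagnoses$icd10_code), seed = 66)
  stats <- fit_scaler(pop, sp$patient_id[sp$split == "train"])
  splits <- featurize_cohort(pop, tab, emb, stats)
  expect_setequal(names(splits), c("train", "validation", "test"))
  tr <- splits$train
  expect_equal(dim(tr$diagnosis$x)[2:3], c(35, 40))
  expect_equal(dim(tr$exam$x)[2:3], c(20, 28))
  # dual pairs align: same labels, diagnosis anchor <= exam anchor
  expect_equal(length(tr$dual$y), nrow(tr$dual$x_d))
  # controls contribute only negatives; cases contribute at least one positive
  ctl_ids <- c(tab$control_id_1, tab$control_id_2)
  expect_true(all(tr$diagnosis$y[tr$diagnosis$patient_id %in% ctl_ids] == 0))
  expect_gt(sum(tr$diagnosis$y), 0)
})
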