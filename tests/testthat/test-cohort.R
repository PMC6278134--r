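test_that("stroke codes are exactly the I60-I69 prefix range", {
  expect_true(is_stroke_code("I639"))
  expect_true(is_stroke_code("I60"))
  expect_false(is_stroke_code("I700"))
  expect_false(is_stroke_code("I599"))
  expect_equal(is_stroke_code(paste0("I6", 0:9)), rep(TRUE, 10))
  expect_error(is_stroke_code(""), "empty")
})

test_that("case selection applies the window, age range, and prior-record rules", {
  mk <- function(id, birth, stroke_date, prior_diag = TRUE, prior_exam = TRUE) {
    d <- data.frame(patient_id = id, date = stroke_date, icd10_code = "I639")
    if (prior_diag)
      d <- rbind(data.frame(patient_id = id,
                            date = as.character(as.Date(stroke_date) - 400),
                            icd10_code = "I10"), d)
    e <- if (prior_exam)
      data.frame(patient_id = id, date = as.character(as.Date(stroke_date) - 200),
                 metric = "Hb", value = 14)
    else
      data.frame(patient_id = id, date = stroke_date, metric = "Hb", value = 14)
    list(p = data.frame(patient_id = id, gender = 1, birth_year = birth),
         d = d, e = e)
  }
  specs <- list(
    ok        = mk("OK", 1950, "2010-06-01"),
    young     = mk("YOUNG", 1966, "2010-06-01"),   # age 44
    old       = mk("OLD", 1914, "2010-06-01"),     # age 96
    early     = mk("EARLY", 1950, "2000-06-01"),   # outside window
    no_exam   = mk("NOEXAM", 1950, "2010-06-01", prior_exam = FALSE),
    boundary45 = mk("B45", 1965, "2010-06-01"),    # age exactly 45
    boundary95 = mk("B95", 1915, "2010-06-01")     # age exactly 95
  )
  pop <- make_population(do.call(rbind, lapply(specs, `[[`, "p")),
                         do.call(rbind, lapply(specs, `[[`, "d")),
                         do.call(rbind, lapply(specs, `[[`, "e")))
  cases <- select_cases(pop)
  expect_setequal(cases$patient_id, c("OK", "B45", "B95"))
  expect_equal(cases$index_date[cases$patient_id == "OK"],
               as.Date("2010-06-01"))

  # a population with no stroke codes yields an empty case list
  pop2 <- make_population(specs$ok$p,
                          data.frame(patient_id = "OK", date = "2005-01-01",
                                     icd10_code = "I10"),
                          specs$ok$e)
  expect_equal(nrow(select_cases(pop2)), 0)
})

test_that("control matching picks exactly 2 eligible controls, reproducibly", {
  pop <- cohort_scenario(n_candidates = 5)
  cases <- select_cases(pop)
  expect_equal(cases$patient_id, "CASE")
  a <- match_controls(cases, pop, seed = 42)
  b <- match_controls(cases, pop, seed = 42)
  expect_equal(nrow(a$cases), 1)
  ctls <- c(a$cases$control_1, a$cases$control_2)
  expect_length(unique(ctls), 2)
  expect_true(all(grepl("^CTL", ctls)))
  expect_identical(a$cases, b$cases)
  # a different seed may pick different controls but still exactly two
  d <- match_controls(cases, pop, seed = 43)
  expect_length(unique(c(d$cases$control_1, d$cases$control_2)), 2)
})

test_that("cases without two eligible controls are excluded", {
  pop <- cohort_scenario(n_candidates = 1)
  cases <- select_cases(pop)
  m <- match_controls(cases, pop, seed = 1)
  expect_equal(nrow(m$cases), 0)
  expect_equal(m$excluded_cases, "CASE")
})

test_that("controls must match birth year and gender and be stroke-free", {
  # wrong birth year -> ineligible
  pop_by <- cohort_scenario(n_candidates = 5, candidate_birth = 1951)
  m1 <- match_controls(select_cases(pop_by), pop_by, seed = 1)
  expect_equal(m1$excluded_cases, "CASE")
  # wrong gender -> ineligible
  pop_g <- cohort_scenario(n_candidates = 5, candidate_gender = 0)
  m2 <- match_controls(select_cases(pop_g), pop_g, seed = 1)
  expect_equal(m2$excluded_cases, "CASE")
  # a candidate with any I6x code is never selected
  pop <- cohort_scenario(n_candidates = 5)
  extra <- data.table::data.table(patient_id = "CTL01",
                                  date = as.Date("2008-01-01"),
                                  icd10_code = "I62")
  pop$diagnoses <- rbind(pop$diagnoses, extra)
  data.table::setkey(pop$diagnoses, patient_id, date)
  for (s in 1:10) {
    m <- match_controls(select_cases(pop), pop, seed = s)
    expect_false("CTL01" %in% c(m$cases$control_1, m$cases$control_2))
  }
})

test_that("controls need records strictly before AND after the index date", {
  pop <- cohort_scenario(n_candidates = 3)
  # remove CTL01's post-index records entirely
  pop$diagnoses <- pop$diagnoses[!(pop$diagnoses$patient_id == "CTL01" &
                                     pop$diagnoses$date > as.Date("2010-06-15")), ]
  pop$exams <- pop$exams[!(pop$exams$patient_id == "CTL01" &
                             pop$exams$date > as.Date("2010-06-15")), ]
  for (s in 1:6) {
    m <- match_controls(select_cases(pop), pop, seed = s)
    expect_false("CTL01" %in% c(m$cases$control_1, m$cases$control_2))
  }
})

test_that("matching is invariant to population row order", {
  cfg <- generator_config(n_patients = 600, seed = 19)
  pop <- inject_stroke_events(generate_population(cfg), cfg)
  cases <- select_cases(pop)
  m1 <- match_controls(cases, pop, seed = 7)
  set.seed(1)
  pop2 <- pop
  pop2$patients <- pop2$patients[sample.int(nrow(pop2$patients)), ]
  pop2$diagnoses <- pop2$diagnoses[sample.int(nrow(pop2$diagnoses)), ]
  pop2$exams <- pop2$exams[sample.int(nrow(pop2$exams)), ]
  m2 <- match_controls(select_cases(pop2), pop2, seed = 7)
  expect_equal(m1$cases[order(m1$cases$patient_id), ],
               m2$cases[order(m2$cases$patient_id), ],
               ignore_attr = TRUE)
})

test_that("no patient serves as both case and control, and controls serve once", {
  cfg <- generator_config(n_patients = 800, seed = 23)
  pop <- inject_stroke_events(generate_population(cfg), cfg)
  m <- match_controls(select_cases(pop), pop, seed = 2)
  expect_gt(nrow(m$cases), 0)
  ctls <- c(m$cases$control_1, m$cases$control_2)
  expect_equal(anyDuplicated(ctls), 0)
  expect_length(intersect(ctls, m$cases$patient_id), 0)
})

test_that("split ratios follow largest-remainder rounding and controls inherit splits", {
  mk_cohort <- function(n) {
    cases <- data.frame(
      patient_id = sprintf("C%03d", seq_len(n)),
      index_date = as.Date("2010-01-01") + seq_len(n),
      control_1 = sprintf("A%03d", seq_len(n)),
      control_2 = sprintf("B%03d", seq_len(n)),
      stringsAsFactors = FALSE
    )
    structure(list(cases = cases, excluded_cases = character(0)),
              class = "matched_cohort")
  }
  sp <- split_cohort(mk_cohort(100), seed = 1)
  tab <- table(sp$split[sp$role == "case"])
  expect_equal(unname(tab[c("train", "validation", "test")]), c(70, 15, 15),
               ignore_attr = TRUE)

  # per-split case:control ratio is exactly 1:2 and grouped
  for (s in c("train", "validation", "test")) {
    sub <- sp[sp$split == s, ]
    expect_equal(sum(sub$role == "control"), 2 * sum(sub$role == "case"))
  }
  expect_true(all(sp$split[match(sp$case_id, sp$patient_id)] == sp$split))

  # a single case lands in train together with both controls
  sp1 <- split_cohort(mk_cohort(1), seed = 1)
  expect_true(all(sp1$split == "train"))

  expect_error(split_cohort(mk_cohort(10), ratios = c(60, 20, 10)), "sum")
})

test_that("the default generator yields a nonempty matched cohort at moderate n", {
  cfg <- generator_config(n_patients = 1200, seed = 55)
  pop <- inject_stroke_events(generate_population(cfg), cfg)
  m <- match_controls(select_cases(pop), pop, seed = 55)
  expect_gt(nrow(m$cases), 0)
})

test_that("the cohort table roundtrips through CSV", {
  pop <- cohort_scenario(n_candidates = 4)
  m <- match_controls(select_cases(pop), pop, seed = 3)
  sp <- split_cohort(m, seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(m, sp, path)
  back <- read_cohort(path)
  expect_equal(back$case_id, m$cases$patient_id)
  expect_equal(back$index_date, m$cases$index_date)
  expect_true(all(back$split %in% c("train", "validation", "test")))
})
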