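#' Configuration for the synthetic EHR generator
#'
#' Describes a synthetic hospital population: demographics, the rate and
#' vocabulary of diagnosis events, the cadence and completeness of blood /
#' biochemical exam panels, and a planted stroke-hazard mechanism. The
#' planted mechanism has two arms so that diagnosis-based and exam-based
#' predictors each have signal to find: designated background codes multiply
#' the annual stroke hazard of their carriers, and designated exam metrics
#' drift (linearly in years-to-event) over the years leading up to a stroke.
#'
#' @param n_patients number of patients to simulate.
#' @param birth_year_range inclusive `c(min, max)` calendar years.
#' @param gender_balance probability a patient is coded male (gender 1).
#' @param diagnosis_rate mean diagnoses per patient-year.
#' @param exam_rate mean exam panels per patient-year (panels fall at roughly
#'   annual intervals with within-year jitter).
#' @param missingness probability any given metric is absent from a panel.
#' @param duplicate_measure_prob probability a recorded metric appears twice
#'   in one panel (second draw listed after the first).
#' @param background_codes named numeric vector: non-stroke ICD-10 codes
#'   (3–4 characters) with sampling weights.
#' @param risk_codes named numeric vector: subset of `background_codes`
#'   whose carriers have their annual stroke hazard multiplied by the given
#'   hazard ratio (all > 1).
#' @param signal_metrics named numeric vector: catalog metrics whose values
#'   drift in the pre-stroke years, magnitude in gender-specific SD units
#'   (sign gives direction).
#' @param baseline_annual_stroke_hazard per patient-year stroke probability
#'   before hazard-ratio multiplication.
#' @param observation_window `c(start, end)` dates (coercible to `Date`)
#'   bounding every generated record.
#' @param code5_prob probability a generated diagnosis is spelled with a 5th
#'   character (exercising downstream truncation); half of those are spelled
#'   with a dot before the 5th character.
#' @param drift_lead_years length of the pre-stroke window over which
#'   `signal_metrics` drift (drift is 0 at the window edge and reaches the
#'   configured magnitude at the event).
#' @param seed integer seed; the generator is bit-reproducible given the
#'   config.
#'
#' @return An object of class `generator_config` (a validated list).
#' @export
generator_config <- function(n_patients = 5000,
                             birth_year_range = c(1920, 1965),
                             gender_balance = 0.5,
                             diagnosis_rate = 1.2,
                             exam_rate = 1.0,
                             missingness = 0.15,
                             duplicate_measure_prob = 0.05,
                             background_codes = default_background_codes(),
                             risk_codes = c(I10 = 3.0, E11 = 2.5, I489 = 5.0),
                             signal_metrics = c("blood glucose" = 0.6,
                                                "HbA1c NGSP" = 0.6,
                                                "platelet count" = 0.5,
                                                "Hb" = -0.5,
                                                "LDL-C" = 0.4),
                             baseline_annual_stroke_hazard = 0.003,
                             observation_window = c("1996-01-01", "2015-12-31"),
                             code5_prob = 0.2,
                             drift_lead_years = 3,
                             seed = 1L) {
  cfg <- list(
    n_patients = n_patients, birth_year_range = birth_year_range,
    gender_balance = gender_balance, diagnosis_rate = diagnosis_rate,
    exam_rate = exam_rate, missingness = missingness,
    duplicate_measure_prob = duplicate_measure_prob,
    background_codes = background_codes, risk_codes = risk_codes,
    signal_metrics = signal_metrics,
    baseline_annual_stroke_hazard = baseline_annual_stroke_hazard,
    observation_window = as.Date(observation_window),
    code5_prob = code5_prob, drift_lead_years = drift_lead_years,
    seed = as.integer(seed)
  )
  validate_generator_config(cfg)
  class(cfg) <- "generator_config"
  cfg
}

#' @export
print.generator_config <- function(x, ...) {
  cat("synthetic EHR generator config:",
      x$n_patients, "patients,",
      format(x$observation_window[1]), "to", format(x$observation_window[2]),
      "\n  hazard:", x$baseline_annual_stroke_hazard, "/patient-year;",
      length(x$risk_codes), "risk codes;",
      length(x$signal_metrics), "drifting metrics\n")
  invisible(x)
}

validate_generator_config <- function(cfg) {
  bad <- function(field, why) {
    stop("invalid generator config: `", field, "` ", why, call. = FALSE)
  }
  chk_prob <- function(field) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1)
      bad(field, "must be a probability in [0, 1]")
  }
  if (!is.numeric(cfg$n_patients) || length(cfg$n_patients) != 1 ||
      is.na(cfg$n_patients) || cfg$n_patients < 0 ||
      cfg$n_patients != floor(cfg$n_patients))
    bad("n_patients", "must be a nonnegative integer")
  if (length(cfg$birth_year_range) != 2 ||
      cfg$birth_year_range[1] > cfg$birth_year_range[2])
    bad("birth_year_range", "must be an ordered year interval")
  for (f in c("gender_balance", "missingness", "duplicate_measure_prob",
              "baseline_annual_stroke_hazard", "code5_prob"))
    chk_prob(f)
  for (f in c("diagnosis_rate", "exam_rate", "drift_lead_years")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0)
      bad(f, "must be a nonnegative rate")
  }
  bc <- cfg$background_codes
  if (is.null(names(bc)) || any(names(bc) == "") || any(bc <= 0))
    bad("background_codes", "must be a named vector of positive weights")
  if (any(!grepl("^[A-Z][0-9]{2,3}$", names(bc))))
    bad("background_codes", "codes must be letter + 2-3 digits (pre-truncation base)")
  if (any(substr(names(bc), 1, 3) %in% paste0("I6", 0:9)))
    bad("background_codes", "must not contain stroke codes I60-I69")
  rc <- cfg$risk_codes
  if (length(rc)) {
    if (is.null(names(rc)) || !all(names(rc) %in% names(bc)))
      bad("risk_codes", "must be a named subset of background_codes")
    if (any(rc <= 1)) bad("risk_codes", "hazard ratios must exceed 1")
  }
  sm <- cfg$signal_metrics
  if (length(sm) && !all(names(sm) %in% metric_catalog()$metric))
    bad("signal_metrics", "must name metrics from the 20-metric catalog")
  if (length(cfg$observation_window) != 2 || anyNA(cfg$observation_window) ||
      cfg$observation_window[1] >= cfg$observation_window[2])
    bad("observation_window", "must be an ordered date interval")
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1 || is.na(cfg$seed))
    bad("seed", "must be a single integer")
  invisible(cfg)
}

#' Default background ICD-10 vocabulary
#'
#' A weighted vocabulary of common non-stroke diagnoses (hypertension,
#' type-2 diabetes, dyslipidaemia, back pain, upper respiratory infection,
#' ...). Weights are relative sampling frequencies, loosely ordered by
#' primary-care prevalence. None of the codes falls in the stroke range
#' I60-I69.
#'
#' @return Named numeric vector of sampling weights.
#' @export
default_background_codes <- function() {
  c(I10 = 8, E780 = 5, E11 = 5, J069 = 5, M545 = 4, E785 = 4, K297 = 3,
    J459 = 3, J209 = 3, H526 = 3, K590 = 2, N390 = 2, I489 = 1.5, F329 = 2,
    G439 = 2, M171 = 2, K210 = 2, J301 = 2, E039 = 1, D509 = 1, M069 = 1,
    N183 = 1, L209 = 1, B029 = 1, K635 = 1, E790 = 1, G473 = 1.5, H813 = 1,
    M479 = 1.5, J42 = 1)
}

# stroke codes appended at event time; I63x (cerebral infarction) dominates,
# matching infarction being the leading stroke subtype
stroke_event_codes <- function() {
  c(I639 = 5, I634 = 2, I619 = 2, I609 = 1, I64 = 1, I652 = 0.5, I694 = 0.5)
}

# stage-derived seed so each pipeline stage has independent, reproducible draws
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% .Machine$integer.max)
}

# spell a base code as a raw EHR string: optionally extend to 5 characters,
# dotted half the time ("E11.6" style), so truncation is always exercised
spell_raw_codes <- function(base, code5_prob) {
  n <- length(base)
  extend <- stats::runif(n) < code5_prob
  fifth <- as.character(sample.int(10, n, replace = TRUE) - 1L)
  dotted <- stats::runif(n) < 0.5
  out <- base
  # pad 3-char bases to 4 chars before extension so the 5th char is 5th
  pad <- extend & nchar(base) == 3
  out[pad] <- paste0(base[pad], "0")
  out[extend] <- paste0(out[extend], ifelse(dotted[extend], ".", ""), fifth[extend])
  out
}

#' Generate a synthetic patient population
#'
#' Simulates `config$n_patients` longitudinal records over the observation
#' window: diagnoses arrive as a Poisson stream over the background
#' vocabulary, and exam panels fall at roughly annual intervals, each panel
#' recording every catalog metric independently with probability
#' `1 - missingness` from its gender-specific reference Gaussian (and
#' duplicating it with probability `duplicate_measure_prob`). No stroke
#' events are generated here; see [inject_stroke_events()].
#'
#' @param config a [generator_config()].
#' @return An `ehr_population`: a list of three data.tables (`patients`,
#'   `diagnoses`, `exams`) mirroring the on-disk CSV layout, with the config
#'   attached.
#' @export
generate_population <- function(config) {
  validate_generator_config(config)
  set.seed(derive_seed(config$seed, "generate"))
  n <- config$n_patients
  win <- config$observation_window
  win_days <- as.numeric(win[2] - win[1])
  years <- win_days / 365.25

  patients <- data.table::data.table(
    patient_id = sprintf("P%06d", seq_len(max(n, 0L))),
    gender = stats::rbinom(n, 1L, config$gender_balance),
    birth_year = sample(seq(config$birth_year_range[1],
                            config$birth_year_range[2]), n, replace = TRUE)
  )
  if (n == 0) {
    empty_d <- data.table::data.table(patient_id = character(), date = as.Date(character()),
                                      icd10_code = character())
    empty_e <- data.table::data.table(patient_id = character(), date = as.Date(character()),
                                      metric = character(), value = numeric())
    pop <- list(patients = patients, diagnoses = empty_d, exams = empty_e)
    class(pop) <- "ehr_population"
    attr(pop, "config") <- config
    return(pop)
  }

  # each patient's record begins at a first-contact (entry) date; coverage
  # spans from entry to the window end, emulating EHR enrolment
  entry_offset <- floor(stats::runif(n, 0, 0.8 * win_days))
  entry_date <- win[1] + entry_offset
  span_days <- win_days - entry_offset
  span_years <- span_days / 365.25

  # diagnoses: one Poisson stream per patient over its covered span
  n_diag <- stats::rpois(n, config$diagnosis_rate * span_years)
  pid_d <- rep(patients$patient_id, n_diag)
  total_d <- sum(n_diag)
  d_dates <- rep(entry_date, n_diag) +
    floor(stats::runif(total_d) * (rep(span_days, n_diag) + 1))
  base <- sample(names(config$background_codes), total_d, replace = TRUE,
                 prob = config$background_codes)
  diagnoses <- data.table::data.table(
    patient_id = pid_d, date = d_dates,
    icd10_code = spell_raw_codes(base, config$code5_prob)
  )
  data.table::setkey(diagnoses, patient_id, date)

  # exam panels: Poisson(exam_rate) panels per patient-year, jittered within
  # the year
  yr0 <- as.integer(format(win[1], "%Y"))
  yr1 <- as.integer(format(win[2], "%Y"))
  yrs <- seq(yr0, yr1)
  n_panel <- stats::rpois(n * length(yrs), config$exam_rate)
  panel_pid <- rep(rep(patients$patient_id, each = length(yrs)), n_panel)
  panel_gender <- rep(rep(patients$gender, each = length(yrs)), n_panel)
  panel_year <- rep(rep(yrs, times = n), n_panel)
  np <- length(panel_pid)
  panel_date <- as.Date(paste0(panel_year, "-01-01")) +
    floor(stats::runif(np, 0, 365))
  panel_entry <- rep(rep(entry_date, each = length(yrs)), n_panel)
  keep <- panel_date >= win[1] & panel_date <= win[2] & panel_date >= panel_entry
  panel_pid <- panel_pid[keep]; panel_gender <- panel_gender[keep]
  panel_date <- panel_date[keep]; np <- sum(keep)

  cat20 <- metric_catalog()
  m <- nrow(cat20)
  # expand panels x metrics, then thin by missingness
  e_pid <- rep(panel_pid, each = m)
  e_gender <- rep(panel_gender, each = m)
  e_date <- rep(panel_date, each = m)
  e_metric <- rep(cat20$metric, times = np)
  present <- stats::runif(np * m) >= config$missingness
  e_pid <- e_pid[present]; e_gender <- e_gender[present]
  e_date <- e_date[present]; e_metric <- e_metric[present]
  mi <- match(e_metric, cat20$metric)
  mu <- ifelse(e_gender == 1, cat20$mean_m[mi], cat20$mean_f[mi])
  sd <- ifelse(e_gender == 1, cat20$sd_m[mi], cat20$sd_f[mi])
  e_value <- stats::rnorm(length(mu), mu, sd)
  # duplicated measurements: an independent re-draw listed after the first
  dup <- stats::runif(length(mu)) < config$duplicate_measure_prob
  exams <- data.table::data.table(
    patient_id = c(e_pid, e_pid[dup]),
    date = c(e_date, e_date[dup]),
    metric = c(e_metric, e_metric[dup]),
    value = c(e_value, stats::rnorm(sum(dup), mu[dup], sd[dup])),
    .listed = c(seq_along(e_pid), length(e_pid) + seq_len(sum(dup)))
  )
  data.table::setorder(exams, patient_id, date, .listed)
  exams[, ".listed" := NULL]

  pop <- list(patients = patients, diagnoses = diagnoses, exams = exams)
  class(pop) <- "ehr_population"
  attr(pop, "config") <- config
  pop
}

#' @export
print.ehr_population <- function(x, ...) {
  cat("ehr_population:", nrow(x$patients), "patients,",
      nrow(x$diagnoses), "diagnoses,", nrow(x$exams), "exam values\n")
  n_stroke <- length(stroke_patients(x))
  cat("  patients with a stroke code:", n_stroke, "\n")
  invisible(x)
}

# ids of patients carrying any I60-I69 code (on truncated codes)
stroke_patients <- function(pop) {
  codes <- truncate_code(pop$diagnoses$icd10_code)
  unique(pop$diagnoses$patient_id[substr(codes, 1, 3) %in% paste0("I6", 0:9)])
}

#' Plant stroke events and the pre-stroke exam drift
#'
#' Walks each patient through the observation window year by year. In a
#' given year the stroke probability is `baseline_annual_stroke_hazard`
#' multiplied by the hazard ratio of every risk code already present in the
#' patient's history at the start of that year (piecewise-constant annual
#' hazard). On the first stroke year, a stroke code (I60-I69 range) is
#' appended at a random date within the year, and every configured signal
#' metric measured within `drift_lead_years` before the event is shifted by
#' `drift * sd * (1 - years_to_event / drift_lead_years)` — a linear ramp
#' that gives temporal models something a last-value summary misses.
#' Records after the stroke are left in place; eligibility as a control is
#' decided downstream.
#'
#' @param population an `ehr_population` from [generate_population()].
#' @param config the same [generator_config()].
#' @return The population with stroke diagnoses appended and signal metrics
#'   drifted.
#' @export
inject_stroke_events <- function(population, config) {
  validate_generator_config(config)
  set.seed(derive_seed(config$seed, "inject"))
  pop <- population
  n <- nrow(pop$patients)
  if (n == 0 || config$baseline_annual_stroke_hazard == 0 && !length(config$risk_codes))
    return(pop)
  win <- config$observation_window
  yr0 <- as.integer(format(win[1], "%Y"))
  yr1 <- as.integer(format(win[2], "%Y"))
  yrs <- seq(yr0, yr1)
  ny <- length(yrs)

  # per-patient first-onset year of each risk code (on truncated codes)
  diag <- pop$diagnoses
  tc <- truncate_code(diag$icd10_code)
  log_hr <- matrix(0, n, ny)
  for (rc in names(config$risk_codes)) {
    hit <- tc == rc | substr(tc, 1, nchar(rc)) == rc
    if (!any(hit)) next
    onset <- diag[hit, list(onset = as.integer(format(min(date), "%Y"))),
                  by = "patient_id"]
    ri <- match(onset$patient_id, pop$patients$patient_id)
    # code counts toward hazard from the year after onset (prior history)
    carrier <- outer(onset$onset, yrs, `<`)
    log_hr[ri, ] <- log_hr[ri, ] + carrier * log(config$risk_codes[[rc]])
  }
  p_year <- pmin(1, config$baseline_annual_stroke_hazard * exp(log_hr))
  u <- matrix(stats::runif(n * ny), n, ny)
  hitmat <- u < p_year
  first_hit <- apply(hitmat, 1, function(r) if (any(r)) which(r)[1] else NA_integer_)
  struck <- which(!is.na(first_hit))
  if (!length(struck)) return(pop)

  stroke_year <- yrs[first_hit[struck]]
  ystart <- as.Date(paste0(stroke_year, "-01-01"))
  stroke_date <- pmin(ystart + floor(stats::runif(length(struck), 0, 365)), win[2])
  sc <- stroke_event_codes()
  stroke_code <- sample(names(sc), length(struck), replace = TRUE, prob = sc)

  new_rows <- data.table::data.table(
    patient_id = pop$patients$patient_id[struck],
    date = stroke_date, icd10_code = stroke_code
  )
  pop$diagnoses <- rbind(pop$diagnoses, new_rows)
  data.table::setkey(pop$diagnoses, patient_id, date)

  # pre-stroke drift of signal metrics
  if (length(config$signal_metrics)) {
    cat20 <- metric_catalog()
    ex <- data.table::copy(pop$exams)
    ev <- data.table::data.table(patient_id = new_rows$patient_id,
                                 stroke_date = new_rows$date)
    ex[, ".row" := .I]
    drifted <- merge(ex, ev, by = "patient_id")
    drifted <- drifted[drifted$metric %in% names(config$signal_metrics), ]
    tte <- as.numeric(drifted$stroke_date - drifted$date) / 365.25
    inwin <- tte >= 0 & tte < config$drift_lead_years
    drifted <- drifted[inwin, ]; tte <- tte[inwin]
    if (nrow(drifted)) {
      g <- pop$patients$gender[match(drifted$patient_id, pop$patients$patient_id)]
      mi <- match(drifted$metric, cat20$metric)
      sd <- ifelse(g == 1, cat20$sd_m[mi], cat20$sd_f[mi])
      mag <- config$signal_metrics[drifted$metric]
      shift <- mag * sd * (1 - tte / config$drift_lead_years)
      ex$value[drifted$.row] <- ex$value[drifted$.row] + shift
    }
    ex[, ".row" := NULL]
    pop$exams <- ex
  }
  pop
}

#' Write / read a population as the three-table CSV layout
#'
#' `patients.csv` (patient_id, gender, birth_year), `diagnoses.csv`
#' (patient_id, date, icd10_code) and `exams.csv` (patient_id, date, metric,
#' value); dates ISO-8601, header row mandatory.
#'
#' @param population an `ehr_population`.
#' @param dir directory to write into (created if needed).
#' @return `write_population` returns the directory invisibly;
#'   `read_population` returns an `ehr_population`.
#' @export
write_population <- function(population, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  data.table::fwrite(population$patients, file.path(dir, "patients.csv"))
  d <- data.table::copy(population$diagnoses)
  d[, "date" := format(d$date, "%Y-%m-%d")]
  data.table::fwrite(d, file.path(dir, "diagnoses.csv"))
  e <- data.table::copy(population$exams)
  e[, "date" := format(e$date, "%Y-%m-%d")]
  data.table::fwrite(e, file.path(dir, "exams.csv"))
  invisible(dir)
}

#' @rdname write_population
#' @export
read_population <- function(dir) {
  pats <- data.table::fread(file.path(dir, "patients.csv"),
                            colClasses = list(character = "patient_id"))
  diag <- data.table::fread(file.path(dir, "diagnoses.csv"),
                            colClasses = list(character = c("patient_id", "icd10_code")))
  ex <- data.table::fread(file.path(dir, "exams.csv"),
                          colClasses = list(character = c("patient_id", "metric")))
  diag[, "date" := as.Date(diag$date)]
  ex[, "date" := as.Date(ex$date)]
  pop <- list(patients = pats, diagnoses = diag, exams = ex)
  class(pop) <- "ehr_population"
  pop
}

#' Extract one patient's record
#'
#' @param population an `ehr_population`.
#' @param patient_id the id to extract.
#' @return A `patient_record`: list with `patient_id`, `gender`,
#'   `birth_year`, and date-ordered `diagnoses` / `exams` tables.
#' @export
as_patient_record <- function(population, patient_id) {
  i <- match(patient_id, population$patients$patient_id)
  if (is.na(i)) stop("unknown patient_id: ", patient_id)
  pid <- patient_id
  rec <- list(
    patient_id = patient_id,
    gender = population$patients$gender[i],
    birth_year = population$patients$birth_year[i],
    diagnoses = as.data.frame(population$diagnoses[population$diagnoses$patient_id == pid, ]),
    exams = as.data.frame(population$exams[population$exams$patient_id == pid, ])
  )
  class(rec) <- "patient_record"
  rec
}

#' Construct a patient record directly
#'
#' Convenience constructor for building small synthetic records in tests and
#' worked examples without running the full generator.
#'
#' @param patient_id id string.
#' @param gender 0 (female) or 1 (male).
#' @param birth_year calendar year.
#' @param diagnoses data.frame with `date`, `icd10_code` (may be empty).
#' @param exams data.frame with `date`, `metric`, `value` (may be empty).
#' @return A `patient_record`.
#' @export
patient_record <- function(patient_id, gender, birth_year,
                           diagnoses = NULL, exams = NULL) {
  if (is.null(diagnoses))
    diagnoses <- data.frame(date = as.Date(character()), icd10_code = character())
  if (is.null(exams))
    exams <- data.frame(date = as.Date(character()), metric = character(),
                        value = numeric())
  diagnoses$date <- as.Date(diagnoses$date)
  exams$date <- as.Date(exams$date)
  diagnoses <- diagnoses[order(diagnoses$date), , drop = FALSE]
  exams <- exams[order(exams$date), , drop = FALSE]
  rec <- list(patient_id = patient_id, gender = gender,
              birth_year = birth_year,
              diagnoses = diagnoses, exams = exams)
  class(rec) <- "patient_record"
  rec
}
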