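#' Is a (truncated) ICD-10 code a stroke code?
#'
#' Stroke diagnoses are identified by the code range I60-I69: a code is a
#' stroke code iff its first three characters are one of I60..I69.
#'
#' @param code character vector of codes already passed through
#'   [truncate_code()].
#' @return logical vector.
#' @export
#' @examples
#' is_stroke_code(c("I639", "I700", "I60"))
is_stroke_code <- function(code) {
  if (length(code) == 0) return(logical(0))
  if (any(is.na(code) | !nzchar(code)))
    stop("is_stroke_code: empty code")
  substr(code, 1, 3) %in% paste0("I6", 0:9)
}

# per-patient first stroke date, from the raw diagnosis table
first_stroke_dates <- function(pop) {
  d <- pop$diagnoses
  hit <- is_stroke_code(truncate_code(d$icd10_code))
  if (!any(hit)) {
    return(data.frame(patient_id = character(), index_date = as.Date(character())))
  }
  s <- d[hit, list(index_date = min(date)), by = "patient_id"]
  as.data.frame(s)
}

#' Select case patients
#'
#' A case is a patient whose first stroke diagnosis falls inside
#' `diagnosis_window`, whose age at that index date is within `age_range`
#' (inclusive), and who has at least one diagnosis and at least one exam
#' result dated at least one day before the index date. Age is index year
#' minus birth year (the record holds birth year only).
#'
#' @param population an `ehr_population`.
#' @param diagnosis_window `c(start, end)` dates for the first stroke
#'   diagnosis; default Jan 1 2001 to Jan 1 2015.
#' @param age_range inclusive `c(min, max)` age at index date.
#' @return data.frame with `patient_id`, `index_date`.
#' @export
select_cases <- function(population,
                         diagnosis_window = as.Date(c("2001-01-01", "2015-01-01")),
                         age_range = c(45, 95)) {
  diagnosis_window <- as.Date(diagnosis_window)
  fs <- first_stroke_dates(population)
  if (!nrow(fs)) return(fs)
  fs <- fs[fs$index_date >= diagnosis_window[1] &
             fs$index_date <= diagnosis_window[2], , drop = FALSE]
  if (!nrow(fs)) return(fs)
  by <- population$patients$birth_year[match(fs$patient_id,
                                             population$patients$patient_id)]
  age <- as.integer(format(fs$index_date, "%Y")) - by
  fs <- fs[age >= age_range[1] & age <= age_range[2], , drop = FALSE]
  if (!nrow(fs)) return(fs)

  # at least one diagnosis and one exam at least one day before index
  d <- population$diagnoses[population$diagnoses$patient_id %in% fs$patient_id, ]
  e <- population$exams[population$exams$patient_id %in% fs$patient_id, ]
  idx <- fs$index_date[match(d$patient_id, fs$patient_id)]
  has_d <- unique(d$patient_id[d$date <= idx - 1L])
  idx_e <- fs$index_date[match(e$patient_id, fs$patient_id)]
  has_e <- unique(e$patient_id[e$date <= idx_e - 1L])
  fs <- fs[fs$patient_id %in% has_d & fs$patient_id %in% has_e, , drop = FALSE]
  fs <- fs[order(fs$patient_id), , drop = FALSE]
  rownames(fs) <- NULL
  fs
}

#' Match two controls to every case
#'
#' Eligible controls for a case share its birth year and gender, have at
#' least one diagnosis and one exam result strictly before the case's index
#' date AND at least one of each strictly after it, and carry no stroke code
#' anywhere in their record. Each retained case receives exactly two
#' controls, drawn uniformly at random (seeded) from its eligible pool; a
#' control serves at most one case. Cases are processed greedily in
#' ascending index-date order (ties broken by patient id), and cases that
#' cannot be given two controls are reported in `excluded_cases`.
#'
#' @param cases data.frame from [select_cases()].
#' @param population the `ehr_population`.
#' @param seed integer seed for the control draws.
#' @return A `matched_cohort`: list with `cases` (data.frame `patient_id`,
#'   `index_date`, `control_1`, `control_2`) and `excluded_cases`
#'   (character vector).
#' @export
match_controls <- function(cases, population, seed = 1L) {
  set.seed(derive_seed(seed, "match"))
  pats <- population$patients
  stroke_ids <- stroke_patients(population)
  pool <- pats[!pats$patient_id %in% stroke_ids, ]

  # records strictly before/after a date, precomputed as per-patient ranges
  d_range <- population$diagnoses[, list(dmin = min(date), dmax = max(date)),
                                  by = "patient_id"]
  e_range <- population$exams[, list(emin = min(date), emax = max(date)),
                              by = "patient_id"]
  pool <- merge(merge(pool, d_range, by = "patient_id"),
                e_range, by = "patient_id")

  ord <- order(cases$index_date, cases$patient_id)
  cases <- cases[ord, , drop = FALSE]
  used <- character(0)
  out <- vector("list", nrow(cases))
  excluded <- character(0)
  for (k in seq_len(nrow(cases))) {
    ci <- cases[k, ]
    by <- pats$birth_year[match(ci$patient_id, pats$patient_id)]
    g <- pats$gender[match(ci$patient_id, pats$patient_id)]
    elig <- pool[pool$birth_year == by & pool$gender == g &
                   pool$dmin < ci$index_date & pool$dmax > ci$index_date &
                   pool$emin < ci$index_date & pool$emax > ci$index_date &
                   !pool$patient_id %in% used &
                   pool$patient_id != ci$patient_id, ]
    if (nrow(elig) < 2) {
      excluded <- c(excluded, ci$patient_id)
      next
    }
    ids <- sort(elig$patient_id)
    pick <- sample(ids, 2L)
    used <- c(used, pick)
    out[[k]] <- data.frame(patient_id = ci$patient_id,
                           index_date = ci$index_date,
                           control_1 = pick[1], control_2 = pick[2],
                           stringsAsFactors = FALSE)
  }
  kept <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(kept))
    kept <- data.frame(patient_id = character(), index_date = as.Date(character()),
                       control_1 = character(), control_2 = character())
  res <- list(cases = kept, excluded_cases = excluded)
  class(res) <- "matched_cohort"
  res
}

#' @export
print.matched_cohort <- function(x, ...) {
  cat("matched_cohort:", nrow(x$cases), "cases with 2 controls each;",
      length(x$excluded_cases), "cases excluded (fewer than 2 eligible controls)\n")
  invisible(x)
}

#' Grouped train/validation/test split
#'
#' Case patients are partitioned at the given percentage ratios
#' (largest-remainder rounding, seeded shuffle), and each case's two
#' controls inherit its split, so every split keeps the exact 1:2
#' case:control ratio.
#'
#' @param cohort a `matched_cohort`.
#' @param ratios percentages for train/validation/test; must sum to 100.
#' @param seed integer seed for the shuffle.
#' @return data.frame `patient_id`, `role` (`"case"`/`"control"`),
#'   `case_id`, `split` (`"train"`, `"validation"`, `"test"`).
#' @export
split_cohort <- function(cohort, ratios = c(70, 15, 15), seed = 1L) {
  if (length(ratios) != 3 || abs(sum(ratios) - 100) > 1e-9)
    stop("split ratios must be three percentages summing to 100")
  cs <- cohort$cases
  n <- nrow(cs)
  if (n == 0) stop("cannot split an empty cohort")
  set.seed(derive_seed(seed, "split"))
  # largest-remainder apportionment of the n cases
  quota <- n * ratios / 100
  base <- floor(quota)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(quota - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  lab <- rep(c("train", "validation", "test"), times = base)
  lab <- lab[sample.int(n)]
  case_rows <- data.frame(patient_id = cs$patient_id, role = "case",
                          case_id = cs$patient_id, split = lab,
                          stringsAsFactors = FALSE)
  ctl_rows <- data.frame(
    patient_id = c(cs$control_1, cs$control_2), role = "control",
    case_id = rep(cs$patient_id, 2), split = rep(lab, 2),
    stringsAsFactors = FALSE
  )
  out <- rbind(case_rows, ctl_rows)
  rownames(out) <- NULL
  out
}

#' Write / read the matched-cohort table
#'
#' One row per retained case: `case_id, control_id_1, control_id_2,
#' index_date, split`.
#'
#' @param cohort a `matched_cohort`.
#' @param split a split assignment from [split_cohort()].
#' @param path CSV path.
#' @export
write_cohort <- function(cohort, split, path) {
  cs <- cohort$cases
  sp <- split$split[match(cs$patient_id, split$patient_id)]
  out <- data.frame(case_id = cs$patient_id, control_id_1 = cs$control_1,
                    control_id_2 = cs$control_2,
                    index_date = format(cs$index_date, "%Y-%m-%d"),
                    split = sp, stringsAsFactors = FALSE)
  data.table::fwrite(out, path)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  x <- data.table::fread(path, colClasses = list(
    character = c("case_id", "control_id_1", "control_id_2", "split")))
  x[, "index_date" := as.Date(x$index_date)]
  as.data.frame(x)
}
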