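#' The 20-metric blood and biochemical exam catalog
#'
#' The pipeline works with a fixed panel of 10 blood-count metrics (ALP,
#' creatinine, Hb, hematocrit, MCH, MCHC, MCV, platelet count, RBC, WBC) and
#' 10 biochemical metrics (GGT, GOT, GPT, HbA1c JDS, HbA1c NGSP, HDL-C,
#' LDL-C, triglyceride, uric acid, blood glucose). The catalog fixes the
#' metric ordering (which defines the layout of every exam feature vector)
#' and carries gender-specific Gaussian reference distributions used by the
#' synthetic generator. Reference means/SDs are plausible adult laboratory
#' values; the pipeline itself only requires standardizable real values.
#'
#' @return A data.frame with one row per metric: `metric`, `panel`
#'   (`"blood"` or `"biochemical"`), `mean_f`, `sd_f`, `mean_m`, `sd_m`
#'   (gender-specific reference distribution; gender code 0 = female,
#'   1 = male), `unit`. Row order is the canonical vector layout.
#' @export
#' @examples
#' metric_catalog()$metric
metric_catalog <- function() {
  ref <- list(
    #                 panel          mean_f  sd_f  mean_m  sd_m  unit
    "ALP"            = c("blood",       220,   60,    240,   60, "U/L"),
    "creatinine"     = c("blood",       0.70, 0.15,  0.90, 0.20, "mg/dL"),
    "Hb"             = c("blood",       13.2,  1.1,  15.0,  1.2, "g/dL"),
    "hematocrit"     = c("blood",       40.0,  3.2,  45.0,  3.5, "%"),
    "MCH"            = c("blood",       29.5,  2.0,  30.0,  2.0, "pg"),
    "MCHC"           = c("blood",       33.5,  1.0,  33.5,  1.0, "g/dL"),
    "MCV"            = c("blood",       89.0,  5.0,  91.0,  5.0, "fL"),
    "platelet count" = c("blood",       25.0,  5.0,  24.0,  5.0, "1e4/uL"),
    "RBC"            = c("blood",       4.40, 0.35,  4.90, 0.40, "1e6/uL"),
    "WBC"            = c("blood",       6.00,  1.5,  6.40,  1.6, "1e3/uL"),
    "GGT"            = c("biochemical", 28.0, 15.0,  45.0, 25.0, "U/L"),
    "GOT"            = c("biochemical", 23.0,  8.0,  26.0,  9.0, "U/L"),
    "GPT"            = c("biochemical", 22.0, 10.0,  29.0, 13.0, "U/L"),
    "HbA1c JDS"      = c("biochemical", 5.40,  0.7,  5.40,  0.7, "%"),
    "HbA1c NGSP"     = c("biochemical", 5.80,  0.7,  5.80,  0.7, "%"),
    "HDL-C"          = c("biochemical", 62.0, 14.0,  52.0, 13.0, "mg/dL"),
    "LDL-C"          = c("biochemical",  122,   30,    122,   30, "mg/dL"),
    "triglyceride"   = c("biochemical",  105,   55,    135,   70, "mg/dL"),
    "uric acid"      = c("biochemical", 4.60,  1.0,  6.00,  1.2, "mg/dL"),
    "blood glucose"  = c("biochemical", 98.0, 18.0,   102,   20, "mg/dL")
  )
  data.frame(
    metric = names(ref),
    panel  = vapply(ref, `[`, "", 1L),
    mean_f = as.numeric(vapply(ref, `[`, "", 2L)),
    sd_f   = as.numeric(vapply(ref, `[`, "", 3L)),
    mean_m = as.numeric(vapply(ref, `[`, "", 4L)),
    sd_m   = as.numeric(vapply(ref, `[`, "", 5L)),
    unit   = vapply(ref, `[`, "", 6L),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Exam ablation groups
#'
#' The nine named exam groups used for group-wise ablation of the dual-input
#' model. Together the groups cover all 20 catalog metrics.
#'
#' @return Named list mapping group name to a character vector of metrics.
#' @export
exam_groups <- function() {
  list(
    "Cholesterol"    = c("HDL-C", "LDL-C", "triglyceride"),
    "Diabetes"       = c("HbA1c JDS", "HbA1c NGSP", "blood glucose"),
    "Kidney"         = "creatinine",
    "Liver"          = c("GGT", "GOT", "GPT"),
    "Platelet count" = "platelet count",
    "ALP"            = "ALP",
    "Blood count"    = c("Hb", "hematocrit", "MCH", "MCHC", "MCV", "RBC"),
    "Uric acid"      = "uric acid",
    "WBC"            = "WBC"
  )
}

# reference mean/sd for one metric under gender code g (0 = female, 1 = male)
metric_reference <- function(metric, gender, catalog = metric_catalog()) {
  i <- match(metric, catalog$metric)
  if (anyNA(i)) stop("unknown metric(s): ", paste(metric[is.na(i)], collapse = ", "))
  data.frame(
    metric = metric,
    mean = ifelse(gender == 1, catalog$mean_m[i], catalog$mean_f[i]),
    sd   = ifelse(gender == 1, catalog$sd_m[i], catalog$sd_f[i]),
    stringsAsFactors = FALSE
  )
}
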