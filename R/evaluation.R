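#' Area under the ROC curve
#'
#' Computed by the rank (probabilistic) formulation: the probability that a
#' randomly chosen positive instance is ranked above a randomly chosen
#' negative one, with tied scores receiving half credit. This equals the
#' trapezoidal area under the empirical ROC curve.
#'
#' @param scores numeric prediction scores (any monotone scale).
#' @param labels 0/1 true classes; both classes must be present.
#' @return AUC in [0, 1].
#' @export
auc_score <- function(scores, labels) {
  labels <- as.integer(labels)
  npos <- sum(labels == 1L); nneg <- sum(labels == 0L)
  if (npos == 0 || nneg == 0)
    stop("auc_score: need at least one positive and one negative label")
  r <- rank(scores)   # average ranks give tied pairs half credit
  (sum(r[labels == 1L]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' ROC curve and AUC
#'
#' Sensitivity (true-positive rate) against specificity (true-negative
#' rate) at every distinct score threshold, plus the rank-formula AUC.
#'
#' @inheritParams auc_score
#' @return A `roc_result`: list with `points` (data.frame `threshold`,
#'   `sensitivity`, `specificity`), `auc`, and `ci` (`NULL` until
#'   [bootstrap_auc_ci()] fills it).
#' @export
roc_and_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  npos <- sum(labels == 1L); nneg <- sum(labels == 0L)
  if (npos == 0 || nneg == 0)
    stop("roc_and_auc: need at least one positive and one negative label")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(y == 1L); fp <- cumsum(y == 0L)
  last <- !duplicated(grp, fromLast = TRUE)   # one point per distinct score
  pts <- data.frame(
    threshold = c(Inf, s[last]),
    sensitivity = c(0, tp[last] / npos),
    specificity = c(1, 1 - fp[last] / nneg)
  )
  out <- list(points = pts, auc = auc_score(scores, labels), ci = NULL)
  class(out) <- "roc_result"
  out
}

#' @export
print.roc_result <- function(x, ...) {
  cat("ROC: AUC", signif(x$auc, 4))
  if (!is.null(x$ci))
    cat(" (95% CI ", signif(x$ci[1], 4), "-", signif(x$ci[2], 4), ")", sep = "")
  cat(";", nrow(x$points), "curve points\n")
  invisible(x)
}

#' Stratified bootstrap confidence interval for the AUC
#'
#' Positives and negatives are resampled separately with replacement (so
#' every replicate keeps the original class counts), the AUC is recomputed
#' per replicate, and the percentile interval is returned.
#'
#' @inheritParams auc_score
#' @param replicates bootstrap replicates.
#' @param level confidence level.
#' @param seed integer seed.
#' @return `c(lower, upper)`.
#' @export
bootstrap_auc_ci <- function(scores, labels, replicates = 2000L,
                             level = 0.95, seed = 1L) {
  labels <- as.integer(labels)
  pos <- which(labels == 1L); neg <- which(labels == 0L)
  if (!length(pos) || !length(neg))
    stop("bootstrap_auc_ci: need both classes")
  set.seed(derive_seed(seed, "bootstrap"))
  stat <- numeric(replicates)
  for (b in seq_len(replicates)) {
    i <- c(sample(pos, length(pos), replace = TRUE),
           sample(neg, length(neg), replace = TRUE))
    stopifnot(sum(labels[i] == 1L) == length(pos),
              sum(labels[i] == 0L) == length(neg))
    stat[b] <- auc_score(scores[i], labels[i])
  }
  a <- (1 - level) / 2
  unname(stats::quantile(stat, c(a, 1 - a)))
}

#' F1 score of the positive class at the argmax threshold
#'
#' For two-class softmax scores the argmax decision is score > 0.5 (ties
#' to negative). If there is no predicted and no true positive the score
#' is defined as 0 (with a message rather than an error).
#'
#' @inheritParams auc_score
#' @param threshold decision threshold on the positive-class score.
#' @return F1 in [0, 1].
#' @export
f1_score <- function(scores, labels, threshold = 0.5) {
  labels <- as.integer(labels)
  pred <- scores > threshold
  tp <- sum(pred & labels == 1L)
  fp <- sum(pred & labels == 0L)
  fn <- sum(!pred & labels == 1L)
  if (tp + fp + fn == 0) {
    message("f1_score: no predicted or true positives; returning 0")
    return(0)
  }
  2 * tp / (2 * tp + fp + fn)
}

# exam-metric columns sit after (gender, age, 6 gap bits) in each row
EXAM_META_COLS <- 8L

#' Zero out an exam metric group in a set of instances
#'
#' Sets the standardized values of the group's metrics to 0 in every row of
#' every instance (0 is the training mean after standardization), leaving
#' all other entries untouched. `"with everything"` is the identity. The
#' operation is idempotent.
#'
#' @param instances an `instance_set` of exam sequences or a
#'   `dual_instance_set`.
#' @param group a group name from [exam_groups()], or `"with everything"`.
#' @return the modified instances.
#' @export
ablate_group <- function(instances, group) {
  if (identical(group, "with everything")) return(instances)
  groups <- exam_groups()
  if (!group %in% names(groups))
    stop("ablate_group: unknown group: ", group)
  cols <- EXAM_META_COLS + match(groups[[group]], metric_catalog()$metric)
  if (inherits(instances, "dual_instance_set")) {
    instances$x_e[, , cols] <- 0
  } else {
    instances$x[, , cols] <- 0
  }
  instances
}

#' Exam-importance ablation table
#'
#' One row for the unablated baseline plus one per metric group: the AUC of
#' the dual-input model on the pooled evaluation instances when that
#' group's standardized values are zeroed, with a stratified bootstrap CI.
#'
#' @param model3 a trained `dual_input` predictor.
#' @param instances the pooled validation+test `dual_instance_set`.
#' @param replicates bootstrap replicates per row.
#' @param seed integer seed.
#' @return data.frame `model_inputs`, `auc`, `ci_lower`, `ci_upper`.
#' @export
ablation_table <- function(model3, instances, replicates = 2000L, seed = 1L) {
  rows <- c("with everything", names(exam_groups()))
  out <- vector("list", length(rows))
  for (k in seq_along(rows)) {
    inst <- ablate_group(instances, rows[k])
    sc <- predict_scores(model3, inst)
    auc <- auc_score(sc, inst$y)
    ci <- bootstrap_auc_ci(sc, inst$y, replicates, seed = seed)
    label <- if (rows[k] == "with everything") rows[k] else paste("w/o", rows[k])
    out[[k]] <- data.frame(model_inputs = label, auc = auc,
                           ci_lower = ci[1], ci_upper = ci[2])
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Loss-function ablation report
#'
#' The experimental grid comparing the imbalance loss against standard
#' cross-entropy: two cells each for the single-input models (loss custom
#' vs CE) and four for the dual model (training loss x which source models
#' the transferred weights came from), evaluated on validation and test
#' with AUC and bootstrap CI. Missing artifacts yield `NA` rows rather than
#' errors.
#'
#' @param models named list of trained predictors; recognized names are
#'   `model1_custom`, `model1_ce`, `model2_custom`, `model2_ce`,
#'   `model3_custom_from_custom`, `model3_custom_from_ce`,
#'   `model3_ce_from_custom`, `model3_ce_from_ce`.
#' @param splits featurized cohort (as from [featurize_cohort()]); the
#'   `validation` and `test` elements are used.
#' @param replicates bootstrap replicates.
#' @param seed integer seed.
#' @return data.frame `configuration`, `split`, `auc`, `ci_lower`,
#'   `ci_upper`.
#' @export
loss_ablation <- function(models, splits, replicates = 500L, seed = 1L) {
  cells <- c("model1_custom", "model1_ce", "model2_custom", "model2_ce",
             "model3_custom_from_custom", "model3_custom_from_ce",
             "model3_ce_from_custom", "model3_ce_from_ce")
  input_for <- function(cell, sp) {
    if (startsWith(cell, "model1")) splits[[sp]]$diagnosis
    else if (startsWith(cell, "model2")) splits[[sp]]$exam
    else splits[[sp]]$dual
  }
  out <- list()
  for (cell in cells) {
    for (sp in c("validation", "test")) {
      m <- models[[cell]]
      if (is.null(m)) {
        out[[length(out) + 1]] <- data.frame(
          configuration = cell, split = sp, auc = NA_real_,
          ci_lower = NA_real_, ci_upper = NA_real_)
        next
      }
      inst <- input_for(cell, sp)
      sc <- predict_scores(m, inst)
      auc <- auc_score(sc, inst$y)
      ci <- bootstrap_auc_ci(sc, inst$y, replicates, seed = seed)
      out[[length(out) + 1]] <- data.frame(
        configuration = cell, split = sp, auc = auc,
        ci_lower = ci[1], ci_upper = ci[2])
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write ROC curve points to CSV
#'
#' @param roc a `roc_result`.
#' @param path CSV path (`threshold`, `sensitivity`, `specificity`).
#' @export
write_roc <- function(roc, path) {
  data.table::fwrite(roc$points, path)
  invisible(path)
}
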