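#' Loss configuration for the imbalance-penalizing objective
#'
#' The training objective is standard categorical cross-entropy weighted by
#' `alpha`, plus `beta` times a surrogate false-positive count and `gamma`
#' times a surrogate false-negative count, where each surrogate is the sum
#' of per-example log losses over the corresponding label stratum. The
#' defaults are the hyperparameters used throughout the pipeline
#' (alpha = 0.2, beta = 5, gamma = 5); asymmetric settings (gamma > beta)
#' penalize missed positives harder, the natural direction for a screening
#' task with rare positives.
#'
#' @param alpha weight of the plain cross-entropy term.
#' @param beta weight of the false-positive surrogate.
#' @param gamma weight of the false-negative surrogate.
#' @return A `loss_config` list.
#' @export
loss_config <- function(alpha = 0.2, beta = 5, gamma = 5) {
  v <- c(alpha = alpha, beta = beta, gamma = gamma)
  if (any(!is.finite(v)) || any(v < 0))
    stop("loss_config: alpha, beta, gamma must be nonnegative")
  if (all(v == 0)) stop("loss_config: at least one weight must be positive")
  out <- list(alpha = alpha, beta = beta, gamma = gamma)
  class(out) <- "loss_config"
  out
}

# a standard-CE config expressed in the same machinery (alpha 1, no
# surrogate terms)
standard_ce_config <- function() loss_config(alpha = 1, beta = 0, gamma = 0)

#' A batch of two-class predictions with labels
#'
#' @param probs n x 2 matrix of predicted class probabilities, columns
#'   (negative, positive); rows on the simplex.
#' @param labels 0/1 vector of true classes.
#' @return A `prediction_batch` list.
#' @export
prediction_batch <- function(probs, labels) {
  probs <- as.matrix(probs)
  if (ncol(probs) != 2) stop("prediction_batch: probs must have 2 columns")
  if (nrow(probs) != length(labels))
    stop("prediction_batch: probs rows and labels length differ")
  if (any(!labels %in% c(0, 1))) stop("prediction_batch: labels must be 0/1")
  if (nrow(probs) && any(abs(rowSums(probs) - 1) > 1e-6))
    stop("prediction_batch: probability rows must sum to 1")
  out <- list(probs = probs, labels = as.integer(labels))
  class(out) <- "prediction_batch"
  out
}

#' False-positive and false-negative counts at the argmax threshold
#'
#' The zero-one versions of the two counts the surrogates bound: fp is the
#' number of negatives predicted positive, fn the number of positives
#' predicted negative. Argmax ties go to the negative class (conservative
#' for screening).
#'
#' @param batch a `prediction_batch`.
#' @return named integer vector `c(fp = ..., fn = ...)`.
#' @export
zero_one_counts <- function(batch) {
  if (!nrow(batch$probs)) return(c(fp = 0L, fn = 0L))
  pred_pos <- batch$probs[, 2] > batch$probs[, 1]   # tie -> negative
  c(fp = sum(pred_pos & batch$labels == 0L),
    fn = sum(!pred_pos & batch$labels == 1L))
}

# per-example log loss -log f(true class), clipped away from zero
log_losses <- function(batch, clip = 1e-7) {
  p_true <- ifelse(batch$labels == 1L, batch$probs[, 2], batch$probs[, 1])
  if (any(p_true <= 0) && clip <= 0)
    stop("log loss undefined at probability 0; set a positive clip")
  -log(pmax(p_true, clip))
}

#' Surrogate false-positive / false-negative counts
#'
#' The differentiable upper bounds on the zero-one counts: the sum of
#' per-example log losses over the negatives (`surrogate_fp`) or the
#' positives (`surrogate_fn`). The bound `surrogate >= count` holds
#' whenever each misclassified example's true-class probability is at most
#' 1/e, since then its log loss is at least 1.
#'
#' @param batch a `prediction_batch`.
#' @param clip lower clip for probabilities before the log.
#' @return scalar.
#' @export
surrogate_fp <- function(batch, clip = 1e-7) {
  ll <- log_losses(batch, clip)
  sum(ll[batch$labels == 0L])
}

#' @rdname surrogate_fp
#' @export
surrogate_fn <- function(batch, clip = 1e-7) {
  ll <- log_losses(batch, clip)
  sum(ll[batch$labels == 1L])
}

#' The imbalance-penalizing training objective
#'
#' `alpha * sum(all log losses) + beta * surrogate_fp + gamma *
#' surrogate_fn`, summed (not averaged) over the batch. Algebraically this
#' equals a per-example-weighted cross-entropy with weight `alpha + beta`
#' on negatives and `alpha + gamma` on positives — that identity is what
#' the training loop exploits and what the tests verify independently.
#'
#' @param batch a `prediction_batch`.
#' @param config a `loss_config`.
#' @param clip lower clip for probabilities before the log.
#' @return scalar loss.
#' @export
custom_loss <- function(batch, config = loss_config(), clip = 1e-7) {
  ll <- log_losses(batch, clip)
  config$alpha * sum(ll) +
    config$beta * sum(ll[batch$labels == 0L]) +
    config$gamma * sum(ll[batch$labels == 1L])
}

#' Gradient of the objective with respect to predicted probabilities
#'
#' @param batch a `prediction_batch`.
#' @param config a `loss_config`.
#' @param clip lower clip; examples at the clip have zero gradient, matching
#'   the clipped loss.
#' @return n x 2 matrix of partial derivatives.
#' @export
custom_loss_grad <- function(batch, config = loss_config(), clip = 1e-7) {
  n <- nrow(batch$probs)
  g <- matrix(0, n, 2)
  w <- ifelse(batch$labels == 1L, config$alpha + config$gamma,
              config$alpha + config$beta)
  true_col <- batch$labels + 1L
  p_true <- batch$probs[cbind(seq_len(n), true_col)]
  active <- p_true > clip
  g[cbind(seq_len(n), true_col)] <- ifelse(active, -w / p_true, 0)
  g
}

# per-example weights implementing the weighted-CE identity; consumed by
# the neural training loop
loss_weights <- function(labels, config) {
  ifelse(labels == 1L, config$alpha + config$gamma,
         config$alpha + config$beta)
}
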