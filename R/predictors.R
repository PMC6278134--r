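#' Specification of a neural predictor
#'
#' Three topologies share one contract (a 2-class softmax head over a
#' padded, masked sequence input):
#' * `diagnosis_rnn` — masked GRU over the 35 x 40 diagnosis sequence, final
#'   hidden state into the head;
#' * `exam_dense` — a shared per-timestep dense transform over the 20 x 28
#'   exam sequence, flattened, then a two-layer dense stack into the head;
#' * `dual_input` — both branches up to their penultimate representations,
#'   concatenated, one fusion layer, then the head.
#'
#' Hidden sizes are configurable; the defaults are modest capacities
#' suitable for CPU training.
#'
#' @param kind one of `"diagnosis_rnn"`, `"exam_dense"`, `"dual_input"`.
#' @param recurrent_width GRU hidden width.
#' @param td_width width of the shared per-timestep dense transform.
#' @param dense_widths widths of the two dense layers after flattening.
#' @param fusion_width width of the dual model's post-concatenation layer.
#' @param diag_dim,diag_len diagnosis row length and sequence cap.
#' @param exam_dim,exam_len exam row length and sequence cap (`exam_dim` is
#'   48 under the indicator imputation strategy).
#' @return A `model_spec` list.
#' @export
model_spec <- function(kind = c("diagnosis_rnn", "exam_dense", "dual_input"),
                       recurrent_width = 64L, td_width = 32L,
                       dense_widths = c(64L, 32L), fusion_width = 32L,
                       diag_dim = 40L, diag_len = 35L,
                       exam_dim = 28L, exam_len = 20L) {
  kind <- match.arg(kind)
  stopifnot(recurrent_width > 0, td_width > 0, all(dense_widths > 0),
            length(dense_widths) == 2, fusion_width > 0)
  out <- list(kind = kind, recurrent_width = as.integer(recurrent_width),
              td_width = as.integer(td_width),
              dense_widths = as.integer(dense_widths),
              fusion_width = as.integer(fusion_width),
              diag_dim = as.integer(diag_dim), diag_len = as.integer(diag_len),
              exam_dim = as.integer(exam_dim), exam_len = as.integer(exam_len))
  class(out) <- "model_spec"
  out
}

glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}

gru_param_names <- function() c("Wz", "Wr", "Wh", "Uz", "Ur", "Uh",
                                "bz", "br", "bh")
mlp_param_names <- function() c("Wt", "bt", "W1", "b1", "W2", "b2")

init_gru_params <- function(D, H) {
  list(Wz = glorot(D, H), Wr = glorot(D, H), Wh = glorot(D, H),
       Uz = glorot(H, H), Ur = glorot(H, H), Uh = glorot(H, H),
       bz = numeric(H), br = numeric(H), bh = numeric(H))
}

init_mlp_params <- function(D, T_, K, d1, d2) {
  list(Wt = glorot(D, K), bt = numeric(K),
       W1 = glorot(T_ * K, d1), b1 = numeric(d1),
       W2 = glorot(d1, d2), b2 = numeric(d2))
}

#' Build (initialize) a predictor
#'
#' Glorot-uniform kernels, zero biases, seeded.
#'
#' @param spec a [model_spec()].
#' @param seed integer seed for the initialization.
#' @return A `stroke_predictor` with untrained parameters.
#' @export
build_model <- function(spec, seed = 1L) {
  set.seed(derive_seed(seed, paste0("init_", spec$kind)))
  H <- spec$recurrent_width; K <- spec$td_width
  d1 <- spec$dense_widths[1]; d2 <- spec$dense_widths[2]
  params <- switch(spec$kind,
    diagnosis_rnn = c(init_gru_params(spec$diag_dim, H),
                      list(Wo = glorot(H, 2), bo = numeric(2))),
    exam_dense = c(init_mlp_params(spec$exam_dim, spec$exam_len, K, d1, d2),
                   list(Wo = glorot(d2, 2), bo = numeric(2))),
    dual_input = c(init_gru_params(spec$diag_dim, H),
                   init_mlp_params(spec$exam_dim, spec$exam_len, K, d1, d2),
                   list(Wf = glorot(H + d2, spec$fusion_width),
                        bf = numeric(spec$fusion_width),
                        Wo = glorot(spec$fusion_width, 2), bo = numeric(2)))
  )
  out <- list(spec = spec, params = params, trained = FALSE, history = NULL)
  class(out) <- "stroke_predictor"
  out
}

#' @export
print.stroke_predictor <- function(x, ...) {
  np <- sum(vapply(x$params, length, 1L))
  cat("stroke_predictor (", x$spec$kind, "): ", np, " parameters, ",
      if (x$trained) paste0("trained (best epoch ", x$best_epoch,
                            ", validation F1 ", signif(x$best_f1, 4), ")")
      else "untrained", "\n", sep = "")
  invisible(x)
}

#' Transfer branch weights into a dual-input model
#'
#' Every dual-branch parameter whose name and shape match the corresponding
#' source model parameter is copied bit-identically: the GRU parameters
#' from the diagnosis model, the dense-branch parameters from the exam
#' model. Fusion and head layers keep their fresh initialization. By
#' default transferred weights are fine-tuned by subsequent training;
#' freezing is available through the training config.
#'
#' @param dual an untrained `dual_input` predictor.
#' @param model1 a `diagnosis_rnn` predictor (or `NULL`).
#' @param model2 an `exam_dense` predictor (or `NULL`).
#' @return the dual predictor; the character vector of transferred
#'   parameter names is attached as attribute `"transferred"`.
#' @export
transfer_weights <- function(dual, model1 = NULL, model2 = NULL) {
  stopifnot(dual$spec$kind == "dual_input")
  moved <- character(0)
  copy_from <- function(src, names) {
    for (nm in names) {
      if (is.null(src$params[[nm]])) next
      if (identical(dim2(src$params[[nm]]), dim2(dual$params[[nm]]))) {
        dual$params[[nm]] <<- src$params[[nm]]
        moved <<- c(moved, nm)
      }
    }
  }
  if (!is.null(model1)) copy_from(model1, gru_param_names())
  if (!is.null(model2)) copy_from(model2, mlp_param_names())
  if (!length(moved))
    warning("transfer_weights: no layer shapes matched; nothing transferred")
  attr(dual, "transferred") <- moved
  dual
}

dim2 <- function(x) if (is.matrix(x)) dim(x) else length(x)

#' Training configuration
#'
#' Mini-batch Adam with framework-default parameters (step 0.001, beta1
#' 0.9, beta2 0.999), batch size 32, a fixed seed, and the imbalance loss
#' by default. The single- input models train for 500 epochs and the dual
#' model for 100 in the full protocol; pass smaller values for desk-scale
#' runs.
#'
#' @param epochs training epochs.
#' @param batch_size mini-batch size.
#' @param lr Adam step size.
#' @param seed seed for shuffling (and any fresh initialization).
#' @param loss a [loss_config()], or the string `"ce"` for plain
#'   cross-entropy.
#' @param freeze parameter names excluded from updates (e.g. transferred
#'   branches).
#' @param verbose print a line every 25 epochs.
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = 500L, batch_size = 32L, lr = 1e-3,
                         seed = 1L, loss = loss_config(),
                         freeze = character(0), verbose = FALSE) {
  if (identical(loss, "ce")) loss <- standard_ce_config()
  stopifnot(inherits(loss, "loss_config"), epochs > 0, batch_size > 0)
  out <- list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
              lr = lr, seed = as.integer(seed), loss = loss,
              freeze = freeze, verbose = isTRUE(verbose))
  class(out) <- "train_config"
  out
}

# permute an n x T x D instance array to the (n, D, T) cube layout the C++
# core expects
nn_cube <- function(x) aperm(x, c(1, 3, 2))

# dispatch one forward/backward call for any model kind
nn_call <- function(kind, params, data, idx, y, w, grad = FALSE,
                    hidden = FALSE) {
  if (kind == "diagnosis_rnn") {
    nn_m1(data$xd[idx, , , drop = FALSE], data$maskd[idx, , drop = FALSE],
          params, y, w, grad, hidden)
  } else if (kind == "exam_dense") {
    nn_m2(data$xe[idx, , , drop = FALSE], params, y, w, grad, hidden)
  } else {
    nn_m3(data$xd[idx, , , drop = FALSE], data$maskd[idx, , drop = FALSE],
          data$xe[idx, , , drop = FALSE], params, y, w, grad, hidden)
  }
}

# normalize any instance container to the cube bundle nn_call consumes
nn_data <- function(set, kind) {
  if (inherits(set, "dual_instance_set")) {
    list(xd = nn_cube(set$x_d), maskd = set$mask_d, xe = nn_cube(set$x_e),
         y = set$y)
  } else if (kind == "diagnosis_rnn") {
    list(xd = nn_cube(set$x), maskd = set$mask, y = set$y)
  } else {
    list(xe = nn_cube(set$x), y = set$y)
  }
}

#' Train a predictor
#'
#' Mini-batch Adam on the configured loss (summed per batch, matching the
#' objective's sum form). After every epoch the validation F1 at the
#' argmax threshold is recorded, and the returned model carries the
#' parameters of the epoch that maximized it (checkpoint selection). A
#' non-finite training loss aborts with diagnostics.
#'
#' @param model a `stroke_predictor` from [build_model()] (optionally after
#'   [transfer_weights()]).
#' @param train,validation instance sets matching the model kind
#'   (`instance_set` or `dual_instance_set`).
#' @param config a [train_config()].
#' @return the trained predictor, with `history` (epoch, train_loss,
#'   val_f1), `best_epoch`, `best_f1`.
#' @export
train_model <- function(model, train, validation, config = train_config()) {
  kind <- model$spec$kind
  tr <- nn_data(train, kind)
  va <- nn_data(validation, kind)
  n <- length(tr$y)
  if (!n || !length(va$y)) stop("train_model: empty training or validation set")
  w_tr <- loss_weights(tr$y, config$loss)
  set.seed(derive_seed(config$seed, paste0("train_", kind)))

  params <- model$params
  frozen <- intersect(config$freeze, names(params))
  mA <- lapply(params, function(p) p * 0)
  vA <- lapply(params, function(p) p * 0)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; step <- 0L
  best_f1 <- -Inf; best_params <- params; best_epoch <- 0L
  hist_loss <- numeric(config$epochs); hist_f1 <- numeric(config$epochs)

  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n)
    total_loss <- 0
    for (b in seq_len(ceiling(n / config$batch_size))) {
      idx <- ord[((b - 1) * config$batch_size + 1):min(b * config$batch_size, n)]
      res <- nn_call(kind, params, tr, idx, tr$y[idx], w_tr[idx], grad = TRUE)
      if (!is.finite(res$loss))
        stop("train_model: non-finite loss at epoch ", ep, ", batch ", b,
             " (kind ", kind, ", lr ", config$lr, ")")
      total_loss <- total_loss + res$loss
      step <- step + 1L
      g <- res$grads
      for (k in names(params)) {
        if (k %in% frozen) next
        gk <- g[[k]]
        if (!is.matrix(params[[k]])) gk <- as.numeric(gk)
        mA[[k]] <- b1 * mA[[k]] + (1 - b1) * gk
        vA[[k]] <- b2 * vA[[k]] + (1 - b2) * gk^2
        params[[k]] <- params[[k]] -
          config$lr * (mA[[k]] / (1 - b1^step)) /
            (sqrt(vA[[k]] / (1 - b2^step)) + eps)
      }
    }
    val <- nn_call(kind, params, va, seq_along(va$y), va$y,
                   rep(1, length(va$y)))
    f1 <- f1_score(val$probs[, 2], va$y)
    hist_loss[ep] <- total_loss; hist_f1[ep] <- f1
    if (f1 >= best_f1) {   # ties keep the later (more trained) checkpoint
      best_f1 <- f1; best_params <- params; best_epoch <- ep
    }
    if (config$verbose && ep %% 25 == 0)
      message("epoch ", ep, ": train loss ", signif(total_loss, 5),
              ", val F1 ", signif(f1, 4))
  }
  model$params <- best_params
  model$trained <- TRUE
  model$best_epoch <- best_epoch
  model$best_f1 <- best_f1
  model$history <- data.frame(epoch = seq_len(config$epochs),
                              train_loss = hist_loss, val_f1 = hist_f1)
  model
}

#' Positive-class scores for an instance set
#'
#' @param model a `stroke_predictor`.
#' @param instances `instance_set` or `dual_instance_set` matching the
#'   model kind.
#' @return numeric vector of positive-class probabilities in [0, 1].
#' @export
predict_scores <- function(model, instances) {
  d <- nn_data(instances, model$spec$kind)
  res <- nn_call(model$spec$kind, model$params, d, seq_along(d$y), d$y,
                 rep(1, length(d$y)))
  as.numeric(res$probs[, 2])
}

# branch representations (used to audit weight transfer)
branch_activations <- function(model, instances) {
  d <- nn_data(instances, model$spec$kind)
  res <- nn_call(model$spec$kind, model$params, d, seq_along(d$y), d$y,
                 rep(1, length(d$y)), hidden = TRUE)
  if (model$spec$kind == "dual_input")
    list(diagnosis = res$hidden_d, exam = res$hidden_e)
  else res$hidden
}
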