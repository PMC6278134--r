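#' Build a code vocabulary
#'
#' The closed set of truncated 4-character codes the embedder supports,
#' ordered lexicographically. Downstream encoding of a code outside the
#' vocabulary is an error: the vocabulary is fixed at training time.
#'
#' @param codes character vector of raw or truncated codes.
#' @return A `code_vocabulary`: character vector of unique truncated codes
#'   (sorted), with a `code->index` environment attached.
#' @export
code_vocabulary <- function(codes) {
  v <- sort(unique(truncate_code(codes)))
  if (length(v) < 2) stop("code_vocabulary: need at least 2 distinct codes")
  attr(v, "index") <- stats::setNames(seq_along(v), v)
  class(v) <- "code_vocabulary"
  v
}

code_index <- function(codes, vocab) {
  i <- attr(vocab, "index")[codes]
  if (anyNA(i))
    stop("unknown ICD-10 code(s) for this vocabulary: ",
         paste(unique(codes[is.na(i)]), collapse = ", "))
  unname(i)
}

#' One-hot encode a code against a vocabulary
#'
#' @param code single code (already truncated or truncatable).
#' @param vocab a `code_vocabulary`.
#' @return length-N 0/1 vector with a single 1 at the code's index.
#' @export
encode_one_hot <- function(code, vocab) {
  i <- code_index(truncate_code(code), vocab)
  out <- numeric(length(vocab))
  out[i] <- 1
  out
}

#' Train the single-hidden-layer code autoencoder
#'
#' The N one-hot code vectors are both input and target. The encoder is
#' `d = tanh(x W_in + b_in)` with a 32-dimensional bottleneck by default;
#' the decoder is `softmax(d W_out + b_out)`, trained under categorical
#' cross-entropy with full-batch Adam (the code set is tiny, so every step
#' sees all N codes). Training stops at perfect argmax reconstruction —
#' every code decodes back to itself — or at `max_epochs`, whichever comes
#' first; non-convergence is a warning, not an error.
#'
#' @param vocab a `code_vocabulary`.
#' @param dim embedding dimension.
#' @param seed integer seed for the weight initialization.
#' @param max_epochs full-batch Adam steps.
#' @param lr Adam step size.
#' @return An `icd_autoencoder`: list with `W_in` (N x dim), `b_in`,
#'   `W_out` (dim x N), `b_out`, the `vocab`, the achieved
#'   `reconstruction_accuracy`, and `epochs_run`.
#' @export
train_autoencoder <- function(vocab, dim = 32L, seed = 1L,
                              max_epochs = 3000L, lr = 0.01) {
  n <- length(vocab)
  if (n < 2) stop("train_autoencoder: need at least 2 codes")
  set.seed(derive_seed(seed, "autoencoder"))
  lim_in <- sqrt(6 / (n + dim))
  params <- list(
    W_in = matrix(stats::runif(n * dim, -lim_in, lim_in), n, dim),
    b_in = numeric(dim),
    W_out = matrix(stats::runif(dim * n, -lim_in, lim_in), dim, n),
    b_out = numeric(n)
  )
  m <- lapply(params, function(p) p * 0)
  v <- lapply(params, function(p) p * 0)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  acc <- 0; ep <- 0
  for (ep in seq_len(max_epochs)) {
    # forward: one-hot input selects rows of W_in
    d <- tanh(sweep(params$W_in, 2, params$b_in, `+`))           # N x dim
    logits <- sweep(d %*% params$W_out, 2, params$b_out, `+`)    # N x N
    logits <- logits - apply(logits, 1, max)
    p <- exp(logits); p <- p / rowSums(p)
    pred <- max.col(p, ties.method = "first")
    acc <- mean(pred == seq_len(n))
    if (acc == 1) break
    # backward (targets = identity)
    dlogits <- (p - diag(n)) / n
    g <- list(
      W_out = t(d) %*% dlogits,
      b_out = colSums(dlogits),
      W_in = (dlogits %*% t(params$W_out)) * (1 - d^2),
      b_in = colSums((dlogits %*% t(params$W_out)) * (1 - d^2))
    )
    for (k in names(params)) {
      m[[k]] <- b1 * m[[k]] + (1 - b1) * g[[k]]
      v[[k]] <- b2 * v[[k]] + (1 - b2) * g[[k]]^2
      mhat <- m[[k]] / (1 - b1^ep)
      vhat <- v[[k]] / (1 - b2^ep)
      params[[k]] <- params[[k]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  if (acc < 1)
    warning("autoencoder did not reach perfect reconstruction (accuracy ",
            signif(acc, 4), " after ", ep, " epochs)")
  model <- c(params, list(vocab = vocab, reconstruction_accuracy = acc,
                          epochs_run = ep))
  class(model) <- "icd_autoencoder"
  model
}

#' @export
print.icd_autoencoder <- function(x, ...) {
  cat("icd_autoencoder:", length(x$vocab), "codes ->", ncol(x$W_in),
      "dims; reconstruction accuracy", signif(x$reconstruction_accuracy, 4),
      "after", x$epochs_run, "epochs\n")
  invisible(x)
}

#' Embed codes as dense vectors
#'
#' Applies the trained encoder: for a one-hot input the encoding reduces to
#' the code's row of `W_in` plus the bias, through tanh, so every entry
#' lies in (-1, 1).
#'
#' @param codes character vector of (truncatable) codes.
#' @param model a trained `icd_autoencoder`.
#' @return `length(codes)` x dim matrix of embeddings.
#' @export
embed_codes <- function(codes, model) {
  i <- code_index(truncate_code(codes), model$vocab)
  tanh(sweep(model$W_in[i, , drop = FALSE], 2, model$b_in, `+`))
}

#' Argmax reconstruction accuracy of an autoencoder
#'
#' Fraction of vocabulary codes whose decoder softmax puts its largest
#' probability on the code's own index.
#'
#' @param model an `icd_autoencoder` (trained or not).
#' @return fraction in [0, 1].
#' @export
reconstruction_accuracy <- function(model) {
  d <- tanh(sweep(model$W_in, 2, model$b_in, `+`))
  logits <- sweep(d %*% model$W_out, 2, model$b_out, `+`)
  mean(max.col(logits, ties.method = "first") == seq_along(model$vocab))
}

#' Persist / load an autoencoder as plain text
#'
#' The four weight arrays go to a flat CSV of numbers and the vocabulary to
#' a one-code-per-line text file, so a trained embedder can be stored and
#' reloaded without binary formats.
#'
#' @param model an `icd_autoencoder`.
#' @param dir directory for `autoencoder_weights.csv` + `vocabulary.txt`.
#' @export
write_autoencoder <- function(model, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  n <- length(model$vocab); dm <- ncol(model$W_in)
  flat <- c(as.numeric(model$W_in), model$b_in,
            as.numeric(model$W_out), model$b_out)
  data.table::fwrite(data.frame(value = flat),
                     file.path(dir, "autoencoder_weights.csv"))
  writeLines(c(paste0("# n=", n, " dim=", dm,
                      " accuracy=", model$reconstruction_accuracy),
               as.character(model$vocab)),
             file.path(dir, "vocabulary.txt"))
  invisible(dir)
}

#' @rdname write_autoencoder
#' @export
read_autoencoder <- function(dir) {
  hdr <- readLines(file.path(dir, "vocabulary.txt"))
  meta <- hdr[1]
  codes <- hdr[-1]
  n <- as.integer(sub(".*n=([0-9]+).*", "\\1", meta))
  dm <- as.integer(sub(".*dim=([0-9]+).*", "\\1", meta))
  acc <- as.numeric(sub(".*accuracy=([0-9.eE+-]+).*", "\\1", meta))
  flat <- data.table::fread(file.path(dir, "autoencoder_weights.csv"))$value
  stopifnot(length(flat) == n * dm + dm + dm * n + n, length(codes) == n)
  W_in <- matrix(flat[seq_len(n * dm)], n, dm)
  b_in <- flat[n * dm + seq_len(dm)]
  W_out <- matrix(flat[n * dm + dm + seq_len(dm * n)], dm, n)
  b_out <- flat[n * dm + dm + dm * n + seq_len(n)]
  vocab <- code_vocabulary(codes)
  model <- list(W_in = W_in, b_in = b_in, W_out = W_out, b_out = b_out,
                vocab = vocab, reconstruction_accuracy = acc,
                epochs_run = NA_integer_)
  class(model) <- "icd_autoencoder"
  model
}
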