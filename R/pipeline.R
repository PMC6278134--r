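#' Experiment configuration
#'
#' Bundles every stage's parameters into one validated object with a single
#' global seed; each stage derives its own stream from it, so any stage is
#' individually reproducible.
#'
#' @param generator a [generator_config()].
#' @param diagnosis_window case-qualifying window for the first stroke
#'   diagnosis.
#' @param age_range inclusive age range at the index date.
#' @param ratios train/validation/test percentages.
#' @param strategy exam imputation strategy.
#' @param window label horizon in days.
#' @param embedding_dim code-embedding width.
#' @param spec_args named list of overrides for [model_spec()] widths.
#' @param epochs_single,epochs_dual training epochs for the single-input
#'   and dual models (500/100 in the full protocol).
#' @param batch_size,lr optimizer settings.
#' @param loss a [loss_config()] or `"ce"`.
#' @param replicates,level bootstrap settings.
#' @param seed global seed.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(generator = generator_config(),
                              diagnosis_window = c("2001-01-01", "2015-01-01"),
                              age_range = c(45, 95),
                              ratios = c(70, 15, 15),
                              strategy = "roll_forward_gender_mean",
                              window = 365L,
                              embedding_dim = 32L,
                              spec_args = list(),
                              epochs_single = 500L, epochs_dual = 100L,
                              batch_size = 32L, lr = 1e-3,
                              loss = loss_config(),
                              replicates = 2000L, level = 0.95,
                              seed = 1L) {
  if (identical(loss, "ce")) loss <- standard_ce_config()
  validate_generator_config(generator)
  if (abs(sum(ratios) - 100) > 1e-9)
    stop("experiment config: `ratios` must sum to 100")
  out <- list(generator = generator,
              diagnosis_window = as.Date(diagnosis_window),
              age_range = age_range, ratios = ratios, strategy = strategy,
              window = as.integer(window),
              embedding_dim = as.integer(embedding_dim),
              spec_args = spec_args,
              epochs_single = as.integer(epochs_single),
              epochs_dual = as.integer(epochs_dual),
              batch_size = as.integer(batch_size), lr = lr, loss = loss,
              replicates = as.integer(replicates), level = level,
              seed = as.integer(seed))
  class(out) <- "experiment_config"
  out
}

#' Run the full pipeline
#'
#' generate -> inject -> cohort -> featurize -> embed -> train (three
#' models, with weight transfer into the dual model) -> evaluate. Every
#' intermediate artifact is written under `out_dir` with a manifest of md5
#' checksums, stage timings, and the config, so a run can be audited and
#' replayed.
#'
#' @param config an [experiment_config()].
#' @param out_dir output directory (created).
#' @param verbose print stage progress.
#' @return list with `population`, `cohort`, `split`, `embedder`, `stats`,
#'   `splits` (featurized instance sets), `models`, `metrics` (per-model
#'   val/test AUC+CI), and `manifest_path`.
#' @export
run_experiment <- function(config, out_dir, verbose = TRUE) {
  stopifnot(inherits(config, "experiment_config"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  say <- function(...) if (verbose) message(...)
  timings <- c()
  tic <- function() proc.time()[["elapsed"]]
  stage <- function(name, expr) {
    t0 <- tic()
    r <- tryCatch(expr, error = function(e)
      stop("pipeline stage `", name, "` failed: ", conditionMessage(e),
           call. = FALSE))
    timings[[name]] <<- round(tic() - t0, 2)
    say("stage ", name, ": ", timings[[name]], "s")
    r
  }

  pop <- stage("generate", {
    p <- generate_population(config$generator)
    inject_stroke_events(p, config$generator)
  })
  write_population(pop, file.path(out_dir, "data"))

  cohort_tab <- stage("cohort", {
    cases <- select_cases(pop, config$diagnosis_window, config$age_range)
    cohort <- match_controls(cases, pop, seed = config$seed)
    if (!nrow(cohort$cases)) stop("no matched cases")
    split <- split_cohort(cohort, config$ratios, seed = config$seed)
    write_cohort(cohort, split, file.path(out_dir, "cohort.csv"))
    read_cohort(file.path(out_dir, "cohort.csv"))
  })

  embedder <- stage("embed", {
    vocab <- code_vocabulary(pop$diagnoses$icd10_code)
    mdl <- train_autoencoder(vocab, dim = config$embedding_dim,
                             seed = config$seed)
    write_autoencoder(mdl, file.path(out_dir, "embedder"))
    mdl
  })

  featurized <- stage("featurize", {
    train_ids <- unique(c(cohort_tab$case_id[cohort_tab$split == "train"],
                          cohort_tab$control_id_1[cohort_tab$split == "train"],
                          cohort_tab$control_id_2[cohort_tab$split == "train"]))
    stats <- fit_scaler(pop, train_ids)
    write_scaler(stats, file.path(out_dir, "scaler_stats.yaml"))
    list(stats = stats,
         splits = featurize_cohort(pop, cohort_tab, embedder, stats,
                                   strategy = config$strategy,
                                   window = config$window))
  })
  splits <- featurized$splits

  exam_dim <- if (config$strategy == "indicator") 48L else 28L
  mspec <- function(kind) do.call(model_spec, c(list(kind = kind,
                                                     exam_dim = exam_dim),
                                                config$spec_args))
  models <- stage("train", {
    cfg1 <- train_config(epochs = config$epochs_single,
                         batch_size = config$batch_size, lr = config$lr,
                         seed = config$seed, loss = config$loss)
    m1 <- train_model(build_model(mspec("diagnosis_rnn"), seed = config$seed),
                      splits$train$diagnosis, splits$validation$diagnosis, cfg1)
    m2 <- train_model(build_model(mspec("exam_dense"), seed = config$seed),
                      splits$train$exam, splits$validation$exam, cfg1)
    m3 <- build_model(mspec("dual_input"), seed = config$seed)
    m3 <- transfer_weights(m3, m1, m2)
    cfg3 <- train_config(epochs = config$epochs_dual,
                         batch_size = config$batch_size, lr = config$lr,
                         seed = config$seed, loss = config$loss)
    m3 <- train_model(m3, splits$train$dual, splits$validation$dual, cfg3)
    list(model1 = m1, model2 = m2, model3 = m3)
  })

  metrics <- stage("evaluate", {
    rows <- list()
    eval_sets <- list(model1 = "diagnosis", model2 = "exam", model3 = "dual")
    for (mn in names(models)) {
      for (sp in c("validation", "test")) {
        inst <- splits[[sp]][[eval_sets[[mn]]]]
        sc <- predict_scores(models[[mn]], inst)
        roc <- roc_and_auc(sc, inst$y)
        roc$ci <- bootstrap_auc_ci(sc, inst$y, config$replicates,
                                   config$level, seed = config$seed)
        write_roc(roc, file.path(out_dir, paste0("roc_", mn, "_", sp, ".csv")))
        rows[[paste(mn, sp)]] <- data.frame(
          model = mn, split = sp, auc = roc$auc,
          ci_lower = roc$ci[1], ci_upper = roc$ci[2],
          f1 = f1_score(sc, inst$y))
      }
    }
    m <- do.call(rbind, rows)
    rownames(m) <- NULL
    data.table::fwrite(m, file.path(out_dir, "metrics.csv"))
    m
  })

  manifest_path <- file.path(out_dir, "manifest.yaml")
  artifacts <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  artifacts <- setdiff(artifacts, manifest_path)
  manifest <- list(
    seed = config$seed,
    config_hash = unname(config_hash(config)),
    timings_seconds = as.list(timings),
    checksums = as.list(stats::setNames(
      unname(tools::md5sum(artifacts)),
      substring(artifacts, nchar(out_dir) + 2)))
  )
  yaml::write_yaml(manifest, manifest_path)

  list(population = pop, cohort = cohort_tab, embedder = embedder,
       stats = featurized$stats, splits = splits, models = models,
       metrics = metrics, manifest_path = manifest_path)
}

# stable hash of a config: md5 of its canonical yaml serialization
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(serialize_config(config), tmp, precision = 15)
  tools::md5sum(tmp)
}

serialize_config <- function(config) {
  # named atomic vectors become YAML maps (as.yaml drops vector names),
  # dates become ISO strings
  rapply(unclass(config), function(x) {
    if (inherits(x, "Date")) format(x, "%Y-%m-%d")
    else if (is.atomic(x) && !is.null(names(x))) as.list(x)
    else x
  }, how = "replace")
}

#' Write / read scaler statistics as structured text
#'
#' @param stats a `scaler_stats`.
#' @param path YAML path.
#' @export
write_scaler <- function(stats, path) {
  yaml::write_yaml(list(
    metrics = lapply(seq_len(nrow(stats$metrics)), function(i)
      as.list(stats$metrics[i, ])),
    gender_means = lapply(seq_len(nrow(stats$gender_means)), function(i)
      as.list(stats$gender_means[i, ]))
  ), path, precision = 15)
  invisible(path)
}

#' @rdname write_scaler
#' @export
read_scaler <- function(path) {
  raw <- yaml::read_yaml(path)
  met <- do.call(rbind, lapply(raw$metrics, as.data.frame))
  gm <- do.call(rbind, lapply(raw$gender_means, as.data.frame))
  out <- list(metrics = met, gender_means = gm)
  class(out) <- "scaler_stats"
  out
}

#' Write / read a generator config as structured text
#'
#' All fields of the generator config are settable from a YAML file.
#'
#' @param config a [generator_config()].
#' @param path YAML path.
#' @export
write_generator_config <- function(config, path) {
  yaml::write_yaml(serialize_config(config), path, precision = 15)
  invisible(path)
}

#' @rdname write_generator_config
#' @export
read_generator_config <- function(path) {
  raw <- yaml::read_yaml(path)
  for (nm in c("background_codes", "risk_codes", "signal_metrics"))
    raw[[nm]] <- unlist(raw[[nm]])
  do.call(generator_config, raw)
}
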