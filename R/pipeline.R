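# Config-driven end-to-end orchestration: synthesize -> curate -> detect
# timings -> propose snippets -> train -> evaluate, with one global seed
# deriving every stage seed and each stage writing its manifest before
# the next starts.

#' Pipeline configuration
#'
#' Nested stage configurations plus a single global seed from which every
#' stage seed is derived (so stages are independently reproducible).
#'
#' @param out_dir artifact directory.
#' @param seed global seed.
#' @param synth list: `n_subjects`, `videos_per_subject`,
#'   `class_balance`, `split_ratio`, `config` ([synthetic_config()]),
#'   `scheme` ([domain_scheme()]).
#' @param curation list: `max_frames`, optional `quality_predicate`.
#' @param timing a [timing_model_config()].
#' @param snippet list: `clip_len`, `stride`, `min_run`, `max_snippets`.
#' @param backbone a [backbone_config()].
#' @param train a [mil_train_config()].
#' @param evaluation list: `threshold`, `n_boot`, `plots`.
#' @param stages character vector of stages to run, a subset of
#'   `c("synth", "curate", "timings", "propose", "train", "evaluate")`
#'   in pipeline order.
#' @param checkpoint optional path to a model checkpoint (`.rds` written
#'   by a previous run's train stage) for evaluation-only runs.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, seed = 1,
                            synth = list(), curation = list(),
                            timing = NULL, snippet = list(),
                            backbone = NULL, train = NULL,
                            evaluation = list(),
                            stages = c("synth", "curate", "timings",
                                       "propose", "train", "evaluate"),
                            checkpoint = NULL) {
  synth <- utils::modifyList(
    list(n_subjects = 16, videos_per_subject = 1, class_balance = 0.5,
         split_ratio = 0.75, config = synthetic_config(),
         scheme = domain_scheme()), synth)
  curation <- utils::modifyList(
    list(max_frames = 300, quality_predicate = NULL), curation)
  if (is.null(timing)) timing <- timing_model_config(epochs = 10)
  snippet <- utils::modifyList(
    list(clip_len = 32, stride = 2, min_run = 2, max_snippets = 16),
    snippet)
  if (is.null(backbone)) backbone <- backbone_config()
  if (is.null(train))
    train <- mil_train_config(lr = 0.02, epochs = 2, iters_per_epoch = 100,
                              dropout = 0, grl_lambda = 0.1)
  evaluation <- utils::modifyList(
    list(threshold = 0.5, n_boot = 500, plots = FALSE), evaluation)
  list(out_dir = out_dir, seed = seed, synth = synth, curation = curation,
       timing = timing, snippet = snippet, backbone = backbone,
       train = train, evaluation = evaluation, stages = stages,
       checkpoint = checkpoint)
}

#' Bundled demo configuration
#'
#' A small, CPU-friendly end-to-end run used by the examples and the
#' determinism checks.
#'
#' @param out_dir artifact directory.
#' @param seed global seed.
#' @return A [pipeline_config()].
#' @export
demo_pipeline_config <- function(out_dir, seed = 1) {
  pipeline_config(
    out_dir, seed = seed,
    synth = list(n_subjects = 10, videos_per_subject = 1,
                 split_ratio = 0.7,
                 config = synthetic_config(n_frames = 200)),
    timing = timing_model_config(epochs = 6, seed = seed),
    train = mil_train_config(lr = 0.05, epochs = 2, iters_per_epoch = 100,
                             dropout = 0, grl_lambda = 0.1, clip = 0.5,
                             seed = seed),
    evaluation = list(n_boot = 200))
}

#' Build a pipeline configuration from a YAML file
#'
#' Top-level keys mirror [pipeline_config()] arguments; the nested
#' `synth$config`, `timing`, `backbone` and `train` blocks mirror their
#' constructors' argument names.
#'
#' @param path YAML file.
#' @return A [pipeline_config()].
#' @export
pipeline_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list(out_dir = y$out_dir)
  if (!is.null(y$seed)) args$seed <- y$seed
  if (!is.null(y$stages)) args$stages <- y$stages
  if (!is.null(y$checkpoint)) args$checkpoint <- y$checkpoint
  if (!is.null(y$synth)) {
    s <- y$synth
    if (!is.null(s$config)) s$config <- do.call(synthetic_config, s$config)
    if (!is.null(s$scheme)) s$scheme <- do.call(domain_scheme, s$scheme)
    args$synth <- s
  }
  if (!is.null(y$timing)) args$timing <- do.call(timing_model_config, y$timing)
  if (!is.null(y$snippet)) args$snippet <- y$snippet
  if (!is.null(y$backbone)) args$backbone <- do.call(backbone_config, y$backbone)
  if (!is.null(y$train)) args$train <- do.call(mil_train_config, y$train)
  if (!is.null(y$evaluation)) args$evaluation <- y$evaluation
  do.call(pipeline_config, args)
}

#' Run the pipeline
#'
#' Executes the enabled stages in order; each stage writes its manifest
#' into `out_dir` before the next starts, and a run log records seeds,
#' sizes and stage wall-times. A stage failure halts the run with the
#' failing stage named; partial outputs are retained.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a list with the dataset, models, predictions and
#'   metric reports produced by the enabled stages.
#' @export
run_pipeline <- function(config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- list()
  run_log <- list(seed = config$seed, stages = config$stages)
  tic <- function() Sys.time()
  stage <- function(name, fun) {
    if (!name %in% config$stages) return(invisible(NULL))
    t0 <- tic()
    r <- tryCatch(fun(), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    run_log[[paste0("time_", name)]] <<- as.numeric(Sys.time() - t0,
                                                   units = "secs")
    r
  }

  ds <- stage("synth", function() {
    d <- generate_dataset(config$synth$n_subjects,
                          config$synth$videos_per_subject,
                          config$synth$class_balance,
                          scheme = config$synth$scheme,
                          split_ratio = config$synth$split_ratio,
                          seed = derive_seed(config$seed, "synth"),
                          config = config$synth$config)
    utils::write.csv(d$manifest, file.path(config$out_dir, "manifest.csv"),
                     row.names = FALSE)
    d
  })
  res$dataset <- ds

  if ("curate" %in% config$stages && !is.null(ds)) {
    cu <- stage("curate", function() {
      allv <- lapply(c(ds$train, ds$test), function(s) s$video)
      curate(allv, config$curation$max_frames,
             config$curation$quality_predicate)
    })
    utils::write.csv(cu$log, file.path(config$out_dir, "curation_log.csv"),
                     row.names = FALSE)
    keep_ids <- vapply(cu$kept, function(v) v$video_id, character(1))
    ds$train <- Filter(function(s) s$video$video_id %in% keep_ids, ds$train)
    ds$test <- Filter(function(s) s$video$video_id %in% keep_ids, ds$test)
    res$curation <- cu$log
  }

  tm <- stage("timings", function() {
    cfg <- config$timing
    cfg$seed <- derive_seed(config$seed, "timing")
    m <- train_timing_model(ds$train, cfg)
    tl <- lapply(c(ds$train, ds$test), function(s) {
      t <- detect_timings(m, s$video, min_run = config$snippet$min_run)
      list(video_id = s$video$video_id, es = t$es, ed = t$ed)
    })
    jsonlite::write_json(tl, file.path(config$out_dir, "timings.json"),
                         auto_unbox = FALSE, digits = NA)
    list(model = m, timings = tl)
  })
  res$timing_model <- tm$model

  bags <- stage("propose", function() {
    mk <- function(s) {
      t <- detect_timings(tm$model, s$video,
                          min_run = config$snippet$min_run)
      propose_cycle_snippets(s$video, t, config$snippet$clip_len,
                             config$snippet$stride,
                             config$snippet$max_snippets)
    }
    b <- list(train = lapply(ds$train, mk), test = lapply(ds$test, mk))
    jsonlite::write_json(lapply(c(b$train, b$test), bag_manifest),
                         file.path(config$out_dir, "bags.json"),
                         auto_unbox = TRUE, digits = NA)
    b
  })
  res$bags <- bags

  model <- NULL
  if ("train" %in% config$stages) {
    model <- stage("train", function() {
      all_bags <- c(bags$train, bags$test)
      D <- max(vapply(all_bags, function(b) b$domain_id, numeric(1))) + 1
      bcfg <- config$backbone
      bcfg$seed <- derive_seed(config$seed, "backbone")
      m <- video_model(bcfg, n_domains = D,
                       seed = derive_seed(config$seed, "model"))
      tcfg <- config$train
      tcfg$seed <- derive_seed(config$seed, "train")
      m <- train_mil(m, bags$train, all_bags, tcfg)
      utils::write.csv(m$log, file.path(config$out_dir, "train_log.csv"),
                       row.names = FALSE)
      saveRDS(m, file.path(config$out_dir, "model.rds"))
      m
    })
  } else if (!is.null(config$checkpoint)) {
    model <- readRDS(config$checkpoint)
  }
  res$model <- model

  if ("evaluate" %in% config$stages) {
    res$metrics <- stage("evaluate", function() {
      preds <- do.call(rbind, lapply(bags$test, function(b) {
        p <- classify_video(model, b)
        data.frame(video_id = p$video_id, subject_id = p$subject_id,
                   score_N = p$class_scores[1],
                   score_HTCM = p$class_scores[2],
                   prob_HTCM = p$class_probabilities[2],
                   label = as.integer(p$class_label == "HTCM"))
      }))
      utils::write.csv(preds, file.path(config$out_dir, "predictions.csv"),
                       row.names = FALSE)
      ev <- config$evaluation
      mv <- compute_metrics(preds$prob_HTCM, preds$label, ev$threshold,
                            granularity = "video", n_boot = ev$n_boot,
                            seed = derive_seed(config$seed, "boot_v"))
      su <- aggregate_subjects(preds)
      ms <- compute_metrics(su$prob_HTCM, su$label, ev$threshold,
                            granularity = "subject", n_boot = ev$n_boot,
                            seed = derive_seed(config$seed, "boot_s"))
      reports <- list("ours/video" = mv, "ours/subject" = ms)
      make_report(reports, config$out_dir, plots = ev$plots)
      res$predictions <<- preds
      reports
    })
  }

  run_log$n_train <- length(ds$train); run_log$n_test <- length(ds$test)
  jsonlite::write_json(run_log, file.path(config$out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(res)
}
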