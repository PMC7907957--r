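# End-to-end pipeline: simulate -> featurize/train -> retrospective and
# prospective evaluation -> out-of-fold ranking -> queue simulation and
# schedule sweep -> cohort statistics. Every artifact is stamped with the
# seed and a configuration fingerprint; a rerun with the same configuration
# is bit-identical.

#' Pipeline configuration
#'
#' @param out_dir directory for artifacts (created if needed).
#' @param cohort a [cohort_config()]; its seed drives all randomness.
#' @param tier feature tier to train.
#' @param prospective_n size of the later-generated batch scored by the
#'   frozen model.
#' @param k cross-validation folds for the out-of-fold confidence scores.
#' @param schedule named vector `c(d = ..., a = ...)`: review period
#'   (days) and per-session budget used for the headline queue simulation.
#' @param d_values,a_values sweep grids.
#' @param corpus_entries phenotype corpus size.
#' @param grid hyperparameter grid.
#' @param min_df TF-IDF minimum document frequency.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, cohort = cohort_config(),
                            tier = "semantic_types", prospective_n = 288L,
                            k = 5L, schedule = c(d = 14, a = 26),
                            d_values = c(3, 6, 9, 12, 15, 30),
                            a_values = c(5, 10, 15, 20, 26, 30, 40),
                            corpus_entries = 200L,
                            grid = default_hyper_grid(), min_df = 2L) {
  stopifnot(inherits(cohort, "cohort_config"))
  structure(list(out_dir = out_dir, cohort = cohort, tier = tier,
                 prospective_n = as.integer(prospective_n), k = as.integer(k),
                 schedule = schedule, d_values = d_values,
                 a_values = a_values,
                 corpus_entries = as.integer(corpus_entries),
                 grid = grid, min_df = as.integer(min_df)),
            class = "pipeline_config")
}

stage <- function(name, expr) {
  tryCatch(force(expr),
           error = function(e) stop("stage '", name, "' failed: ",
                                    conditionMessage(e), call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Executes simulate-data, featurize/train, retrospective evaluation,
#' prospective evaluation of a later batch under the frozen model,
#' out-of-fold confidence scoring, queue simulation under all four
#' heuristics, the (d, a) sweep, and the cohort summary table; writes every
#' artifact under `config$out_dir` and returns a manifest with an md5 per
#' artifact. Reruns with an identical configuration produce identical
#' hashes.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress per-stage messages.
#' @return manifest list (also written as `manifest.json`).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  pth <- function(f) file.path(config$out_dir, f)
  seed <- config$cohort$seed
  say <- function(...) if (!quiet) message(...)
  t0 <- Sys.time()
  log <- list()
  note <- function(name, n) {
    log[[name]] <<- list(elapsed_s = round(
      as.numeric(difftime(Sys.time(), t0, units = "secs")), 2), n = n)
  }

  say("stage simulate-data")
  coh <- stage("simulate-data", generate_cohort(config$cohort))
  write_applications(coh, pth("applications.jsonl"))
  corpus <- stage("simulate-data",
                  generate_phenotype_corpus(config$corpus_entries,
                                            config$cohort$letter,
                                            seed = seed + 1L))
  write_phenotype_corpus(corpus, pth("phenotype_corpus.jsonl"))
  note("simulate_data", nrow(coh))

  say("stage train")
  sp <- stage("train", stratified_split(coh, seed = seed))
  fit <- stage("train",
               admit_fit(sp$train, sp$validation, tier = config$tier,
                         grid = config$grid, corpus = corpus,
                         min_df = config$min_df))
  save_model(fit, pth("model.json"))
  model_hash_at_save <- unname(tools::md5sum(pth("model.json")))
  note("train", length(fit$weights))

  say("stage evaluate (retrospective)")
  retro <- stage("evaluate", evaluate(fit, sp$test))
  note("evaluate", retro$n)

  say("stage prospective")
  pro_cfg <- config$cohort
  pro_cfg$n_total <- config$prospective_n
  pro_cfg$seed <- seed + 2L
  pro <- stage("prospective", generate_cohort(pro_cfg))
  # later batch: arrivals start after the retrospective window closes
  shift <- max(coh$submission_day) + 1L
  pro$submission_day <- pro$submission_day + shift
  pro$recorded_review_day <- pro$recorded_review_day + shift
  prospective <- stage("prospective", evaluate(fit, pro))
  model_hash_after <- unname(tools::md5sum(pth("model.json")))
  note("prospective", prospective$n)

  say("stage crossval-scores")
  scores <- stage("crossval-scores",
                  crossval_scores(coh, tier = config$tier, k = config$k,
                                  seed = seed + 3L, grid = config$grid,
                                  corpus = corpus, min_df = config$min_df))
  write_scores(scores, pth("scores.csv"))
  note("crossval_scores", nrow(scores))

  say("stage simulate-queue")
  d <- config$schedule[["d"]]; a <- config$schedule[["a"]]
  queue <- lapply(setNames(nm = HEURISTICS), function(h)
    stage("simulate-queue",
          simulate_queue(coh, h, d, a, scores = scores)$by_label))
  jsonlite::write_json(list(schedule = list(d = d, a = a), queue = queue),
                       pth("queue.json"), auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  note("simulate_queue", length(queue))

  say("stage sweep")
  sw <- stage("sweep", sweep_schedule(coh, d_values = config$d_values,
                                      a_values = config$a_values,
                                      scores = scores))
  write.csv(as.data.frame(sw), pth("sweep.csv"), row.names = FALSE)
  jsonlite::write_json(attr(sw, "optimum"), pth("sweep_optimum.json"),
                       auto_unbox = TRUE, digits = NA)
  note("sweep", nrow(sw))

  say("stage cohort-stats")
  tab <- stage("cohort-stats", summarize_cohort(coh))
  jsonlite::write_json(unclass(tab), pth("cohort_table.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  note("cohort_stats", tab$n[1] + tab$n[2])

  say("stage report")
  config_hash <- object_hash(list(
    n_total = config$cohort$n_total,
    accepted_fraction = config$cohort$accepted_fraction,
    arrival = c(config$cohort$arrival_rate_mean,
                config$cohort$arrival_rate_sd),
    demo = config$cohort$demo_params,
    symptom_probs = as.numeric(config$cohort$symptom_probs),
    letter = unclass(config$cohort$letter),
    seed = seed, tier = config$tier, k = config$k,
    schedule = as.numeric(config$schedule),
    grids = list(config$d_values, config$a_values),
    prospective_n = config$prospective_n, min_df = config$min_df))
  metrics <- list(
    retrospective = unclass(retro),
    prospective = unclass(prospective),
    model_frozen_for_prospective =
      identical(model_hash_at_save, model_hash_after))
  jsonlite::write_json(metrics, pth("metrics.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  artifacts <- c("applications.jsonl", "phenotype_corpus.jsonl",
                 "model.json", "metrics.json", "scores.csv", "queue.json",
                 "sweep.csv", "sweep_optimum.json", "cohort_table.json")
  manifest <- list(version = "udnadmit-pipeline-1", seed = seed,
                   config_hash = config_hash,
                   model_frozen_for_prospective =
                     metrics$model_frozen_for_prospective,
                   stages = log,
                   artifacts = lapply(setNames(nm = artifacts), function(f)
                     list(file = f, md5 = unname(tools::md5sum(pth(f))))))
  jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}
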