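# Pipeline stages tying the modules together, plus manifest-stamped artifact
# output. Each stage reads its predecessor's artifacts from `out_dir`,
# writes its own, and records a manifest (seed, config digest, package
# version) so a run is reproducible from its outputs. The thin command-line
# wrapper in inst/cli/acuityssm.R maps subcommands onto run_stage().

.manifest <- function(out_dir, stage, seed, extra = list()) {
  man <- c(list(stage = stage, seed = seed,
                package_version = as.character(utils::packageVersion("acuityssm")),
                timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
           extra)
  jsonlite::write_json(man, file.path(out_dir, paste0("manifest_", stage,
                                                      ".json")),
                       auto_unbox = TRUE, digits = NA)
}

.require_artifact <- function(path, needed_stage) {
  if (!file.exists(path)) {
    abort(sprintf("missing artifact %s: run the `%s` stage first",
                  path, needed_stage),
          class = "acuityssm_user_error")
  }
  path
}

#' Run one pipeline stage
#'
#' Stages: `simulate` (synthetic cohort to CSV), `phenotype` (labeled-window
#' table), `encode` (vocabulary + encoded dataset), `train` (fitted model +
#' Youden thresholds), `predict` (per-window probabilities, thresholded
#' binaries and decided acuity state), `calibrate` (isotonic calibration of
#' each head), `evaluate` (step/episode metric report), `explain` (aggregated
#' feature importance). Every stage writes a JSON manifest beside its
#' artifacts.
#'
#' @param stage One of the stage names above.
#' @param out_dir Artifact directory shared by all stages of a run.
#' @param seed Integer seed governing all randomness of the stage.
#' @param n_stays Cohort size (simulate).
#' @param params Optional [synth_params()] override (simulate).
#' @param pheno_cfg A [phenotype_config()].
#' @param model_cfg A [model_config()].
#' @param n_boot Bootstrap iterations (evaluate).
#' @param target_episode_ppv Episode precision target (evaluate).
#' @param heads Heads to evaluate/explain.
#' @return Stage-dependent value, invisibly (paths or tibbles).
#' @export
run_stage <- function(stage, out_dir, seed = 1L, n_stays = 200L,
                      params = NULL, pheno_cfg = phenotype_config(),
                      model_cfg = model_config(),
                      n_boot = 100L, target_episode_ppv = 0.33,
                      heads = c("unstable", "deceased")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  switch(
    stage,
    simulate = {
      sp <- params %||% synth_params(n_stays, seed = seed)
      coh <- simulate_cohort(sp)
      write_cohort(coh, file.path(out_dir, "cohort"))
      .manifest(out_dir, "simulate", seed, list(n_stays = sp$n_stays))
      invisible(coh)
    },
    phenotype = {
      coh <- read_cohort(.require_artifact(file.path(out_dir, "cohort"),
                                           "simulate"))
      win <- label_windows(coh, pheno_cfg)
      write.csv(win, file.path(out_dir, "windows.csv"), row.names = FALSE)
      write.csv(attr(win, "excluded"), file.path(out_dir, "excluded.csv"),
                row.names = FALSE)
      .manifest(out_dir, "phenotype", seed,
                list(window_hours = pheno_cfg$window_hours,
                     n_windows = nrow(win),
                     n_excluded = nrow(attr(win, "excluded"))))
      invisible(win)
    },
    encode = {
      coh <- read_cohort(file.path(out_dir, "cohort"))
      win <- tibble::as_tibble(
        read.csv(.require_artifact(file.path(out_dir, "windows.csv"),
                                   "phenotype")))
      vocab <- build_vocabulary(coh$events, coh$static)
      ev <- scale_events(filter_outliers(coh$events, vocab), vocab)
      ds <- encode_windows(ev, win, vocab, coh$static, L = model_cfg$L)
      write_vocabulary(vocab, file.path(out_dir, "vocabulary.json"))
      saveRDS(ds, file.path(out_dir, "dataset.rds"))
      .manifest(out_dir, "encode", seed,
                list(n_codes = nrow(vocab$table), L = model_cfg$L))
      invisible(ds)
    },
    train = {
      ds <- readRDS(.require_artifact(file.path(out_dir, "dataset.rds"),
                                      "encode"))
      model_cfg$seed <- as.integer(seed)
      sp <- split_by_stay(ds, 0.2, seed = seed)
      model <- train_model(sp$train, sp$val, model_cfg)
      pv <- predict(model, sp$val)
      thr <- select_thresholds(pv, sp$val$windows)
      model$thresholds <- thr
      saveRDS(model, file.path(out_dir, "model.rds"))
      write.csv(model$history, file.path(out_dir, "training_history.csv"),
                row.names = FALSE)
      .manifest(out_dir, "train", seed,
                list(n_params = n_params(model$params),
                     best_epoch = model$best_epoch))
      invisible(model)
    },
    predict = {
      model <- readRDS(.require_artifact(file.path(out_dir, "model.rds"),
                                         "train"))
      ds <- readRDS(file.path(out_dir, "dataset.rds"))
      pv <- predict(model, ds)
      out <- apply_decision_logic(pv, as.list(model$thresholds))
      write.csv(out, file.path(out_dir, "predictions.csv"), row.names = FALSE)
      .manifest(out_dir, "predict", seed, list(n_windows = nrow(out)))
      invisible(out)
    },
    calibrate = {
      model <- readRDS(.require_artifact(file.path(out_dir, "model.rds"),
                                         "train"))
      ds <- readRDS(file.path(out_dir, "dataset.rds"))
      sp <- split_by_stay(ds, 0.2, seed = seed)
      pv <- predict(model, sp$val)
      res <- list()
      for (i in seq_along(HEAD_NAMES)) {
        h <- HEAD_NAMES[i]
        y <- sp$val$windows[[LABEL_COLS[i]]]
        p <- pv[[paste0("p_", h)]]
        ok <- !is.na(y)
        if (sum(y[ok] == 1) == 0 || sum(y[ok] == 0) == 0) next
        cal <- tryCatch(
          fit_isotonic(p[ok], y[ok], stay_id = pv$stay_id[ok], seed = seed),
          error = function(e) NULL)
        if (is.null(cal)) next
        write_calibration(cal, file.path(out_dir,
                                         paste0("calibration_", h, ".json")))
        res[[h]] <- tibble::tibble(
          head = h,
          brier_raw = brier(p[ok], y[ok]),
          brier_calibrated = brier(apply_calibration(cal, p[ok]), y[ok]))
      }
      out <- dplyr::bind_rows(res)
      write.csv(out, file.path(out_dir, "calibration_report.csv"),
                row.names = FALSE)
      .manifest(out_dir, "calibrate", seed, list(heads = names(res)))
      invisible(out)
    },
    evaluate = {
      preds <- tibble::as_tibble(
        read.csv(.require_artifact(file.path(out_dir, "predictions.csv"),
                                   "predict")))
      win <- tibble::as_tibble(read.csv(file.path(out_dir, "windows.csv")))
      model <- readRDS(file.path(out_dir, "model.rds"))
      rows <- list()
      for (h in heads) {
        i <- match(h, HEAD_NAMES)
        y <- win[[LABEL_COLS[i]]]
        p <- preds[[paste0("p_", h)]]
        ok <- !is.na(y)
        rep <- evaluate_head(p[ok], y[ok], win$stay_id[ok],
                             threshold = model$thresholds[[h]] %||% 0.5,
                             n_boot = n_boot, seed = seed)
        es <- episode_scores(p[ok], y[ok], win$stay_id[ok])
        pt <- precision_targeted_threshold(es, target_episode_ppv)
        rows[[h]] <- dplyr::mutate(rep, head = h, .before = 1) |>
          dplyr::bind_rows(tibble::tibble(
            head = h, level = "episode", metric = "sensitivity_at_target_ppv",
            estimate = pt$sensitivity, lo = NA, hi = NA))
      }
      out <- dplyr::bind_rows(rows)
      write.csv(out, file.path(out_dir, "evaluation.csv"), row.names = FALSE)
      jsonlite::write_json(out, file.path(out_dir, "evaluation.json"),
                           digits = NA)
      .manifest(out_dir, "evaluate", seed,
                list(n_boot = n_boot, target_episode_ppv = target_episode_ppv))
      invisible(out)
    },
    explain = {
      model <- readRDS(.require_artifact(file.path(out_dir, "model.rds"),
                                         "train"))
      ds <- readRDS(file.path(out_dir, "dataset.rds"))
      set.seed(seed)
      rows <- sample(nrow(ds$windows), min(200L, nrow(ds$windows)))
      imp <- aggregate_importance(model, ds, rows = rows)
      write.csv(attr(imp, "full"), file.path(out_dir, "importance.csv"),
                row.names = FALSE)
      .manifest(out_dir, "explain", seed, list(n_windows = length(rows)))
      invisible(imp)
    },
    abort(paste("unknown stage:", stage), class = "acuityssm_user_error")
  )
}

#' Run the full pipeline end to end
#'
#' `simulate -> phenotype -> encode -> train -> predict -> calibrate ->
#' evaluate` on a seeded synthetic cohort.
#'
#' @inheritParams run_stage
#' @return The evaluation tibble, invisibly.
#' @export
run_pipeline <- function(out_dir, seed = 1L, n_stays = 200L, params = NULL,
                         pheno_cfg = phenotype_config(),
                         model_cfg = model_config(), n_boot = 100L,
                         target_episode_ppv = 0.33,
                         heads = c("unstable", "deceased")) {
  for (st in c("simulate", "phenotype", "encode", "train", "predict",
               "calibrate")) {
    run_stage(st, out_dir, seed = seed, n_stays = n_stays, params = params,
              pheno_cfg = pheno_cfg, model_cfg = model_cfg)
  }
  run_stage("evaluate", out_dir, seed = seed, n_boot = n_boot,
            target_episode_ppv = target_episode_ppv, heads = heads)
}
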