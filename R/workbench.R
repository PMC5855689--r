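#' Run a reproducible experiment from a manifest
#'
#' Drives the whole pipeline — simulate, encode, screen, train, evaluate —
#' from a single manifest so that every run can be replayed exactly.  All
#' randomness flows through the manifest seed: replaying a manifest
#' reproduces every report file byte for byte (the manifest echo carries the
#' only timestamp).
#'
#' Manifest fields (all optional except `out`):
#' * `seed`: integer master seed (default 1);
#' * `out`: output directory;
#' * `synthetic`: list of [synthetic_config()] arguments;
#' * `strategy`: negative-sampling strategy, `"N1"` or `"N2"`;
#' * `classifier`: list with `algorithm` and optional `hyperparameters`;
#' * `selector`: `"ellipse"`, `"mrmr"` or `"none"`; `n_features` (default 30);
#' * `experiments`: subset of `"evaluate"` (LOOCV metrics + ROC + fitted
#'   model), `"benchmark"` (all four classifiers side by side),
#'   `"ratio-sweep"` (1:1, 1:2, 1:3 independent tests), `"yrandom"`
#'   (label-shuffling validation); default `"evaluate"`.
#'
#' @param manifest a named list, or the path of a JSON manifest file.
#' @return invisibly, a named list of the report files written.
#' @export
run_experiment <- function(manifest) {
  if (is.character(manifest)) {
    manifest <- jsonlite::fromJSON(manifest, simplifyVector = TRUE)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }
  cfg <- stage("config", {
    stop_if_not(!is.null(manifest$out), "manifest needs an 'out' directory")
    seed <- if (is.null(manifest$seed)) 1L else as.integer(manifest$seed)
    syn <- do.call(synthetic_config,
                   c(as.list(manifest$synthetic), list(seed = seed)))
    cls <- if (is.null(manifest$classifier)) list(algorithm = "improved_nb")
           else manifest$classifier
    spec <- do.call(classifier_spec,
                    c(list(algorithm = cls$algorithm),
                      as.list(cls$hyperparameters)))
    list(seed = seed, out = manifest$out, syn = syn, spec = spec,
         strategy = if (is.null(manifest$strategy)) "N2"
                    else manifest$strategy,
         selector = if (is.null(manifest$selector)) "ellipse"
                    else manifest$selector,
         n_features = if (is.null(manifest$n_features)) 30L
                      else as.integer(manifest$n_features),
         experiments = if (is.null(manifest$experiments)) "evaluate"
                       else manifest$experiments)
  })
  dir.create(cfg$out, showWarnings = FALSE, recursive = TRUE)
  written <- list()
  log_con <- file(file.path(cfg$out, "run.log"), open = "wt")
  on.exit(close(log_con), add = TRUE)
  say <- function(...) writeLines(sprintf(...), log_con)

  say("experiment start: seed=%d strategy=%s selector=%s",
      cfg$seed, cfg$strategy, cfg$selector)
  study <- stage("simulate", generate_pair_study(cfg$syn, cfg$strategy))
  stage("encode", export_pair_study(study, file.path(cfg$out, "data")))
  lab <- study_labeled(study)
  unl <- study_unlabeled(study)
  say("simulated %d labeled + %d unlabeled pairs, %d features",
      nrow(lab$X), if (is.null(unl)) 0L else nrow(unl), ncol(lab$X))

  screen <- stage("select", {
    sc <- select_by_ellipse(binarize(lab$X), lab$y, cfg$n_features)
    export_feature_screen(sc, file.path(cfg$out, "screen"))
    sc
  })
  written$screen <- file.path(cfg$out, "screen.tsv")

  if ("evaluate" %in% cfg$experiments) {
    res <- stage("evaluate",
                 loocv(cfg$spec, lab$X, lab$y, unlabeled = unl,
                       selector = cfg$selector, n_features = cfg$n_features))
    export_metrics(res$metrics, file.path(cfg$out, "loocv_metrics"),
                   roc = res$roc)
    written$loocv <- file.path(cfg$out, "loocv_metrics.json")
    say("LOOCV %s: AUC %.4f", cfg$spec$algorithm, res$roc$auc)
    if (cfg$spec$algorithm == "improved_nb") {
      fit <- stage("train", {
        keep <- screen$selected
        train_baseline(cfg$spec, lab$X[, keep, drop = FALSE], lab$y,
                       unlabeled = if (is.null(unl)) NULL
                                   else unl[, keep, drop = FALSE])
      })
      write_improved_nb(fit$model, file.path(cfg$out, "model.json"))
      written$model <- file.path(cfg$out, "model.json")
    }
  }

  if ("benchmark" %in% cfg$experiments) {
    bench <- stage("benchmark", {
      algos <- c("improved_nb", "categorical_nb", "knn", "svm_rbf")
      do.call(rbind, lapply(algos, function(a) {
        r <- loocv(classifier_spec(a), lab$X, lab$y, unlabeled = unl,
                   selector = cfg$selector, n_features = cfg$n_features)
        cbind(data.frame(algorithm = a, auc = r$roc$auc),
              as.data.frame(r$metrics)[1:6])
      }))
    })
    f <- file.path(cfg$out, "benchmark.tsv")
    utils::write.table(bench, f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    jsonlite::write_json(bench, file.path(cfg$out, "benchmark.json"),
                         digits = NA, dataframe = "rows")
    written$benchmark <- f
    say("benchmark AUCs: %s",
        paste(sprintf("%s=%.4f", bench$algorithm, bench$auc),
              collapse = ", "))
  }

  if ("ratio-sweep" %in% cfg$experiments) {
    sweep_res <- stage("ratio-sweep", {
      ds <- study$dataset
      pos <- ds$pairs[!is.na(ds$y) & ds$y == 1L, , drop = FALSE]
      ratio_sweep(study$universe, pos, cfg$spec, strategy = cfg$strategy,
                  universe = study$universe$drug_ids,
                  selector = cfg$selector, n_features = cfg$n_features,
                  unlabeled = unl, seed = cfg$seed + 100L)
    })
    df <- do.call(rbind, lapply(names(sweep_res), function(r) {
      cbind(data.frame(ratio = r, auc = sweep_res[[r]]$roc$auc),
            as.data.frame(sweep_res[[r]]$metrics)[1:6])
    }))
    f <- file.path(cfg$out, "ratio_sweep.tsv")
    utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
    written$ratio_sweep <- f
  }

  if ("yrandom" %in% cfg$experiments) {
    yr <- stage("yrandom",
                y_randomization(cfg$spec, lab$X, lab$y, unlabeled = unl,
                                selector = cfg$selector,
                                n_features = cfg$n_features,
                                seed = cfg$seed + 200L))
    payload <- list(original_auc = yr$original_auc,
                    shuffled_auc = yr$shuffled_auc)
    f <- file.path(cfg$out, "yrandom.json")
    jsonlite::write_json(payload, f, digits = NA)
    written$yrandom <- f
    say("y-randomization: original %.4f vs shuffled %s", yr$original_auc,
        paste(sprintf("%.4f", yr$shuffled_auc), collapse = ", "))
  }

  ## echo the manifest (the only file allowed to differ between replays)
  echo <- list(manifest = manifest, resolved_seed = cfg$seed,
               package_version = as.character(utils::packageVersion("combiNB")),
               timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(echo, file.path(cfg$out, "manifest_echo.json"),
                       auto_unbox = TRUE, null = "null")
  invisible(written)
}
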