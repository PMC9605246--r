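## File formats and experiment driver.
##
## Channel files use the Empatica E4 export dialect: line 1 = session
## start as a UNIX timestamp, line 2 = sampling rate in Hz, then one
## sample per line (the ACC file carries three comma-separated columns).
## Labels are a two-column CSV (second_index, condition).  A YAML manifest
## ties a cohort's files together; a YAML experiment config drives the
## four pipeline stages.

fmt_num <- function(x) sprintf("%.10g", x)

#' Write one channel in the E4 export dialect
#'
#' @param path Output file.
#' @param start_timestamp Session start, UNIX seconds.
#' @param rate Sampling rate, Hz.
#' @param samples Numeric vector, or an n x 3 matrix for the combined
#'   accelerometer file.
#' @return `path`, invisibly.
#' @export
write_channel_csv <- function(path, start_timestamp, rate, samples) {
  body <- if (is.matrix(samples)) {
    apply(samples, 1, function(r) paste(fmt_num(r), collapse = ","))
  } else {
    fmt_num(samples)
  }
  writeLines(c(fmt_num(start_timestamp), fmt_num(rate), body), path)
  invisible(path)
}

#' Read one E4-dialect channel file
#'
#' @param path Channel CSV path.
#' @return `list(start_timestamp, rate, samples)`; `samples` is a matrix
#'   when the body has several columns.
#' @export
read_channel_csv <- function(path) {
  if (!file.exists(path)) {
    stop_with("stressfl_missing_file", "no such channel file: %s", path)
  }
  lines <- readLines(path)
  if (length(lines) < 2) {
    stop_with("stressfl_malformed_header",
              "%s: need timestamp and rate header lines", path)
  }
  ts <- suppressWarnings(as.numeric(lines[1]))
  rate <- suppressWarnings(as.numeric(lines[2]))
  if (is.na(ts) || is.na(rate) || rate <= 0) {
    stop_with("stressfl_malformed_header",
              "%s: non-numeric timestamp or rate header", path)
  }
  body <- lines[-(1:2)]
  body <- body[nzchar(body)]
  if (length(body) == 0) {
    stop_with("stressfl_empty_body", "%s: no sample lines", path)
  }
  fields <- strsplit(body, ",", fixed = TRUE)
  ncols <- length(fields[[1]])
  vals <- suppressWarnings(as.numeric(unlist(fields)))
  if (any(is.na(vals)) || any(lengths(fields) != ncols)) {
    stop_with("stressfl_bad_sample", "%s: non-numeric sample line", path)
  }
  samples <- if (ncols > 1) {
    matrix(vals, ncol = ncols, byrow = TRUE)
  } else {
    vals
  }
  list(start_timestamp = ts, rate = rate, samples = samples)
}

#' Write / read the per-second label CSV
#'
#' Two columns: `second_index` (0-based) and `condition`.
#'
#' @param labels Character vector of per-second conditions.
#' @param path File path.
#' @return The labels (reader) or `path` invisibly (writer).
#' @export
write_label_csv <- function(labels, path) {
  write.csv(data.frame(second_index = seq_along(labels) - 1L,
                       condition = labels),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_label_csv
#' @export
read_label_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("second_index", "condition") %in% names(df)))
  df$condition[order(df$second_index)]
}

#' Write a cohort to disk with a YAML manifest
#'
#' One directory per participant (`P01`, `P02`, ...) holding `ST.csv`,
#' `ACC.csv` (three columns), `EDA.csv`, `BVP.csv` and `labels.csv`;
#' `manifest.yaml` lists ids, relative paths and rates.
#'
#' @param cohort List of `sensor_recording`s.
#' @param dir Output directory (created if needed).
#' @param start_timestamp Session start written into every channel file.
#' @return Path of the manifest, invisibly.
#' @export
write_cohort <- function(cohort, dir, start_timestamp = 0) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  entries <- lapply(cohort, function(rec) {
    sub <- sprintf("P%02d", rec$participant_id)
    pdir <- file.path(dir, sub)
    dir.create(pdir, showWarnings = FALSE)
    ch <- rec$channels
    write_channel_csv(file.path(pdir, "ST.csv"), start_timestamp,
                      ch$ST$rate, ch$ST$samples)
    acc <- cbind(ch$ACCx$samples, ch$ACCy$samples, ch$ACCz$samples)
    write_channel_csv(file.path(pdir, "ACC.csv"), start_timestamp,
                      ch$ACCx$rate, acc)
    write_channel_csv(file.path(pdir, "EDA.csv"), start_timestamp,
                      ch$EDA$rate, ch$EDA$samples)
    write_channel_csv(file.path(pdir, "BVP.csv"), start_timestamp,
                      ch$BVP$rate, ch$BVP$samples)
    write_label_csv(rec$labels, file.path(pdir, "labels.csv"))
    list(id = rec$participant_id,
         files = list(ST = file.path(sub, "ST.csv"),
                      ACC = file.path(sub, "ACC.csv"),
                      EDA = file.path(sub, "EDA.csv"),
                      BVP = file.path(sub, "BVP.csv"),
                      labels = file.path(sub, "labels.csv")),
         rates = list(ST = ch$ST$rate, ACC = ch$ACCx$rate,
                      EDA = ch$EDA$rate, BVP = ch$BVP$rate))
  })
  manifest <- list(cohort_id = basename(dir), participants = entries)
  path <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(manifest, path)
  invisible(path)
}

#' Load a cohort from a manifest
#'
#' @param manifest_path Path to a `manifest.yaml` written by
#'   [write_cohort()].
#' @return List of `sensor_recording`s.
#' @export
read_cohort <- function(manifest_path) {
  if (!file.exists(manifest_path)) {
    stop_with("stressfl_missing_file", "no manifest at %s", manifest_path)
  }
  man <- yaml::read_yaml(manifest_path)
  base <- dirname(manifest_path)
  lapply(man$participants, function(ent) {
    paths <- lapply(ent$files, function(f) file.path(base, f))
    missing_f <- !vapply(paths, file.exists, TRUE)
    if (any(missing_f)) {
      stop_with("stressfl_missing_file", "manifest references missing: %s",
                toString(unlist(paths)[missing_f]))
    }
    st <- read_channel_csv(paths$ST)
    acc <- read_channel_csv(paths$ACC)
    eda <- read_channel_csv(paths$EDA)
    bvp <- read_channel_csv(paths$BVP)
    structure(list(
      participant_id = as.integer(ent$id),
      channels = list(
        ST = list(rate = st$rate, samples = st$samples),
        ACCx = list(rate = acc$rate, samples = acc$samples[, 1]),
        ACCy = list(rate = acc$rate, samples = acc$samples[, 2]),
        ACCz = list(rate = acc$rate, samples = acc$samples[, 3]),
        EDA = list(rate = eda$rate, samples = eda$samples),
        BVP = list(rate = bvp$rate, samples = bvp$samples)
      ),
      labels = read_label_csv(paths$labels)
    ), class = "sensor_recording")
  })
}

#' Write / read a feature matrix CSV
#'
#' Header row: `participant`, `window_id`, `start_time`, `label` and the
#' 420 registry feature names.
#'
#' @param fm Feature matrix tibble.
#' @param path File path.
#' @return Tibble (reader) or `path` invisibly (writer).
#' @export
write_feature_csv <- function(fm, path) {
  write.csv(fm, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_csv
#' @export
read_feature_csv <- function(path) {
  tibble::as_tibble(read.csv(path, check.names = FALSE))
}

EXPERIMENT_KEYS <- c("cohort", "split", "strategies", "train", "federated",
                     "output_dir", "seed")
COHORT_KEYS <- c("manifest", "n_participants", "atypical_fraction",
                 "session_minutes", "heterogeneity")

#' Load and validate an experiment configuration
#'
#' YAML schema: `cohort` (either `manifest: path` or synthesis parameters
#' `n_participants`, `session_minutes`, `atypical_fraction`), `split`
#' (`train_fraction`, `mode`, `seed`), `strategies` (subset of individual
#' / centralized / federated), `train`, `federated`, `output_dir`, `seed`.
#' Unknown keys are rejected.
#'
#' @param path YAML config path.
#' @return Validated config list.
#' @export
load_experiment_config <- function(path) {
  if (!file.exists(path)) {
    stop_with("stressfl_missing_file", "no config at %s", path)
  }
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), EXPERIMENT_KEYS)
  if (length(unknown) > 0) {
    stop_with("stressfl_bad_config", "unknown config key(s): %s",
              toString(unknown))
  }
  if (is.null(cfg$cohort) || is.null(cfg$seed) || is.null(cfg$output_dir)) {
    stop_with("stressfl_bad_config",
              "config needs cohort, seed and output_dir")
  }
  unknown_c <- setdiff(names(cfg$cohort), COHORT_KEYS)
  if (length(unknown_c) > 0) {
    stop_with("stressfl_bad_config", "unknown cohort key(s): %s",
              toString(unknown_c))
  }
  cfg$strategies <- cfg$strategies %||%
    c("individual", "centralized", "federated")
  bad <- setdiff(cfg$strategies,
                 c("individual", "centralized", "federated"))
  if (length(bad) > 0) {
    stop_with("stressfl_bad_config", "unknown strategy: %s", toString(bad))
  }
  cfg
}

config_plan <- function(cohort_cfg) {
  minutes <- cohort_cfg$session_minutes %||% 36.5
  scale <- minutes * 60 / 2190
  session_plan(data.frame(
    condition = c("neutral", "stress", "amusement"),
    duration = round(c(1200, 600, 390) * scale)
  ))
}

config_split <- function(cfg) {
  s <- cfg$split %||% list()
  split_spec(train_fraction = s$train_fraction %||% 0.8,
             mode = s$mode %||% "stratified_random",
             seed = s$seed %||% cfg$seed)
}

config_train <- function(cfg) {
  t <- cfg$train %||% list()
  train_config(l2_strength = t$l2_strength %||% 1,
               max_iterations = t$max_iterations %||% 100,
               tolerance = t$tolerance %||% 1e-6,
               learning_rate = t$learning_rate %||% 0.1,
               local_epochs = t$local_epochs %||% 1,
               batch_size = t$batch_size %||% 32,
               seed = t$seed %||% cfg$seed)
}

config_federated <- function(cfg) {
  f <- cfg$federated %||% list()
  federated_config(rounds = f$rounds %||% 20,
                   local_epochs = f$local_epochs %||% 1,
                   client_fraction = f$client_fraction %||% 1,
                   train = config_train(cfg),
                   seed = f$seed %||% cfg$seed)
}

log_msg <- function(...) message(sprintf(...))

#' Run a configured experiment end to end
#'
#' Stages: `simulate` (generate or load the cohort, write channel CSVs),
#' `extract` (feature matrices), `run` (the configured strategies,
#' models as JSON and predictions as CSV), `report` (per-strategy metric
#' tables plus the cross-strategy summary).  `all` chains the four.
#'
#' @param config Config list from [load_experiment_config()].
#' @param stage One of `"simulate"`, `"extract"`, `"run"`, `"report"`,
#'   `"all"`.
#' @return Invisibly, a list of output paths.
#' @export
run_experiment <- function(config, stage = "all") {
  out_dir <- config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- if (stage == "all") {
    c("simulate", "extract", "run", "report")
  } else {
    stage
  }
  cohort_dir <- file.path(out_dir, "cohort")
  feat_dir <- file.path(out_dir, "features")
  run_dir <- file.path(out_dir, "runs")
  rep_dir <- file.path(out_dir, "reports")
  paths <- list()

  if ("simulate" %in% stages) {
    cc <- config$cohort
    if (!is.null(cc$manifest)) {
      log_msg("simulate: external manifest %s, nothing to generate",
              cc$manifest)
    } else {
      log_msg("simulate: %d participants, seed %d",
              cc$n_participants %||% 15, config$seed)
      cohort <- generate_cohort(
        n_participants = cc$n_participants %||% 15,
        atypical_fraction = cc$atypical_fraction %||% 0.2,
        seed = config$seed,
        plan = config_plan(cc))
      paths$manifest <- write_cohort(cohort, cohort_dir)
      log_msg("simulate: wrote %s", paths$manifest)
    }
  }

  manifest <- config$cohort$manifest %||% file.path(cohort_dir,
                                                    "manifest.yaml")
  if ("extract" %in% stages) {
    cohort <- read_cohort(manifest)
    dir.create(feat_dir, showWarnings = FALSE)
    paths$features <- vapply(cohort, function(rec) {
      fm <- build_feature_matrix(rec)
      p <- file.path(feat_dir, sprintf("P%02d.csv", rec$participant_id))
      write_feature_csv(fm, p)
      log_msg("extract: participant %d -> %d windows x %d features",
              rec$participant_id, nrow(fm), length(feature_columns(fm)))
      p
    }, "")
  }

  if (any(c("run", "report") %in% stages)) {
    feat_files <- sort(list.files(feat_dir, pattern = "^P\\d+\\.csv$",
                                  full.names = TRUE))
    if (length(feat_files) == 0) {
      stop_with("stressfl_missing_file",
                "no feature matrices under %s; run the extract stage",
                feat_dir)
    }
    matrices <- lapply(feat_files, read_feature_csv)
  }

  if ("run" %in% stages) {
    dir.create(run_dir, showWarnings = FALSE)
    sp <- config_split(config)
    tc <- config_train(config)
    for (strat in config$strategies) {
      log_msg("run: %s (split seed %d)", strat, sp$seed)
      res <- switch(strat,
        individual = run_individual(matrices, sp, tc),
        centralized = run_centralized(matrices, sp, tc),
        federated = run_federated(matrices, sp, config_federated(config)))
      for (mn in names(res$models)) {
        model_to_json(res$models[[mn]],
                      file.path(run_dir,
                                sprintf("%s-model-%s.json", strat, mn)),
                      config = tc)
      }
      pred <- do.call(rbind, Map(function(pid, pr) {
        cbind(participant = pid, pr)
      }, names(res$predictions), res$predictions))
      p <- file.path(run_dir, sprintf("%s-predictions.csv", strat))
      write.csv(pred, p, row.names = FALSE, quote = FALSE)
      paths[[paste0(strat, "_predictions")]] <- p
      log_msg("run: %s -> %d test predictions", strat, nrow(pred))
    }
  }

  if ("report" %in% stages) {
    dir.create(rep_dir, showWarnings = FALSE)
    reports <- list()
    for (strat in config$strategies) {
      p <- file.path(run_dir, sprintf("%s-predictions.csv", strat))
      if (!file.exists(p)) {
        stop_with("stressfl_missing_file",
                  "no predictions for %s; run the run stage", strat)
      }
      pred <- read.csv(p, stringsAsFactors = FALSE)
      res <- new_strategy_result(strat, list(), lapply(
        split(pred, factor(pred$participant,
                           levels = unique(pred$participant))),
        tibble::as_tibble))
      rep <- evaluate_strategy(res)
      write_report(rep,
                   file.path(rep_dir, sprintf("%s-report.csv", strat)),
                   file.path(rep_dir, sprintf("%s-report.json", strat)))
      reports[[strat]] <- rep
      paths[[paste0(strat, "_report")]] <-
        file.path(rep_dir, sprintf("%s-report.csv", strat))
    }
    cmp <- compare_strategies(reports)
    cmp_path <- file.path(rep_dir, "strategy-comparison.csv")
    cmp_out <- cmp
    cmp_out[-1] <- lapply(cmp_out[-1], function(x) sprintf("%.4f", x))
    write.csv(cmp_out, cmp_path, row.names = FALSE, quote = FALSE)
    paths$comparison <- cmp_path
    log_msg("report: wrote %s", cmp_path)
  }

  invisible(paths)
}

cli_usage <- function() {
  paste(
    "usage: stressfl <simulate|extract|run|report|all> --config <path>",
    "", sep = "\n")
}

#' Command-line style entry point
#'
#' Thin argv wrapper over [run_experiment()]: subcommands `simulate`,
#' `extract`, `run`, `report`, `all`, each taking `--config <path>`.
#'
#' @param argv Character vector of arguments, e.g.
#'   `c("all", "--config", "experiment.yaml")`.
#' @return Integer exit code: 0 on success, 2 on usage errors, 1 on
#'   runtime failure.
#' @export
run_experiment_cli <- function(argv) {
  subcommands <- c("simulate", "extract", "run", "report", "all")
  if (length(argv) < 1 || !argv[1] %in% subcommands) {
    message(cli_usage())
    return(2L)
  }
  ci <- which(argv == "--config")
  if (length(ci) != 1 || ci + 1 > length(argv)) {
    message(cli_usage())
    return(2L)
  }
  tryCatch({
    cfg <- load_experiment_config(argv[ci + 1])
    run_experiment(cfg, stage = argv[1])
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
}

#' Experimental WESAD directory adapter
#'
#' Minimal reader for an on-disk layout with per-participant
#' subdirectories holding E4-dialect channel CSVs (`ST.csv`, `ACC.csv`,
#' `EDA.csv`, `BVP.csv`) and a `labels.csv`.  Untested against the real
#' dataset distribution; provided as a starting point only.
#'
#' @param dir Dataset root directory.
#' @return List of `sensor_recording`s.
#' @keywords internal
#' @export
read_wesad_dir <- function(dir) {
  subs <- list.dirs(dir, recursive = FALSE)
  recs <- list()
  for (sub in subs) {
    id <- as.integer(gsub("\\D", "", basename(sub)))
    if (is.na(id)) next
    fake_manifest <- list(participants = list(list(
      id = id,
      files = list(ST = "ST.csv", ACC = "ACC.csv", EDA = "EDA.csv",
                   BVP = "BVP.csv", labels = "labels.csv"))))
    man_path <- file.path(sub, ".stressfl-manifest.yaml")
    yaml::write_yaml(fake_manifest, man_path)
    on.exit(unlink(man_path), add = TRUE)
    recs <- c(recs, read_cohort(man_path))
  }
  recs
}
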