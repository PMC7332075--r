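TRIAL_FIELDS <- c("session_id", "trial", "forced_stage", "error_code", "a1",
                  "s2", "transition", "a2", "outcome_level", "juice_ms",
                  "reward", "rt1", "rt2", "fix_rt", "side1", "side2")

#' Write sessions to a tidy per-trial CSV
#'
#' One row per trial across all sessions, columns matching the trial-record
#' fields plus `subject_id`. The latent outcome schedule is not serialized.
#'
#' @param sessions list of `session_data` frames (or one).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sessions_csv <- function(sessions, path) {
  sessions <- session_list(sessions)
  rows <- lapply(sessions, function(s) {
    s$subject_id <- attr(s, "subject_id") %||% NA_character_
    as.data.frame(s)[c(TRIAL_FIELDS, "subject_id")]
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read sessions from the tidy per-trial CSV dialect
#'
#' @param path file written by [write_sessions_csv()] (or matching its
#'   layout).
#' @return list of `session_data` frames, trial order preserved.
#' @export
read_sessions_csv <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(TRIAL_FIELDS, names(d))
  if (length(missing))
    stop("missing mandatory column(s): ", paste(missing, collapse = ", "))
  for (col in c("juice_ms", "reward", "rt1", "rt2", "fix_rt"))
    d[[col]] <- as.numeric(d[[col]])
  lapply(split(d, d$session_id), function(s) {
    s <- s[order(s$trial), ]
    subject <- if ("subject_id" %in% names(s)) s$subject_id[1] else NA
    juice <- s$juice_ms[s$error_code == "none"]
    structure(s[TRIAL_FIELDS],
              max_juice_ms = if (length(juice) && any(juice > 0, na.rm = TRUE))
                max(juice, na.rm = TRUE) else 0,
              subject_id = subject,
              class = c("session_data", "data.frame"))
  })
}

# human-readable names used in reader error messages
FIELD_LABELS <- c(a1 = "first-stage choice", a2 = "second-stage choice",
                  s2 = "second-stage state", outcome_level = "outcome level",
                  transition = "transition type", session_id = "session id",
                  trial = "trial index")

#' Glossary-driven reader for a deposited per-trial dataset
#'
#' Reads a per-trial table whose column names are defined by an accompanying
#' glossary (a two-column table mapping each source `column` to a canonical
#' trial-record `field`), rather than hard-coding names. Unmapped source
#' columns are preserved as passthrough. The study's exclusion rules (error
#' trials; forced trials) can be applied on demand while the raw rows are
#' retained.
#'
#' Categorical codings are normalized: actions given as 1/2 become x/y,
#' second-stage states 1/2 become B/C, transitions 0/1 become common/rare
#' (rare = 1), and a logical/0-1 `forced` column is accepted for
#' `forced_stage` meaning "forced at stage 1".
#'
#' @param path CSV file with one row per trial.
#' @param glossary_path CSV file with columns `column` and `field`.
#' @param exclude_errors,exclude_forced apply the analysis exclusions to the
#'   returned sessions.
#' @return a `dataset_bundle`: list with `sessions` (list of `session_data`),
#'   `raw` (the untouched table), `passthrough` (unmapped column names), and
#'   `n_dropped`.
#' @export
read_deposited_dataset <- function(path, glossary_path,
                                   exclude_errors = FALSE,
                                   exclude_forced = FALSE) {
  gl <- read.csv(glossary_path, stringsAsFactors = FALSE)
  if (!all(c("column", "field") %in% names(gl)))
    stop("glossary must have 'column' and 'field' columns")
  raw <- tryCatch(read.csv(path, stringsAsFactors = FALSE),
                  error = function(e) stop("unparseable dataset container: ",
                                           conditionMessage(e)))
  dup <- gl$field[duplicated(gl$field)]
  if (length(dup))
    stop("glossary maps several columns to: ", paste(dup, collapse = ", "))
  gl <- gl[gl$column %in% names(raw), , drop = FALSE]
  mandatory <- c("session_id", "trial", "a1", "s2", "a2", "outcome_level",
                 "transition")
  absent <- setdiff(mandatory, gl$field)
  if (length(absent))
    stop("glossary missing mandatory field(s): ",
         paste(FIELD_LABELS[absent], collapse = ", "))
  d <- raw
  names(d)[match(gl$column, names(raw))] <- gl$field
  passthrough <- setdiff(names(raw), gl$column)
  if (!"forced_stage" %in% names(d)) d$forced_stage <- 0L
  if (is.logical(d$forced_stage)) d$forced_stage <- as.integer(d$forced_stage)
  if (!"error_code" %in% names(d)) d$error_code <- "none"
  if (is.numeric(d$a1)) d$a1 <- c("x", "y")[d$a1]
  if (is.numeric(d$a2)) d$a2 <- c("x", "y")[d$a2]
  if (is.numeric(d$s2)) d$s2 <- c("B", "C")[d$s2]
  if (is.numeric(d$transition))
    d$transition <- c("common", "rare")[d$transition + 1]
  for (f in setdiff(TRIAL_FIELDS, names(d))) d[[f]] <- NA
  sessions <- lapply(split(d, d$session_id), function(s) {
    s <- s[order(s$trial), ]
    ok <- s$error_code == "none"
    juice <- s$juice_ms[ok]
    has_juice <- length(juice) && any(is.finite(juice) & juice > 0)
    if (all(is.na(s$reward)) && has_juice)
      s$reward <- s$juice_ms / max(juice, na.rm = TRUE)
    structure(s[c(TRIAL_FIELDS, intersect(passthrough, names(s)))],
              max_juice_ms = if (has_juice) max(juice, na.rm = TRUE) else 0,
              subject_id = if ("subject_id" %in% names(s)) s$subject_id[1]
                           else NA,
              class = c("session_data", "data.frame"))
  })
  n_raw <- sum(vapply(sessions, nrow, numeric(1)))
  if (exclude_errors || exclude_forced)
    sessions <- lapply(sessions, analyzed_trials,
                       drop_forced = exclude_forced,
                       drop_errors = exclude_errors)
  structure(list(sessions = sessions, raw = raw, passthrough = passthrough,
                 n_dropped = n_raw - sum(vapply(sessions, nrow, numeric(1)))),
            class = "dataset_bundle")
}

#' Run a named pipeline stage and write its artifacts
#'
#' Thin dispatcher over the package's analysis stages, for scripted use.
#' Every run writes a `manifest.json` (command, seed, parameters, package
#' version, artifact list, dropped-trial counts) next to its outputs, so any
#' artifact is regenerable from its manifest alone.
#'
#' Commands: `simulate` (synthetic subject to CSV), `fit` (hierarchical fit
#' of one model to a dataset CSV), `compare` (fit several models and report
#' BIC, integrated BIC and protected exceedance probability), `regress`
#' (stay table, lagged choice regression and decay fits), `recover`
#' (parameter recovery on a grid).
#'
#' @param config named list: `command`, `out_dir`, `seed`, and per-command
#'   fields (`model`/`models`, `data` for a CSV path, `n_sessions`,
#'   `n_trials`, `fit_args`, `K`, `grid`).
#' @return the manifest, invisibly.
#' @export
run_command <- function(config) {
  cmd <- config$command %||% stop("config$command required")
  known <- c("simulate", "fit", "compare", "regress", "recover")
  if (!cmd %in% known)
    stop("unknown command '", cmd, "'; expected one of: ",
         paste(known, collapse = ", "))
  out_dir <- config$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed %||% 1L)
  fit_args <- config$fit_args %||% list()
  artifacts <- character(0)
  info <- list()
  emit <- function(name) { artifacts <<- c(artifacts, name); file.path(out_dir, name) }

  load_data <- function() {
    if (!is.null(config$data)) read_sessions_csv(config$data)
    else generate_subject_dataset(subject_profile(
      model = config$model %||% "HybridPlus",
      n_sessions = config$n_sessions %||% 10,
      trials_mean = config$n_trials %||% 500, seed = seed))
  }

  if (cmd == "simulate") {
    ds <- load_data()
    write_sessions_csv(ds, emit("sessions.csv"))
    tp <- attr(ds, "true_params")
    if (!is.null(tp)) write.csv(tp, emit("true_params.csv"), row.names = FALSE)
    info$n_sessions <- length(ds)
  } else if (cmd == "fit") {
    ds <- load_data()
    spec <- model_registry()[[config$model %||% "HybridPlus"]]
    fit <- do.call(fit_empirical_bayes,
                   c(list(sessions = ds, spec = spec, seed = seed), fit_args))
    maps <- as.data.frame(t(sapply(fit$fits, `[[`, "map_params")))
    maps$session <- seq_len(nrow(maps))
    maps$nll <- sapply(fit$fits, `[[`, "nll")
    write.csv(maps, emit("session_maps.csv"), row.names = FALSE)
    jsonlite::write_json(list(model = spec$name,
                              prior_mu_natural = as.list(fit$prior$mu_natural),
                              prior_mu = as.list(fit$prior$mu),
                              prior_sigma = as.list(fit$prior$sigma),
                              converged = fit$converged,
                              n_iter = fit$n_iter),
                         emit("prior.json"), auto_unbox = TRUE, digits = NA)
    info$converged <- fit$converged
  } else if (cmd == "compare") {
    ds <- load_data()
    models <- config$models %||% c("SARSA", "Forward1", "Hybrid", "HybridPlus")
    reg <- model_registry()
    lme <- matrix(NA_real_, length(ds), length(models),
                  dimnames = list(NULL, models))
    rows <- list()
    for (m in models) {
      fit <- do.call(fit_empirical_bayes,
                     c(list(sessions = ds, spec = reg[[m]], seed = seed),
                       fit_args))
      bi <- bic_int(ds, fit$prior, reg[[m]], K = config$K %||% 1000,
                    seed = seed)
      nll <- sum(sapply(fit$ml_fits, `[[`, "nll"))
      nobs <- sum(sapply(fit$ml_fits, `[[`, "n_obs"))
      lme[, m] <- bi$session_lme
      rows[[m]] <- data.frame(
        model = m, k_free = length(reg[[m]]$free), total_nll = nll,
        bic = bic(-nll, length(reg[[m]]$free) * length(ds), nobs),
        bic_int = bi$bic_int,
        pred_prob = predictive_probability(-nll, nobs)$prob)
    }
    rep_df <- do.call(rbind, rows)
    rep_df$pep <- protected_exceedance_probability(lme, seed = seed)$pep
    write.csv(rep_df, emit("model_comparison.csv"), row.names = FALSE)
    info$best <- rep_df$model[which.min(rep_df$bic_int)]
  } else if (cmd == "regress") {
    ds <- load_data()
    st <- stay_table(ds)
    write.csv(st$per_session, emit("stay_table.csv"), row.names = FALSE)
    fx <- fit_logistic_fixed(build_choice_design(ds))
    write.csv(fx$summary, emit("choice_regression.csv"), row.names = FALSE)
    dec <- lapply(c(RxC = "RxC", RxTxC = "RxTxC"), function(b) {
      f <- fit_decay(fx$summary$mean[match(paste0(b, "_lag", 1:5),
                                           fx$summary$term)])
      list(A = f$A, b = f$b, adj_r2 = f$adj_r2)
    })
    jsonlite::write_json(dec, emit("decay_fits.json"), auto_unbox = TRUE,
                         digits = NA)
    info$n_flagged <- length(fx$flags)
  } else if (cmd == "recover") {
    spec <- model_registry()[[config$model %||% "HybridPlus"]]
    grid <- config$grid %||% {
      base <- preset_params(config$model %||% "HybridPlus")
      lapply(c(0.1, 0.5, 0.9), function(w) { base["omega"] <- w; base })
    }
    rec <- parameter_recovery(spec, grid,
                              n_sessions = config$n_sessions %||% 10,
                              n_trials = config$n_trials %||% 500,
                              seed = seed, fit_args = fit_args)
    write.csv(rec$per_session, emit("recovery_sessions.csv"),
              row.names = FALSE)
    write.csv(rec$summary, emit("recovery_summary.csv"), row.names = FALSE)
    info$rank_cor <- rec$summary$rank_cor[rec$summary$parameter == "omega"]
  }

  manifest <- list(command = cmd, seed = seed,
                   package = as.character(utils::packageVersion("twostepRL")),
                   timestamp = format(Sys.time(), tz = "UTC"),
                   config = config[setdiff(names(config), "out_dir")],
                   artifacts = artifacts, info = info)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}
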