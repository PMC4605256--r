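#' Pipeline configuration
#'
#' Collects all module parameters. Defaults reproduce the documented design
#' choices: 6D embeddings, delayed-embedding lag 3 for phase-dependent
#' stability, Wolf exponent with dimension 6 / lag 8, four PLS latent
#' variables, leave-one-out cross-validation.
#'
#' @param bout a [bout_params()] list.
#' @param lag delay (samples) of the phase-dependent delayed embedding.
#' @param phases step-cycle phases at which lambda is computed.
#' @param radius,phase_tol,theiler neighbourhood parameters of
#'   [reaction_curve()].
#' @param wolf_dim,wolf_lag Wolf embedding dimension and delay (samples).
#' @param ncomp PLS latent variables.
#' @param seed integer seed recorded for provenance (the analysis itself is
#'   deterministic).
#' @param ... overrides stored verbatim.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(bout = bout_params(), lag = 3, phases = LDS_PHASES,
                            radius = NULL, phase_tol = 0.05, theiler = 1,
                            wolf_dim = 6, wolf_lag = 8, ncomp = 4,
                            seed = NULL, ...) {
  cfg <- c(as.list(environment()), list(...))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Analyse one subject's recording
#'
#' Detects walking bouts, preprocesses each bout, computes phase-dependent
#' lambda for both state-space constructions, the per-axis Wolf exponent and
#' the conventional gait features, and aggregates to subject level (median
#' across bouts; totals over the recording).
#'
#' @param rec a [triaxial_recording].
#' @param config a [pipeline_config()].
#' @return list: `features` (named vector of the 46 features), `lambda_bouts`
#'   (per-bout lambda table), `log` (counts of bouts found/rejected and
#'   stride exclusions).
#' @export
analyze_subject <- function(rec, config = pipeline_config()) {
  fs <- rec$sample_rate
  bouts <- detect_walking_bouts(rec, config$bout)
  log <- list(subject_id = rec$subject_id, n_bouts = nrow(bouts),
              n_rejected = 0L, excluded_fraction = NA_real_)
  empty <- list(features = NULL, lambda_bouts = NULL, log = log)
  if (nrow(bouts) == 0) return(empty)

  feat_rows <- list(); lam_rows <- list(); wolf_rows <- list()
  steps_list <- list(); durations <- numeric(0); excl <- numeric(0)

  for (b in seq_len(nrow(bouts))) {
    acc <- bout_acc(rec, bouts[b, ])
    prep <- tryCatch(preprocess_bout(acc, fs),
                     gaitlds_bout_rejected = function(e) NULL)
    if (is.null(prep)) { log$n_rejected <- log$n_rejected + 1L; next }

    traj_diff <- embed_differential(prep$acc, prep$vel, prep$steps)
    traj_lag <- embed_delayed(prep$vel, l = config$lag, prep$steps)
    args <- list(radius = config$radius, phase_tol = config$phase_tol,
                 theiler = config$theiler)
    ld <- do.call(bout_phase_lambda,
                  c(list(traj_diff, prep$steps, phases = config$phases), args))
    ll <- do.call(bout_phase_lambda,
                  c(list(traj_lag, prep$steps, phases = config$phases), args))
    ld$embedding <- "diff"; ll$embedding <- "lag"
    lam <- rbind(ld, ll)
    lam$bout <- b
    lam_rows[[length(lam_rows) + 1]] <- lam
    excl <- c(excl, mean(lam$excluded_fraction))

    wolf <- vapply(1:3, function(j)
      wolf_lambda(prep$acc[, j], fs, dim = config$wolf_dim,
                  lag = config$wolf_lag), numeric(1))
    names(wolf) <- paste0("wolf_", AXES)
    wolf_rows[[length(wolf_rows) + 1]] <- wolf

    feat_rows[[length(feat_rows) + 1]] <-
      bout_gait_features(prep$acc, prep$steps, fs)
    steps_list[[length(steps_list) + 1]] <- prep$steps
    durations <- c(durations, bouts$duration[b])
  }
  if (length(feat_rows) == 0) return(empty)

  lambda_bouts <- do.call(rbind, lam_rows)
  lambda_bouts$subject_id <- rec$subject_id

  med_feats <- apply(do.call(rbind, feat_rows), 2, median, na.rm = TRUE)
  med_wolf <- apply(do.call(rbind, wolf_rows), 2, median, na.rm = TRUE)
  timing <- timing_features(durations, steps_list, nrow(rec$acc), fs)

  lam_feats <- vapply(PHASE_LAMBDA_FEATURES, function(f) {
    parts <- strsplit(f, "_")[[1]]  # lambda, <embedding>, p<phase>, eq<e>
    emb <- parts[2]
    ph <- as.numeric(sub("p", "", parts[3])) / 100
    eq <- as.integer(sub("eq", "", parts[4]))
    sel <- lambda_bouts$embedding == emb &
      abs(lambda_bouts$phase - ph) < 1e-9 & lambda_bouts$eq == eq
    subject_lambda(lambda_bouts$lambda[sel])
  }, numeric(1))

  log$excluded_fraction <- mean(excl)
  features <- c(lam_feats, med_wolf, med_feats, timing)[feature_names()]
  list(features = features, lambda_bouts = lambda_bouts, log = log)
}

#' Run the full analysis pipeline on a cohort
#'
#' recordings -> walking bouts -> preprocessing -> phase-dependent and Wolf
#' stability -> gait features -> PLS-DA with target projection,
#' leave-one-out classification metrics per predictor matrix, Mann-Whitney
#' group comparison, and first-third vs last-third ICC of the
#' phase-dependent stability features.
#'
#' @param cohort either the result of [simulate_cohort()], a list with
#'   `recordings` and `manifest`, or the path of a `manifest.csv`
#'   (subject_id, group, file) whose files sit alongside it.
#' @param config a [pipeline_config()].
#' @return list of class `gaitlds_results`: `features`, `lambda_bouts`,
#'   `matrices`, `metrics` (per predictor matrix), `tp` (target-projection
#'   loadings for X1), `group_tests`, `icc`, `log`, `config`.
#' @export
run_pipeline <- function(cohort, config = pipeline_config()) {
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  recs <- cohort$recordings
  manifest <- cohort$manifest
  if (length(recs) == 0) stop_data("empty cohort")

  res <- lapply(manifest$subject_id, function(id)
    analyze_subject(recs[[id]], config))
  ok <- !vapply(res, function(r) is.null(r$features), logical(1))
  if (!all(ok)) warning(sum(!ok), " subject(s) without usable bouts dropped")
  res <- res[ok]
  manifest <- manifest[ok, , drop = FALSE]
  if (nrow(manifest) == 0) stop_data("no subject produced features")

  features <- data.frame(subject_id = manifest$subject_id,
                         do.call(rbind, lapply(res, `[[`, "features")),
                         row.names = NULL, check.names = FALSE)
  lambda_bouts <- do.call(rbind, lapply(res, `[[`, "lambda_bouts"))
  y <- as.integer(manifest$group == "faller")

  mats <- assemble_matrices(features, scale = FALSE)
  metrics <- lapply(mats[c("X1", "X2", "X3")], function(X)
    cross_validate(X, y, ncomp = min(config$ncomp, ncol(X))))

  fit <- fit_pls_nipals(mats$X1, y, ncomp = config$ncomp,
                        on_constant = "zero")
  tp <- target_projection(fit)

  group_tests <- group_compare(features[, feature_names()], manifest$group)

  icc <- lambda_split_icc(lambda_bouts, manifest$subject_id)

  structure(
    list(features = features, lambda_bouts = lambda_bouts,
         matrices = mats, metrics = metrics, tp = tp,
         group_tests = group_tests, icc = icc,
         manifest = manifest, y = y,
         log = lapply(res, `[[`, "log"), config = config),
    class = "gaitlds_results")
}

#' Test-retest ICC of phase-dependent stability across bout splits
#'
#' Per-subject medians over the first and last third of each subject's
#' bouts, compared by ICC(A,1), for each of the eight phase-dependent
#' stability features.
#'
#' @param lambda_bouts per-bout lambda table from [run_pipeline()].
#' @param subject_ids subjects to include.
#' @return data.frame: feature, icc, lower, upper, n.
#' @export
lambda_split_icc <- function(lambda_bouts, subject_ids) {
  split_median <- function(sub, emb, ph, eq, which_third) {
    d <- lambda_bouts[lambda_bouts$subject_id == sub &
                        lambda_bouts$embedding == emb &
                        abs(lambda_bouts$phase - ph) < 1e-9 &
                        lambda_bouts$eq == eq, ]
    if (nrow(d) == 0) return(NA_real_)
    bts <- sort(unique(d$bout))
    third <- max(1L, floor(length(bts) / 3))
    sel <- if (which_third == 1) head(bts, third) else tail(bts, third)
    subject_lambda(d$lambda[d$bout %in% sel])
  }
  rows <- lapply(PHASE_LAMBDA_FEATURES, function(f) {
    parts <- strsplit(f, "_")[[1]]
    emb <- parts[2]
    ph <- as.numeric(sub("p", "", parts[3])) / 100
    eq <- as.integer(sub("eq", "", parts[4]))
    a <- vapply(subject_ids, split_median, numeric(1), emb, ph, eq, 1)
    b <- vapply(subject_ids, split_median, numeric(1), emb, ph, eq, 2)
    r <- tryCatch(icc_absolute(a, b), error = function(e) NULL)
    data.frame(feature = f,
               icc = r$icc %||% NA_real_, lower = r$lower %||% NA_real_,
               upper = r$upper %||% NA_real_, n = r$n %||% 0L)
  })
  do.call(rbind, rows)
}

#' Read a cohort from a manifest file
#'
#' @param manifest_path path to `manifest.csv` with columns subject_id,
#'   group, file (paths relative to the manifest directory).
#' @return list with `recordings` and `manifest`, as [simulate_cohort()].
#' @export
read_cohort <- function(manifest_path) {
  manifest <- read.csv(manifest_path, stringsAsFactors = FALSE)
  dir <- dirname(manifest_path)
  recs <- lapply(seq_len(nrow(manifest)), function(i) {
    read_recording(file.path(dir, manifest$file[i]),
                   subject_id = manifest$subject_id[i],
                   group = manifest$group[i])
  })
  names(recs) <- manifest$subject_id
  list(recordings = recs, manifest = manifest[c("subject_id", "group")])
}

#' Write a results bundle to disk
#'
#' @param results a `gaitlds_results` bundle.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_results <- function(results, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(results$features, file.path(dir, "features.csv"), row.names = FALSE)
  write.csv(results$lambda_bouts, file.path(dir, "lambda_bouts.csv"),
            row.names = FALSE)
  write.csv(data.frame(feature = names(results$tp$loadings),
                       tp_loading = results$tp$loadings),
            file.path(dir, "tp_loadings.csv"), row.names = FALSE)
  write.csv(results$icc, file.path(dir, "icc.csv"), row.names = FALSE)
  write.csv(results$group_tests, file.path(dir, "group_tests.csv"),
            row.names = FALSE)
  for (m in names(results$metrics)) {
    write.csv(results$metrics[[m]]$roc,
              file.path(dir, paste0("roc_", m, ".csv")), row.names = FALSE)
  }
  metrics <- lapply(results$metrics, function(m)
    m[c("sensitivity", "specificity", "auc", "error")])
  jsonlite::write_json(metrics, file.path(dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Human-readable summary of a results bundle
#'
#' @param results a `gaitlds_results` bundle.
#' @return character vector of report lines (also printed).
#' @export
make_report <- function(results) {
  lines <- c("Phase-dependent local dynamic stability: cohort report",
             sprintf("Subjects: %d (%d fallers / %d nonfallers)",
                     nrow(results$manifest), sum(results$y == 1),
                     sum(results$y == 0)),
             "", "Classification (leave-one-out):")
  for (m in names(results$metrics)) {
    mt <- results$metrics[[m]]
    lines <- c(lines, sprintf(
      "  %s: sensitivity %.2f  specificity %.2f  AUC %.2f  error %.2f",
      m, mt$sensitivity, mt$specificity, mt$auc, mt$error))
  }
  ord <- order(abs(results$tp$loadings), decreasing = TRUE)
  top <- names(results$tp$loadings)[ord][1:8]
  lines <- c(lines, "", "Top |TP| loadings (X1):",
             paste0("  ", seq_along(top), ". ", top, sprintf(
               " (%.2f)", results$tp$loadings[ord][1:8])))
  if (all(is.na(results$icc$icc))) {
    lines <- c(lines, "", "ICC section unavailable (insufficient bouts)")
  } else {
    lines <- c(lines, "", "Test-retest ICC (first vs last third of bouts):",
               sprintf("  %s: %.2f [%.2f, %.2f]", results$icc$feature,
                       results$icc$icc, results$icc$lower, results$icc$upper))
  }
  cat(lines, sep = "\n")
  invisible(lines)
}

#' @export
print.gaitlds_results <- function(x, ...) {
  make_report(x)
  invisible(x)
}
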