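#' Build and validate a pipeline configuration
#'
#' Assembles the configuration driving [run_pipeline()]: the cohort to
#' simulate (or a directory of fixtures to load), the preprocessing and
#' cross-validation settings, group thresholds, screening settings, and the
#' master seed.  Unknown keys are rejected and band edges are validated
#' against Nyquist before any computation.
#'
#' @param cohort Named list of [cohort_spec()] arguments (simulate mode), or
#'   `NULL` when `fixture_dir` is given.
#' @param fixture_dir Directory of fixture recordings to load instead of
#'   simulating (see [write_fixture()]); trials must then be simulated or
#'   supplied separately, so simulate mode is the usual path.
#' @param bands Band table (name/low/high), default [eeg_bands()].
#' @param filter_order Butterworth order for all filtering.
#' @param epoch_len Resting epoch length in samples.
#' @param mi_window Trial window in samples (directory input mode).
#' @param cv List with `folds`, `reps`, `cost` for the MI scoring.
#' @param thresholds H/M/L group thresholds.
#' @param pairs Channel pairs for the scalar features.
#' @param screening List with `folds` for the screening CV.
#' @param features Which features to compute.
#' @param seed Master seed.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(cohort = NULL, fixture_dir = NULL,
                            bands = eeg_bands(), filter_order = 4,
                            epoch_len = 1500, mi_window = 640,
                            cv = list(folds = 10, reps = 10, cost = 1),
                            thresholds = c(40, 60),
                            pairs = default_feature_pairs(),
                            screening = list(folds = 10),
                            features = c("RPL", "PSE", "LZC"),
                            seed = 1L) {
  cfg <- list(cohort = cohort, fixture_dir = fixture_dir, bands = bands,
              filter_order = filter_order, epoch_len = epoch_len,
              mi_window = mi_window, cv = cv,
              thresholds = thresholds, pairs = pairs, screening = screening,
              features = features, seed = as.integer(seed))
  validate_pipeline_config(cfg)
}

validate_pipeline_config <- function(cfg) {
  known <- c("cohort", "fixture_dir", "bands", "filter_order", "epoch_len",
             "mi_window", "cv", "thresholds", "pairs", "screening",
             "features", "seed")
  extra <- setdiff(names(cfg), known)
  if (length(extra))
    stop("unknown configuration key(s): ", paste(extra, collapse = ", "))
  if (is.null(cfg$cohort) && is.null(cfg$fixture_dir))
    stop("configuration needs either `cohort` (simulate) or `fixture_dir`")
  if (is.null(cfg$mi_window)) cfg$mi_window <- 640
  stopifnot(is.data.frame(cfg$bands),
            all(c("name", "low", "high") %in% names(cfg$bands)))
  fs <- if (!is.null(cfg$cohort$sample_rate)) cfg$cohort$sample_rate else 160
  for (i in seq_len(nrow(cfg$bands)))
    validate_band(cfg$bands$low[i], cfg$bands$high[i], fs)
  stopifnot(cfg$cv$folds >= 2, cfg$cv$reps >= 1,
            length(cfg$thresholds) == 2, diff(cfg$thresholds) > 0)
  if (!all(cfg$features %in% c("RPL", "PSE", "LZC")))
    stop("features must be a subset of RPL, PSE, LZC")
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file whose keys mirror [pipeline_config()] arguments.
#' @return A validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$bands)) raw$bands <- as.data.frame(raw$bands)
  do.call(pipeline_config, raw)
}

# Stack several trial sets of one subject (e.g. three runs) into one.
combine_trial_sets <- function(sets) {
  sets <- Filter(function(s) dim(s$data)[3] > 0, sets)
  if (!length(sets)) stop("no trials found")
  d <- dim(sets[[1]]$data)
  stopifnot(all(vapply(sets, function(s)
    all(dim(s$data)[1:2] == d[1:2]), TRUE)))
  data <- array(unlist(lapply(sets, function(s) s$data)),
                c(d[1], d[2], sum(vapply(sets, function(s) dim(s$data)[3], 0L))),
                dimnames = list(dimnames(sets[[1]]$data)[[1]], NULL, NULL))
  new_trial_set(data, unlist(lapply(sets, function(s) as.character(s$labels))),
                sets[[1]]$sample_rate, sets[[1]]$subject_id)
}

#' Load a directory of recordings into resting runs and MI trial sets
#'
#' Reads every `.edf` (see [read_edf()]) or `.rafx` fixture (see
#' [read_fixture()]) file in a directory, splits the recordings by state,
#' and cuts the annotated motor-imagery runs into per-subject trial sets
#' (multiple runs per subject are concatenated).
#'
#' @param dir Directory containing recording files.
#' @param mi_window Trial window in samples for [extract_mi_trials()].
#' @param exclude Subject ids to skip.
#' @return List with `recordings` (resting [eeg_recording()]s) and `trials`
#'   (named list of `trial_set`, one per subject with MI runs).
#' @export
load_recordings_dir <- function(dir, mi_window = 640, exclude = character()) {
  files <- sort(list.files(dir, pattern = "\\.(edf|rafx)$",
                           ignore.case = TRUE, full.names = TRUE))
  if (!length(files)) stop("no .edf or .rafx files in ", dir)
  recs <- lapply(files, function(f)
    if (grepl("\\.edf$", f, ignore.case = TRUE))
      read_edf(f, exclude = exclude) else read_fixture(f))
  recs <- Filter(function(r) !(r$subject_id %in% exclude), recs)
  rest <- Filter(function(r)
    r$state %in% c("eyes_open", "eyes_closed"), recs)
  mi <- Filter(function(r) r$state == "mi_run", recs)
  subj <- unique(vapply(mi, function(r) r$subject_id, ""))
  trials <- lapply(subj, function(s)
    combine_trial_sets(lapply(Filter(function(r) r$subject_id == s, mi),
                              extract_mi_trials, window = mi_window)))
  names(trials) <- subj
  list(recordings = rest, trials = trials)
}

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(cfg), tmp, auto_unbox = TRUE, digits = 12,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}

pipeline_log <- function(...) message("[restalpha] ", ...)

#' Run the full analysis pipeline
#'
#' Simulates (or loads) the cohort, computes the resting-state feature table,
#' scores every subject's MI performance, runs the correlation and contrast
#' analyses, fits the screening classifiers, and writes all intermediate
#' tables (CSV) plus a JSON summary embedding the configuration hash and
#' master seed.  Subjects are processed one at a time, so memory stays flat
#' in cohort size.  Re-running with the same configuration and seed
#' reproduces every output byte for byte.
#'
#' @param config A `pipeline_config` (or list coercible to one).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with all result objects (`ground_truth`,
#'   `features`, `performance`, `correlations`, `band_contrasts`,
#'   `pair_features`, `group_contrasts`, `screening`, `summary`).
#' @export
run_pipeline <- function(config, out_dir = tempfile("restalpha_")) {
  if (!inherits(config, "pipeline_config"))
    config <- validate_pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  pipeline_log("config hash ", hash, ", seed ", config$seed)

  stage <- function(what, sid, expr) tryCatch(expr, error = function(e)
    stop("stage '", what, "' failed for subject ", sid, ": ",
         conditionMessage(e), call. = FALSE))

  if (!is.null(config$cohort)) {
    spec <- do.call(cohort_spec, c(config$cohort, list(seed = config$seed)))
    gt <- ground_truth(spec)
    n <- spec$n_subjects
    feat_rows <- vector("list", n)
    perf_rows <- vector("list", n)
    for (i in seq_len(n)) {
      sid <- gt$subject[i]
      recs <- stage("simulate", sid, list(
        make_resting_recording(spec, i, "eyes_open", gt),
        make_resting_recording(spec, i, "eyes_closed", gt)))
      feat_rows[[i]] <- stage("features", sid, build_feature_table(
        recs, bands = config$bands, features = config$features,
        epoch_len = config$epoch_len, order = config$filter_order))
      trials <- stage("simulate", sid, make_mi_trials(spec, i, gt))
      perf_rows[[i]] <- stage("performance", sid, mi_performance(
        trials, folds = config$cv$folds, reps = config$cv$reps,
        cost = config$cv$cost, seed = derive_seed(config$seed, "cv", i),
        order = config$filter_order, thresholds = config$thresholds))
      if (i %% 10 == 0) pipeline_log("scored ", i, "/", n, " subjects")
    }
  } else {
    gt <- NULL
    loaded <- load_recordings_dir(config$fixture_dir,
                                  mi_window = config$mi_window)
    feat_rows <- list(suppressWarnings(build_feature_table(
      loaded$recordings, bands = config$bands, features = config$features,
      epoch_len = config$epoch_len, order = config$filter_order)))
    perf_rows <- lapply(seq_along(loaded$trials), function(i)
      stage("performance", names(loaded$trials)[i], mi_performance(
        loaded$trials[[i]], folds = config$cv$folds, reps = config$cv$reps,
        cost = config$cv$cost, seed = derive_seed(config$seed, "cv", i),
        order = config$filter_order, thresholds = config$thresholds)))
  }
  features <- do.call(rbind, feat_rows)
  performance <- do.call(rbind, perf_rows)
  pipeline_log("group sizes: ",
               paste(names(table(performance$group)),
                     table(performance$group), collapse = " ", sep = "="))

  cmap <- correlation_map(features, performance, "acc4_mean")
  contrasts <- lapply(intersect(config$features, unique(cmap$feature)),
                      function(ft) tryCatch(
                        band_contrast(cmap, "eyes_open", ft),
                        error = function(e) NULL))
  names(contrasts) <- intersect(config$features, unique(cmap$feature))
  pairf <- channel_pair_average(features, config$pairs)
  gcon <- tryCatch(suppressWarnings(group_contrasts(pairf, performance)),
                   error = function(e) NULL)
  scr_seed <- derive_seed(config$seed, "screening")
  scr_bin <- tryCatch(suppressWarnings(
    screen_binary(pairf, performance, folds = config$screening$folds,
                  seed = scr_seed)), error = function(e) NULL)
  scr_tri <- tryCatch(suppressWarnings(
    screen_three_class(pairf, performance, folds = config$screening$folds,
                       seed = scr_seed)), error = function(e) NULL)

  write.csv(features, file.path(out_dir, "features.csv"), row.names = FALSE)
  write.csv(performance, file.path(out_dir, "performance.csv"),
            row.names = FALSE)
  write.csv(as.data.frame(cmap), file.path(out_dir, "correlations.csv"),
            row.names = FALSE)
  write.csv(pairf, file.path(out_dir, "pair_features.csv"), row.names = FALSE)

  summary <- list(
    config_hash = hash, seed = config$seed,
    n_subjects = nrow(performance),
    group_sizes = as.list(table(performance$group)),
    acc4 = list(mean = mean(performance$acc4_mean),
                range = range(performance$acc4_mean)),
    band_contrasts = lapply(contrasts, function(ct) if (is.null(ct)) NULL else
      list(mauchly_p = ct$mauchly_p, gg_epsilon = ct$gg_epsilon,
           gg_p = ct$gg_p)),
    group_contrasts = gcon,
    screening_binary = if (!is.null(scr_bin))
      lapply(scr_bin, function(s) s$cv_accuracy) else NULL,
    screening_three_class = if (!is.null(scr_tri))
      list(accuracy = scr_tri$cv_accuracy,
           confusion = as.data.frame.matrix(unclass(scr_tri$confusion)))
      else NULL)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE,
                       force = TRUE)
  pipeline_log("summary written to ", file.path(out_dir, "summary.json"))
  invisible(list(ground_truth = gt, features = features,
                 performance = performance, correlations = cmap,
                 band_contrasts = contrasts, pair_features = pairf,
                 group_contrasts = gcon,
                 screening = list(binary = scr_bin, three_class = scr_tri),
                 summary = summary, out_dir = out_dir))
}

#' Reduced 24-channel montage for quick runs
#'
#' The motor-cortex channels plus a frontal/parietal/occipital rim — enough
#' spatial coverage for CSP and the occipital eyes-closed alpha boost while
#' keeping small demonstrations fast.
#'
#' @return Character vector of 24 channel labels.
#' @export
demo_channels <- function() {
  c(motor_cortex_channels(), "Cz",
    "Fp1", "Fpz", "Fp2", "F3", "F4", "T7", "T8",
    "P3", "P4", "O1", "O2")
}

#' One-command synthetic demonstration run
#'
#' Runs the whole pipeline on a small synthetic cohort (16 subjects, 24
#' channels, 30 trials per class, 5x2 cross-validation) — a smoke-test
#' preset that finishes in about a minute and exercises every stage,
#' including the screening models.
#'
#' @param seed Master seed.
#' @param out_dir Output directory.
#' @return See [run_pipeline()].
#' @export
run_demo <- function(seed = 7, out_dir = tempfile("restalpha_demo_")) {
  cfg <- pipeline_config(
    cohort = list(n_subjects = 16, trials_per_class = 30, planted_rho = 0.9,
                  channels = demo_channels()),
    cv = list(folds = 5, reps = 2, cost = 1),
    screening = list(folds = 3),
    seed = seed)
  run_pipeline(cfg, out_dir)
}
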