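# Dataset simulation at study scale, delimited-text serialization with a
# manifest, and validated reading. The CSV dialect is pinned (UTF-8, header
# row, '.' decimal, full %.17g precision) so write -> read round-trips are
# exact.

SCHEMA_VERSION <- "1.0"

GAZE_COLS <- c("trial_id", "t_s", "head_x", "head_y", "head_z", "quat_w",
               "quat_x", "quat_y", "quat_z", "gaze_x", "gaze_y", "gaze_z",
               "valid", "visible")
CLUB_COLS <- c("trial_id", "t_s", "x", "y", "z")
OUTCOME_COLS <- c("trial_id", "land_x_cm", "land_z_cm")

#' Simulate a complete synthetic study with traces
#'
#' Generates the trial-level outcome table via [generate_dataset()], then
#' plants and renders gaze and club traces for every trial, with the planted
#' quiet-eye duration taken from the effect model draw. Per-trial seeds are
#' derived deterministically from `rng_seed`.
#'
#' @inheritParams generate_dataset
#' @param scene A [scene_geometry()].
#' @return A `qe_study` list: `scene`, `scenarios`, `trials` (with
#'   `trial_id`), `gaze`, `club`, `outcomes` tables and per-trial ground
#'   `truth`.
#' @export
simulate_study <- function(n_participants, scenarios, effects,
                           rng_seed = 1L, scene = scene_geometry()) {
  if (inherits(scenarios, "scenario_config")) scenarios <- list(scenarios)
  ds <- generate_dataset(n_participants, scenarios, effects, rng_seed)
  trials <- ds$trials
  trials$trial_id <- sprintf("%s_%s_t%02d", trials$participant_id,
                             trials$condition, trials$trial_index)
  scen_by_cond <- stats::setNames(scenarios,
                                  vapply(scenarios, `[[`, "", "condition"))
  set.seed(rng_seed + 1000L)
  layout_onset <- stats::runif(nrow(trials), 2.2, 2.6)
  layout_early <- stats::runif(nrow(trials), 0.4, 0.8)
  gaze_l <- vector("list", nrow(trials))
  club_l <- vector("list", nrow(trials))
  truth_l <- vector("list", nrow(trials))
  for (i in seq_len(nrow(trials))) {
    scen <- scen_by_cond[[trials$condition[i]]]
    tr <- generate_trial_traces(scene, scen,
                                qe_total_ms = trials$qe_planted_ms[i],
                                qe_early_frac = layout_early[i],
                                swing_onset_s = layout_onset[i],
                                rng_seed = (rng_seed + 7L * i) %% .Machine$integer.max)
    tr$gaze$trial_id <- trials$trial_id[i]
    tr$club$trial_id <- trials$trial_id[i]
    gaze_l[[i]] <- tr$gaze[, GAZE_COLS]
    club_l[[i]] <- tr$club[, CLUB_COLS]
    truth_l[[i]] <- c(list(trial_id = trials$trial_id[i]),
                      tr$truth[c("swing_onset_s", "contact_s", "trial_end_s",
                                 "qe_onset_s", "qe_offset_s")],
                      list(fixations = tr$truth$fixations))
  }
  outcomes <- trials[, OUTCOME_COLS]
  structure(list(scene = scene, scenarios = scenarios, trials = trials,
                 gaze = do.call(rbind, gaze_l), club = do.call(rbind, club_l),
                 outcomes = outcomes, truth = truth_l,
                 participant_effects = ds$truth$participants),
            class = "qe_study")
}

fmt_table <- function(df) {
  out <- df
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]]) && !is.integer(out[[j]])) {
      out[[j]] <- sprintf("%.17g", out[[j]])
    }
  }
  out
}

write_pinned_csv <- function(df, path) {
  utils::write.table(fmt_table(df), path, sep = ",", dec = ".",
                     row.names = FALSE, col.names = TRUE, qmethod = "double",
                     fileEncoding = "UTF-8", quote = FALSE)
}

#' Write a simulated study to a dataset directory
#'
#' Serializes gaze/club/outcome tables as delimited text and the ground
#' truth, scene and scenario configurations as JSON, under a per-dataset
#' directory with a manifest.
#'
#' @param study A `qe_study` from [simulate_study()].
#' @param dir Output directory (created if absent).
#' @param dataset_id Identifier recorded in the manifest.
#' @return The manifest path, invisibly.
#' @export
write_dataset <- function(study, dir, dataset_id = "synthetic") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- list(gaze = "gaze.csv", club = "club.csv", outcomes = "outcomes.csv",
                trials = "trials.csv", ground_truth = "ground_truth.json")
  write_pinned_csv(study$gaze, file.path(dir, files$gaze))
  write_pinned_csv(study$club, file.path(dir, files$club))
  write_pinned_csv(study$outcomes, file.path(dir, files$outcomes))
  write_pinned_csv(study$trials, file.path(dir, files$trials))
  jsonlite::write_json(study$truth, file.path(dir, files$ground_truth),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  manifest <- list(dataset_id = dataset_id, schema_version = SCHEMA_VERSION,
                   files = files,
                   scene = unclass(study$scene),
                   scenarios = lapply(study$scenarios, unclass))
  mpath <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA)
  invisible(mpath)
}

read_pinned_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}

check_trace_table <- function(df, cols, label, path) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop(sprintf("%s (%s): missing columns %s", label, path,
                 paste(miss, collapse = ", ")))
  }
  if ("t_s" %in% names(df)) {
    for (id in unique(df$trial_id)) {
      t <- df$t_s[df$trial_id == id]
      if (any(diff(t) <= 0)) {
        bad <- which(diff(t) <= 0)[1]
        stop(sprintf("%s: non-monotone or duplicated timestamp in trial %s (row %d of that trial)",
                     label, id, bad + 1L))
      }
    }
  }
  df
}

#' Read a dataset directory back into memory
#'
#' Reads the manifest and the referenced delimited-text tables, validating
#' schema version, required columns and strictly increasing per-trial
#' timestamps. Malformed inputs fail with the offending trial and path.
#'
#' @param dir Dataset directory (or a path to its `manifest.json`).
#' @return A `qe_study`-like list with `scene`, `scenarios`, `trials`,
#'   `gaze`, `club`, `outcomes` and (when present) `truth`.
#' @export
read_dataset <- function(dir) {
  mpath <- if (grepl("\\.json$", dir)) dir else file.path(dir, "manifest.json")
  if (!file.exists(mpath)) stop("manifest not found: ", mpath)
  manifest <- jsonlite::read_json(mpath, simplifyVector = FALSE)
  if (!identical(manifest$schema_version, SCHEMA_VERSION)) {
    stop("unknown schema_version: ", manifest$schema_version)
  }
  base <- dirname(mpath)
  need <- function(name) {
    p <- file.path(base, manifest$files[[name]])
    if (!file.exists(p)) stop("manifest references an absent file: ", p)
    p
  }
  gaze <- check_trace_table(read_pinned_csv(need("gaze")), GAZE_COLS, "gaze", need("gaze"))
  club <- check_trace_table(read_pinned_csv(need("club")), CLUB_COLS, "club", need("club"))
  outcomes <- check_trace_table(read_pinned_csv(need("outcomes")), OUTCOME_COLS,
                                "outcomes", need("outcomes"))
  trials <- read_pinned_csv(need("trials"))
  truth <- NULL
  tp <- file.path(base, manifest$files$ground_truth)
  if (!is.null(manifest$files$ground_truth) && file.exists(tp)) {
    truth <- jsonlite::read_json(tp, simplifyVector = TRUE)
  }
  scene <- do.call(scene_geometry,
                   lapply(manifest$scene[c("ball_position", "hole_position",
                                           "target_radius", "eye_height")], unlist))
  scenarios <- lapply(manifest$scenarios, function(s) {
    s <- lapply(s, unlist)
    do.call(scenario_config, s[intersect(names(s), names(formals(scenario_config)))])
  })
  list(scene = scene, scenarios = scenarios, trials = trials, gaze = gaze,
       club = club, outcomes = outcomes, truth = truth, manifest = manifest)
}
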