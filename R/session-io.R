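#' Construct and validate a session object
#'
#' A session bundles one recording day of one task: a trial table, per-unit
#' spike times (seconds, relative to fixation onset), mean waveforms with
#' per-sample SD, and unit metadata.
#'
#' @param session_id Character id.
#' @param task One of "strategy", "novelmap", "fammap".
#' @param trials Data frame with columns trial_id, stimulus_id,
#'   response_target, association_id, correct, correction,
#'   fixation_onset_s, is_onset_s, is_duration_s, go_s.
#' @param spikes Data frame with columns unit_id, trial_id, t_s.
#' @param waveforms Data frame with columns unit_id, sample_idx, mean_v,
#'   sd_v.
#' @param units Data frame with columns unit_id, tasks.
#' @param sampling_interval_us Raw waveform sampling interval (25 for raw
#'   input).
#' @param metadata Free-form list.
#' @return A validated list of class `pf_session`.
#' @export
pf_session <- function(session_id, task, trials, spikes, waveforms, units,
                       sampling_interval_us = 25, metadata = list()) {
  s <- structure(list(session_id = session_id, task = task, trials = trials,
                      spikes = spikes, waveforms = waveforms, units = units,
                      sampling_interval_us = sampling_interval_us,
                      metadata = metadata),
                 class = "pf_session")
  validate_session(s)
  s
}

session_schema <- list(
  trials = c("trial_id", "stimulus_id", "response_target", "association_id",
             "correct", "correction", "fixation_onset_s", "is_onset_s",
             "is_duration_s", "go_s"),
  spikes = c("unit_id", "trial_id", "t_s"),
  waveforms = c("unit_id", "sample_idx", "mean_v", "sd_v"),
  units = c("unit_id", "tasks")
)

check_columns <- function(df, expected, file) {
  missing <- setdiff(expected, names(df))
  if (length(missing)) {
    stop(sprintf("%s: missing column(s): %s", file,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
}

validate_session <- function(s) {
  stopifnot(inherits(s, "pf_session"))
  for (nm in names(session_schema)) {
    check_columns(s[[nm]], session_schema[[nm]], paste0(nm, ".csv"))
  }
  tr <- s$trials
  if (anyDuplicated(tr$trial_id)) stop("trials.csv: duplicate trial_id")
  if (is.unsorted(tr$trial_id)) stop("trials.csv: trial_id not ordered")
  bad <- !(tr$is_duration_s %in% c(1, 1.5, 2))
  if (any(bad)) stop("trials.csv: is_duration_s must be one of 1, 1.5, 2")
  if (any(tr$is_onset_s <= tr$fixation_onset_s) ||
      any(tr$go_s <= tr$is_onset_s)) {
    stop("trials.csv: event times not monotone within trial")
  }
  if (nrow(s$spikes)) {
    if (!all(s$spikes$trial_id %in% tr$trial_id)) {
      stop("spikes.csv: trial_id references unknown trial")
    }
    if (!all(s$spikes$unit_id %in% s$units$unit_id)) {
      stop("spikes.csv: unit_id references unknown unit")
    }
    if (any(s$spikes$t_s < 0)) stop("spikes.csv: t_s must be >= 0")
  }
  if (nrow(s$waveforms) &&
      !all(s$waveforms$unit_id %in% s$units$unit_id)) {
    stop("waveforms.csv: unit_id references unknown unit")
  }
  invisible(s)
}

#' Write a session to a directory
#'
#' Emits trials.csv, spikes.csv, waveforms.csv, units.csv and session.json.
#'
#' @param session A [pf_session()].
#' @param path Directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  validate_session(session)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(session_schema)) {
    write.csv(session[[nm]], file.path(path, paste0(nm, ".csv")),
              row.names = FALSE)
  }
  meta <- list(session_id = session$session_id, task = session$task,
               sampling_interval_us = session$sampling_interval_us,
               metadata = session$metadata)
  jsonlite::write_json(meta, file.path(path, "session.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a session from a directory
#'
#' @param path Directory written by [write_session()].
#' @return A [pf_session()].
#' @export
read_session <- function(path) {
  for (f in c(paste0(names(session_schema), ".csv"), "session.json")) {
    if (!file.exists(file.path(path, f))) {
      stop(sprintf("session directory is missing %s", f), call. = FALSE)
    }
  }
  tabs <- lapply(names(session_schema), function(nm) {
    df <- read.csv(file.path(path, paste0(nm, ".csv")),
                   stringsAsFactors = FALSE)
    check_columns(df, session_schema[[nm]], paste0(nm, ".csv"))
    df
  })
  names(tabs) <- names(session_schema)
  meta <- jsonlite::read_json(file.path(path, "session.json"),
                              simplifyVector = TRUE)
  pf_session(session_id = meta$session_id, task = meta$task,
             trials = tabs$trials, spikes = tabs$spikes,
             waveforms = tabs$waveforms, units = tabs$units,
             sampling_interval_us = meta$sampling_interval_us,
             metadata = as.list(meta$metadata))
}

# number of spikes of sorted vector s in [a, b): #{s < b} - #{s < a}
count_in <- function(s, a, b) {
  findInterval(b, s, left.open = TRUE) - findInterval(a, s, left.open = TRUE)
}

#' Bin spike trains into a units x trials x bins rate tensor
#'
#' Bin b covers the half-open interval
#' `[t0 + b*step, t0 + b*step + width)` relative to the alignment event;
#' only fully contained bins are produced
#' (`floor((span - width)/step) + 1` of them).  Bins extending past a
#' trial's recorded span (e.g. past IS end on 1 s IS trials) are flagged
#' invalid (NA counts), not zero-filled.
#'
#' @param session A [pf_session()].
#' @param align Alignment event: "is" (IS onset) or "fixation".
#' @param window Numeric `c(t0, t1)` window in seconds relative to the
#'   alignment event; bins tile `[t0, t1)`.
#' @param width_ms,step_ms Bin width and step in milliseconds.
#' @param units Optional subset of unit ids.
#' @return List of class `rate_tensor` with `counts` and `rates`
#'   (units x trials x bins arrays), `centers_s` (bin centers relative to
#'   the alignment event), `valid` (trials x bins), bin geometry and ids.
#' @export
bin_spikes <- function(session, align = c("is", "fixation"),
                       window = c(0, 1), width_ms = 50, step_ms = 50,
                       units = NULL) {
  align <- match.arg(align)
  stopifnot(width_ms > 0, step_ms > 0, window[2] > window[1])
  tr <- session$trials
  unit_ids <- if (is.null(units)) session$units$unit_id else units
  w <- width_ms / 1000
  st <- step_ms / 1000
  span <- window[2] - window[1]
  nb <- floor((span - w) / st + 1e-9) + 1
  if (nb < 1) stop("window shorter than one bin")
  starts_rel <- window[1] + (seq_len(nb) - 1) * st
  centers <- starts_rel + w / 2

  align_t <- if (align == "is") tr$is_onset_s else tr$fixation_onset_s
  # recorded span per trial: fixation onset to 1 s past go
  t_lo <- tr$fixation_onset_s
  t_hi <- tr$go_s + 1
  nt <- nrow(tr)
  valid <- matrix(TRUE, nt, nb)
  for (b in seq_len(nb)) {
    a0 <- align_t + starts_rel[b]
    valid[, b] <- a0 >= t_lo & (a0 + w) <= t_hi
  }
  # IS-aligned bins must not outlive the IS period when the window asks
  # for more than the trial's IS duration
  if (align == "is") {
    for (b in seq_len(nb)) {
      valid[, b] <- valid[, b] &
        (starts_rel[b] + w <= tr$is_duration_s | starts_rel[b] + w <= 0)
    }
  }

  counts <- array(NA_real_, dim = c(length(unit_ids), nt, nb),
                  dimnames = list(unit_ids, tr$trial_id, NULL))
  sp <- session$spikes
  sp_by_unit <- split(sp[c("trial_id", "t_s")], factor(sp$unit_id,
                                                       levels = unit_ids))
  for (ui in seq_along(unit_ids)) {
    su <- sp_by_unit[[ui]]
    by_trial <- split(su$t_s, factor(su$trial_id, levels = tr$trial_id))
    for (ti in seq_len(nt)) {
      s <- sort(by_trial[[ti]])
      a <- align_t[ti] + starts_rel
      cnt <- count_in(s, a, a + w)
      cnt[!valid[ti, ]] <- NA_real_
      counts[ui, ti, ] <- cnt
    }
  }
  structure(list(counts = counts, rates = counts / w,
                 width_ms = width_ms, step_ms = step_ms,
                 t0 = window[1], centers_s = centers, align = align,
                 valid = valid, unit_ids = unit_ids,
                 trial_ids = tr$trial_id),
            class = "rate_tensor")
}

#' Keep units with enough correct trials in every condition
#'
#' Units recorded for fewer than `min_per_condition` correct,
#' non-correction trials in any of the three conditions of the variable are
#' excluded (defaults to 10; learning/post-learning blocks use 6).
#'
#' @param session A [pf_session()].
#' @param variable Trial column with exactly three conditions
#'   ("stimulus_id", "response_target" or "association_id").
#' @param min_per_condition Minimum correct trials per condition.
#' @param trial_ids Optional trial subset (e.g. a learning block).
#' @return Character vector of retained unit ids (possibly empty, with a
#'   warning).
#' @export
filter_units_by_trials <- function(session, variable,
                                   min_per_condition = 10,
                                   trial_ids = NULL) {
  tr <- session$trials
  if (!is.null(trial_ids)) tr <- tr[tr$trial_id %in% trial_ids, ]
  stopifnot(variable %in% names(tr))
  tr <- tr[tr$correct & !tr$correction & !is.na(tr[[variable]]), ]
  conds <- unique(tr[[variable]])
  if (length(conds) != 3) {
    warning(sprintf("variable %s has %d conditions (expected 3)",
                    variable, length(conds)))
  }
  un <- session$units
  # units may be recorded for only part of the session; optional
  # first_trial/last_trial columns bound the trials they contribute
  first <- if ("first_trial" %in% names(un)) un$first_trial else
    rep(min(session$trials$trial_id), nrow(un))
  last <- if ("last_trial" %in% names(un)) un$last_trial else
    rep(max(session$trials$trial_id), nrow(un))
  keep <- vapply(seq_len(nrow(un)), function(i) {
    tri <- tr[tr$trial_id >= first[i] & tr$trial_id <= last[i], ]
    cnt <- table(factor(tri[[variable]], levels = conds))
    all(cnt >= min_per_condition)
  }, logical(1))
  out <- session$units$unit_id[keep]
  if (!length(out)) warning("no units survive the trial-count filter")
  out
}
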