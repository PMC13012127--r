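# Plain-text session export/import: one CSV event table per container
# (trials, spikes, stimuli) plus a YAML sidecar for the generating
# configuration.  EMG samples are regenerable from (config, seed) and are
# not exported.

#' Export session event tables as CSV
#'
#' Writes `trials.csv` (one row per trial event), `spikes.csv`, and
#' `stims.csv` into `dir`, each row `kind, time_s, trial_id, attrs`.
#'
#' @param session an `ag_session`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
export_session_events <- function(session, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tr <- session$trials
  ev <- do.call(rbind, lapply(seq_len(nrow(tr)), function(i) {
    times <- as.numeric(tr[i, .trial_events])
    keep <- !is.na(times)
    data.frame(kind = .trial_events[keep], time_s = times[keep],
               trial_id = tr$trial_id[i],
               attrs = sprintf("direction=%s;outcome=%s",
                               tr$direction[i], tr$outcome[i]))
  }))
  if (is.null(ev)) ev <- data.frame(kind = character(0), time_s = numeric(0),
                                    trial_id = character(0),
                                    attrs = character(0))
  utils::write.csv(ev, file.path(dir, "trials.csv"), row.names = FALSE)
  sp <- do.call(rbind, lapply(names(session$spikes), function(id)
    data.frame(kind = "spike", time_s = as.numeric(session$spikes[[id]]),
               trial_id = NA_character_, attrs = sprintf("neuron=%s", id))))
  if (is.null(sp)) sp <- ev[0, ]
  utils::write.csv(sp, file.path(dir, "spikes.csv"), row.names = FALSE)
  st <- session$stims
  stv <- data.frame(kind = "stim", time_s = st$time, trial_id = st$trial_id,
                    attrs = sprintf("nerve=%s;volley=%.6f;intensity=%.3f",
                                    st$nerve_id, st$volley_time, st$intensity))
  utils::write.csv(stv, file.path(dir, "stims.csv"), row.names = FALSE)
  invisible(dir)
}

#' Write / read a session configuration as YAML
#'
#' Data frames inside the configuration are stored as column lists and
#' restored on read.
#'
#' @param config a [session_config()].
#' @param path YAML file path.
#' @return `write_session_config` returns `path` invisibly;
#'   `read_session_config` returns a validated `session_config`.
#' @export
write_session_config <- function(config, path) {
  cfg <- unclass(config)
  cfg$n_trials <- as.list(cfg$n_trials)
  cfg$muscles <- as.list(cfg$muscles)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname write_session_config
#' @export
read_session_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$n_trials <- as.data.frame(cfg$n_trials)
  cfg$muscles <- as.data.frame(cfg$muscles)
  do.call(session_config, cfg)
}

#' Write a per-muscle postspike-effect table as CSV
#'
#' @param effects list of classified `postspike_effect`s.
#' @param neuron_id neuron label.
#' @param path CSV path.
#' @return the table, invisibly.
#' @export
write_effect_table <- function(effects, neuron_id, path) {
  tab <- do.call(rbind, lapply(effects, function(e)
    data.frame(neuron_id = neuron_id, muscle = e$muscle, sign = e$sign,
               onset_ms = e$onset_ms, pwhm_ms = e$pwhm_ms,
               magnitude_pct = e$magnitude_pct, p = e$p_value,
               label = e$label)))
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(tab)
}
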