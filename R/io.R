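#' Write a simulation result as CSV files with a JSON sidecar
#'
#' Spike times go to `<prefix>_spikes.csv` (columns `trial`, `time_ms`),
#' the PSTH to `<prefix>_psth.csv` (columns `bin_start_ms`, `count`, the
#' count being across-trial spike counts per bin), and the run metadata
#' (parameters, seed, package version) to `<prefix>_meta.json`.
#'
#' @param res A `sim_result` from [run_trials()] or a runner built on it.
#' @param dir Output directory (created if missing).
#' @param prefix File-name prefix.
#' @param params Optional [network_params()] recorded in the sidecar.
#' @param lif Optional [lif_params()] recorded in the sidecar.
#' @param seed Optional seed recorded in the sidecar.
#' @return Invisibly, the named list of file paths.
#' @export
write_sim_result <- function(res, dir, prefix = "run", params = NULL,
                             lif = NULL, seed = NULL) {
  stopifnot(inherits(res, "sim_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f_sp <- file.path(dir, paste0(prefix, "_spikes.csv"))
  sp <- data.frame(
    trial = rep(seq_along(res$spike_times), lengths(res$spike_times)),
    time_ms = unlist(res$spike_times))
  write.csv(sp, f_sp, row.names = FALSE)
  f_ps <- file.path(dir, paste0(prefix, "_psth.csv"))
  write.csv(data.frame(bin_start_ms = (seq_along(res$psth) - 1L) * res$dt,
                       count = res$psth * res$n_trials),
            f_ps, row.names = FALSE)
  f_meta <- file.path(dir, paste0(prefix, "_meta.json"))
  meta <- list(n_trials = res$n_trials, duration_ms = res$duration,
               dt_ms = res$dt, mean_rate_Hz = res$mean_rate,
               rate_sd_Hz = res$rate_sd, seed = seed,
               version = as.character(utils::packageVersion("einet")))
  if (!is.null(params)) meta$network <- unclass(params)
  if (!is.null(lif)) meta$lif <- unclass(lif)
  jsonlite::write_json(meta, f_meta, auto_unbox = TRUE, digits = NA)
  invisible(list(spikes = f_sp, psth = f_ps, meta = f_meta))
}

#' Export an input-output table as CSV
#'
#' @param io Data frame from [predict_io_curve()], [run_io_sweep()] or
#'   [transient_io_curve()].
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_io_csv <- function(io, path) {
  write.csv(io, path, row.names = FALSE)
  invisible(path)
}
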