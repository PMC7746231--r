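#' Read and write trial tables as TSV
#'
#' Trial tables travel as plain tab-separated text (BIDS-events-like): one
#' row per trial with `stim_id`, feature columns `f1`-`f8`, `dist_to_A`,
#' `label`, `item_type`, `phase`, `repetition`, timing columns and the
#' subject's `response` where present.
#'
#' @param trials A trial tibble.
#' @param path File path.
#' @return `read_trials()` returns a tibble; `write_trials()` returns
#'   `trials` invisibly.
#' @export
write_trials <- function(trials, path) {
  utils::write.table(trials, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "n/a")
  invisible(trials)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  out <- tibble::as_tibble(
    utils::read.table(path, sep = "\t", header = TRUE, na.strings = "n/a",
                      stringsAsFactors = FALSE))
  if ("stim_id" %in% names(out)) {
    # restore leading zeros lost to numeric parsing
    out$stim_id <- sprintf("%08d", as.integer(as.character(out$stim_id)))
  }
  out
}

#' Export BIDS-style events with model modulators
#'
#' Writes the per-run events table the fMRI stage consumes: `onset`,
#' `duration`, `stim_id`, `match_proto`, `match_exem`.
#'
#' @param trials An augmented trial tibble (see [augment_trials()]) for one
#'   run.
#' @param path File path.
#' @export
write_events <- function(trials, path) {
  ev <- trials[, c("onset", "duration", "stim_id", "match_prototype",
                   "match_exemplar")]
  names(ev) <- c("onset", "duration", "stim_id", "match_proto", "match_exem")
  utils::write.table(ev, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "n/a")
  invisible(ev)
}
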