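# Session directory serialization -------------------------------------------
#
# A session is a directory of plain-text files:
#   cells.csv    cell_id, class_label, depth, rf_x, rf_y
#   traces.csv   long form: cell_id, t, F, N  (seconds; a.u.)
#   stimuli.csv  stim_id, onset, duration, diameter
#   speed.csv    t, speed (cm/s)
#   pupil.csv    t, x, y (degrees)
#   meta.json    sampling rate, correction state, stimulus center
#   truth.json   ground truth of synthetic sessions (optional)

#' Write a session to a directory
#'
#' @param session an `nf_session`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  stopifnot(inherits(session, "nf_session"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(d, f) utils::write.csv(d, file.path(dir, f), row.names = FALSE)
  w(session$cells, "cells.csv")
  n_cells <- nrow(session$cells)
  traces <- data.frame(
    cell_id = rep(session$cells$cell_id, each = length(session$time)),
    t = rep(session$time, n_cells),
    F = round(as.vector(t(session$F)), 4),
    N = round(as.vector(t(session$N)), 4))
  w(traces, "traces.csv")
  w(session$stimuli, "stimuli.csv")
  w(data.frame(t = session$time, speed = round(session$speed, 4)), "speed.csv")
  w(data.frame(t = session$time, x = round(session$pupil$x, 4),
               y = round(session$pupil$y, 4)), "pupil.csv")
  meta <- session$meta
  meta$corrected <- isTRUE(meta$corrected)
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA),
             file.path(dir, "meta.json"))
  if (!is.null(session$truth)) {
    truth <- session$truth
    truth$events <- NULL   # bulky; regenerate from the seed when needed
    writeLines(jsonlite::toJSON(truth, auto_unbox = TRUE, digits = NA),
               file.path(dir, "truth.json"))
  }
  invisible(dir)
}

#' Read a session directory
#'
#' @param dir directory written by [write_session()].
#' @return an `nf_session`.
#' @export
read_session <- function(dir) {
  rd <- function(f) utils::read.csv(file.path(dir, f))
  cells <- rd("cells.csv")
  traces <- rd("traces.csv")
  speed <- rd("speed.csv")
  pupil <- rd("pupil.csv")
  stimuli <- rd("stimuli.csv")
  meta <- jsonlite::fromJSON(file.path(dir, "meta.json"))
  t_axis <- sort(unique(traces$t))
  n <- length(t_axis)
  ord <- order(traces$cell_id, traces$t)
  traces <- traces[ord, ]
  n_cells <- nrow(cells)
  F <- matrix(traces$F, n_cells, n, byrow = TRUE)
  N <- matrix(traces$N, n_cells, n, byrow = TRUE)
  truth <- NULL
  if (file.exists(file.path(dir, "truth.json")))
    truth <- jsonlite::fromJSON(file.path(dir, "truth.json"))
  structure(list(cells = cells, F = F, N = N,
                 fs = meta$fs, time = t_axis,
                 speed = speed$speed,
                 pupil = data.frame(x = pupil$x, y = pupil$y),
                 stimuli = stimuli, meta = meta, truth = truth),
            class = "nf_session")
}
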