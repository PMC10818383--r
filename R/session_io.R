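## Plain-text session containers: one directory per session with
## emg.csv (time s + 4 muscle columns, microvolt), acc.csv (time s + 4
## columns, m/s^2), events.csv (timestamp, pulse_type, current,
## repetition) and meta.json (subject metadata, position, measurement,
## protocol, ground truth). Real exports in the same format are read back
## identically.

#' Write a session recording to a directory
#'
#' @param session A `tscs_session`.
#' @param dir Target directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  stopifnot(inherits(session, "tscs_session"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(session$emg, file.path(dir, "emg.csv"),
                   row.names = FALSE)
  utils::write.csv(session$acc, file.path(dir, "acc.csv"),
                   row.names = FALSE)
  utils::write.csv(session$events, file.path(dir, "events.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(meta = session$meta, position = session$position,
         measurement = session$measurement,
         protocol = unclass(session$protocol),
         ground_truth = session$ground_truth),
    file.path(dir, "meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a session recording from a directory
#'
#' @param dir Directory written by [write_session()] (or an equivalently
#'   formatted real export).
#' @return A `tscs_session`.
#' @export
read_session <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  protocol <- do.call(stimulation_protocol, meta$protocol)
  structure(list(
    meta = as.list(meta$meta),
    position = meta$position,
    measurement = meta$measurement,
    emg = as_tibble(utils::read.csv(file.path(dir, "emg.csv"))),
    acc = as_tibble(utils::read.csv(file.path(dir, "acc.csv"))),
    events = as_tibble(utils::read.csv(file.path(dir, "events.csv"))),
    ground_truth = as_tibble(meta$ground_truth),
    protocol = protocol), class = "tscs_session")
}
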