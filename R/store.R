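# Longitudinal monitoring store: patients (name, IP index, birthdate) and
# their timestamped automatic assessments. Plain-text persistence (two
# delimited tables); encryption is a deployment concern outside this
# package's scope. Erasing a patient cascades to their sessions.

#' Create an empty monitoring store
#'
#' @return object of class \code{monitor_store}.
#' @export
monitor_store <- function() {
  structure(list(
    patients = data.frame(ip_index = character(0), full_name = character(0),
                          birthdate = as.Date(character(0)),
                          stringsAsFactors = FALSE),
    sessions = data.frame(entry_id = character(0), ip_index = character(0),
                          timestamp = as.POSIXct(character(0), tz = "UTC"),
                          int = numeric(0), sev = numeric(0),
                          audio_ref = character(0), stringsAsFactors = FALSE),
    next_entry = 1L
  ), class = "monitor_store")
}

#' @export
print.monitor_store <- function(x, ...) {
  cat(sprintf("<monitor_store> %d patients, %d sessions\n",
              nrow(x$patients), nrow(x$sessions)))
  invisible(x)
}

#' Add a patient
#'
#' @param store a \code{monitor_store}.
#' @param full_name patient's complete name.
#' @param ip_index patient index, unique within the store.
#' @param birthdate calendar date (coercible via \code{as.Date}); must not lie
#'   in the future.
#' @return the updated store.
#' @export
add_patient <- function(store, full_name, ip_index, birthdate) {
  stopifnot(inherits(store, "monitor_store"))
  birthdate <- as.Date(birthdate)
  ps_validate(!is.na(birthdate) && birthdate <= Sys.Date(),
              "birthdate must be a valid date not in the future")
  if (ip_index %in% store$patients$ip_index) {
    ps_stop(sprintf("patient with ip_index '%s' already exists", ip_index),
            "ps_conflict_error")
  }
  store$patients <- rbind(store$patients,
                          data.frame(ip_index = ip_index,
                                     full_name = full_name,
                                     birthdate = birthdate,
                                     stringsAsFactors = FALSE))
  store
}

#' Look up a patient record
#' @param store a \code{monitor_store}.
#' @param ip_index patient index.
#' @return one-row data.frame.
#' @export
get_patient <- function(store, ip_index) {
  i <- match(ip_index, store$patients$ip_index)
  if (is.na(i)) {
    ps_stop(sprintf("unknown patient '%s'", ip_index), "ps_referential_error")
  }
  store$patients[i, ]
}

#' List patients
#' @param store a \code{monitor_store}.
#' @return data.frame of patient records.
#' @export
list_patients <- function(store) store$patients

#' Erase a patient (cascade)
#'
#' Removes the patient record and, by design, all of their sessions.
#'
#' @param store a \code{monitor_store}.
#' @param ip_index patient index.
#' @return the updated store.
#' @export
erase_patient <- function(store, ip_index) {
  get_patient(store, ip_index)  # errors if unknown
  store$patients <- store$patients[store$patients$ip_index != ip_index, ]
  store$sessions <- store$sessions[store$sessions$ip_index != ip_index, ]
  store
}

#' Record an assessment session
#'
#' Appends a timestamped score pair for an existing patient, assigning a
#' generated unique entry id. A score is only registered for a selected
#' (existing) patient; unknown patients are a referential error.
#'
#' @param store a \code{monitor_store}.
#' @param ip_index patient index (must exist).
#' @param int,sev intelligibility and severity scores in [0, 10].
#' @param timestamp UTC datetime (coercible via \code{as.POSIXct}); defaults
#'   to now.
#' @param audio_ref optional path to the stored recording.
#' @return the updated store.
#' @export
record_session <- function(store, ip_index, int, sev,
                           timestamp = Sys.time(), audio_ref = NA_character_) {
  get_patient(store, ip_index)  # errors if unknown
  ps_validate(is.finite(int) && int >= 0 && int <= 10 &&
                is.finite(sev) && sev >= 0 && sev <= 10,
              "scores must lie in [0, 10]")
  ts <- as.POSIXct(timestamp, tz = "UTC")
  entry <- data.frame(entry_id = sprintf("E%06d", store$next_entry),
                      ip_index = ip_index, timestamp = ts,
                      int = int, sev = sev, audio_ref = audio_ref,
                      stringsAsFactors = FALSE)
  store$sessions <- rbind(store$sessions, entry)
  store$next_entry <- store$next_entry + 1L
  store
}

#' Session history of one patient
#'
#' Returns the patient's entries under a stable total order (ties broken by
#' entry id) with optional conjunctive date-range and score-range filters.
#'
#' @param store a \code{monitor_store}.
#' @param ip_index patient index (must exist).
#' @param sort \code{"chronological"} or \code{"by_score"}.
#' @param score which score \code{by_score} sorts on (ascending):
#'   \code{"int"} (default) or \code{"sev"}.
#' @param from,to optional datetime bounds (inclusive).
#' @param score_min,score_max optional bounds on the sorted-on score.
#' @return data.frame of session entries.
#' @export
history <- function(store, ip_index, sort = c("chronological", "by_score"),
                    score = c("int", "sev"), from = NULL, to = NULL,
                    score_min = NULL, score_max = NULL) {
  sort <- match.arg(sort)
  score <- match.arg(score)
  get_patient(store, ip_index)  # errors if unknown
  h <- store$sessions[store$sessions$ip_index == ip_index, ]
  if (!is.null(from)) h <- h[h$timestamp >= as.POSIXct(from, tz = "UTC"), ]
  if (!is.null(to)) h <- h[h$timestamp <= as.POSIXct(to, tz = "UTC"), ]
  if (!is.null(score_min)) h <- h[h[[score]] >= score_min, ]
  if (!is.null(score_max)) h <- h[h[[score]] <= score_max, ]
  key <- if (sort == "chronological") h$timestamp else h[[score]]
  h[order(key, h$entry_id), ]
}

#' Delete one measurement
#'
#' @param store a \code{monitor_store}.
#' @param entry_id session entry id.
#' @return the updated store; unknown ids are a not-found error.
#' @export
delete_measurement <- function(store, entry_id) {
  if (!entry_id %in% store$sessions$entry_id) {
    ps_stop(sprintf("no measurement with entry_id '%s'", entry_id),
            "ps_notfound_error")
  }
  store$sessions <- store$sessions[store$sessions$entry_id != entry_id, ]
  store
}

#' Persist / load a store as two delimited tables
#'
#' \code{patients.tsv} (ip_index, full_name, birthdate) and
#' \code{sessions.tsv} (entry_id, ip_index, timestamp in UTC ISO-8601, int,
#' sev, audio_ref). Round-trips exactly.
#'
#' @param store a \code{monitor_store}.
#' @param dir directory for the two tables.
#' @return `dir` (save) or the reconstructed store (load).
#' @export
save_store <- function(store, dir) {
  stopifnot(inherits(store, "monitor_store"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- store$patients
  p$birthdate <- format(p$birthdate, "%Y-%m-%d")
  utils::write.table(p, file.path(dir, "patients.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  s <- store$sessions
  s$timestamp <- format(s$timestamp, "%Y-%m-%dT%H:%M:%OS3Z", tz = "UTC")
  utils::write.table(s, file.path(dir, "sessions.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname save_store
#' @export
load_store <- function(dir) {
  store <- monitor_store()
  pp <- file.path(dir, "patients.tsv")
  ps_input(file.exists(pp), sprintf("no patients.tsv in %s", dir))
  p <- utils::read.table(pp, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE,
                         colClasses = c("character", "character", "character"))
  p$birthdate <- as.Date(p$birthdate)
  store$patients <- p
  s <- utils::read.table(file.path(dir, "sessions.tsv"), header = TRUE,
                         sep = "\t", stringsAsFactors = FALSE,
                         colClasses = c("character", "character", "character",
                                        "numeric", "numeric", "character"))
  s$timestamp <- as.POSIXct(s$timestamp, tz = "UTC",
                            format = "%Y-%m-%dT%H:%M:%OSZ")
  store$sessions <- s
  store$next_entry <- if (nrow(s) == 0L) 1L else {
    max(as.integer(sub("^E", "", s$entry_id))) + 1L
  }
  store
}
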