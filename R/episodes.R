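#' Aggregate records into contact episodes
#'
#' A contact episode is a maximal run of consecutive recording intervals in
#' which the same pair is in proximity; its duration is the run length times
#' the recording resolution. A single isolated record is an episode of one
#' resolution interval.
#'
#' @param x a [contact_records] object.
#' @return data frame of class `contact_episodes` with columns `i`, `j`,
#'   `start`, `duration`, `end` (`end = start + duration`, seconds).
#' @seealso [median_contact_duration()], [median_delay()]
#' @export
build_episodes <- function(x) {
  stopifnot(inherits(x, "contact_records"))
  rec <- x$records
  res <- x$resolution
  if (!nrow(rec)) {
    out <- data.frame(i = character(), j = character(), start = numeric(),
                      duration = numeric(), end = numeric())
    class(out) <- c("contact_episodes", "data.frame")
    return(out)
  }
  key <- pair_key(rec$i, rec$j)
  ord <- order(key, rec$time)
  key <- key[ord]
  tt <- rec$time[ord]
  # a new episode starts at a pair change or a gap of >= one missing interval
  new_run <- c(TRUE, key[-1] != key[-length(key)] | diff(tt) != res)
  run_id <- cumsum(new_run)
  start <- tt[new_run]
  n_rec <- tabulate(run_id)
  out <- data.frame(i = rec$i[ord][new_run], j = rec$j[ord][new_run],
                    start = start, duration = n_rec * res,
                    stringsAsFactors = FALSE)
  out$end <- out$start + out$duration
  out <- out[order(out$start, out$i, out$j), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("contact_episodes", "data.frame")
  out
}

#' Median contact duration
#'
#' Median episode duration across all episodes of a network. Used as the
#' per-network validity threshold: a pair counts as a contact within a time
#' step only if it accumulates at least this much contact time.
#'
#' @param episodes a `contact_episodes` data frame from [build_episodes()].
#' @return Median duration in seconds.
#' @export
median_contact_duration <- function(episodes) {
  if (!nrow(episodes)) stop_("no episodes: median duration undefined")
  stats::median(episodes$duration)
}

#' Median delay between repeat contacts
#'
#' Median gap between consecutive episodes of the same pair (start of the
#' next episode minus end of the previous). Used to choose the snapshot
#' time-step length: steps shorter than the typical delay would record few
#' repeated contacts over consecutive steps.
#'
#' @param episodes a `contact_episodes` data frame.
#' @return Median delay in seconds.
#' @export
median_delay <- function(episodes) {
  if (!nrow(episodes)) stop_("no episodes: median delay undefined")
  key <- pair_key(episodes$i, episodes$j)
  ord <- order(key, episodes$start)
  key <- key[ord]
  same <- key[-1] == key[-length(key)]
  gaps <- (episodes$start[ord][-1] - episodes$end[ord][-length(key)])[same]
  if (!length(gaps))
    stop_("no pair has repeat episodes: median delay undefined")
  stats::median(gaps)
}

#' Per-network analysis presets
#'
#' Default recording resolution, valid-contact duration threshold and
#' snapshot step length for the common sensor-study settings, reflecting the
#' per-network median contact duration and median delay of the source
#' studies. `fixed15min` and `fixed1h` are the standardized sensitivity
#' settings.
#'
#' @param name optional preset name; omit to get the full table.
#' @return A one-row (or full) data frame with columns `preset`,
#'   `resolution`, `duration_threshold`, `step_length` (seconds).
#' @export
network_presets <- function(name = NULL) {
  tab <- data.frame(
    preset = c("cruise", "community", "highschool", "hospital",
               "workplace", "fixed15min", "fixed1h"),
    resolution = c(15, 300, 20, 20, 20, 20, 20),
    duration_threshold = c(900, 300, 20, 20, 20, 20, 20),
    step_length = c(900, 600, 140, 140, 220, 900, 3600),
    stringsAsFactors = FALSE)
  if (is.null(name)) return(tab)
  row <- tab[tab$preset == name, , drop = FALSE]
  if (!nrow(row)) stop_("unknown preset '", name, "'")
  rownames(row) <- NULL
  row
}
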