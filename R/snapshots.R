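#' Snapshot series: per-time-step contact graphs
#'
#' Low-level constructor for a series of per-time-step contact snapshots.
#' Most users will call [build_snapshots()] on a [contact_records] object or
#' one of the synthetic generators instead.
#'
#' The population is the full set of individuals observed over the study;
#' individuals with no contact in a given step are part of every snapshot
#' with degree zero, and all per-capita averages are taken over the whole
#' population.
#'
#' @param contacts data frame with columns `step` (1-based integer), `i`,
#'   `j` (character node ids) and optionally `seconds` (recorded contact time
#'   within the step, used as the duration weight).
#' @param n_steps total number of steps `S` (empty trailing steps allowed).
#' @param population character vector of all node ids.
#' @param step_length step length in seconds.
#' @param duration_threshold validity threshold used to build the series.
#' @param directed logical.
#' @param node_attributes optional node-attribute data frame.
#' @return An object of class `snapshot_series`.
#' @export
snapshot_series <- function(contacts, n_steps, population, step_length,
                            duration_threshold = step_length,
                            directed = FALSE, node_attributes = NULL) {
  stopifnot(is.data.frame(contacts),
            all(c("step", "i", "j") %in% names(contacts)))
  if (!is_count(n_steps, min = 1)) stop_("`n_steps` must be a positive integer")
  ct <- data.frame(step = as.integer(contacts$step),
                   i = as.character(contacts$i),
                   j = as.character(contacts$j),
                   stringsAsFactors = FALSE)
  ct$seconds <- if ("seconds" %in% names(contacts))
    as.numeric(contacts$seconds) else rep(step_length, nrow(ct))
  if (nrow(ct)) {
    if (any(ct$step < 1L | ct$step > n_steps))
      stop_("contact step index outside 1..n_steps")
    if (any(ct$i == ct$j)) stop_("self-contact in snapshot")
    if (!directed) {
      o <- orient_pairs(ct$i, ct$j)
      ct$i <- o$i; ct$j <- o$j
    }
    if (anyDuplicated(paste(ct$step, pair_key(ct$i, ct$j))))
      stop_("duplicate contact within a step")
    ct <- ct[order(ct$step, ct$i, ct$j), , drop = FALSE]
    rownames(ct) <- NULL
  }
  population <- sort(unique(as.character(population)))
  if (!all(c(ct$i, ct$j) %in% population))
    stop_("contact involves node outside the population")
  structure(list(contacts = ct, n_steps = as.integer(n_steps),
                 population = population, step_length = step_length,
                 duration_threshold = duration_threshold,
                 directed = isTRUE(directed),
                 node_attributes = node_attributes),
            class = "snapshot_series")
}

#' Build per-time-step snapshots from contact records
#'
#' Partitions the study span into contiguous half-open windows of
#' `step_length` seconds (anchored at time 0, i.e. the first record) and
#' declares a pair a valid contact within a window when its recorded contact
#' time there reaches `duration_threshold` — by default cumulative recorded
#' time, or the longest unbroken episode within the window when
#' `require_continuous = TRUE`. Windows with no valid contact are kept as
#' empty snapshots so that the series tiles the span exactly.
#'
#' @param x a [contact_records] object.
#' @param step_length snapshot window length in seconds (typically the
#'   network's median delay in contact; see [network_presets()]).
#' @param duration_threshold minimum in-window contact time in seconds for a
#'   valid contact (typically the median contact duration).
#' @param require_continuous logical; require a single unbroken run of
#'   records of at least the threshold instead of cumulative time.
#' @param population optional character vector of node ids to use as the
#'   population (defaults to all nodes appearing in `x`, plus any nodes in
#'   its attribute table).
#' @return A [snapshot_series].
#' @export
build_snapshots <- function(x, step_length, duration_threshold,
                            require_continuous = FALSE, population = NULL) {
  stopifnot(inherits(x, "contact_records"))
  res <- x$resolution
  if (step_length < res) stop_("step_length must be >= the resolution")
  if (duration_threshold < res) stop_("duration_threshold must be >= the resolution")
  if (duration_threshold > step_length)
    stop_("duration_threshold cannot exceed step_length")
  rec <- x$records
  if (!nrow(rec)) stop_("no records to build snapshots from")
  pop <- unique(c(rec$i, rec$j, population,
                  if (!is.null(x$node_attributes)) x$node_attributes$node))
  step <- rec$time %/% step_length + 1L
  n_steps <- max(step)
  grp <- paste(step, pair_key(rec$i, rec$j))
  if (require_continuous) {
    # longest run of consecutive records per (step, pair) must reach the
    # threshold; the reported weight stays the cumulative in-window time
    ord <- order(grp, rec$time)
    g <- grp[ord]; tt <- rec$time[ord]
    new_run <- c(TRUE, g[-1] != g[-length(g)] | diff(tt) != res)
    run_len <- tabulate(cumsum(new_run))
    max_run <- tapply(run_len, g[new_run], max)
    cum <- tapply(rep(res, length(g)), g, sum)
    keep_keys <- names(max_run)[as.numeric(max_run) * res >= duration_threshold]
    first_idx <- match(keep_keys, grp)
    seconds <- as.numeric(cum[keep_keys])
  } else {
    cum <- tapply(rep(res, nrow(rec)), grp, sum)
    keep_keys <- names(cum)[cum >= duration_threshold]
    first_idx <- match(keep_keys, grp)
    seconds <- as.numeric(cum[keep_keys])
  }
  contacts <- data.frame(step = step[first_idx],
                         i = rec$i[first_idx], j = rec$j[first_idx],
                         seconds = seconds, stringsAsFactors = FALSE)
  snapshot_series(contacts, n_steps = n_steps, population = pop,
                  step_length = step_length,
                  duration_threshold = duration_threshold,
                  directed = x$directed, node_attributes = x$node_attributes)
}

#' Per-node weights of one snapshot
#'
#' @param series a [snapshot_series].
#' @param step step index in `1..n_steps`.
#' @param weight `"contacts"` for the degree (number of contacts in the
#'   step) or `"duration"` for total in-step contact seconds.
#' @return Named numeric vector over the whole population (zeros included).
#' @export
step_weights <- function(series, step, weight = c("contacts", "duration")) {
  weight <- match.arg(weight)
  stopifnot(inherits(series, "snapshot_series"))
  if (!is_count(step, min = 1) || step > series$n_steps)
    stop_("`step` must be in 1..n_steps")
  ct <- series$contacts[series$contacts$step == step, , drop = FALSE]
  w <- stats::setNames(numeric(length(series$population)), series$population)
  if (nrow(ct)) {
    val <- if (weight == "contacts") rep(1, nrow(ct)) else ct$seconds
    inc <- tapply(c(val, val), c(ct$i, ct$j), sum)
    w[names(inc)] <- as.numeric(inc)
  }
  w
}

#' Degrees of one snapshot
#'
#' Number of contacts each individual has in the given step, over the whole
#' population (zero-degree individuals included).
#'
#' @inheritParams step_weights
#' @return Named integer vector.
#' @export
step_degrees <- function(series, step) {
  d <- step_weights(series, step, "contacts")
  stats::setNames(as.integer(d), names(d))
}

step_pairs <- function(series, step) {
  ct <- series$contacts[series$contacts$step == step, c("i", "j"), drop = FALSE]
  rownames(ct) <- NULL
  ct
}

#' @export
print.snapshot_series <- function(x, ...) {
  per_step <- tabulate(x$contacts$step, nbins = x$n_steps)
  cat("<snapshot_series> ", x$n_steps, " steps x ", length(x$population),
      " nodes (", if (x$directed) "directed" else "undirected", ")\n",
      "  step length ", x$step_length, " s, validity threshold ",
      x$duration_threshold, " s\n",
      "  contacts per step: median ", stats::median(per_step),
      " (range ", min(per_step), "-", max(per_step), "); ",
      sum(per_step == 0), " empty step(s)\n", sep = "")
  invisible(x)
}

#' @export
summary.snapshot_series <- function(object, ...) {
  per_step <- tabulate(object$contacts$step, nbins = object$n_steps)
  deg_sum <- vapply(seq_len(object$n_steps),
                    function(s) mean(step_degrees(object, s)), numeric(1))
  out <- data.frame(step = seq_len(object$n_steps), contacts = per_step,
                    mean_degree = deg_sum)
  class(out) <- c("summary.snapshot_series", "data.frame")
  out
}
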