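# Repeated contacts across days and the bias from assuming daily
# independence of contacts (contact-tracing resource estimation).

day_of_step <- function(series, day_length) {
  if (day_length < series$step_length)
    stop_("day_length must be >= the step length")
  win_start <- (seq_len(series$n_steps) - 1L) * series$step_length
  as.integer(win_start %/% day_length) + 1L
}

#' Distribution of encounter-days over contact pairs
#'
#' For every pair ever in valid contact, counts the number of distinct study
#' days on which the pair has at least one valid contact in some step, and
#' returns the frequency distribution (and CDF) of these encounter-day
#' counts over pairs. Days are consecutive `day_length` windows from study
#' start, not calendar days.
#'
#' @param series a [snapshot_series].
#' @param day_length day window length in seconds (default 86400).
#' @return Object of class `encounter_summary`: list with `pair_days`
#'   (named integer per pair key `"i|j"`), `days_observed`, and
#'   `distribution` (data frame `days`, `n_pairs`, `proportion`, `cum`).
#' @export
encounter_days <- function(series, day_length = 86400) {
  stopifnot(inherits(series, "snapshot_series"))
  day <- day_of_step(series, day_length)[series$contacts$step]
  days_observed <- max(day_of_step(series, day_length))
  key <- paste(series$contacts$i, series$contacts$j, sep = "|")
  pd <- tapply(day, key, function(d) length(unique(d)))
  pair_days <- stats::setNames(as.integer(pd), names(pd))
  tab <- table(factor(pair_days, levels = seq_len(days_observed)))
  dist <- data.frame(days = seq_len(days_observed),
                     n_pairs = as.integer(tab),
                     proportion = as.numeric(tab) / length(pair_days))
  dist$cum <- cumsum(dist$proportion)
  structure(list(pair_days = pair_days, days_observed = days_observed,
                 distribution = dist),
            class = "encounter_summary")
}

#' @export
print.encounter_summary <- function(x, ...) {
  cat("<encounter_summary> ", length(x$pair_days), " pairs over ",
      x$days_observed, " day(s)\n", sep = "")
  one <- x$distribution$proportion[1]
  cat("  pairs meeting on exactly one day: ",
      sprintf("%.1f%%", 100 * one), "\n", sep = "")
  invisible(x)
}

#' Cumulative-unique versus summed-daily-unique contact ledger
#'
#' For each study day `d`, tallies the number of distinct pairs in valid
#' contact that day (`daily_unique`), the cumulative number of distinct
#' pairs seen from day 1 to day `d` (`cumulative_unique`), and the running
#' sum of the daily counts (`summed_daily`). A planning model that assumes
#' contacts are independent across days effectively uses `summed_daily`;
#' the excess over `cumulative_unique` is the repeat-contact overcount.
#'
#' @inheritParams encounter_days
#' @return Object of class `unique_ledger`: data frame with columns `day`,
#'   `daily_unique`, `cumulative_unique`, `summed_daily`; attribute `N`
#'   (population size).
#' @export
unique_contact_ledger <- function(series, day_length = 86400) {
  stopifnot(inherits(series, "snapshot_series"))
  day <- day_of_step(series, day_length)[series$contacts$step]
  D <- max(day_of_step(series, day_length))
  key <- pair_key(series$contacts$i, series$contacts$j)
  daily <- integer(D)
  cumulative <- integer(D)
  seen <- character(0)
  for (d in seq_len(D)) {
    kd <- unique(key[day == d])
    daily[d] <- length(kd)
    seen <- union(seen, kd)
    cumulative[d] <- length(seen)
  }
  out <- data.frame(day = seq_len(D), daily_unique = daily,
                    cumulative_unique = cumulative,
                    summed_daily = cumsum(daily))
  attr(out, "N") <- length(series$population)
  class(out) <- c("unique_ledger", "data.frame")
  out
}

#' Overcount of unique contacts under daily independence
#'
#' Per-day difference between the summed daily unique contacts and the true
#' cumulative unique contacts, reported absolutely and relative to the
#' population size (`relative_to_population`) and to the true cumulative
#' unique count (`relative_to_unique`). Both relative versions are emitted;
#' `relative_to_unique` is `NA` on days with no contacts yet.
#'
#' @param ledger a `unique_ledger` from [unique_contact_ledger()].
#' @param N population size; defaults to the ledger's `N` attribute.
#' @return The ledger data frame with columns `difference`,
#'   `relative_to_population` and `relative_to_unique` appended.
#' @export
overcount_metrics <- function(ledger, N = attr(ledger, "N")) {
  stopifnot(inherits(ledger, "unique_ledger"))
  if (is.null(N) || N < 1) stop_("population size N must be >= 1")
  out <- as.data.frame(ledger)
  out$difference <- out$summed_daily - out$cumulative_unique
  out$relative_to_population <- out$difference / N
  out$relative_to_unique <- ifelse(out$cumulative_unique > 0,
                                   out$difference / out$cumulative_unique,
                                   NA_real_)
  attr(out, "N") <- N
  class(out) <- c("unique_ledger", "data.frame")
  out
}
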