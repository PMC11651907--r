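# Per-step top-80% contributor sets, their persistence over the study, and
# the superspreader / superspreading-event classification.

#' Top contributors of one snapshot
#'
#' The smallest set of individuals whose cumulative weight (number of
#' contacts, or total contact duration) reaches at least `threshold` (by
#' default 80%) of the snapshot's total, taking nodes in decreasing weight
#' order with ties broken by node identifier (ascending) so the set is
#' deterministic. An empty snapshot yields an empty set.
#'
#' @param series a [snapshot_series].
#' @param step step index.
#' @param weight `"contacts"` (degree) or `"duration"` (in-step seconds).
#' @param threshold cumulative-weight fraction defining the top group.
#' @param random_ties logical; break ties uniformly at random instead of by
#'   node id (set a seed for reproducibility).
#' @return Character vector of node ids.
#' @export
top_group <- function(series, step, weight = c("contacts", "duration"),
                      threshold = 0.8, random_ties = FALSE) {
  weight <- match.arg(weight)
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1)
    stop_("`threshold` must be in (0, 1]")
  w <- step_weights(series, step, weight)
  total <- sum(w)
  if (total == 0) return(character(0))
  ord <- if (random_ties) order(-w, sample.int(length(w)))
         else order(-w, names(w))
  w <- w[ord]
  n_top <- which(cumsum(w) >= threshold * total - 1e-9)[1]
  names(w)[seq_len(n_top)]
}

#' Top-group persistence over a series
#'
#' Counts, for every individual, the number of time steps in which it
#' belongs to the per-step top group. Individuals never identified get
#' count 0. Steps with no contacts contribute no memberships but still
#' count towards the total number of steps `S` unless
#' `skip_empty_steps = TRUE`.
#'
#' @inheritParams top_group
#' @param skip_empty_steps logical; drop contact-free steps from `S`.
#' @return Object of class `top_trajectory`: list with `counts` (named
#'   integer over the population), `S`, `weight`, `threshold`, and
#'   `p80_per_step` (fraction of the population in the top group each step).
#' @export
top_group_trajectory <- function(series, weight = c("contacts", "duration"),
                                 threshold = 0.8, skip_empty_steps = FALSE,
                                 random_ties = FALSE) {
  stopifnot(inherits(series, "snapshot_series"))
  weight <- match.arg(weight)
  if (series$n_steps < 1) stop_("empty series")
  counts <- stats::setNames(integer(length(series$population)),
                            series$population)
  steps <- seq_len(series$n_steps)
  if (skip_empty_steps) {
    nonempty <- unique(series$contacts$step)
    steps <- steps[steps %in% nonempty]
    if (!length(steps)) stop_("all steps are empty")
  }
  p80 <- numeric(length(steps))
  for (k in seq_along(steps)) {
    g <- top_group(series, steps[k], weight, threshold, random_ties)
    counts[g] <- counts[g] + 1L
    p80[k] <- length(g) / length(series$population)
  }
  structure(list(counts = counts, S = length(steps), weight = weight,
                 threshold = threshold, p80_per_step = p80),
            class = "top_trajectory")
}

#' @export
print.top_trajectory <- function(x, ...) {
  cat("<top_trajectory> ", length(x$counts), " nodes over S = ", x$S,
      " steps (weight: ", x$weight, ", top ",
      sprintf("%.0f%%", 100 * x$threshold), ")\n",
      "  mean per-step top-group fraction p80 = ",
      format(mean(x$p80_per_step), digits = 3), "\n", sep = "")
  invisible(x)
}

#' Persistence curve of top-group membership
#'
#' `rho_s` is the cumulative proportion of the population identified in the
#' per-step top group for at most `s` of the `S` steps, for `s = 0..S`;
#' `rho_S = 1` by construction. A curve hugging the bottom-right indicates
#' consistently identifiable highly connected individuals.
#'
#' @param traj a `top_trajectory` from [top_group_trajectory()].
#' @return Object of class `persistence_curve`: data frame with columns `s`
#'   and `rho`; attribute `S`.
#' @export
persistence_curve <- function(traj) {
  stopifnot(inherits(traj, "top_trajectory"))
  N <- length(traj$counts)
  n_at <- tabulate(traj$counts + 1L, nbins = traj$S + 1L)
  out <- data.frame(s = 0:traj$S, rho = cumsum(n_at) / N)
  attr(out, "S") <- traj$S
  class(out) <- c("persistence_curve", "data.frame")
  out
}

#' Classify superspreaders versus superspreading-event drivers
#'
#' Individuals in the per-step top group for at least `ss_frac` of the steps
#' (default half) are potential superspreaders: persistently highly
#' connected, identifiable from past observation. Individuals identified for
#' less than `sse_frac` of the steps (default a quarter) are, if anything,
#' drivers of superspreading events: occasionally highly connected, hard to
#' predict. The rest fall in between. Fractional thresholds are applied
#' unrounded (`counts >= ss_frac * S`, `counts < sse_frac * S`).
#'
#' @param traj a `top_trajectory`.
#' @param ss_frac minimum fraction of steps for the superspreader class.
#' @param sse_frac upper (exclusive) fraction for the superspreading-event
#'   class.
#' @return List with character vectors `superspreaders`, `sse_drivers`,
#'   `neither`.
#' @export
classify_contributors <- function(traj, ss_frac = 0.5, sse_frac = 0.25) {
  stopifnot(inherits(traj, "top_trajectory"))
  if (traj$S < 4)
    warning("S < 4: superspreader and superspreading-event thresholds overlap",
            call. = FALSE)
  cnt <- traj$counts
  ss <- names(cnt)[cnt >= ss_frac * traj$S]
  sse <- names(cnt)[cnt < sse_frac * traj$S]
  list(superspreaders = ss, sse_drivers = sse,
       neither = setdiff(names(cnt), c(ss, sse)))
}

#' Fully-dynamic reference persistence curve
#'
#' In a fully dynamic network where a fraction `p80` of the population forms
#' the top group independently each step, the proportion of the population
#' in the top group for at least `s` out of `S` steps is approximately
#' `p80^s`. Returned for `s = 0..S` as the reference curve against which
#' observed persistence is compared.
#'
#' @param p80 per-step top-group fraction (0.8 for a homogeneous network,
#'   0.5 for the overdispersed reference).
#' @param S number of time steps.
#' @return Named numeric vector `p80^s`, `s = 0..S`.
#' @export
dynamic_reference_curve <- function(p80, S) {
  if (!is.numeric(p80) || p80 <= 0 || p80 > 1) stop_("`p80` must be in (0, 1]")
  if (!is_count(S, min = 1)) stop_("`S` must be a positive integer")
  stats::setNames(p80^(0:S), 0:S)
}

#' @export
plot.persistence_curve <- function(x, ..., reference_p80 = NULL) {
  S <- attr(x, "S")
  # fraction identified for *at least* s steps = 1 - rho_{s-1}
  at_least <- c(1, 1 - x$rho[-nrow(x)])
  graphics::plot(x$s / S, at_least, type = "s", lwd = 2,
                 xlab = "proportion of time steps s/S",
                 ylab = "proportion identified for at least s steps",
                 ylim = c(0, 1), ...)
  if (!is.null(reference_p80))
    graphics::lines(0:S / S, reference_p80^(0:S), lty = 3, col = "grey40")
  invisible(x)
}
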