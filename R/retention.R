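#' Retained contacts over a consecutive step pair
#'
#' A retained contact is a pair in contact in both of two consecutive time
#' steps. Returns the per-individual retained-contact counts (over the whole
#' population, zeros included) and the retained pair set.
#'
#' @param series a [snapshot_series].
#' @param t index of the earlier step; the pair analysed is `(t, t+1)`.
#' @return List with `r` (named integer vector of per-node retained counts)
#'   and `pairs` (data frame `i`, `j` of retained pairs).
#' @export
retained_contacts <- function(series, t) {
  stopifnot(inherits(series, "snapshot_series"))
  if (!is_count(t, min = 1) || t + 1 > series$n_steps)
    stop_("`t` must index a consecutive step pair within the series")
  e1 <- step_pairs(series, t)
  e2 <- step_pairs(series, t + 1)
  keep <- pair_key(e1$i, e1$j) %in% pair_key(e2$i, e2$j)
  ret <- e1[keep, , drop = FALSE]
  r <- stats::setNames(integer(length(series$population)), series$population)
  if (nrow(ret)) {
    cnt <- table(c(ret$i, ret$j))
    r[names(cnt)] <- as.integer(cnt)
  }
  rownames(ret) <- NULL
  list(r = r, pairs = ret)
}

#' Static null: expected retained contacts
#'
#' In a fully static network every contact persists, so the distribution of
#' retained contacts equals the degree distribution at step `t` and the
#' expected retained contacts per individual is the mean degree over the
#' whole population.
#'
#' @param degrees named integer vector of step-`t` degrees over the
#'   population (see [step_degrees()]).
#' @return Mean degree (scalar).
#' @export
static_null_mean <- function(degrees) {
  if (!length(degrees)) stop_("empty degree vector")
  mean(degrees)
}

# empirical degree PMF over the whole population: P(k), k = 0..max
degree_pmf <- function(degrees) {
  tab <- tabulate(degrees + 1L, nbins = max(degrees) + 1L)
  tab / length(degrees)
}

#' Fully-dynamic null: expected retained contacts
#'
#' Under the fully-dynamic null, degrees at the two steps are independent
#' draws from the empirical marginal degree distributions and each of an
#' individual's `min(k_t, k_{t+1})` earlier contacts persists independently
#' with probability `k_{t+1}/(N-1)`. The expected retained contacts per
#' individual is then `E[min(k_t, k_{t+1}) * k_{t+1}] / (N-1)` over the
#' product of the two marginals.
#'
#' With `joint = TRUE` the per-node observed degree pairs `(k_t, k_{t+1})`
#' are used instead of the independence assumption across the two marginals
#' (degree-preserving reading).
#'
#' @param deg_t,deg_t1 named degree vectors of the two consecutive steps over
#'   the same population.
#' @param joint logical; use per-node degree pairs rather than independent
#'   marginals.
#' @return Expected retained contacts per individual (scalar).
#' @export
dynamic_null_mean <- function(deg_t, deg_t1, joint = FALSE) {
  N <- length(deg_t)
  if (N < 2 || length(deg_t1) != N)
    stop_("need degree vectors of equal length N >= 2")
  if (joint) return(mean(pmin(deg_t, deg_t1) * deg_t1) / (N - 1))
  p_t <- degree_pmf(deg_t)
  p_t1 <- degree_pmf(deg_t1)
  k_t <- seq_along(p_t) - 1L
  k_t1 <- seq_along(p_t1) - 1L
  m <- outer(k_t, k_t1, pmin) * rep(k_t1, each = length(k_t))
  sum(m * outer(p_t, p_t1)) / (N - 1)
}

#' Fully-dynamic null: distribution of retained contacts
#'
#' Probability mass function of the per-individual retained-contact count
#' under the binomial null: a mixture over degree pairs `(k_t, k_{t+1})` of
#' `Binomial(min(k_t, k_{t+1}), p)`. For the fully-dynamic null
#' `p = k_{t+1}/(N-1)`; forcing `p = 1` (`model = "static"`) collapses each
#' mixture component to a point mass at `min(k_t, k_{t+1})`, and with the
#' static degree coupling `k_{t+1} = k_t` the distribution reduces to the
#' degree distribution at step `t`.
#'
#' @inheritParams dynamic_null_mean
#' @param model `"dynamic"` (default) or `"static"` (`p` forced to 1 and
#'   degrees coupled, `k_{t+1} = k_t`).
#' @return Numeric vector `pmf` where `pmf[r+1] = P(r)` for
#'   `r = 0..max(min degree)`; sums to 1.
#' @export
null_retained_distribution <- function(deg_t, deg_t1,
                                       model = c("dynamic", "static")) {
  model <- match.arg(model)
  N <- length(deg_t)
  if (N < 2 || length(deg_t1) != N)
    stop_("need degree vectors of equal length N >= 2")
  if (model == "static") {
    # P(k_{t+1} | k_t) = 1{k_{t+1} = k_t}, p = 1: P(r) = P(k_t)
    return(degree_pmf(deg_t))
  }
  p_t <- degree_pmf(deg_t)
  p_t1 <- degree_pmf(deg_t1)
  k_max <- min(max(deg_t), max(deg_t1))
  pmf <- numeric(k_max + 1L)
  for (a in which(p_t > 0) - 1L) {
    for (b in which(p_t1 > 0) - 1L) {
      k <- min(a, b)
      w <- p_t[a + 1L] * p_t1[b + 1L]
      pmf[seq_len(k + 1L)] <- pmf[seq_len(k + 1L)] +
        w * stats::dbinom(0:k, size = k, prob = b / (N - 1))
    }
  }
  pmf
}

#' Retention index of a consecutive step pair
#'
#' The retention index rescales the observed mean retained contacts between
#' the fully-dynamic null mean (index 0) and the static null mean (index 1):
#' `(r_temp - r_dyna) / (r_stat - r_dyna)`. Values near 1 indicate a nearly
#' static (predictable) network; values near 0 a fully dynamic one. The
#' index is not clamped: sampling noise can push it slightly outside
#' `[0, 1]`.
#'
#' The step pair is flagged undefined (index `NA`) when the two null means
#' coincide (e.g. an empty earlier snapshot), since the rescaling is then
#' uninformative; such pairs are excluded from summaries.
#'
#' @inheritParams retained_contacts
#' @param joint passed to [dynamic_null_mean()].
#' @return An object of class `retention_result`: list with `t`,
#'   `r_bar_temp`, `r_bar_stat`, `r_bar_dyna`, `index`, `defined`,
#'   `retained_pairs` and `r` (per-node retained counts).
#' @export
retention_index <- function(series, t, joint = FALSE) {
  rc <- retained_contacts(series, t)
  deg_t <- step_degrees(series, t)
  deg_t1 <- step_degrees(series, t + 1)
  r_temp <- mean(rc$r)
  r_stat <- static_null_mean(deg_t)
  r_dyna <- dynamic_null_mean(deg_t, deg_t1, joint = joint)
  denom <- r_stat - r_dyna
  defined <- is.finite(denom) && denom > .Machine$double.eps^0.5
  structure(list(t = t, r_bar_temp = r_temp, r_bar_stat = r_stat,
                 r_bar_dyna = r_dyna,
                 index = if (defined) (r_temp - r_dyna) / denom else NA_real_,
                 defined = defined,
                 retained_pairs = rc$pairs, r = rc$r),
            class = "retention_result")
}

#' @export
print.retention_result <- function(x, ...) {
  cat("<retention_result> steps (", x$t, ", ", x$t + 1, ")\n",
      "  r_temp = ", format(x$r_bar_temp, digits = 4),
      ", r_stat = ", format(x$r_bar_stat, digits = 4),
      ", r_dyna = ", format(x$r_bar_dyna, digits = 4), "\n",
      "  retention index = ",
      if (x$defined) format(x$index, digits = 4) else "undefined", "\n",
      sep = "")
  invisible(x)
}

#' Contact-type composition of retained pairs
#'
#' Labels each retained pair by comparing the two endpoints' value of one
#' node attribute: `same-<attribute>` when the labels agree,
#' `different-<attribute>` otherwise, `unknown` when either endpoint lacks
#' the attribute. Returns the proportion of retained pairs of each type
#' (summing to 1 when any pair is retained).
#'
#' @param pairs data frame of retained pairs (`i`, `j`), e.g. the
#'   `retained_pairs` element of a `retention_result`.
#' @param node_attributes node-attribute data frame (see
#'   [read_node_attributes()]).
#' @param attribute name of the attribute column to compare.
#' @return Named numeric vector of proportions (empty when no pairs).
#' @export
retained_type_breakdown <- function(pairs, node_attributes, attribute) {
  if (!attribute %in% names(node_attributes))
    stop_("attribute '", attribute, "' not in the attribute table")
  if (!nrow(pairs)) return(stats::setNames(numeric(0), character(0)))
  lab <- stats::setNames(node_attributes[[attribute]], node_attributes$node)
  li <- lab[pairs$i]
  lj <- lab[pairs$j]
  type <- ifelse(is.na(li) | is.na(lj) | li == "unknown" | lj == "unknown",
                 "unknown",
                 ifelse(li == lj, paste0("same-", attribute),
                        paste0("different-", attribute)))
  tab <- table(type)
  stats::setNames(as.numeric(tab) / nrow(pairs), names(tab))
}

#' Retention summary over a whole series
#'
#' Computes the retention index for every consecutive step pair and
#' summarises the defined indices by their median and interquartile range
#' (linear-interpolation quantiles, R type 7). Optionally adds the per-step
#' contact-type composition of retained pairs.
#'
#' @param series a [snapshot_series].
#' @param joint passed to [dynamic_null_mean()].
#' @param attribute optional attribute name for the type breakdown (requires
#'   the series to carry `node_attributes`).
#' @return An object of class `retention_summary`: list with `per_step`
#'   (data frame `t`, `r_bar_temp`, `r_bar_stat`, `r_bar_dyna`, `index`,
#'   `defined`), `median_index`, `iqr_index` (length-2 vector), and
#'   `type_breakdown` (list per step pair, or `NULL`).
#' @export
summarize_retention <- function(series, joint = FALSE, attribute = NULL) {
  stopifnot(inherits(series, "snapshot_series"))
  if (series$n_steps < 2) stop_("need at least two snapshots")
  results <- lapply(seq_len(series$n_steps - 1L), retention_index,
                    series = series, joint = joint)
  per_step <- data.frame(
    t = vapply(results, `[[`, numeric(1), "t"),
    r_bar_temp = vapply(results, `[[`, numeric(1), "r_bar_temp"),
    r_bar_stat = vapply(results, `[[`, numeric(1), "r_bar_stat"),
    r_bar_dyna = vapply(results, `[[`, numeric(1), "r_bar_dyna"),
    index = vapply(results, `[[`, numeric(1), "index"),
    defined = vapply(results, `[[`, logical(1), "defined"))
  idx <- per_step$index[per_step$defined]
  if (length(idx) < 2)
    stop_("fewer than two defined step pairs: retention summary unavailable")
  breakdown <- NULL
  if (!is.null(attribute)) {
    if (is.null(series$node_attributes))
      stop_("series carries no node attributes")
    breakdown <- lapply(results, function(res)
      retained_type_breakdown(res$retained_pairs, series$node_attributes,
                              attribute))
    names(breakdown) <- per_step$t
  }
  structure(list(per_step = per_step,
                 median_index = stats::median(idx),
                 iqr_index = stats::quantile(idx, c(0.25, 0.75), names = FALSE,
                                             type = 7),
                 n_defined = length(idx),
                 type_breakdown = breakdown),
            class = "retention_summary")
}

#' @export
print.retention_summary <- function(x, ...) {
  cat("<retention_summary> ", nrow(x$per_step), " step pairs (",
      x$n_defined, " defined)\n",
      "  retention index: median ", format(x$median_index, digits = 3),
      " (IQR ", format(x$iqr_index[1], digits = 3), "-",
      format(x$iqr_index[2], digits = 3), ")\n", sep = "")
  invisible(x)
}

#' @describeIn summarize_retention Plot the per-step-pair retention index.
#' @param x a `retention_summary`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.retention_summary <- function(x, ...) {
  ps <- x$per_step[x$per_step$defined, ]
  graphics::plot(ps$t, ps$index, type = "b", pch = 16,
                 xlab = "time step t", ylab = "retention index",
                 ylim = range(c(0, 1, ps$index)), ...)
  graphics::abline(h = c(0, 1), lty = 3, col = "grey50")
  graphics::abline(h = x$median_index, lty = 2, col = "firebrick")
  invisible(x)
}
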