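# Seed-reproducible synthetic temporal contact networks spanning the
# static <-> fully-dynamic continuum. Single-snapshot graphs are sampled
# with the configuration model (igraph); the partial-retention generator
# re-pairs freed stubs by hand because the kept-edge constraint has no
# off-the-shelf sampler.

#' Degree laws for synthetic networks
#'
#' Per-node target degree distributions: `deg_constant(k)` (homogeneous),
#' `deg_poisson(mu)` (mildly heterogeneous) and `deg_nbinom(mu, size)`
#' (overdispersed; smaller `size` means heavier overdispersion and a
#' smaller fraction of the population carrying 80% of contacts).
#'
#' @param k,mu,size distribution parameters (`size` is the negative-binomial
#'   dispersion parameter).
#' @return An object of class `degree_law`.
#' @name degree_law
NULL

#' @rdname degree_law
#' @export
deg_constant <- function(k) {
  if (!is_count(k, min = 1)) stop_("`k` must be a positive integer")
  structure(list(type = "constant", k = k), class = "degree_law")
}

#' @rdname degree_law
#' @export
deg_poisson <- function(mu) {
  if (!is.numeric(mu) || mu <= 0) stop_("`mu` must be positive")
  structure(list(type = "poisson", mu = mu), class = "degree_law")
}

#' @rdname degree_law
#' @export
deg_nbinom <- function(mu, size) {
  if (!is.numeric(mu) || mu <= 0) stop_("`mu` must be positive")
  if (!is.numeric(size) || size <= 0) stop_("`size` must be positive")
  structure(list(type = "nbinom", mu = mu, size = size), class = "degree_law")
}

#' @export
print.degree_law <- function(x, ...) {
  cat("<degree_law> ", x$type, ": ",
      paste(names(x)[-1], unlist(x[-1]), sep = " = ", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Draw a graphical degree sequence
#'
#' Samples per-node target degrees from a [degree_law], capped at `N - 1`,
#' then repairs the sequence to be realizable as a simple graph: an odd stub
#' sum is fixed by decrementing one random positive-degree node, and a
#' non-graphical sequence by decrementing the largest degree until
#' Erdos-Gallai feasibility holds.
#'
#' @param law a `degree_law`.
#' @param N population size.
#' @return Integer vector of length `N`.
#' @export
sample_degrees <- function(law, N) {
  stopifnot(inherits(law, "degree_law"))
  if (!is_count(N, min = 2)) stop_("`N` must be an integer >= 2")
  deg <- switch(law$type,
    constant = rep(law$k, N),
    poisson = stats::rpois(N, law$mu),
    nbinom = stats::rnbinom(N, mu = law$mu, size = law$size))
  deg <- pmin(as.integer(deg), N - 1L)
  if (sum(deg) %% 2 == 1) {
    pos <- which(deg > 0)
    pick <- if (length(pos) == 1) pos else sample(pos, 1)
    deg[pick] <- deg[pick] - 1L
  }
  while (!igraph::is_graphical(deg)) {
    # decrement the two largest degrees to keep the sum even
    ord <- order(deg, decreasing = TRUE)[1:2]
    deg[ord] <- pmax(deg[ord] - 1L, 0L)
  }
  deg
}

node_ids <- function(N) sprintf("n%04d", seq_len(N))

# simple configuration-model realization as a two-column character data
# frame: stub matching with bounded repair (robust for the overdispersed
# sequences where igraph's simple-graph heuristics can stall)
sample_simple_graph <- function(degrees, nodes) {
  if (sum(degrees) == 0)
    return(data.frame(i = character(), j = character(),
                      stringsAsFactors = FALSE))
  pair_stubs(rep(nodes, degrees), forbidden = character(0))
}

edges_to_series <- function(edge_list, N, step_length) {
  nodes <- node_ids(N)
  steps <- rep(seq_along(edge_list),
               vapply(edge_list, nrow, integer(1)))
  contacts <- do.call(rbind, edge_list)
  contacts <- data.frame(step = steps, i = contacts$i, j = contacts$j,
                         seconds = step_length, stringsAsFactors = FALSE)
  snapshot_series(contacts, n_steps = length(edge_list), population = nodes,
                  step_length = step_length,
                  duration_threshold = step_length, directed = FALSE)
}

#' Generate a fully static temporal network
#'
#' One configuration-model graph drawn from the degree law and repeated
#' unchanged for `T` steps: the static extreme, whose retention index is 1
#' at every step pair and whose top-group membership never changes.
#'
#' @param N population size.
#' @param T_steps number of time steps.
#' @param degree_law a [degree_law] (default Poisson with mean 5).
#' @param step_length nominal step length in seconds (metadata only).
#' @param seed optional RNG seed (calls `set.seed`).
#' @return A [snapshot_series].
#' @export
generate_static <- function(N, T_steps, degree_law = deg_poisson(5),
                            step_length = 900, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  deg <- sample_degrees(degree_law, N)
  g <- sample_simple_graph(deg, node_ids(N))
  edges_to_series(rep(list(g), T_steps), N, step_length)
}

#' Generate a fully dynamic temporal network
#'
#' Per-node target degrees are fixed once from the degree law; every step is
#' an independent configuration-model realization of that degree sequence
#' (degree-preserving rewiring). The dynamic extreme: retained contacts
#' occur only by chance and the retention index is approximately 0.
#'
#' @inheritParams generate_static
#' @return A [snapshot_series].
#' @export
generate_fully_dynamic <- function(N, T_steps, degree_law = deg_poisson(5),
                                   step_length = 900, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  deg <- sample_degrees(degree_law, N)
  nodes <- node_ids(N)
  edges <- lapply(seq_len(T_steps),
                  function(s) sample_simple_graph(deg, nodes))
  edges_to_series(edges, N, step_length)
}

# re-pair free stubs into simple edges avoiding `forbidden` pair keys.
# Random stub matching followed by bounded double-edge-swap repair: each
# clashing pair (self-loop, multi-edge or forbidden) trades endpoints with a
# randomly chosen partner pair when both resulting pairs are valid. Drops
# irreparable pairs as a last resort (vanishingly rare at realistic
# densities).
pair_stubs <- function(stubs, forbidden, max_rounds = 100, max_tries = 60) {
  m <- length(stubs) %/% 2
  empty <- data.frame(i = character(), j = character(),
                      stringsAsFactors = FALSE)
  if (m == 0) return(empty)
  key_of <- function(x, y) {
    sw <- x > y
    paste(ifelse(sw, y, x), ifelse(sw, x, y), sep = "\r")
  }
  stubs <- sample(stubs)
  a <- stubs[2 * seq_len(m) - 1]
  b <- stubs[2 * seq_len(m)]
  keys <- key_of(a, b)
  for (round in seq_len(max_rounds)) {
    bad <- which(a == b | duplicated(keys) | keys %in% forbidden)
    if (!length(bad)) break
    for (idx in bad) {
      for (try in seq_len(max_tries)) {
        jdx <- sample.int(m, 1)
        if (jdx == idx) next
        if (a[idx] == b[jdx] || a[jdx] == b[idx]) next
        k1 <- key_of(a[idx], b[jdx])
        k2 <- key_of(a[jdx], b[idx])
        if (k1 == k2 || k1 %in% forbidden || k2 %in% forbidden) next
        other <- keys[-c(idx, jdx)]
        if (k1 %in% other || k2 %in% other) next
        tmp <- b[idx]; b[idx] <- b[jdx]; b[jdx] <- tmp
        keys[idx] <- k1; keys[jdx] <- k2
        break
      }
    }
  }
  bad <- a == b | duplicated(keys) | keys %in% forbidden
  if (any(bad))
    warning(sum(bad), " free stub pair(s) could not be placed and were dropped",
            call. = FALSE)
  o <- orient_pairs(a[!bad], b[!bad])
  data.frame(i = o$i, j = o$j, stringsAsFactors = FALSE)
}

#' Generate a partial-retention temporal network
#'
#' Interpolates between the static and fully dynamic extremes: the first
#' step is a configuration-model graph; at each subsequent step every edge
#' persists independently with probability `q` and the freed stubs are
#' randomly re-paired (avoiding self-loops, multi-edges and kept edges), so
#' per-node degrees are preserved. `q = 1` reduces to [generate_static()];
#' `q = 0` redraws all edges each step. The recovered retention index tracks
#' `q` closely (the residual chance retention is of order mean degree / N).
#'
#' @inheritParams generate_static
#' @param q per-edge one-step retention probability in `[0, 1]`.
#' @return A [snapshot_series].
#' @export
generate_partial_retention <- function(N, T_steps, q,
                                       degree_law = deg_poisson(5),
                                       step_length = 900, seed = NULL) {
  if (!is.numeric(q) || q < 0 || q > 1) stop_("`q` must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  deg <- sample_degrees(degree_law, N)
  nodes <- node_ids(N)
  edges <- vector("list", T_steps)
  edges[[1]] <- sample_simple_graph(deg, nodes)
  if (T_steps > 1) for (s in 2:T_steps) {
    prev <- edges[[s - 1]]
    keep <- if (nrow(prev)) stats::runif(nrow(prev)) < q else logical(0)
    kept <- prev[keep, , drop = FALSE]
    freed <- prev[!keep, , drop = FALSE]
    new <- pair_stubs(c(freed$i, freed$j), pair_key(kept$i, kept$j))
    out <- rbind(kept, new)
    edges[[s]] <- out[order(out$i, out$j), , drop = FALSE]
  }
  edges_to_series(edges, N, step_length)
}

#' Realized top-group fraction of a degree law
#'
#' Simulates single snapshots from the degree law and returns the average
#' fraction of the population in the top-80% contact group, i.e. the
#' achieved `p80`. A homogeneous (constant or Poisson) law yields about
#' 0.8; overdispersed laws yield less.
#'
#' @param law a [degree_law].
#' @param N population size used for the probe snapshots.
#' @param replicates number of snapshots averaged.
#' @param threshold top-group cumulative-weight fraction.
#' @param seed optional RNG seed.
#' @return Achieved `p80` (scalar).
#' @export
achieved_p80 <- function(law, N = 1000, replicates = 5, threshold = 0.8,
                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mean(vapply(seq_len(replicates), function(r) {
    s <- edges_to_series(list(sample_simple_graph(sample_degrees(law, N),
                                                  node_ids(N))), N, 900)
    length(top_group(s, 1, "contacts", threshold)) / N
  }, numeric(1)))
}

#' Calibrate negative-binomial dispersion to a target p80
#'
#' Searches the negative-binomial dispersion (`size`) so that the achieved
#' fraction of the population carrying 80% of contacts matches
#' `p80_target` within `tol`. Used to build the overdispersed reference
#' network (`p80 = 0.5`) when only the concentration target, not a degree
#' distribution, is specified.
#'
#' @param mu mean degree.
#' @param p80_target target top-group fraction (e.g. 0.5).
#' @param N,replicates probe-snapshot settings (see [achieved_p80()]).
#' @param tol acceptable |achieved - target|.
#' @param seed optional RNG seed.
#' @return A `deg_nbinom` law with attributes `achieved_p80` and `size`.
#' @export
calibrate_p80 <- function(mu, p80_target, N = 1000, replicates = 3,
                          tol = 0.02, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  probe <- function(size) achieved_p80(deg_nbinom(mu, size), N, replicates)
  lo <- log(0.02); hi <- log(200)
  p_lo <- probe(exp(lo)); p_hi <- probe(exp(hi))
  if (p80_target < p_lo - tol || p80_target > p_hi + tol)
    stop_("target p80 = ", p80_target, " unattainable for mu = ", mu,
          " (achievable range ~", round(p_lo, 3), "-", round(p_hi, 3), ")")
  for (iter in 1:25) {
    mid <- (lo + hi) / 2
    p_mid <- probe(exp(mid))
    if (abs(p_mid - p80_target) <= tol) {
      law <- deg_nbinom(mu, exp(mid))
      attr(law, "achieved_p80") <- p_mid
      return(law)
    }
    if (p_mid < p80_target) lo <- mid else hi <- mid
  }
  stop_("calibration did not converge to tol = ", tol)
}

#' Assign nodes to contact-type groups
#'
#' Random partition of a population into `n_groups` groups of near-equal
#' size, returned as a node-attribute table. Pair types then derive from
#' label agreement (same-group vs different-group), mirroring the
#' department/class/cabin taxonomies of sensor studies.
#'
#' @param nodes character vector of node ids (e.g. a series' population).
#' @param n_groups number of groups.
#' @param attribute attribute column name.
#' @param seed optional RNG seed.
#' @return data frame with columns `node` and `<attribute>`.
#' @export
assign_groups <- function(nodes, n_groups, attribute = "group",
                          seed = NULL) {
  if (!is_count(n_groups, min = 1)) stop_("`n_groups` must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  lab <- sample(rep_len(sprintf("g%02d", seq_len(n_groups)), length(nodes)))
  out <- data.frame(node = as.character(nodes), stringsAsFactors = FALSE)
  out[[attribute]] <- lab
  out
}

#' Generate multi-day raw contact records
#'
#' Emits raw tij records with day structure for testing the repeated-contact
#' metrics: a base set of pairs meets on day 1; on each later day every base
#' pair recurs independently with probability `rho`, and never-seen pairs
#' top the day up to `pairs_per_day` contacts. Each daily contact is written
#' as `records_per_contact` consecutive records, so it passes any validity
#' threshold up to that duration.
#'
#' @param N population size.
#' @param days number of study days.
#' @param pairs_per_day distinct pairs in contact per day.
#' @param rho per-pair daily repeat probability in `[0, 1]`.
#' @param resolution recording interval in seconds.
#' @param records_per_contact consecutive records per daily contact.
#' @param day_length day window in seconds.
#' @param seed optional RNG seed.
#' @return A [contact_records] object (undirected).
#' @export
generate_multiday <- function(N, days, pairs_per_day, rho,
                              resolution = 20, records_per_contact = 3,
                              day_length = 86400, seed = NULL) {
  if (!is.numeric(rho) || rho < 0 || rho > 1) stop_("`rho` must be in [0, 1]")
  if (pairs_per_day > choose(N, 2))
    stop_("pairs_per_day exceeds the number of distinct pairs")
  if (pairs_per_day * records_per_contact * 2 * resolution > day_length)
    stop_("day_length too short for the requested contacts")
  if (!is.null(seed)) set.seed(seed)
  nodes <- node_ids(N)
  sample_pair <- function(used) {
    repeat {
      p <- sort(sample(nodes, 2))
      k <- pair_key(p[1], p[2])
      if (!k %in% used) return(k)
    }
  }
  base <- character(0)
  while (length(base) < pairs_per_day) base <- c(base, sample_pair(base))
  used <- base
  day_pairs <- vector("list", days)
  day_pairs[[1]] <- base
  if (days > 1) for (d in 2:days) {
    rep_pairs <- base[stats::runif(length(base)) < rho]
    fresh <- character(0)
    while (length(rep_pairs) + length(fresh) < pairs_per_day) {
      k <- sample_pair(used)
      used <- c(used, k)
      fresh <- c(fresh, k)
    }
    day_pairs[[d]] <- c(rep_pairs, fresh)
  }
  recs <- lapply(seq_len(days), function(d) {
    pairs <- day_pairs[[d]]
    if (!length(pairs)) return(NULL)
    parts <- do.call(rbind, strsplit(pairs, "\r", fixed = TRUE))
    slot0 <- (d - 1) * day_length +
      (seq_along(pairs) - 1) * records_per_contact * 2 * resolution
    data.frame(
      time = rep(slot0, each = records_per_contact) +
        (seq_len(records_per_contact) - 1) * resolution,
      i = rep(parts[, 1], each = records_per_contact),
      j = rep(parts[, 2], each = records_per_contact),
      stringsAsFactors = FALSE)
  })
  contact_records(do.call(rbind, recs), directed = FALSE,
                  resolution = resolution)
}
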