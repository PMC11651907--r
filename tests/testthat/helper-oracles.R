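# Test helpers: tiny builders and independent oracles. The oracles use only
# base R (no package internals, no igraph) so they stay independent of the
# implementation paths they check.

# build a snapshot_series from a list of 2-column pair matrices
make_series <- function(pair_lists, population, step_length = 100,
                        duration_threshold = 100, directed = FALSE) {
  rows <- lapply(seq_along(pair_lists), function(s) {
    p <- pair_lists[[s]]
    if (is.null(p) || !length(p)) return(NULL)
    m <- matrix(p, ncol = 2, byrow = TRUE)
    data.frame(step = s, i = m[, 1], j = m[, 2], stringsAsFactors = FALSE)
  })
  contacts <- do.call(rbind, rows)
  if (is.null(contacts))
    contacts <- data.frame(step = integer(), i = character(), j = character())
  snapshot_series(contacts, n_steps = length(pair_lists),
                  population = population, step_length = step_length,
                  duration_threshold = duration_threshold,
                  directed = directed)
}

# brute-force re-implementation of the dynamic-null expected retained
# contacts: plain double loop over the degree supports
oracle_dyna_mean <- function(deg_t, deg_t1) {
  N <- length(deg_t)
  tab_t <- table(deg_t) / N
  tab_t1 <- table(deg_t1) / N
  total <- 0
  for (a in as.integer(names(tab_t)))
    for (b in as.integer(names(tab_t1)))
      total <- total + min(a, b) * (b / (N - 1)) *
        tab_t[[as.character(a)]] * tab_t1[[as.character(b)]]
  total
}

# uniform simple graph with a given degree multiset assigned uniformly at
# random to nodes: permute the degree sequence, then stub-match with
# rejection until simple (configuration model conditioned on simplicity)
rand_simple_graph_permuted <- function(degrees) {
  N <- length(degrees)
  repeat {
    deg <- sample(degrees)
    stubs <- sample(rep.int(seq_len(N), deg))
    if (!length(stubs)) return(matrix(integer(), ncol = 2))
    a <- stubs[c(TRUE, FALSE)]
    b <- stubs[c(FALSE, TRUE)]
    lo <- pmin(a, b); hi <- pmax(a, b)
    if (any(lo == hi)) next
    if (anyDuplicated(paste(lo, hi))) next
    return(cbind(lo, hi))
  }
}

# Monte-Carlo rewiring oracle: mean retained contacts per individual when
# snapshot t+1 is replaced by a degree-distribution-preserving uniform
# rewiring (degrees reassigned uniformly across nodes each draw)
oracle_rewire_mc <- function(edges_t, deg_t1, N, draws = 10000) {
  keys_t <- paste(pmin(edges_t[, 1], edges_t[, 2]),
                  pmax(edges_t[, 1], edges_t[, 2]))
  vals <- vapply(seq_len(draws), function(d) {
    g <- rand_simple_graph_permuted(deg_t1)
    if (!nrow(g)) return(0)
    2 * sum(paste(g[, 1], g[, 2]) %in% keys_t) / N
  }, numeric(1))
  list(mean = mean(vals), se = stats::sd(vals) / sqrt(draws))
}

# random Erdos-Renyi-ish snapshot on integer nodes 1..N
rand_edges <- function(N, n_edges) {
  all_pairs <- t(utils::combn(N, 2))
  all_pairs[sample(nrow(all_pairs), min(n_edges, nrow(all_pairs))), ,
            drop = FALSE]
}

# random matching on 1..N with m edges (all degrees <= 1)
rand_matching <- function(N, m) {
  v <- sample(N, 2 * m)
  cbind(v[seq_len(m)], v[m + seq_len(m)])
}

edges_to_named <- function(edges) {
  matrix(sprintf("n%04d", edges), ncol = 2)
}

degrees_from_edges <- function(edges, N) {
  tabulate(as.vector(edges), nbins = N)
}
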