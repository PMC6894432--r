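# Independent brute-force oracles used across the suite. These are
# deliberately naive implementations kept separate from the package's
# computation paths.

# Upper-tail hypergeometric by exhaustive subset enumeration: draw every
# n-subset of a universe 1..N whose first K elements are "marked", count
# draws with >= m marked members.
oracle_hyper_enum <- function(N, K, n, m) {
  if (n == 0) return(as.numeric(m <= 0))
  draws <- utils::combn(N, n)
  overlap <- colSums(draws <= K)
  mean(overlap >= m)
}

# BH step-up by the literal definition: adj_(i) = min_{j >= i} N p_(j)/j,
# computed with an explicit double loop over the sorted p-values.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(n)
  for (i in seq_len(n)) {
    best <- Inf
    for (j in i:n) best <- min(best, n * ps[j] / j)
    adj[i] <- min(best, 1)
  }
  out <- numeric(n)
  out[o] <- adj
  out
}

# Exhaustive betweenness: BFS distances, then enumerate every shortest
# path between every ordered pair by walking the shortest-path DAG, and
# count the fraction passing through each interior vertex.
oracle_betweenness <- function(adj) {
  n <- nrow(adj)
  bfs_dist <- function(s) {
    d <- rep(Inf, n); d[s] <- 0; queue <- s
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      for (w in which(adj[u, ] > 0)) if (d[w] == Inf) {
        d[w] <- d[u] + 1; queue <- c(queue, w)
      }
    }
    d
  }
  all_shortest_paths <- function(s, t, d) {
    if (!is.finite(d[t]) || s == t) return(list())
    extend <- function(path) {
      u <- path[length(path)]
      if (u == t) return(list(path))
      nxt <- which(adj[u, ] > 0 & d == d[u] + 1)
      unlist(lapply(nxt, function(w) extend(c(path, w))), recursive = FALSE)
    }
    extend(s)
  }
  btw <- numeric(n)
  for (s in seq_len(n)) {
    d <- bfs_dist(s)
    for (t in seq_len(n)) {
      if (t <= s) next
      paths <- all_shortest_paths(s, t, d)
      if (!length(paths)) next
      for (v in seq_len(n)) {
        if (v == s || v == t) next
        thru <- sum(vapply(paths, function(p) v %in% p, TRUE))
        btw[v] <- btw[v] + thru / length(paths)
      }
    }
  }
  btw
}

# Naive triple-loop topological overlap.
oracle_tom <- function(a) {
  n <- nrow(a)
  tom <- diag(n)
  k <- rowSums(a)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    num <- sum(a[i, ] * a[, j]) + a[i, j]
    tom[i, j] <- num / (min(k[i], k[j]) + 1 - a[i, j])
  }
  tom
}

# Hand-rolled two-group log-rank chi-square (O/E/V worksheet over the
# distinct event times), independent of the survival package.
oracle_logrank_chisq <- function(ta, ea, tb, eb) {
  times <- c(ta, tb); events <- c(ea, eb)
  ina <- rep(c(TRUE, FALSE), c(length(ta), length(tb)))
  evt <- sort(unique(times[events == 1]))
  o_minus_e <- 0; v <- 0
  for (tt in evt) {
    at_risk <- times >= tt
    n_tot <- sum(at_risk); n_a <- sum(at_risk & ina)
    d_tot <- sum(times == tt & events == 1)
    d_a <- sum(times == tt & events == 1 & ina)
    if (n_tot < 2) next
    e_a <- d_tot * n_a / n_tot
    v_a <- d_tot * (n_a / n_tot) * (1 - n_a / n_tot) *
      (n_tot - d_tot) / (n_tot - 1)
    o_minus_e <- o_minus_e + (d_a - e_a)
    v <- v + v_a
  }
  if (v == 0) return(0)
  o_minus_e^2 / v
}

# Product-limit survival by hand over distinct event times.
oracle_km <- function(times, events) {
  evt <- sort(unique(times[events == 1]))
  surv <- numeric(length(evt)); s <- 1
  for (i in seq_along(evt)) {
    n_i <- sum(times >= evt[i])
    d_i <- sum(times == evt[i] & events == 1)
    s <- s * (1 - d_i / n_i)
    surv[i] <- s
  }
  list(time = evt, surv = surv)
}

# Random undirected simple graph as a 0/1 adjacency matrix.
random_adjacency <- function(n, p) {
  a <- matrix(0, n, n)
  up <- which(upper.tri(a))
  a[up] <- stats::rbinom(length(up), 1, p)
  a + t(a)
}
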