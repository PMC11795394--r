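# Shared fixtures, all built in code.

path_graph <- function(ids = c("a", "b", "c")) {
  n <- length(ids)
  areal_graph(data.frame(from = ids[-n], to = ids[-1]), area_ids = ids)
}

# A path of 4 areas plus one isolate: the smallest interesting disconnected
# map (used for oracle comparisons).
toy_graph <- function() {
  areal_graph(
    data.frame(from = c("a", "b", "c"), to = c("b", "c", "d")),
    area_ids = c("a", "b", "c", "d", "island")
  )
}

# Random multi-component graph: Erdos-Renyi-style per component, components
# forced connected by a spanning path.
random_graph <- function(n_components, max_size = 8, p = 0.3) {
  ids <- character(0)
  edges <- list()
  for (comp in seq_len(n_components)) {
    m <- sample(2:max_size, 1)
    cid <- sprintf("g%d_%d", comp, seq_len(m))
    ids <- c(ids, cid)
    for (a in 2:m) edges[[length(edges) + 1L]] <- c(cid[a - 1L], cid[a])
    if (m > 2) {
      for (a in 1:(m - 1)) for (b in (a + 1):m) {
        if (runif(1) < p) edges[[length(edges) + 1L]] <- c(cid[a], cid[b])
      }
    }
  }
  areal_graph(as.data.frame(do.call(rbind, edges)), area_ids = ids)
}

numerical_rank <- function(M, tol = NULL) {
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  tol <- tol %||% (max(abs(ev), 1e-12) * 1e-8)
  sum(ev > tol)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Tiny deterministic panel on the toy graph.
toy_panel <- function(graph = toy_graph(), T = 3, k = 1, seed = 42, ...) {
  simulate_panel(graph, n_periods = T, k = k, seed = seed, ...)
}
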