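# internal helpers shared across modules

# Kahn topological sort on an edge list; returns ordered variable names or
# aborts with class "pathmed_cycle_error" when the graph is cyclic.
topological_order <- function(variables, edges) {
  n_in <- setNames(integer(length(variables)), variables)
  if (nrow(edges) > 0) {
    tab <- table(edges$to)
    n_in[names(tab)] <- as.integer(tab)
  }
  order <- character(0)
  queue <- variables[n_in == 0L]
  n_in <- n_in[setdiff(names(n_in), queue)]
  edges_left <- edges
  while (length(queue) > 0) {
    v <- queue[[1L]]
    queue <- queue[-1L]
    order <- c(order, v)
    if (nrow(edges_left) > 0) {
      out <- edges_left$from == v
      for (child in edges_left$to[out]) {
        n_in[[child]] <- n_in[[child]] - 1L
        if (n_in[[child]] == 0L) {
          queue <- c(queue, child)
          n_in <- n_in[setdiff(names(n_in), child)]
        }
      }
      edges_left <- edges_left[!out, , drop = FALSE]
    }
  }
  if (length(order) < length(variables)) {
    abort(
      paste0(
        "model is not recursive: directed cycle involving ",
        paste(setdiff(variables, order), collapse = ", ")
      ),
      class = "pathmed_cycle_error"
    )
  }
  order
}

check_edge_frame <- function(edges, arg = "edges") {
  if (!is.data.frame(edges) || !all(c("from", "to") %in% names(edges))) {
    abort(sprintf("`%s` must be a data frame with columns `from` and `to`", arg),
          class = "pathmed_spec_error")
  }
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  if (any(edges$from == edges$to)) {
    abort("self-loop edges are not allowed", class = "pathmed_spec_error")
  }
  edges
}

# deterministic child seed derived from a user seed, kept < 2^31
derive_seed <- function(seed, offset) {
  (as.integer(seed) * 48271 + as.integer(offset) * 9973) %% 2147483647L
}

`%||%` <- function(x, y) if (is.null(x)) y else x
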