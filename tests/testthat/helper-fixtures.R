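# Shared fixtures: random recursive models, random DAGs, and independent
# brute-force oracles kept deliberately separate from the package internals.

# random DAG edge list on `k` nodes: edges only from lower to higher index
# (guarantees acyclicity), each possible edge kept with probability p_edge
random_dag <- function(k, p_edge = 0.4) {
  vars <- paste0("v", seq_len(k))
  pairs <- expand.grid(i = seq_len(k), j = seq_len(k))
  pairs <- pairs[pairs$i < pairs$j, ]
  keep <- runif(nrow(pairs)) < p_edge
  data.frame(from = vars[pairs$i[keep]], to = vars[pairs$j[keep]],
             stringsAsFactors = FALSE)
}

# random recursive model with standardized coefficients small enough that
# every implied R^2 stays below 1
random_recursive_paths <- function(k, p_edge = 0.5, coef_max = 0.35) {
  edges <- random_dag(k, p_edge)
  if (nrow(edges) == 0) {
    edges <- data.frame(from = "v1", to = "v2", stringsAsFactors = FALSE)
  }
  edges$coef <- runif(nrow(edges), -coef_max, coef_max)
  edges
}

# simulate raw data from a recursive linear system (independent route from
# the package's generator: plain equation-by-equation simulation)
simulate_recursive <- function(paths, n, resid_sd = 1) {
  vars <- unique(c(paths$from, paths$to))
  # order by repeatedly peeling variables whose parents are all placed
  remaining <- vars
  edges <- paths
  ord <- character(0)
  while (length(remaining) > 0) {
    free <- remaining[!remaining %in% edges$to]
    stopifnot(length(free) > 0)  # acyclic input assumed
    ord <- c(ord, free)
    remaining <- setdiff(remaining, free)
    edges <- edges[!edges$from %in% ord, , drop = FALSE]
  }
  X <- matrix(NA_real_, n, length(vars), dimnames = list(NULL, vars))
  for (v in ord) {
    par_rows <- paths[paths$to == v, ]
    X[, v] <- rnorm(n, sd = resid_sd)
    if (nrow(par_rows) > 0) {
      X[, v] <- X[, v] +
        drop(X[, par_rows$from, drop = FALSE] %*% par_rows$coef)
    }
  }
  as.data.frame(X)
}

# brute-force directed-path enumeration: plain recursive DFS over the edge
# list, no shared code with the package
oracle_paths <- function(edges, source, target) {
  out <- list()
  recurse <- function(node, seen) {
    if (node == target) {
      out[[length(out) + 1L]] <<- seen
      return(invisible())
    }
    nxt <- edges$to[edges$from == node]
    for (v in nxt) {
      if (!v %in% seen) recurse(v, c(seen, v))
    }
  }
  recurse(source, source)
  out
}

# brute-force BH step-up: literal evaluation of the definition
oracle_bh <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  ks <- which(ps <= seq_len(m) * q / m)
  k_star <- if (length(ks) > 0) max(ks) else 0
  rejected <- rep(FALSE, m)
  if (k_star > 0) rejected[p <= ps[k_star]] <- TRUE
  list(rejected = rejected,
       alpha_adj = if (k_star > 0) ps[k_star] else 0)
}

canonical_path_set <- function(paths) {
  sort(vapply(paths, paste, character(1), collapse = ">"))
}
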