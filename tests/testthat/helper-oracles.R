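# Independent reference implementations used as oracles. These deliberately
# share no code with the package: the MCL reference is a loop-based matrix
# iteration with igraph component extraction, the midpoint oracle searches
# every edge, and the RF oracle enumerates bipartitions explicitly.

# --- Markov clustering reference (loop-based) -------------------------------

reference_mcl <- function(edges, inflation = 2, nodes = NULL, max_iter = 200) {
  nodes <- sort(unique(c(nodes, edges$from, edges$to)))
  n <- length(nodes)
  if (n == 0) return(list())
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  for (r in seq_len(nrow(edges))) {
    i <- match(edges$from[r], nodes); j <- match(edges$to[r], nodes)
    A[i, j] <- max(A[i, j], edges$weight[r])
    A[j, i] <- max(A[j, i], edges$weight[r])
  }
  for (k in seq_len(n)) {
    mk <- max(A[, k])
    A[k, k] <- if (mk > 0) mk else 1
  }
  for (k in seq_len(n)) A[, k] <- A[, k] / sum(A[, k])
  for (it in seq_len(max_iter)) {
    B <- matrix(0, n, n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      s <- 0
      for (k in seq_len(n)) s <- s + A[i, k] * A[k, j]
      B[i, j] <- s
    }
    B <- B^inflation
    B[B < 1e-10] <- 0
    for (k in seq_len(n)) {
      cs <- sum(B[, k])
      if (cs > 0) B[, k] <- B[, k] / cs
    }
    if (max(abs(B - A)) < 1e-8) { A <- B; break }
    A <- B
  }
  adj <- (A > 1e-6) | (t(A) > 1e-6)
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  cl <- lapply(split(nodes, comp), sort)
  names(cl) <- NULL
  cl
}

partition_key <- function(clusters) {
  sort(vapply(clusters, function(x) paste(sort(x), collapse = ","), character(1)))
}

# --- midpoint rooting oracle: all-edge search --------------------------------

# Minimal achievable maximum root-to-leaf distance over all rootings of the
# tree (root anywhere on any edge).
bruteforce_minmax_depth <- function(tree) {
  nd <- ape::dist.nodes(tree)
  ntip <- length(tree$tip.label)
  best <- Inf
  for (e in seq_len(nrow(tree$edge))) {
    u <- tree$edge[e, 1]; v <- tree$edge[e, 2]
    L <- tree$edge.length[e]
    # leaves are on u's side iff their path to u avoids v
    du <- nd[u, seq_len(ntip)]; dv <- nd[v, seq_len(ntip)]
    on_v_side <- dv < du
    # root at distance t from u (0 <= t <= L):
    # depth = t + du for u-side leaves, (L - t) + dv for v-side leaves
    mu <- if (any(!on_v_side)) max(du[!on_v_side]) else -Inf
    mv <- if (any(on_v_side)) max(dv[on_v_side]) else -Inf
    # max(t + mu, L - t + mv) minimized at t* = (L + mv - mu) / 2, clamped
    t_star <- min(max((L + mv - mu) / 2, 0), L)
    best <- min(best, max(t_star + mu, L - t_star + mv))
  }
  best
}

max_root_depth <- function(tree) {
  nd <- ape::dist.nodes(tree)
  root <- length(tree$tip.label) + 1L
  max(nd[root, seq_len(length(tree$tip.label))])
}

# --- Robinson-Foulds oracle: explicit bipartition enumeration ----------------

tree_bipartitions <- function(tree) {
  tree <- ape::unroot(tree)
  tips <- sort(tree$tip.label)
  ntip <- length(tree$tip.label)
  children <- split(tree$edge[, 2], tree$edge[, 1])
  desc_tips <- function(node) {
    if (node <= ntip) return(tree$tip.label[node])
    unlist(lapply(children[[as.character(node)]], desc_tips))
  }
  parts <- character(0)
  for (e in seq_len(nrow(tree$edge))) {
    child <- tree$edge[e, 2]
    if (child <= ntip) next  # trivial bipartition
    side <- sort(desc_tips(child))
    if (length(side) <= 1 || length(side) >= ntip - 1) next
    if (!(tips[1] %in% side)) side <- setdiff(tips, side)
    parts <- c(parts, paste(side, collapse = "|"))
  }
  unique(parts)
}

reference_rf <- function(a, b) {
  pa <- tree_bipartitions(a); pb <- tree_bipartitions(b)
  length(setdiff(pa, pb)) + length(setdiff(pb, pa))
}

# --- small fixture builders --------------------------------------------------

make_toy_package <- function(seed = 1, ...) {
  suppressWarnings(simulate_genome(seed = seed, ...))
}

random_weighted_graph <- function(n, p = 0.25) {
  nodes <- sprintf("n%02d", seq_len(n))
  from <- character(0); to <- character(0); w <- numeric(0)
  for (i in seq_len(n - 1)) for (j in seq.int(i + 1, n)) {
    if (stats::runif(1) < p) {
      from <- c(from, nodes[i]); to <- c(to, nodes[j])
      w <- c(w, stats::runif(1, 0.5, 1))
    }
  }
  list(edges = data.frame(from = from, to = to, weight = w,
                          stringsAsFactors = FALSE),
       nodes = nodes)
}

random_bl_tree <- function(n) {
  tr <- ape::rtree(n, rooted = FALSE)
  tr$edge.length <- stats::runif(length(tr$edge.length), 0.1, 2)
  tr
}
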