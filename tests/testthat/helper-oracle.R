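# Brute-force union-find over symmetrized edges: the independent oracle
# for component grouping. Deliberately naive and separate from the
# igraph-backed implementation it checks.
uf_components <- function(nodes, edges) {
  parent <- seq_along(nodes)
  idx <- stats::setNames(seq_along(nodes), nodes)
  find <- function(i) {
    while (parent[[i]] != i) {
      parent[[i]] <<- parent[[parent[[i]]]]
      i <- parent[[i]]
    }
    i
  }
  if (nrow(edges)) {
    for (e in seq_len(nrow(edges))) {
      a <- find(idx[[edges$from[[e]]]])
      b <- find(idx[[edges$to[[e]]]])
      if (a != b) parent[[b]] <- a
    }
  }
  roots <- vapply(seq_along(nodes), find, 0L)
  groups <- split(nodes, roots)
  groups <- lapply(unname(groups), function(x) sort(x, method = "radix"))
  groups[order(vapply(groups, `[[`, "", 1L), method = "radix")]
}

# Erdos-Renyi digraph as a bare reference_graph (node labels are arbitrary
# strings; component grouping does not require CURIE semantics)
random_digraph <- function(n, p, seed) {
  set.seed(seed)
  nodes <- sprintf("n%03d", seq_len(n))
  pairs <- expand.grid(from = nodes, to = nodes, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$from != pairs$to, , drop = FALSE]
  keep <- runif(nrow(pairs)) < p
  structure(list(nodes = nodes,
                 edges = pairs[keep, , drop = FALSE],
                 dangling = data.frame(from = character(), to = character())),
            class = "reference_graph")
}

# canonical string form of a partition, for set comparison
partition_key <- function(groups)
  sort(vapply(groups, paste, "", collapse = "|"), method = "radix")

# ground-truth partition of a generated fixture
truth_partition <- function(fixture) {
  groups <- split(names(fixture$truth$membership), fixture$truth$membership)
  lapply(unname(groups), function(x) sort(x, method = "radix"))
}

recovered_partition <- function(concepts) lapply(concepts, `[[`, "members")
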