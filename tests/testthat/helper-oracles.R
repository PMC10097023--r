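# Independent brute-force oracles and fixture builders used across tests.

# Triple-loop TOM, straight from the definition.
tom_oracle <- function(a) {
  p <- ncol(a)
  k <- sapply(seq_len(p), function(i) sum(a[i, -i]))
  tom <- diag(p)
  for (i in seq_len(p)) {
    for (j in seq_len(p)) {
      if (i == j) next
      l <- 0
      for (u in seq_len(p)) {
        if (u != i && u != j) l <- l + a[i, u] * a[u, j]
      }
      tom[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
    }
  }
  tom
}

# MNC by hand: largest connected component (depth-first search on an
# adjacency matrix) of the open neighbourhood of v.
mnc_oracle <- function(adj, v) {
  nb <- which(adj[v, ] > 0)
  nb <- setdiff(nb, v)
  if (length(nb) == 0) return(0L)
  sub <- adj[nb, nb, drop = FALSE]
  seen <- rep(FALSE, length(nb))
  best <- 0L
  for (s in seq_along(nb)) {
    if (seen[s]) next
    stack <- s
    comp <- 0L
    while (length(stack) > 0) {
      cur <- stack[length(stack)]
      stack <- stack[-length(stack)]
      if (seen[cur]) next
      seen[cur] <- TRUE
      comp <- comp + 1L
      stack <- c(stack, which(sub[cur, ] > 0 & !seen))
    }
    best <- max(best, comp)
  }
  best
}

# weighted_network object from a 0/1 (or weighted) adjacency matrix.
network_from_adjacency <- function(adj, ids = NULL) {
  p <- ncol(adj)
  if (is.null(ids)) ids <- sprintf("n%02d", seq_len(p))
  idx <- which(upper.tri(adj) & adj > 0, arr.ind = TRUE)
  edges <- data.frame(from = ids[idx[, 1]], to = ids[idx[, 2]],
                      weight = adj[idx], stringsAsFactors = FALSE)
  conn <- sapply(seq_len(p), function(i) sum(adj[i, -i]))
  nodes <- data.frame(id = ids, genus = NA_character_, connectivity = conn,
                      stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges), class = "weighted_network")
}

# Adjacency matrix of the g-th labelled graph on n nodes (g indexes the
# edge bit pattern).
graph_from_bits <- function(n, g) {
  m <- n * (n - 1) / 2
  bits <- as.integer(intToBits(g))[seq_len(m)]
  adj <- matrix(0L, n, n)
  adj[upper.tri(adj)] <- bits
  adj + t(adj)
}

# Tiny abundance table with explicit lineages.
toy_table <- function() {
  counts <- matrix(c(3, 4, 2,
                     0, 5, 1), nrow = 2, byrow = TRUE,
                   dimnames = list(c("s1", "s2"), c("o1", "o2", "o3")))
  tax <- data.frame(
    otu_id = c("o1", "o2", "o3"),
    lineage = c(
      "k__Bacteria;p__Firmicutes;c__Bacilli;o__Lactobacillales;f__Lactobacillaceae;g__Lactobacillus;s__",
      "k__Bacteria;p__Firmicutes;c__Bacilli;o__Lactobacillales;f__Lactobacillaceae;g__Lactobacillus;s__",
      "k__Bacteria;p__Bacteroidetes;c__Bacteroidia;o__Bacteroidales;f__Rikenellaceae;g__;s__"
    ), stringsAsFactors = FALSE
  )
  abundance_table(counts, cbind(tax["otu_id"], parse_lineage(tax$lineage),
                                tax["lineage"]))
}
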