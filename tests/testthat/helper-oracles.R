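# independent brute-force oracles (explicit loops and per-branch sums),
# deliberately unrelated to the package's vectorized implementations

bc_brute <- function(x, y) sum(abs(x - y)) / sum(x + y)

bc_matrix_brute <- function(counts) {
  n <- nrow(counts)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    d[i, j] <- bc_brute(counts[i, ], counts[j, ])
  d
}

# descendant tips of a node, by recursive edge walk
desc_tips <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(node)
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  unlist(lapply(kids, desc_tips, tree = tree))
}

wu_brute <- function(counts, tree, normalized = TRUE) {
  rel <- counts / rowSums(counts)
  S <- nrow(rel)
  d <- matrix(0, S, S)
  for (i in seq_len(S)) for (j in seq_len(S)) {
    num <- 0; den <- 0
    for (e in seq_len(nrow(tree$edge))) {
      tips <- tree$tip.label[desc_tips(tree, tree$edge[e, 2])]
      tips <- intersect(tips, colnames(rel))
      a <- sum(rel[i, tips]); b <- sum(rel[j, tips])
      num <- num + tree$edge.length[e] * abs(a - b)
      den <- den + tree$edge.length[e] * (a + b)
    }
    d[i, j] <- if (normalized) { if (den > 0) num / den else 0 } else num
  }
  d
}

mntd_brute <- function(x, tree, abundance_weighted = FALSE) {
  D <- stats::cophenetic(tree)
  present <- names(x)[x > 0]
  nn <- numeric(length(present))
  for (k in seq_along(present)) {
    others <- setdiff(present, present[k])
    nn[k] <- min(D[present[k], others])
  }
  if (abundance_weighted) {
    w <- x[present] / sum(x[present])
    sum(w * nn)
  } else mean(nn)
}

bmntd_brute <- function(a, b, tree, abundance_weighted = TRUE) {
  D <- stats::cophenetic(tree)
  pa <- names(a)[a > 0]; pb <- names(b)[b > 0]
  da <- vapply(pa, function(i) min(D[i, pb]), numeric(1))
  db <- vapply(pb, function(j) min(D[j, pa]), numeric(1))
  if (abundance_weighted) {
    wa <- a[pa] / sum(a[pa]); wb <- b[pb] / sum(b[pb])
    (sum(wa * da) + sum(wb * db)) / 2
  } else (mean(da) + mean(db)) / 2
}

spearman_brute <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  n <- length(x)
  r <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  tval <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * pt(abs(tval), n - 2, lower.tail = FALSE))
}

# Newman modularity by explicit double sum over node pairs
modularity_brute <- function(edges, membership) {
  nodes <- names(membership)
  A <- matrix(0, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  for (k in seq_len(nrow(edges))) {
    A[edges$taxon_a[k], edges$taxon_b[k]] <- 1
    A[edges$taxon_b[k], edges$taxon_a[k]] <- 1
  }
  m2 <- sum(A)                      # 2m
  deg <- rowSums(A)
  q <- 0
  for (i in nodes) for (j in nodes) {
    if (membership[i] == membership[j])
      q <- q + A[i, j] - deg[i] * deg[j] / m2
  }
  unname(q / m2)
}
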