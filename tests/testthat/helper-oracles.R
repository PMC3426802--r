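# Shared fixtures and independent brute-force oracles.

# worked-example patterns: a, its shifted copy b1 = a + 6, and the shifted
# anti-correlated pattern b8 = 17 - a
wx_a  <- c(4, 7, 6, 3, 6, 5, 8, 7, 3)
wx_b1 <- c(10, 13, 12, 9, 12, 11, 14, 13, 9)
wx_b8 <- c(13, 10, 11, 14, 11, 12, 9, 10, 14)

# the 8-pattern interpolation family at full precision, by direct arithmetic
# (independent of interpolate_patterns)
wx_family <- t(sapply(0:7, function(k) wx_b1 + (k / 7) * (wx_b8 - wx_b1)))

# frozen regression constants for nmrs(a, b_k): closed-form values of the
# centered-residue ratio along the family, (1-2t)/(1-t) for t <= 1/2, else 0
wx_nmrs_family <- c(1, 5 / 6, 3 / 5, 1 / 4, 0, 0, 0, 0)

# wrap a binary adjacency as a coexpression_network
net_from_adj <- function(A) {
  S <- A
  diag(S) <- 1
  if (is.null(rownames(S))) rownames(S) <- colnames(S) <- paste0("g", seq_len(nrow(S)))
  threshold_network(S, 0.5)
}

rand_adj <- function(n, p = 0.35) {
  A <- matrix(0L, n, n)
  A[upper.tri(A)] <- stats::rbinom(n * (n - 1) / 2, 1L, p)
  A <- A + t(A)
  rownames(A) <- colnames(A) <- paste0("g", seq_len(n))
  A
}

rand_connected_adj <- function(n, p = 0.5) {
  repeat {
    A <- rand_adj(n, p)
    if (is_connected_brute(A)) return(A)
  }
}

# connectivity / components by boolean matrix powering (transitive closure)
reach_matrix <- function(A) {
  R <- (A > 0) | diag(TRUE, nrow(A))
  for (i in seq_len(ceiling(log2(max(2, nrow(A)))))) R <- (R %*% R) > 0
  R
}

is_connected_brute <- function(A) all(reach_matrix(A))

components_brute <- function(A) {
  R <- reach_matrix(A)
  groups <- unique(apply(R, 1L, paste, collapse = ""))
  lapply(groups, function(gk) which(apply(R, 1L, paste, collapse = "") == gk))
}

# TOM by literal triple loop over the defining formula
brute_tom <- function(A) {
  n <- nrow(A)
  k <- rowSums(A)
  Tm <- diag(1, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    l <- 0
    for (u in seq_len(n)) l <- l + A[i, u] * A[u, j]
    Tm[i, j] <- (l + A[i, j]) / (min(k[i], k[j]) + 1 - A[i, j])
  }
  Tm
}

# exhaustive spanning-tree enumeration: all (n-1)-subsets of the edge set
# that connect every vertex; returns the maximum total weight
max_spanning_weight_brute <- function(A, W) {
  n <- nrow(A)
  idx <- which(upper.tri(A) & A == 1, arr.ind = TRUE)
  ne <- nrow(idx)
  stopifnot(ne >= n - 1)
  best <- -Inf
  for (cols in utils::combn(ne, n - 1, simplify = FALSE)) {
    sub <- matrix(0, n, n)
    for (r in cols) {
      sub[idx[r, 1], idx[r, 2]] <- 1
      sub[idx[r, 2], idx[r, 1]] <- 1
    }
    if (is_connected_brute(sub))
      best <- max(best, sum(W[idx[cols, , drop = FALSE]]))
  }
  best
}

# upper-tail hypergeometric by full subset enumeration: all C(g, n) draws of
# a module from a genome whose first f genes carry the annotation
hyper_tail_enum <- function(n, f, g) {
  draws <- utils::combn(g, n)
  overlap <- colSums(draws <= f)
  vapply(0:min(n, f), function(k) mean(overlap >= k), numeric(1))
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

# verify a spanning_tree object is a spanning tree of the graph
expect_valid_tree <- function(tree, A) {
  n <- nrow(A)
  expect_equal(nrow(tree$edges), n - 1)
  sub <- matrix(0, n, n)
  for (r in seq_len(nrow(tree$edges))) {
    e <- tree$edges[r, ]
    expect_equal(A[e$u, e$v], 1)  # tree edges exist in the graph
    sub[e$u, e$v] <- sub[e$v, e$u] <- 1
  }
  expect_true(is_connected_brute(sub))
}
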