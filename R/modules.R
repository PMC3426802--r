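# Topological overlap, maximum spanning trees, and recursive
# weakest-edge splitting into network modules.

region_adjacency <- function(region) {
  A <- if (inherits(region, "connected_region")) region$adjacency else as.matrix(region)
  if (nrow(A) != ncol(A)) stop("adjacency must be square", call. = FALSE)
  if (nrow(A) < 2L) stop("a region needs at least 2 vertices", call. = FALSE)
  if (!all(A %in% c(0, 1))) stop("adjacency must be binary", call. = FALSE)
  if (any(A != t(A))) stop("adjacency must be symmetric", call. = FALSE)
  if (any(diag(A) != 0)) stop("adjacency must have a zero diagonal", call. = FALSE)
  storage.mode(A) <- "double"
  A
}

#' Topological overlap matrix of an unweighted region
#'
#' For a binary, symmetric, zero-diagonal adjacency `A`, the topological
#' overlap between distinct vertices i and j is
#'
#' \deqn{TOM_{ij} = \frac{l_{ij} + a_{ij}}{\min(k_i, k_j) + 1 - a_{ij}}}{
#'   TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)}
#'
#' where \eqn{l_{ij} = \sum_u a_{iu} a_{uj}} counts shared neighbours and
#' \eqn{k_i = \sum_u a_{iu}} is the node connectivity (degree). The diagonal
#' is defined as 1. TOM lies in \[0, 1\] and equals 1 whenever one vertex's
#' closed neighbourhood contains the other's: it rewards pairs that are both
#' directly linked and embedded in the same neighbourhood.
#'
#' @param region A `connected_region` (from [connected_regions()]) or a
#'   binary symmetric adjacency matrix with zero diagonal, size >= 2.
#' @return A symmetric numeric matrix in \[0, 1\] with unit diagonal.
#' @examples
#' path <- rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0))  # a - b - c
#' tom_matrix(path)   # TOM(a,b) = 1, TOM(a,c) = 0.5
#' @export
tom_matrix <- function(region) {
  A <- region_adjacency(region)
  L <- A %*% A                       # shared-neighbour counts l_ij
  k <- rowSums(A)                    # node connectivity k_i
  Tm <- (L + A) / (outer(k, k, pmin) + 1 - A)
  diag(Tm) <- 1
  dimnames(Tm) <- dimnames(A)
  Tm
}

#' Average topological overlap of a vertex set
#'
#' Mean TOM over all unordered pairs in the set; this is the homogeneity
#' score that drives module acceptance in [extract_modules()].
#'
#' @param tom A TOM matrix from [tom_matrix()].
#' @param vertices Indices or names of the vertices to average over; all
#'   vertices of `tom` by default. At least 2.
#' @return A single number in \[0, 1\].
#' @export
average_tom <- function(tom, vertices = NULL) {
  tom <- as.matrix(tom)
  if (is.null(vertices)) vertices <- seq_len(nrow(tom))
  if (length(vertices) < 2L)
    stop("average TOM needs at least 2 vertices", call. = FALSE)
  sub <- tom[vertices, vertices, drop = FALSE]
  mean(sub[upper.tri(sub)])
}

#' Maximum spanning tree of a connected region under TOM weights
#'
#' Prim's algorithm run for maximum instead of minimum total weight. Only
#' edges actually present in the region's adjacency are candidates; their
#' weights are the corresponding TOM values. Ties between equal-weight
#' frontier edges are broken by the smallest (source index, target index)
#' pair, making the tree deterministic.
#'
#' @param region A `connected_region` or binary adjacency matrix (connected).
#' @param tom Optional TOM matrix; computed from the region if omitted.
#' @return An object of class `spanning_tree`: list with `edges` (data frame
#'   `u`, `v`, `weight`, vertex indices with `u < v`, in insertion order),
#'   `vertex_ids`, and `total_weight`.
#' @export
maximum_spanning_tree <- function(region, tom = NULL) {
  A <- region_adjacency(region)
  if (is.null(tom)) tom <- tom_matrix(A)
  Tm <- as.matrix(tom)
  n <- nrow(A)
  in_tree <- logical(n)
  in_tree[1L] <- TRUE
  # best known connection of each outside vertex to the tree
  cand_w <- ifelse(A[1L, ] == 1, Tm[1L, ], -Inf)
  cand_src <- rep(1L, n)
  eu <- ev <- integer(n - 1L)
  ew <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    w <- ifelse(in_tree, -Inf, cand_w)
    if (all(w == -Inf))
      stop("region is disconnected; pass a connected_region", call. = FALSE)
    # pick max weight; ties by smallest (source, target)
    best <- which(w == max(w))
    best <- best[order(cand_src[best], best)][1L]
    i <- cand_src[best]
    eu[step] <- min(i, best)
    ev[step] <- max(i, best)
    ew[step] <- Tm[i, best]
    in_tree[best] <- TRUE
    upd <- which(!in_tree & A[best, ] == 1 &
                   (Tm[best, ] > cand_w |
                      (Tm[best, ] == cand_w & best < cand_src)))
    if (length(upd)) {
      cand_w[upd] <- Tm[best, upd]
      cand_src[upd] <- best
    }
  }
  structure(
    list(edges = data.frame(u = eu, v = ev, weight = ew),
         vertex_ids = rownames(A) %||% as.character(seq_len(n)),
         total_weight = sum(ew)),
    class = "spanning_tree"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.spanning_tree <- function(x, ...) {
  cat(sprintf("spanning_tree: %d vertices, total weight %.4f\n",
              length(x$vertex_ids), x$total_weight))
  invisible(x)
}

#' Weakest edge of a spanning tree
#'
#' The edge of minimum weight; ties are broken by (weight, smaller endpoint
#' index, larger endpoint index).
#'
#' @param tree A `spanning_tree` from [maximum_spanning_tree()].
#' @return A one-row data frame with columns `u`, `v`, `weight`.
#' @export
weakest_edge <- function(tree) {
  if (!inherits(tree, "spanning_tree"))
    stop("expected a spanning_tree", call. = FALSE)
  e <- tree$edges
  if (nrow(e) == 0L) stop("tree has no edges", call. = FALSE)
  e[order(e$weight, e$u, e$v)[1L], , drop = FALSE]
}

# Split the vertex set 'v' (indices into A0) at the weakest edge of its
# maximum spanning tree, or accept it as a module. Adjacency and TOM are
# recomputed on the induced subgraph, which is what makes a split child a
# fresh connected region.
split_or_accept <- function(A0, v, epsilon) {
  A <- A0[v, v, drop = FALSE]
  Tm <- tom_matrix(A)
  avg <- average_tom(Tm)
  if (length(v) == 2L)
    return(list(accept = TRUE, avg = avg))
  tree <- maximum_spanning_tree(A, Tm)
  we <- weakest_edge(tree)
  keep <- rep(TRUE, nrow(tree$edges))
  keep[as.integer(rownames(we))] <- FALSE  # remove exactly the weakest edge
  # components of the tree after removing the weakest edge
  nb <- vector("list", length(v))
  for (r in which(keep)) {
    e <- tree$edges[r, ]
    nb[[e$u]] <- c(nb[[e$u]], e$v)
    nb[[e$v]] <- c(nb[[e$v]], e$u)
  }
  side <- logical(length(v))
  stack <- we$u
  side[we$u] <- TRUE
  while (length(stack)) {
    cur <- stack[[1L]]
    stack <- stack[-1L]
    for (x in nb[[cur]]) if (!side[x]) {
      side[x] <- TRUE
      stack <- c(stack, x)
    }
  }
  kids <- list(v[side], v[!side])
  kids <- kids[order(vapply(kids, min, numeric(1)))]
  child_avg <- vapply(kids, function(kv) {
    if (length(kv) < 2L) return(-Inf)
    average_tom(tom_matrix(A0[kv, kv, drop = FALSE]))
  }, numeric(1))
  if (max(child_avg) > avg + epsilon)
    list(accept = FALSE, avg = avg, children = kids)
  else
    list(accept = TRUE, avg = avg)
}

#' Extract network modules from a connected region
#'
#' Recursive weakest-edge splitting: a candidate vertex set (initially the
#' whole region) is scored by its average TOM, then split into two subtrees
#' by removing the weakest edge of its TOM-weighted maximum spanning tree.
#' If neither child's average TOM (recomputed on its own induced subgraph)
#' strictly exceeds the parent's, no split helps and the parent is emitted
#' whole as a module; otherwise both children re-enter the queue as new
#' connected regions. Sets that can no longer split (2 vertices) are
#' emitted; sets smaller than `min_size` are discarded with a log message.
#'
#' Emitted modules are pairwise disjoint subsets of the region, each
#' connected in the original network.
#'
#' @param region A `connected_region` (or binary adjacency matrix of a
#'   connected graph) with >= 2 vertices.
#' @param min_size Minimum module size (>= 2); smaller vertex sets are
#'   dropped, not reported. Default 4.
#' @param epsilon Tolerance on the average-TOM improvement required to keep
#'   splitting.
#' @return A list of `network_module` objects: `gene_ids`, `avg_tom`,
#'   `size`, `parent_region`. The attribute `"discarded"` holds the vertex
#'   sets dropped for being smaller than `min_size`.
#' @examples
#' # two 4-cliques joined by one bridge edge: the cliques are the modules
#' A <- matrix(0, 8, 8)
#' A[1:4, 1:4] <- 1; A[5:8, 5:8] <- 1; A[4, 5] <- A[5, 4] <- 1
#' diag(A) <- 0
#' rownames(A) <- colnames(A) <- paste0("g", 1:8)
#' extract_modules(A, min_size = 4)
#' @export
extract_modules <- function(region, min_size = 4L, epsilon = 1e-12) {
  if (!is.numeric(min_size) || length(min_size) != 1L || min_size < 2)
    stop("min_size must be a single integer >= 2", call. = FALSE)
  min_size <- as.integer(min_size)
  A0 <- region_adjacency(region)
  ids <- rownames(A0) %||% as.character(seq_len(nrow(A0)))
  parent <- if (inherits(region, "connected_region")) region$region_id else NA_character_
  modules <- list()
  discarded <- list()
  queue <- list(seq_len(nrow(A0)))
  while (length(queue)) {
    v <- queue[[1L]]
    queue <- queue[-1L]
    if (length(v) < min_size) {
      discarded[[length(discarded) + 1L]] <- ids[v]
      next
    }
    res <- split_or_accept(A0, v, epsilon)
    if (res$accept) {
      modules[[length(modules) + 1L]] <- structure(
        list(gene_ids = ids[v], avg_tom = res$avg, size = length(v),
             parent_region = parent),
        class = "network_module"
      )
    } else {
      queue <- c(res$children, queue)  # depth-first, smaller-index child first
    }
  }
  if (length(discarded))
    message(sprintf("extract_modules: discarded %d vertex set(s) below min_size = %d (%d gene(s))",
                    length(discarded), min_size, sum(lengths(discarded))))
  attr(modules, "discarded") <- discarded
  modules
}

#' @export
print.network_module <- function(x, ...) {
  cat(sprintf("network_module: %d genes, average TOM %.4f (region %s)\n",
              x$size, x$avg_tom, x$parent_region))
  invisible(x)
}

#' Mine all network modules of a co-expression network
#'
#' Convenience wrapper: finds the connected regions of the network and runs
#' [extract_modules()] on each, assigning module identifiers `M1`, `M2`, ...
#' in deterministic order.
#'
#' @param network A `coexpression_network` from [threshold_network()].
#' @inheritParams extract_modules
#' @return A list of `network_module` objects with attributes `isolated`
#'   (genes with no edge) and `n_discarded` (count of dropped small sets).
#' @export
mine_modules <- function(network, min_size = 4L, epsilon = 1e-12) {
  regions <- connected_regions(network)
  modules <- list()
  n_disc <- 0L
  for (r in regions) {
    if (length(r$vertex_ids) < min_size) {
      n_disc <- n_disc + 1L
      message(sprintf("mine_modules: region %s (%d genes) below min_size, discarded",
                      r$region_id, length(r$vertex_ids)))
      next
    }
    mods <- extract_modules(r, min_size = min_size, epsilon = epsilon)
    n_disc <- n_disc + length(attr(mods, "discarded"))
    modules <- c(modules, mods)
  }
  if (length(modules)) {
    for (i in seq_along(modules)) modules[[i]]$module_id <- paste0("M", i)
  }
  attr(modules, "isolated") <- attr(regions, "isolated")
  attr(modules, "n_discarded") <- n_disc
  modules
}

#' Tabulate mined modules
#'
#' @param modules A list of `network_module`s from [mine_modules()] or
#'   [extract_modules()].
#' @return A data frame with one row per gene: `module_id`, `gene_id`,
#'   `avg_tom`, `parent_region`.
#' @export
modules_to_data_frame <- function(modules) {
  if (!length(modules))
    return(data.frame(module_id = character(), gene_id = character(),
                      avg_tom = numeric(), parent_region = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, lapply(seq_along(modules), function(i) {
    m <- modules[[i]]
    data.frame(module_id = m$module_id %||% paste0("M", i),
               gene_id = m$gene_ids,
               avg_tom = m$avg_tom,
               parent_region = m$parent_region,
               stringsAsFactors = FALSE)
  }))
}
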