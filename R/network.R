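# Similarity matrix, signum hard thresholding, and connected regions.

check_expression_matrix <- function(D) {
  D <- as.matrix(D)
  if (!is.numeric(D)) stop("expression matrix must be numeric", call. = FALSE)
  if (nrow(D) < 2L || ncol(D) < 2L)
    stop("expression matrix needs at least 2 genes and 2 conditions", call. = FALSE)
  if (is.null(rownames(D)))
    rownames(D) <- paste0("g", seq_len(nrow(D)))
  if (anyDuplicated(rownames(D)))
    stop("duplicate gene identifiers in expression matrix", call. = FALSE)
  if (!all(is.finite(D)))
    stop("expression matrix contains non-finite values; screen rows at ingest",
         call. = FALSE)
  D
}

#' Pairwise similarity matrix of an expression matrix
#'
#' Evaluates the chosen measure on every unordered gene pair (the upper
#' triangle, n(n-1)/2 evaluations), mirrors it, and sets the diagonal to 1.
#' The default `nmrs` yields values in \[0, 1\] and is the measure the
#' downstream hard thresholding expects; `pearson` and `spearman` are
#' provided for comparison and yield values in \[-1, 1\].
#'
#' @param D Numeric gene-by-condition matrix with unique rownames (gene
#'   identifiers); at least 2 genes and 2 conditions, all values finite.
#' @param measure One of `"nmrs"`, `"pearson"`, `"spearman"`.
#' @return A symmetric n x n numeric matrix with unit diagonal and the gene
#'   identifiers as dimnames.
#' @examples
#' pats <- pattern_family()
#' S <- similarity_matrix(pats[c("a", "b1", "b8"), ])
#' S["a", "b1"]  # 1: b1 is a shifted copy of a
#' S["a", "b8"]  # 0: b8 is shifted and anti-correlated
#' @export
similarity_matrix <- function(D, measure = c("nmrs", "pearson", "spearman")) {
  if (is.character(measure) && length(measure) == 1L &&
      !measure %in% c("nmrs", "pearson", "spearman"))
    stop(sprintf("unknown similarity measure '%s'", measure), call. = FALSE)
  measure <- match.arg(measure)
  D <- check_expression_matrix(D)
  n <- nrow(D)

  if (measure == "nmrs") {
    Xc <- D - rowMeans(D)
    A <- rowSums(abs(Xc))
    S <- diag(1, n)
    for (i in seq_len(n - 1L)) {
      rest <- (i + 1L):n
      num <- rowSums(abs(Xc[rest, , drop = FALSE] -
                           rep(Xc[i, ], each = length(rest))))
      den <- A[i] + A[rest]
      s <- ifelse(den == 0, 1, 1 - num / den)  # both-constant pairs are mutual shifts
      s <- pmin(1, pmax(0, s))
      S[i, rest] <- s
      S[rest, i] <- s
    }
  } else {
    if (any(apply(D, 1L, stats::sd) == 0))
      stop(sprintf("%s correlation is undefined for a constant profile", measure),
           call. = FALSE)
    S <- stats::cor(t(D), method = measure)
    diag(S) <- 1
  }
  dimnames(S) <- list(rownames(D), rownames(D))
  S
}

#' Hard-threshold a similarity matrix into a co-expression network
#'
#' Applies the signum function at threshold `delta`: two distinct genes are
#' connected by an (unweighted, undirected) edge when their similarity is at
#' least `delta` (or strictly above it with `strict = TRUE`). Self-loops are
#' never created.
#'
#' @param S Symmetric similarity matrix (as from [similarity_matrix()]).
#' @param delta Similarity threshold in \[0, 1\].
#' @param strict If `TRUE`, require similarity strictly greater than `delta`;
#'   the default includes boundary pairs (similarity equal to `delta`).
#' @return An object of class `coexpression_network`: a list with the binary
#'   `adjacency` matrix, `gene_ids`, `delta` and `strict`.
#' @export
threshold_network <- function(S, delta, strict = FALSE) {
  S <- as.matrix(S)
  if (!is.numeric(delta) || length(delta) != 1L || !is.finite(delta) ||
      delta < 0 || delta > 1)
    stop("threshold delta must be a single number in [0, 1]", call. = FALSE)
  if (nrow(S) != ncol(S))
    stop("similarity matrix must be square", call. = FALSE)
  if (max(abs(S - t(S))) > 1e-8)
    stop("similarity matrix must be symmetric", call. = FALSE)
  if (is.null(rownames(S)))
    rownames(S) <- colnames(S) <- paste0("g", seq_len(nrow(S)))
  adj <- if (strict) (S > delta) else (S >= delta)
  storage.mode(adj) <- "integer"
  diag(adj) <- 0L
  structure(
    list(adjacency = adj, gene_ids = rownames(S), delta = delta, strict = strict),
    class = "coexpression_network"
  )
}

#' @export
print.coexpression_network <- function(x, ...) {
  n <- length(x$gene_ids)
  e <- sum(x$adjacency) / 2
  cat(sprintf(
    "coexpression_network: %d genes, %d edges (delta %s %.4g)\n",
    n, e, if (x$strict) ">" else ">=", x$delta))
  invisible(x)
}

#' Connected regions of a co-expression network
#'
#' Partitions the non-isolated vertices into maximal connected components
#' ("connected regions": every vertex pair joined by a path). Regions of
#' size >= 2 are returned in deterministic order (by smallest member gene
#' index); vertices without any edge are reported separately in the
#' `"isolated"` attribute, never inside a region.
#'
#' @param network A `coexpression_network` from [threshold_network()].
#' @return A list of `connected_region` objects, each holding `vertex_ids`
#'   (gene identifiers) and the induced binary `adjacency` submatrix, with
#'   attribute `isolated` (character vector of degree-0 gene identifiers).
#' @export
connected_regions <- function(network) {
  if (!inherits(network, "coexpression_network"))
    stop("expected a coexpression_network", call. = FALSE)
  adj <- network$adjacency
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)
  members <- split(seq_len(nrow(adj)), comp$membership)
  deg <- rowSums(adj)
  isolated <- rownames(adj)[deg == 0]
  members <- Filter(function(v) length(v) >= 2L, members)
  members <- members[order(vapply(members, min, integer(1)))]
  regions <- lapply(seq_along(members), function(i) {
    v <- members[[i]]
    structure(
      list(region_id = paste0("R", i),
           vertex_ids = rownames(adj)[v],
           adjacency = adj[v, v, drop = FALSE]),
      class = "connected_region"
    )
  })
  attr(regions, "isolated") <- isolated
  regions
}

#' @export
print.connected_region <- function(x, ...) {
  cat(sprintf("connected_region %s: %d genes, %d edges\n",
              x$region_id, length(x$vertex_ids), sum(x$adjacency) / 2))
  invisible(x)
}

#' Export a co-expression network to GraphML
#'
#' @param network A `coexpression_network`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
export_graphml <- function(network, path) {
  if (!inherits(network, "coexpression_network"))
    stop("expected a coexpression_network", call. = FALSE)
  g <- igraph::graph_from_adjacency_matrix(network$adjacency, mode = "undirected")
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
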