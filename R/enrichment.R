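# Hypergeometric enrichment of network modules against gene-set
# annotations, with Benjamini-Hochberg q-values.

#' Upper-tail cumulative hypergeometric p-value
#'
#' Probability of observing `k` or more annotated genes in a module of size
#' `n` drawn without replacement from a genome of `g` genes of which `f`
#' carry the annotation:
#'
#' \deqn{p = \sum_{i=k}^{\min(n,f)}
#'   \frac{\binom{f}{i}\binom{g-f}{n-i}}{\binom{g}{n}}}{
#'   p = sum_{i=k..min(n,f)} C(f,i) C(g-f,n-i) / C(g,n)}
#'
#' Computed via the upper tail of [stats::phyper()], whose log-space
#' internals keep tiny tails accurate. `k = 0` returns exactly 1.
#'
#' @param k Observed overlap count (0 <= k <= min(n, f)).
#' @param n Module size (n <= g).
#' @param f Category size (f <= g).
#' @param g Genome size.
#' @return A number in (0, 1].
#' @examples
#' hypergeom_p(2, 3, 4, 10)  # 1/3
#' @export
hypergeom_p <- function(k, n, f, g) {
  vals <- c(k = k, n = n, f = f, g = g)
  if (!all(is.finite(vals)) || any(vals != round(vals)) || any(vals < 0))
    stop("k, n, f, g must be nonnegative integers", call. = FALSE)
  if (k > min(n, f) || n > g || f > g)
    stop(sprintf("infeasible counts: k=%d, n=%d, f=%d, g=%d", k, n, f, g),
         call. = FALSE)
  if (k == 0) return(1)
  stats::phyper(k - 1, f, g - f, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment: with the p-values sorted ascending,
#' `q_(i) = min_{j >= i} p_(j) * m / j`, capped at 1 and returned in the
#' input order. A single test is returned unchanged.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted q-values, same length and order as `p`.
#' @export
bh_qvalues <- function(p) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must be numeric in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' Read a GMT gene-set annotation file
#'
#' One set per line: term identifier, description, then the member genes,
#' tab-separated. The genome size defaults to the number of distinct genes
#' in the union of all sets, and can be overridden when a better estimate of
#' the annotated genome is available.
#'
#' @param path Path to a GMT file.
#' @param genome_size Optional genome size `g`; must be at least the size
#'   of every category and of the gene universe.
#' @return An `annotation_catalog`: list with `sets` (named list of gene
#'   vectors), `descriptions` (named character), `universe`, `genome_size`.
#' @export
read_gmt <- function(path, genome_size = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty GMT file", call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad))
    stop(sprintf("GMT parse error at line %d: need term, description and >= 1 gene",
                 bad[1L]), call. = FALSE)
  ids <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(ids))
    stop("duplicate term identifiers in GMT file", call. = FALSE)
  sets <- lapply(fields, function(fl) unique(fl[-(1:2)]))
  names(sets) <- ids
  descriptions <- vapply(fields, `[[`, character(1), 2L)
  names(descriptions) <- ids
  annotation_catalog(sets, descriptions, genome_size)
}

#' Build an annotation catalog from gene sets
#'
#' @param sets Named list of character vectors (term id -> member genes).
#' @param descriptions Optional named character vector of term descriptions.
#' @param genome_size Optional genome size; defaults to the universe size.
#' @return An `annotation_catalog` (see [read_gmt()]).
#' @export
annotation_catalog <- function(sets, descriptions = NULL, genome_size = NULL) {
  if (!length(sets) || is.null(names(sets)))
    stop("sets must be a non-empty named list", call. = FALSE)
  if (any(lengths(sets) == 0L))
    stop("every category must contain at least one gene", call. = FALSE)
  sets <- lapply(sets, function(s) unique(as.character(s)))
  universe <- sort(unique(unlist(sets, use.names = FALSE)))
  if (is.null(genome_size)) genome_size <- length(universe)
  genome_size <- as.integer(genome_size)
  if (genome_size < length(universe) || any(lengths(sets) > genome_size))
    stop("genome_size smaller than the annotation universe", call. = FALSE)
  if (is.null(descriptions)) {
    descriptions <- stats::setNames(rep("", length(sets)), names(sets))
  }
  structure(
    list(sets = sets, descriptions = descriptions,
         universe = universe, genome_size = genome_size),
    class = "annotation_catalog"
  )
}

#' @export
print.annotation_catalog <- function(x, ...) {
  cat(sprintf("annotation_catalog: %d categories, %d genes in universe, genome size %d\n",
              length(x$sets), length(x$universe), x$genome_size))
  invisible(x)
}

#' Write gene sets to a GMT file
#'
#' @param modules A list of `network_module`s, or a named list of gene
#'   identifier vectors.
#' @param path Output path.
#' @param descriptions Optional descriptions, one per set.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(modules, path, descriptions = NULL) {
  if (length(modules) && inherits(modules[[1]], "network_module")) {
    sets <- lapply(modules, `[[`, "gene_ids")
    names(sets) <- vapply(seq_along(modules), function(i)
      modules[[i]]$module_id %||% paste0("M", i), character(1))
    if (is.null(descriptions))
      descriptions <- sprintf("network module (avg TOM %.4f)",
                              vapply(modules, `[[`, numeric(1), "avg_tom"))
  } else {
    sets <- modules
  }
  if (is.null(descriptions)) descriptions <- rep("", length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric enrichment of one module against a catalog
#'
#' Module genes absent from the catalog's gene universe are logged and
#' excluded from the effective module size `n`. Every category in the
#' catalog is tested (categories with zero overlap contribute p = 1 to the
#' multiple-testing family); q-values are Benjamini-Hochberg adjusted within
#' this module's family of tests, and only categories with overlap k >= 1
#' are reported, sorted by ascending p-value.
#'
#' @param genes Character vector of module gene identifiers, or a
#'   `network_module`.
#' @param catalog An `annotation_catalog` from [read_gmt()] or
#'   [annotation_catalog()].
#' @return A data frame with columns `term_id`, `description`, `k`, `n`,
#'   `f`, `g`, `p_value`, `q_value`.
#' @export
enrich_module <- function(genes, catalog) {
  if (inherits(genes, "network_module")) genes <- genes$gene_ids
  if (!inherits(catalog, "annotation_catalog"))
    stop("expected an annotation_catalog", call. = FALSE)
  genes <- unique(as.character(genes))
  eff <- intersect(genes, catalog$universe)
  missed <- length(genes) - length(eff)
  if (missed > 0)
    message(sprintf("enrich_module: %d gene(s) not in the annotation universe, excluded", missed))
  empty <- data.frame(term_id = character(), description = character(),
                      k = integer(), n = integer(), f = integer(), g = integer(),
                      p_value = numeric(), q_value = numeric(),
                      stringsAsFactors = FALSE)
  if (!length(eff)) {
    warning("module has no genes in the annotation universe", call. = FALSE)
    return(empty)
  }
  n <- length(eff)
  g <- catalog$genome_size
  k <- vapply(catalog$sets, function(s) length(intersect(eff, s)), integer(1))
  f <- lengths(catalog$sets)
  p <- vapply(seq_along(k), function(i) hypergeom_p(k[i], n, f[i], g), numeric(1))
  q <- bh_qvalues(p)
  res <- data.frame(term_id = names(catalog$sets),
                    description = unname(catalog$descriptions[names(catalog$sets)]),
                    k = unname(k), n = n, f = unname(f), g = g,
                    p_value = p, q_value = q,
                    stringsAsFactors = FALSE)
  res <- res[res$k >= 1L, , drop = FALSE]
  res <- res[order(res$p_value, res$term_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Enrichment of a set of mined modules
#'
#' Runs [enrich_module()] on each module and concatenates the results, with
#' a `module_id` column, filtered at a q-value display cutoff (default 0.1).
#'
#' @param modules A list of `network_module`s from [mine_modules()].
#' @param catalog An `annotation_catalog`.
#' @param q_cutoff Report categories with q-value at or below this cutoff;
#'   `Inf` disables filtering. Default 0.1.
#' @return A data frame: `module_id`, `term_id`, `description`, `k`, `n`,
#'   `f`, `g`, `p_value`, `q_value`.
#' @export
enrich_modules <- function(modules, catalog, q_cutoff = 0.1) {
  out <- lapply(seq_along(modules), function(i) {
    res <- enrich_module(modules[[i]], catalog)
    if (!nrow(res)) return(NULL)
    cbind(module_id = modules[[i]]$module_id %||% paste0("M", i), res,
          stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(module_id = character(), term_id = character(),
                      description = character(), k = integer(), n = integer(),
                      f = integer(), g = integer(),
                      p_value = numeric(), q_value = numeric(),
                      stringsAsFactors = FALSE)
  out <- out[out$q_value <= q_cutoff, , drop = FALSE]
  rownames(out) <- NULL
  out
}
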