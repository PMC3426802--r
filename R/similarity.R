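# Pairwise expression-similarity measures and the interpolated-pattern
# family used to characterise them.

# package-local state: remember whether the [0,1] clamp ever fired so the
# note is emitted once per session, not once per gene pair
.modminer_state <- new.env(parent = emptyenv())
.modminer_state$clamp_noted <- FALSE

check_profile_pair <- function(x, y, require_equal_length = TRUE) {
  if (!is.numeric(x) || !is.numeric(y))
    stop("expression profiles must be numeric vectors", call. = FALSE)
  if (require_equal_length && length(x) != length(y))
    stop(sprintf("profile lengths differ (%d vs %d)", length(x), length(y)),
         call. = FALSE)
  if (length(x) < 2L || length(y) < 2L)
    stop("profiles must cover at least 2 conditions", call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("profiles must be finite (no NA/NaN/Inf)", call. = FALSE)
  invisible(TRUE)
}

clamp01 <- function(s) {
  # mathematically s is already in [0,1]; this guards floating-point rounding
  if (s < 0 || s > 1) {
    if (!.modminer_state$clamp_noted) {
      message(sprintf("nmrs: value %.3e clamped into [0, 1] (reported once per session)", s))
      .modminer_state$clamp_noted <- TRUE
    }
    s <- min(1, max(0, s))
  }
  s
}

#' Normalized mean residue similarity (NMRS) between two expression profiles
#'
#' NMRS measures how close two gene expression profiles are to a *shifting
#' pattern*, i.e. to differing only by an additive constant across all
#' conditions. Both profiles are centered by their own means and compared on
#' the residue scale:
#'
#' \deqn{\mathrm{NMRS}(x, y) = 1 -
#'   \frac{\sum_i |\tilde x_i - \tilde y_i|}
#'        {\sum_i (|\tilde x_i| + |\tilde y_i|)}}{
#'   NMRS(x, y) = 1 - sum(|xc - yc|) / sum(|xc| + |yc|)}
#'
#' where \eqn{\tilde x = x - \bar x}. The score is symmetric and lies in
#' \[0, 1\]: it equals 1 exactly when `y` is `x` plus a constant (including
#' `y == x`), and 0 when the centered profiles are exact negations of one
#' another (a shifted, perfectly anti-correlated pattern). Unlike Euclidean
#' distance, no prior normalization of the profiles is needed; unlike rank
#' correlation, the magnitudes of the residues matter.
#'
#' Degenerate inputs: if both profiles are constant the centered profiles
#' vanish and the pair is a perfect mutual shift, so NMRS is 1; if exactly
#' one is constant the ratio equals 1 and NMRS is 0.
#'
#' Note that although `1 - nmrs(x, y)` behaves like a dissimilarity, it does
#' not satisfy the triangle inequality for very short profiles (length 3-5);
#' see the package vignette for a counterexample and for the observed
#' behaviour at realistic condition counts.
#'
#' @param x,y Numeric vectors of equal length (>= 2), finite values.
#' @return A single number in \[0, 1\].
#' @examples
#' a  <- c(4, 7, 6, 3, 6, 5, 8, 7, 3)
#' nmrs(a, a + 6)      # shifting pattern -> 1
#' nmrs(a, 17 - a)     # shifted anti-correlated pattern -> 0
#' @seealso [similarity_matrix()], [interpolate_patterns()]
#' @export
nmrs <- function(x, y) {
  check_profile_pair(x, y)
  xc <- x - mean(x)
  yc <- y - mean(y)
  denom <- sum(abs(xc) + abs(yc))
  if (denom == 0) return(1)  # both constant: mutual shifts of each other
  clamp01(1 - sum(abs(xc - yc)) / denom)
}

#' Pearson correlation between two expression profiles
#'
#' Standard product-moment correlation, provided as a comparison baseline.
#' Pearson detects shifting patterns and scaling patterns alike, and also
#' assigns maximal |correlation| to any other affine transform of a profile.
#'
#' @inheritParams nmrs
#' @return Correlation in \[-1, 1\].
#' @export
pearson_cor <- function(x, y) {
  check_profile_pair(x, y)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("Pearson correlation is undefined for a constant profile", call. = FALSE)
  stats::cor(x, y)
}

#' Spearman rank correlation between two expression profiles
#'
#' Pearson correlation of the rank vectors; ties receive average ranks.
#' Because only rank information is used, Spearman detects neither shifting
#' nor scaling patterns specifically: any monotone transform scores 1.
#'
#' @inheritParams nmrs
#' @return Correlation in \[-1, 1\].
#' @export
spearman_cor <- function(x, y) {
  check_profile_pair(x, y)
  rx <- rank(x)
  ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    stop("Spearman correlation is undefined for a constant profile", call. = FALSE)
  stats::cor(rx, ry)
}

#' Euclidean distance between two raw expression profiles
#'
#' L2 distance of the un-normalized profiles. A pure shift of magnitude `c`
#' over `m` conditions scores `c * sqrt(m)` rather than 0, which is why
#' Euclidean distance needs prior normalization to recognise shifting
#' patterns.
#'
#' @inheritParams nmrs
#' @return A nonnegative number.
#' @export
euclidean_dist <- function(x, y) {
  if (!is.numeric(x) || !is.numeric(y))
    stop("expression profiles must be numeric vectors", call. = FALSE)
  if (length(x) != length(y))
    stop(sprintf("profile lengths differ (%d vs %d)", length(x), length(y)),
         call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("profiles must be finite (no NA/NaN/Inf)", call. = FALSE)
  sqrt(sum((x - y)^2))
}

#' Mean squared residue of a set of expression profiles
#'
#' Aggregate homogeneity score of a gene set (Cheng-Church residue): each
#' entry minus its row mean, minus its column mean, plus the overall mean,
#' squared and averaged over the submatrix. Zero exactly when all profiles
#' are mutual shifts of one another. MSR operates on a whole set at once
#' (aggregate mode) and cannot score a single gene pair symmetrically in the
#' mutual sense the network construction requires.
#'
#' @param profiles Numeric matrix, one gene per row (>= 2 rows), conditions
#'   in columns.
#' @return A nonnegative number.
#' @examples
#' a <- c(4, 7, 6, 3, 6, 5, 8, 7, 3)
#' msr(rbind(a, a + 6))  # perfect shifting pattern -> 0
#' @export
msr <- function(profiles) {
  m <- as.matrix(profiles)
  if (nrow(m) < 2L)
    stop("msr needs at least 2 gene profiles", call. = FALSE)
  if (ncol(m) < 2L)
    stop("profiles must cover at least 2 conditions", call. = FALSE)
  if (!all(is.finite(m)))
    stop("profiles must be finite (no NA/NaN/Inf)", call. = FALSE)
  res <- m - rowMeans(m) - rep(colMeans(m), each = nrow(m)) + mean(m)
  mean(res^2)
}

#' Uniformly interpolated patterns between two profiles
#'
#' Returns `count` profiles stepping linearly (elementwise) from `start` to
#' `end`: step `k` is `start + (k-1)/(count-1) * (end - start)`. This is the
#' construction behind the worked example family `b1..b8` (see
#' [pattern_family()]), used to show how a similarity measure degrades from
#' a pure shifting pattern to a shifted anti-correlated pattern.
#'
#' @param start,end Numeric vectors of equal length.
#' @param count Number of patterns to generate (>= 2); the first equals
#'   `start` and the last equals `end`.
#' @return A `count` x `length(start)` numeric matrix, one pattern per row.
#' @export
interpolate_patterns <- function(start, end, count) {
  check_profile_pair(start, end)
  if (!is.numeric(count) || length(count) != 1L || count < 2 || count != round(count))
    stop("count must be a single integer >= 2", call. = FALSE)
  count <- as.integer(count)
  t <- (seq_len(count) - 1) / (count - 1)
  out <- outer(1 - t, start) + outer(t, end)
  rownames(out) <- paste0("p", seq_len(count))
  colnames(out) <- names(start)
  out
}

#' Qualitative comparison of the implemented proximity measures
#'
#' One row per measure: whether it scores gene pairs (mutual) or whole sets
#' (aggregate), whether profiles must be normalized beforehand, and whether
#' the measure recognises shifting (additive) and scaling (multiplicative)
#' patterns.
#'
#' @return A data frame with columns `measure`, `mode`,
#'   `normalization_required`, `detects_shifting`, `detects_scaling`.
#' @export
measure_table <- function() {
  data.frame(
    measure = c("euclidean", "pearson", "spearman", "msr", "nmrs"),
    mode = c("mutual", "mutual", "mutual", "aggregate", "mutual"),
    normalization_required = c(TRUE, FALSE, FALSE, FALSE, FALSE),
    detects_shifting = c(TRUE, TRUE, FALSE, TRUE, TRUE),
    detects_scaling = c(FALSE, TRUE, FALSE, TRUE, TRUE),
    stringsAsFactors = FALSE
  )
}
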