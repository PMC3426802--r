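k_n <- function(n) {
  A <- matrix(1, n, n) - diag(1, n)
  rownames(A) <- colnames(A) <- paste0("g", seq_len(n))
  A
}

path_3 <- function() {
  A <- rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0))
  rownames(A) <- colnames(A) <- c("a", "b", "c")
  A
}

test_that("tom_matrix matches hand-enumerated values on small graphs", {
  Tm <- tom_matrix(k_n(3))
  expect_equal(unname(Tm), matrix(1, 3, 3))      # triangle: all overlaps 1
  Tp <- tom_matrix(path_3())
  expect_equal(Tp["a", "b"], 1)                  # (0+1)/(1+1-1)
  expect_equal(Tp["b", "c"], 1)
  expect_equal(Tp["a", "c"], 0.5)                # (1+0)/(1+1-0)
  # two vertices joined by a single edge
  pair <- rbind(c(0, 1), c(1, 0))
  expect_equal(unname(tom_matrix(pair)), matrix(1, 2, 2))
  expect_error(tom_matrix(matrix(0, 1, 1)), "at least 2")
  expect_error(tom_matrix(rbind(c(0, 2), c(2, 0))), "binary")
})

test_that("tom_matrix equals the brute-force triple-loop evaluation", {
  set.seed(21)
  for (rep in 1:30) {
    A <- rand_adj(sample(3:12, 1))
    Tm <- tom_matrix(A)
    expect_equal(unname(Tm), unname(brute_tom(A)), tolerance = 1e-12)
    expect_true(all(Tm >= 0 & Tm <= 1))
  }
})

test_that("TOM is 1 whenever one closed neighbourhood contains the other", {
  set.seed(22)
  for (rep in 1:20) {
    A <- rand_adj(8, p = 0.4)
    Tm <- tom_matrix(A)
    for (i in 1:7) for (j in (i + 1):8) {
      ni <- c(which(A[i, ] == 1), i)
      nj <- c(which(A[j, ] == 1), j)
      if (all(nj %in% ni) || all(ni %in% nj))
        expect_equal(Tm[i, j], 1)
    }
  }
})

test_that("average_tom is the mean over unordered pairs", {
  Tp <- tom_matrix(path_3())
  expect_equal(average_tom(Tp), (1 + 1 + 0.5) / 3)
  expect_equal(average_tom(Tp, c("a", "b")), 1)
  expect_equal(average_tom(tom_matrix(k_n(3))), 1)
  expect_error(average_tom(Tp, "a"), "at least 2")
})

test_that("maximum_spanning_tree returns the unique tree of a tree input", {
  P <- path_3()
  tree <- maximum_spanning_tree(P)
  expect_equal(nrow(tree$edges), 2)
  expect_equal(sort(paste(tree$edges$u, tree$edges$v)), c("1 2", "2 3"))
})

test_that("maximum_spanning_tree attains the exhaustive-enumeration optimum", {
  set.seed(23)
  for (rep in 1:12) {
    n <- sample(4:6, 1)
    A <- rand_connected_adj(n)
    W <- matrix(0, n, n)
    W[upper.tri(W)] <- runif(sum(upper.tri(W)))
    W <- W + t(W)
    tree <- maximum_spanning_tree(A, W)
    expect_valid_tree(tree, A)
    expect_equal(tree$total_weight, max_spanning_weight_brute(A, W),
                 tolerance = 1e-12)
  }
})

test_that("equal-weight ties are broken lexicographically", {
  W <- matrix(1, 3, 3)
  tree <- maximum_spanning_tree(k_n(3), W)
  expect_equal(tree$edges$u, c(1, 1))
  expect_equal(tree$edges$v, c(2, 3))
  expect_error(maximum_spanning_tree(rbind(c(0, 0), c(0, 0))), "disconnected")
})

test_that("weakest_edge picks the minimum with deterministic tie-breaks", {
  tree <- structure(list(
    edges = data.frame(u = c(1, 2, 3), v = c(2, 3, 4),
                       weight = c(0.9, 0.3, 0.7)),
    vertex_ids = paste0("g", 1:4), total_weight = 1.9),
    class = "spanning_tree")
  expect_equal(weakest_edge(tree)$weight, 0.3)
  tree$edges$weight <- c(0.5, 0.5, 0.5)
  expect_equal(unlist(weakest_edge(tree)[, c("u", "v")], use.names = FALSE), c(1, 2))
  # agrees with a linear-scan oracle on random weights
  set.seed(24)
  for (rep in 1:20) {
    tree$edges$weight <- runif(3)
    expect_equal(weakest_edge(tree)$weight, min(tree$edges$weight))
  }
  tree$edges <- tree$edges[0, ]
  expect_error(weakest_edge(tree), "no edges")
})

test_that("a homogeneous clique is emitted whole as a single module", {
  mods <- extract_modules(k_n(5), min_size = 4)
  expect_length(mods, 1)
  expect_setequal(mods[[1]]$gene_ids, paste0("g", 1:5))
  expect_equal(mods[[1]]$avg_tom, 1)
})

test_that("two cliques joined by a bridge are recovered exactly", {
  A <- matrix(0, 8, 8)
  A[1:4, 1:4] <- 1
  A[5:8, 5:8] <- 1
  A[4, 5] <- A[5, 4] <- 1
  diag(A) <- 0
  rownames(A) <- colnames(A) <- paste0("g", 1:8)
  parent_avg <- average_tom(tom_matrix(A))
  mods <- extract_modules(A, min_size = 4)
  expect_length(mods, 2)
  expect_setequal(mods[[1]]$gene_ids, paste0("g", 1:4))
  expect_setequal(mods[[2]]$gene_ids, paste0("g", 5:8))
  # each emitted module is at least as coherent as its parent region
  expect_true(all(vapply(mods, `[[`, numeric(1), "avg_tom") >= parent_avg))
})

test_that("chains are split at the weakest edge and small sets are discarded", {
  expect_message(
    mods <- extract_modules(path_3(), min_size = 2),
    "discarded"
  )
  expect_length(mods, 1)
  expect_setequal(mods[[1]]$gene_ids, c("b", "c"))
  expect_equal(lengths(attr(mods, "discarded")), 1L)  # the singleton "a"
  expect_error(extract_modules(path_3(), min_size = 1), "min_size")
})

test_that("modules are disjoint, connected in the source graph, and deterministic", {
  set.seed(25)
  for (rep in 1:10) {
    A <- rand_connected_adj(sample(6:12, 1), p = 0.35)
    m1 <- suppressMessages(extract_modules(A, min_size = 2))
    m2 <- suppressMessages(extract_modules(A, min_size = 2))
    expect_identical(m1, m2)
    genes <- unlist(lapply(m1, `[[`, "gene_ids"))
    expect_equal(anyDuplicated(genes), 0L)
    for (mod in m1) {
      v <- match(mod$gene_ids, rownames(A))
      if (length(v) >= 2)
        expect_true(is_connected_brute(A[v, v, drop = FALSE]))
    }
  }
})

test_that("mine_modules assigns ids across regions and reports isolated genes", {
  A <- matrix(0, 9, 9)
  A[1:4, 1:4] <- 1
  A[5:8, 5:8] <- 1
  diag(A) <- 0
  rownames(A) <- colnames(A) <- paste0("g", 1:9)  # g9 isolated
  mods <- mine_modules(net_from_adj(A), min_size = 4)
  expect_length(mods, 2)
  expect_equal(vapply(mods, `[[`, character(1), "module_id"), c("M1", "M2"))
  expect_equal(attr(mods, "isolated"), "g9")
  df <- modules_to_data_frame(mods)
  expect_equal(nrow(df), 8)
  expect_setequal(colnames(df), c("module_id", "gene_id", "avg_tom", "parent_region"))
})
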