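test_that("similarity_matrix mirrors the upper triangle with unit diagonal", {
  D <- rbind(a = wx_a, b1 = wx_b1, b8 = wx_b8)
  S <- similarity_matrix(D)
  expect_identical(S, t(S))
  expect_equal(unname(diag(S)), rep(1, 3))
  expect_equal(S["a", "b1"], 1)
  expect_equal(S["a", "b8"], 0)
  # b8 = 23 - b1: centered profiles are exact negations
  expect_equal(S["b1", "b8"], 0)
  # agrees with the pairwise function on random data
  set.seed(11)
  D2 <- matrix(rnorm(8 * 10), 8, dimnames = list(paste0("g", 1:8), NULL))
  S2 <- similarity_matrix(D2)
  for (i in 1:7) for (j in (i + 1):8)
    expect_equal(S2[i, j], nmrs(D2[i, ], D2[j, ]))
  expect_error(similarity_matrix(D, measure = "manhattan"), "unknown")
})

test_that("pearson and spearman similarity matrices use the standard estimators", {
  set.seed(12)
  D <- matrix(rnorm(5 * 9), 5, dimnames = list(paste0("g", 1:5), NULL))
  expect_equal(similarity_matrix(D, "pearson")[1, 2], pearson_cor(D[1, ], D[2, ]))
  expect_equal(similarity_matrix(D, "spearman")[1, 2], spearman_cor(D[1, ], D[2, ]))
  D[1, ] <- 3
  expect_error(similarity_matrix(D, "pearson"), "constant")
})

test_that("threshold_network binarizes at delta with no self-loops", {
  D <- rbind(a = wx_a, b1 = wx_b1, b8 = wx_b8)
  S <- similarity_matrix(D)
  net <- threshold_network(S, 0.9)
  expect_s3_class(net, "coexpression_network")
  expect_identical(net$adjacency, t(net$adjacency))
  expect_equal(unname(diag(net$adjacency)), rep(0L, 3))
  expect_equal(sum(net$adjacency) / 2, 1)  # only the (a, b1) pair survives
  expect_equal(net$adjacency["a", "b1"], 1L)
  # delta = 0: complete graph; delta above the max off-diagonal: empty
  expect_equal(sum(threshold_network(S, 0)$adjacency) / 2, 3)
  expect_equal(sum(threshold_network(S, 1)$adjacency) / 2, 1)
  expect_error(threshold_network(S, 1.01), "\\[0, 1\\]")
  expect_error(threshold_network(S, -0.1), "\\[0, 1\\]")
})

test_that("strict thresholding excludes boundary pairs", {
  S <- diag(1, 3)
  S[1, 2] <- S[2, 1] <- 0.5
  S[1, 3] <- S[3, 1] <- 0.7
  expect_equal(sum(threshold_network(S, 0.5)$adjacency) / 2, 2)
  expect_equal(sum(threshold_network(S, 0.5, strict = TRUE)$adjacency) / 2, 1)
})

test_that("edge count is monotone non-increasing in delta", {
  set.seed(13)
  D <- matrix(rnorm(12 * 9, sd = 2), 12,
              dimnames = list(paste0("g", 1:12), NULL))
  S <- similarity_matrix(D)
  counts <- sapply(seq(0, 1, by = 0.05), function(d)
    sum(threshold_network(S, d)$adjacency))
  expect_true(all(diff(counts) <= 0))
})

test_that("connected_regions finds maximal components deterministically", {
  # two disjoint triangles
  A <- matrix(0L, 6, 6)
  A[1:3, 1:3] <- 1L
  A[4:6, 4:6] <- 1L
  diag(A) <- 0L
  rownames(A) <- colnames(A) <- paste0("g", 1:6)
  regs <- connected_regions(net_from_adj(A))
  expect_length(regs, 2)
  expect_equal(lengths(lapply(regs, `[[`, "vertex_ids")), c(3L, 3L))
  expect_equal(regs[[1]]$vertex_ids, c("g1", "g2", "g3"))
  expect_length(attr(regs, "isolated"), 0)

  # path on 5 vertices: one region
  P <- matrix(0L, 5, 5)
  for (i in 1:4) P[i, i + 1] <- P[i + 1, i] <- 1L
  rownames(P) <- colnames(P) <- paste0("g", 1:5)
  regs <- connected_regions(net_from_adj(P))
  expect_length(regs, 1)
  expect_length(regs[[1]]$vertex_ids, 5)
})

test_that("connected_regions agrees with a transitive-closure oracle", {
  set.seed(14)
  for (rep in 1:20) {
    A <- rand_adj(8, p = 0.25)
    regs <- connected_regions(net_from_adj(A))
    oracle <- components_brute(A)
    oracle_big <- Filter(function(v) length(v) >= 2, oracle)
    oracle_big <- oracle_big[order(vapply(oracle_big, min, integer(1)))]
    expect_equal(lapply(regs, function(r) match(r$vertex_ids, rownames(A))),
                 lapply(oracle_big, unname))
    # regions partition the non-isolated vertices
    got <- unlist(lapply(regs, `[[`, "vertex_ids"))
    expect_equal(anyDuplicated(got), 0L)
    expect_setequal(c(got, attr(regs, "isolated")), rownames(A))
    # induced adjacency is the corresponding submatrix
    for (r in regs)
      expect_identical(r$adjacency, A[r$vertex_ids, r$vertex_ids])
  }
})

test_that("a zero threshold yields a single region containing every gene", {
  set.seed(15)
  D <- matrix(rnorm(7 * 8), 7, dimnames = list(paste0("g", 1:7), NULL))
  regs <- connected_regions(threshold_network(similarity_matrix(D), 0))
  expect_length(regs, 1)
  expect_setequal(regs[[1]]$vertex_ids, rownames(D))
})
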