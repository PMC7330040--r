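test_that("count filter removes low-count genes and quantile-normalizes", {
  set.seed(1)
  counts <- matrix(rpois(100, 50), 10, 10,
                   dimnames = list(sprintf("g%02d", 1:10),
                                   sprintf("s%02d", 1:10)))
  counts["g01", ] <- 0                      # silent gene: must go
  counts["g02", ] <- c(rep(0, 9), 40)       # low in 90% of samples: must go
  counts["g03", ] <- c(rep(2, 9), 60)       # low in 90% of samples: must go
  expr <- filter_and_normalize(counts)
  expect_setequal(rownames(expr), sprintf("g%02d", 4:10))
  # quantile normalization: every sample has the same sorted value vector
  sorted <- apply(expr, 2, sort)
  expect_true(all(abs(sorted - sorted[, 1]) < 1e-12))
})

test_that("sample permutations are identical after quantile normalization", {
  set.seed(2)
  counts <- matrix(rpois(40, 100), 20, 2,
                   dimnames = list(sprintf("g%02d", 1:20), c("a", "b")))
  counts[, 2] <- sample(counts[, 1])  # b is a permutation of a
  expr <- filter_and_normalize(counts)
  expect_equal(unname(sort(expr[, "a"])), unname(sort(expr[, "b"])),
               tolerance = 1e-12)
})

test_that("network-gene mask applies the signal threshold", {
  set.seed(3)
  counts <- matrix(rpois(60, 200), 6, 10,
                   dimnames = list(sprintf("g%d", 1:6),
                                   sprintf("s%02d", 1:10)))
  counts[1, ] <- rpois(10, 8)  # above count filter, below 5 log2 units
  expr <- filter_and_normalize(counts)
  expect_false("g1" %in% network_genes(expr))
  expect_true(all(sprintf("g%d", 2:6) %in% network_genes(expr)))
})

test_that("adjacency is |cor|^beta with zero diagonal", {
  # exact r = 1 pair and an exact r = 0.5 construction
  x <- rbind(g1 = c(1, 2, 3, 4),
             g2 = c(2, 4, 6, 8),
             g3 = c(1, 3, 2, 4))
  colnames(x) <- paste0("s", 1:4)
  a <- adjacency(x, network_params(beta = 6))
  expect_equal(a["g1", "g2"], 1)
  expect_equal(diag(a), c(g1 = 0, g2 = 0, g3 = 0))
  r <- cor(x["g1", ], x["g3", ])
  expect_equal(a["g1", "g3"], abs(r)^6, tolerance = 1e-14)
  expect_equal(0.5^6, 0.015625)  # the beta = 6 attenuation of r = 0.5
  set.seed(4)
  y <- matrix(rnorm(100), 5, 20,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:20)))
  expect_equal(adjacency(y, network_params(beta = 6)),
               adjacency_oracle(y, 6), tolerance = 1e-12)
})

test_that("zero-variance genes are dropped with a warning", {
  x <- rbind(g1 = c(1, 2, 3, 4), g2 = c(5, 5, 5, 5), g3 = c(2, 1, 4, 3))
  colnames(x) <- paste0("s", 1:4)
  expect_warning(a <- adjacency(x), "zero-variance.*g2")
  expect_setequal(rownames(a), c("g1", "g3"))
})

test_that("raising beta never increases an off-diagonal adjacency", {
  set.seed(5)
  x <- matrix(rnorm(200), 10, 20,
              dimnames = list(paste0("g", 1:10), paste0("s", 1:20)))
  a1 <- adjacency(x, network_params(beta = 1))
  a6 <- adjacency(x, network_params(beta = 6))
  a12 <- adjacency(x, network_params(beta = 12))
  expect_true(all(a6 <= a1 + 1e-15))
  expect_true(all(a12 <= a6 + 1e-15))
})

test_that("scale-free fit is exact on an exact power law", {
  # gene frequencies proportional to k^-1 over k = 2^(1:10): log10(freq) is
  # exactly linear in log10(k), one log-width bin per distinct k. Disjoint
  # gene pairs joined by a single edge of weight k give exact row sums k.
  k_vals <- c(10, 20, 30, 40, 50)    # one equal-width bin per value
  counts <- 1200 / k_vals            # even counts so pairs close
  rowk <- rep(k_vals, counts)
  n <- length(rowk)
  adj <- matrix(0, n, n)
  i <- seq(1, n - 1, by = 2)
  adj[cbind(i, i + 1L)] <- rowk[i]
  adj[cbind(i + 1L, i)] <- rowk[i]
  fit <- scale_free_fit(adj, n_bins = 5)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  expect_lt(fit$slope, 0)
})

test_that("degenerate all-equal connectivity raises an error", {
  adj <- matrix(0.5, 6, 6); diag(adj) <- 0
  expect_error(scale_free_fit(adj), "all connectivities equal")
})

test_that("soft thresholding at beta 6 improves the scale-free fit", {
  # one factor with uniform loadings: k(beta) ~ lambda^beta, so the degree
  # density approaches a power law as beta grows but is flat at beta = 1
  set.seed(42)
  ns <- 100; ng <- 300
  f <- rnorm(ns)
  lam <- runif(ng, 0.2, 0.95)
  x <- lam %o% f + matrix(rnorm(ng * ns, sd = 0.3), ng)
  dimnames(x) <- list(sprintf("g%03d", 1:ng), sprintf("s%03d", 1:ns))
  r1 <- scale_free_fit(adjacency(x, network_params(beta = 1)))
  r6 <- scale_free_fit(adjacency(x, network_params(beta = 6)))
  expect_gt(r6$signed_r_squared, r1$signed_r_squared)
  expect_lt(r6$slope, r1$slope)
})

test_that("TOM handles cliques and isolated nodes exactly", {
  # 3-gene clique with all pairwise adjacency 1: TOM = (1+1)/(2+1-1) = 1
  clique <- matrix(1, 3, 3) - diag(3)
  dimnames(clique) <- list(paste0("g", 1:3), paste0("g", 1:3))
  tom <- topological_overlap(clique)
  expect_equal(tom, matrix(1, 3, 3, dimnames = dimnames(clique)))
  # isolated gene: zero row off-diagonal, unit diagonal
  adj <- rbind(c(0, 0.8, 0), c(0.8, 0, 0), c(0, 0, 0))
  dimnames(adj) <- list(paste0("g", 1:3), paste0("g", 1:3))
  tom2 <- topological_overlap(adj)
  expect_equal(unname(tom2[3, 1:2]), c(0, 0))
  expect_equal(unname(diag(tom2)), rep(1, 3))
})

test_that("TOM equals the triple-loop oracle on a fixed 4x4 fixture", {
  adj <- rbind(c(0, 0.9, 0.2, 0.1),
               c(0.9, 0, 0.4, 0.3),
               c(0.2, 0.4, 0, 0.7),
               c(0.1, 0.3, 0.7, 0))
  dimnames(adj) <- list(paste0("g", 1:4), paste0("g", 1:4))
  expect_equal(topological_overlap(adj), tom_oracle(adj),
               tolerance = 1e-12)
})

test_that("TOM stays in [0, 1] and symmetric on random inputs", {
  set.seed(6)
  for (rep in 1:5) {
    n <- sample(8:20, 1)
    r <- cor(matrix(rnorm(n * 30), 30, n))
    a <- abs(r)^6; diag(a) <- 0
    dimnames(a) <- list(paste0("g", 1:n), paste0("g", 1:n))
    tom <- topological_overlap(a)
    expect_true(all(tom >= 0 & tom <= 1 + 1e-12))
    expect_equal(tom, t(tom), tolerance = 1e-12)
  }
})

test_that("non-symmetric adjacency is rejected", {
  adj <- matrix(c(0, 0.5, 0.2, 0), 2, 2,
                dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(topological_overlap(adj), "symmetric")
})

test_that("two perfect cliques are recovered as two modules", {
  n <- 8  # per clique; min_module_size lowered accordingly
  tom <- diag(2 * n)
  tom[1:n, 1:n] <- 1
  tom[(n + 1):(2 * n), (n + 1):(2 * n)] <- 1
  dimnames(tom) <- list(sprintf("g%02d", 1:(2 * n)),
                        sprintf("g%02d", 1:(2 * n)))
  part <- detect_modules(tom, network_params(min_module_size = 5L))
  expect_length(unique(part), 2L)
  expect_length(unique(part[1:n]), 1L)
  expect_length(unique(part[(n + 1):(2 * n)]), 1L)
  # deterministic labels: GM1 is the clique containing the smallest gene id
  expect_identical(unname(part[["g01"]]), "GM1")
})

test_that("flat TOM collapses to one module under a high cut", {
  n <- 10
  tom <- matrix(0.5, n, n); diag(tom) <- 1
  dimnames(tom) <- list(paste0("g", 1:n), paste0("g", 1:n))
  part <- detect_modules(tom, network_params(cut_height = 0.8,
                                             min_module_size = 5L))
  expect_length(unique(part), 1L)
  expect_identical(unique(unname(part)), "GM1")
  # with the cut below the common dissimilarity everything is unassigned
  expect_warning(
    part2 <- detect_modules(tom, network_params(cut_height = 0.3,
                                                min_module_size = 5L)),
    "unassigned")
  expect_true(all(part2 == "unassigned"))
})

test_that("module detection and labels are deterministic", {
  coh <- generate_cohort(tiny_config(seed = 13L))
  tom <- topological_overlap(adjacency(coh$expression))
  p1 <- detect_modules(tom, network_params(min_module_size = 10L))
  p2 <- detect_modules(tom, network_params(min_module_size = 10L))
  expect_identical(p1, p2)
})

test_that("duplicated modules merge; dissimilar ones stay separate", {
  # blocks with eigengene correlation exactly 1 (duplicate) merge
  blocks <- exact_cor_blocks(diag(2), block_size = 4, n_samples = 10)
  dup <- rbind(blocks$expr, blocks$expr[1:4, ] * 3 + 1)
  rownames(dup)[9:12] <- paste0("dup_g", 1:4)
  pdup <- c(blocks$partition, stats::setNames(rep("GM3", 4),
                                              rownames(dup)[9:12]))
  merged <- merge_close_modules(pdup, dup, network_params())
  # GM1 and its duplicate collapse; the orthogonal block survives
  expect_length(module_labels(merged), 2L)
  expect_length(unique(merged[c(1:4, 9:12)]), 1L)
})

test_that("eigengene dissimilarity 0.15 is not merged at threshold 0.10", {
  R <- matrix(c(1, 0.85, 0.85, 1), 2)
  blocks <- exact_cor_blocks(R, block_size = 5, n_samples = 12)
  merged <- merge_close_modules(blocks$partition, blocks$expr,
                                network_params(merge_threshold = 0.10))
  expect_length(module_labels(merged), 2L)
  # but a 0.12 threshold (dissimilarity 0.15 still above) also keeps them,
  # while 0.20 merges them
  merged2 <- merge_close_modules(blocks$partition, blocks$expr,
                                 network_params(merge_threshold = 0.20))
  expect_length(module_labels(merged2), 1L)
})

test_that("a chain of near-identical modules merges to one", {
  R <- matrix(0.95, 3, 3); diag(R) <- 1
  blocks <- exact_cor_blocks(R, block_size = 5, n_samples = 12)
  merged <- merge_close_modules(blocks$partition, blocks$expr,
                                network_params(merge_threshold = 0.10))
  expect_length(module_labels(merged), 1L)
})
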