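make_refs <- function(n_genes = 30, n_types = 3, n_per = 4, seed = 31) {
  set.seed(seed)
  genes <- sprintf("g%02d", seq_len(n_genes))
  ct <- rep(paste0("ct", seq_len(n_types)), each = n_per)
  prof <- matrix(rnorm(n_genes * length(ct)), n_genes,
                 dimnames = list(genes, sprintf("p%02d", seq_along(ct))))
  list(expression = prof, celltype = ct)
}

test_that("a strongly shifted cell type dominates the module ANOVA", {
  refs <- make_refs()
  part <- stats::setNames(c(rep("GM1", 10), rep("unassigned", 20)),
                          rownames(refs$expression))
  refs$expression[1:10, refs$celltype == "ct2"] <-
    refs$expression[1:10, refs$celltype == "ct2"] + 5
  res <- celltype_enrichment_anova(refs, part)
  expect_lt(res$p, 1e-6)
  expect_identical(res$top_celltype, "ct2")
  expect_equal(res$score, -log10(res$p))
})

test_that("exactly equal group means give F = 0", {
  genes <- paste0("g", 1:2)
  # profile scores come out proportional to (1, -1, -1, 1): both cell-type
  # means are zero while profiles within a type still differ
  prof <- rbind(g1 = c(5, 1, 1, 5), g2 = c(9, 3, 3, 9))
  colnames(prof) <- c("a1", "a2", "b1", "b2")
  refs <- list(expression = prof, celltype = c("A", "A", "B", "B"))
  part <- stats::setNames(rep("GM1", 2), genes)
  res <- celltype_enrichment_anova(refs, part)
  expect_equal(res$statistic, 0, tolerance = 1e-12)
})

test_that("overlap percentage follows the printed formula exactly", {
  universe <- sprintf("g%03d", 1:400)
  part <- stats::setNames(c(rep("GM1", 100), rep("unassigned", 300)),
                          universe)
  sig <- c(universe[1:25], universe[301:375])  # 25 of 100 members
  res <- signature_overlap(part, list(S = sig), universe, n_null = 50,
                           seed = 1)
  expect_equal(res$overlap_count, 25)
  expect_equal(res$overlap_pct, 25)
  # signature identical to the module: 100 percent
  res2 <- signature_overlap(part, list(S = universe[1:100]), universe,
                            n_null = 50, seed = 1)
  expect_equal(res2$overlap_pct, 100)
})

test_that("random-signature null mean matches the closed form", {
  set.seed(32)
  universe <- sprintf("g%04d", 1:1000)
  part <- stats::setNames(c(rep("GM1", 50), rep("unassigned", 950)),
                          universe)
  sig <- sample(universe, 100)
  res <- signature_overlap(part, list(S = sig), universe, n_null = 1000,
                           seed = 7)
  # E[overlap_pct] = 100 * |sig| / |universe| = 10; SE of the mean
  se <- res$null_sd_pct / sqrt(1000)
  expect_lt(abs(res$null_mean_pct - 10), 3 * se)
  expect_error(signature_overlap(part, list(S = c(universe, "extra")),
                                 universe), "larger than the universe")
})

test_that("chi-square and Fisher overlap p-values rank overlap the same way", {
  universe <- sprintf("g%03d", 1:300)
  part <- stats::setNames(c(rep("GM1", 60), rep("unassigned", 240)),
                          universe)
  overlaps <- c(12, 20, 30, 45)
  p_chi <- p_fis <- numeric(length(overlaps))
  for (i in seq_along(overlaps)) {
    sig <- c(universe[seq_len(overlaps[i])],
             universe[61:(60 + 60 - overlaps[i])])
    p_chi[i] <- signature_overlap(part, list(S = sig), universe,
                                  n_null = 10, seed = 1)$p
    p_fis[i] <- signature_overlap(part, list(S = sig), universe,
                                  n_null = 10, seed = 1,
                                  test = "fisher")$p
  }
  expect_identical(order(p_chi), order(p_fis))
})

test_that("hypergeometric ORA equals the enumeration oracle", {
  universe <- sprintf("g%03d", 1:100)
  hits <- universe[1:20]
  gene_set <- c(universe[1:5], universe[21:25])  # overlap 5, size 10
  res <- ora_hypergeometric(hits, list(S = gene_set), universe)
  expect_equal(res$p, hyper_upper_oracle(5, 10, 100, 20),
               tolerance = 1e-12)
  # overlap 0: p = P(X >= 0) = 1
  res0 <- ora_hypergeometric(universe[1:10], list(S = universe[51:60]),
                             universe)
  expect_equal(res0$p, 1)
  # degenerate: set = hits = universe
  resu <- ora_hypergeometric(universe, list(S = universe), universe)
  expect_equal(resu$p, 1)
})

test_that("ORA matches the oracle across random configurations", {
  set.seed(33)
  universe <- sprintf("g%03d", 1:150)
  for (i in 1:20) {
    hits <- sample(universe, sample(5:40, 1))
    s <- sample(universe, sample(5:40, 1))
    res <- ora_hypergeometric(hits, list(S = s), universe)
    expect_equal(res$p,
                 hyper_upper_oracle(length(intersect(hits, s)), length(s),
                                    150, length(hits)),
                 tolerance = 1e-12)
  }
})

test_that("mHG score is exact for a fully front-loaded set", {
  u <- sprintf("g%02d", 1:10)
  res <- ranked_min_hypergeometric(u, u[1:3], n_perm = 400, seed = 5)
  # all 3 members in the top 3: HGT(3) = 1/C(10,3) = 1/120
  expect_equal(res$mhg_score, 1 / 120, tolerance = 1e-12)
  expect_equal(res$argmin_prefix, 3L)
  # a larger universe makes the front-loaded minimum essentially
  # unreachable by chance, so the permutation p sits at its floor
  u2 <- sprintf("g%02d", 1:50)
  res2 <- ranked_min_hypergeometric(u2, u2[1:5], n_perm = 200, seed = 6)
  expect_equal(res2$mhg_score, 1 / choose(50, 5), tolerance = 1e-12)
  expect_equal(res2$p, 1 / 201, tolerance = 1e-12)
  expect_error(ranked_min_hypergeometric(u2, character(0)), "empty")
})

test_that("mHG permutation p is calibrated under random ranking", {
  set.seed(34)
  u <- sprintf("g%02d", 1:40)
  ps <- vapply(1:200, function(i) {
    ranked <- sample(u)
    ranked_min_hypergeometric(ranked, u[1:6], n_perm = 99,
                              seed = 1000 + i)$p
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)
})

test_that("intramodular connectivity is exact on cliques and isolates", {
  tom <- matrix(1, 3, 3)
  dimnames(tom) <- list(paste0("g", 1:3), paste0("g", 1:3))
  part <- stats::setNames(rep("GM1", 3), rownames(tom))
  res <- intramodular_connectivity(tom, part)
  expect_equal(res$kIM, rep(2, 3))
  expect_equal(res$rank, 1:3)  # tie broken by gene id
  # a member with zero TOM to its module mates ranks last with kIM 0
  tom2 <- diag(4)
  tom2[1:3, 1:3] <- 1
  dimnames(tom2) <- list(paste0("g", 1:4), paste0("g", 1:4))
  part2 <- stats::setNames(rep("GM1", 4), rownames(tom2))
  res2 <- intramodular_connectivity(tom2, part2)
  expect_equal(res2$kIM[res2$gene == "g4"], 0)
  expect_equal(res2$rank[res2$gene == "g4"], 4L)
  # unassigned genes get NA and kIM never exceeds module size - 1
  part3 <- c(part2[1:3], g4 = "unassigned")
  res3 <- intramodular_connectivity(tom2, part3)
  expect_true(is.na(res3$kIM[res3$gene == "g4"]))
  expect_true(all(res3$kIM[1:3] <= 2))
})

test_that("the designated hub gene ranks first in nearly all seeds", {
  hits <- 0; n_seeds <- 20
  for (s in seq_len(n_seeds)) {
    set.seed(400 + s)
    ns <- 100; ng <- 30
    f <- rnorm(ns)
    lam <- c(0.9, runif(ng - 1, 0.4, 0.6))  # clear loading gap to the hub
    x <- lam %o% f + matrix(rnorm(ng * ns, sd = 0.4), ng)
    rownames(x) <- sprintf("g%02d", seq_len(ng))
    colnames(x) <- sprintf("s%03d", seq_len(ns))
    tom <- topological_overlap(adjacency(x))
    part <- stats::setNames(rep("GM1", ng), rownames(x))
    res <- intramodular_connectivity(tom, part)
    hits <- hits + (res$rank[res$gene == "g01"] == 1L)
  }
  expect_gte(hits / n_seeds, 0.9)
})

test_that("hub neighborhoods respect module size and tie-breaks", {
  tom <- matrix(1, 4, 4)
  dimnames(tom) <- list(paste0("g", 1:4), paste0("g", 1:4))
  part <- stats::setNames(rep("GM1", 4), rownames(tom))
  # n_per_module larger than the module: the whole module comes back
  res <- hub_neighborhood("g1", tom, part, n_per_module = 10)
  expect_setequal(res$target, c("g2", "g3", "g4"))
  # all mates tied at TOM 1: lexicographic order decides
  res2 <- hub_neighborhood("g1", tom, part, n_per_module = 2)
  expect_identical(res2$target, c("g2", "g3"))
  expect_error(hub_neighborhood("nope", tom, part), "unknown gene")
})

test_that("a bridging gene's neighborhood spans both its modules", {
  set.seed(35)
  ns <- 80
  f1 <- rnorm(ns); f2 <- rnorm(ns)
  x <- rbind(
    outer(runif(10, 0.7, 0.9), f1),
    outer(runif(10, 0.7, 0.9), f2),
    bridge = 0.7 * f1 + 0.7 * f2)
  x <- x + matrix(rnorm(length(x), sd = 0.3), nrow(x))
  rownames(x) <- c(sprintf("a%02d", 1:10), sprintf("b%02d", 1:10), "bridge")
  colnames(x) <- sprintf("s%02d", seq_len(ns))
  tom <- topological_overlap(adjacency(x))
  part <- stats::setNames(c(rep("GM1", 10), rep("GM2", 10), "unassigned"),
                          rownames(x))
  nb_bridge <- hub_neighborhood("bridge", tom, part, n_per_module = 5)
  mean_w <- tapply(nb_bridge$weight, nb_bridge$module, mean)
  # the bridge connects strongly into both modules
  expect_gt(min(mean_w), 0.5 * max(mean_w))
  # a pure member of module 1 does not
  nb_pure <- hub_neighborhood("a01", tom, part, n_per_module = 5)
  w_pure <- tapply(nb_pure$weight, nb_pure$module, mean)
  expect_lt(w_pure[["GM2"]], 0.5 * w_pure[["GM1"]])
})

test_that("global edge export returns the strongest edges only", {
  set.seed(36)
  r <- cor(matrix(rnorm(30 * 12), 30, 12))
  a <- abs(r)^6; diag(a) <- 0
  dimnames(a) <- list(paste0("g", 1:12), paste0("g", 1:12))
  tom <- topological_overlap(a)
  edges <- export_network_edges(tom, quantile_threshold = 0.9,
                                max_edges = 5)
  expect_lte(nrow(edges), 5)
  expect_true(all(diff(edges$weight) <= 0))
  thr <- quantile(tom[upper.tri(tom)], 0.9)
  expect_true(all(edges$weight >= thr))
})
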