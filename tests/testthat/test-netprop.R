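triangle_edges <- function(conf = 0.95) {
  data.frame(node_a = c("a", "b", "c"), node_b = c("b", "c", "a"),
             confidence = conf)
}

test_that("network construction filters, rescues and normalises", {
  net <- build_network(triangle_edges())
  expect_equal(net$n_nodes, 3)
  expect_equal(net$n_edges, 3)
  expect_equal(unname(Matrix::colSums(net$P)), rep(1, 3))
  expect_true(all(net$P@x >= 0))
  expect_equal(unname(Matrix::diag(net$P)), rep(0, 3))

  # a node whose only edge is sub-threshold survives via the rescue rule
  edges <- rbind(triangle_edges(),
                 data.frame(node_a = "d", node_b = "a", confidence = 0.5))
  expect_false("d" %in% build_network(edges)$node_ids)
  rescued <- build_network(edges, rescue_targets = "d")
  expect_true("d" %in% rescued$node_ids)
  expect_equal(rescued$rescued, "d")
  expect_equal(unname(Matrix::colSums(rescued$P)), rep(1, 4))

  # STRING-style 0-999 confidences are auto-rescaled
  edges999 <- triangle_edges(conf = c(950, 990, 910))
  expect_equal(build_network(edges999)$n_edges, 3)

  expect_error(build_network(triangle_edges(conf = 0.1)), "no edges")
})

test_that("filtering matches a brute-force filter + flood-fill oracle", {
  set.seed(47)
  nodes <- sprintf("n%03d", 1:200)
  edges <- data.frame(node_a = sample(nodes, 600, replace = TRUE),
                      node_b = sample(nodes, 600, replace = TRUE),
                      confidence = runif(600))
  threshold <- 0.5  # excludes about half the edges
  net <- build_network(edges, confidence_threshold = threshold)
  oracle <- oracle_filter_component(edges, threshold)
  expect_equal(net$n_nodes, oracle$n_nodes)
  expect_equal(net$n_edges, oracle$n_edges)
})

test_that("the two-node walk matches its closed form", {
  P <- matrix(c(0, 1, 1, 0), 2, 2,
              dimnames = list(c("a", "b"), c("a", "b")))
  ev <- rwr(P, c(a = 1, b = 0), r = 0.3)
  expect_equal(unname(round(ev$chi, 4)), c(0.5882, 0.4118))
  expect_equal(unname(ev$chi), unname(oracle_rwr(P, c(1, 0), 0.3)),
               tolerance = 1e-9)

  # zero seed stays zero; seed mass is conserved
  expect_equal(unname(rwr(P, c(a = 0, b = 0))$chi), c(0, 0))
  expect_equal(sum(rwr(P, c(a = 2, b = 3))$chi), 5, tolerance = 1e-9)

  expect_error(rwr(P, c(1, 0), r = 1.3), "r")
  expect_error(rwr(P, c(1, 0, 0)), "length")
  expect_error(rwr(P, c(1, 0), max_iter = 2L), "residual")
})

test_that("the iterative walk satisfies its fixed point and closed form", {
  set.seed(53)
  for (i in 1:8) {
    n <- sample(10:60, 1)
    P <- random_stochastic_operator(n)
    chi0 <- numeric(n)
    chi0[sample.int(n, 3)] <- c(1, 1, 0.01)
    r <- runif(1, 0.1, 0.9)
    ev <- rwr(P, chi0, r = r, tol = 1e-12)
    # fixed point
    expect_lt(sum(abs(ev$chi - ((1 - r) * P %*% ev$chi + r * chi0))),
              1e-10)
    # dense-solve oracle
    expect_lt(max(abs(ev$chi - oracle_rwr(P, chi0, r))), 1e-10)
    # conservation
    expect_equal(sum(ev$chi), sum(chi0), tolerance = 1e-10)
  }
})

test_that("restart probability interpolates seeds and stationarity", {
  set.seed(59)
  P <- random_stochastic_operator(30)
  chi0 <- numeric(30)
  chi0[c(4, 9)] <- 1
  # r -> 1 pins the walk at its seeds
  expect_lt(max(abs(rwr(P, chi0, r = 0.999)$chi - chi0)), 0.01)
  # r -> 0 approaches the degree-proportional stationary distribution
  A <- (P > 0) + 0
  stationary <- colSums(A) / sum(A) * sum(chi0)
  expect_lt(max(abs(rwr(P, chi0, r = 0.001, max_iter = 1e5)$chi -
                      stationary)), 0.01)
})

test_that("effect scores are inner products over shared nodes", {
  a <- c(x = 0.2, y = 0, z = 0.5)
  b <- c(x = 0, y = 0.3, z = 0)
  expect_equal(effect_score(a, b), 0)
  expect_equal(effect_score(a, a), sum(a^2))

  set.seed(61)
  P <- random_stochastic_operator(50)
  u <- rwr(P, setNames(as.numeric(seq_len(50) <= 5), rownames(P)))
  v <- rwr(P, setNames(0.01 * (seq_len(50) > 40), rownames(P)))
  acc <- 0
  for (i in 1:50) acc <- acc + u$chi[[i]] * v$chi[[i]]
  expect_equal(effect_score(u, v), acc)
  expect_error(effect_score(a, c(x = 1, y = 2)), "indexed")
})

test_that("z-scores centre at the null and are seed-reproducible", {
  set.seed(67)
  P <- random_stochastic_operator(60)
  net <- as_network(P)
  chi_d <- rwr(net, seed_vector(net, rownames(P)[1:6], 1, quiet = TRUE))

  z1 <- z_score(net, chi_d, s = 0.5, n_targets = 5, n_random = 50,
                seed = 101)
  expect_equal(z1$z_score, (0.5 - z1$null_mean) / z1$null_sd)
  # s equal to the null mean gives Z = 0
  z0 <- z_score(net, chi_d, s = z1$null_mean, n_targets = 5,
                n_random = 50, seed = 101)
  expect_equal(z0$z_score, 0)
  # identical seed, identical result
  z2 <- z_score(net, chi_d, s = 0.5, n_targets = 5, n_random = 50,
                seed = 101)
  expect_identical(z1$null_scores, z2$null_scores)

  # degenerate null: zero disease vector
  chi0 <- rwr(net, seed_vector(net, character(0), 1, quiet = TRUE))
  expect_warning(zna <- z_score(net, chi0, s = 0, n_targets = 5,
                                n_random = 20, seed = 1), "undefined")
  expect_true(is.na(zna$z_score))
})

test_that("adjoint and direct null evaluation agree", {
  set.seed(71)
  P <- random_stochastic_operator(40)
  net <- as_network(P)
  chi_d <- rwr(net, seed_vector(net, rownames(P)[1:5], 1, quiet = TRUE),
               tol = 1e-12)
  za <- z_score(net, chi_d, s = 0.1, n_targets = 6, n_random = 30,
                seed = 7, method = "adjoint", tol = 1e-12)
  zd <- z_score(net, chi_d, s = 0.1, n_targets = 6, n_random = 30,
                seed = 7, method = "direct", tol = 1e-12)
  expect_equal(za$null_scores, zd$null_scores, tolerance = 1e-8)
  expect_equal(za$z_score, zd$z_score, tolerance = 1e-6)
})

test_that("synergy tables share protocol across rows", {
  set.seed(73)
  sim <- simulate_network(network_scenario(
    n_nodes = 200, module_size = 20,
    targets = list(A = list(size = 15, overlap = 0.5)), seed = 73))
  net <- build_network(sim$edges)

  # identical target sets: mixture equals the component up to null noise
  same <- list(c1 = sim$target_sets$A, c2 = sim$target_sets$A)
  tab <- suppressMessages(synergy_table(net, sim$disease_module, same,
                                        n_random = 200, seed = 5))
  expect_equal(tab$label[1], "mixture")
  expect_equal(tab$target_number, rep(tab$target_number[1], 3))
  expect_equal(tab$effect_score, rep(tab$effect_score[1], 3),
               tolerance = 1e-9)
  expect_lt(max(abs(tab$z_score - mean(tab$z_score))), 1.5)

  # an empty-after-intersection set is flagged, others still computed
  mixed <- list(A = sim$target_sets$A, ghost = c("zzz1", "zzz2"))
  expect_warning(tab2 <- synergy_table(net, sim$disease_module, mixed,
                                       n_random = 100, seed = 5),
                 "ghost")
  expect_true(is.na(tab2$z_score[tab2$label == "ghost"]))
  expect_false(anyNA(tab2$z_score[tab2$label == "A"]))
})

test_that("targets far from the disease module score lowest", {
  sim <- simulate_network(network_scenario(
    n_nodes = 500, attachment = 2, module_size = 20,
    module_density = 0.25,
    targets = list(near = list(size = 20, overlap = 0.5),
                   far = list(size = 20, overlap = 0,
                              min_distance = 3)),
    seed = 4))
  net <- build_network(sim$edges)
  tab <- suppressMessages(synergy_table(net, sim$disease_module,
                                        sim$target_sets,
                                        n_random = 500, seed = 2))
  z <- setNames(tab$z_score, tab$label)
  expect_lt(z[["far"]], min(z[["near"]], z[["mixture"]]))
  expect_lt(z[["far"]], 3)
})

test_that("gene sets and edge lists read from their text formats", {
  dir <- withr::local_tempdir()
  gs <- file.path(dir, "set.txt")
  writeLines(c("g1", "g2", "", "g3"), gs)
  expect_identical(read_gene_set(gs), c("g1", "g2", "g3"))

  el <- file.path(dir, "edges.tsv")
  writeLines(c("node_a\tnode_b\tconfidence", "a\tb\t0.95", "b\tc\t0.99"),
             el)
  tab <- read_edge_list(el)
  expect_equal(nrow(tab), 2)
  expect_type(tab$confidence, "double")
  # headerless dialect
  writeLines(c("a\tb\t0.95", "b\tc\t0.99"), el)
  expect_equal(nrow(read_edge_list(el)), 2)
})
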