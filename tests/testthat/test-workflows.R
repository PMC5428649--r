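# end-to-end scenario shared by the connectivity workflow tests
connectivity_fixture <- function(dir, effect = 4) {
  sc <- expression_scenario(n_probes = 150, planted_up = 10L,
                            planted_down = 10L, effect = effect,
                            noise_sd = 0, seed = 14)
  em <- simulate_expression(sc)
  paths <- write_expression_matrix(em, file.path(dir, "expr.tsv"))
  sig <- build_signature(fold_change(average_replicates(em, "treated"),
                                     average_replicates(em, "control")))
  # compound c01 owns instances 1, 6, 11, 16 — all planted concordant
  concordance <- rep(0L, 20)
  concordance[c(1, 6, 11, 16)] <- 1L
  coll <- simulate_reference_collection(
    sig, sc$probe_ids, concordance = concordance,
    compound_names = rep(sprintf("c%02d", 1:5), 4), seed = 15)
  coll_dir <- file.path(dir, "collection")
  write_reference_collection(coll, coll_dir)
  list(expression = paths[["table"]], condition_map = paths[["conditions"]],
       collection = coll_dir)
}

test_that("the connectivity workflow recovers a planted instance end-to-end", {
  dir <- withr::local_tempdir()
  fx <- connectivity_fixture(dir)
  config <- list(expression = fx$expression,
                 condition_map = fx$condition_map,
                 collection = fx$collection,
                 n_permutations = 1000, seed = 8,
                 out_dir = file.path(dir, "out"))
  res <- suppressMessages(run_connectivity_workflow(config))

  expect_true(res$instances$instance_id[1] %in%
                sprintf("inst_%03d", c(1, 6, 11, 16)))
  expect_equal(res$instances$connectivity[1], 1)
  # all four concordant instances lead the ranking
  expect_setequal(res$instances$instance_id[1:4],
                  sprintf("inst_%03d", c(1, 6, 11, 16)))
  expect_true(all(file.exists(res$files)))
  # persisted grp files reload to the signature that was scored
  sig <- read_signature(res$files[["up"]], res$files[["down"]])
  expect_identical(sig$up_tags, res$signature$up_tags)
  # the planted instance's compound leads the name report
  expect_equal(res$names$compound_name[1], "c01")
})

test_that("workflow reports are byte-identical across reruns", {
  dir <- withr::local_tempdir()
  fx <- connectivity_fixture(dir)
  base <- list(expression = fx$expression,
               condition_map = fx$condition_map,
               collection = fx$collection,
               n_permutations = 1000, seed = 8)
  r1 <- suppressMessages(run_connectivity_workflow(
    c(base, out_dir = file.path(dir, "o1"))))
  r2 <- suppressMessages(run_connectivity_workflow(
    c(base, out_dir = file.path(dir, "o2"))))
  for (f in c("instances", "names")) {
    expect_identical(readLines(r1$files[[f]]), readLines(r2$files[[f]]))
  }
  # provenance header present
  expect_match(readLines(r1$files[["instances"]], n = 1), "^# herbconnect")
})

test_that("an empty signature aborts with the failing stage named", {
  dir <- withr::local_tempdir()
  fx <- connectivity_fixture(dir, effect = 1.2)  # below the FC filter
  config <- list(expression = fx$expression,
                 condition_map = fx$condition_map,
                 collection = fx$collection,
                 out_dir = file.path(dir, "out"))
  expect_error(suppressMessages(run_connectivity_workflow(config)),
               "signature stage: empty signature")
})

test_that("the synergy workflow recovers planted synergy end-to-end", {
  dir <- withr::local_tempdir()
  sim <- simulate_network(network_scenario(
    n_nodes = 300, module_size = 30, module_density = 0.25,
    targets = list(compA = list(size = 30, overlap = 0.5,
                                module_part = 1:15),
                   compB = list(size = 30, overlap = 0.5,
                                module_part = 16:30)),
    seed = 19))
  write_network_simulation(sim, dir)
  config <- list(network = file.path(dir, "edges.tsv"),
                 disease = file.path(dir, "disease_genes.txt"),
                 components = file.path(dir, "components"),
                 n_random = 500, seed = 3,
                 out_dir = file.path(dir, "out"))
  res <- suppressMessages(run_synergy_workflow(config))
  tab <- res$synergy
  expect_equal(tab$label[1], "mixture")
  expect_gt(tab$z_score[1], max(tab$z_score[-1]))
  expect_true(file.exists(res$file))

  # the report is stage-isolated: the written table reloads as valid input
  reread <- read.delim(res$file, comment.char = "#")
  expect_equal(reread$z_score, tab$z_score, tolerance = 1e-6)
})

test_that("degenerate synergy configurations are handled", {
  dir <- withr::local_tempdir()
  sim <- simulate_network(network_scenario(
    n_nodes = 150, module_size = 15,
    targets = list(only = list(size = 12, overlap = 0.5)), seed = 27))
  net <- build_network(sim$edges)

  # single component: mixture row duplicates it (union is the set itself)
  config <- list(network = net, disease = sim$disease_module,
                 components = sim$target_sets["only"],
                 n_random = 100, seed = 6,
                 out_dir = file.path(dir, "out1"))
  res <- suppressMessages(run_synergy_workflow(config))
  expect_equal(nrow(res$synergy), 2)
  expect_equal(res$synergy$effect_score[1], res$synergy$effect_score[2],
               tolerance = 1e-9)

  # tiny null triggers the low-precision warning but still reports
  config2 <- list(network = net, disease = sim$disease_module,
                  components = sim$target_sets["only"],
                  n_random = 2, seed = 6,
                  out_dir = file.path(dir, "out2"))
  expect_warning(
    res2 <- suppressMessages(run_synergy_workflow(config2)),
    "low-precision")
  expect_true(file.exists(res2$file))
})

test_that("configs load from YAML with flag-style defaults applied", {
  dir <- withr::local_tempdir()
  cfg_path <- file.path(dir, "run.yaml")
  yaml::write_yaml(list(treated = "treated", fc_up = 3, seed = 12), cfg_path)
  cfg <- read_run_config(cfg_path)
  expect_equal(cfg$fc_up, 3)
  expect_equal(cfg$seed, 12)
})
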