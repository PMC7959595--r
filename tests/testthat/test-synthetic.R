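# The synthetic generator: planted effects, network wiring, determinism and
# round-trip through the file formats.

test_that("infeasible specifications are rejected", {
  expect_error(synthetic_spec(n_planted = 5, n_pathways = 3), "n_planted")
  expect_error(synthetic_spec(n_genes = 10, n_pathways = 3, pathway_size = 5),
               "exceeds")
})

test_that("the planted mean shift matches the spec within 3 standard errors", {
  # a 1% KS check on a single seed falsely fails 1 seed in 100, so both
  # checks run over 5 seeds and must hold in at least 4
  shift_ok <- 0L; ks_ok <- 0L
  for (s in 101:105) {
    spec <- synthetic_spec(n_genes = 300, n_pos = 40, n_neg = 40,
                           n_pathways = 6, pathway_size = 12,
                           effect_size = 1.5, noise_sd = 2,
                           pin_extra_edges = 300, seed = s)
    gen <- simulate_dataset(spec)
    planted_genes <- gen$sets$sets[[gen$truth]]
    diffs <- colMeans(gen$data$values[gen$data$labels == "pos", planted_genes]) -
      colMeans(gen$data$values[gen$data$labels == "neg", planted_genes])
    se <- spec$noise_sd * sqrt(1 / spec$n_pos + 1 / spec$n_neg)
    if (abs(mean(diffs) - spec$effect_size * spec$noise_sd) <
        3 * se / sqrt(length(planted_genes))) shift_ok <- shift_ok + 1L
    # non-planted genes stay null: their t-test p-values look uniform
    st <- t_test_genes(gen$data)
    null_p <- st$p_value[!st$gene %in% planted_genes]
    if (stats::ks.test(null_p, "punif")$p.value > 0.01) ks_ok <- ks_ok + 1L
  }
  expect_gte(shift_ok, 4L)
  expect_gte(ks_ok, 4L)
})

test_that("planted pathway genes are wired as stated; pathways are disjoint", {
  spec <- synthetic_spec(n_genes = 200, n_pathways = 5, pathway_size = 8,
                         n_planted = 2, pin_extra_edges = 100, seed = 7)
  gen <- simulate_dataset(spec)
  expect_length(gen$truth, 2)
  for (id in gen$truth) {
    g <- gen$sets$sets[[id]]
    sub <- igraph::induced_subgraph(gen$pin, g)
    expect_equal(igraph::ecount(sub), choose(length(g), 2))  # clique
  }
  expect_equal(anyDuplicated(unlist(gen$sets$sets)), 0)
  # path connectivity: exactly a chain
  gen2 <- simulate_dataset(synthetic_spec(n_genes = 100, n_pathways = 3,
                                          pathway_size = 6,
                                          planted_connectivity = "path",
                                          pin_extra_edges = 0, seed = 7))
  chain <- igraph::induced_subgraph(gen2$pin, gen2$sets$sets[[gen2$truth]])
  expect_equal(igraph::ecount(chain), 5)
  expect_true(igraph::is_connected(chain))
})

test_that("generation is deterministic and fixtures are byte-identical", {
  spec <- synthetic_spec(n_genes = 80, n_pos = 5, n_neg = 5, n_pathways = 4,
                         pathway_size = 6, pin_extra_edges = 60, seed = 33)
  d1 <- tempfile(); d2 <- tempfile()
  g1 <- write_synthetic_fixture(d1, spec)
  g2 <- write_synthetic_fixture(d2, spec)
  expect_identical(g1$data$values, g2$data$values)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f), warn = FALSE),
                     readLines(file.path(d2, f), warn = FALSE), info = f)
  }
})

test_that("fixtures round-trip through the package readers", {
  spec <- synthetic_spec(n_genes = 80, n_pos = 5, n_neg = 5, n_pathways = 4,
                         pathway_size = 6, pin_extra_edges = 60, seed = 33)
  out <- tempfile()
  gen <- write_synthetic_fixture(out, spec)
  d <- read_expression(file.path(out, "expression.tsv"),
                       file.path(out, "labels.tsv"))
  expect_equal(d$values, gen$data$values, tolerance = 1e-15)
  expect_identical(d$labels, gen$data$labels)
  gs <- read_gmt(file.path(out, "pathways.gmt"))
  expect_identical(gs$sets, gen$sets$sets)
  pin <- read_pin(file.path(out, "pin.tsv"))
  expect_equal(igraph::ecount(pin), igraph::ecount(gen$pin))
  expect_setequal(igraph::V(pin)$name, igraph::V(gen$pin)$name)
  truth <- jsonlite::read_json(file.path(out, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$planted, gen$truth)
})
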