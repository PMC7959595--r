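# Hypergeometric ORA, BH adjustment, and aggregation over iterations.

test_that("hypergeometric tail matches enumeration of all draws", {
  expect_equal(hypergeom_test(0, 4, 5, 10), 1)           # X >= 0 is certain
  expect_equal(hypergeom_test(3, 4, 5, 10), 66 / 252,    # counted by hand
               tolerance = 1e-12)
  expect_equal(hypergeom_test(3, 4, 5, 10), hyper_oracle_enum(3, 4, 5, 10),
               tolerance = 1e-12)
  expect_equal(hypergeom_test(4, 4, 10, 10), 1)          # query = background
  expect_error(hypergeom_test(5, 4, 5, 10), "overlap")
  expect_error(hypergeom_test(1, 11, 5, 10), "background")
})

test_that("BH adjustment equals the hand-written step-up", {
  expect_equal(bh_adjust(0.05), 0.05)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(17)
  for (rep in 1:20) {
    p <- runif(sample(1:50, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, bh_oracle(p), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-15) && all(adj <= 1))
    expect_true(all(diff(adj[order(p)]) >= -1e-15))  # order-statistics monotone
  }
})

test_that("subnetwork enrichment honors overlap, adjustment and the minimum rule", {
  sets <- gene_sets(list(PW1 = c("A", "B", "C"), PW2 = c("D", "E"),
                         PW3 = c("X", "Y", "Z")))
  background <- c("A", "B", "C", "D", "E", "F", "G", "H")  # X,Y,Z unannotated in data
  sub_exact <- list(genes = c("A", "B", "C"))
  res <- enrich_subnetworks(list(sub_exact), sets, background, threshold = 1)
  # the pathway identical to the subnetwork beats any partial overlap
  expect_true("PW1" %in% names(res))
  expect_equal(unname(res["PW1"]), min(res))
  # zero overlap: PW3 never tested
  expect_false("PW3" %in% names(res))
  # two subnetworks: the better adjusted p is kept per pathway
  sub_partial <- list(genes = c("A", "F", "G"))
  res2 <- enrich_subnetworks(list(sub_exact, sub_partial), sets, background,
                             threshold = 1)
  # within sub_exact only PW1 overlaps, so its adjusted p is its raw p,
  # and that beats the partial-overlap subnetwork's value
  p_exact <- hypergeom_test(3, 3, 3, 8)
  expect_equal(unname(res2["PW1"]), p_exact, tolerance = 1e-12)
  expect_lt(p_exact, hypergeom_test(1, 3, 3, 8))
  expect_length(enrich_subnetworks(list(), sets, background), 0)
})

test_that("a strict threshold never reports more pathways than a lenient one", {
  sets <- gene_sets(list(PW1 = c("A", "B"), PW2 = c("C", "D"), PW3 = c("A", "D")))
  bg <- LETTERS[1:10]
  subs <- list(list(genes = c("A", "B", "C")), list(genes = c("D", "E")))
  lenient <- enrich_subnetworks(subs, sets, bg, threshold = 0.9)
  strict <- enrich_subnetworks(subs, sets, bg, threshold = 0.2)
  expect_lte(length(strict), length(lenient))
  expect_true(all(names(strict) %in% names(lenient)))
})

planted_fixture <- function(seed = 5) {
  simulate_dataset(synthetic_spec(n_genes = 200, n_pos = 15, n_neg = 15,
                                  n_pathways = 8, pathway_size = 10,
                                  pin_extra_edges = 400, seed = seed))
}

test_that("repeated enrichment aggregates lowest/highest p and occurrences", {
  gen <- planted_fixture()
  st <- t_test_genes(gen$data)
  one <- run_enrichment(gen$pin, st, gen$sets, subnetwork_config(iterations = 1,
                                                                seed = 3))
  expect_true(all(one$lowest_adj_p == one$highest_adj_p))
  expect_true(all(one$occurrences == 1L))
  many <- run_enrichment(gen$pin, st, gen$sets,
                         subnetwork_config(iterations = 5, seed = 3))
  expect_true(all(many$lowest_adj_p <= many$highest_adj_p))
  expect_true(all(many$occurrences >= 1 & many$occurrences <= 5))
  # the planted clique pathway is found every iteration, with the best p
  planted <- many[many$pathway_id == gen$truth, ]
  expect_equal(planted$occurrences, 5L)
  expect_equal(many$pathway_id[1], gen$truth)
  # member genes are significant input genes inside the pathway
  sig <- significant_genes(st, 0.2)
  expect_true(all(planted$member_genes[[1]] %in%
                    intersect(sig, gen$sets$sets[[gen$truth]])))
})

test_that("repeated enrichment is deterministic given the master seed", {
  gen <- planted_fixture(seed = 9)
  st <- t_test_genes(gen$data)
  cfg <- subnetwork_config(iterations = 3, seed = 21)
  a <- run_enrichment(gen$pin, st, gen$sets, cfg)
  b <- run_enrichment(gen$pin, st, gen$sets, cfg)
  expect_identical(a, b)
})
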