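test_that("overlap p-value matches exact tail enumeration", {
  target <- subnetwork(paste0("T", 1:5), "T1", "target")
  disease_nodes <- c("T1", "T2", "T3", "D1")
  disease <- subnetwork(disease_nodes, "D1", "disease")
  # universe 20, marked 5, draws 4, overlap 3 -> 155/4845
  expect_equal(
    overlap_pvalue(target, disease, 20),
    (choose(5, 3) * choose(15, 1) + choose(5, 4)) / choose(20, 4),
    tolerance = 1e-12
  )
  expect_equal(
    overlap_pvalue(target, disease, 20),
    oracle_hyper_tail(3, 5, 4, 20),
    tolerance = 1e-12
  )

  disjoint <- subnetwork(paste0("D", 1:4), "D1", "disease")
  expect_equal(overlap_pvalue(target, disjoint, 20), 1)

  # target covering the whole universe forces full overlap
  expect_equal(overlap_pvalue(paste0("U", 1:6), paste0("U", 1:3), 6), 1)
  expect_error(overlap_pvalue(character(0), disease, 20), "non-empty")
})

test_that("seed-doubling variant enlarges draw, overlap and universe coherently", {
  target <- subnetwork(paste0("T", 1:5), "T1", "target")
  # disease of 4 nodes with 2 designated seeds, overlap 3 of which 2 seeds
  disease <- subnetwork(c("T1", "T2", "T3", "D1"), c("T1", "T2"), "disease")
  expect_equal(
    weighted_overlap_pvalue(target, disease, 20),
    oracle_hyper_tail(5, 5, 6, 22),
    tolerance = 1e-12
  )

  # no designated seeds: reduces exactly to the plain test
  no_seed <- subnetwork(c("T1", "T2", "T3", "D1"), character(0), "disease")
  expect_equal(
    weighted_overlap_pvalue(target, no_seed, 20),
    overlap_pvalue(target, no_seed, 20)
  )

  # hitting seeds is more surprising than hitting the same count of
  # expansion nodes
  seed_hit <- subnetwork(c("T1", "T2", "D1", "D2"), c("T1", "T2"), "disease")
  other_hit <- subnetwork(c("T1", "T2", "D1", "D2"), c("D1", "D2"), "disease")
  expect_lt(
    weighted_overlap_pvalue(target, seed_hit, 20),
    weighted_overlap_pvalue(target, other_hit, 20)
  )
})

test_that("hypergeometric tails agree with enumeration across small universes", {
  for (universe in c(8, 15, 23, 30)) {
    for (marked in unique(c(1, 3, universe %/% 2, universe - 1))) {
      for (draws in unique(c(1, 2, universe %/% 3, universe - 1))) {
        # feasible overlaps only: the two sets must fit in the universe
        for (k in max(0, marked + draws - universe):min(marked, draws)) {
          expect_equal(
            overlap_pvalue(
              paste0("M", seq_len(marked)),
              c(if (k > 0) paste0("M", seq_len(k)),
                if (draws > k) paste0("X", seq_len(draws - k))),
              universe
            ),
            oracle_hyper_tail(k, marked, draws, universe),
            tolerance = 1e-10,
            info = paste(universe, marked, draws, k)
          )
        }
      }
    }
  }
})

test_that("Holm adjustment reproduces step-down values and preserves order", {
  expect_equal(holm_adjust(c(0.01, 0.02, 0.04)), c(0.03, 0.04, 0.04))
  expect_equal(holm_adjust(0.2), 0.2)
  expect_equal(holm_adjust(rep(1, 4)), rep(1, 4))
  expect_error(holm_adjust(c(0.5, 1.2)), "0, 1")

  set.seed(8)
  for (i in 1:50) {
    p <- runif(sample(2:20, 1))
    adj <- holm_adjust(p)
    expect_equal(adj, oracle_holm(p), tolerance = 1e-12)
    # adjusted ordering never inverts the raw ordering
    expect_true(all(diff(adj[order(p)]) >= 0))
  }
})

test_that("ranking metric follows the two-branch seed-count adjustment", {
  expect_equal(ranking_metric(1, 5), 1)
  expect_equal(ranking_metric(1, 500), 1)
  expect_equal(ranking_metric(0.37, 1), 0.37) # log2(2) = 1
  expect_equal(ranking_metric(0.05, 7), 0.05 / 3, tolerance = 1e-12)
  expect_error(ranking_metric(0.5, 0), "n_seeds")
  # vectorised with recycling
  expect_equal(ranking_metric(c(0.5, 1), c(3, 3)), c(0.5 / 2, 1))
})

ranking_fixture <- function(n_diseases = 4, seed = 3) {
  set.seed(seed)
  net <- random_network(60, 0.1)
  nodes <- network_nodes(net)
  entries <- purrr::map(seq_len(n_diseases), function(i) {
    seeds <- sample(nodes, 4)
    tibble::tibble(
      disease_id = sprintf("D%02d", i),
      disease_name = paste("disease", i),
      mesh_id = sprintf("M%02d", i),
      seeds = list(seeds),
      scores = list(setNames(runif(4, 0.3, 1), seeds))
    )
  })
  list(net = net, catalog = disease_catalog(dplyr::bind_rows(entries)))
}

test_that("indication ranking is dense, inverse-rank scored and metric-sorted", {
  fx <- ranking_fixture(6)
  sub <- build_target_subnetwork(
    fx$net, network_nodes(fx$net)[1], top_k = 10
  )
  rk <- rank_indications(fx$net, sub, fx$catalog, module_iterations = 5)
  expect_equal(rk$rank, seq_len(nrow(rk)))
  expect_equal(rk$score, 1 / rk$rank)
  expect_true(all(diff(rk$metric) >= 0))
  expect_equal(sum(rk$score), sum(1 / seq_len(nrow(rk))))
  expect_equal(rk$fdr, holm_adjust(rk$pvalue), ignore_attr = TRUE)

  # single-disease catalog: rank 1, score 1 regardless of p
  one <- dplyr::slice(fx$catalog, 1)
  rk1 <- rank_indications(fx$net, sub, disease_catalog(one),
                          module_iterations = 3)
  expect_equal(rk1$rank, 1L)
  expect_equal(rk1$score, 1)
})

test_that("at equal p-value the disease with more seeds ranks first", {
  expect_lt(ranking_metric(0.3, 15), ranking_metric(0.3, 3))
  fx <- ranking_fixture(2)
  # directly exercise the sort on a synthetic metric tie
  df <- tibble::tibble(
    disease_id = c("A", "B"), n_seeds = c(3L, 15L), pvalue = c(0.3, 0.3)
  )
  metric <- ranking_metric(df$pvalue, df$n_seeds)
  expect_equal(df$disease_id[order(metric)], c("B", "A"))
})

test_that("weighted and plain variants are both exposed through rank_indications", {
  fx <- ranking_fixture(4, seed = 13)
  sub <- build_target_subnetwork(
    fx$net, network_nodes(fx$net)[2], top_k = 8
  )
  modules <- compute_disease_modules(fx$net, fx$catalog, 5)
  plain <- rank_indications(fx$net, sub, fx$catalog, "plain",
                            modules = modules)
  weighted <- rank_indications(fx$net, sub, fx$catalog, "weighted",
                               modules = modules)
  expect_setequal(plain$disease_id, weighted$disease_id)
  universe <- length(network_nodes(fx$net))
  id1 <- plain$disease_id[1]
  expect_equal(
    plain$pvalue[1],
    overlap_pvalue(sub, modules[[id1]], universe)
  )
  wid <- weighted$disease_id[2]
  expect_equal(
    weighted$pvalue[weighted$disease_id == wid],
    weighted_overlap_pvalue(sub, modules[[wid]], universe)
  )
})
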