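catalog_from_scores <- function(score_list) {
  entries <- purrr::imap(score_list, function(s, id) {
    tibble::tibble(
      disease_id = id,
      disease_name = paste("disease", id),
      mesh_id = paste0("M", id),
      seeds = list(names(s)),
      scores = list(s)
    )
  })
  disease_catalog(dplyr::bind_rows(entries))
}

test_that("genetic baseline sorts by association score with zero fallback", {
  cat <- catalog_from_scores(list(
    D1 = c(TG = 0.7, X1 = 0.2),
    D2 = c(TG = 0.3),
    D3 = c(X2 = 0.9)
  ))
  rk <- genetic_association_rank(cat, "TG")
  expect_equal(rk$disease_id, c("D1", "D2", "D3"))
  expect_equal(rk$assoc_score, c(0.7, 0.3, 0))
  expect_equal(rk$score, 1 / (1:3))

  # target absent everywhere: all zero, lexicographic order
  rk0 <- genetic_association_rank(cat, "NOPE")
  expect_equal(rk0$disease_id, c("D1", "D2", "D3"))
  expect_equal(rk0$assoc_score, rep(0, 3))

  # combination scoring takes the max over targets, checked per target
  cat2 <- catalog_from_scores(list(
    D1 = c(T1 = 0.2, T2 = 0.8),
    D2 = c(T1 = 0.5)
  ))
  combo <- genetic_association_rank(cat2, c("T1", "T2"))
  per_target <- pmax(
    genetic_association_rank(cat2, "T1")$assoc_score[
      order(genetic_association_rank(cat2, "T1")$disease_id)],
    genetic_association_rank(cat2, "T2")$assoc_score[
      order(genetic_association_rank(cat2, "T2")$disease_id)]
  )
  expect_equal(combo$assoc_score[order(combo$disease_id)], per_target)
})

path4 <- interaction_network(tibble::tibble(
  from = c("a", "b", "c"), to = c("b", "c", "d"), weight = 1
))

test_that("proximity distances reproduce the hand-computed path cases", {
  expect_equal(closest_distance(path4, c("a", "b"), c("c", "d")), 1.5)
  expect_equal(closest_distance(path4, "a", c("c", "d")), 2.5)
  expect_equal(shortest_distance(path4, c("a", "b"), c("c", "d")), 2.0)
  expect_equal(shortest_distance(path4, "a", "a"), 0)
  expect_equal(closest_distance(path4, c("c", "d"), c("c", "d")), 0)

  # kernel: singletons at distance d give d + 1; the two-target case
  path3 <- interaction_network(tibble::tibble(
    from = c("a", "b"), to = c("b", "c"), weight = 1
  ))
  expect_equal(kernel_distance(path3, "a", "b"), 2.0)
  expect_equal(kernel_distance(path3, "a", "a"), 1.0)
  expect_equal(kernel_distance(path3, c("a", "c"), "b"),
               -log(0.5 * (exp(-2) + exp(-2))))
  expect_equal(kernel_distance(path3, c("a", "c"), "b"), 2.0)
})

test_that("closest never exceeds shortest and both match the BFS oracle", {
  set.seed(21)
  for (i in 1:20) {
    net <- random_network(sample(15:80, 1), runif(1, 0.06, 0.2))
    nodes <- network_nodes(net)
    targets <- sample(nodes, sample(1:3, 1))
    genes <- sample(nodes, sample(2:5, 1))
    d <- oracle_distance_matrix(net, targets, genes)
    mins <- apply(d, 2, min)
    finite_min <- mins[is.finite(mins)]
    if (length(finite_min) == 0) next
    expect_equal(quiet(closest_distance(net, targets, genes)),
                 mean(finite_min), tolerance = 1e-12)
    expect_equal(quiet(shortest_distance(net, targets, genes)),
                 mean(d[is.finite(d)]), tolerance = 1e-12)
    inner <- apply(d, 2, function(col) mean(exp(-(col + 1))))
    expect_equal(quiet(kernel_distance(net, targets, genes)),
                 -mean(log(inner[inner > 0])), tolerance = 1e-12)
    expect_lte(quiet(closest_distance(net, targets, genes)),
               quiet(shortest_distance(net, targets, genes)))
  }
})

test_that("unreachable nodes are excluded or rejected", {
  two_comp <- interaction_network(tibble::tibble(
    from = c("a", "x"), to = c("b", "y"), weight = 1
  ))
  expect_error(closest_distance(two_comp, "a", "x"), "reachable")
  expect_message(
    val <- closest_distance(two_comp, "a", c("b", "x")),
    "excluded"
  )
  expect_equal(val, 1)
})

test_that("proximity z-scores are deterministic, centred and rank sensibly", {
  set.seed(31)
  net <- random_network(60, 0.12)
  nodes <- network_nodes(net)
  z1 <- proximity_zscore(net, nodes[1], nodes[10:13], "closest",
                         n_random = 25, seed = 9, min_bin_size = 5)
  z2 <- proximity_zscore(net, nodes[1], nodes[10:13], "closest",
                         n_random = 25, seed = 9, min_bin_size = 5)
  expect_identical(z1, z2)
  expect_equal(z1$zscore,
               (z1$distance - z1$background_mean) / z1$background_sd)

  # degree-matched sampling returns distinct nodes of the requested size
  drawn <- withr::with_seed(4, netindic:::sample_degree_matched(
    net, nodes[10:13], min_bin_size = 5
  ))
  expect_equal(length(drawn), 4L)
  expect_equal(anyDuplicated(drawn), 0L)

  # a target's own neighbourhood must look closer than chance
  nb <- utils::head(c(nodes[1], netindic:::neighbors_of(net, nodes[1])), 3)
  z_self <- proximity_zscore(net, nodes[1], nb, "closest",
                             n_random = 40, seed = 2, min_bin_size = 5)
  expect_lt(z_self$zscore, 0)
})
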