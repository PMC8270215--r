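test_that("edge filtering keeps strictly super-threshold edges and drops lone nodes", {
  f <- withr::local_tempfile()
  writeLines(c("A B 0.9", "B C 0.5", "A C 0.71"), f)
  net <- quiet(read_interactions(f, score_threshold = 0.7))
  expect_setequal(network_nodes(net), c("A", "B", "C"))
  expect_equal(nrow(network_edges(net)), 2L)
  expect_setequal(
    paste(network_edges(net)$from, network_edges(net)$to),
    c("A B", "A C")
  )

  # node D only touches a sub-threshold edge and must vanish
  writeLines(c("A B 0.9", "C D 0.2", "A C 0.8"), f)
  net2 <- quiet(read_interactions(f, 0.7))
  expect_false("D" %in% network_nodes(net2))
})

test_that("0-1000 STRING scale is detected and normalised before thresholding", {
  f <- withr::local_tempfile()
  writeLines(
    c("protein1 protein2 combined_score", "A B 900", "B C 700", "A C 701"),
    f
  )
  net <- quiet(read_interactions(f, 0.7))
  # strictly greater than 700: the 700 edge is excluded, 701 kept
  expect_setequal(
    paste(network_edges(net)$from, network_edges(net)$to),
    c("A B", "A C")
  )
  expect_true(all(network_edges(net)$weight > 0.7))

  # explicit scale flag gives the same result
  net2 <- quiet(read_interactions(f, 0.7, score_scale = "0-1000"))
  expect_equal(network_edges(net2), network_edges(net))
})

test_that("degenerate inputs error informatively", {
  f <- withr::local_tempfile()
  writeLines(c("A B 0.9", "B C"), f)
  expect_error(quiet(read_interactions(f)), "line 2")
  writeLines(c("A B 0.9", "B C x"), f)
  expect_error(quiet(read_interactions(f)), "line 2")
  writeLines(c("A B 0.9"), f)
  expect_error(
    quiet(read_interactions(f, score_threshold = 1.0)),
    class = "netindic_empty_network"
  )
})

test_that("filtering is idempotent and monotone in the threshold", {
  f <- withr::local_tempfile()
  set.seed(11)
  edges <- random_graph_edges(25, 0.2)
  edges$weight <- round(runif(nrow(edges)), 3)
  readr::write_tsv(edges, f, col_names = FALSE)
  sizes <- sapply(c(0.2, 0.5, 0.8), function(th) {
    net <- tryCatch(
      quiet(read_interactions(f, th)),
      error = function(e) NULL
    )
    if (is.null(net)) c(0, 0) else
      c(length(network_nodes(net)), nrow(network_edges(net)))
  })
  expect_true(all(diff(sizes[1, ]) <= 0))
  expect_true(all(diff(sizes[2, ]) <= 0))

  # refiltering an already-filtered network changes nothing
  net <- quiet(read_interactions(f, 0.5))
  f2 <- withr::local_tempfile()
  readr::write_tsv(network_edges(net), f2, col_names = FALSE)
  net2 <- quiet(read_interactions(f2, 0.5))
  expect_equal(network_edges(net2), network_edges(net))
})

make_disease_file <- function(rows) {
  f <- withr::local_tempfile(.local_envir = parent.frame())
  readr::write_tsv(rows, f)
  f
}

test_that("disease catalog intersects seeds, drops MeSH-less and underseeded entries", {
  net <- interaction_network(tibble::tibble(
    from = c("G1", "G2"), to = c("G2", "G3"), weight = 1
  ))
  rows <- tibble::tibble(
    geneSymbol = c("G1", "G2", "G9", "G1", "G1", "G9"),
    diseaseId = c("D1", "D1", "D1", "D2", "D3", "D3"),
    diseaseName = paste("disease", c(1, 1, 1, 2, 3, 3)),
    meshId = c("M1", "M1", "M1", NA, "M3", "M3"),
    score = c(0.9, 0.5, 0.4, 0.8, 0.7, 0.6)
  )
  cat1 <- quiet(read_disease_catalog(make_disease_file(rows), net))
  # D2 lacks a MeSH id; D1 loses G9; D3 keeps G1 only
  expect_setequal(cat1$disease_id, c("D1", "D3"))
  expect_setequal(cat1$seeds[[which(cat1$disease_id == "D1")]], c("G1", "G2"))
  expect_equal(cat1$n_seeds[cat1$disease_id == "D3"], 1L)
  rep <- attr(cat1, "drop_report")
  expect_equal(rep$dropped_no_mesh, 1L)

  cat2 <- quiet(read_disease_catalog(make_disease_file(rows), net,
                                     min_seeds = 2))
  expect_equal(cat2$disease_id, "D1")
  expect_equal(attr(cat2, "drop_report")$dropped_few_seeds, 1L)

  expect_error(
    quiet(read_disease_catalog(
      make_disease_file(dplyr::select(rows, -meshId)), net
    )),
    "meshId"
  )
})

test_that("MeSH deduplication keeps the best rank and re-ranks densely", {
  ranking <- tibble::tibble(
    rank = 1:5,
    disease_id = paste0("D", 1:5),
    mesh_id = c("M1", "M2", "M1", "M3", "M1"),
    score = 1 / (1:5)
  )
  out <- deduplicate_by_mesh(ranking)
  expect_equal(out$disease_id, c("D1", "D2", "D4"))
  expect_equal(out$rank, 1:3)
  expect_equal(out$score, 1 / (1:3))
  # output size equals the number of distinct MeSH ids
  expect_equal(nrow(out), dplyr::n_distinct(ranking$mesh_id))

  # all-distinct input passes through unchanged
  distinct_in <- dplyr::mutate(ranking, mesh_id = paste0("M", 1:5))
  expect_equal(
    deduplicate_by_mesh(distinct_in)$disease_id,
    distinct_in$disease_id
  )
})
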