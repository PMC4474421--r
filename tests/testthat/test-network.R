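test_that("build_network keeps records matching the allowed role sets", {
  tab <- ra_table()
  cr <- build_network(tab, "compound", "regulator")
  expect_equal(nrow(cr$edges), 1L)
  expect_equal(cr$edges$source, "RA")
  expect_equal(cr$edges$sign, 1L)
  expect_setequal(cr$nodes$id, c("RA", "DAX1")) # only compound/regulator roles

  full <- build_network(tab, c("compound", "regulator"), c("regulator", "enzyme"))
  expect_equal(nrow(full$edges), 2L)
  expect_equal(nrow(full$nodes), 3L)

  empty <- interaction_table(
    entities = tibble::tibble(id = character(), name = character(), role = character()),
    records = tibble::tibble(source_id = character(), target_id = character(), sign = integer())
  )
  out <- build_network(empty, "compound", "regulator")
  expect_equal(nrow(out$nodes), 0L)
  expect_equal(nrow(out$edges), 0L)

  expect_error(build_network(tab, character(), "regulator"), class = "cypnet_argument_error")
})

test_that("conflicting-sign duplicates collapse to a single sign-0 edge with a warning", {
  tab <- interaction_table(
    entities = tibble::tibble(
      id = c("A", "B"), name = c("A", "B"), role = c("compound", "regulator")
    ),
    records = tibble::tibble(
      source_id = c("A", "A"), target_id = c("B", "B"), sign = c(1L, -1L)
    )
  )
  expect_warning(
    net <- build_network(tab, "compound", "regulator"),
    "conflicting"
  )
  expect_equal(nrow(net$edges), 1L)
  expect_equal(net$edges$sign, 0L)
})

filter_fixture <- function() {
  signed_network(
    nodes = tibble::tibble(
      id = c("c1", "c2", "r1", "r2", "r3", "r4"),
      role = c("compound", "compound", rep("regulator", 4))
    ),
    edges = tibble::tibble(
      source = c("c1", "c1", "c1", "c2", "c2"),
      target = c("r1", "r2", "r3", "r1", "r2"),
      sign = 1L
    )
  )
}

test_that("filter removes low-degree compounds then orphan regulators", {
  out <- filter_network(filter_fixture(), filter_config(min_compound_edges = 3))
  expect_setequal(out$nodes$id, c("c1", "r1", "r2", "r3")) # c2 (deg 2) and r4 (orphan) go
  expect_same_network(out, oracle_filter(filter_fixture(), 3))
})

test_that("filter with zero threshold and no orphan rule is the identity", {
  net <- filter_fixture()
  out <- filter_network(
    net,
    filter_config(min_compound_edges = 0, drop_orphan_regulators = FALSE)
  )
  expect_same_network(out, net)
})

test_that("when every compound is below threshold, regulators orphan out too", {
  out <- filter_network(filter_fixture(), filter_config(min_compound_edges = 10))
  expect_equal(nrow(out$nodes), 0L)
  expect_equal(nrow(out$edges), 0L)
})

test_that("fixpoint filtering is idempotent and matches the iterated oracle", {
  for (seed in 1:20) {
    net <- with_seed(seed, random_network(n_nodes = 10L, p_edge = 0.15))
    for (fix in c(FALSE, TRUE)) {
      cfg <- filter_config(min_compound_edges = 2, iterate_to_fixpoint = fix)
      out <- filter_network(net, cfg)
      expect_same_network(out, oracle_filter(net, 2, fixpoint = fix))
      if (fix) expect_same_network(filter_network(out, cfg), out)
    }
  }
})

test_that("merging the two layer networks joins them on shared regulators", {
  tab <- ra_table()
  cr <- build_network(tab, "compound", "regulator")
  re <- build_network(tab, "regulator", "enzyme")
  merged <- merge_networks(cr, re)
  expect_equal(nrow(merged$nodes), 3L)
  expect_equal(nrow(merged$edges), 2L)
})

test_that("merge is idempotent, commutative, associative, with empty identity", {
  empty <- signed_network(
    nodes = tibble::tibble(id = character(), role = character()),
    edges = tibble::tibble(source = character(), target = character(), sign = integer())
  )
  for (seed in 1:10) {
    # three networks over one shared role-annotated node set, so merging
    # never trips the role-conflict check
    nets <- with_seed(seed, {
      base <- random_network(8L, 0)
      lapply(1:3, function(i) {
        e <- random_network(8L, 0.2)$edges
        signed_network(base$nodes, e)
      })
    })
    x <- nets[[1]]
    expect_same_network(merge_networks(x, empty), x)
    expect_same_network(merge_networks(x, x), x)
    ab <- suppressWarnings(merge_networks(nets[[1]], nets[[2]]))
    ba <- suppressWarnings(merge_networks(nets[[2]], nets[[1]]))
    expect_same_network(ab, ba)
    abc1 <- suppressWarnings(merge_networks(ab, nets[[3]]))
    abc2 <- suppressWarnings(merge_networks(
      nets[[1]], merge_networks(nets[[2]], nets[[3]])
    ))
    expect_same_network(abc1, abc2)
  }
})

test_that("merge resolves sign conflicts to 0 and rejects role conflicts", {
  a <- signed_network(
    nodes = tibble::tibble(id = c("c1", "r1"), role = c("compound", "regulator")),
    edges = tibble::tibble(source = "c1", target = "r1", sign = 1L)
  )
  b <- signed_network(
    nodes = tibble::tibble(id = c("c1", "r1"), role = c("compound", "regulator")),
    edges = tibble::tibble(source = "c1", target = "r1", sign = -1L)
  )
  expect_warning(m <- merge_networks(a, b), "conflicting")
  expect_equal(m$edges$sign, 0L)

  role_clash <- signed_network(
    nodes = tibble::tibble(id = "c1", role = "enzyme"),
    edges = tibble::tibble(source = character(), target = character(), sign = integer())
  )
  expect_error(merge_networks(a, role_clash), class = "cypnet_validation_error")
})

cluster_fixture <- function() {
  compounds <- sprintf("c%d", 1:6)
  signed_network(
    nodes = tibble::tibble(
      id = c(compounds, "r1", "r2", "r3"),
      role = c(rep("compound", 6), rep("regulator", 3))
    ),
    edges = tibble::tibble(
      source = c("c1", "c2", "c3", "c4", "c5", "c1", "c5", "c6"),
      target = c(rep("r1", 5), rep("r2", 3)),
      sign = 1L
    )
  )
}

test_that("clusters are compound in-neighbour sets ranked by size", {
  cl <- find_clusters(cluster_fixture())
  expect_equal(cl$hub_id, c("r1", "r2")) # r3 has no compounds -> no cluster
  expect_equal(cl$size, c(5L, 3L))
  # c1 and c5 influence both regulators and sit in both clusters
  expect_true(all(c("c1", "c5") %in% cl$member_compound_ids[[1]]))
  expect_true(all(c("c1", "c5") %in% cl$member_compound_ids[[2]]))
})

test_that("cluster sizes sum to the number of compound-regulator edges", {
  for (seed in 1:10) {
    net <- with_seed(seed, random_network(12L, 0.25))
    cl <- find_clusters(net)
    role_of <- stats::setNames(net$nodes$role, net$nodes$id)
    n_cr <- sum(role_of[net$edges$source] == "compound" &
      role_of[net$edges$target] == "regulator")
    expect_equal(sum(cl$size), n_cr)
    # ranking: size descending, hub id ascending on ties
    expect_equal(order(-cl$size, cl$hub_id), seq_len(nrow(cl)))
  }
})

test_that("an empty network has no clusters and an all-zero summary", {
  empty <- signed_network(
    nodes = tibble::tibble(id = character(), role = character()),
    edges = tibble::tibble(source = character(), target = character(), sign = integer())
  )
  expect_equal(nrow(find_clusters(empty)), 0L)
  s <- network_summary(empty)
  expect_true(all(unlist(s) == 0))
})

test_that("path tracing composes signs along the RA motif", {
  tr <- trace_paths(ra_network(), "RA")
  expect_equal(nrow(tr), 1L)
  expect_equal(tr$node_sequence[[1]], c("RA", "DAX1", "CYP19A1"))
  expect_equal(tr$edge_signs[[1]], c(1L, -1L))
  expect_equal(tr$net_sign, -1L)
  expect_equal(tr$terminal_id, "CYP19A1")
})

test_that("single-edge and unknown-sign paths behave as specified", {
  net <- signed_network(
    nodes = tibble::tibble(id = c("c1", "e1"), role = c("compound", "enzyme")),
    edges = tibble::tibble(source = "c1", target = "e1", sign = 1L)
  )
  tr <- trace_paths(net, "c1")
  expect_equal(tr$net_sign, 1L)
  expect_equal(lengths(tr$edge_signs), 1L)

  with_zero <- signed_network(
    nodes = tibble::tibble(
      id = c("c1", "r1", "e1"), role = c("compound", "regulator", "enzyme")
    ),
    edges = tibble::tibble(
      source = c("c1", "r1"), target = c("r1", "e1"), sign = c(0L, -1L)
    )
  )
  expect_equal(trace_paths(with_zero, "c1")$net_sign, 0L)
})

test_that("trace_paths errors on unknown or non-compound start nodes", {
  expect_error(trace_paths(ra_network(), "NOPE"), class = "cypnet_lookup_error")
  expect_error(trace_paths(ra_network(), "DAX1"), class = "cypnet_argument_error")
})

test_that("trace_paths equals the exhaustive igraph oracle on random graphs", {
  skip_if_not_installed("igraph")
  for (seed in 1:25) {
    net <- with_seed(seed, random_network(n_nodes = sample(4:12, 1), p_edge = 0.3))
    compounds <- net$nodes$id[net$nodes$role == "compound"]
    if (!length(compounds)) next
    for (cid in compounds) {
      got <- trace_paths(net, cid, max_depth = 10L)
      keys <- vapply(got$node_sequence, paste, character(1), collapse = ">")
      expect_equal(keys, sort(keys)) # lexicographic output order
      want <- oracle_paths(net, cid, max_depth = 10L)
      expect_equal(keys, want$sequences)
      expect_equal(as.numeric(got$net_sign), want$net_signs)
      # net sign re-derivable from the edge signs, 0 absorbing
      expect_equal(
        got$net_sign,
        vapply(got$edge_signs, function(s) as.integer(prod(s)), integer(1))
      )
    }
  }
})

test_that("max_depth caps the traced path length", {
  ids <- sprintf("n%d", 1:5)
  chain <- signed_network(
    nodes = tibble::tibble(id = ids, role = c("compound", rep("regulator", 3), "enzyme")),
    edges = tibble::tibble(source = ids[-5], target = ids[-1], sign = 1L)
  )
  expect_equal(nrow(trace_paths(chain, "n1", max_depth = 4L)), 1L)
  expect_equal(nrow(trace_paths(chain, "n1", max_depth = 3L)), 0L)
})

test_that("predict_interactions aggregates enzyme-terminated paths per compound", {
  pred <- predict_interactions(ra_network())
  expect_equal(nrow(pred), 1L)
  expect_equal(pred$compound_id, "RA")
  expect_equal(pred$enzyme_id, "CYP19A1")
  expect_equal(pred$net_sign, -1L)
  expect_equal(pred$n_paths, 1L)

  # compound with no enzyme-terminated path yields no row
  dangling <- signed_network(
    nodes = tibble::tibble(id = c("c1", "r1"), role = c("compound", "regulator")),
    edges = tibble::tibble(source = "c1", target = "r1", sign = 1L)
  )
  expect_equal(nrow(predict_interactions(dangling)), 0L)
})

test_that("disagreeing paths to the same enzyme aggregate to sign 0", {
  net <- signed_network(
    nodes = tibble::tibble(
      id = c("c1", "r1", "r2", "e1"),
      role = c("compound", "regulator", "regulator", "enzyme")
    ),
    edges = tibble::tibble(
      source = c("c1", "c1", "r1", "r2"),
      target = c("r1", "r2", "e1", "e1"),
      sign = c(1L, 1L, 1L, -1L)
    )
  )
  pred <- predict_interactions(net)
  expect_equal(pred$net_sign, 0L)
  expect_equal(pred$n_paths, 2L)
})

test_that("network_summary counts match the generator's declared composition", {
  cfg <- network_sim_config(
    n_compounds = 12, n_regulators = 6, n_enzymes = 5,
    mean_compound_degree = 3, seed = 11
  )
  db <- generate_interaction_db(cfg)
  net <- build_network(db$table, c("compound", "regulator"), c("regulator", "enzyme"))
  s <- network_summary(net)
  expect_equal(s$n_compounds, 12L)
  expect_equal(s$n_regulators, 6L)
  expect_equal(s$n_enzymes, 5L)
  expect_equal(s$n_nodes, s$n_compounds + s$n_regulators + s$n_enzymes)
  expect_equal(s$n_edges, nrow(net$edges))
})
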