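# Shared fixtures and independent oracles. Everything here is deliberately
# naive (loops, exhaustive enumeration, igraph for path sets) so it stays
# independent of the implementation paths it checks.

# The retinoic-acid motif: RA --(+)--> DAX1 --(-)--> CYP19A1.
ra_table <- function() {
  interaction_table(
    entities = tibble::tibble(
      id = c("RA", "DAX1", "CYP19A1"),
      name = c("retinoic acid", "DAX1", "aromatase"),
      role = c("compound", "regulator", "enzyme")
    ),
    records = tibble::tibble(
      source_id = c("RA", "DAX1"),
      target_id = c("DAX1", "CYP19A1"),
      sign = c(1L, -1L)
    )
  )
}

ra_network <- function() {
  build_network(ra_table(), c("compound", "regulator"), c("regulator", "enzyme"))
}

# Write an interaction table to edge + roles TSV files in a temp dir.
write_table_fixture <- function(tab, dir = withr::local_tempdir(.local_envir = parent.frame()),
                                dialect = "tsv") {
  edge_path <- file.path(dir, paste0("edges.", dialect))
  roles_path <- file.path(dir, "roles.tsv")
  write_network(tab, edge_path, dialect)
  write_roles(tab, roles_path)
  list(edges = edge_path, roles = roles_path, dir = dir)
}

# Random role-annotated signed network: distinct ordered pairs, no self
# loops. Used for filter/merge/trace property tests.
random_network <- function(n_nodes = 10L, p_edge = 0.25,
                           roles = c("compound", "regulator", "enzyme")) {
  ids <- sprintf("n%02d", seq_len(n_nodes))
  nodes <- tibble::tibble(
    id = ids, name = ids,
    role = sample(roles, n_nodes, replace = TRUE)
  )
  pairs <- expand.grid(source = ids, target = ids, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$source != pairs$target, ]
  pairs <- pairs[stats::runif(nrow(pairs)) < p_edge, ]
  pairs$sign <- sample(c(-1L, 0L, 1L), nrow(pairs), replace = TRUE)
  signed_network(nodes, pairs)
}

# Brute-force oracle for the two elimination rules, written as plain loops.
oracle_filter <- function(net, min_edges, fixpoint = FALSE) {
  nodes <- as.data.frame(net$nodes)
  edges <- as.data.frame(net$edges)
  repeat {
    n_before <- nrow(nodes)
    # rule 1: compounds with < min_edges distinct incident edges
    keep <- rep(TRUE, nrow(nodes))
    for (i in seq_len(nrow(nodes))) {
      if (nodes$role[i] != "compound") next
      deg <- 0L
      for (j in seq_len(nrow(edges))) {
        if (edges$source[j] == nodes$id[i] || edges$target[j] == nodes$id[i]) {
          deg <- deg + 1L
        }
      }
      if (deg < min_edges) keep[i] <- FALSE
    }
    nodes <- nodes[keep, ]
    edges <- edges[edges$source %in% nodes$id & edges$target %in% nodes$id, ]
    # rule 2: regulators with no compound neighbour
    keep <- rep(TRUE, nrow(nodes))
    role_of <- stats::setNames(nodes$role, nodes$id)
    for (i in seq_len(nrow(nodes))) {
      if (nodes$role[i] != "regulator") next
      has_compound <- FALSE
      for (j in seq_len(nrow(edges))) {
        other <- if (edges$source[j] == nodes$id[i]) {
          edges$target[j]
        } else if (edges$target[j] == nodes$id[i]) {
          edges$source[j]
        } else {
          next
        }
        if (role_of[[other]] == "compound") has_compound <- TRUE
      }
      if (!has_compound) keep[i] <- FALSE
    }
    nodes <- nodes[keep, ]
    edges <- edges[edges$source %in% nodes$id & edges$target %in% nodes$id, ]
    if (!fixpoint || nrow(nodes) == n_before) break
  }
  signed_network(nodes, edges)
}

# Exhaustive simple-path oracle via igraph: all simple directed paths from
# `from` to every out-degree-0 node, at most max_depth edges.
oracle_paths <- function(net, from, max_depth = 10L) {
  g <- igraph::graph_from_data_frame(
    as.data.frame(net$edges), directed = TRUE,
    vertices = as.data.frame(net$nodes)
  )
  terminals <- igraph::V(g)$name[igraph::degree(g, mode = "out") == 0]
  terminals <- setdiff(terminals, from)
  seqs <- list()
  for (t in terminals) {
    ps <- igraph::all_simple_paths(g, from = from, to = t,
      mode = "out", cutoff = max_depth
    )
    for (p in ps) seqs[[length(seqs) + 1L]] <- igraph::as_ids(p)
  }
  # net sign: product of edge signs along the sequence, 0 absorbing
  sign_of <- function(s) {
    prod(vapply(seq_len(length(s) - 1L), function(i) {
      net$edges$sign[net$edges$source == s[i] & net$edges$target == s[i + 1L]]
    }, integer(1)))
  }
  keys <- vapply(seqs, paste, character(1), collapse = ">")
  ord <- order(keys)
  list(
    sequences = keys[ord],
    net_signs = vapply(seqs, sign_of, numeric(1))[ord]
  )
}

# Balanced one-group-per-dose expression dataset from raw values.
make_dataset <- function(values_by_group, value_kind = "relative",
                         cell_line = "HeLa", gene = "CYP19A1") {
  doses <- as.numeric(names(values_by_group))
  expression_dataset(tibble::tibble(
    cell_line = cell_line, gene = gene,
    dose_nM = rep(doses, lengths(values_by_group)),
    replicate = unlist(lapply(lengths(values_by_group), seq_len)),
    value = unlist(values_by_group, use.names = FALSE),
    value_kind = value_kind
  ))
}

# Explicit sums-of-squares ANOVA oracle from brute-force group sums.
oracle_anova <- function(values, groups) {
  groups <- as.character(groups)
  grand <- mean(values)
  ss_between <- 0
  ss_within <- 0
  for (g in unique(groups)) {
    y <- values[groups == g]
    ss_between <- ss_between + length(y) * (mean(y) - grand)^2
    ss_within <- ss_within + sum((y - mean(y))^2)
  }
  k <- length(unique(groups))
  n <- length(values)
  f <- (ss_between / (k - 1)) / (ss_within / (n - k))
  list(F = f, df1 = k - 1, df2 = n - k,
    p = stats::pf(f, k - 1, n - k, lower.tail = FALSE)
  )
}

edge_triples <- function(x) {
  e <- if (inherits(x, "interaction_table")) {
    data.frame(s = x$records$source_id, t = x$records$target_id, g = x$records$sign)
  } else {
    data.frame(s = x$edges$source, t = x$edges$target, g = x$edges$sign)
  }
  sort(paste(e$s, e$t, e$g))
}

expect_same_network <- function(a, b) {
  expect_setequal(a$nodes$id, b$nodes$id)
  expect_equal(
    a$nodes$role[order(a$nodes$id)],
    b$nodes$role[order(b$nodes$id)]
  )
  expect_equal(edge_triples(a), edge_triples(b))
}
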