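#' Signed directed interaction networks
#'
#' A `signed_network` is a directed graph whose nodes are role-annotated
#' entities (compound, regulator, enzyme) and whose edges carry a sign:
#' +1 for activation / up-regulation, -1 for inhibition / down-regulation,
#' 0 for an interaction with no stated direction. There is at most one edge
#' per ordered node pair and no self-loops.
#'
#' @param nodes Data frame with columns `id`, `name`, `role`.
#' @param edges Data frame with columns `source`, `target`, `sign`.
#' @return An object of class `signed_network`.
#' @export
signed_network <- function(nodes, edges) {
  nodes <- tibble::as_tibble(nodes)
  if (!all(c("id", "role") %in% names(nodes))) {
    abort_argument("nodes must have columns id and role (and optionally name)")
  }
  if (!"name" %in% names(nodes)) nodes$name <- nodes$id
  nodes$id <- as.character(nodes$id)
  nodes$name <- as.character(nodes$name)
  if (anyDuplicated(nodes$id)) {
    abort_validation(paste0(
      "duplicate node ids: ",
      paste(unique(nodes$id[duplicated(nodes$id)]), collapse = ", ")
    ))
  }
  check_roles(nodes$role, nodes$id)

  edges <- tibble::as_tibble(edges)
  if (!all(c("source", "target", "sign") %in% names(edges))) {
    abort_argument("edges must have columns source, target, sign")
  }
  edges$source <- as.character(edges$source)
  edges$target <- as.character(edges$target)
  edges$sign <- check_sign(edges$sign)
  if (any(edges$source == edges$target)) {
    abort_validation("self-loops are not allowed in a signed_network")
  }
  loose <- setdiff(c(edges$source, edges$target), nodes$id)
  if (length(loose)) {
    abort_validation(paste0(
      "edge endpoints not in node set: ", paste(loose, collapse = ", ")
    ))
  }
  if (anyDuplicated(paste(edges$source, edges$target, sep = "\r"))) {
    abort_validation("at most one edge per ordered (source, target) pair")
  }

  structure(
    list(
      nodes = nodes[, c("id", "name", "role")],
      edges = edges[, c("source", "target", "sign")]
    ),
    class = "signed_network"
  )
}

#' @export
print.signed_network <- function(x, ...) {
  tab <- table(factor(x$nodes$role, levels = ENTITY_ROLES))
  cat(
    "<signed_network> ", nrow(x$nodes), " nodes (",
    paste(names(tab), tab, sep = "=", collapse = ", "), "), ",
    nrow(x$edges), " edges\n",
    sep = ""
  )
  invisible(x)
}

node_role <- function(net, ids) {
  net$nodes$role[match(ids, net$nodes$id)]
}

#' Build a signed network from an interaction table
#'
#' Keeps exactly the records whose endpoint roles match the allowed source
#' and target role sets, e.g. `allowed_source_roles = "compound"`,
#' `allowed_target_roles = "regulator"` for the compound-regulator layer.
#' Records for the same ordered pair that conflict in sign are collapsed to
#' a single sign-0 (unknown-direction) edge with a warning; agreeing
#' duplicates collapse silently. Nodes are all table entities whose role is
#' in the union of the two allowed sets, so entities without a surviving
#' edge are kept as isolated nodes.
#'
#' @param table An [interaction_table()].
#' @param allowed_source_roles,allowed_target_roles Non-empty subsets of
#'   `c("compound", "regulator", "enzyme")`.
#' @return A [signed_network()].
#' @export
build_network <- function(table, allowed_source_roles, allowed_target_roles) {
  if (!inherits(table, "interaction_table")) {
    abort_argument("table must be an interaction_table")
  }
  if (!length(allowed_source_roles) || !length(allowed_target_roles)) {
    abort_argument("allowed role sets must be non-empty")
  }
  check_roles(allowed_source_roles)
  check_roles(allowed_target_roles)

  role_of <- stats::setNames(table$entities$role, table$entities$id)
  rec <- table$records
  keep <- role_of[rec$source_id] %in% allowed_source_roles &
    role_of[rec$target_id] %in% allowed_target_roles
  rec <- rec[keep, ]

  edges <- resolve_sign_conflicts(
    tibble::tibble(source = rec$source_id, target = rec$target_id, sign = rec$sign),
    context = "build_network"
  )
  nodes <- table$entities[
    table$entities$role %in% union(allowed_source_roles, allowed_target_roles),
  ]
  signed_network(nodes = nodes, edges = edges)
}

# Collapse duplicate ordered pairs: equal signs dedupe, conflicting signs
# become 0 (unknown) -- conservative, never majority vote -- with a warning.
resolve_sign_conflicts <- function(edges, context) {
  if (!nrow(edges)) {
    return(tibble::tibble(source = character(), target = character(), sign = integer()))
  }
  out <- dplyr::summarise(
    dplyr::group_by(edges, .data$source, .data$target),
    n_signs = length(unique(.data$sign)),
    sign = if (length(unique(.data$sign)) == 1L) .data$sign[1L] else 0L,
    .groups = "drop"
  )
  conflicted <- out$n_signs > 1L
  if (any(conflicted)) {
    rlang::warn(paste0(
      context, ": ", sum(conflicted),
      " edge(s) with conflicting signs collapsed to sign 0 (",
      paste(utils::head(paste0(out$source[conflicted], "->", out$target[conflicted]), 5L),
        collapse = ", "
      ), ")"
    ))
  }
  out$n_signs <- NULL
  out
}

#' Filtering thresholds for the discovery network
#'
#' Captures the two elimination rules applied to the compound-regulator
#' network: compounds with fewer than `min_compound_edges` distinct incident
#' edges are removed, and regulators not associated with any compound are
#' removed.
#'
#' @param min_compound_edges Minimum number of distinct incident edges
#'   (in + out, in the deduplicated network) a compound needs to survive.
#'   Default 3.
#' @param drop_orphan_regulators Drop regulators with no compound
#'   neighbour? Default `TRUE`.
#' @param iterate_to_fixpoint If `TRUE` the two passes repeat until no node
#'   is removed (removals cascade: dropping regulators lowers compound
#'   degrees). Default `FALSE`: a single compound pass followed by a single
#'   orphan pass.
#' @return An object of class `filter_config`.
#' @export
filter_config <- function(min_compound_edges = 3L,
                          drop_orphan_regulators = TRUE,
                          iterate_to_fixpoint = FALSE) {
  min_compound_edges <- as.integer(min_compound_edges)
  if (is.na(min_compound_edges) || min_compound_edges < 0L) {
    abort_argument("min_compound_edges must be a non-negative integer")
  }
  structure(
    list(
      min_compound_edges = min_compound_edges,
      drop_orphan_regulators = isTRUE(drop_orphan_regulators),
      iterate_to_fixpoint = isTRUE(iterate_to_fixpoint)
    ),
    class = "filter_config"
  )
}

#' Apply the degree and orphan elimination rules
#'
#' Pass 1 removes every compound node with fewer than
#' `cfg$min_compound_edges` distinct incident edges (in + out). Pass 2
#' removes every regulator left with no compound neighbour in either
#' direction. With `iterate_to_fixpoint = TRUE` the two passes repeat until
#' the network is stable, in which case re-applying the filter is the
#' identity. The input network is not modified. An empty result is legal.
#'
#' @param net A [signed_network()].
#' @param cfg A [filter_config()].
#' @return The filtered [signed_network()].
#' @export
filter_network <- function(net, cfg = filter_config()) {
  if (!inherits(net, "signed_network")) abort_argument("net must be a signed_network")
  if (!inherits(cfg, "filter_config")) abort_argument("cfg must be a filter_config")

  repeat {
    n_before <- nrow(net$nodes)
    net <- drop_low_degree_compounds(net, cfg$min_compound_edges)
    if (cfg$drop_orphan_regulators) net <- drop_orphan_regulators(net)
    if (!cfg$iterate_to_fixpoint || nrow(net$nodes) == n_before) break
  }
  net
}

incident_degree <- function(net, ids) {
  vapply(
    ids,
    function(id) sum(net$edges$source == id) + sum(net$edges$target == id),
    integer(1)
  )
}

drop_nodes <- function(net, drop_ids) {
  if (!length(drop_ids)) return(net)
  nodes <- net$nodes[!(net$nodes$id %in% drop_ids), ]
  edges <- net$edges[
    !(net$edges$source %in% drop_ids) & !(net$edges$target %in% drop_ids),
  ]
  signed_network(nodes, edges)
}

drop_low_degree_compounds <- function(net, min_edges) {
  compounds <- net$nodes$id[net$nodes$role == "compound"]
  deg <- incident_degree(net, compounds)
  drop_nodes(net, compounds[deg < min_edges])
}

drop_orphan_regulators <- function(net) {
  regulators <- net$nodes$id[net$nodes$role == "regulator"]
  role_src <- node_role(net, net$edges$source)
  role_tgt <- node_role(net, net$edges$target)
  has_compound <- vapply(
    regulators,
    function(r) {
      any(net$edges$target == r & role_src == "compound") ||
        any(net$edges$source == r & role_tgt == "compound")
    },
    logical(1)
  )
  drop_nodes(net, regulators[!has_compound])
}

#' Merge two signed networks
#'
#' Node and edge sets are unioned. A node id annotated with two different
#' roles is a validation error. Identical edges with equal signs dedupe;
#' edges present in both networks with conflicting signs collapse to sign 0
#' with a warning. Merging is commutative, associative and idempotent up to
#' node/edge set equality.
#'
#' @param a,b [signed_network()] objects.
#' @return The merged [signed_network()].
#' @export
merge_networks <- function(a, b) {
  if (!inherits(a, "signed_network") || !inherits(b, "signed_network")) {
    abort_argument("both arguments must be signed_network objects")
  }
  both <- intersect(a$nodes$id, b$nodes$id)
  ra <- node_role(a, both)
  rb <- node_role(b, both)
  if (any(ra != rb)) {
    abort_validation(paste0(
      "node ids annotated with conflicting roles: ",
      paste(both[ra != rb], collapse = ", ")
    ))
  }
  nodes <- dplyr::distinct(
    dplyr::bind_rows(a$nodes, b$nodes), .data$id,
    .keep_all = TRUE
  )
  edges <- resolve_sign_conflicts(
    dplyr::distinct(dplyr::bind_rows(a$edges, b$edges)),
    context = "merge_networks"
  )
  signed_network(nodes, edges)
}

#' Regulator hub clusters
#'
#' One cluster per regulator that has at least one compound in-neighbour;
#' the members are its compound in-neighbours. A compound influencing more
#' than one regulator appears in every one of those clusters. Clusters are
#' returned sorted by size descending, ties broken by hub id ascending.
#'
#' @param net A [signed_network()] containing compound-to-regulator edges.
#' @return A tibble with columns `hub_id`, `size`, `member_compound_ids`
#'   (list column of sorted character vectors).
#' @export
find_clusters <- function(net) {
  if (!inherits(net, "signed_network")) abort_argument("net must be a signed_network")
  regulators <- sort(net$nodes$id[net$nodes$role == "regulator"])
  role_src <- node_role(net, net$edges$source)
  members <- lapply(regulators, function(r) {
    sort(unique(net$edges$source[net$edges$target == r & role_src == "compound"]))
  })
  size <- lengths(members)
  keep <- size >= 1L
  out <- tibble::tibble(
    hub_id = regulators[keep],
    size = as.integer(size[keep]),
    member_compound_ids = members[keep]
  )
  out[order(-out$size, out$hub_id), ]
}

#' Trace sign-composed paths from a compound to its terminal leaves
#'
#' Enumerates every simple (no repeated node) directed path of at most
#' `max_depth` edges from `compound_id` to any terminal leaf, i.e. any node
#' with out-degree 0. Each path carries the ordered edge signs and their
#' product as `net_sign` (+1 net activation, -1 net inhibition), with 0
#' absorbing: a single unknown-direction edge makes the whole path's
#' predicted direction unknown. Paths are returned in lexicographic order
#' of their node sequences.
#'
#' @param net A [signed_network()].
#' @param compound_id Id of a compound node in `net`.
#' @param max_depth Maximum number of edges per path. The curated layered
#'   network rarely needs more than 2, but regulator-regulator edges can
#'   deepen it; default 10.
#' @return A tibble with columns `compound_id`, `terminal_id`,
#'   `node_sequence` (list), `edge_signs` (list), `net_sign`.
#' @export
trace_paths <- function(net, compound_id, max_depth = 10L) {
  if (!inherits(net, "signed_network")) abort_argument("net must be a signed_network")
  idx <- match(compound_id, net$nodes$id)
  if (is.na(idx)) {
    rlang::abort(paste0("unknown node id: ", compound_id), class = "cypnet_lookup_error")
  }
  if (net$nodes$role[idx] != "compound") {
    abort_argument(paste0(compound_id, " is not a compound node"))
  }
  max_depth <- as.integer(max_depth)
  if (is.na(max_depth) || max_depth < 1L) abort_argument("max_depth must be >= 1")

  # adjacency with lexicographically sorted targets => DFS emits paths in
  # lexicographic node-sequence order
  adj <- split(
    data.frame(target = net$edges$target, sign = net$edges$sign),
    factor(net$edges$source, levels = unique(net$edges$source))
  )
  adj <- lapply(adj, function(d) d[order(d$target), , drop = FALSE])
  out_deg <- function(id) {
    d <- adj[[id]]
    if (is.null(d)) 0L else nrow(d)
  }

  paths <- list()
  walk <- function(node_seq, sign_seq) {
    head_id <- node_seq[length(node_seq)]
    if (length(node_seq) > 1L && out_deg(head_id) == 0L) {
      paths[[length(paths) + 1L]] <<- list(nodes = node_seq, signs = sign_seq)
      return(invisible())
    }
    if (length(sign_seq) >= max_depth) return(invisible())
    nxt <- adj[[head_id]]
    if (is.null(nxt)) return(invisible())
    for (i in seq_len(nrow(nxt))) {
      tgt <- nxt$target[i]
      if (tgt %in% node_seq) next # simple paths only
      walk(c(node_seq, tgt), c(sign_seq, nxt$sign[i]))
    }
    invisible()
  }
  walk(compound_id, integer())

  tibble::tibble(
    compound_id = compound_id,
    terminal_id = vapply(paths, function(p) p$nodes[length(p$nodes)], character(1)),
    node_sequence = lapply(paths, function(p) p$nodes),
    edge_signs = lapply(paths, function(p) as.integer(p$signs)),
    net_sign = vapply(paths, function(p) as.integer(prod(p$signs)), integer(1))
  )
}

#' Predict compound-enzyme interactions by sign composition
#'
#' For every compound node, traces all simple paths to terminal leaves
#' ([trace_paths()]) and keeps those ending at an enzyme. Paths from one
#' compound to the same enzyme are aggregated: if all agree in net sign
#' that sign is reported, otherwise the aggregate sign is 0 (unknown) and
#' all paths remain listed in `paths`.
#'
#' @param net A merged [signed_network()].
#' @param max_depth Passed to [trace_paths()].
#' @return A tibble with columns `compound_id`, `enzyme_id`, `net_sign`,
#'   `n_paths`, `paths` (human-readable `a>b>c` sequences, `;`-separated).
#' @export
predict_interactions <- function(net, max_depth = 10L) {
  if (!inherits(net, "signed_network")) abort_argument("net must be a signed_network")
  compounds <- sort(net$nodes$id[net$nodes$role == "compound"])
  enzyme_ids <- net$nodes$id[net$nodes$role == "enzyme"]

  per_compound <- lapply(compounds, function(cid) {
    tr <- trace_paths(net, cid, max_depth = max_depth)
    tr <- tr[tr$terminal_id %in% enzyme_ids, ]
    if (!nrow(tr)) return(NULL)
    tr$path_str <- vapply(
      tr$node_sequence, function(s) paste(s, collapse = ">"), character(1)
    )
    dplyr::summarise(
      dplyr::group_by(tr, .data$compound_id, enzyme_id = .data$terminal_id),
      net_sign = if (length(unique(.data$net_sign)) == 1L) .data$net_sign[1L] else 0L,
      n_paths = dplyr::n(),
      paths = paste(.data$path_str, collapse = ";"),
      .groups = "drop"
    )
  })
  out <- dplyr::bind_rows(per_compound)
  if (!nrow(out)) {
    out <- tibble::tibble(
      compound_id = character(), enzyme_id = character(),
      net_sign = integer(), n_paths = integer(), paths = character()
    )
  }
  dplyr::arrange(out, .data$compound_id, .data$enzyme_id)
}

#' Summary counts for a signed network
#'
#' @param net A [signed_network()].
#' @return A one-row tibble: node counts (total and by role), edge count and
#'   number of regulator hub clusters. Role counts sum to the node count.
#' @export
network_summary <- function(net) {
  if (!inherits(net, "signed_network")) abort_argument("net must be a signed_network")
  tab <- table(factor(net$nodes$role, levels = ENTITY_ROLES))
  tibble::tibble(
    n_nodes = nrow(net$nodes),
    n_compounds = as.integer(tab[["compound"]]),
    n_regulators = as.integer(tab[["regulator"]]),
    n_enzymes = as.integer(tab[["enzyme"]]),
    n_edges = nrow(net$edges),
    n_clusters = nrow(find_clusters(net))
  )
}
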