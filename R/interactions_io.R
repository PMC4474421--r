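#' Curated signed interaction tables
#'
#' An `interaction_table` bundles a set of role-annotated entities
#' (compounds, CYP regulators, CYP enzymes) with an ordered collection of
#' curated signed interaction records. It is the validated in-memory form of
#' a curated-literature interaction export.
#'
#' @param entities A data frame with columns `id`, `name`, `role`
#'   (`role` one of `"compound"`, `"regulator"`, `"enzyme"`).
#' @param records A data frame with columns `source_id`, `target_id`, `sign`
#'   (integer in -1/0/+1) and optionally `provenance` and `multiplicity`.
#'
#' @details Exact duplicate `(source, target, sign)` rows are collapsed and
#' their count kept in `multiplicity`. Duplicates that *conflict* in sign
#' (same ordered pair, different sign) are retained as separate records;
#' their resolution (collapse to sign 0) happens at network build time.
#' Self-loops are rejected: the regulatory graph is layered and a self-edge
#' has no defined meaning in it.
#'
#' @return An object of class `interaction_table` with elements `entities`
#'   and `records` (both tibbles).
#' @export
interaction_table <- function(entities, records) {
  entities <- tibble::as_tibble(entities)
  need <- c("id", "name", "role")
  if (!all(need %in% names(entities))) {
    abort_argument("entities must have columns id, name, role")
  }
  entities$id <- as.character(entities$id)
  entities$name <- as.character(entities$name)
  if (any(!nzchar(entities$id)) || anyNA(entities$id)) {
    abort_validation("entity ids must be non-empty")
  }
  if (anyDuplicated(entities$id)) {
    abort_validation(paste0(
      "duplicate entity ids: ",
      paste(unique(entities$id[duplicated(entities$id)]), collapse = ", ")
    ))
  }
  check_roles(entities$role, entities$id)

  records <- tibble::as_tibble(records)
  if (!all(c("source_id", "target_id", "sign") %in% names(records))) {
    abort_argument("records must have columns source_id, target_id, sign")
  }
  records$source_id <- as.character(records$source_id)
  records$target_id <- as.character(records$target_id)
  records$sign <- check_sign(records$sign)
  if (!"provenance" %in% names(records)) records$provenance <- ""
  records$provenance <- as.character(records$provenance)
  if (!"multiplicity" %in% names(records)) records$multiplicity <- 1L
  records$multiplicity <- as.integer(records$multiplicity)

  if (any(records$source_id == records$target_id)) {
    bad <- unique(records$source_id[records$source_id == records$target_id])
    abort_validation(paste0("self-loops are not allowed: ", paste(bad, collapse = ", ")))
  }
  unresolved <- setdiff(c(records$source_id, records$target_id), entities$id)
  if (length(unresolved)) {
    abort_validation(paste0(
      "records reference entities without a role annotation: ",
      paste(unresolved, collapse = ", ")
    ))
  }
  key <- paste(records$source_id, records$target_id, records$sign, sep = "\r")
  if (anyDuplicated(key)) {
    abort_validation("exact duplicate (source, target, sign) records must be collapsed")
  }

  structure(
    list(
      entities = entities[, c("id", "name", "role")],
      records = records[, c("source_id", "target_id", "sign", "provenance", "multiplicity")]
    ),
    class = "interaction_table"
  )
}

#' @export
print.interaction_table <- function(x, ...) {
  cat(
    "<interaction_table> ", nrow(x$entities), " entities, ",
    nrow(x$records), " records\n",
    sep = ""
  )
  tab <- table(factor(x$entities$role, levels = ENTITY_ROLES))
  cat("  roles:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  invisible(x)
}

# Effect keyword vocabulary (case-insensitive). Unknown keywords are hard
# parse errors, never silently coerced to sign 0: silent coercion would
# corrupt sign composition downstream.
EFFECT_KEYWORDS <- c(
  activation = 1L, activates = 1L, up = 1L,
  inhibition = -1L, inhibits = -1L, down = -1L,
  unknown = 0L, unspecified = 0L
)

map_effect <- function(effect, line_no) {
  sign <- unname(EFFECT_KEYWORDS[tolower(effect)])
  bad <- is.na(sign)
  if (any(bad)) {
    i <- which(bad)[1L]
    abort_parse(paste0(
      "line ", line_no[i], ": unmappable effect keyword \"", effect[i], "\""
    ))
  }
  sign
}

sign_to_relation <- function(sign) {
  c(`-1` = "inhibits", `0` = "unknown", `1` = "activates")[as.character(sign)]
}

#' Read an entity role annotation file
#'
#' The roles file is a UTF-8 TSV with header `id`, `name`, `role`, mapping
#' every entity id that appears in an edge file to one of the three node
#' classes (`compound`, `regulator`, `enzyme`).
#'
#' @param path Path to the roles TSV.
#' @return A tibble with columns `id`, `name`, `role`.
#' @export
read_roles <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(paste0("roles file not found: ", path), class = "cypnet_io_error")
  }
  df <- utils::read.delim(path, colClasses = "character", check.names = FALSE)
  if (!all(c("id", "name", "role") %in% names(df))) {
    abort_parse(paste0("roles file must have header id<TAB>name<TAB>role: ", path))
  }
  df <- tibble::as_tibble(df)[, c("id", "name", "role")]
  if (anyDuplicated(df$id)) {
    abort_validation(paste0(
      "duplicate ids in roles file: ",
      paste(unique(df$id[duplicated(df$id)]), collapse = ", ")
    ))
  }
  check_roles(df$role, df$id)
  df
}

#' Write a role annotation file
#'
#' @param x An `interaction_table` or `signed_network`.
#' @param path Output path.
#' @export
write_roles <- function(x, path) {
  nodes <- if (inherits(x, "interaction_table")) x$entities else x$nodes
  utils::write.table(
    nodes[, c("id", "name", "role")],
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' Read a curated interaction edge file
#'
#' Reads curated signed interactions in one of two dialects and validates
#' them against a role annotation file.
#'
#' Supported dialects:
#' \describe{
#'   \item{`tsv`}{UTF-8 tab-separated with header
#'     `source<TAB>effect<TAB>target[<TAB>provenance]`.}
#'   \item{`sif`}{Cytoscape simple-interaction format: no header, each line
#'     `source<TAB>relation<TAB>target1[<TAB>target2 ...]`; a line with a
#'     single token declares an isolated node.}
#' }
#'
#' Effect keywords are mapped case-insensitively: activation/activates/up to
#' +1, inhibition/inhibits/down to -1, unknown/unspecified to 0. Any other
#' keyword is a parse error naming the offending line. Exact duplicate rows
#' are collapsed with their count kept in `multiplicity`; duplicates that
#' conflict in sign are retained as separate records.
#'
#' @param path Path to the edge file.
#' @param dialect `"tsv"` or `"sif"`.
#' @param roles_path Path to the roles TSV (see [read_roles()]); it must
#'   annotate every entity id appearing in the edge file.
#' @return An [interaction_table()]. Its entities are the ids appearing in
#'   the edge file, annotated from the roles file, in order of first
#'   appearance.
#' @export
read_interactions <- function(path, dialect = c("tsv", "sif"), roles_path) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    rlang::abort(paste0("edge file not found: ", path), class = "cypnet_io_error")
  }
  roles <- read_roles(roles_path)

  parsed <- switch(dialect,
    tsv = parse_edge_tsv(path),
    sif = parse_edge_sif(path)
  )
  edges <- parsed$edges
  seen_ids <- parsed$ids

  if (nrow(edges)) {
    self <- edges$source_id == edges$target_id
    if (any(self)) {
      abort_validation(paste0(
        "self-loop at line ", edges$line[which(self)[1L]], ": ",
        edges$source_id[which(self)[1L]]
      ))
    }
    missing_role <- setdiff(seen_ids, roles$id)
    if (length(missing_role)) {
      abort_validation(paste0(
        "entities without role annotation: ",
        paste(missing_role, collapse = ", ")
      ))
    }
    edges <- dplyr::summarise(
      dplyr::group_by(edges, .data$source_id, .data$target_id, .data$sign),
      provenance = paste(unique(.data$provenance[nzchar(.data$provenance)]), collapse = ";"),
      multiplicity = dplyr::n(),
      .first_line = min(.data$line),
      .groups = "drop"
    )
    edges <- dplyr::arrange(edges, .data$.first_line)
    edges$.first_line <- NULL
  } else {
    edges <- tibble::tibble(
      source_id = character(), target_id = character(),
      sign = integer(), provenance = character(), multiplicity = integer()
    )
    missing_role <- setdiff(seen_ids, roles$id)
    if (length(missing_role)) {
      abort_validation(paste0(
        "entities without role annotation: ",
        paste(missing_role, collapse = ", ")
      ))
    }
  }

  entities <- roles[match(seen_ids, roles$id), ]
  interaction_table(entities = entities, records = edges)
}

parse_edge_tsv <- function(path) {
  df <- utils::read.delim(path, colClasses = "character", check.names = FALSE)
  if (!all(c("source", "effect", "target") %in% names(df))) {
    abort_parse(paste0(
      "TSV edge file must have header source<TAB>effect<TAB>target[<TAB>provenance]: ",
      path
    ))
  }
  n <- nrow(df)
  line <- seq_len(n) + 1L # header is line 1
  sign <- if (n) map_effect(df$effect, line) else integer()
  prov <- if ("provenance" %in% names(df)) df$provenance else rep("", n)
  edges <- tibble::tibble(
    source_id = df$source, target_id = df$target,
    sign = sign, provenance = prov, line = line
  )
  ids <- unique(c(rbind(edges$source_id, edges$target_id)))
  list(edges = edges, ids = ids)
}

parse_edge_sif <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)))
  edges <- vector("list", length(keep))
  ids <- character()
  for (j in seq_along(keep)) {
    i <- keep[j]
    tokens <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(tokens) == 1L) {
      ids <- c(ids, tokens) # isolated node declaration
      next
    }
    if (length(tokens) == 2L) {
      abort_parse(paste0("line ", i, ": SIF line with a relation but no target"))
    }
    sign <- map_effect(tokens[2L], i)
    targets <- tokens[-(1:2)]
    edges[[j]] <- tibble::tibble(
      source_id = tokens[1L], target_id = targets,
      sign = sign, provenance = "", line = i
    )
    ids <- c(ids, as.vector(rbind(tokens[1L], targets)))
  }
  edges <- dplyr::bind_rows(edges)
  if (!nrow(edges)) {
    edges <- tibble::tibble(
      source_id = character(), target_id = character(),
      sign = integer(), provenance = character(), line = integer()
    )
  }
  list(edges = edges, ids = unique(ids))
}

#' Write a network or interaction table to an edge file
#'
#' The SIF dialect writes one line per edge as
#' `source<TAB>relation<TAB>target` with relation in
#' activates/inhibits/unknown, plus one single-token line per isolated node
#' (standard Cytoscape SIF), and no header. The TSV dialect writes the
#' `source<TAB>effect<TAB>target` header format (isolated nodes are not
#' representable in it; pair the file with [write_roles()] to keep them).
#' Reading a written file back reproduces every `(source, target, sign)`
#' triple exactly.
#'
#' @param net A `signed_network` or `interaction_table`.
#' @param path Output path.
#' @param dialect `"sif"` or `"tsv"`.
#' @export
write_network <- function(net, path, dialect = c("sif", "tsv")) {
  dialect <- match.arg(dialect)
  if (inherits(net, "interaction_table")) {
    edges <- net$records
    nodes <- net$entities
    src <- edges$source_id
    tgt <- edges$target_id
  } else if (inherits(net, "signed_network")) {
    edges <- net$edges
    nodes <- net$nodes
    src <- edges$source
    tgt <- edges$target
  } else {
    abort_argument("net must be a signed_network or interaction_table")
  }

  con <- tryCatch(file(path, "w"), error = function(e) {
    rlang::abort(paste0("cannot open path for writing: ", path),
      class = "cypnet_io_error", parent = e
    )
  })
  on.exit(close(con))

  if (dialect == "sif") {
    rel <- sign_to_relation(edges$sign)
    lines <- if (nrow(edges)) paste(src, rel, tgt, sep = "\t") else character()
    isolated <- setdiff(nodes$id, c(src, tgt))
    writeLines(c(lines, isolated), con)
  } else {
    writeLines("source\teffect\ttarget", con)
    if (nrow(edges)) {
      writeLines(paste(src, sign_to_relation(edges$sign), tgt, sep = "\t"), con)
    }
  }
  invisible(path)
}
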