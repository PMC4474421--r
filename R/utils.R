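# Internal helpers shared across modules.

# Classed conditions so callers can distinguish parse, validation and
# argument failures programmatically.
abort_parse <- function(msg, ...) {
  rlang::abort(msg, class = "cypnet_parse_error", ...)
}

abort_validation <- function(msg, ...) {
  rlang::abort(msg, class = "cypnet_validation_error", ...)
}

abort_argument <- function(msg, ...) {
  rlang::abort(msg, class = "cypnet_argument_error", ...)
}

#' @importFrom rlang %||%
NULL

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG
# stream: the global seed is saved and restored on exit.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(expr)
}

# Signs are stored as integers in {-1, 0, +1}; 0 marks an interaction whose
# direction the curated source did not state.
check_sign <- function(sign) {
  if (!all(sign %in% c(-1L, 0L, 1L))) {
    abort_validation("interaction signs must be -1, 0 or +1")
  }
  as.integer(sign)
}

ENTITY_ROLES <- c("compound", "regulator", "enzyme")

check_roles <- function(role, ids = NULL) {
  bad <- !(role %in% ENTITY_ROLES)
  if (any(bad)) {
    what <- if (is.null(ids)) unique(role[bad]) else unique(ids[bad])
    abort_validation(paste0(
      "entity role must be one of ", paste(ENTITY_ROLES, collapse = ", "),
      "; offending: ", paste(what, collapse = ", ")
    ))
  }
  role
}
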