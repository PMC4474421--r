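#' Configuration for the synthetic curated-interaction database
#'
#' Describes a two-layer signed interaction database: compounds attach to
#' regulators (optionally with hub-like skew via per-regulator attachment
#' weights) and regulators attach to enzymes. Explicit
#' compound-regulator-enzyme paths with fixed signs can be planted; the
#' generator records their expected net signs as ground truth.
#'
#' @param n_compounds,n_regulators,n_enzymes Entity counts (>= 0).
#' @param mean_compound_degree Mean number of regulator edges per compound
#'   (Poisson-distributed, truncated at `n_regulators`). Default 3.
#' @param mean_regulator_degree Mean number of enzyme edges per regulator
#'   (same scheme). Default 2.
#' @param hub_weights Optional per-regulator attachment weights (length
#'   `n_regulators`, non-negative, not all zero); heavier regulators
#'   collect more compounds, producing the skewed hub-cluster sizes seen
#'   in curated pharmacology networks. Default: uniform.
#' @param sign_probs Probabilities for sampling edge signs +1, -1, 0 (in
#'   that order); must sum to 1. Default `c(0.45, 0.45, 0.10)`.
#' @param planted_paths Optional data frame with columns `compound`,
#'   `regulator`, `enzyme` (1-based indices within the declared counts)
#'   and `sign_cr`, `sign_re` (signs of the two planted edges).
#' @param seed Integer seed; the same config and seed reproduce the
#'   database exactly.
#' @return An object of class `network_sim_config`.
#' @export
network_sim_config <- function(n_compounds,
                               n_regulators,
                               n_enzymes,
                               mean_compound_degree = 3,
                               mean_regulator_degree = 2,
                               hub_weights = NULL,
                               sign_probs = c(0.45, 0.45, 0.10),
                               planted_paths = NULL,
                               seed = 1L) {
  counts <- c(n_compounds, n_regulators, n_enzymes)
  if (any(is.na(counts)) || any(counts < 0) || any(counts != floor(counts))) {
    rlang::abort("entity counts must be non-negative integers",
      class = "cypnet_config_error"
    )
  }
  if (mean_compound_degree <= 0 || mean_regulator_degree <= 0) {
    rlang::abort("mean degrees must be positive", class = "cypnet_config_error")
  }
  if (length(sign_probs) != 3L || any(sign_probs < 0) ||
    abs(sum(sign_probs) - 1) > 1e-12) {
    rlang::abort("sign_probs must be 3 non-negative values summing to 1",
      class = "cypnet_config_error"
    )
  }
  if (is.null(hub_weights)) hub_weights <- rep(1, n_regulators)
  if (length(hub_weights) != n_regulators || any(hub_weights < 0) ||
    (n_regulators > 0 && sum(hub_weights) == 0)) {
    rlang::abort("hub_weights must be n_regulators non-negative values, not all 0",
      class = "cypnet_config_error"
    )
  }
  if (!is.null(planted_paths)) {
    planted_paths <- tibble::as_tibble(planted_paths)
    need <- c("compound", "regulator", "enzyme", "sign_cr", "sign_re")
    if (!all(need %in% names(planted_paths))) {
      rlang::abort(paste0("planted_paths needs columns ", paste(need, collapse = ", ")),
        class = "cypnet_config_error"
      )
    }
    in_range <- function(i, n) all(i >= 1 & i <= n & i == floor(i))
    if (!in_range(planted_paths$compound, n_compounds) ||
      !in_range(planted_paths$regulator, n_regulators) ||
      !in_range(planted_paths$enzyme, n_enzymes)) {
      rlang::abort("planted path references an entity outside the declared counts",
        class = "cypnet_config_error"
      )
    }
    if (!all(planted_paths$sign_cr %in% c(-1, 0, 1)) ||
      !all(planted_paths$sign_re %in% c(-1, 0, 1))) {
      rlang::abort("planted signs must be -1, 0 or +1", class = "cypnet_config_error")
    }
  }
  structure(
    list(
      n_compounds = as.integer(n_compounds),
      n_regulators = as.integer(n_regulators),
      n_enzymes = as.integer(n_enzymes),
      mean_compound_degree = mean_compound_degree,
      mean_regulator_degree = mean_regulator_degree,
      hub_weights = hub_weights,
      sign_probs = sign_probs,
      planted_paths = planted_paths,
      seed = as.integer(seed)
    ),
    class = "network_sim_config"
  )
}

sim_ids <- function(prefix, n) {
  if (n == 0L) return(character())
  sprintf("%s%03d", prefix, seq_len(n))
}

sim_names <- function(prefix, n) {
  if (n == 0L) return(character()) # paste0 would recycle 0-length to ""
  paste0(prefix, seq_len(n))
}

sample_signs <- function(n, probs) {
  sample(c(1L, -1L, 0L), n, replace = TRUE, prob = probs)
}

#' Generate a synthetic curated-interaction database
#'
#' Draws a two-layer signed edge list under a [network_sim_config()]:
#' each compound receives a Poisson(`mean_compound_degree`) number of
#' distinct regulator partners sampled with `hub_weights`, each regulator
#' a Poisson(`mean_regulator_degree`) number of distinct enzyme partners
#' sampled uniformly, and every random edge an independent sign from
#' `sign_probs`. Planted paths are embedded verbatim with their specified
#' signs.
#'
#' So that planted ground truth stays exact at the path level, random
#' edges are never drawn out of a planted compound or planted regulator:
#' a random out-edge from a planted node could open a second path to a
#' planted enzyme with a different composed sign, turning the planted
#' prediction to 0. Planted nodes may still *receive* random edges.
#' Contradictory planted edges (same ordered pair, different sign) are a
#' config error.
#'
#' @param cfg A [network_sim_config()].
#' @return A list:
#' \describe{
#'   \item{table}{An [interaction_table()] with entities `C001...`,
#'     `R001...`, `E001...`.}
#'   \item{truth}{Tibble of expected pipeline output for planted paths:
#'     `compound_id`, `enzyme_id`, `net_sign` (product of planted signs;
#'     0 if planted paths to the same enzyme disagree), `n_paths`.}
#'   \item{config}{The config used.}
#' }
#' @export
generate_interaction_db <- function(cfg) {
  if (!inherits(cfg, "network_sim_config")) {
    rlang::abort("cfg must be a network_sim_config", class = "cypnet_config_error")
  }
  compounds <- sim_ids("C", cfg$n_compounds)
  regulators <- sim_ids("R", cfg$n_regulators)
  enzymes <- sim_ids("E", cfg$n_enzymes)
  entities <- tibble::tibble(
    id = c(compounds, regulators, enzymes),
    name = c(
      sim_names("compound_", cfg$n_compounds),
      sim_names("regulator_", cfg$n_regulators),
      sim_names("enzyme_", cfg$n_enzymes)
    ),
    role = rep(
      c("compound", "regulator", "enzyme"),
      c(cfg$n_compounds, cfg$n_regulators, cfg$n_enzymes)
    )
  )

  planted <- cfg$planted_paths
  if (!is.null(planted) && nrow(planted)) {
    planted_edges <- tibble::tibble(
      source_id = c(compounds[planted$compound], regulators[planted$regulator]),
      target_id = c(regulators[planted$regulator], enzymes[planted$enzyme]),
      sign = as.integer(c(planted$sign_cr, planted$sign_re))
    )
    planted_edges <- dplyr::distinct(planted_edges)
    pair <- paste(planted_edges$source_id, planted_edges$target_id)
    if (anyDuplicated(pair)) {
      rlang::abort(paste0(
        "contradictory planted edges (same pair, different sign): ",
        paste(unique(pair[duplicated(pair)]), collapse = ", ")
      ), class = "cypnet_config_error")
    }
    planted_compounds <- compounds[unique(planted$compound)]
    planted_regulators <- regulators[unique(planted$regulator)]
  } else {
    planted_edges <- tibble::tibble(
      source_id = character(), target_id = character(), sign = integer()
    )
    planted_compounds <- character()
    planted_regulators <- character()
  }

  records <- with_seed(cfg$seed, {
    cr <- random_layer_edges(
      sources = setdiff(compounds, planted_compounds),
      targets = regulators,
      mean_degree = cfg$mean_compound_degree,
      weights = cfg$hub_weights,
      sign_probs = cfg$sign_probs
    )
    re <- random_layer_edges(
      sources = setdiff(regulators, planted_regulators),
      targets = enzymes,
      mean_degree = cfg$mean_regulator_degree,
      weights = NULL,
      sign_probs = cfg$sign_probs
    )
    dplyr::bind_rows(planted_edges, cr, re)
  })
  records$provenance <- ifelse(
    seq_len(nrow(records)) <= nrow(planted_edges), "planted", "random"
  )

  truth <- if (!is.null(planted) && nrow(planted)) {
    per_path <- tibble::tibble(
      compound_id = compounds[planted$compound],
      enzyme_id = enzymes[planted$enzyme],
      path_sign = as.integer(planted$sign_cr * planted$sign_re)
    )
    dplyr::summarise(
      dplyr::group_by(per_path, .data$compound_id, .data$enzyme_id),
      net_sign = if (length(unique(.data$path_sign)) == 1L) .data$path_sign[1L] else 0L,
      n_paths = dplyr::n(),
      .groups = "drop"
    )
  } else {
    tibble::tibble(
      compound_id = character(), enzyme_id = character(),
      net_sign = integer(), n_paths = integer()
    )
  }

  list(
    table = interaction_table(entities, records),
    truth = dplyr::arrange(truth, .data$compound_id, .data$enzyme_id),
    config = cfg
  )
}

# One layer of random edges: each source draws a truncated-Poisson number
# of distinct targets (weighted sampling without replacement).
random_layer_edges <- function(sources, targets, mean_degree, weights, sign_probs) {
  if (!length(sources) || !length(targets)) {
    return(tibble::tibble(
      source_id = character(), target_id = character(), sign = integer()
    ))
  }
  out <- lapply(sources, function(s) {
    d <- min(stats::rpois(1L, mean_degree), length(targets))
    if (d == 0L) return(NULL)
    picked <- if (is.null(weights)) {
      sample(targets, d)
    } else {
      targets[sample.int(length(targets), d, prob = weights)]
    }
    tibble::tibble(source_id = s, target_id = picked)
  })
  out <- dplyr::bind_rows(out)
  if (!nrow(out)) {
    return(tibble::tibble(
      source_id = character(), target_id = character(), sign = integer()
    ))
  }
  out$sign <- sample_signs(nrow(out), sign_probs)
  out
}

#' Configuration for the qPCR dose-response simulator
#'
#' Emulates a single-gene qPCR dose-response experiment: one vehicle group
#' (dose 0) plus treatment doses, measured as Ct cycles with Gaussian
#' noise on the Ct (log2-expression) scale — the standard qPCR error
#' model. A dose's transcriptional effect is its shift in log2 expression
#' relative to vehicle; one effect unit = one Ct cycle = a 2-fold change.
#'
#' @param doses Distinct dose levels in nM, including 0 (vehicle).
#'   Default `c(0, 0.1, 1, 10, 100, 1000)`, a vehicle plus five
#'   half-log-spaced treatment doses.
#' @param n_replicates Replicates per dose (>= 2). Default 3.
#' @param baseline_ct Mean vehicle Ct in cycles. Default 24.
#' @param log2_effects Per-dose log2 expression shift relative to vehicle,
#'   same order as `doses`; the vehicle entry must be 0. The default
#'   `c(0, 0.75, 1.5, 2.25, 2.4, 2.5)` is a saturating profile: roughly
#'   proportional increase over the low doses flattening from the
#'   mid-doses on.
#' @param noise_sd SD of the Ct noise in cycles (> 0). Default 0.25,
#'   a typical between-replicate Ct spread for a well-behaved assay.
#' @param cell_line,gene Labels for the simulated series.
#' @param seed Integer seed.
#' @return An object of class `qpcr_sim_config`.
#' @export
qpcr_sim_config <- function(doses = c(0, 0.1, 1, 10, 100, 1000),
                            n_replicates = 3L,
                            baseline_ct = 24,
                            log2_effects = c(0, 0.75, 1.5, 2.25, 2.4, 2.5),
                            noise_sd = 0.25,
                            cell_line = "HeLa",
                            gene = "CYP19A1",
                            seed = 1L) {
  if (anyDuplicated(doses)) {
    rlang::abort("doses must be distinct", class = "cypnet_config_error")
  }
  if (!any(doses == 0)) {
    rlang::abort("doses must include 0 (vehicle)", class = "cypnet_config_error")
  }
  if (length(log2_effects) != length(doses)) {
    rlang::abort("log2_effects must match doses in length", class = "cypnet_config_error")
  }
  if (log2_effects[doses == 0] != 0) {
    rlang::abort("the vehicle effect must be 0", class = "cypnet_config_error")
  }
  if (!is.numeric(noise_sd) || noise_sd <= 0) {
    rlang::abort("noise_sd must be > 0", class = "cypnet_config_error")
  }
  n_replicates <- as.integer(n_replicates)
  if (is.na(n_replicates) || n_replicates < 2L) {
    rlang::abort("n_replicates must be >= 2", class = "cypnet_config_error")
  }
  if (baseline_ct <= 0) {
    rlang::abort("baseline_ct must be positive", class = "cypnet_config_error")
  }
  structure(
    list(
      doses = as.numeric(doses), n_replicates = n_replicates,
      baseline_ct = baseline_ct, log2_effects = as.numeric(log2_effects),
      noise_sd = noise_sd, cell_line = cell_line, gene = gene,
      seed = as.integer(seed)
    ),
    class = "qpcr_sim_config"
  )
}

#' Simulate a qPCR dose-response dataset
#'
#' For dose `d`, replicate `r`:
#' `Ct = baseline_ct - log2_effects[d] + N(0, noise_sd)` — higher
#' expression means fewer amplification cycles. The same config and seed
#' reproduce the dataset exactly.
#'
#' @param cfg A [qpcr_sim_config()].
#' @return An [expression_dataset()] with `value_kind = "ct"`.
#' @export
generate_qpcr <- function(cfg) {
  if (!inherits(cfg, "qpcr_sim_config")) {
    rlang::abort("cfg must be a qpcr_sim_config", class = "cypnet_config_error")
  }
  n_dose <- length(cfg$doses)
  ct <- with_seed(cfg$seed, {
    rep(cfg$baseline_ct - cfg$log2_effects, each = cfg$n_replicates) +
      stats::rnorm(n_dose * cfg$n_replicates, 0, cfg$noise_sd)
  })
  expression_dataset(tibble::tibble(
    cell_line = cfg$cell_line,
    gene = cfg$gene,
    dose_nM = rep(cfg$doses, each = cfg$n_replicates),
    replicate = rep(seq_len(cfg$n_replicates), times = n_dose),
    value = ct,
    value_kind = "ct"
  ))
}
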