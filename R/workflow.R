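#' End-to-end compound-CYP discovery run
#'
#' Wires the pipeline stages together: read the compound-regulator and
#' regulator-enzyme edge files, build the two layer networks, apply the
#' degree/orphan filter to the compound-regulator layer, merge, rank the
#' regulator hub clusters and predict compound-enzyme interactions by
#' sign-composed path tracing. All outputs are written as TSV under
#' `out_dir` together with a JSON run manifest (config echo plus package
#' version), so identical inputs and config give identical outputs.
#'
#' @param cr_edges_path,re_edges_path Edge files for the
#'   compound-regulator and regulator-enzyme layers (see
#'   [read_interactions()]).
#' @param roles_path Role annotation TSV covering both edge files.
#' @param out_dir Output directory (created if missing).
#' @param dialect Edge file dialect, `"tsv"` or `"sif"`.
#' @param filter_cfg A [filter_config()]; default: minimum 3 compound
#'   edges, drop orphan regulators, single pass.
#' @param max_depth Path-tracing depth cap, see [trace_paths()].
#' @return Invisibly, a list with `merged` (the final network),
#'   `predictions`, `clusters`, `summary` and the output file paths.
#' @export
run_discovery <- function(cr_edges_path, re_edges_path, roles_path, out_dir,
                          dialect = c("tsv", "sif"),
                          filter_cfg = filter_config(),
                          max_depth = 10L) {
  dialect <- match.arg(dialect)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  cr_table <- read_interactions(cr_edges_path, dialect, roles_path)
  re_table <- read_interactions(re_edges_path, dialect, roles_path)

  cr_net <- build_network(cr_table, "compound", "regulator")
  cr_net <- filter_network(cr_net, filter_cfg)
  re_net <- build_network(re_table, "regulator", "enzyme")
  merged <- merge_networks(cr_net, re_net)

  clusters <- find_clusters(merged)
  predictions <- predict_interactions(merged, max_depth = max_depth)
  summary <- network_summary(merged)

  paths <- list(
    predictions = file.path(out_dir, "predictions.tsv"),
    clusters = file.path(out_dir, "clusters.tsv"),
    summary = file.path(out_dir, "summary.tsv"),
    network = file.path(out_dir, "merged_network.sif"),
    manifest = file.path(out_dir, "manifest.json")
  )
  write_tsv_plain(
    stats::setNames(
      predictions,
      c("compound", "enzyme", "net_sign", "n_paths", "paths")
    ),
    paths$predictions
  )
  cl_flat <- clusters
  cl_flat$member_compound_ids <- vapply(
    cl_flat$member_compound_ids, paste, character(1), collapse = ";"
  )
  write_tsv_plain(cl_flat, paths$clusters)
  write_tsv_plain(summary, paths$summary)
  write_network(merged, paths$network, "sif")
  write_manifest(paths$manifest, list(
    stage = "discovery",
    cr_edges = basename(cr_edges_path), re_edges = basename(re_edges_path),
    roles = basename(roles_path), dialect = dialect,
    filter = unclass(filter_cfg), max_depth = max_depth
  ))

  invisible(list(
    merged = merged, predictions = predictions, clusters = clusters,
    summary = summary, files = paths
  ))
}

#' Dose-response validation statistics run
#'
#' For every (cell line, gene) series in a long-format expression table:
#' compute the relative fold change against vehicle, a one-way
#' between-treatments ANOVA (on the per-replicate fold changes by
#' default) and all-pairs Tukey HSD comparisons. Writes a fold-change
#' TSV, an ANOVA table in the style of a per-gene/per-cell-line F-and-p
#' report (full-precision values plus 4-decimal rounded columns), a Tukey
#' pairwise TSV, and a JSON manifest.
#'
#' @param expression An [expression_dataset()] or a path to a long-format
#'   expression TSV ([read_expression()]).
#' @param out_dir Output directory (created if missing).
#' @param fc_method Fold-change method, `"ddct"` or `"ratio"`.
#' @param alpha Tukey family-wise significance level.
#' @param anova_on `"fold_change"` (default) or `"value"` (raw measured
#'   values).
#' @return Invisibly, a list with per-series results (`fold_change`,
#'   `anova`, `tukey`), the assembled `anova_table`, and output paths.
#' @export
run_validation <- function(expression, out_dir,
                           fc_method = c("ddct", "ratio"),
                           alpha = 0.05,
                           anova_on = c("fold_change", "value")) {
  fc_method <- match.arg(fc_method)
  anova_on <- match.arg(anova_on)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ds <- if (is.character(expression)) read_expression(expression) else expression
  if (!inherits(ds, "expression_dataset")) {
    abort_argument("expression must be an expression_dataset or a file path")
  }

  keys <- dplyr::distinct(
    tibble::as_tibble(ds)[, c("cell_line", "gene")]
  )
  series <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- ds[ds$cell_line == keys$cell_line[i] & ds$gene == keys$gene[i], ]
    fct <- fold_change(sub, method = fc_method)
    fit <- anova_oneway(if (anova_on == "fold_change") fct else sub)
    tk <- tukey_hsd(if (anova_on == "fold_change") fct else sub, alpha = alpha)
    list(
      cell_line = keys$cell_line[i], gene = keys$gene[i],
      fold_change = fct, anova = fit, tukey = tk
    )
  })

  anova_table <- dplyr::bind_rows(lapply(series, function(s) {
    tibble::tibble(
      cell_line = s$cell_line, gene = s$gene,
      F = s$anova$F, df_between = s$anova$df_between,
      df_within = s$anova$df_within, p = s$anova$p,
      F_4dp = round(s$anova$F, 4), p_4dp = round(s$anova$p, 4)
    )
  }))
  fc_table <- dplyr::bind_rows(lapply(series, function(s) {
    out <- s$fold_change$summary
    out$cell_line <- s$cell_line
    out$gene <- s$gene
    out[, c("cell_line", "gene", "dose_nM", "n", "mean_fc", "sd_log2")]
  }))
  tukey_table <- dplyr::bind_rows(lapply(series, function(s) {
    out <- tibble::as_tibble(s$tukey)
    out$cell_line <- s$cell_line
    out$gene <- s$gene
    out[, c(
      "cell_line", "gene", "group_a", "group_b",
      "mean_difference", "q", "p_adjusted", "significant"
    )]
  }))

  paths <- list(
    fold_change = file.path(out_dir, "fold_change.tsv"),
    anova = file.path(out_dir, "anova.tsv"),
    tukey = file.path(out_dir, "tukey.tsv"),
    manifest = file.path(out_dir, "manifest.json")
  )
  write_tsv_plain(fc_table, paths$fold_change)
  write_tsv_plain(anova_table, paths$anova)
  write_tsv_plain(tukey_table, paths$tukey)
  write_manifest(paths$manifest, list(
    stage = "validation", fc_method = fc_method, alpha = alpha,
    anova_on = anova_on
  ))

  invisible(list(
    series = series, anova_table = anova_table,
    fold_change_table = fc_table, tukey_table = tukey_table, files = paths
  ))
}

write_tsv_plain <- function(df, path) {
  df <- as.data.frame(df)
  utils::write.table(df, path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

write_manifest <- function(path, config) {
  manifest <- list(
    package = "cypnet",
    version = as.character(utils::packageVersion("cypnet")),
    config = config
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
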