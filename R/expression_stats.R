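#' Long-format dose-response expression data
#'
#' Container for qPCR-style measurements of one or more (cell line, gene)
#' series: per dose (nM; 0 = vehicle) and replicate, either a raw Ct cycle
#' value (`value_kind = "ct"`, lower Ct = more transcript) or a relative
#' expression value (`value_kind = "relative"`).
#'
#' @param data Data frame with columns `cell_line`, `gene`, `dose_nM`,
#'   `replicate`, `value`, `value_kind`.
#' @return A tibble of class `expression_dataset`.
#' @export
expression_dataset <- function(data) {
  data <- tibble::as_tibble(data)
  need <- c("cell_line", "gene", "dose_nM", "replicate", "value", "value_kind")
  if (!all(need %in% names(data))) {
    abort_argument(paste0(
      "expression data must have columns ", paste(need, collapse = ", ")
    ))
  }
  data$dose_nM <- as.numeric(data$dose_nM)
  data$value <- as.numeric(data$value)
  if (anyNA(data$dose_nM) || any(data$dose_nM < 0)) {
    abort_validation("doses must be numeric and >= 0 (0 = vehicle)")
  }
  if (anyNA(data$value)) abort_validation("expression values must be numeric")
  if (!all(data$value_kind %in% c("ct", "relative"))) {
    abort_validation('value_kind must be "ct" or "relative"')
  }
  if (any(data$value_kind == "ct" & data$value <= 0)) {
    abort_validation("Ct values must be positive")
  }
  class(data) <- c("expression_dataset", class(data))
  data
}

#' Read a long-format expression TSV
#'
#' Header: `cell_line<TAB>gene<TAB>dose_nM<TAB>replicate<TAB>value<TAB>value_kind`.
#'
#' @param path Path to the TSV file.
#' @return An [expression_dataset()].
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(paste0("expression file not found: ", path), class = "cypnet_io_error")
  }
  df <- utils::read.delim(path, check.names = FALSE)
  need <- c("cell_line", "gene", "dose_nM", "replicate", "value", "value_kind")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    abort_parse(paste0(
      "expression file header (line 1) is missing columns: ",
      paste(missing, collapse = ", ")
    ))
  }
  bad <- which(is.na(suppressWarnings(as.numeric(df$value))))
  if (length(bad)) {
    abort_parse(paste0("line ", bad[1L] + 1L, ": non-numeric expression value"))
  }
  expression_dataset(df)
}

one_series <- function(ds) {
  key <- unique(paste(ds$cell_line, ds$gene, sep = "\r"))
  if (length(key) != 1L) {
    abort_argument(
      "data contains more than one (cell_line, gene) series; split first"
    )
  }
  invisible(ds)
}

#' Relative fold change against the vehicle group
#'
#' Computes per-replicate fold changes relative to the vehicle (dose 0)
#' group for a single (cell line, gene) series.
#'
#' Methods:
#' \describe{
#'   \item{`ddct`}{For raw Ct data: per replicate
#'     \eqn{2^{-(Ct - \bar{Ct}_{vehicle})}} (no reference-gene
#'     normalisation).}
#'   \item{`ratio`}{For relative expression data: value divided by the
#'     vehicle mean.}
#' }
#'
#' The per-dose mean fold change is the geometric mean (arithmetic mean on
#' the log2 scale), so the vehicle group's mean fold change is exactly 1 by
#' construction; spread is reported as the SD of the per-replicate log2
#' fold changes.
#'
#' @param ds An [expression_dataset()] holding one (cell line, gene) series
#'   including a vehicle (dose 0) group.
#' @param method `"ddct"` (requires `value_kind == "ct"`) or `"ratio"`.
#' @return An object of class `fold_change_table`: a list with tibbles
#'   `replicates` (`dose_nM`, `replicate`, `fold_change`, `log2_fc`) and
#'   `summary` (`dose_nM`, `n`, `mean_fc`, `sd_log2`).
#' @export
fold_change <- function(ds, method = c("ddct", "ratio")) {
  method <- match.arg(method)
  if (!inherits(ds, "expression_dataset")) {
    abort_argument("ds must be an expression_dataset")
  }
  one_series(ds)
  if (!any(ds$dose_nM == 0)) {
    abort_argument("no vehicle (dose 0) group present")
  }
  kind <- unique(ds$value_kind)
  if (length(kind) != 1L) abort_validation("mixed value_kind in one series")

  if (method == "ddct") {
    if (kind != "ct") abort_argument('method "ddct" requires value_kind "ct"')
    vehicle_mean_ct <- mean(ds$value[ds$dose_nM == 0])
    log2_fc <- -(ds$value - vehicle_mean_ct)
  } else {
    if (any(ds$value <= 0)) {
      abort_validation("ratio method requires strictly positive values")
    }
    vehicle_mean <- mean(ds$value[ds$dose_nM == 0])
    log2_fc <- log2(ds$value / vehicle_mean)
  }

  replicates <- tibble::tibble(
    dose_nM = ds$dose_nM,
    replicate = ds$replicate,
    fold_change = 2^log2_fc,
    log2_fc = log2_fc
  )
  summary <- dplyr::summarise(
    dplyr::group_by(replicates, .data$dose_nM),
    n = dplyr::n(),
    mean_fc = 2^mean(.data$log2_fc),
    sd_log2 = stats::sd(.data$log2_fc),
    .groups = "drop"
  )
  structure(
    list(
      cell_line = unique(ds$cell_line), gene = unique(ds$gene),
      method = method,
      replicates = replicates,
      summary = dplyr::arrange(summary, .data$dose_nM)
    ),
    class = "fold_change_table"
  )
}

#' @export
print.fold_change_table <- function(x, ...) {
  cat(
    "<fold_change_table> ", x$cell_line, " / ", x$gene,
    " (method ", x$method, ")\n",
    sep = ""
  )
  print(x$summary)
  invisible(x)
}

# Extract (group factor, response vector) from an expression_dataset (raw
# values) or a fold_change_table (per-replicate fold changes).
anova_groups <- function(x) {
  if (inherits(x, "fold_change_table")) {
    g <- factor(x$replicates$dose_nM)
    y <- x$replicates$fold_change
  } else if (inherits(x, "expression_dataset")) {
    one_series(x)
    g <- factor(x$dose_nM)
    y <- x$value
  } else {
    abort_argument("expected an expression_dataset or fold_change_table")
  }
  list(g = g, y = y)
}

#' One-way between-treatments ANOVA
#'
#' Standard one-way fixed-effects ANOVA across dose groups: the F statistic
#' is the ratio of the between-group to the within-group mean square and
#' its p-value is the upper tail of the F distribution with (k-1, N-k)
#' degrees of freedom, computed by [f_sf()]. The decomposition itself is
#' delegated to [stats::aov()].
#'
#' @param x An [expression_dataset()] (ANOVA on raw values) or a
#'   [fold_change_table()] (ANOVA on per-replicate fold changes, the
#'   default input in the validation workflow).
#' @return An object of class `anova_result`: list with `F`, `df_between`,
#'   `df_within`, `p`, `group_means`, `ms_between`, `ms_within`.
#' @export
anova_oneway <- function(x) {
  gy <- anova_groups(x)
  g <- gy$g
  y <- gy$y
  k <- nlevels(g)
  if (k < 2L) abort_argument("ANOVA needs at least 2 groups")
  sizes <- table(g)
  if (any(sizes < 2L)) {
    abort_argument(paste0(
      "every group needs >= 2 replicates; offending group(s): ",
      paste(names(sizes)[sizes < 2L], collapse = ", ")
    ))
  }
  if (stats::sd(y) == 0) {
    rlang::abort(
      "all values identical: zero between- and within-group variance",
      class = "cypnet_degenerate_data_error"
    )
  }

  fit <- stats::aov(y ~ g)
  tab <- summary(fit)[[1L]]
  df_between <- tab$Df[1L]
  df_within <- tab$Df[2L]
  ms_between <- tab$`Mean Sq`[1L]
  ms_within <- tab$`Mean Sq`[2L]
  F_stat <- ms_between / ms_within

  structure(
    list(
      F = F_stat,
      df_between = as.integer(df_between),
      df_within = as.integer(df_within),
      p = f_sf(F_stat, df_between, df_within),
      group_means = vapply(split(y, g), mean, numeric(1)),
      ms_between = ms_between,
      ms_within = ms_within,
      n_per_group = as.integer(sizes)
    ),
    class = "anova_result"
  )
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf(
    "One-way ANOVA: F(%d/%d) = %.4f, p = %s\n",
    x$df_between, x$df_within, x$F, format(x$p, digits = 4)
  ))
  invisible(x)
}

#' Upper-tail probability of the F distribution
#'
#' Computes \eqn{P(F_{d_1,d_2} > F)} through the regularized incomplete
#' beta identity \eqn{I_x(d_2/2, d_1/2)} with
#' \eqn{x = d_2 / (d_2 + d_1 F)} (the regularized incomplete beta is
#' [stats::pbeta()]). Strictly decreasing in `F`; accurate to well below
#' 1e-10 absolutely.
#'
#' @param F F statistic, >= 0 (vectorised).
#' @param df1 Numerator (between-groups) degrees of freedom, > 0.
#' @param df2 Denominator (within-groups) degrees of freedom, > 0.
#' @return Upper-tail probability in `[0, 1]`.
#' @export
f_sf <- function(F, df1, df2) {
  if (any(is.na(F)) || any(F < 0)) abort_argument("F must be >= 0")
  if (df1 <= 0 || df2 <= 0) abort_argument("degrees of freedom must be positive")
  stats::pbeta(df2 / (df2 + df1 * F), df2 / 2, df1 / 2)
}

#' Upper-tail probability of the studentized range distribution
#'
#' \eqn{P(Q_{k,\nu} > q)} for the range of `k` iid standard-normal group
#' means divided by an independent pooled scale estimate on `df` error
#' degrees of freedom. Evaluated by Gauss-Legendre quadrature of the
#' classical double integral
#' \deqn{P(Q \le q) = \int_0^\infty f_\nu(s)\, k \int_{-\infty}^{\infty}
#'   \phi(z)\,[\Phi(z) - \Phi(z - qs)]^{k-1}\, dz\, ds,}
#' where \eqn{f_\nu} is the density of the scaled chi variate
#' \eqn{s = \hat\sigma/\sigma}. Absolute accuracy is 1e-6 or better over
#' the ranges used in Tukey testing; the function is monotone decreasing
#' in `q`.
#'
#' @param q Studentized range statistic, >= 0 (vectorised).
#' @param k Number of groups, >= 2.
#' @param df Error degrees of freedom, >= 1.
#' @return Upper-tail probability in `[0, 1]`.
#' @export
studentized_range_sf <- function(q, k, df) {
  if (any(is.na(q)) || any(q < 0)) abort_argument("q must be >= 0")
  k <- as.integer(k)
  df <- as.numeric(df)
  if (is.na(k) || k < 2L) abort_argument("k must be an integer >= 2")
  if (is.na(df) || df < 1) abort_argument("df must be >= 1")
  vapply(q, function(qi) 1 - ptukey_quad(qi, k, df), numeric(1))
}

# Gauss-Legendre nodes/weights, cached per (n, a, b).
gl_cache <- new.env(parent = emptyenv())
gl_nodes <- function(n, a, b) {
  key <- paste(n, a, b, sep = "_")
  if (is.null(gl_cache[[key]])) {
    gl_cache[[key]] <- pracma::gaussLegendre(n, a, b)
  }
  gl_cache[[key]]
}

# Inner integral: P(range of k std-normal means < w) for known sigma.
range_cdf_known_sigma <- function(w, k, z, wz) {
  if (w <= 0) return(0)
  pz <- stats::pnorm(z)
  bracket <- pz - stats::pnorm(z - w)
  sum(wz * stats::dnorm(z) * bracket^(k - 1)) * k
}

ptukey_quad <- function(q, k, df) {
  if (q <= 0) return(0)
  inner <- gl_nodes(192L, -9, 9)

  # scale-estimate density: s = sigma_hat/sigma, s^2 ~ chi^2_df / df
  half <- min(1, 14 / sqrt(2 * df))
  outer_lim <- c(max(0, 1 - half), 1 + 13 / sqrt(2 * df))
  outer <- gl_nodes(192L, outer_lim[1L], outer_lim[2L])
  log_fs <- (df / 2) * log(df) + (df - 1) * log(outer$x) -
    df * outer$x^2 / 2 - lgamma(df / 2) - (df / 2 - 1) * log(2)
  fs <- exp(log_fs)

  inner_vals <- vapply(
    outer$x,
    function(s) range_cdf_known_sigma(q * s, k, inner$x, inner$w),
    numeric(1)
  )
  min(1, sum(outer$w * fs * inner_vals))
}

#' Tukey HSD post hoc comparisons
#'
#' All-pairs honest-significant-difference test for a balanced one-way
#' layout: for each unordered pair of dose groups,
#' \eqn{q = |\bar{y}_a - \bar{y}_b| / \sqrt{MS_{within}/n}} and the
#' adjusted p-value is the studentized-range upper tail
#' [studentized_range_sf()] at (k groups, within degrees of freedom),
#' which controls the family-wise error rate. Only balanced designs are
#' accepted; unbalanced input is an error (no silent Tukey-Kramer switch).
#'
#' @param x An [expression_dataset()] or [fold_change_table()] (same input
#'   convention as [anova_oneway()]).
#' @param alpha Family-wise significance level; default 0.05.
#' @return An object of class `tukey_result`: tibble with one row per
#'   unordered pair (`group_a`, `group_b`, `mean_difference`, `q`,
#'   `p_adjusted`, `significant`), with the ANOVA context in attributes
#'   `k`, `df_within`, `ms_within`, `n_per_group`, `alpha`.
#' @export
tukey_hsd <- function(x, alpha = 0.05) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    abort_argument("alpha must be in (0, 1)")
  }
  gy <- anova_groups(x)
  sizes <- table(gy$g)
  if (length(unique(as.integer(sizes))) != 1L) {
    abort_argument(paste0(
      "Tukey HSD requires balanced groups; sizes: ",
      paste(names(sizes), as.integer(sizes), sep = "=", collapse = ", ")
    ))
  }
  fit <- anova_oneway(x)
  k <- length(fit$group_means)
  n <- unique(as.integer(sizes))
  se <- sqrt(fit$ms_within / n)
  lev <- names(fit$group_means)

  pairs <- utils::combn(seq_len(k), 2L)
  comp <- tibble::tibble(
    group_a = lev[pairs[1L, ]],
    group_b = lev[pairs[2L, ]],
    mean_difference = unname(
      fit$group_means[pairs[1L, ]] - fit$group_means[pairs[2L, ]]
    )
  )
  comp$q <- abs(comp$mean_difference) / se
  comp$p_adjusted <- studentized_range_sf(comp$q, k, fit$df_within)
  comp$significant <- comp$p_adjusted < alpha

  structure(comp,
    class = c("tukey_result", class(comp)),
    k = k, df_within = fit$df_within, ms_within = fit$ms_within,
    n_per_group = n, alpha = alpha
  )
}
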