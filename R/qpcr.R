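#' Hemolysis quality control for serum miRNA panels
#'
#' Red-blood-cell contamination of serum inflates miR-451a relative to the
#' stable miR-23a-3p, so the hemolysis indicator is `dCT = CT(miR-23a-3p) -
#' CT(miR-451a)`. Samples with `dCT` strictly greater than the threshold
#' (default 7 cycles) are excluded; a delta of exactly 7.0 passes. Technical
#' replicates are collapsed by mean CT first. Samples missing either marker
#' cannot be assessed and are flagged `passed = NA` (excluded downstream,
#' with a message).
#'
#' @param ct CT tibble (`sample_id`, `assay`, `ct`, optional `replicate`).
#' @param marker_23a,marker_451a Assay names of the two hemolysis markers.
#' @param threshold Exclusion threshold in cycles (exclusive).
#' @return Tibble `sample_id`, `ct_mir23a`, `ct_mir451a`,
#'   `delta_ct_hemolysis`, `passed`.
#' @examples
#' ct <- tibble::tibble(sample_id = "s1",
#'                      assay = c("miR-23a-3p", "miR-451a"), ct = c(25, 20))
#' hemolysis_qc(ct) # delta 5, passes
#' @export
hemolysis_qc <- function(ct, marker_23a = "miR-23a-3p", marker_451a = "miR-451a",
                         threshold = 7) {
  ct <- validate_ct_table(ct)
  collapsed <- ct |>
    filter(.data$assay %in% c(marker_23a, marker_451a)) |>
    group_by(.data$sample_id, .data$assay) |>
    summarise(ct = mean(.data$ct), .groups = "drop")
  out <- tibble(sample_id = unique(ct$sample_id)) |>
    left_join(collapsed |> filter(.data$assay == marker_23a) |>
                select("sample_id", ct_mir23a = "ct"), by = "sample_id") |>
    left_join(collapsed |> filter(.data$assay == marker_451a) |>
                select("sample_id", ct_mir451a = "ct"), by = "sample_id") |>
    mutate(
      delta_ct_hemolysis = .data$ct_mir23a - .data$ct_mir451a,
      passed = .data$delta_ct_hemolysis <= threshold
    )
  n_na <- sum(is.na(out$passed))
  if (n_na > 0) {
    inform(sprintf(
      "hemolysis_qc: %d sample(s) missing a hemolysis marker; flagged un-assessable",
      n_na))
  }
  out
}

#' Relative expression by the comparative-CT method
#'
#' For each sample, `dCT = CT(target) - mean(CT of references)` and relative
#' expression `2^(-dCT)`. Averaging reference CTs arithmetically equals
#' normalizing to the geometric mean of the references' linear-scale
#' quantities, which unifies the multi-reference serum normalization and the
#' geometric-mean normalization used for cell-culture panels. Values are
#' log-converted (default base 10; qPCR expression data approach normality
#' on the log scale) for downstream statistics.
#'
#' @param ct CT tibble (`sample_id`, `assay`, `ct`, optional `replicate`,
#'   optional `group` carried through).
#' @param target Target assay name.
#' @param references Character vector of reference assay names (>= 1).
#' @param log_base Base of the log conversion (default 10).
#' @return Tibble `sample_id` (+ `group` if present), `target`, `delta_ct`,
#'   `value` (`2^(-dCT)`), `log_value`. Samples missing the target or all
#'   references are dropped with a message.
#' @examples
#' ct <- tibble::tibble(sample_id = "s1",
#'                      assay = c("miR-21-5p", "ref1", "ref2"),
#'                      ct = c(25, 20, 22))
#' relative_expression(ct, "miR-21-5p", c("ref1", "ref2"))$value # 0.0625
#' @export
relative_expression <- function(ct, target, references, log_base = 10) {
  if (length(references) < 1) abort("at least one reference assay is required")
  ct <- validate_ct_table(ct)
  grp <- if ("group" %in% names(ct)) distinct(ct, .data$sample_id, .data$group) else NULL
  collapsed <- ct |>
    group_by(.data$sample_id, .data$assay) |>
    summarise(ct = mean(.data$ct), .groups = "drop")
  tgt <- collapsed |> filter(.data$assay == target)
  refs <- collapsed |>
    filter(.data$assay %in% references) |>
    group_by(.data$sample_id) |>
    summarise(ref_ct = mean(.data$ct), n_refs = n(), .groups = "drop")
  out <- inner_join(tgt, refs, by = "sample_id")
  dropped <- setdiff(unique(ct$sample_id), out$sample_id)
  if (length(dropped) > 0) {
    inform(sprintf(
      "relative_expression: %d sample(s) missing target or references; dropped",
      length(dropped)))
  }
  out <- out |>
    transmute(
      sample_id = .data$sample_id, target = target,
      delta_ct = .data$ct - .data$ref_ct,
      value = 2^(-.data$delta_ct),
      log_value = log(.data$value, base = log_base)
    )
  if (!is.null(grp)) out <- left_join(out, grp, by = "sample_id")
  attr(out, "log_base") <- log_base
  out
}

#' Fold change between two groups of relative-expression values
#'
#' Mean of the treated group's linear-scale values over the mean of the
#' control group's; when the values derive from comparative CT this equals
#' `2^(-ddCT)`.
#'
#' @param group_values,control_values Numeric vectors of relative-expression
#'   values (> 0), both non-empty.
#' @return A single fold change (dimensionless).
#' @examples
#' fold_change(c(2, 2), c(1, 1)) # 2
#' @export
fold_change <- function(group_values, control_values) {
  if (length(group_values) == 0 || length(control_values) == 0) {
    abort("both value vectors must be non-empty")
  }
  if (any(group_values <= 0) || any(control_values <= 0)) {
    abort("relative-expression values must be positive")
  }
  mean(group_values) / mean(control_values)
}

#' Compare expression between groups
#'
#' Two groups: unpaired two-sample t-test (Welch by default). More groups:
#' one-way ANOVA followed by all pairwise unpaired t-tests — the design used
#' for serum panels compared across patient/control strata. Values should be
#' log-converted upstream (see [relative_expression()]); group descriptives
#' (mean, SD, min, max) are emitted for boxplot-style reporting.
#'
#' @param values Data frame with the value and group columns.
#' @param value_col,group_col Column names (defaults `log_value`, `group`).
#' @param design `"auto"` picks by the number of groups; `"two_group"` /
#'   `"multi_group"` force a design.
#' @param var_equal Passed to [stats::t.test()].
#' @return An `mg_group_comparison`: list with `descriptives`, `pairwise`
#'   (tibble of t-tests), `anova` (tibble, multi-group only) and `meta`.
#'   [tidy()] returns the pairwise tests, [glance()] the headline test.
#' @export
compare_groups <- function(values, value_col = "log_value", group_col = "group",
                           design = c("auto", "two_group", "multi_group"),
                           var_equal = FALSE) {
  design <- match.arg(design)
  stopifnot(is.data.frame(values))
  if (!all(c(value_col, group_col) %in% names(values))) {
    abort(paste0("values needs columns '", value_col, "' and '", group_col, "'"))
  }
  v <- values[[value_col]]
  g <- as.character(values[[group_col]])
  keep <- !is.na(v) & !is.na(g)
  v <- v[keep]; g <- g[keep]
  groups <- sort(unique(g))
  if (length(groups) < 2) abort("need at least 2 groups")
  sizes <- table(g)
  if (any(sizes < 2)) {
    abort(paste0("need >= 2 values per group; offending group: ",
                 names(sizes)[sizes < 2][[1]]))
  }
  if (all(tapply(v, g, stats::sd) == 0)) {
    abort("degenerate input: zero variance in every group")
  }
  if (design == "auto") {
    design <- if (length(groups) == 2) "two_group" else "multi_group"
  }
  if (design == "two_group" && length(groups) != 2) {
    abort("two_group design requires exactly 2 groups")
  }

  descriptives <- tibble(group = groups) |>
    mutate(
      n = as.integer(sizes[.data$group]),
      mean = map_dbl(.data$group, ~ mean(v[g == .x])),
      sd = map_dbl(.data$group, ~ stats::sd(v[g == .x])),
      min = map_dbl(.data$group, ~ min(v[g == .x])),
      max = map_dbl(.data$group, ~ max(v[g == .x]))
    )

  pairs <- utils::combn(groups, 2, simplify = FALSE)
  pairwise <- map(pairs, function(p) {
    tt <- stats::t.test(v[g == p[[1]]], v[g == p[[2]]], var.equal = var_equal)
    tibble(group1 = p[[1]], group2 = p[[2]],
           estimate = unname(tt$estimate[1] - tt$estimate[2]),
           statistic = unname(tt$statistic), df = unname(tt$parameter),
           p.value = tt$p.value)
  }) |> list_rbind()

  anova_tbl <- NULL
  if (design == "multi_group") {
    fit <- stats::aov(v ~ factor(g))
    s <- summary(fit)[[1]]
    anova_tbl <- tibble(statistic = s[["F value"]][[1]],
                        df1 = s[["Df"]][[1]], df2 = s[["Df"]][[2]],
                        p.value = s[["Pr(>F)"]][[1]])
  }

  structure(
    list(descriptives = descriptives, pairwise = pairwise, anova = anova_tbl,
         meta = list(design = design, value_col = value_col,
                     var_equal = var_equal, n = length(v))),
    class = "mg_group_comparison"
  )
}

#' @export
print.mg_group_comparison <- function(x, ...) {
  cat(sprintf("<mg_group_comparison> %s design, n=%d\n",
              x$meta$design, x$meta$n))
  if (!is.null(x$anova)) {
    cat(sprintf("one-way ANOVA: F=%.3f, p=%.4g\n",
                x$anova$statistic, x$anova$p.value))
  }
  print(x$pairwise)
  invisible(x)
}

#' Spearman rank correlation helper
#'
#' Convenience wrapper around [stats::cor.test()] with `method =
#' "spearman"`, the non-parametric check used for covariates such as age or
#' hormone levels against miRNA expression.
#'
#' @param data A data frame.
#' @param x_col,y_col Names of the two numeric columns.
#' @return Tibble `estimate` (rho), `statistic` (S), `p.value`, `n`.
#' @export
correlate_spearman <- function(data, x_col, y_col) {
  x <- data[[x_col]]; y <- data[[y_col]]
  keep <- !is.na(x) & !is.na(y)
  ct <- suppressWarnings(stats::cor.test(x[keep], y[keep], method = "spearman"))
  tibble(estimate = unname(ct$estimate), statistic = unname(ct$statistic),
         p.value = ct$p.value, n = sum(keep))
}
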