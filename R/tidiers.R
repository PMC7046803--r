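#' Tidy an occupancy table
#'
#' @param x An `mg_occupancy` from [tabulate_occupancy()].
#' @param ... Unused.
#' @return The long entries tibble (`mir_id`, `tf`, `region_type`,
#'   `n_sites`).
#' @method tidy mg_occupancy
#' @export
tidy.mg_occupancy <- function(x, ...) x$entries

#' @rdname tidy.mg_occupancy
#' @method glance mg_occupancy
#' @export
glance.mg_occupancy <- function(x, ...) {
  tibble(
    n_mirnas = length(unique(x$entries$mir_id)),
    n_tfs = length(x$meta$tfs),
    n_regions = x$meta$n_regions,
    total_sites = sum(x$entries$n_sites),
    total_dedup_sites = sum(x$dedup_totals$n_sites),
    merge_cell_lines = x$meta$merge_cell_lines
  )
}

#' Tidy a group comparison
#'
#' @param x An `mg_group_comparison` from [compare_groups()].
#' @param ... Unused.
#' @return [tidy()]: one row per pairwise t-test. [glance()]: the headline
#'   test (ANOVA F for multi-group designs, the t-test otherwise).
#' @method tidy mg_group_comparison
#' @export
tidy.mg_group_comparison <- function(x, ...) x$pairwise

#' @rdname tidy.mg_group_comparison
#' @method glance mg_group_comparison
#' @export
glance.mg_group_comparison <- function(x, ...) {
  if (!is.null(x$anova)) {
    tibble(method = "one-way ANOVA", statistic = x$anova$statistic,
           p.value = x$anova$p.value, n = x$meta$n)
  } else {
    tibble(method = "unpaired t-test", statistic = x$pairwise$statistic[[1]],
           p.value = x$pairwise$p.value[[1]], n = x$meta$n)
  }
}

#' Tidy a summary report
#'
#' @param x An `mg_summary`.
#' @param ... Unused.
#' @return The family-by-subtype counts when present, else family totals.
#' @method tidy mg_summary
#' @export
tidy.mg_summary <- function(x, ...) {
  x$per_family_per_subtype %||% x$per_family
}
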