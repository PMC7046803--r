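#' Default TF-family and miRNA-subtype maps
#'
#' The default family map reproduces the grouping used in the source study
#' of myasthenia gravis (MG)-associated miRNAs, where the "FOXO" group in
#' fact mixes FOXA/FOXM/FOXP forkhead factors; the map is fully overridable
#' (see [read_group_config()]) and kept as-is here for fidelity to that
#' analysis rather than nomenclatural correctness. The subtype map carries
#' the circulating-miRNA signatures of the two MG serotypes: AChR+
#' (acetylcholine-receptor antibody seropositive) and MuSK+ (muscle-specific
#' kinase antibody seropositive).
#'
#' @return A named list of character vectors.
#' @export
default_family_map <- function() {
  list(
    FOXO_group = c("FoxA1", "FoxA2", "FoxM1", "FoxP2"),
    AP1 = c("FOS", "Jun", "JunB", "JunD"),
    IRF = c("IRF1", "IRF3", "IRF4"),
    STAT = c("Stat1", "Stat3", "Stat5a"),
    NFKB = "RELA",
    ESR = "ESR1",
    NFAT = "NFATC1",
    EGR = "EGR1"
  )
}

#' @rdname default_family_map
#' @export
default_subtype_map <- function() {
  list(
    `AChR+` = c("miR-150-5p", "miR-21-5p", "miR-30e-5p"),
    `MuSK+` = c("miR-151a-3p", "miR-423-5p", "let-7a-5p", "let-7f-5p")
  )
}

validate_family_map <- function(families) {
  all_tfs <- unlist(families, use.names = FALSE)
  if (anyDuplicated(all_tfs)) {
    abort(paste0("TF assigned to more than one family: ",
                 all_tfs[duplicated(all_tfs)][[1]]))
  }
  if (anyDuplicated(names(families))) abort("family names must be unique")
  invisible(families)
}

validate_subtype_map <- function(subtypes) {
  all_m <- unlist(subtypes, use.names = FALSE)
  if (anyDuplicated(all_m)) {
    abort(paste0("miRNA assigned to more than one subtype: ",
                 all_m[duplicated(all_m)][[1]]))
  }
  invisible(subtypes)
}

# per-TF totals under either counting convention
per_tf_totals <- function(occupancy,
                          count_field = c("per_region_sum", "dedup_total")) {
  count_field <- match.arg(count_field)
  src <- if (count_field == "per_region_sum") occupancy$entries else occupancy$dedup_totals
  src |>
    group_by(.data$tf) |>
    summarise(total = sum(.data$n_sites), .groups = "drop")
}

#' Aggregate occupancy counts by TF family
#'
#' Sums the chosen count field over the members of each TF family (and over
#' all miRNAs). TFs absent from the occupancy table contribute zero; TFs in
#' the table but in no family are reported under `unassigned`, so family
#' sums plus `unassigned` conserve the grand total.
#'
#' @param occupancy An `mg_occupancy` from [tabulate_occupancy()].
#' @param families Named list mapping family name to TF names; a TF may
#'   belong to at most one family.
#' @param count_field `"per_region_sum"` (sum over the region types; the
#'   headline convention) or `"dedup_total"` (distinct sites per miRNA).
#' @return An `mg_summary`: list with `per_tf_totals` and `per_family`
#'   tibbles plus `meta`.
#' @export
aggregate_by_family <- function(occupancy, families = default_family_map(),
                                count_field = c("per_region_sum", "dedup_total")) {
  stopifnot(inherits(occupancy, "mg_occupancy"))
  count_field <- match.arg(count_field)
  validate_family_map(families)
  totals <- per_tf_totals(occupancy, count_field)
  fam_tbl <- tibble(
    tf = unlist(families, use.names = FALSE),
    family = rep(names(families), lengths(families))
  )
  absent <- setdiff(fam_tbl$tf, totals$tf)
  if (length(absent) > 0) {
    inform(paste0("family members absent from occupancy table (count 0): ",
                  paste(absent, collapse = ", ")))
  }
  per_family <- totals |>
    left_join(fam_tbl, by = "tf") |>
    mutate(family = coalesce(.data$family, "unassigned")) |>
    group_by(.data$family) |>
    summarise(total = sum(.data$total), .groups = "drop") |>
    complete(family = c(names(families), "unassigned"),
             fill = list(total = 0L)) |>
    arrange(factor(.data$family, levels = c(names(families), "unassigned")))
  structure(
    list(per_tf_totals = arrange(totals, .data$tf), per_family = per_family,
         meta = list(count_field = count_field)),
    class = "mg_summary"
  )
}

#' Compare TF-family occupancy between miRNA subtypes
#'
#' Builds the family-by-subtype count matrix (e.g. AChR+ vs MuSK+ signature
#' miRNAs) plus per-subtype TF rankings. Every miRNA named in the subtype
#' map must be present in the occupancy table; subtype sets must be
#' disjoint.
#'
#' @inheritParams aggregate_by_family
#' @param subtypes Named list mapping subtype name to `mir_id`s.
#' @return An `mg_summary` with `per_family_per_subtype` and `rankings`
#'   tibbles (plus the [aggregate_by_family()] components).
#' @export
subtype_comparison <- function(occupancy, subtypes = default_subtype_map(),
                               families = default_family_map(),
                               count_field = c("per_region_sum", "dedup_total")) {
  stopifnot(inherits(occupancy, "mg_occupancy"))
  count_field <- match.arg(count_field)
  validate_subtype_map(subtypes)
  validate_family_map(families)
  present <- unique(occupancy$entries$mir_id)
  absent <- setdiff(unlist(subtypes, use.names = FALSE), present)
  if (length(absent) > 0) {
    abort(paste0("subtype miRNA(s) absent from occupancy table: ",
                 paste(absent, collapse = ", ")))
  }
  sub_tbl <- tibble(
    mir_id = unlist(subtypes, use.names = FALSE),
    subtype = rep(names(subtypes), lengths(subtypes))
  )
  fam_tbl <- tibble(
    tf = unlist(families, use.names = FALSE),
    family = rep(names(families), lengths(families))
  )
  src <- if (count_field == "per_region_sum") occupancy$entries else occupancy$dedup_totals
  per_mir_tf <- src |>
    group_by(.data$mir_id, .data$tf) |>
    summarise(n = sum(.data$n_sites), .groups = "drop")

  joined <- per_mir_tf |>
    left_join(sub_tbl, by = "mir_id") |>
    left_join(fam_tbl, by = "tf") |>
    mutate(subtype = coalesce(.data$subtype, "unassigned"),
           family = coalesce(.data$family, "unassigned"))

  per_family_per_subtype <- joined |>
    group_by(.data$family, .data$subtype) |>
    summarise(total = sum(.data$n), .groups = "drop") |>
    complete(family = c(names(families), "unassigned"),
             subtype = c(names(subtypes), "unassigned"),
             fill = list(total = 0L)) |>
    arrange(factor(.data$family, levels = c(names(families), "unassigned")),
            factor(.data$subtype, levels = c(names(subtypes), "unassigned")))

  rankings <- joined |>
    filter(.data$subtype != "unassigned") |>
    group_by(.data$subtype, .data$tf) |>
    summarise(total = sum(.data$n), .groups = "drop") |>
    arrange(.data$subtype, desc(.data$total), .data$tf) |>
    group_by(.data$subtype) |>
    mutate(rank = row_number()) |>
    ungroup()

  base <- aggregate_by_family(occupancy, families, count_field)
  structure(
    list(per_tf_totals = base$per_tf_totals, per_family = base$per_family,
         per_family_per_subtype = per_family_per_subtype, rankings = rankings,
         meta = list(count_field = count_field)),
    class = "mg_summary"
  )
}

#' @export
print.mg_summary <- function(x, ...) {
  cat(sprintf("<mg_summary> count_field=%s\n", x$meta$count_field))
  if (!is.null(x$per_family_per_subtype)) {
    print(pivot_wider(x$per_family_per_subtype, names_from = "subtype",
                      values_from = "total"))
  } else {
    print(x$per_family)
  }
  invisible(x)
}

#' Top-occupancy transcription factors
#'
#' Ranks TFs by their deduplicated binding-site totals summed over all
#' miRNAs (distinct merged sites per miRNA), the convention behind "highest
#' occupancy" statements. Ties are broken lexicographically.
#'
#' @param occupancy An `mg_occupancy`.
#' @param n Number of TFs to return (>= 1); when larger than the number of
#'   TFs present, all are returned with a message.
#' @return Tibble `tf`, `total`, ordered by decreasing total.
#' @export
top_occupancy <- function(occupancy, n = 4) {
  stopifnot(inherits(occupancy, "mg_occupancy"))
  if (n < 1) abort("n must be >= 1")
  ranked <- per_tf_totals(occupancy, "dedup_total") |>
    arrange(desc(.data$total), .data$tf)
  if (n > nrow(ranked)) {
    inform(sprintf("top_occupancy: only %d TFs available (asked for %d)",
                   nrow(ranked), n))
    n <- nrow(ranked)
  }
  ranked[seq_len(n), ]
}
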