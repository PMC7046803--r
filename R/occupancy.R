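#' Tabulate TF binding-site occupancy per regulatory region
#'
#' Counts, for every `(miRNA, TF, region type)` triple, the number of ChIP-seq
#' peaks of that TF overlapping the region by at least one base. When
#' `merge_cell_lines = TRUE` (the default), same-TF peaks are interval-merged
#' across cell lines first, so one genomic site supported in several cell
#' lines counts once — the semantics of clustered cross-cell-line evidence
#' tracks. Because a miRNA's promoter lies inside its enhancer window (and
#' host windows can overlap its own), a peak may be counted in several region
#' types; `dedup_totals` therefore also reports, per `(miRNA, TF)`, the
#' number of distinct (merged) peaks overlapping the union of that miRNA's
#' regions.
#'
#' @param regions Region tibble from [build_regions()].
#' @param peaks Peak tibble (see [read_peaks()]) with TF names in `label`.
#' @param merge_cell_lines Merge same-TF peaks before counting?
#' @return An `mg_occupancy` object: list with `entries` (tibble `mir_id`,
#'   `tf`, `region_type`, `n_sites`), `dedup_totals` (tibble `mir_id`, `tf`,
#'   `n_sites`), and `meta` (merge policy, TF labels).
#' @examples
#' regions <- tibble::tibble(mir_id = "mir-1", region_type = "mir_promoter",
#'                           source_id = "mir-1", chrom = "chr1",
#'                           start = 8000L, end = 10000L, strand = "+")
#' peaks <- tibble::tibble(chrom = "chr1", start = c(8100L, 9000L),
#'                         end = c(8200L, 9100L), strand = "*", label = "FOS")
#' tabulate_occupancy(regions, peaks)$entries
#' @export
tabulate_occupancy <- function(regions, peaks, merge_cell_lines = TRUE) {
  check_intervals(regions, "region")
  stopifnot(all(c("mir_id", "region_type") %in% names(regions)))
  if (nrow(peaks) == 0) {
    warn("tabulate_occupancy: empty peak collection; all counts are zero")
    peaks <- tibble(chrom = character(), start = integer(), end = integer(),
                    strand = character(), label = character())
  }
  check_intervals(peaks, "peak")
  if (!"label" %in% names(peaks)) abort("peaks need a 'label' column (TF name)")

  tfs <- sort(unique(peaks$label))
  by_tf <- map(tfs, function(tf) {
    p <- peaks[peaks$label == tf, c("chrom", "start", "end")]
    p$strand <- "*"
    if (merge_cell_lines) merge_intervals(p) else p
  })
  names(by_tf) <- tfs

  entries <- map(tfs, function(tf) {
    cnt <- count_overlapping(regions, by_tf[[tf]])
    tibble(mir_id = regions$mir_id, tf = tf,
           region_type = regions$region_type, n_sites = cnt)
  }) |> list_rbind()

  # per-miRNA union of regions -> distinct peaks touching any of them
  dedup <- regions |>
    group_by(.data$mir_id) |>
    group_modify(function(rr, key) {
      u <- merge_intervals(rr[, c("chrom", "start", "end")] |> mutate(strand = "*"))
      map(tfs, function(tf) {
        p <- by_tf[[tf]]
        n <- if (nrow(p) == 0 || nrow(u) == 0) 0L else {
          sum(suppressWarnings(
            GenomicRanges::countOverlaps(as_gr(p), as_gr(u))) > 0)
        }
        n <- as.integer(n)
        tibble(tf = tf, n_sites = n)
      }) |> list_rbind()
    }) |>
    ungroup()

  if (length(tfs) == 0) {
    entries <- tibble(mir_id = character(), tf = character(),
                      region_type = character(), n_sites = integer())
    dedup <- tibble(mir_id = character(), tf = character(), n_sites = integer())
  }

  entries <- arrange(entries, .data$mir_id, .data$tf,
                     factor(.data$region_type, levels = region_types()))
  dedup <- arrange(dedup, .data$mir_id, .data$tf)

  structure(
    list(
      entries = entries,
      dedup_totals = dedup,
      meta = list(merge_cell_lines = merge_cell_lines, tfs = tfs,
                  n_regions = nrow(regions))
    ),
    class = "mg_occupancy"
  )
}

#' @export
print.mg_occupancy <- function(x, ...) {
  cat(sprintf("<mg_occupancy> %d miRNA(s) x %d TF(s), %d region rows (merge_cell_lines=%s)\n",
              length(unique(x$entries$mir_id)), length(x$meta$tfs),
              x$meta$n_regions, x$meta$merge_cell_lines))
  invisible(x)
}

#' Classify regulatory regions by histone-mark chromatin state
#'
#' Overlays H3K4me3 (promoter mark), H3K4me1 (regulatory-element mark) and
#' H3K27ac (active-element mark) peaks on each region and calls a chromatin
#' state with promoter-mark precedence: any overlapping H3K4me3 peak makes
#' the region an `active_promoter`; otherwise H3K4me1 together with H3K27ac
#' makes an `active_enhancer`; H3K4me1 alone a `poised_enhancer`; no mark,
#' `unmarked`. States annotate regions — they do not filter occupancy counts
#' unless [run_occupancy_pipeline()] is asked to (`require_marked`).
#'
#' @param regions Region tibble from [build_regions()].
#' @param histone_peaks Peak tibble whose `label` column holds mark names
#'   (`H3K4me3`, `H3K4me1`, `H3K27ac`); any other label is an error.
#' @return `regions` with logical columns `has_H3K4me3`, `has_H3K4me1`,
#'   `has_H3K27ac` and a character `call` column.
#' @export
classify_regions <- function(regions, histone_peaks) {
  check_intervals(regions, "region")
  marks <- c("H3K4me3", "H3K4me1", "H3K27ac")
  if (nrow(histone_peaks) > 0) {
    check_intervals(histone_peaks, "histone peak")
    unknown <- setdiff(unique(histone_peaks$label), marks)
    if (length(unknown) > 0) {
      abort(paste0("unknown histone mark label: ", unknown[[1]]))
    }
  }
  flag <- function(mark) {
    p <- histone_peaks[histone_peaks$label == mark, , drop = FALSE]
    if (nrow(p) == 0) rep(FALSE, nrow(regions)) else count_overlapping(regions, p) > 0
  }
  out <- regions |>
    mutate(
      has_H3K4me3 = flag("H3K4me3"),
      has_H3K4me1 = flag("H3K4me1"),
      has_H3K27ac = flag("H3K27ac"),
      call = case_when(
        has_H3K4me3 ~ "active_promoter",
        has_H3K4me1 & has_H3K27ac ~ "active_enhancer",
        has_H3K4me1 ~ "poised_enhancer",
        TRUE ~ "unmarked"
      )
    )
  out
}
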