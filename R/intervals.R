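#' Genomic interval tables
#'
#' All coordinates in mirreg are 0-based half-open (BED-native): an interval
#' covers bases `start, start+1, ..., end-1` and has length `end - start`.
#' GFF3 input (1-based closed) is converted once, at read time. An interval
#' table is any data frame with columns `chrom` (character), `start`, `end`
#' (integers) and optionally `strand` (`"+"`, `"-"`, or `"*"` for unstranded).
#'
#' @param chrom,start,end,strand Vectors of equal length (recycled).
#' @return A tibble with columns `chrom`, `start`, `end`, `strand`.
#' @examples
#' genomic_intervals("chr1", 100, 200)
#' @export
genomic_intervals <- function(chrom, start, end, strand = "*") {
  x <- tibble(
    chrom = as.character(chrom),
    start = as.integer(start),
    end = as.integer(end),
    strand = as.character(strand)
  )
  check_intervals(x)
  x
}

#' Validate an interval table
#'
#' Errors (naming the offending row) unless every record satisfies
#' `0 <= start < end` with a non-empty chromosome name and, when a `strand`
#' column is present, a strand in `+`, `-`, `*`.
#'
#' @param x A data frame with `chrom`, `start`, `end` (and optionally
#'   `strand`) columns.
#' @param what Label used in error messages.
#' @return `x`, invisibly.
#' @export
check_intervals <- function(x, what = "interval") {
  stopifnot(is.data.frame(x))
  missing <- setdiff(c("chrom", "start", "end"), names(x))
  if (length(missing) > 0) {
    abort(paste0(what, " table lacks column(s): ", paste(missing, collapse = ", ")))
  }
  if (nrow(x) == 0) return(invisible(x))
  bad <- which(is.na(x$chrom) | x$chrom == "" |
                 is.na(x$start) | is.na(x$end) |
                 x$start < 0 | x$start >= x$end)
  if (length(bad) > 0) {
    i <- bad[[1]]
    abort(sprintf(
      "invalid %s at row %d: %s:[%s,%s) (need non-empty chrom and 0 <= start < end)",
      what, i, x$chrom[[i]], format(x$start[[i]]), format(x$end[[i]])
    ))
  }
  if ("strand" %in% names(x)) {
    bad <- which(!x$strand %in% .strands)
    if (length(bad) > 0) {
      abort(sprintf("invalid strand %s at row %d of %s table",
                    deparse(x$strand[[bad[[1]]]]), bad[[1]], what))
    }
  }
  invisible(x)
}

# interval table -> unstranded GRanges (1-based closed internally)
as_gr <- function(x) {
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end)
  )
}

gr_to_tbl <- function(gr) {
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = "*"
  )
}

#' Pairwise interval overlap test
#'
#' Two intervals overlap iff they are on the same chromosome and share at
#' least one base under half-open semantics (`a.start < b.end` and
#' `b.start < a.end`). Strand is ignored: ChIP-seq peaks are unstranded.
#' Rows of `x` and `y` are compared pairwise with recycling of single rows.
#'
#' @param x,y Interval tables (see [genomic_intervals()]).
#' @return Logical vector.
#' @examples
#' a <- genomic_intervals("chr1", 100, 200)
#' interval_overlaps(a, genomic_intervals("chr1", 199, 300)) # TRUE
#' interval_overlaps(a, genomic_intervals("chr1", 200, 300)) # FALSE (abutting)
#' @export
interval_overlaps <- function(x, y) {
  check_intervals(x, "x")
  check_intervals(y, "y")
  if (nrow(x) == 1 && nrow(y) > 1) x <- x[rep(1L, nrow(y)), ]
  if (nrow(y) == 1 && nrow(x) > 1) y <- y[rep(1L, nrow(x)), ]
  stopifnot(nrow(x) == nrow(y))
  x$chrom == y$chrom & x$start < y$end & y$start < x$end
}

#' Merge an interval table
#'
#' Coalesces overlapping *and abutting* intervals on the same chromosome into
#' maximal runs, i.e. returns the union of covered bases (the semantics of
#' clustered ChIP-seq evidence tracks, where contiguous evidence is one
#' site). The result is sorted by `(chrom, start)`, carries `strand = "*"`,
#' and is marked with `attr(, "merged") = TRUE`. An empty input merges to an
#' empty table.
#'
#' @param x An interval table.
#' @return A tibble of disjoint, sorted intervals.
#' @examples
#' merge_intervals(genomic_intervals("chr1", c(100, 150), c(200, 250)))
#' @export
merge_intervals <- function(x) {
  check_intervals(x, "interval")
  if (nrow(x) == 0) {
    out <- tibble(chrom = character(), start = integer(), end = integer(),
                  strand = character())
    attr(out, "merged") <- TRUE
    return(out)
  }
  out <- gr_to_tbl(GenomicRanges::reduce(as_gr(x)))
  out <- arrange(out, .data$chrom, .data$start)
  attr(out, "merged") <- TRUE
  out
}

#' Count peaks overlapping each region
#'
#' For each row of `regions`, the number of rows of `peaks` overlapping it by
#' at least one base (half-open semantics, strand ignored). Whether `peaks`
#' has been merged first is the caller's policy; see [tabulate_occupancy()].
#'
#' @param regions,peaks Interval tables.
#' @return Integer vector, one count per region row.
#' @examples
#' region <- genomic_intervals("chr1", 0, 1000)
#' peaks <- genomic_intervals("chr1", c(10, 990, 1000), c(20, 1005, 1100))
#' count_overlapping(region, peaks) # 2: the abutting third peak is excluded
#' @export
count_overlapping <- function(regions, peaks) {
  check_intervals(regions, "region")
  check_intervals(peaks, "peak")
  if (nrow(regions) == 0) return(integer())
  if (nrow(peaks) == 0) return(rep(0L, nrow(regions)))
  # suppressed: GenomicRanges warns when the two sides share no seqlevels,
  # which here just means a count of zero
  suppressWarnings(GenomicRanges::countOverlaps(as_gr(regions), as_gr(peaks)))
}
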