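#' Proximal promoter windows
#'
#' The proximal promoter of a locus is the region directly upstream of it,
#' `size_bp` wide (default 2 kb): `[start - size_bp, start)` on the `+`
#' strand, `[end, end + size_bp)` on the `-` strand, clipped at the
#' chromosome origin and, when `chrom_sizes` is supplied, at the chromosome
#' end. The window abuts but never overlaps the locus body. Unstranded loci
#' are rejected: promoter placement is meaningless without a strand.
#'
#' @param loci Interval table with a `strand` column (`+` or `-`).
#' @param size_bp Window size in base pairs (> 0).
#' @param chrom_sizes Optional named integer vector of chromosome lengths.
#' @return A tibble like `loci` with `start`/`end` replaced by the window.
#' @examples
#' promoter_window(genomic_intervals("chr1", 10000, 10090, "+"))
#' @export
promoter_window <- function(loci, size_bp = 2000, chrom_sizes = NULL) {
  check_intervals(loci, "locus")
  if (size_bp <= 0) abort("size_bp must be > 0")
  if (!"strand" %in% names(loci) || any(loci$strand == "*")) {
    abort(paste0("promoter_window needs stranded loci; set a strand ",
                 "convention for unstranded records before calling"))
  }
  out <- loci |>
    mutate(
      .wstart = ifelse(.data$strand == "+", .data$start - size_bp, .data$end),
      .wend = ifelse(.data$strand == "+", .data$start, .data$end + size_bp)
    )
  clip_windows(out, chrom_sizes)
}

#' Enhancer neighborhood windows
#'
#' The enhancer neighborhood is the region within `size_bp` (default 10 kb)
#' of the locus on either side, *including* the locus body:
#' `[start - size_bp, end + size_bp)`, clipped at chromosome bounds. The
#' window is strand-symmetric, so unstranded loci are accepted. It is not
#' promoter-subtracted: a peak in the 2 kb upstream window lies in both the
#' promoter and the enhancer window (deduplicated per-miRNA totals are
#' reported separately by [tabulate_occupancy()]).
#'
#' @inheritParams promoter_window
#' @return A tibble like `loci` with `start`/`end` replaced by the window.
#' @examples
#' enhancer_window(genomic_intervals("chr1", 10000, 10090, "+"))
#' @export
enhancer_window <- function(loci, size_bp = 10000, chrom_sizes = NULL) {
  check_intervals(loci, "locus")
  if (size_bp < 0) abort("size_bp must be >= 0")
  out <- loci |>
    mutate(.wstart = .data$start - size_bp, .wend = .data$end + size_bp)
  clip_windows(out, chrom_sizes)
}

clip_windows <- function(x, chrom_sizes) {
  x <- mutate(x, .wstart = pmax(.data$.wstart, 0L))
  if (!is.null(chrom_sizes)) {
    lim <- unname(chrom_sizes[x$chrom])
    if (anyNA(lim)) {
      abort(paste0("chrom_sizes lacks chromosome ",
                   x$chrom[is.na(lim)][[1]]))
    }
    x <- mutate(x, .wend = pmin(.data$.wend, lim))
  }
  x |>
    mutate(start = as.integer(.data$.wstart), end = as.integer(.data$.wend)) |>
    select(-".wstart", -".wend")
}

#' Assign intronic miRNAs to host genes
#'
#' A gene hosts a miRNA iff the miRNA interval is fully contained in the
#' gene interval and does not overlap any exon of that gene, i.e. it lies
#' entirely within an intron. Genes without annotated exons are treated as
#' single-exon and therefore intron-free. When several genes qualify, the
#' shortest one wins (the most specific host), with ties broken by
#' lexicographic `gene_id`. Intergenic and exonic miRNAs get `NA`.
#'
#' @param mirnas miRNA locus tibble (`mir_id`, `chrom`, `start`, `end`, ...).
#' @param genes Gene tibble (`gene_id`, `chrom`, `start`, `end`, `strand`).
#' @param exons Exon tibble (`gene_id`, `chrom`, `start`, `end`).
#' @return A tibble `mir_id`, `host_gene_id` (`NA` when no host).
#' @export
find_host_gene <- function(mirnas, genes, exons) {
  check_intervals(mirnas, "miRNA")
  check_intervals(genes, "gene")
  check_intervals(exons, "exon")
  if (nrow(mirnas) == 0) {
    return(tibble(mir_id = character(), host_gene_id = character()))
  }
  host <- rep(NA_character_, nrow(mirnas))
  if (nrow(genes) > 0) {
    ov <- GenomicRanges::findOverlaps(as_gr(mirnas), as_gr(genes), type = "within")
    cand <- tibble(
      mi = S4Vectors_from(ov, "query"),
      gi = S4Vectors_from(ov, "subject")
    )
    if (nrow(cand) > 0) {
      cand <- cand |>
        mutate(
          gene_id = genes$gene_id[.data$gi],
          gene_len = genes$end[.data$gi] - genes$start[.data$gi]
        ) |>
        filter(map_lgl(seq_len(n()), function(k) {
          ex <- exons[exons$gene_id == genes$gene_id[[cand$gi[[k]]]], ]
          if (nrow(ex) == 0) return(FALSE)  # no exons -> intron-free
          m <- mirnas[cand$mi[[k]], ]
          !any(ex$chrom == m$chrom & ex$start < m$end & m$start < ex$end)
        })) |>
        arrange(.data$mi, .data$gene_len, .data$gene_id) |>
        distinct(.data$mi, .keep_all = TRUE)
      host[cand$mi] <- cand$gene_id
    }
  }
  tibble(mir_id = mirnas$mir_id, host_gene_id = host)
}

# queryHits/subjectHits without importing S4Vectors wholesale
S4Vectors_from <- function(hits, side) {
  if (side == "query") S4Vectors::queryHits(hits) else S4Vectors::subjectHits(hits)
}

#' Build the regulatory region set for each miRNA
#'
#' For every miRNA locus: its own proximal promoter (`mir_promoter`) and
#' enhancer neighborhood (`mir_enhancer`), plus — when the miRNA is intronic
#' — the host gene's promoter (`host_promoter`) and enhancer
#' (`host_enhancer`) built from the host gene's interval and strand.
#' Intergenic miRNAs therefore contribute two regions, intronic miRNAs four.
#'
#' @param annotation An [mg_annotation] bundle.
#' @param promoter_bp,enhancer_bp Window sizes in bp (defaults 2 kb, 10 kb).
#' @param chrom_sizes Optional named chromosome lengths for clipping.
#' @param mir_ids Optional subset of miRNAs to build regions for.
#' @return A tibble with columns `mir_id`, `region_type`, `source_id`,
#'   `chrom`, `start`, `end`, `strand`.
#' @export
build_regions <- function(annotation, promoter_bp = 2000, enhancer_bp = 10000,
                          chrom_sizes = NULL, mir_ids = NULL) {
  stopifnot(inherits(annotation, "mg_annotation"))
  mirnas <- annotation$mirnas
  if (!is.null(mir_ids)) {
    missing <- setdiff(mir_ids, mirnas$mir_id)
    if (length(missing) > 0) {
      abort(paste0("miRNA(s) not in annotation: ", paste(missing, collapse = ", ")))
    }
    mirnas <- filter(mirnas, .data$mir_id %in% mir_ids)
  }
  if (nrow(mirnas) == 0) {
    return(tibble(mir_id = character(), region_type = character(),
                  source_id = character(), chrom = character(),
                  start = integer(), end = integer(), strand = character()))
  }
  hosts <- find_host_gene(mirnas, annotation$genes, annotation$exons)

  own_prom <- promoter_window(mirnas, promoter_bp, chrom_sizes) |>
    transmute(mir_id = .data$mir_id, region_type = "mir_promoter",
              source_id = .data$mir_id, chrom = .data$chrom,
              start = .data$start, end = .data$end, strand = .data$strand)
  own_enh <- enhancer_window(mirnas, enhancer_bp, chrom_sizes) |>
    transmute(mir_id = .data$mir_id, region_type = "mir_enhancer",
              source_id = .data$mir_id, chrom = .data$chrom,
              start = .data$start, end = .data$end, strand = .data$strand)

  hosted <- hosts |>
    filter(!is.na(.data$host_gene_id)) |>
    left_join(annotation$genes, by = c(host_gene_id = "gene_id"))
  host_regions <- if (nrow(hosted) > 0) {
    hp <- promoter_window(hosted, promoter_bp, chrom_sizes)
    he <- enhancer_window(hosted, enhancer_bp, chrom_sizes)
    bind_rows(
      transmute(hp, mir_id = .data$mir_id, region_type = "host_promoter",
                source_id = .data$host_gene_id, chrom = .data$chrom,
                start = .data$start, end = .data$end, strand = .data$strand),
      transmute(he, mir_id = .data$mir_id, region_type = "host_enhancer",
                source_id = .data$host_gene_id, chrom = .data$chrom,
                start = .data$start, end = .data$end, strand = .data$strand)
    )
  } else NULL

  out <- bind_rows(own_prom, own_enh, host_regions) |>
    arrange(.data$mir_id,
            factor(.data$region_type, levels = region_types()))
  check_intervals(out, "regulatory region")
  out
}

#' @rdname build_regions
#' @export
region_types <- function() {
  c("mir_promoter", "mir_enhancer", "host_promoter", "host_enhancer")
}
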