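#' Annotation bundles
#'
#' An annotation bundle holds the gene models and miRNA loci of one genome
#' assembly as three tibbles:
#'
#' * `genes`: `gene_id`, `chrom`, `start`, `end`, `strand`, `biotype`
#' * `exons`: `gene_id`, `chrom`, `start`, `end`
#' * `mirnas`: `mir_id`, `chrom`, `start`, `end`, `strand`, `mature_names`
#'   (comma-separated when a precursor yields several mature miRNAs)
#'
#' All coordinates 0-based half-open. Identifiers must be unique within
#' their table; exons must lie inside their gene.
#'
#' @param genes,exons,mirnas Tibbles as described above.
#' @param genome_build Free-text assembly label (e.g. `"hg19"`), or `NA`.
#' @return An object of class `mg_annotation`.
#' @export
mg_annotation <- function(genes, exons, mirnas, genome_build = NA_character_) {
  genes <- as_tibble(genes)
  exons <- as_tibble(exons)
  mirnas <- as_tibble(mirnas)
  check_intervals(genes, "gene")
  check_intervals(exons, "exon")
  check_intervals(mirnas, "miRNA")
  if (anyDuplicated(genes$gene_id)) {
    abort(paste0("duplicated gene_id: ",
                 genes$gene_id[duplicated(genes$gene_id)][[1]]))
  }
  if (anyDuplicated(mirnas$mir_id)) {
    abort(paste0("duplicated mir_id: ",
                 mirnas$mir_id[duplicated(mirnas$mir_id)][[1]]))
  }
  if (nrow(exons) > 0) {
    chk <- left_join(exons, genes, by = "gene_id", suffix = c("", ".g"))
    bad <- which(is.na(chk$start.g) | chk$chrom != chk$chrom.g |
                   chk$start < chk$start.g | chk$end > chk$end.g)
    if (length(bad) > 0) {
      abort(sprintf("exon %d of gene %s not contained in its gene interval",
                    bad[[1]], exons$gene_id[[bad[[1]]]]))
    }
  }
  structure(
    list(genes = genes, exons = exons, mirnas = mirnas,
         genome_build = genome_build),
    class = "mg_annotation"
  )
}

#' @export
print.mg_annotation <- function(x, ...) {
  cat(sprintf("<mg_annotation> %d genes (%d exons), %d miRNA loci, build: %s\n",
              nrow(x$genes), nrow(x$exons), nrow(x$mirnas),
              ifelse(is.na(x$genome_build), "<unknown>", x$genome_build)))
  invisible(x)
}

#' Read a GFF3 annotation
#'
#' Parses a GFF3 file into an annotation bundle. GFF3's 1-based closed
#' coordinates are converted to the package's 0-based half-open convention at
#' this single point. Feature typing is configurable via Sequence Ontology
#' terms; exons are attached to their parent gene through the `Parent`
#' attribute (exons with an unknown parent are dropped with a warning).
#'
#' @param path Path to a GFF3 file.
#' @param mirna_feature_types,gene_feature_types SO feature types selecting
#'   miRNA loci and genes.
#' @return An [mg_annotation] bundle. The `genome_build` field is taken from
#'   a `#!genome-build` directive when present.
#' @export
read_gff3 <- function(path,
                      mirna_feature_types = c("miRNA", "miRNA_primary_transcript"),
                      gene_feature_types = c("gene", "protein_coding_gene")) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  lines <- readr::read_lines(path)
  body <- !startsWith(lines, "#") & nzchar(str_trim(lines))
  for (i in which(body)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) != 9) {
      abort(sprintf("malformed GFF3 line %d: expected 9 tab-separated fields, got %d",
                    i, length(f)))
    }
    s <- suppressWarnings(as.numeric(f[[4]])); e <- suppressWarnings(as.numeric(f[[5]]))
    if (is.na(s) || is.na(e)) {
      abort(sprintf("malformed GFF3 line %d: non-numeric coordinates", i))
    }
    if (e < s) abort(sprintf("GFF3 line %d: end (%s) < start (%s)", i, f[[5]], f[[4]]))
  }
  build <- NA_character_
  gb <- grep("^#!genome-build", lines, value = TRUE)
  if (length(gb) > 0) build <- str_trim(sub("^#!genome-build\\s*", "", gb[[1]]))

  gr <- rtracklayer::import(path, format = "gff3")
  feat <- tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,   # to 0-based half-open
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(gr$type),
    id = if (!is.null(gr$ID)) as.character(gr$ID) else NA_character_,
    name = if (!is.null(gr$Name)) as.character(gr$Name) else NA_character_,
    biotype = if (!is.null(gr$biotype)) as.character(gr$biotype) else NA_character_,
    mature = if (!is.null(gr$mature_names)) as.character(gr$mature_names) else NA_character_,
    parent = map_chr(as.list(gr$Parent %||% vector("list", length(gr))),
                     ~ if (length(.x) == 0) NA_character_ else .x[[1]])
  )

  genes <- feat |>
    filter(.data$type %in% gene_feature_types) |>
    transmute(
      gene_id = coalesce(.data$id, .data$name),
      chrom = .data$chrom, start = .data$start, end = .data$end,
      strand = .data$strand,
      biotype = coalesce(.data$biotype, "protein_coding")
    )
  if (any(is.na(genes$gene_id))) abort("gene feature without ID or Name attribute")

  mirnas <- feat |>
    filter(.data$type %in% mirna_feature_types) |>
    transmute(
      mir_id = coalesce(.data$name, .data$id),
      chrom = .data$chrom, start = .data$start, end = .data$end,
      strand = .data$strand,
      mature_names = coalesce(.data$mature, "")
    )
  if (any(is.na(mirnas$mir_id))) abort("miRNA feature without ID or Name attribute")

  exons <- feat |> filter(.data$type == "exon")
  orphan <- !exons$parent %in% genes$gene_id
  if (any(orphan)) {
    warn(sprintf("dropping %d exon(s) with unknown Parent (first: %s)",
                 sum(orphan), exons$parent[orphan][[1]] %||% "<none>"))
    exons <- exons[!orphan, ]
  }
  exons <- transmute(exons, gene_id = .data$parent, chrom = .data$chrom,
                     start = .data$start, end = .data$end)

  mg_annotation(genes, exons, mirnas, genome_build = build)
}

#' Write an annotation bundle as GFF3
#'
#' Inverse of [read_gff3()] on the feature types this package uses (genes
#' with exon children, miRNA primary transcripts). Coordinates are converted
#' back to GFF3's 1-based closed convention.
#'
#' @param annotation An [mg_annotation] bundle.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(annotation, path) {
  stopifnot(inherits(annotation, "mg_annotation"))
  esc <- function(x) gsub("[;=\t]", "_", x)
  hdr <- "##gff-version 3"
  if (!is.na(annotation$genome_build)) {
    hdr <- c(hdr, paste0("#!genome-build ", annotation$genome_build))
  }
  g <- annotation$genes
  gene_lines <- sprintf("%s\tmirreg\tgene\t%d\t%d\t.\t%s\t.\tID=%s;biotype=%s",
                        g$chrom, g$start + 1L, g$end, g$strand,
                        esc(g$gene_id), esc(g$biotype))
  e <- annotation$exons
  exon_lines <- if (nrow(e) > 0) {
    sprintf("%s\tmirreg\texon\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
            e$chrom, e$start + 1L, e$end,
            g$strand[match(e$gene_id, g$gene_id)],
            paste0(esc(e$gene_id), ":exon", seq_len(nrow(e))), esc(e$gene_id))
  } else character()
  m <- annotation$mirnas
  mir_lines <- sprintf(
    "%s\tmirreg\tmiRNA_primary_transcript\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s;mature_names=%s",
    m$chrom, m$start + 1L, m$end, m$strand,
    esc(m$mir_id), esc(m$mir_id), esc(m$mature_names))
  readr::write_lines(c(hdr, gene_lines, exon_lines, mir_lines), path)
  invisible(path)
}
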