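#' Read ChIP-seq peaks (BED6 / narrowPeak / broadPeak / clustered)
#'
#' Returns one row per peak with columns `chrom`, `start`, `end`, `strand`
#' (always `"*"`; peaks are unstranded), `label` (TF or histone-mark name,
#' taken from the BED name column unless overridden), `score`, `cell_lines`
#' (comma-separated; empty unless the `clustered` dialect supplies one) and
#' `summit_offset` (narrowPeak column 10; `NA` when absent or `-1`).
#'
#' Dialects: `bed6` (6 columns), `narrowPeak` (ENCODE 10-column),
#' `broadPeak` (ENCODE 9-column), `clustered` (BED5 plus a comma-separated
#' cell-line list in column 6, the shape of cross-cell-line clustered TFBS
#' exports). Peaks duplicated on `(chrom, start, end, label)` are dropped
#' with a message, since browser exports can repeat records.
#'
#' @param path Path to a peak file (plain text, tab-separated, no header).
#' @param dialect One of `"bed6"`, `"narrowPeak"`, `"broadPeak"`,
#'   `"clustered"`.
#' @param label Optional label overriding the name column (e.g. when the
#'   file is one TF's track and its name column holds peak ids).
#' @return A tibble of peaks.
#' @export
read_peaks <- function(path, dialect = c("bed6", "narrowPeak", "broadPeak", "clustered"),
                       label = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  ncols <- c(bed6 = 6L, narrowPeak = 10L, broadPeak = 9L, clustered = 6L)[[dialect]]
  lines <- readr::read_lines(path)
  keep <- nzchar(str_trim(lines)) & !startsWith(lines, "#") & !startsWith(lines, "track")
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  lineno <- which(keep)
  nf <- lengths(fields)
  if (any(nf != ncols)) {
    i <- which(nf != ncols)[[1]]
    abort(sprintf("line %d: %s dialect needs %d columns, found %d",
                  lineno[[i]], dialect, ncols, nf[[i]]))
  }
  if (length(fields) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  strand = character(), label = character(), score = numeric(),
                  cell_lines = character(), summit_offset = integer()))
  }
  col <- function(j) map_chr(fields, j)
  num <- function(j, what) {
    v <- suppressWarnings(as.numeric(col(j)))
    if (anyNA(v)) {
      i <- which(is.na(v))[[1]]
      abort(sprintf("line %d: non-numeric %s '%s'", lineno[[i]], what, col(j)[[i]]))
    }
    v
  }
  out <- tibble(
    chrom = col(1),
    start = as.integer(num(2, "start")),
    end = as.integer(num(3, "end")),
    strand = "*",
    label = if (is.null(label)) col(4) else label,
    score = num(5, "score"),
    cell_lines = if (dialect == "clustered") col(6) else "",
    summit_offset = if (dialect == "narrowPeak") {
      s <- as.integer(num(10, "summit offset"))
      ifelse(s < 0, NA_integer_, s)
    } else NA_integer_
  )
  check_intervals(out, "peak")
  bad <- which(!is.na(out$summit_offset) &
                 out$summit_offset >= (out$end - out$start))
  if (length(bad) > 0) {
    abort(sprintf("line %d: summit offset %d outside peak of length %d",
                  lineno[[bad[[1]]]], out$summit_offset[[bad[[1]]]],
                  out$end[[bad[[1]]]] - out$start[[bad[[1]]]]))
  }
  dup <- duplicated(out[, c("chrom", "start", "end", "label")])
  if (any(dup)) {
    inform(sprintf("read_peaks: dropped %d duplicated record(s) in %s",
                   sum(dup), basename(path)))
    out <- out[!dup, ]
  }
  out
}

#' Write peaks as BED6
#'
#' @param peaks A peak tibble (see [read_peaks()]).
#' @param path Output path.
#' @param score_col Column written to the BED score field.
#' @return `path`, invisibly.
#' @export
write_peaks_bed <- function(peaks, path, score_col = "score") {
  check_intervals(peaks, "peak")
  score <- if (score_col %in% names(peaks)) peaks[[score_col]] else 0
  readr::write_lines(sprintf("%s\t%d\t%d\t%s\t%s\t.",
                             peaks$chrom, peaks$start, peaks$end, peaks$label,
                             format(score, trim = TRUE, scientific = FALSE)),
                     path)
  invisible(path)
}

#' Read a FASTA file into a named character vector
#'
#' Sequence names are taken up to the first whitespace; sequences are
#' uppercased. Characters outside the IUPAC nucleotide alphabet are replaced
#' by `N` with a warning. Duplicate names are an error.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector, one element per record.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  ss <- Biostrings::readBStringSet(path)
  nm <- map_chr(str_split(names(ss), "\\s+"), 1)
  if (anyDuplicated(nm)) {
    abort(paste0("duplicate sequence name in FASTA: ", nm[duplicated(nm)][[1]]))
  }
  seqs <- toupper(as.character(ss))
  non_iupac <- "[^ACGTRYSWKMBDHVN]"
  if (any(grepl(non_iupac, seqs))) {
    warn("read_fasta: non-IUPAC characters replaced by N")
    seqs <- gsub(non_iupac, "N", seqs)
  }
  stats::setNames(seqs, nm)
}

#' Write sequences as FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  ss <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Read a CT-value table
#'
#' Expects a tab-separated file with header columns `sample_id`, `assay`,
#' `ct`, and optionally `replicate` and `group`. The `(sample_id, assay,
#' replicate)` triple must be unique. CT values must be positive; values at
#' or above 40 cycles are kept but flagged in a `near_undetected` column.
#'
#' @param path Path to a TSV file.
#' @return A tibble of CT records.
#' @export
read_ct_table <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- setdiff(c("sample_id", "assay", "ct"), names(x))
  if (length(need) > 0) {
    abort(paste0("CT table lacks column(s): ", paste(need, collapse = ", ")))
  }
  if (!"replicate" %in% names(x)) x$replicate <- 1L
  validate_ct_table(x)
}

validate_ct_table <- function(x) {
  x <- as_tibble(x)
  if (!"replicate" %in% names(x)) x$replicate <- 1L
  if (any(is.na(x$ct) | x$ct <= 0)) {
    i <- which(is.na(x$ct) | x$ct <= 0)[[1]]
    abort(sprintf("non-positive CT for sample %s, assay %s",
                  x$sample_id[[i]], x$assay[[i]]))
  }
  key <- paste(x$sample_id, x$assay, x$replicate, sep = "\r")
  if (anyDuplicated(key)) {
    i <- which(duplicated(key))[[1]]
    abort(sprintf("duplicated (sample, assay, replicate): (%s, %s, %s)",
                  x$sample_id[[i]], x$assay[[i]], x$replicate[[i]]))
  }
  x$near_undetected <- x$ct >= 40
  x
}

#' Serialize / read back an occupancy table
#'
#' The TSV has one row per `(mir_id, region_type)` and one column per TF,
#' in lexicographic order (deterministic bytes for identical tables).
#'
#' @param occupancy An `mg_occupancy` object (see [tabulate_occupancy()]) or
#'   its `entries` tibble (`mir_id`, `tf`, `region_type`, `n_sites`).
#' @param path Output path.
#' @return `path` invisibly for the writer; an entries tibble for the reader.
#' @export
write_occupancy_tsv <- function(occupancy, path) {
  entries <- if (inherits(occupancy, "mg_occupancy")) occupancy$entries else occupancy
  wide <- entries |>
    arrange(.data$mir_id, .data$region_type, .data$tf) |>
    pivot_wider(id_cols = c("mir_id", "region_type"),
                names_from = "tf", values_from = "n_sites", values_fill = 0L,
                names_sort = TRUE)
  readr::write_tsv(wide, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_occupancy_tsv
#' @export
read_occupancy_tsv <- function(path) {
  wide <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (ncol(wide) == 2) {
    return(tibble(mir_id = character(), tf = character(),
                  region_type = character(), n_sites = integer()))
  }
  wide |>
    pivot_longer(-c("mir_id", "region_type"),
                 names_to = "tf", values_to = "n_sites") |>
    mutate(n_sites = as.integer(.data$n_sites)) |>
    select("mir_id", "tf", "region_type", "n_sites") |>
    arrange(.data$mir_id, .data$tf, .data$region_type)
}

#' Read a motif count matrix (.pfm)
#'
#' Accepts either a JASPAR-style file (`>name` header, four rows labelled
#' `A`/`C`/`G`/`T`, optionally with brackets) or a plain tab-separated
#' 4-row matrix with a header row of positions, rows in A, C, G, T order.
#'
#' @param path Path to the matrix file.
#' @param name Motif (TF) name; defaults to the JASPAR header or filename.
#' @inheritParams pwm_from_counts
#' @return An `mg_motif` (see [pwm_from_counts()]).
#' @export
read_motif_pfm <- function(path, name = NULL, pseudocount = 0.5,
                           background = rep(0.25, 4)) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(str_trim(lines))]
  if (startsWith(lines[[1]], ">")) {
    if (is.null(name)) name <- str_trim(sub("^>", "", lines[[1]]))
    lines <- lines[-1]
  }
  toks <- map(str_split(str_trim(gsub("[][]", " ", lines)), "[\\s\t]+"), ~ .x[nzchar(.x)])
  first_tok <- map_chr(toks, 1)
  is_base_row <- first_tok %in% c("A", "C", "G", "T")
  if (sum(is_base_row) == 4) {
    # JASPAR-style labelled rows; reorder to A, C, G, T
    rows <- toks[is_base_row][match(c("A", "C", "G", "T"), first_tok[is_base_row])]
    counts <- map(rows, ~ as.numeric(.x[-1]))
  } else {
    if (length(toks) == 5) toks <- toks[-1]   # positions header row
    if (length(toks) != 4) abort("motif file must have 4 count rows (A, C, G, T)")
    counts <- map(toks, as.numeric)
  }
  if (any(map_lgl(counts, anyNA))) abort("non-numeric value in motif count matrix")
  L <- unique(lengths(counts))
  if (length(L) != 1) abort("motif count rows have unequal lengths")
  m <- do.call(rbind, counts)
  rownames(m) <- c("A", "C", "G", "T")
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  pwm_from_counts(m, name = name, pseudocount = pseudocount, background = background)
}

#' Read TF-family and miRNA-subtype maps from a YAML config
#'
#' The file may hold keys `families` and/or `subtypes`, each mapping a name
#' to a list of members, e.g. `families: {AP1: [FOS, JunD]}`.
#'
#' @param path YAML file path.
#' @return List with elements `families` and `subtypes` (either may be
#'   `NULL`), each a named list of character vectors.
#' @export
read_group_config <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  cfg <- yaml::read_yaml(path)
  out <- list(
    families = if (!is.null(cfg$families)) map(cfg$families, as.character),
    subtypes = if (!is.null(cfg$subtypes)) map(cfg$subtypes, as.character)
  )
  if (!is.null(out$families)) validate_family_map(out$families)
  if (!is.null(out$subtypes)) validate_subtype_map(out$subtypes)
  out
}
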