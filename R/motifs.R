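#' Build a position weight matrix from base counts
#'
#' Per-column probabilities are `(count + pseudocount) / (total + 4 *
#' pseudocount)`; log-odds scores are `log2(p / background)` in bits. The
#' defaults (pseudocount 0.5, uniform background) are deliberately plain and
#' are recorded on the returned object.
#'
#' @param counts 4 x L numeric matrix of non-negative base counts, rows in
#'   A, C, G, T order (row names, if present, must be those letters).
#' @param name Motif / TF name.
#' @param pseudocount Non-negative smoothing count added to every cell.
#' @param background Length-4 probability vector (A, C, G, T), summing to 1.
#' @return An `mg_motif`: list with `name`, `counts`, `pseudocount`,
#'   `background`, `prob` (4 x L), `log_odds` (4 x L, bits), `width`,
#'   `max_score`.
#' @examples
#' m <- pwm_from_counts(matrix(c(10, 0, 0, 0), 4, 1), name = "demo",
#'                      pseudocount = 0)
#' m$log_odds["A", 1] # 2 bits: log2(1 / 0.25)
#' @export
pwm_from_counts <- function(counts, name = "motif", pseudocount = 0.5,
                            background = rep(0.25, 4)) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4) abort("counts must have 4 rows (A, C, G, T)")
  if (ncol(counts) < 1) abort("motif must have at least one column")
  if (!is.null(rownames(counts)) && !identical(rownames(counts), c("A", "C", "G", "T"))) {
    counts <- counts[c("A", "C", "G", "T"), , drop = FALSE]
  }
  rownames(counts) <- c("A", "C", "G", "T")
  if (any(counts < 0) || anyNA(counts)) abort("counts must be non-negative")
  if (pseudocount < 0) abort("pseudocount must be non-negative")
  if (length(background) != 4 || abs(sum(background) - 1) > 1e-9 || any(background <= 0)) {
    abort("background must be 4 positive probabilities summing to 1")
  }
  if (any(colSums(counts) == 0 & pseudocount == 0)) {
    abort("all-zero count column with pseudocount 0")
  }
  if (any(apply(counts, 2, max) == 0)) {
    abort("every column needs at least one positive count")
  }
  totals <- colSums(counts) + 4 * pseudocount
  prob <- sweep(counts + pseudocount, 2, totals, "/")
  log_odds <- log2(sweep(prob, 1, background, "/"))
  structure(
    list(name = name, counts = counts, pseudocount = pseudocount,
         background = background, prob = prob, log_odds = log_odds,
         width = ncol(counts), max_score = sum(apply(log_odds, 2, max))),
    class = "mg_motif"
  )
}

#' @export
print.mg_motif <- function(x, ...) {
  cat(sprintf("<mg_motif> %s: %d bp, max score %.2f bits, consensus %s\n",
              x$name, x$width, x$max_score, consensus_string(x)))
  invisible(x)
}

# two-base IUPAC degenerate codes, keyed by sorted base pair
.iupac_pairs <- c(AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K")

#' IUPAC consensus string of a motif
#'
#' Per column: the single base whose probability reaches `heavy_threshold`;
#' otherwise the two-base IUPAC degenerate code when the top two
#' probabilities together reach `pair_threshold`; otherwise `N`.
#'
#' @param motif An `mg_motif`.
#' @param heavy_threshold Single-base dominance threshold (default 0.6).
#' @param pair_threshold Top-two sum threshold (default 0.8).
#' @return Uppercase IUPAC string of the motif's width.
#' @export
consensus_string <- function(motif, heavy_threshold = 0.6, pair_threshold = 0.8) {
  stopifnot(inherits(motif, "mg_motif"))
  bases <- rownames(motif$prob)
  paste(map_chr(seq_len(motif$width), function(j) {
    p <- motif$prob[, j]
    ord <- order(p, decreasing = TRUE)
    if (p[ord[1]] >= heavy_threshold) return(bases[ord[1]])
    if (p[ord[1]] + p[ord[2]] >= pair_threshold) {
      key <- paste(sort(bases[ord[1:2]]), collapse = "")
      return(.iupac_pairs[[key]])
    }
    "N"
  }), collapse = "")
}

revcomp <- function(s) {
  chartr("ACGTN", "TGCAN",
         vapply(s, function(x) paste(rev(strsplit(x, "", fixed = TRUE)[[1]]),
                                     collapse = ""), character(1), USE.NAMES = FALSE))
}

# log-odds score of every window of seq (integer-encoded); N scores 0
window_scores <- function(enc, lo) {
  L <- ncol(lo)
  n_win <- length(enc) - L + 1L
  if (n_win < 1) return(numeric(0))
  total <- numeric(n_win)
  for (j in seq_len(L)) {
    b <- enc[j:(j + n_win - 1L)]
    contrib <- lo[cbind(b, j)]
    contrib[is.na(b)] <- 0
    total <- total + contrib
  }
  total
}

encode_dna <- function(seq) {
  match(strsplit(seq, "", fixed = TRUE)[[1]], c("A", "C", "G", "T"))
}

#' Scan a sequence for motif occurrences
#'
#' Scores every window of the motif's width by summed log-odds and reports
#' those reaching `min_score_frac` of the maximum attainable score. `N`
#' bases contribute the background-expected score of 0. With
#' `both_strands`, each window is additionally scored on its reverse
#' complement; such hits are reported at the `+`-coordinates of the window
#' with `strand = "-"` (for palindromic motifs both strands of the same
#' window are reported). Hits are sorted by `(offset, strand)`.
#'
#' @param seq A single nucleotide string over A, C, G, T, N.
#' @param motif An `mg_motif`.
#' @param min_score_frac Score threshold as a fraction of the maximum
#'   attainable score, in (0, 1].
#' @param both_strands Scan the reverse complement too?
#' @return Tibble with `offset` (0-based window start), `strand`, `score`
#'   (bits) and `matched_sequence` (the sequence as seen by the motif, i.e.
#'   reverse-complemented for `-` hits).
#' @export
scan_sequence <- function(seq, motif, min_score_frac = 0.8, both_strands = TRUE) {
  stopifnot(inherits(motif, "mg_motif"), is.character(seq), length(seq) == 1)
  if (is.na(min_score_frac) || min_score_frac <= 0 || min_score_frac > 1) {
    abort("min_score_frac must be in (0, 1]")
  }
  seq <- toupper(seq)
  if (grepl("[^ACGTN]", seq)) abort("sequence must be over A, C, G, T, N")
  L <- motif$width
  empty <- tibble(offset = integer(), strand = character(),
                  score = numeric(), matched_sequence = character())
  if (nchar(seq) < L) {
    inform(sprintf("scan_sequence: sequence shorter than motif (%d < %d)",
                   nchar(seq), L))
    return(empty)
  }
  threshold <- min_score_frac * motif$max_score - 1e-9
  fwd <- window_scores(encode_dna(seq), motif$log_odds)
  hit_f <- which(fwd >= threshold)
  res <- list(tibble(
    offset = hit_f - 1L, strand = "+", score = fwd[hit_f],
    matched_sequence = str_sub(seq, hit_f, hit_f + L - 1L)
  ))
  if (both_strands) {
    rc <- revcomp(seq)
    rev_scores <- window_scores(encode_dna(rc), motif$log_odds)
    hit_r <- which(rev_scores >= threshold)
    n <- nchar(seq)
    res[[2]] <- tibble(
      offset = n - L - (hit_r - 1L), strand = "-", score = rev_scores[hit_r],
      matched_sequence = str_sub(rc, hit_r, hit_r + L - 1L)
    )
  }
  list_rbind(res) |>
    arrange(.data$offset, factor(.data$strand, levels = c("+", "-")))
}

#' Scan TF peaks for motif occurrences
#'
#' Peak-restricted motif search: each peak's sequence is extracted from the
#' genome and scanned with [scan_sequence()], mirroring the practice of
#' identifying a TF's binding motifs within the regions that TF actually
#' binds. Hits are reported in genomic coordinates.
#'
#' @param peaks Peak tibble; typically pre-filtered to one TF's label.
#' @param genome Named character vector of chromosome sequences.
#' @param motif An `mg_motif`.
#' @inheritParams scan_sequence
#' @return Tibble `chrom`, `start`, `end`, `strand`, `score`,
#'   `matched_sequence`, `label`, `peak_index`.
#' @export
scan_peaks <- function(peaks, genome, motif, min_score_frac = 0.8,
                       both_strands = TRUE) {
  check_intervals(peaks, "peak")
  missing <- setdiff(unique(peaks$chrom), names(genome))
  if (length(missing) > 0) {
    abort(paste0("genome lacks chromosome ", missing[[1]]))
  }
  map(seq_len(nrow(peaks)), function(i) {
    p <- peaks[i, ]
    s <- str_sub(genome[[p$chrom]], p$start + 1L, p$end)
    hits <- scan_sequence(s, motif, min_score_frac, both_strands)
    if (nrow(hits) == 0) return(NULL)
    tibble(chrom = p$chrom, start = p$start + hits$offset,
           end = p$start + hits$offset + motif$width,
           strand = hits$strand, score = hits$score,
           matched_sequence = hits$matched_sequence,
           label = if ("label" %in% names(p)) p$label else motif$name,
           peak_index = i)
  }) |>
    list_rbind()
}

#' Write motif hits as BED6
#'
#' BED scores are bits x 100, capped at 1000 (the BED score range).
#'
#' @param hits Hit tibble from [scan_peaks()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hits_bed <- function(hits, path) {
  score <- pmin(round(hits$score * 100), 1000)
  readr::write_lines(sprintf("%s\t%d\t%d\t%s\t%d\t%s",
                             hits$chrom, hits$start, hits$end,
                             hits$matched_sequence, as.integer(score), hits$strand),
                     path)
  invisible(path)
}
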