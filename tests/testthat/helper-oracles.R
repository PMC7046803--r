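# Independent oracles: deliberately naive per-base / per-window loops that
# never touch the package's counting or scanning machinery.

# pairwise O(n*m) overlap count of one region against a peak table
bf_count_overlaps <- function(region, peaks) {
  n <- 0L
  for (i in seq_len(nrow(peaks))) {
    if (peaks$chrom[[i]] == region$chrom &&
        region$start < peaks$end[[i]] && peaks$start[[i]] < region$end) {
      n <- n + 1L
    }
  }
  n
}

# set of covered (chrom, base) keys, by per-base enumeration
bf_coverage <- function(x) {
  keys <- character(0)
  for (i in seq_len(nrow(x))) {
    if (x$end[[i]] > x$start[[i]]) {
      keys <- c(keys, paste0(x$chrom[[i]], ":", seq(x$start[[i]], x$end[[i]] - 1L)))
    }
  }
  unique(keys)
}

# per-base label of a position within a gene: "exon", "intron", or "outside"
bf_base_label <- function(chrom, pos, gene, exons) {
  if (chrom != gene$chrom || pos < gene$start || pos >= gene$end) return("outside")
  ex <- exons[exons$gene_id == gene$gene_id, ]
  for (i in seq_len(nrow(ex))) {
    if (pos >= ex$start[[i]] && pos < ex$end[[i]]) return("exon")
  }
  if (nrow(ex) == 0) return("exon")  # exon-less genes treated as one exon
  "intron"
}

# exhaustive per-window rescoring motif scan (own revcomp, own scoring loop)
oracle_scan <- function(seq, motif, min_score_frac = 0.8, both_strands = TRUE) {
  lo <- motif$log_odds
  L <- ncol(lo)
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  n <- length(chars)
  if (n < L) {
    return(data.frame(offset = integer(), strand = character()))
  }
  th <- min_score_frac * sum(apply(lo, 2, max)) - 1e-9
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  score_word <- function(w) {
    s <- 0
    for (j in seq_along(w)) {
      if (w[[j]] != "N") s <- s + lo[w[[j]], j]
    }
    s
  }
  out <- list()
  for (o in 0:(n - L)) {
    w <- chars[(o + 1):(o + L)]
    if (score_word(w) >= th) {
      out[[length(out) + 1]] <- data.frame(offset = o, strand = "+")
    }
    if (both_strands) {
      wrc <- rev(unname(comp[w]))
      if (score_word(wrc) >= th) {
        out[[length(out) + 1]] <- data.frame(offset = o, strand = "-")
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(offset = integer(), strand = character()))
  }
  do.call(rbind, out)
}

# random helpers for property tests
random_intervals <- function(n, chroms = c("chrA", "chrB"), max_coord = 10000,
                             max_len = 500) {
  start <- sample.int(max_coord - max_len, n, replace = TRUE) - 1L
  len <- sample.int(max_len, n, replace = TRUE)
  tibble::tibble(chrom = sample(chroms, n, replace = TRUE),
                 start = start, end = start + len, strand = "*")
}

random_motif <- function(width = sample(4:10, 1), name = "rand") {
  counts <- matrix(stats::rpois(4 * width, 5), nrow = 4,
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  counts[cbind(sample.int(4, width, replace = TRUE), seq_len(width))] <-
    counts[cbind(sample.int(4, width, replace = TRUE), seq_len(width))] + 20
  pwm_from_counts(counts, name = name)
}

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

hit_key <- function(d) sort(paste(d$offset, d$strand))

# tiny hand-built annotation: one gene with an intron hosting nothing yet
demo_annotation <- function() {
  genes <- tibble::tibble(gene_id = "G1", chrom = "chr1", start = 1000L,
                          end = 5000L, strand = "+", biotype = "protein_coding")
  exons <- tibble::tibble(gene_id = "G1", chrom = "chr1",
                          start = c(1000L, 4000L), end = c(1200L, 5000L))
  mirnas <- tibble::tibble(mir_id = "mir-demo", chrom = "chr1", start = 1500L,
                           end = 1600L, strand = "+", mature_names = "mir-demo")
  mg_annotation(genes, exons, mirnas)
}
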