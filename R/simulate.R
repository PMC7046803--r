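#' Simulation configuration for a planted regulatory landscape
#'
#' Bundles and validates the parameters of [simulate_regulatory_landscape()].
#' The defaults describe the package's demo fixture: a 2 x 200 kb genome, 6
#' genes, the 7 signature miRNAs of the two myasthenia gravis serotypes with
#' about half placed in host-gene introns, 8 TFs with 0-6 planted binding
#' sites per (miRNA, TF, region type), a background peak rate of 5 per Mb
#' placed clear of every tracked window, histone marks co-placed with the
#' planted regions, and one information-rich forkhead-style motif embedded
#' in the designated TF's peaks.
#'
#' @param seed Mandatory integer seed; the whole fixture is a deterministic
#'   function of the config (including the seed).
#' @param n_chromosomes,chromosome_length_bp Genome shape.
#' @param n_genes,exons_per_gene Gene models (exons 1.5-2.5 kb, introns
#'   3-5 kb).
#' @param n_mirnas,fraction_intronic Number of miRNA loci and the fraction
#'   (rounded) planted inside host-gene introns.
#' @param mirna_names Locus names; defaults to the seven MG signature
#'   miRNAs so subtype summaries run on the fixture unchanged.
#' @param tf_names TF labels for the planted ChIP-seq peaks.
#' @param planted_count_range Inclusive range of planted binding-site counts
#'   per (miRNA, TF, region type).
#' @param peak_width_range,histone_width_range Peak widths in bp.
#' @param background_rate_per_mb Poisson rate of background (untracked) peaks.
#' @param histone_prob Per region class (promoter / enhancer windows), the
#'   probability that each histone mark is co-placed with the region.
#' @param promoter_bp,enhancer_bp Window sizes used for the planted regions.
#' @param motif_tf,motif_consensus,motif_dominance,motifs_per_peak The motif
#'   planted in `motif_tf` peaks: a count matrix with `motif_dominance` at
#'   the consensus base and 1 elsewhere (the default is ~1.67 bits/column),
#'   `motifs_per_peak` occurrences embedded per peak of that TF.
#' @param qpcr Parameter block for [simulate_ct_table()]; see that help page.
#' @return A validated list of class `mg_sim_config`.
#' @export
simulation_config <- function(
    seed = 17,
    n_chromosomes = 2,
    chromosome_length_bp = 200000,
    n_genes = 6,
    exons_per_gene = 3,
    n_mirnas = 7,
    fraction_intronic = 0.5,
    mirna_names = c("miR-150-5p", "miR-21-5p", "miR-30e-5p", "miR-151a-3p",
                    "miR-423-5p", "let-7a-5p", "let-7f-5p"),
    tf_names = c("FoxA1", "FoxA2", "FOS", "JunD", "RELA", "ESR1", "Stat1", "IRF1"),
    planted_count_range = c(0L, 6L),
    peak_width_range = c(20L, 30L),
    background_rate_per_mb = 5,
    histone_prob = list(
      promoter = c(H3K4me3 = 0.7, H3K4me1 = 0.3, H3K27ac = 0.4),
      enhancer = c(H3K4me3 = 0.1, H3K4me1 = 0.7, H3K27ac = 0.5)
    ),
    histone_width_range = c(400L, 1200L),
    promoter_bp = 2000,
    enhancer_bp = 10000,
    motif_tf = "FoxA1",
    motif_consensus = "TGTTTAC",
    motif_dominance = 97,
    motifs_per_peak = 1,
    qpcr = default_qpcr_config()) {
  if (missing(seed) && is.null(seed)) abort("seed is mandatory")
  stopifnot(length(seed) == 1, is.finite(seed))
  if (fraction_intronic < 0 || fraction_intronic > 1) {
    abort("fraction_intronic must be in [0, 1]")
  }
  if (any(planted_count_range < 0) || background_rate_per_mb < 0) {
    abort("counts and rates must be non-negative")
  }
  if (length(mirna_names) != n_mirnas) {
    abort("mirna_names must have length n_mirnas")
  }
  if (!motif_tf %in% tf_names) abort("motif_tf must be one of tf_names")
  if (grepl("[^ACGT]", motif_consensus)) {
    abort("motif_consensus must be over A, C, G, T")
  }
  # feasibility: worst-case planted peaks must fit in the promoter window
  demand <- length(tf_names) * planted_count_range[[2]] * peak_width_range[[2]]
  if (demand > 0.85 * promoter_bp) {
    abort(sprintf(
      "planted counts exhaust promoter window space (%d bp needed, %d available)",
      demand, promoter_bp))
  }
  structure(as.list(environment()), class = "mg_sim_config")
}

#' @rdname simulate_ct_table
#' @export
default_qpcr_config <- function() {
  list(
    groups = c("HC", "MG"),
    n_per_group = c(HC = 20, MG = 20),
    target = "miR-21-5p",
    target_delta_ct_mean = c(HC = 6, MG = 4),
    target_delta_ct_sd = c(HC = 0.5, MG = 0.5),
    references = c("miR-93-5p", "miR-191-5p", "miR-423-4p", "miR-103a"),
    reference_ct_mean = c(`miR-93-5p` = 20, `miR-191-5p` = 21,
                          `miR-423-4p` = 22, `miR-103a` = 23),
    reference_ct_sd = 0.3,
    hemolysis_fraction = 0.1,
    marker_451a_mean = 24,
    marker_451a_sd = 0.3,
    hemolysis_delta_clean = c(3, 6),
    hemolysis_delta_contam = c(8, 12)
  )
}

## ---- local interval helpers (generator-side truth is computed with these
## ---- plain loops, independent of the package's counting path) ----

# coalesce possibly overlapping/abutting [s,e) pairs
iv_merge_local <- function(s, e) {
  if (length(s) == 0) return(list(s = integer(), e = integer()))
  o <- order(s)
  s <- s[o]; e <- e[o]
  ms <- s[[1]]; me <- e[[1]]
  outs <- c(); oute <- c()
  for (i in seq_along(s)[-1]) {
    if (s[[i]] <= me) me <- max(me, e[[i]]) else {
      outs <- c(outs, ms); oute <- c(oute, me)
      ms <- s[[i]]; me <- e[[i]]
    }
  }
  list(s = c(outs, ms), e = c(oute, me))
}

# [0, L) minus merged intervals
iv_complement <- function(s, e, L) {
  m <- iv_merge_local(pmax(s, 0L), pmin(e, L))
  gs <- c(0L, m$e); ge <- c(m$s, L)
  keep <- gs < ge
  list(s = gs[keep], e = ge[keep])
}

# one interval minus a set of intervals -> fragments
iv_subtract <- function(s0, e0, subs, sube) {
  frags <- list(s = s0, e = e0)
  if (length(subs) == 0) return(frags)
  m <- iv_merge_local(subs, sube)
  fs <- c(); fe <- c()
  cur <- s0
  for (i in seq_along(m$s)) {
    a <- max(m$s[[i]], s0); b <- min(m$e[[i]], e0)
    if (a >= b) next
    if (cur < a) { fs <- c(fs, cur); fe <- c(fe, a) }
    cur <- max(cur, b)
  }
  if (cur < e0) { fs <- c(fs, cur); fe <- c(fe, e0) }
  list(s = as.integer(fs), e = as.integer(fe))
}

# place n disjoint intervals of given widths inside zone fragments,
# avoiding 'occupied'; returns starts or errors
place_in_zone <- function(zone, widths, occupied, what, max_try = 4000) {
  starts <- integer(0)
  occ_s <- occupied$s; occ_e <- occupied$e
  for (w in widths) {
    ok_frag <- which(zone$e - zone$s >= w)
    if (length(ok_frag) == 0) {
      abort(sprintf("infeasible placement: no fragment of %s can hold width %d",
                    what, w))
    }
    placed <- FALSE
    for (try in seq_len(max_try)) {
      f <- if (length(ok_frag) == 1) ok_frag else {
        sample(ok_frag, 1, prob = zone$e[ok_frag] - zone$s[ok_frag] - w + 1)
      }
      st <- zone$s[[f]] + sample.int(zone$e[[f]] - zone$s[[f]] - w + 1L, 1) - 1L
      # >= 1 bp clearance: abutting same-TF peaks would coalesce under merging
      if (!any(st <= occ_e & occ_s <= st + w)) {
        starts <- c(starts, st)
        occ_s <- c(occ_s, st); occ_e <- c(occ_e, st + w)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      abort(sprintf("infeasible placement after %d retries in %s", max_try, what))
    }
  }
  list(starts = starts, occupied = list(s = occ_s, e = occ_e))
}

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## ---- landscape simulation ----

#' Simulate a regulatory landscape with planted ground truth
#'
#' Generates a complete desk-scale fixture: a random multi-chromosome
#' genome, gene models with exon/intron structure, miRNA loci (intronic
#' miRNAs strictly inside a host intron, positioned so the host promoter
#' stays clear of the miRNA's own enhancer window), per-TF ChIP-seq peaks
#' planted inside designated regulatory windows, histone-mark peaks
#' co-placed with those windows, background peaks at least 1 bp clear of
#' every tracked window, and motif occurrences embedded at recorded offsets
#' inside the designated TF's peaks. Planted peaks are pairwise disjoint
#' within each miRNA's windows, so counts are unambiguous under
#' cross-cell-line merging.
#'
#' The returned `truth` tables are computed by plain pairwise scans over
#' the generated coordinates (not by the package's counting machinery), so
#' downstream recovery is a genuine two-route check.
#'
#' @param config An [simulation_config()] object.
#' @return An `mg_simulation`: list with `genome` (named sequences),
#'   `chrom_sizes`, `annotation` ([mg_annotation]), `tf_peaks`,
#'   `histone_peaks`, `regions` (the planted windows), `motif`
#'   (the planted `mg_motif`), `truth` (occupancy, dedup_totals, chromatin,
#'   motifs, hosts tibbles), and `config`.
#' @export
simulate_regulatory_landscape <- function(config = simulation_config()) {
  stopifnot(inherits(config, "mg_sim_config"))
  withr::with_seed(as.integer(config$seed), simulate_landscape_impl(config))
}

simulate_landscape_impl <- function(cfg) {
  chroms <- paste0("chr", seq_len(cfg$n_chromosomes))
  L <- cfg$chromosome_length_bp
  chrom_sizes <- stats::setNames(rep(as.integer(L), cfg$n_chromosomes), chroms)
  prom_bp <- as.integer(cfg$promoter_bp); enh_bp <- as.integer(cfg$enhancer_bp)

  n_intronic <- min(round(cfg$n_mirnas * cfg$fraction_intronic), cfg$n_genes)
  intronic_flag <- c(rep(TRUE, n_intronic), rep(FALSE, cfg$n_mirnas - n_intronic))

  ## ---- layout: pack gene / intergenic-miRNA territories ----
  gene_geom <- function() {
    ew <- sample(1500:2500, cfg$exons_per_gene, replace = TRUE)
    iw <- if (cfg$exons_per_gene > 1) {
      sample(3000:5000, cfg$exons_per_gene - 1, replace = TRUE)
    } else integer()
    list(ew = ew, iw = iw, len = sum(ew) + sum(iw))
  }
  margin_gene <- enh_bp + prom_bp        # host windows + poking miRNA enhancer
  margin_mir <- enh_bp + 500L

  units <- list()
  for (i in seq_len(cfg$n_genes)) {
    units[[length(units) + 1]] <- list(
      kind = "gene", gene_id = sprintf("GENE%d", i),
      hosts_mirna = i <= n_intronic,
      mir_id = if (i <= n_intronic) cfg$mirna_names[[i]] else NA_character_
    )
  }
  for (j in seq_len(cfg$n_mirnas - n_intronic)) {
    units[[length(units) + 1]] <- list(
      kind = "intergenic_mirna", mir_id = cfg$mirna_names[[n_intronic + j]]
    )
  }

  genes <- list(); exons <- list(); mirnas <- list()
  ci <- 1L; cursor <- 500L
  for (u in units) {
    if (u$kind == "gene") {
      geom <- gene_geom()
      span <- geom$len + 2L * margin_gene
    } else {
      mir_len <- sample(80:120, 1)
      span <- mir_len + 2L * margin_mir
    }
    gap <- sample(500:1500, 1)
    while (cursor + gap + span > L - 500L) {
      ci <- ci + 1L
      if (ci > cfg$n_chromosomes) {
        abort("infeasible placement: gene/miRNA territories exceed genome size")
      }
      cursor <- 500L
      gap <- sample(500:1500, 1)
    }
    at <- cursor + gap
    chrom <- chroms[[ci]]
    if (u$kind == "gene") {
      gs <- at + margin_gene
      strand <- sample(c("+", "-"), 1)
      # exon/intron structure along the gene
      starts <- gs
      ex_s <- integer(); ex_e <- integer(); in_s <- integer(); in_e <- integer()
      pos <- gs
      for (k in seq_len(cfg$exons_per_gene)) {
        ex_s <- c(ex_s, pos); ex_e <- c(ex_e, pos + geom$ew[[k]])
        pos <- pos + geom$ew[[k]]
        if (k < cfg$exons_per_gene) {
          in_s <- c(in_s, pos); in_e <- c(in_e, pos + geom$iw[[k]])
          pos <- pos + geom$iw[[k]]
        }
      }
      ge <- pos
      genes[[length(genes) + 1]] <- tibble(
        gene_id = u$gene_id, chrom = chrom, start = gs, end = ge,
        strand = strand, biotype = "protein_coding")
      exons[[length(exons) + 1]] <- tibble(
        gene_id = u$gene_id, chrom = chrom, start = ex_s, end = ex_e)
      if (u$hosts_mirna) {
        mir_len <- sample(80:120, 1)
        # keep the host promoter clear of the miRNA's enhancer window
        feas_lo <- if (strand == "+") gs + enh_bp + 50L else gs
        feas_hi <- if (strand == "+") ge else ge - enh_bp - 50L - mir_len
        ok <- integer()
        for (k in seq_along(in_s)) {
          lo <- max(in_s[[k]] + 25L, feas_lo)
          hi <- min(in_e[[k]] - 25L, feas_hi + mir_len) - mir_len
          if (lo <= hi) ok <- c(ok, k)
        }
        if (length(ok) == 0) {
          abort(sprintf("infeasible placement: no intron of %s can host a miRNA %s",
                        u$gene_id, "clear of the host promoter"))
        }
        k <- if (length(ok) == 1) ok else sample(ok, 1)
        lo <- max(in_s[[k]] + 25L, feas_lo)
        hi <- min(in_e[[k]] - 25L, feas_hi + mir_len) - mir_len
        ms <- lo + sample.int(hi - lo + 1L, 1) - 1L
        mirnas[[length(mirnas) + 1]] <- tibble(
          mir_id = u$mir_id, chrom = chrom, start = ms, end = ms + mir_len,
          strand = sample(c("+", "-"), 1), mature_names = u$mir_id,
          intronic = TRUE, host_gene_id = u$gene_id)
      }
      cursor <- at + span
    } else {
      mir_len <- span - 2L * margin_mir
      ms <- at + margin_mir
      mirnas[[length(mirnas) + 1]] <- tibble(
        mir_id = u$mir_id, chrom = chrom, start = ms, end = ms + mir_len,
        strand = sample(c("+", "-"), 1), mature_names = u$mir_id,
        intronic = FALSE, host_gene_id = NA_character_)
      cursor <- at + span
    }
  }
  genes <- list_rbind(genes)
  exons <- list_rbind(exons)
  mirnas <- list_rbind(mirnas)

  ## ---- planted regulatory windows (plain arithmetic) ----
  win_prom <- function(s, e, strand) {
    if (strand == "+") c(max(s - prom_bp, 0L), s) else c(e, e + prom_bp)
  }
  regions <- list()
  for (i in seq_len(nrow(mirnas))) {
    m <- mirnas[i, ]
    pw <- win_prom(m$start, m$end, m$strand)
    regions[[length(regions) + 1]] <- tibble(
      mir_id = m$mir_id,
      region_type = c("mir_promoter", "mir_enhancer"),
      source_id = m$mir_id, chrom = m$chrom,
      start = c(pw[[1]], max(m$start - enh_bp, 0L)),
      end = c(pw[[2]], m$end + enh_bp),
      strand = m$strand)
    if (isTRUE(m$intronic)) {
      g <- genes[genes$gene_id == m$host_gene_id, ]
      gw <- win_prom(g$start, g$end, g$strand)
      regions[[length(regions) + 1]] <- tibble(
        mir_id = m$mir_id,
        region_type = c("host_promoter", "host_enhancer"),
        source_id = g$gene_id, chrom = g$chrom,
        start = c(gw[[1]], max(g$start - enh_bp, 0L)),
        end = c(gw[[2]], g$end + enh_bp),
        strand = g$strand)
    }
  }
  regions <- list_rbind(regions)

  ## ---- placement zones: disjoint sub-intervals per (miRNA, region type) ----
  zones <- list()
  for (id in unique(regions$mir_id)) {
    rr <- regions[regions$mir_id == id, ]
    m <- mirnas[mirnas$mir_id == id, ]
    get <- function(rt) rr[rr$region_type == rt, ]
    z <- list()
    pr <- get("mir_promoter"); en <- get("mir_enhancer")
    z$mir_promoter <- list(s = pr$start, e = pr$end)
    z$mir_enhancer <- iv_subtract(en$start, en$end,
                                  c(pr$start, m$start), c(pr$end, m$end))
    if ("host_promoter" %in% rr$region_type) {
      hp <- get("host_promoter"); he <- get("host_enhancer")
      z$host_promoter <- iv_subtract(hp$start, hp$end,
                                     c(en$start), c(en$end))
      z$host_enhancer <- iv_subtract(he$start, he$end,
                                     c(en$start, hp$start), c(en$end, hp$end))
    }
    zones[[id]] <- z
  }

  ## ---- plant TF peaks ----
  kmin <- cfg$planted_count_range[[1]]; kmax <- cfg$planted_count_range[[2]]
  tf_peaks <- list()
  for (id in unique(regions$mir_id)) {
    chrom <- regions$chrom[regions$mir_id == id][[1]]
    for (rt in names(zones[[id]])) {
      occupied <- list(s = integer(), e = integer())
      for (tf in cfg$tf_names) {
        k <- sample(seq(kmin, kmax), 1)
        if (k == 0) next
        widths <- sample(seq(cfg$peak_width_range[[1]], cfg$peak_width_range[[2]]),
                         k, replace = TRUE)
        pl <- place_in_zone(zones[[id]][[rt]], widths, occupied,
                            what = paste(id, rt))
        occupied <- pl$occupied
        tf_peaks[[length(tf_peaks) + 1]] <- tibble(
          chrom = chrom, start = pl$starts, end = pl$starts + widths,
          strand = "*", label = tf, score = 100,
          origin = "planted", mir_id = id, region_origin = rt)
      }
    }
  }
  tf_peaks <- if (length(tf_peaks) > 0) list_rbind(tf_peaks) else {
    tibble(chrom = character(), start = integer(), end = integer(),
           strand = character(), label = character(), score = numeric(),
           origin = character(), mir_id = character(),
           region_origin = character())
  }

  ## ---- background peaks, >= 1 bp clear of every tracked window ----
  genome_mb <- cfg$n_chromosomes * L / 1e6
  n_bg <- stats::rpois(1, cfg$background_rate_per_mb * genome_mb)
  bg <- list()
  if (n_bg > 0) {
    for (b in seq_len(n_bg)) {
      chrom <- sample(chroms, 1)
      rr <- regions[regions$chrom == chrom, ]
      comp <- iv_complement(rr$start - 1L, rr$end + 1L, as.integer(L))
      w <- sample(seq(cfg$peak_width_range[[1]], cfg$peak_width_range[[2]]), 1)
      occupied <- if (length(bg) > 0) {
        done <- list_rbind(bg)
        done <- done[done$chrom == chrom, ]
        list(s = done$start, e = done$end)
      } else list(s = integer(), e = integer())
      pl <- place_in_zone(comp, w, occupied, what = "background territory")
      bg[[length(bg) + 1]] <- tibble(
        chrom = chrom, start = pl$starts, end = pl$starts + w, strand = "*",
        label = sample(cfg$tf_names, 1), score = 100,
        origin = "background", mir_id = NA_character_,
        region_origin = NA_character_)
    }
    tf_peaks <- bind_rows(tf_peaks, list_rbind(bg))
  }
  tf_peaks <- arrange(tf_peaks, .data$chrom, .data$start, .data$label)

  ## ---- histone peaks co-placed with regions ----
  histone_peaks <- list()
  for (i in seq_len(nrow(regions))) {
    r <- regions[i, ]
    cls <- if (grepl("promoter", r$region_type)) "promoter" else "enhancer"
    probs <- cfg$histone_prob[[cls]]
    zone <- zones[[r$mir_id]][[r$region_type]]
    for (mark in names(probs)) {
      if (stats::runif(1) < probs[[mark]]) {
        wmax <- max(zone$e - zone$s)
        w <- min(sample(seq(cfg$histone_width_range[[1]],
                            cfg$histone_width_range[[2]]), 1), wmax)
        pl <- place_in_zone(zone, w, list(s = integer(), e = integer()),
                            what = paste(r$mir_id, r$region_type, mark))
        histone_peaks[[length(histone_peaks) + 1]] <- tibble(
          chrom = r$chrom, start = pl$starts, end = pl$starts + w,
          strand = "*", label = mark, score = 100,
          mir_id = r$mir_id, region_origin = r$region_type)
      }
    }
  }
  histone_peaks <- if (length(histone_peaks) > 0) {
    list_rbind(histone_peaks)
  } else {
    tibble(chrom = character(), start = integer(), end = integer(),
           strand = character(), label = character(), score = numeric(),
           mir_id = character(), region_origin = character())
  }

  ## ---- genome sequence + planted motifs ----
  genome <- stats::setNames(map_chr(chroms, ~ rand_dna(L)), chroms)
  motif_counts <- consensus_to_counts(cfg$motif_consensus, cfg$motif_dominance)
  motif <- pwm_from_counts(motif_counts, name = cfg$motif_tf)
  word <- cfg$motif_consensus
  wordL <- nchar(word)
  rc_word <- revcomp(word)
  motif_truth <- list()
  target_peaks <- which(tf_peaks$label == cfg$motif_tf)
  for (i in target_peaks) {
    p <- tf_peaks[i, ]
    w <- p$end - p$start
    n_occ <- if (p$origin == "planted") cfg$motifs_per_peak else 0L
    for (try in seq_len(60)) {
      s <- rand_dna(w)
      if (n_occ > 0) {
        offs <- integer(); guard <- 0L
        while (length(offs) < n_occ && guard < 200L) {
          o <- sample.int(w - wordL + 1L, 1) - 1L
          if (!any(abs(o - offs) < wordL)) offs <- c(offs, o)
          guard <- guard + 1L
        }
        if (length(offs) < n_occ) next
        strands <- sample(c("+", "-"), n_occ, replace = TRUE)
        for (k in seq_len(n_occ)) {
          ins <- if (strands[[k]] == "+") word else rc_word
          str_sub(s, offs[[k]] + 1L, offs[[k]] + wordL) <- ins
        }
      } else {
        offs <- integer(); strands <- character()
      }
      fwd_hits <- int_positions(s, word)
      rev_hits <- int_positions(s, rc_word)
      ok <- setequal(fwd_hits, offs[strands == "+"]) &&
        setequal(rev_hits, offs[strands == "-"]) &&
        length(fwd_hits) == sum(strands == "+") &&
        length(rev_hits) == sum(strands == "-")
      if (ok) break
      if (try == 60) abort("infeasible placement: motif embedding kept colliding")
    }
    str_sub(genome[[p$chrom]], p$start + 1L, p$end) <- s
    if (n_occ > 0) {
      motif_truth[[length(motif_truth) + 1]] <- tibble(
        chrom = p$chrom, peak_start = p$start, peak_end = p$end,
        offset = offs, start = p$start + offs, end = p$start + offs + wordL,
        strand = strands, label = cfg$motif_tf)
    }
  }
  motif_truth <- if (length(motif_truth) > 0) {
    list_rbind(motif_truth) |> arrange(.data$chrom, .data$start, .data$strand)
  } else {
    tibble(chrom = character(), peak_start = integer(), peak_end = integer(),
           offset = integer(), start = integer(), end = integer(),
           strand = character(), label = character())
  }

  ## ---- truth tables via plain pairwise scans ----
  ov <- function(rs, re, ss, se, same) same & rs < se & ss < re
  truth_occ <- list()
  for (i in seq_len(nrow(regions))) {
    r <- regions[i, ]
    for (tf in sort(cfg$tf_names)) {
      p <- tf_peaks[tf_peaks$label == tf, ]
      n <- sum(ov(r$start, r$end, p$start, p$end, p$chrom == r$chrom))
      truth_occ[[length(truth_occ) + 1]] <- tibble(
        mir_id = r$mir_id, tf = tf, region_type = r$region_type,
        n_sites = as.integer(n))
    }
  }
  truth_occ <- list_rbind(truth_occ)

  truth_dedup <- list()
  for (id in unique(regions$mir_id)) {
    rr <- regions[regions$mir_id == id, ]
    for (tf in sort(cfg$tf_names)) {
      p <- tf_peaks[tf_peaks$label == tf, ]
      hit <- rep(FALSE, nrow(p))
      for (j in seq_len(nrow(rr))) {
        hit <- hit | ov(rr$start[[j]], rr$end[[j]], p$start, p$end,
                        p$chrom == rr$chrom[[j]])
      }
      truth_dedup[[length(truth_dedup) + 1]] <- tibble(
        mir_id = id, tf = tf, n_sites = as.integer(sum(hit)))
    }
  }
  truth_dedup <- list_rbind(truth_dedup)

  truth_chrom <- list()
  for (i in seq_len(nrow(regions))) {
    r <- regions[i, ]
    has <- map_lgl(c("H3K4me3", "H3K4me1", "H3K27ac"), function(mark) {
      h <- histone_peaks[histone_peaks$label == mark, ]
      any(ov(r$start, r$end, h$start, h$end, h$chrom == r$chrom))
    })
    call <- if (has[[1]]) "active_promoter"
    else if (has[[2]] && has[[3]]) "active_enhancer"
    else if (has[[2]]) "poised_enhancer"
    else "unmarked"
    truth_chrom[[length(truth_chrom) + 1]] <- tibble(
      mir_id = r$mir_id, region_type = r$region_type,
      has_H3K4me3 = has[[1]], has_H3K4me1 = has[[2]], has_H3K27ac = has[[3]],
      call = call)
  }
  truth_chrom <- list_rbind(truth_chrom)

  annotation <- mg_annotation(
    genes, exons,
    mirnas[, c("mir_id", "chrom", "start", "end", "strand", "mature_names")],
    genome_build = "mirreg_sim1")

  structure(
    list(
      genome = genome,
      chrom_sizes = chrom_sizes,
      annotation = annotation,
      tf_peaks = tf_peaks,
      histone_peaks = histone_peaks,
      regions = regions,
      motif = motif,
      truth = list(
        occupancy = arrange(truth_occ, .data$mir_id, .data$tf,
                            factor(.data$region_type, levels = region_types())),
        dedup_totals = arrange(truth_dedup, .data$mir_id, .data$tf),
        chromatin = truth_chrom,
        motifs = motif_truth,
        hosts = mirnas[, c("mir_id", "host_gene_id", "intronic")]
      ),
      config = cfg
    ),
    class = "mg_simulation"
  )
}

# 0-based offsets of (possibly overlapping) fixed-string occurrences
int_positions <- function(s, word) {
  m <- gregexpr(paste0("(?=", word, ")"), s, perl = TRUE)[[1]]
  if (m[[1]] == -1) integer() else as.integer(m) - 1L
}

# count matrix with `dominance` at the consensus base, 1 elsewhere
consensus_to_counts <- function(consensus, dominance = 97) {
  bases <- strsplit(consensus, "", fixed = TRUE)[[1]]
  m <- matrix(1, nrow = 4, ncol = length(bases),
              dimnames = list(c("A", "C", "G", "T"), NULL))
  for (j in seq_along(bases)) m[bases[[j]], j] <- dominance
  m
}

#' @export
print.mg_simulation <- function(x, ...) {
  cat(sprintf(
    "<mg_simulation> seed=%s: %d chrom, %d genes, %d miRNAs (%d intronic), %d TF peaks, %d histone peaks\n",
    format(x$config$seed), length(x$genome), nrow(x$annotation$genes),
    nrow(x$annotation$mirnas), sum(x$truth$hosts$intronic),
    nrow(x$tf_peaks), nrow(x$histone_peaks)))
  invisible(x)
}

#' Write a simulated landscape as standard files
#'
#' Emits `annotation.gff3`, `genome.fa`, `tf_peaks.bed` (BED6, TF in the
#' name column), `histone_peaks.broadPeak`, and the truth tables as TSV
#' (`truth_*.tsv`), all plain text.
#'
#' @param sim An `mg_simulation`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_landscape <- function(sim, dir) {
  stopifnot(inherits(sim, "mg_simulation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_gff3(sim$annotation, file.path(dir, "annotation.gff3"))
  write_fasta(sim$genome, file.path(dir, "genome.fa"))
  write_peaks_bed(sim$tf_peaks, file.path(dir, "tf_peaks.bed"))
  h <- sim$histone_peaks
  readr::write_lines(
    sprintf("%s\t%d\t%d\t%s\t%d\t.\t-1\t-1\t-1",
            h$chrom, h$start, h$end, h$label, as.integer(h$score)),
    file.path(dir, "histone_peaks.broadPeak"))
  readr::write_tsv(sim$truth$occupancy, file.path(dir, "truth_occupancy.tsv"),
                   progress = FALSE)
  readr::write_tsv(sim$truth$dedup_totals, file.path(dir, "truth_dedup.tsv"),
                   progress = FALSE)
  readr::write_tsv(sim$truth$chromatin, file.path(dir, "truth_chromatin.tsv"),
                   progress = FALSE)
  readr::write_tsv(sim$truth$motifs, file.path(dir, "truth_motifs.tsv"),
                   progress = FALSE)
  readr::write_tsv(sim$truth$hosts, file.path(dir, "truth_hosts.tsv"),
                   progress = FALSE)
  invisible(dir)
}

#' Simulate a qPCR CT table with planted truth
#'
#' Emulates a serum panel study design: two (or more) groups of samples,
#' one target assay, several reference assays, and the two hemolysis marker
#' assays. Each sample's reference CTs are drawn around fixed means; the
#' target CT is the mean of that sample's reference CTs plus a group-specific
#' dCT draw, so noise-free configurations (`target_delta_ct_sd = 0`) recover
#' the configured group means exactly. A designated fraction of samples is
#' made hemolytic (`dCT(hemolysis) > 7`) so QC exclusions are exercised.
#'
#' @param qpcr Parameter block, see [default_qpcr_config()]: group names and
#'   sizes, target/reference assay names, per-group dCT mean and SD
#'   (cycles), reference CT means and SD (cycles), hemolysis fraction and
#'   the clean / contaminated dCT ranges (cycles).
#' @param seed Integer seed.
#' @return List with `ct` (long CT tibble: `sample_id`, `assay`, `ct`,
#'   `replicate`, `group`) and `truth` (`sample_id`, `group`,
#'   `true_delta_ct`, `hemolysed`).
#' @export
simulate_ct_table <- function(qpcr = default_qpcr_config(), seed = 17) {
  stopifnot(length(seed) == 1, is.finite(seed))
  if (any(qpcr$n_per_group < 2)) abort("n_per_group must be >= 2")
  if (any(qpcr$target_delta_ct_sd < 0) || any(qpcr$reference_ct_sd < 0)) {
    abort("SDs must be >= 0")
  }
  withr::with_seed(as.integer(seed), {
    rows <- list(); truth <- list()
    all_ids <- unlist(map(qpcr$groups, function(g) {
      sprintf("%s_%02d", g, seq_len(qpcr$n_per_group[[g]]))
    }))
    n_total <- length(all_ids)
    n_hemo <- round(qpcr$hemolysis_fraction * n_total)
    hemo_ids <- if (n_hemo > 0) sample(all_ids, n_hemo) else character()
    for (g in qpcr$groups) {
      for (i in seq_len(qpcr$n_per_group[[g]])) {
        sid <- sprintf("%s_%02d", g, i)
        ref_ct <- stats::rnorm(length(qpcr$references),
                               unname(qpcr$reference_ct_mean[qpcr$references]),
                               qpcr$reference_ct_sd)
        delta <- stats::rnorm(1, qpcr$target_delta_ct_mean[[g]],
                              qpcr$target_delta_ct_sd[[g]])
        ct451 <- stats::rnorm(1, qpcr$marker_451a_mean, qpcr$marker_451a_sd)
        hemo <- sid %in% hemo_ids
        rng <- if (hemo) qpcr$hemolysis_delta_contam else qpcr$hemolysis_delta_clean
        ct23 <- ct451 + stats::runif(1, rng[[1]], rng[[2]])
        rows[[length(rows) + 1]] <- tibble(
          sample_id = sid,
          assay = c(qpcr$target, qpcr$references, "miR-23a-3p", "miR-451a"),
          ct = c(mean(ref_ct) + delta, ref_ct, ct23, ct451),
          replicate = 1L, group = g)
        truth[[length(truth) + 1]] <- tibble(
          sample_id = sid, group = g, true_delta_ct = delta, hemolysed = hemo)
      }
    }
    list(ct = list_rbind(rows), truth = list_rbind(truth))
  })
}
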