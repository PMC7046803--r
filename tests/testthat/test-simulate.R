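test_that("fixtures are byte-reproducible per seed and differ across seeds", {
  a <- simulate_regulatory_landscape(simulation_config(seed = 17))
  b <- simulate_regulatory_landscape(simulation_config(seed = 17))
  expect_identical(a$genome, b$genome)
  expect_identical(a$tf_peaks, b$tf_peaks)
  expect_identical(a$truth, b$truth)
  c <- simulate_regulatory_landscape(simulation_config(seed = 18))
  expect_false(identical(a$genome, c$genome))
  # the global RNG stream is left untouched
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(simulate_regulatory_landscape(simulation_config(seed = 5)))
  expect_identical(runif(1), before)
})

test_that("fraction_intronic = 1 gives every miRNA a host gene", {
  cfg <- simulation_config(seed = 7, n_mirnas = 4, fraction_intronic = 1,
                           mirna_names = paste0("mir-", 1:4))
  sim <- simulate_regulatory_landscape(cfg)
  hosts <- find_host_gene(sim$annotation$mirnas, sim$annotation$genes,
                          sim$annotation$exons)
  expect_true(all(!is.na(hosts$host_gene_id)))
  expect_true(all(sim$truth$hosts$intronic))
})

test_that("an empty landscape tabulates to all-zero occupancy", {
  cfg <- simulation_config(seed = 8, planted_count_range = c(0L, 0L),
                           background_rate_per_mb = 0)
  sim <- simulate_regulatory_landscape(cfg)
  expect_equal(nrow(sim$tf_peaks), 0)
  expect_equal(sum(sim$truth$occupancy$n_sites), 0)
  regions <- build_regions(sim$annotation, chrom_sizes = sim$chrom_sizes)
  expect_warning(occ <- tabulate_occupancy(regions, sim$tf_peaks), "empty peak")
  expect_equal(sum(occ$entries$n_sites), 0)
})

test_that("planted peaks stay inside their windows; background stays clear", {
  sim <- simulate_regulatory_landscape(simulation_config(seed = 19))
  planted <- sim$tf_peaks[sim$tf_peaks$origin == "planted", ]
  for (i in seq_len(nrow(planted))) {
    r <- sim$regions[sim$regions$mir_id == planted$mir_id[[i]] &
                       sim$regions$region_type == planted$region_origin[[i]], ]
    expect_true(planted$start[[i]] >= r$start && planted$end[[i]] <= r$end)
  }
  bg <- sim$tf_peaks[sim$tf_peaks$origin == "background", ]
  if (nrow(bg) > 0) {
    pad <- sim$regions
    pad$start <- pad$start - 1L
    pad$end <- pad$end + 1L
    for (i in seq_len(nrow(bg))) {
      expect_equal(bf_count_overlaps(bg[i, ], pad), 0L)
    }
  }
})

test_that("planted peaks are pairwise disjoint within each miRNA's windows", {
  sim <- simulate_regulatory_landscape(simulation_config(seed = 20))
  planted <- sim$tf_peaks[sim$tf_peaks$origin == "planted", ]
  for (id in unique(planted$mir_id)) {
    p <- planted[planted$mir_id == id, ]
    p <- p[order(p$start), ]
    if (nrow(p) > 1) expect_true(all(p$start[-1] > p$end[-nrow(p)]))
  }
})

test_that("infeasible configurations fail loudly", {
  expect_error(simulation_config(seed = 1, planted_count_range = c(0L, 40L)),
               "exhaust")
  expect_error(simulation_config(seed = 1, fraction_intronic = 2),
               "fraction_intronic")
  expect_error(
    simulate_regulatory_landscape(
      simulation_config(seed = 1, n_genes = 12, n_mirnas = 12,
                        mirna_names = paste0("m", 1:12))),
    "infeasible|exceed")
})

test_that("CT simulation is deterministic and honors planted hemolysis", {
  q <- default_qpcr_config()
  q$hemolysis_fraction <- 0.5
  a <- simulate_ct_table(q, seed = 4)
  b <- simulate_ct_table(q, seed = 4)
  expect_identical(a, b)
  expect_false(identical(a$ct$ct, simulate_ct_table(q, seed = 5)$ct$ct))
  expect_equal(sum(a$truth$hemolysed), 20)  # 0.5 * 40 samples, exactly
  qc <- hemolysis_qc(a$ct)
  expect_setequal(qc$sample_id[!qc$passed],
                  a$truth$sample_id[a$truth$hemolysed])
})

test_that("noise-free CT tables recover configured group means exactly", {
  q <- default_qpcr_config()
  q$target_delta_ct_sd <- c(HC = 0, MG = 0)
  q$reference_ct_sd <- 0
  simct <- simulate_ct_table(q, seed = 2)
  e <- relative_expression(simct$ct, q$target, q$references)
  expect_equal(e$delta_ct[e$group == "HC"], rep(6, 20))
  expect_equal(e$delta_ct[e$group == "MG"], rep(4, 20))
  expect_error(simulate_ct_table(within(q, n_per_group <- c(HC = 1, MG = 5))),
               "n_per_group")
})

test_that("written fixture bundles read back consistently", {
  sim <- simulate_regulatory_landscape(simulation_config(seed = 13))
  dir <- withr::local_tempdir()
  write_landscape(sim, dir)
  peaks <- read_peaks(file.path(dir, "tf_peaks.bed"), "bed6")
  expect_equal(nrow(peaks), nrow(sim$tf_peaks))
  expect_equal(peaks$start, sim$tf_peaks$start)
  expect_equal(peaks$label, sim$tf_peaks$label)
  histone <- read_peaks(file.path(dir, "histone_peaks.broadPeak"), "broadPeak")
  expect_equal(nrow(histone), nrow(sim$histone_peaks))
  genome <- read_fasta(file.path(dir, "genome.fa"))
  expect_identical(genome, sim$genome)
  truth_occ <- readr::read_tsv(file.path(dir, "truth_occupancy.tsv"),
                               show_col_types = FALSE)
  expect_equal(nrow(truth_occ), nrow(sim$truth$occupancy))
})
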