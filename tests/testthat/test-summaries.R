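mk_occ <- function(entries, dedup = NULL) {
  entries <- tibble::as_tibble(entries)
  if (is.null(dedup)) {
    dedup <- entries |>
      dplyr::group_by(mir_id, tf) |>
      dplyr::summarise(n_sites = sum(n_sites), .groups = "drop")
  }
  structure(list(entries = entries, dedup_totals = dedup,
                 meta = list(merge_cell_lines = TRUE,
                             tfs = sort(unique(entries$tf)),
                             n_regions = nrow(entries))),
            class = "mg_occupancy")
}

test_that("family aggregation is additive over members", {
  occ <- mk_occ(tibble::tibble(
    mir_id = "m1", region_type = "mir_promoter",
    tf = c("FoxA1", "FoxA2", "RELA"), n_sites = c(3L, 2L, 4L)))
  s <- suppressMessages(aggregate_by_family(occ))
  expect_equal(s$per_family$total[s$per_family$family == "FOXO_group"], 5)
  expect_equal(s$per_family$total[s$per_family$family == "NFKB"], 4)
  # empty family contributes zero
  expect_equal(s$per_family$total[s$per_family$family == "IRF"], 0)
})

test_that("family sums plus unassigned conserve the grand total", {
  withr::local_seed(431)
  for (rep in 1:20) {
    tfs <- paste0("TF", 1:10)
    entries <- tidyr::crossing(mir_id = c("m1", "m2", "m3"),
                               region_type = c("mir_promoter", "mir_enhancer"),
                               tf = tfs) |>
      dplyr::mutate(n_sites = sample(0:5, dplyr::n(), replace = TRUE))
    # random partition of a random subset of TFs into 3 families
    members <- sample(tfs, 6)
    fam <- split(members, rep(1:3, each = 2))
    names(fam) <- paste0("F", 1:3)
    s <- suppressMessages(aggregate_by_family(mk_occ(entries), fam))
    expect_equal(sum(s$per_family$total), sum(entries$n_sites))
    # brute-force re-summation per family
    for (f in names(fam)) {
      expect_equal(s$per_family$total[s$per_family$family == f],
                   sum(entries$n_sites[entries$tf %in% fam[[f]]]))
    }
  }
})

test_that("a TF in two families is rejected at map validation", {
  occ <- mk_occ(tibble::tibble(mir_id = "m1", region_type = "mir_promoter",
                               tf = "A", n_sites = 1L))
  expect_error(aggregate_by_family(occ, list(f1 = "A", f2 = c("A", "B"))),
               "more than one family")
})

test_that("subtype comparison reproduces planted per-subtype family counts", {
  sim <- simulate_regulatory_landscape(simulation_config(seed = 17))
  regions <- build_regions(sim$annotation, chrom_sizes = sim$chrom_sizes)
  occ <- tabulate_occupancy(regions, sim$tf_peaks)
  s <- suppressMessages(subtype_comparison(occ))
  truth <- sim$truth$occupancy
  fam <- default_family_map()
  sub <- default_subtype_map()
  for (f in names(fam)) {
    for (st in names(sub)) {
      want <- sum(truth$n_sites[truth$tf %in% fam[[f]] &
                                  truth$mir_id %in% sub[[st]]])
      got <- s$per_family_per_subtype$total[
        s$per_family_per_subtype$family == f &
          s$per_family_per_subtype$subtype == st]
      expect_equal(got, want, info = paste(f, st))
    }
  }
})

test_that("singleton subtypes equal that miRNA's counts; order is irrelevant", {
  entries <- tidyr::crossing(mir_id = c("miR-21-5p", "miR-150-5p"),
                             region_type = "mir_promoter",
                             tf = c("FoxA1", "RELA")) |>
    dplyr::mutate(n_sites = c(2L, 3L, 1L, 4L))
  occ <- mk_occ(entries)
  sub <- list(one = "miR-21-5p", other = "miR-150-5p")
  s <- suppressMessages(subtype_comparison(occ, sub))
  one <- sum(entries$n_sites[entries$mir_id == "miR-21-5p"])
  expect_equal(sum(s$per_family_per_subtype$total[
    s$per_family_per_subtype$subtype == "one"]), one)
  # permuting input rows changes nothing
  occ2 <- mk_occ(entries[sample.int(nrow(entries)), ])
  s2 <- suppressMessages(subtype_comparison(occ2, sub))
  expect_equal(as.data.frame(s$per_family_per_subtype),
               as.data.frame(s2$per_family_per_subtype))
})

test_that("subtype maps are validated against the table and each other", {
  occ <- mk_occ(tibble::tibble(mir_id = "m1", region_type = "mir_promoter",
                               tf = "A", n_sites = 1L))
  expect_error(suppressMessages(subtype_comparison(occ, list(s1 = "m1", s2 = "mX"))),
               "absent.*mX")
  expect_error(subtype_comparison(occ, list(s1 = "m1", s2 = "m1")),
               "more than one subtype")
})

test_that("top occupancy ranks by dedup totals with lexicographic ties", {
  occ <- mk_occ(
    tibble::tibble(mir_id = "m1", region_type = "mir_promoter",
                   tf = c("A", "B", "C"), n_sites = c(5L, 7L, 7L)))
  top <- top_occupancy(occ, 2)
  expect_equal(top$tf, c("B", "C"))
  expect_equal(top$total, c(7L, 7L))
  expect_message(all_tfs <- top_occupancy(occ, 10), "only 3")
  expect_equal(nrow(all_tfs), 3)
  expect_equal(top_occupancy(occ, 1)$tf, "B")
  # agreement with a full-sort oracle on random tables
  withr::local_seed(432)
  for (rep in 1:10) {
    entries <- tidyr::crossing(mir_id = c("m1", "m2"),
                               region_type = "mir_promoter",
                               tf = paste0("TF", 1:8)) |>
      dplyr::mutate(n_sites = sample(0:9, dplyr::n(), replace = TRUE))
    occ <- mk_occ(entries)
    totals <- tapply(occ$dedup_totals$n_sites, occ$dedup_totals$tf, sum)
    want <- names(totals)[order(-totals, names(totals))][1:3]
    expect_equal(top_occupancy(occ, 3)$tf, want)
  }
})

test_that("summary generation is a pure function of its inputs", {
  sim <- simulate_regulatory_landscape(simulation_config(seed = 17))
  regions <- build_regions(sim$annotation, chrom_sizes = sim$chrom_sizes)
  occ <- tabulate_occupancy(regions, sim$tf_peaks)
  s1 <- suppressMessages(subtype_comparison(occ))
  s2 <- suppressMessages(subtype_comparison(occ))
  expect_identical(s1$per_family_per_subtype, s2$per_family_per_subtype)
  expect_identical(s1$rankings, s2$rankings)
})
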