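test_that("promoter windows sit directly upstream on the correct strand", {
  plus <- promoter_window(genomic_intervals("chr1", 10000, 10090, "+"))
  expect_equal(c(plus$start, plus$end), c(8000L, 10000L))
  minus <- promoter_window(genomic_intervals("chr1", 10000, 10090, "-"))
  expect_equal(c(minus$start, minus$end), c(10090L, 12090L))
  clipped <- promoter_window(genomic_intervals("chr1", 500, 600, "+"))
  expect_equal(c(clipped$start, clipped$end), c(0L, 500L))
  expect_error(promoter_window(genomic_intervals("chr1", 0, 10, "*")),
               "strand convention")
  expect_error(promoter_window(genomic_intervals("chr1", 0, 10, "+"), size_bp = 0),
               "size_bp")
})

test_that("promoter windows abut the locus body for random loci on both strands", {
  withr::local_seed(411)
  loci <- random_intervals(200, max_coord = 100000, max_len = 200)
  loci$strand <- sample(c("+", "-"), 200, replace = TRUE)
  loci$start <- loci$start + 3000L  # keep clear of the origin clip
  loci$end <- loci$end + 3000L
  win <- promoter_window(loci)
  plus <- loci$strand == "+"
  expect_true(all(win$end[plus] == loci$start[plus]))
  expect_true(all(win$start[plus] == loci$start[plus] - 2000L))
  expect_true(all(win$start[!plus] == loci$end[!plus]))
  expect_true(all(win$end[!plus] == loci$end[!plus] + 2000L))
  # windows never overlap the locus body
  expect_false(any(interval_overlaps(win, loci)))
})

test_that("enhancer windows are symmetric, contain the locus, and grow monotonely", {
  e <- enhancer_window(genomic_intervals("chr1", 10000, 10090, "+"))
  expect_equal(c(e$start, e$end), c(0L, 20090L))
  e2 <- enhancer_window(genomic_intervals("chr2", 50000, 50100, "*"))
  expect_equal(c(e2$start, e2$end), c(40000L, 60100L))
  # size 0 degenerates to the locus itself
  locus <- genomic_intervals("chr1", 12345, 12400, "+")
  e0 <- enhancer_window(locus, size_bp = 0)
  expect_equal(e0[, c("start", "end")], locus[, c("start", "end")])
  # monotone in size, always containing the locus
  withr::local_seed(412)
  loci <- random_intervals(50, max_coord = 100000)
  last <- enhancer_window(loci, 0)
  for (s in c(100, 1000, 5000, 10000)) {
    cur <- enhancer_window(loci, s)
    expect_true(all(cur$start <= last$start & cur$end >= last$end))
    expect_true(all(cur$start <= loci$start & cur$end >= loci$end))
    last <- cur
  }
})

test_that("host-gene assignment requires full intronic containment", {
  genes <- tibble::tibble(gene_id = "G1", chrom = "chr1", start = 1000L,
                          end = 5000L, strand = "+", biotype = "pc")
  exons <- tibble::tibble(gene_id = "G1", chrom = "chr1",
                          start = c(1000L, 4000L), end = c(1200L, 5000L))
  intronic <- tibble::tibble(mir_id = "m1", chrom = "chr1",
                             start = 1500L, end = 1600L, strand = "+")
  expect_equal(find_host_gene(intronic, genes, exons)$host_gene_id, "G1")
  exonic <- tibble::tibble(mir_id = "m2", chrom = "chr1",
                           start = 1100L, end = 1150L, strand = "+")
  expect_true(is.na(find_host_gene(exonic, genes, exons)$host_gene_id))
  # exon-less genes are intron-free
  expect_true(is.na(find_host_gene(intronic, genes, exons[0, ])$host_gene_id))
})

test_that("among nested hosts the shortest gene wins, ties lexicographically", {
  genes <- tibble::tibble(
    gene_id = c("GBIG", "GB", "GA"), chrom = "chr1",
    start = c(0L, 1000L, 1000L), end = c(10000L, 3000L, 3000L),
    strand = "+", biotype = "pc")
  exons <- tibble::tibble(
    gene_id = c("GBIG", "GBIG", "GB", "GB", "GA", "GA"), chrom = "chr1",
    start = c(0L, 9000L, 1000L, 2800L, 1000L, 2800L),
    end = c(100L, 10000L, 1100L, 3000L, 1100L, 3000L))
  m <- tibble::tibble(mir_id = "m", chrom = "chr1", start = 1500L, end = 1550L,
                      strand = "+")
  expect_equal(find_host_gene(m, genes, exons)$host_gene_id, "GA")
})

test_that("host assignment matches the per-base intron-membership oracle", {
  withr::local_seed(413)
  sim <- simulate_regulatory_landscape(simulation_config(seed = 21))
  ann <- sim$annotation
  for (rep in 1:200) {
    g <- ann$genes[sample.int(nrow(ann$genes), 1), ]
    len <- sample(50:150, 1)
    start <- g$start - 2000L + sample.int(g$end - g$start + 4000L, 1)
    probe <- tibble::tibble(mir_id = "probe", chrom = g$chrom,
                            start = start, end = start + len, strand = "+")
    got <- find_host_gene(probe, ann$genes, ann$exons)$host_gene_id
    labels <- vapply(seq(start, start + len - 1L), bf_base_label,
                     character(1), chrom = g$chrom, gene = g, exons = ann$exons)
    # oracle: hosted by G iff every base of the probe is intronic in G
    expect_equal(identical(got, g$gene_id), all(labels == "intron"),
                 info = sprintf("gene %s probe [%d,%d)", g$gene_id, start,
                                start + len))
  }
})

test_that("region sets have two windows for intergenic, four for intronic miRNAs", {
  sim <- simulate_regulatory_landscape(simulation_config(seed = 17))
  regions <- build_regions(sim$annotation, chrom_sizes = sim$chrom_sizes)
  sizes <- table(regions$mir_id)
  truth <- sim$truth$hosts
  for (i in seq_len(nrow(truth))) {
    expect_equal(unname(sizes[[truth$mir_id[[i]]]]),
                 if (truth$intronic[[i]]) 4L else 2L)
  }
  per_mir <- split(regions$region_type, regions$mir_id)
  for (rt in per_mir) {
    expect_equal(sum(rt == "mir_promoter"), 1)
    expect_equal(sum(rt == "mir_enhancer"), 1)
  }
})
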