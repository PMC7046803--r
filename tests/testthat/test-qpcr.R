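ct_row <- function(sample_id, assay, ct, group = NULL) {
  d <- tibble::tibble(sample_id = sample_id, assay = assay, ct = ct)
  if (!is.null(group)) d$group <- group
  d
}

test_that("hemolysis delta-CT and the >7 exclusion boundary are exact", {
  qc <- hemolysis_qc(ct_row("s1", c("miR-23a-3p", "miR-451a"), c(25, 20)))
  expect_equal(qc$delta_ct_hemolysis, 5)
  expect_true(qc$passed)
  qc2 <- hemolysis_qc(ct_row("s2", c("miR-23a-3p", "miR-451a"), c(28, 20)))
  expect_false(qc2$passed)
  # a delta of exactly 7.0 passes (">7" is a strict exclusion)
  qc3 <- hemolysis_qc(ct_row("s3", c("miR-23a-3p", "miR-451a"), c(27, 20)))
  expect_equal(qc3$delta_ct_hemolysis, 7)
  expect_true(qc3$passed)
})

test_that("hemolysis QC is monotone in the miR-23a CT", {
  withr::local_seed(441)
  for (rep in 1:30) {
    base <- runif(1, 15, 30)
    d1 <- runif(1, 0, 10); d2 <- d1 + runif(1, 0, 5)
    lo <- hemolysis_qc(ct_row("s", c("miR-23a-3p", "miR-451a"), c(base + d1, base)))
    hi <- hemolysis_qc(ct_row("s", c("miR-23a-3p", "miR-451a"), c(base + d2, base)))
    expect_false(!lo$passed && hi$passed)
  }
})

test_that("samples missing a marker are flagged un-assessable", {
  ct <- dplyr::bind_rows(
    ct_row("s1", c("miR-23a-3p", "miR-451a"), c(25, 20)),
    ct_row("s2", "miR-23a-3p", 25))
  expect_message(qc <- hemolysis_qc(ct), "un-assessable")
  expect_true(is.na(qc$passed[qc$sample_id == "s2"]))
  expect_error(hemolysis_qc(ct_row("s1", "miR-23a-3p", -3)), "non-positive")
})

test_that("comparative CT gives 2^(-dCT) against the mean reference", {
  ct <- ct_row("s1", c("miR-21-5p", "r1", "r2"), c(25, 20, 22))
  e <- relative_expression(ct, "miR-21-5p", c("r1", "r2"))
  expect_equal(e$delta_ct, 4)
  expect_equal(e$value, 0.0625)
  expect_equal(e$log_value, log10(0.0625))
  # target equal to its single reference -> unit expression
  e2 <- relative_expression(ct_row("s", c("t", "r"), c(21, 21)), "t", "r")
  expect_equal(e2$value, 1)
  expect_error(relative_expression(ct, "miR-21-5p", character()), "reference")
})

test_that("relative expression matches an independent exp2 recomputation", {
  withr::local_seed(442)
  for (rep in 1:100) {
    n_ref <- sample(1:4, 1)
    cts <- runif(n_ref + 1, 15, 35)
    ct <- ct_row("s", c("tgt", paste0("r", seq_len(n_ref))), cts)
    got <- relative_expression(ct, "tgt", paste0("r", seq_len(n_ref)))
    want <- 2^(-(cts[[1]] - sum(cts[-1]) / n_ref))
    expect_equal(got$value, want)
  }
})

test_that("relative expression is invariant to a common CT shift", {
  withr::local_seed(443)
  for (rep in 1:20) {
    cts <- runif(4, 18, 30)
    shift <- runif(1, -5, 5)
    a <- relative_expression(ct_row("s", c("t", "r1", "r2", "r3"), cts),
                             "t", c("r1", "r2", "r3"))
    b <- relative_expression(ct_row("s", c("t", "r1", "r2", "r3"), cts + shift),
                             "t", c("r1", "r2", "r3"))
    expect_equal(a$value, b$value)
  }
})

test_that("technical replicates collapse by mean CT before quantification", {
  ct <- tibble::tibble(sample_id = "s1",
                       assay = c("t", "t", "r"), ct = c(24, 26, 20),
                       replicate = c(1L, 2L, 1L))
  e <- relative_expression(ct, "t", "r")
  expect_equal(e$delta_ct, 5)
})

test_that("fold changes follow mean ratios and planted ddCT", {
  expect_equal(fold_change(c(2, 2), c(1, 1)), 2)
  expect_equal(fold_change(c(3, 5), c(3, 5)), 1)
  expect_error(fold_change(numeric(), 1), "non-empty")
  expect_error(fold_change(c(1, -1), c(1, 1)), "positive")
  # noise-free simulated table with a planted ddCT of -3 -> fold 8
  q <- default_qpcr_config()
  q$target_delta_ct_mean <- c(HC = 6, MG = 3)
  q$target_delta_ct_sd <- c(HC = 0, MG = 0)
  q$reference_ct_sd <- 0
  q$hemolysis_fraction <- 0
  simct <- simulate_ct_table(q, seed = 9)
  e <- relative_expression(simct$ct, q$target, q$references)
  expect_equal(fold_change(e$value[e$group == "MG"], e$value[e$group == "HC"]), 8)
})

test_that("two-group comparison reduces to an unpaired t-test", {
  d <- tibble::tibble(log_value = c(1, 2, 3, 1, 2, 3),
                      group = rep(c("a", "b"), each = 3))
  cmp <- compare_groups(d)
  expect_equal(cmp$meta$design, "two_group")
  expect_equal(cmp$pairwise$statistic, 0)
  expect_equal(cmp$pairwise$p.value, 1)
  ref <- t.test(c(1, 2, 3) + 1, c(1, 2, 3))
  d2 <- tibble::tibble(log_value = c(2, 3, 4, 1, 2, 3),
                       group = rep(c("a", "b"), each = 3))
  cmp2 <- compare_groups(d2)
  expect_equal(cmp2$pairwise$statistic, unname(ref$statistic))
  expect_equal(cmp2$pairwise$p.value, ref$p.value)
})

test_that("multi-group designs run ANOVA then all pairwise t-tests", {
  withr::local_seed(444)
  d <- tibble::tibble(log_value = rnorm(30), group = rep(c("a", "b", "c"), 10))
  cmp <- compare_groups(d)
  expect_equal(cmp$meta$design, "multi_group")
  expect_equal(nrow(cmp$pairwise), 3)
  ref <- summary(aov(log_value ~ factor(group), data = d))[[1]]
  expect_equal(cmp$anova$statistic, ref[["F value"]][[1]])
  expect_equal(cmp$anova$p.value, ref[["Pr(>F)"]][[1]])
  expect_equal(glance(cmp)$method, "one-way ANOVA")
  expect_equal(nrow(tidy(cmp)), 3)
  expect_equal(cmp$descriptives$n, rep(10L, 3))
})

test_that("degenerate group inputs are rejected", {
  expect_error(compare_groups(tibble::tibble(log_value = 1:4, group = "a")),
               "2 groups")
  expect_error(compare_groups(tibble::tibble(log_value = 1:3,
                                             group = c("a", "a", "b"))),
               ">= 2 values")
  expect_error(compare_groups(tibble::tibble(log_value = rep(1, 6),
                                             group = rep(c("a", "b"), 3))),
               "zero variance")
})

test_that("Spearman helper recovers monotone association", {
  d <- tibble::tibble(x = 1:20, y = (1:20)^3)
  r <- correlate_spearman(d, "x", "y")
  expect_equal(r$estimate, 1)
  expect_equal(r$n, 20L)
  d2 <- tibble::tibble(x = 1:20, y = -(1:20))
  expect_equal(correlate_spearman(d2, "x", "y")$estimate, -1)
})

test_that("a processed CT table yields identical reports on reprocessing", {
  q <- default_qpcr_config()
  simct <- simulate_ct_table(q, seed = 3)
  e1 <- relative_expression(simct$ct, q$target, q$references)
  e2 <- relative_expression(simct$ct, q$target, q$references)
  expect_identical(e1, e2)
  c1 <- compare_groups(e1)
  c2 <- compare_groups(e2)
  expect_identical(c1$pairwise, c2$pairwise)
})
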