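make_ctrl_stack <- function(pos, neg_mean, neg_sd_vals) {
  # one probe with 4 replicate pos/neg control measurements
  tibble::tibble(
    probe = "p1",
    sample = rep(c("pos_control", "neg_control"), each = 4),
    replicate = rep(1:4, 2),
    intensity = c(rep(pos, 4), neg_mean + neg_sd_vals)
  )
}

test_that("control filter removes probes without pTyr-dependent signal", {
  # positive below negative: removed at any threshold
  s <- make_ctrl_stack(5, 10, c(-1, 1, -1, 1))
  expect_equal(filter_probes_by_controls(s, k_sd = 0)$removed$feature, "p1")
  # positive = negative + 10 sd: retained at k_sd = 2
  s2 <- make_ctrl_stack(10 + 10 * sd(c(-1, 1, -1, 1)), 10, c(-1, 1, -1, 1))
  expect_equal(filter_probes_by_controls(s2, k_sd = 2)$retained, "p1")
  # identical controls everywhere: removed
  s3 <- make_ctrl_stack(10, 10, c(0, 0, 0, 0))
  expect_equal(nrow(filter_probes_by_controls(s3, k_sd = 0)$removed), 1)
})

test_that("filter calibration finds a threshold matching a removal target", {
  panel <- fixture_panel()
  co <- fixture_cohort()
  truth <- binding_truth(panel)
  ro <- simulate_rosette(panel, co, truth, seed = 2)
  cal <- calibrate_control_filter(ro, target_removed = 26)
  expect_true(cal$exact)
  rep <- filter_probes_by_controls(ro, k_sd = cal$k_sd)
  expect_equal(nrow(rep$removed), 26)
  expect_equal(length(rep$retained), 70)
})

test_that("band filter applies both criteria on raw values", {
  # constant row: sd 0, removed
  m <- tibble::tibble(feature = "const", !!!setNames(as.list(rep(7, 22)),
                                                     paste0("s", 1:22)))
  expect_equal(filter_bands(m)$removed$feature, "const")
  # eleven 10s and eleven 0s: sample sd = sqrt(25*22/21) ~ 5.12 > 5,
  # 11 values above 5 -> retained
  vals <- c(rep(10, 11), rep(0, 11))
  m2 <- tibble::tibble(feature = "half",
                       !!!setNames(as.list(vals), paste0("s", 1:22)))
  expect_equal(sd(unlist(m2[1, -1])), sqrt(25 * 22 / 21))
  expect_equal(filter_bands(m2)$retained, "half")
  # same shape but only 10 lines above threshold -> removed
  vals3 <- c(rep(10, 10), rep(0, 12))
  m3 <- tibble::tibble(feature = "ten",
                       !!!setNames(as.list(vals3), paste0("s", 1:22)))
  expect_equal(filter_bands(m3)$removed$reason, "low_prevalence")
})

test_that("band filter is idempotent and partitions features exactly", {
  fw <- fixture_far_western()
  rep1 <- filter_bands(fw)
  kept <- apply_filter(fw, rep1)
  rep2 <- filter_bands(kept)
  expect_setequal(rep2$retained, rep1$retained)
  expect_equal(nrow(rep2$removed), 0)
  expect_setequal(c(rep1$retained, rep1$removed$feature), fw$feature)
  expect_equal(length(rep1$retained) + nrow(rep1$removed), nrow(fw))
  td <- tidy(rep1)
  expect_equal(nrow(td), nrow(fw))
})

test_that("median centering zeroes row medians and is involutive once", {
  m <- tibble::tibble(feature = c("a", "b", "c"),
                      s1 = c(1, 5, 1), s2 = c(2, 5, 3), s3 = c(3, 5, 9))
  c1 <- median_center_rows(m)
  expect_equal(unlist(c1[1, -1], use.names = FALSE), c(-1, 0, 1))
  expect_equal(unlist(c1[2, -1], use.names = FALSE), c(0, 0, 0))
  expect_identical(median_center_rows(c1), c1)
  # even sample count: midpoint convention
  m2 <- tibble::tibble(feature = "a", s1 = 1, s2 = 3)
  expect_equal(unlist(median_center_rows(m2)[1, -1], use.names = FALSE),
               c(-1, 1))
  expect_true(all(apply(binding_as_matrix(c1), 1, median) == 0))
})

test_that("replicate QC matches closed forms and flags bad correlation", {
  stack <- tibble::tibble(
    probe = rep("p", 4), sample = rep("s", 4), replicate = 1:4,
    intensity = rep(3, 4)
  )
  qc <- qc_replicates(stack)
  expect_equal(qc$line_cv$mean_cv, 0)
  # replicate 2 doubled everywhere: CV per cell = sd({x,2x})/mean = sqrt(2)/3
  st2 <- tibble::tibble(
    probe = rep(c("a", "b"), each = 2 * 3),
    sample = rep(rep(paste0("s", 1:3), each = 2), 2),
    replicate = rep(1:2, 6),
    intensity = rep(c(4, 8, 6, 12, 2, 4), 2)
  )
  qc2 <- qc_replicates(st2, rep_pair = c(1, 2))
  expect_equal(unique(round(qc2$line_cv$mean_cv, 10)),
               round(sqrt(2) / 3, 10))
  expect_true(all(qc2$replicate_cor$r == 1))
  # anti-correlated replicates get flagged
  st3 <- tibble::tibble(
    probe = rep("z", 6),
    sample = rep(paste0("s", 1:3), each = 2),
    replicate = rep(1:2, 3),
    intensity = c(1, 9, 5, 5, 9, 1)
  )
  qc3 <- qc_replicates(st3)
  expect_true(qc3$replicate_cor$flagged)
})

test_that("normality QC reports p-values and degenerate rows as missing", {
  set.seed(42)
  m <- binding_as_tibble(rbind(
    normal = rnorm(22, 10, 2),
    constant = rep(4, 22)
  ))
  colnames(m)[-1] <- paste0("s", 1:22)
  q <- qc_normality(m)
  expect_true(q$p_normality[1] > 0 && q$p_normality[1] <= 1)
  expect_true(is.na(q$p_normality[2]))
  tiny <- binding_as_tibble(matrix(c(1, 2), 1,
                                   dimnames = list("f", c("a", "b"))))
  expect_true(is.na(qc_normality(tiny)$p_normality))
})

test_that("normality p-values are uniform for Gaussian features", {
  set.seed(7)
  m <- matrix(rnorm(300 * 22), 300, 22,
              dimnames = list(paste0("f", 1:300), paste0("s", 1:22)))
  p <- qc_normality(binding_as_tibble(m))$p_normality
  ks <- suppressWarnings(ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("activation categories follow the marker-specific cutoffs", {
  v <- setNames(c(100, 60, 25, 10, 4), paste0("L", 1:5))
  met <- categorize_activation(v, "MET")
  expect_equal(met$category, c("positive", "positive", "intermediate",
                               "negative", "negative"))
  pt <- categorize_activation(v, "pTyr_MW194")
  expect_equal(pt$category, c("positive", "positive", "intermediate",
                              "intermediate", "negative"))
  # boundaries belong to the intermediate class
  vb <- setNames(c(100, 50, 25), paste0("L", 1:3))
  expect_equal(categorize_activation(vb, "MET")$category,
               c("positive", "intermediate", "intermediate"))
  # categories partition [0, 100]
  grid <- setNames(c(100, seq(0, 100, by = 0.5)),
                   paste0("g", 0:201))
  cats <- categorize_activation(grid, "MET")$category
  expect_true(all(cats %in% c("negative", "intermediate", "positive")))
})
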