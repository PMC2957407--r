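test_that("exact Mann-Whitney p matches hand enumeration on the toy case", {
  m <- binding_as_tibble(matrix(c(1, 2, 3, 10, 11, 12), 1,
                                dimnames = list("f", paste0("s", 1:6))))
  labels <- setNames(c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
                     paste0("s", 1:6))
  res <- mann_whitney_screen(m, labels)
  expect_equal(res$p, 0.1)  # 2 / C(6,3) by enumeration of 20 arrangements
  expect_equal(res$direction, "lower_in_positive")
  # identical groups -> p = 1
  m2 <- binding_as_tibble(matrix(c(1, 2, 3, 1, 2, 3), 1,
                                 dimnames = list("f", paste0("s", 1:6))))
  expect_equal(suppressWarnings(mann_whitney_screen(m2, labels)$p), 1)
  # rank test: invariant under monotone transform
  m3 <- m
  m3[1, -1] <- log(m3[1, -1])
  expect_equal(mann_whitney_screen(m3, labels)$p, res$p)
})

test_that("exact path equals the enumeration oracle for n1+n2 <= 10", {
  set.seed(31)
  for (n1 in 2:5) {
    for (n2 in 2:min(5, 10 - n1)) {
      x <- rnorm(n1)
      y <- rnorm(n2, 1)
      p_pkg <- suppressWarnings(
        stats::wilcox.test(x, y, exact = TRUE)$p.value
      )
      expect_equal(p_pkg, mw_exact_enumeration(x, y), tolerance = 1e-12,
                   info = sprintf("n1=%d n2=%d", n1, n2))
      # and the screen takes the exact route for these sizes
      m <- binding_as_tibble(matrix(c(x, y), 1,
                                    dimnames = list("f",
                                                    paste0("s", 1:(n1 + n2)))))
      lab <- setNames(rep(c(TRUE, FALSE), c(n1, n2)),
                      paste0("s", 1:(n1 + n2)))
      expect_equal(mann_whitney_screen(m, lab)$p,
                   mw_exact_enumeration(x, y), tolerance = 1e-12)
    }
  }
})

test_that("U statistics complement: U + U' = n1*n2", {
  set.seed(5)
  x <- rnorm(7); y <- rnorm(15)
  m <- binding_as_tibble(matrix(c(x, y), 1,
                                dimnames = list("f", paste0("s", 1:22))))
  lab <- setNames(rep(c(TRUE, FALSE), c(7, 15)), paste0("s", 1:22))
  u_pos <- mann_whitney_screen(m, lab)$statistic
  u_neg <- mann_whitney_screen(m, !lab)$statistic
  expect_equal(u_pos + u_neg, 7 * 15)
})

test_that("q-values reduce to Benjamini-Hochberg with pi0 = 1", {
  q <- estimate_qvalues(c(0.02, 0.04, 0.9), pi0 = 1)
  expect_equal(as.numeric(q), c(0.06, 0.06, 0.9))
  expect_equal(as.numeric(q), unname(p.adjust(c(0.02, 0.04, 0.9), "BH")))
  # single p: q = pi0 * p
  expect_equal(as.numeric(estimate_qvalues(0.03, pi0 = 1)), 0.03)
  expect_equal(as.numeric(estimate_qvalues(0.03, pi0 = 0.5)), 0.015)
  # agreement with p.adjust on random vectors
  set.seed(12)
  p <- runif(500)
  expect_equal(as.numeric(estimate_qvalues(p, pi0 = 1)),
               unname(p.adjust(p, "BH")))
  # monotone in ranked p, capped at 1
  q2 <- as.numeric(estimate_qvalues(p, pi0 = 1))
  expect_true(all(diff(q2[order(p)]) >= -1e-12))
  expect_true(max(q2) <= 1)
  expect_error(estimate_qvalues(numeric(0)), "empty")
  expect_error(estimate_qvalues(c(0.5, 1.2)), "0, 1")
})

test_that("pi0 smoother is near 1 on uniform p-values", {
  set.seed(77)
  p <- runif(1000)
  q <- estimate_qvalues(p)
  expect_equal(attr(q, "pi0"), 1, tolerance = 0.1)
  # short vectors fall back to BH
  q_short <- estimate_qvalues(runif(50))
  expect_equal(attr(q_short, "pi0"), 1)
})

test_that("significant_features filters at q_max and sorts by p", {
  rec <- tibble::tibble(
    feature = c("a", "b", "c"),
    p = c(0.9, 0.001, 0.002)
  )
  hits <- significant_features(rec, q_max = 0.1, pi0 = 1)
  expect_equal(hits$feature, c("b", "c"))
  expect_true(all(diff(hits$p) >= 0))
  none <- significant_features(tibble::tibble(feature = "a", p = 0.9),
                               q_max = 0.1, pi0 = 1)
  expect_equal(nrow(none), 0)
  allrec <- attr(hits, "all_records")
  expect_equal(nrow(allrec), 3)
})

test_that("Pearson screen uses ln IC50 and flags |r| > 0.5", {
  ic50 <- setNames(exp(seq(1, 4, length.out = 10)), paste0("s", 1:10))
  m <- binding_as_tibble(rbind(
    prop = log(ic50),          # r = 1
    anti = -log(ic50),         # r = -1
    flat = rep(2, 10)          # undefined
  ))
  colnames(m)[-1] <- names(ic50)
  res <- pearson_screen(m, ic50)
  expect_equal(res$r[1], 1)
  expect_equal(res$r[2], -1)
  expect_true(is.na(res$r[3]))
  expect_equal(res$flagged, c(TRUE, TRUE, FALSE))
  # affine invariance with positive slope
  m2 <- m
  m2[1, -1] <- 3 * m2[1, -1] + 7
  expect_equal(pearson_screen(m2, ic50)$r[1], 1)
  expect_error(pearson_screen(m, setNames(rep(-1, 10), names(ic50))),
               "positive")
})

test_that("null screens keep the called fraction under the FDR target", {
  panel <- fixture_panel()
  co <- fixture_cohort()
  truth0 <- binding_truth(panel, egfr_delta = 0, ras_delta = 0,
                          met_delta = 0)
  egfr <- setNames(co$egfr == "mutant", co$line_id)
  frac <- vapply(1:30, function(s) {
    ro <- simulate_rosette(panel, co, truth0, seed = 3000 + s)
    av <- average_replicates(ro)
    m <- av[, !names(av) %in% c("pos_control", "neg_control")]
    sc <- mann_whitney_screen(m, egfr)
    hits <- significant_features(sc, q_max = 0.1, pi0 = 1)
    nrow(hits) / nrow(sc)
  }, numeric(1))
  expect_lte(mean(frac), 0.1)
})

test_that("MET dichotomization folds intermediate into the low group", {
  met <- c(a = "positive", b = "intermediate", c = "negative")
  hi <- dichotomize_met(met)
  expect_equal(unname(hi), c(TRUE, FALSE, FALSE))
  expect_equal(names(hi), c("a", "b", "c"))
  expect_error(dichotomize_met(c("weird")))
})
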