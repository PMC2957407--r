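# Shared fixtures, all generated in code under fixed seeds.

fixture_panel <- function() sh2_panel()

fixture_cohort <- function(seed = 1) make_cohort(22, 7, 9, 6, seed = seed)

# Deposited-style far-Western matrix: 36 probes x 20 bins = 720 bands over
# 22 lines, from the seeded lane simulator + binning pipeline.
fixture_far_western <- function(seed = 20101026) {
  panel <- fixture_panel()
  cohort <- fixture_cohort(1)
  truth <- binding_truth(panel)
  dep <- setdiff(
    panel$probe[!panel$probe_class %in% c("GST_control", "actin_antibody")],
    truth$low_signal
  )
  lanes <- simulate_lanes(panel, cohort, truth, probes = dep[1:36],
                          seed = seed)
  quantify_lanes(lanes)
}

# Small noiseless rosette for exact-recovery checks.
fixture_rosette_exact <- function(n_replicates = 1, seed = 5) {
  panel <- fixture_panel()
  cohort <- fixture_cohort(1)
  truth <- binding_truth(panel, noise_sd = 0, line_sd = 0)
  list(panel = panel, cohort = cohort, truth = truth,
       rosette = simulate_rosette(panel, cohort, truth,
                                  n_replicates = n_replicates, seed = seed))
}

# Brute-force complete-linkage agglomeration: independent oracle for the
# clustering route. Returns the sorted merge heights.
bf_complete_heights <- function(d) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        h <- max(d[clusters[[i]], clusters[[j]]])
        if (h < best[1]) best <- c(h, i, j)
      }
    }
    heights <- c(heights, best[1])
    i <- best[2]; j <- best[3]
    clusters[[i]] <- c(clusters[[i]], clusters[[j]])
    clusters[[j]] <- NULL
  }
  sort(heights)
}

# Pairwise uncentered-correlation distances computed independently of the
# package's vectorised route.
bf_uncentered_dist <- function(m) {
  n <- nrow(m)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      d[i, j] <- 1 - sum(m[i, ] * m[j, ]) /
        (sqrt(sum(m[i, ]^2)) * sqrt(sum(m[j, ]^2)))
    }
  }
  d
}
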