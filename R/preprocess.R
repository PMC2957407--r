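new_filter_report <- function(retained, removed, reasons, thresholds) {
  stopifnot(length(removed) == length(reasons),
            length(intersect(retained, removed)) == 0)
  structure(list(
    retained = retained,
    removed = tibble(feature = removed, reason = reasons),
    thresholds = thresholds
  ), class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat("Filter report:", length(x$retained), "retained,",
      nrow(x$removed), "removed\n")
  th <- unlist(x$thresholds)
  cat("thresholds:", paste(names(th), th, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.filter_report <- function(x, ...) {
  dplyr::bind_rows(
    tibble(feature = x$retained, retained = TRUE, reason = NA_character_),
    tibble(feature = x$removed$feature, retained = FALSE,
           reason = x$removed$reason)
  )
}

#' Remove low-signal probes using the control samples
#'
#' A probe is removed when its mean positive-control intensity does not
#' exceed its mean negative-control intensity by more than `k_sd` negative
#' -control standard deviations: such probes show no phosphotyrosine-
#' dependent signal above background. Probes whose positive control falls
#' below the negative control are always removed (at any `k_sd >= 0`).
#'
#' @param stack Long replicate tibble (`probe`, `sample`, `replicate`,
#'   `intensity`) containing the two control samples.
#' @param positive,negative Sample ids of the pervanadate-treated positive
#'   and phosphatase-treated negative control columns.
#' @param k_sd Threshold multiplier on the negative-control replicate sd.
#' @return A `filter_report` (retained/removed probe ids, thresholds).
#' @export
filter_probes_by_controls <- function(stack, positive = "pos_control",
                                      negative = "neg_control", k_sd = 2) {
  stopifnot(k_sd >= 0)
  ctrl <- dplyr::filter(stack, .data$sample %in% c(positive, negative))
  if (nrow(ctrl) == 0) abort("control samples not found in stack")
  summ <- dplyr::summarise(
    dplyr::group_by(ctrl, .data$probe),
    pos_mean = mean(.data$intensity[.data$sample == positive]),
    neg_mean = mean(.data$intensity[.data$sample == negative]),
    neg_sd = stats::sd(.data$intensity[.data$sample == negative]),
    .groups = "drop"
  )
  summ$neg_sd[is.na(summ$neg_sd)] <- 0
  keep <- (summ$pos_mean - summ$neg_mean) > k_sd * summ$neg_sd
  new_filter_report(
    retained = summ$probe[keep],
    removed = summ$probe[!keep],
    reasons = rep("low_control_difference", sum(!keep)),
    thresholds = list(k_sd = k_sd, positive = positive, negative = negative)
  )
}

#' Calibrate the control-filter threshold to a target removal count
#'
#' Searches `k_sd` over a grid so that [filter_probes_by_controls()] removes
#' a requested number of probes (used to match a deposited panel size, e.g.
#' 26 of 96 probes removed leaving 70).
#'
#' @inheritParams filter_probes_by_controls
#' @param target_removed Number of probes the filter should remove.
#' @param grid Candidate `k_sd` values.
#' @return A list: `k_sd` (smallest grid value whose removal count is
#'   closest to the target), `n_removed` achieved, `exact` flag.
#' @export
calibrate_control_filter <- function(stack, target_removed,
                                     positive = "pos_control",
                                     negative = "neg_control",
                                     grid = seq(0, 50, by = 0.25)) {
  n_rm <- vapply(grid, function(k) {
    nrow(filter_probes_by_controls(stack, positive, negative, k)$removed)
  }, numeric(1))
  i <- which.min(abs(n_rm - target_removed))
  list(k_sd = grid[i], n_removed = n_rm[i],
       exact = n_rm[i] == target_removed)
}

#' Filter far-Western bands on variability and prevalence
#'
#' Retains a band only when its sample standard deviation across cell lines
#' exceeds `sd_min` AND at least `min_lines` lines have intensity above
#' `min_intensity`. Both criteria are evaluated on raw (uncentered) values;
#' the filter is idempotent.
#'
#' @param mat Wide far-Western tibble (feature column + sample columns).
#' @param sd_min Minimum sample (n-1) standard deviation, exclusive.
#' @param min_lines Minimum number of lines above `min_intensity`.
#' @param min_intensity Intensity threshold, exclusive.
#' @return A `filter_report`.
#' @export
#' @examples
#' m <- tibble::tibble(feature = c("a", "b"),
#'                     s1 = c(10, 1), s2 = c(0, 1), s3 = c(10, 1))
#' filter_bands(m, sd_min = 5, min_lines = 2, min_intensity = 5)
filter_bands <- function(mat, sd_min = 5, min_lines = 11,
                         min_intensity = 5.0) {
  m <- binding_as_matrix(mat)
  sds <- apply(m, 1, stats::sd)
  n_above <- rowSums(m > min_intensity)
  keep <- (sds > sd_min) & (n_above >= min_lines)
  reasons <- ifelse(sds <= sd_min & n_above < min_lines, "low_sd_and_prevalence",
                    ifelse(sds <= sd_min, "low_sd", "low_prevalence"))
  new_filter_report(
    retained = rownames(m)[keep],
    removed = rownames(m)[!keep],
    reasons = unname(reasons[!keep]),
    thresholds = list(sd_min = sd_min, min_lines = min_lines,
                      min_intensity = min_intensity)
  )
}

#' Subset a wide matrix to the features a filter retained
#'
#' @param mat Wide binding tibble.
#' @param report A `filter_report`.
#' @return The retained rows of `mat`, in original order.
#' @export
apply_filter <- function(mat, report) {
  dplyr::filter(mat, .data[[names(mat)[1]]] %in% report$retained)
}

#' Median-center every row of a binding matrix
#'
#' Subtracts each feature's median across samples so row medians become
#' exactly zero (the heat-map convention: values below the median probe
#' value in green, above in red). Applying it twice is a no-op.
#'
#' @param mat Wide binding tibble.
#' @return Tibble of the same shape with row medians 0.
#' @export
median_center_rows <- function(mat) {
  m <- binding_as_matrix(mat)
  centered <- m - apply(m, 1, stats::median, na.rm = TRUE)
  out <- binding_as_tibble(centered, feature_col = names(mat)[1])
  names(out) <- names(mat)
  out
}

#' Replicate-level quality control
#'
#' Computes (i) the per-line mean coefficient of variation over replicates
#' (CV = sd/mean per probe/line cell, averaged within line) and (ii) for
#' two chosen replicates, the per-feature Pearson correlation across lines;
#' features correlating below `flag_below` are flagged low-signal.
#'
#' @param stack Long replicate tibble.
#' @param rep_pair Which two replicate indices to correlate.
#' @param flag_below Correlation flag threshold.
#' @return List with `line_cv` (tibble `sample`, `mean_cv`) and
#'   `replicate_cor` (tibble `feature`, `r`, `flagged`).
#' @export
qc_replicates <- function(stack, rep_pair = c(1, 2), flag_below = 0.5) {
  feature_col <- if ("probe" %in% names(stack)) "probe" else "feature"
  cv <- dplyr::summarise(
    dplyr::group_by(stack, .data[[feature_col]], .data$sample),
    cv = stats::sd(.data$intensity) / mean(.data$intensity),
    .groups = "drop"
  )
  line_cv <- dplyr::summarise(
    dplyr::group_by(cv, .data$sample),
    mean_cv = mean(.data$cv, na.rm = TRUE), .groups = "drop"
  )
  two <- dplyr::filter(stack, .data$replicate %in% rep_pair)
  wide <- tidyr::pivot_wider(two, names_from = "replicate",
                             values_from = "intensity",
                             names_prefix = "rep")
  rc <- dplyr::summarise(
    dplyr::group_by(wide, .data[[feature_col]]),
    r = tryCatch(
      stats::cor(.data[[paste0("rep", rep_pair[1])]],
                 .data[[paste0("rep", rep_pair[2])]]),
      error = function(e) NA_real_
    ),
    .groups = "drop"
  )
  names(rc)[1] <- "feature"
  rc$flagged <- !is.na(rc$r) & rc$r < flag_below
  list(line_cv = line_cv, replicate_cor = rc)
}

#' Per-feature normality diagnostics
#'
#' Shapiro-Wilk p-value per feature across samples. Diagnostic only; never
#' used to filter. Features with fewer than 3 observed samples or constant
#' values are reported as missing.
#'
#' @param mat Wide binding tibble.
#' @return Tibble `feature`, `p_normality`.
#' @export
qc_normality <- function(mat) {
  m <- binding_as_matrix(mat)
  p <- apply(m, 1, function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 3 || stats::sd(x) == 0) return(NA_real_)
    stats::shapiro.test(x)$p.value
  })
  tibble(feature = rownames(m), p_normality = unname(p))
}

#' Categorize marker activation from percent-of-maximum signal
#'
#' Converts per-line marker quantifications (phospho-MET immunoblot signal,
#' or anti-pTyr signal in the 194 kDa bin as an EGFR-family readout) into
#' negative / intermediate / positive calls by percent of the panel maximum.
#' Cutoffs: MET positive > 50% of max, intermediate 25-50%, negative < 25%;
#' pTyr MW194 positive > 25%, intermediate 10-25%, negative < 10%.
#' Boundaries belong to the intermediate class.
#'
#' @param values Named numeric vector (names = sample ids) of marker signal.
#' @param marker `"MET"` or `"pTyr_MW194"`.
#' @param cutoffs Optional `c(lower, upper)` percent cutoffs overriding the
#'   marker defaults.
#' @return Tibble `sample`, `marker`, `percent_of_max`, `category`.
#' @export
categorize_activation <- function(values, marker = c("MET", "pTyr_MW194"),
                                  cutoffs = NULL) {
  marker <- match.arg(marker)
  if (is.null(cutoffs)) {
    cutoffs <- if (marker == "MET") c(25, 50) else c(10, 25)
  }
  stopifnot(length(cutoffs) == 2, cutoffs[1] < cutoffs[2], all(values >= 0))
  pct <- 100 * values / max(values)
  category <- dplyr::case_when(
    pct > cutoffs[2] ~ "positive",
    pct >= cutoffs[1] ~ "intermediate",
    TRUE ~ "negative"
  )
  tibble(sample = names(values), marker = marker,
         percent_of_max = unname(pct), category = unname(category))
}
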