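#' Mann-Whitney biomarker screen against a dichotomous label
#'
#' Tests every feature of a binding matrix for a distributional difference
#' between label-positive and label-negative samples with a two-sided
#' Mann-Whitney (Wilcoxon rank-sum) test. The exact null distribution is
#' used when both groups are small and the data are tie-free; otherwise the
#' tie-corrected normal approximation applies. Features where either group
#' has fewer than 2 members are skipped with a reason.
#'
#' @param mat Wide binding tibble (feature column + sample columns).
#' @param labels Logical (or 0/1) vector naming the positive group, named
#'   by sample id or ordered as the sample columns.
#' @return Tibble: `feature`, group sizes, group means and standard errors,
#'   `statistic` (U for the positive group), `p`, `direction`
#'   (`"higher_in_positive"` / `"lower_in_positive"`), `skipped_reason`.
#' @export
mann_whitney_screen <- function(mat, labels) {
  m <- binding_as_matrix(mat)
  lab <- align_labels(labels, colnames(m))
  if (sum(lab) < 2 || sum(!lab) < 2) {
    abort("both label groups need at least 2 samples")
  }
  rows <- purrr::map(seq_len(nrow(m)), function(i) {
    x <- m[i, lab]; y <- m[i, !lab]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (length(x) < 2 || length(y) < 2) {
      return(tibble(
        feature = rownames(m)[i], n_pos = length(x), n_neg = length(y),
        mean_pos = NA_real_, mean_neg = NA_real_, se_pos = NA_real_,
        se_neg = NA_real_, statistic = NA_real_, p = NA_real_,
        direction = NA_character_, skipped_reason = "group_too_small"
      ))
    }
    use_exact <- (length(x) + length(y) <= 12) &&
      anyDuplicated(c(x, y)) == 0
    wt <- suppressWarnings(stats::wilcox.test(x, y, exact = use_exact,
                                              correct = TRUE))
    tibble(
      feature = rownames(m)[i], n_pos = length(x), n_neg = length(y),
      mean_pos = mean(x), mean_neg = mean(y),
      se_pos = stats::sd(x) / sqrt(length(x)),
      se_neg = stats::sd(y) / sqrt(length(y)),
      statistic = unname(wt$statistic), p = wt$p.value,
      direction = if (mean(x) >= mean(y)) "higher_in_positive"
      else "lower_in_positive",
      skipped_reason = NA_character_
    )
  })
  dplyr::bind_rows(rows)
}

align_labels <- function(labels, samples) {
  lab <- as.logical(labels)
  if (!is.null(names(labels))) {
    if (!all(samples %in% names(labels))) {
      abort("labels missing for some samples")
    }
    lab <- lab[match(samples, names(labels))]
  } else if (length(lab) != length(samples)) {
    abort("labels length does not match sample count")
  }
  if (anyNA(lab)) abort("labels must be TRUE/FALSE with no NA")
  lab
}

#' Exact Mann-Whitney p by complete enumeration
#'
#' Brute-force two-sided p-value: enumerates all assignments of the pooled
#' values into the two groups and counts arrangements with a rank-sum
#' statistic at least as extreme as observed. Used as an independent oracle
#' for small groups; feasible for `n1 + n2` up to ~12.
#'
#' @param x,y Numeric group vectors.
#' @return Two-sided exact p-value.
#' @export
mw_exact_enumeration <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  n <- length(pooled)
  r <- rank(pooled)
  u_of <- function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2
  obs <- u_of(seq_len(n1))
  mu <- n1 * (n - n1) / 2
  combs <- utils::combn(n, n1)
  us <- apply(combs, 2, u_of)
  # two-sided: arrangements at least as far from the null mean as observed
  mean(abs(us - mu) >= abs(obs - mu) - 1e-9)
}

#' Storey q-values with smoother-based pi0 estimation
#'
#' Converts p-values to q-values (positive FDR): `pi0` is estimated on the
#' lambda grid by a cubic smoothing spline of `pi0(lambda)` evaluated at the
#' largest lambda, then `q_(i) = min over j >= i of pi0 * m * p_(j) / j`.
#' With `pi0 = 1` the result is exactly the Benjamini-Hochberg adjusted
#' p-value. With fewer than `min_m` p-values the estimator falls back to
#' `pi0 = 1` (the smoother is unstable on short vectors).
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param pi0 Optional fixed pi0 override (e.g. `1` for BH).
#' @param lambda Grid for pi0 estimation.
#' @param min_m Minimum number of p-values for smoother-based estimation.
#' @return Numeric q-values, same order as `p`; attribute `"pi0"`.
#' @export
#' @examples
#' estimate_qvalues(c(0.02, 0.04, 0.9), pi0 = 1)  # BH: 0.06 0.06 0.90
estimate_qvalues <- function(p, pi0 = NULL, lambda = seq(0.05, 0.95, 0.05),
                             min_m = 100) {
  if (length(p) == 0) abort("empty p-value vector")
  if (anyNA(p) || any(p < 0 | p > 1)) abort("p-values must lie in [0, 1]")
  m <- length(p)
  if (is.null(pi0)) {
    if (m < min_m) {
      pi0 <- 1
    } else {
      pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
      fit <- stats::smooth.spline(lambda, pi0_l, df = 3)
      pi0 <- stats::predict(fit, max(lambda))$y
      pi0 <- min(max(pi0, 1e-8), 1)
    }
  }
  stopifnot(pi0 > 0, pi0 <= 1)
  ord <- order(p)
  q_sorted <- pi0 * m * p[ord] / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q_sorted <- pmin(q_sorted, 1)
  q <- numeric(m)
  q[ord] <- q_sorted
  attr(q, "pi0") <- pi0
  q
}

#' Add q-values to a screen and extract the significant features
#'
#' @param records Screen output from [mann_whitney_screen()].
#' @param q_max Significance threshold on q (default 0.1 = 10% FDR).
#' @param pi0 Optional pi0 override passed to [estimate_qvalues()].
#' @return Tibble of records with a `q` column, filtered to `q <= q_max`
#'   and sorted by `p`. The full annotated table is in attribute
#'   `"all_records"`.
#' @export
significant_features <- function(records, q_max = 0.1, pi0 = NULL) {
  tested <- dplyr::filter(records, !is.na(.data$p))
  if (nrow(tested) == 0) abort("no testable features in screen records")
  q <- estimate_qvalues(tested$p, pi0 = pi0)
  tested$q <- as.numeric(q)
  all_records <- dplyr::left_join(
    records, dplyr::select(tested, "feature", "q"), by = "feature"
  )
  hits <- dplyr::arrange(
    dplyr::filter(tested, .data$q <= q_max), .data$p
  )
  attr(hits, "all_records") <- all_records
  attr(hits, "pi0") <- attr(q, "pi0")
  hits
}

#' Pearson correlation screen against log IC50
#'
#' Correlates every feature with the natural log of a per-sample drug IC50.
#' Negative correlations mean higher binding in more sensitive (lower IC50)
#' lines. Records with `|r|` above the flag threshold are marked; constant
#' features are reported with missing `r`.
#'
#' @param mat Wide binding tibble.
#' @param ic50 Named numeric IC50 per sample (nM, > 0), or ordered as the
#'   sample columns.
#' @param flag_abs_r Flag threshold on `|r|` (default 0.5).
#' @param log_base Base for the IC50 log transform; default natural log.
#' @return Tibble `feature`, `r`, `p`, `flagged`.
#' @export
pearson_screen <- function(mat, ic50, flag_abs_r = 0.5, log_base = exp(1)) {
  m <- binding_as_matrix(mat)
  if (!is.null(names(ic50))) {
    if (!all(colnames(m) %in% names(ic50))) abort("ic50 missing for samples")
    ic50 <- ic50[match(colnames(m), names(ic50))]
  }
  stopifnot(length(ic50) == ncol(m))
  if (any(ic50 <= 0 | is.na(ic50))) abort("IC50 must be positive")
  lx <- log(ic50, base = log_base)
  rows <- purrr::map(seq_len(nrow(m)), function(i) {
    y <- m[i, ]
    ok <- !is.na(y)
    if (sum(ok) < 3 || stats::sd(y[ok]) == 0) {
      return(tibble(feature = rownames(m)[i], r = NA_real_, p = NA_real_,
                    flagged = FALSE))
    }
    ct <- stats::cor.test(y[ok], lx[ok], method = "pearson")
    tibble(feature = rownames(m)[i], r = unname(ct$estimate),
           p = ct$p.value, flagged = abs(unname(ct$estimate)) > flag_abs_r)
  })
  dplyr::bind_rows(rows)
}

#' Dichotomize MET activation categories for the screen
#'
#' High = positive; Low includes both intermediate and negative categories.
#'
#' @param met_activation Character vector of categories per sample
#'   (`"negative"`, `"intermediate"`, `"positive"`), optionally named.
#' @return Logical vector (TRUE = high), names preserved.
#' @export
dichotomize_met <- function(met_activation) {
  stopifnot(all(met_activation %in% c("negative", "intermediate", "positive")))
  out <- met_activation == "positive"
  names(out) <- names(met_activation)
  out
}
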