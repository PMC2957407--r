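#' Log2 fold-change matrix between treated and untreated data
#'
#' `FC = log2((treated + floor) / (untreated + floor))`. The positive floor
#' keeps fold changes finite for near-zero signals; by default it is 1% of
#' the matrix-wide positive median intensity. `log2_fc(M, M)` is exactly 0
#' and the operation is antisymmetric in its arguments.
#'
#' @param treated,untreated Wide binding tibbles sharing features and
#'   samples.
#' @param floor Positive intensity floor; `NULL` uses the 1%-of-median
#'   default computed from both matrices.
#' @return Wide tibble of log2 fold changes, same shape as the inputs;
#'   attribute `"floor"` records the value used.
#' @export
log2_fc <- function(treated, untreated, floor = NULL) {
  mt <- binding_as_matrix(treated)
  mu <- binding_as_matrix(untreated)
  if (!identical(dim(mt), dim(mu)) ||
      !identical(rownames(mt), rownames(mu)) ||
      !identical(colnames(mt), colnames(mu))) {
    abort("treated and untreated matrices must share features and samples")
  }
  if (is.null(floor)) {
    pos <- c(mt[mt > 0], mu[mu > 0])
    floor <- if (length(pos) == 0) 1 else 0.01 * stats::median(pos)
  }
  stopifnot(floor > 0)
  fc <- log2((mt + floor) / (mu + floor))
  out <- binding_as_tibble(fc, feature_col = names(treated)[1])
  attr(out, "floor") <- floor
  out
}

#' Waterfall ranking of per-feature fold changes
#'
#' Orders features by their fold change in one condition (default
#' ascending, so the strongest decreases come first) and carries the other
#' conditions' values along per feature. Ties preserve feature order.
#'
#' @param fc Wide fold-change tibble (feature column + condition columns).
#' @param rank_by Condition column to rank on.
#' @param descending Rank descending instead of ascending.
#' @return Long-ish tibble: `feature`, `rank`, then one column per
#'   condition.
#' @export
waterfall <- function(fc, rank_by, descending = FALSE) {
  stopifnot(rank_by %in% names(fc))
  key <- fc[[rank_by]]
  ord <- order(if (descending) -key else key, seq_len(nrow(fc)))
  out <- fc[ord, ]
  dplyr::bind_cols(tibble(rank = seq_len(nrow(out))), out)
}

#' Mean log2 fold change per probe family
#'
#' Averages fold changes over the members of each functional probe family
#' (RAS activators, PI3K, Crk, Nck) present in the matrix, per condition
#' column. Families with no member present are reported with a missing
#' mean and a reason.
#'
#' @param fc Wide fold-change tibble with probe ids in the first column.
#' @param panel Probe panel ([sh2_panel()]) supplying the family map.
#' @param families Families to summarize.
#' @return Tibble `family`, `condition`, `mean_fc`, `n_probes`, `reason`.
#' @export
group_summary <- function(fc, panel,
                          families = c("RAS_activator", "PI3K", "Crk",
                                       "Nck")) {
  fam <- setNames(panel$family, panel$probe)
  feature_col <- names(fc)[1]
  long <- tidyr::pivot_longer(fc, -dplyr::all_of(feature_col),
                              names_to = "condition", values_to = "fc")
  long$family <- fam[long[[feature_col]]]
  conds <- unique(long$condition)
  out <- purrr::map(families, function(f) {
    sub <- dplyr::filter(long, .data$family == f)
    if (nrow(sub) == 0) {
      return(tibble(family = f, condition = conds, mean_fc = NA_real_,
                    n_probes = 0L, reason = "no_family_members_in_matrix"))
    }
    s <- dplyr::summarise(
      dplyr::group_by(sub, .data$condition),
      mean_fc = mean(.data$fc, na.rm = TRUE),
      n_probes = dplyr::n_distinct(.data[[feature_col]]), .groups = "drop"
    )
    dplyr::bind_cols(tibble(family = f), s, tibble(reason = NA_character_))
  })
  dplyr::bind_rows(out)
}

#' Flag features whose binding changed significantly with treatment
#'
#' Per-feature exact Mann-Whitney test between treated and untreated
#' replicate intensities; features with `p <= p_max` (default 0.125) are
#' flagged and summarized by the median log2 fold change across replicate
#' pairs and its median absolute deviation.
#'
#' @param treated,untreated Long replicate tibbles (`probe`, `sample`,
#'   `replicate`, `intensity`) for one cell line / condition.
#' @param p_max Significance threshold.
#' @param floor Intensity floor for the per-replicate fold change.
#' @return Tibble `feature`, `p`, `median_fc`, `mad_fc`, `flagged`.
#' @export
change_significance <- function(treated, untreated, p_max = 0.125,
                                floor = NULL) {
  feature_col <- if ("probe" %in% names(treated)) "probe" else "feature"
  tr <- split(treated$intensity, treated[[feature_col]])
  un <- split(untreated$intensity, untreated[[feature_col]])
  feats <- intersect(names(tr), names(un))
  if (is.null(floor)) {
    pos <- c(treated$intensity[treated$intensity > 0],
             untreated$intensity[untreated$intensity > 0])
    floor <- if (length(pos) == 0) 1 else 0.01 * stats::median(pos)
  }
  rows <- purrr::map(feats, function(f) {
    x <- tr[[f]]; y <- un[[f]]
    p <- if (identical(sort(x), sort(y))) {
      1
    } else {
      suppressWarnings(stats::wilcox.test(
        x, y, exact = anyDuplicated(c(x, y)) == 0
      )$p.value)
    }
    fc <- log2((x + floor) / (y + floor))   # replicate-paired by position
    tibble(feature = f, p = p, median_fc = stats::median(fc),
           mad_fc = stats::mad(fc), flagged = p <= p_max)
  })
  dplyr::bind_rows(rows)
}

#' Cluster conditions by their fold-change profiles
#'
#' Reuses the package's complete-linkage / uncentered-correlation machinery
#' on the condition columns of a fold-change matrix (cell line x treatment
#' combinations).
#'
#' @param fc Wide fold-change tibble.
#' @return An `sh2_tree` over conditions.
#' @export
fc_cluster <- function(fc) {
  hcluster(fc, axis = "samples")
}

#' Pearson correlation matrix between conditions
#'
#' @param fc Wide fold-change tibble (feature column + condition columns).
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
condition_correlation <- function(fc) {
  m <- binding_as_matrix(fc)
  stats::cor(m, use = "pairwise.complete.obs")
}

#' Waterfall plot of fold changes
#'
#' @param fc Wide fold-change tibble.
#' @param rank_by Condition to rank by (default first condition column).
#' @param panel Optional panel to colour the four tracked families.
#' @return A ggplot bar chart, features ranked by fold change, one bar set
#'   per condition.
#' @export
plot_waterfall <- function(fc, rank_by = names(fc)[2], panel = NULL) {
  wf <- waterfall(fc, rank_by)
  feature_col <- names(fc)[1]
  long <- tidyr::pivot_longer(
    wf, -dplyr::all_of(c("rank", feature_col)),
    names_to = "condition", values_to = "log2_fc"
  )
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$rank, y = .data$log2_fc,
                                          fill = .data$condition)) +
    ggplot2::geom_col(position = "dodge", width = 0.8) +
    ggplot2::labs(x = paste("probes ranked by", rank_by),
                  y = "log2 fold change (treated / untreated)") +
    ggplot2::theme_minimal()
  if (!is.null(panel)) {
    fam <- setNames(panel$family, panel$probe)
    marks <- dplyr::filter(
      dplyr::mutate(wf, family = fam[.data[[feature_col]]]),
      .data$family %in% c("RAS_activator", "PI3K", "Crk", "Nck")
    )
    p <- p + ggplot2::geom_rug(
      data = marks,
      mapping = ggplot2::aes(x = .data$rank, colour = .data$family),
      inherit.aes = FALSE, sides = "b"
    )
  }
  p
}

#' Bar plot of family-level mean fold changes
#'
#' @param summary Output of [group_summary()].
#' @return A ggplot grouped bar chart (family x condition).
#' @export
plot_group_summary <- function(summary) {
  ggplot2::ggplot(summary,
                  ggplot2::aes(x = .data$family, y = .data$mean_fc,
                               fill = .data$condition)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = NULL, y = "mean log2 fold change") +
    ggplot2::theme_minimal()
}
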