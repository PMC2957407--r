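#' Integrated spot density with local background subtraction
#'
#' Quantifies a single array spot from a 2D intensity patch: the integrated
#' density is the sum over the spot disk minus the median of a surrounding
#' background annulus times the disk pixel count, floored at zero. The
#' median background makes the estimate robust to bleed from neighbouring
#' spots, and the result is invariant to adding a constant background level.
#'
#' @param patch Numeric matrix of nonnegative pixel intensities.
#' @param center Spot center `c(row, col)` in pixels; defaults to the patch
#'   center.
#' @param radius Spot disk radius in pixels (> 0).
#' @param annulus Background annulus radii `c(inner, outer)`; must be
#'   disjoint from the disk (`inner >= radius`).
#' @return Nonnegative scalar density.
#' @export
#' @examples
#' patch <- matrix(10, 21, 21)  # flat background: density 0
#' quantify_spot(patch, radius = 4, annulus = c(6, 9))
quantify_spot <- function(patch,
                          center = (dim(patch) + 1) / 2,
                          radius = min(dim(patch)) / 4,
                          annulus = c(radius * 1.5, radius * 2)) {
  stopifnot(is.matrix(patch), all(is.finite(patch)), all(patch >= 0),
            radius > 0, length(annulus) == 2, annulus[2] > annulus[1])
  if (annulus[1] < radius) abort("annulus must be disjoint from the spot disk")
  rr <- row(patch) - center[1]
  cc <- col(patch) - center[2]
  d <- sqrt(rr^2 + cc^2)
  disk <- d <= radius
  ring <- d > annulus[1] & d <= annulus[2]
  if (!any(ring)) abort("empty background annulus for this patch geometry")
  bg <- median(patch[ring])
  max(0, sum(patch[disk]) - bg * sum(disk))
}

#' Average a replicate stack into a binding matrix
#'
#' Collapses a long replicate-stacked table to the arithmetic mean per
#' (feature, sample) cell. Missing replicates (NA intensities) are dropped
#' from the mean and counted.
#'
#' @param stack Long tibble with columns `probe` (or `feature`), `sample`,
#'   `replicate`, `intensity`.
#' @return A wide tibble (feature column + one column per sample) with
#'   attribute `"n_missing"`: a tibble of cells that lost replicates.
#' @export
average_replicates <- function(stack) {
  feature_col <- if ("probe" %in% names(stack)) "probe" else "feature"
  stopifnot(all(c(feature_col, "sample", "replicate", "intensity") %in%
                  names(stack)))
  summ <- dplyr::summarise(
    dplyr::group_by(stack, .data[[feature_col]], .data$sample),
    mean_intensity = mean(.data$intensity, na.rm = TRUE),
    n_missing = sum(is.na(.data$intensity)),
    .groups = "drop"
  )
  missing <- dplyr::filter(summ, .data$n_missing > 0)
  wide <- tidyr::pivot_wider(
    dplyr::select(summ, dplyr::all_of(c(feature_col, "sample",
                                        "mean_intensity"))),
    names_from = "sample", values_from = "mean_intensity"
  )
  # preserve input feature order
  wide <- wide[match(unique(stack[[feature_col]]), wide[[feature_col]]), ]
  attr(wide, "n_missing") <- dplyr::select(
    missing, dplyr::all_of(c(feature_col, "sample", "n_missing"))
  )
  wide
}

#' The default 20-bin molecular-weight grid
#'
#' Far-Western lanes are partitioned into 20 fixed molecular-weight bins
#' from 291 kDa down to an open bottom bin (< 22 kDa). Boundaries follow a
#' geometric (log-linear) ladder `b_i = 291 * ratio^i` with
#' `ratio = (22/291)^(1/19)`,
#' matching log-linear SDS-PAGE migration; bin labels are the upper boundary
#' rounded to one decimal. Bin 1 is the largest-MW bin (~256-291 kDa); the
#' bin labelled 193.6 ("MW194") contains EGFR-family receptors (band at
#' ~185 kDa) and the bin labelled 147.5 ("MW148") the MET-associated band
#' (~145 kDa).
#'
#' @param boundaries Optional explicit descending boundary vector of length
#'   20 (upper edges); overrides the geometric ladder.
#' @return A tibble with columns `bin` (1 = largest MW), `upper_mw`,
#'   `lower_mw` (0 for the open bottom bin) and `label`.
#' @export
#' @examples
#' grid <- default_bin_grid()
#' grid[c(1, 4, 6), ]  # 291 / 193.6 / 147.5 kDa bins
default_bin_grid <- function(boundaries = NULL) {
  if (is.null(boundaries)) {
    r <- (22 / 291)^(1 / 19)
    boundaries <- 291 * r^(0:19)
  }
  stopifnot(length(boundaries) == 20, all(diff(boundaries) < 0))
  tibble(
    bin = 1:20,
    upper_mw = boundaries,
    lower_mw = c(boundaries[-1], 0),
    label = sprintf("%.1f", round(boundaries, 1))
  )
}

#' Align a lane profile to a reference by integer shift
#'
#' Finds the integer migration shift within `±max_shift` positions that
#' maximizes the cross-correlation with a reference profile (the anti-pTyr
#' lane of the same sample) and applies it. Intensities are only translated,
#' never warped; positions shifted in from outside the profile are zero.
#'
#' @param profile Tibble with `position` and `intensity` columns.
#' @param reference Tibble with `position` and `intensity` (same length).
#' @param max_shift Maximum absolute shift in positions.
#' @return A list: `profile` (aligned tibble), `shift` (integer applied),
#'   `at_limit` (`TRUE` when the optimum sat on the window edge).
#' @export
align_lane <- function(profile, reference, max_shift = 10) {
  stopifnot(nrow(profile) == nrow(reference), max_shift >= 0)
  y <- profile$intensity
  r <- reference$intensity
  if (stats::sd(r) == 0) abort("alignment undefined: flat reference profile")
  shifts <- seq(-max_shift, max_shift)
  score <- vapply(shifts, function(s) {
    ys <- shift_vec(y, s)
    sum(ys * r)
  }, numeric(1))
  best <- shifts[which.max(score)]
  at_limit <- abs(best) == max_shift && max_shift > 0
  if (at_limit) {
    warn("best alignment shift sits on the search-window edge")
  }
  out <- profile
  out$intensity <- shift_vec(y, best)
  list(profile = out, shift = best, at_limit = at_limit)
}

shift_vec <- function(y, s) {
  n <- length(y)
  out <- numeric(n)
  if (s >= 0) {
    out[(1 + s):n] <- y[1:(n - s)]
  } else {
    out[1:(n + s)] <- y[(1 - s):n]
  }
  out
}

#' Interpolate molecular weight along a lane from ladder anchors
#'
#' Position-to-MW calibration by linear interpolation in log(MW) between
#' ladder anchors, with linear extrapolation beyond the outermost anchors.
#'
#' @param positions Migration positions to calibrate.
#' @param ladder Tibble with `position` and `mw` columns (>= 2 anchors, MW
#'   strictly decreasing with position).
#' @return Numeric vector of MW (kDa) per position.
#' @export
calibrate_mw <- function(positions, ladder) {
  if (nrow(ladder) < 2) abort("ladder needs at least 2 anchors")
  ord <- order(ladder$position)
  pos <- ladder$position[ord]
  mw <- ladder$mw[ord]
  if (any(diff(mw) >= 0)) abort("ladder MW must strictly decrease with position")
  fit <- stats::approx(pos, log(mw), xout = positions, rule = 2)
  logmw <- fit$y
  # extrapolate linearly in log(MW) outside the anchor span
  below <- positions < pos[1]
  above <- positions > pos[length(pos)]
  s1 <- (log(mw[2]) - log(mw[1])) / (pos[2] - pos[1])
  sn <- (log(mw[length(mw)]) - log(mw[length(mw) - 1])) /
    (pos[length(pos)] - pos[length(pos) - 1])
  logmw[below] <- log(mw[1]) + s1 * (positions[below] - pos[1])
  logmw[above] <- log(mw[length(mw)]) + sn *
    (positions[above] - pos[length(pos)])
  exp(logmw)
}

#' Bin a calibrated lane profile onto the molecular-weight grid
#'
#' Sums profile intensity into each MW bin. A position falls into the bin
#' whose half-open interval `(lower, upper]` contains its interpolated MW;
#' MW above the top boundary is clamped into bin 1 with a warning (gels do
#' not resolve above it), and everything below the 19th boundary lands in
#' the open bottom bin. Binning conserves mass: the bin totals sum to the
#' total profile intensity.
#'
#' @param profile Tibble with `position` and `intensity`.
#' @param ladder Ladder anchor tibble (see [calibrate_mw()]).
#' @param grid Bin grid from [default_bin_grid()].
#' @param warn_clamp Warn when positions above the top boundary are clamped
#'   into bin 1.
#' @return Tibble `bin`, `label`, `density` with 20 rows.
#' @export
bin_lane <- function(profile, ladder, grid = default_bin_grid(),
                     warn_clamp = TRUE) {
  mw <- calibrate_mw(profile$position, ladder)
  over <- mw > grid$upper_mw[1]
  if (any(over) && warn_clamp) {
    warn(sprintf("%d positions above %.0f kDa clamped into bin 1",
                 sum(over), grid$upper_mw[1]))
  }
  idx <- assign_bin(mw, grid)
  dens <- vapply(grid$bin, function(b) {
    sum(profile$intensity[idx == b])
  }, numeric(1))
  tibble(bin = grid$bin, label = grid$label, density = dens)
}

# bin index per MW value; bin i covers [lower_i, upper_i) with the lower
# edge inclusive; MW at or above the top-of-gel boundary clamps into bin 1.
assign_bin <- function(mw, grid) {
  # boundaries descending; findInterval needs ascending
  edges <- sort(c(grid$upper_mw, 0))          # 0, b19, ..., b0
  k <- findInterval(mw, edges)                # e_k <= mw < e_{k+1}
  idx <- 21L - pmin(pmax(k, 1L), 20L)
  idx
}

#' Quantify a set of simulated/scanned lanes into a far-Western matrix
#'
#' Aligns each probe lane to the sample's anti-pTyr reference, bins it on
#' the MW grid and assembles the `probe_bin x sample` matrix with feature
#' ids `"PROBE_label"` (e.g. `"p85A_147.5"`).
#'
#' @param lanes List as returned by [simulate_lanes()] (`profiles`,
#'   `reference`, `ladder`).
#' @param grid Bin grid.
#' @param max_shift Alignment search window (positions).
#' @param align If `FALSE`, skip alignment (profiles already registered).
#' @return Wide tibble: `feature` column (`probe_binlabel`) + one column per
#'   sample.
#' @export
quantify_lanes <- function(lanes, grid = default_bin_grid(), max_shift = 10,
                           align = TRUE) {
  profs <- lanes$profiles
  refs <- split(lanes$reference, lanes$reference$sample)
  keyed <- dplyr::group_split(dplyr::group_by(profs, .data$probe,
                                              .data$sample))
  rows <- purrr::map(keyed, function(p) {
    probe <- p$probe[1]
    samp <- p$sample[1]
    prof <- dplyr::select(p, "position", "intensity")
    if (align) {
      prof <- align_lane(prof, refs[[samp]], max_shift = max_shift)$profile
    }
    b <- bin_lane(prof, lanes$ladder, grid, warn_clamp = FALSE)
    tibble(feature = paste0(probe, "_", b$label), sample = samp,
           density = b$density, bin = b$bin, probe = probe)
  })
  long <- dplyr::bind_rows(rows)
  long <- dplyr::arrange(long, match(.data$probe, unique(profs$probe)),
                         .data$bin)
  tidyr::pivot_wider(
    dplyr::select(long, "feature", "sample", "density"),
    names_from = "sample", values_from = "density"
  )
}
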