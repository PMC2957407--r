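#' Four-parameter logistic curve
#'
#' `y = d + (a - d) / (1 + (x / c)^b)`: `a` = top asymptote (viability at
#' zero dose), `d` = bottom, `c` = inflection = IC50, `b` = Hill slope.
#' At `x = c` the curve passes through `(a + d) / 2`.
#'
#' @param x Dose (same units as `c`).
#' @param a,d Top and bottom asymptotes.
#' @param b Hill slope.
#' @param c Inflection concentration (IC50).
#' @return Predicted response.
#' @export
four_pl <- function(x, a = 1, d = 0, b = 1, c) {
  d + (a - d) / (1 + (x / c)^b)
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Nonlinear least squares on log-dose with Levenberg-Marquardt and
#' multi-start initialization (`a = max(y)`, `d = min(y)`, `c` = geometric
#' mid-dose, Hill slope started at both +1 and -1; the better fit wins).
#' All replicate points are fitted jointly. The fit is canonicalized so
#' that `a >= d` (the 4PL is invariant under swapping asymptotes with
#' `b -> -b`). IC50 (`c`) is bounded within `[min dose / 10, max dose * 10]`
#' to avoid extrapolation artifacts on curves that do not span the response.
#'
#' @param table Dose-response tibble with columns `dose` (> 0) and
#'   `viability` (from [simulate_dose_response()] or a CSV).
#' @return A `fourpl_fit` object: parameters `a`, `d`, `b`, `c` (= IC50),
#'   `rss`, `converged`, `n`, plus the data for plotting.
#' @export
#' @examples
#' tab <- simulate_dose_response(50, noise_sd = 0, seed = 1)
#' fit <- fit_4pl(tab)
#' fit$c  # ~50
fit_4pl <- function(table) {
  stopifnot(all(c("dose", "viability") %in% names(table)))
  x <- table$dose
  y <- table$viability
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(unique(x)) < 4) abort("need at least 4 distinct doses")
  if (stats::sd(y) == 0) abort("no fit: flat response across all doses")
  rng <- diff(range(y))
  if (rng < 1e-10) abort("no fit: flat response across all doses")

  lo_c <- min(x) / 10
  hi_c <- max(x) * 10
  start_c <- exp(mean(log(range(x))))
  fits <- list()
  for (b0 in c(1, -1)) {
    fits[[length(fits) + 1]] <- tryCatch(
      minpack.lm::nlsLM(
        y ~ d + (a - d) / (1 + (x / c)^b),
        start = list(a = max(y), d = min(y), b = b0, c = start_c),
        lower = c(a = -Inf, d = -Inf, b = -Inf, c = lo_c),
        upper = c(a = Inf, d = Inf, b = Inf, c = hi_c),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
  }
  fits <- Filter(Negate(is.null), fits)
  if (length(fits) == 0) abort("4PL fit failed to converge from any start")
  rss <- vapply(fits, function(f) sum(stats::residuals(f)^2), numeric(1))
  best <- fits[[which.min(rss)]]
  cf <- as.list(stats::coef(best))
  # canonical orientation: top >= bottom
  if (cf$a < cf$d) {
    tmp <- cf$a; cf$a <- cf$d; cf$d <- tmp
    cf$b <- -cf$b
  }
  conv <- best$convInfo$isConv %||% TRUE
  structure(list(
    a = cf$a, d = cf$d, b = cf$b, c = cf$c,
    rss = min(rss), converged = isTRUE(conv), n = length(y),
    data = tibble(dose = x, viability = y),
    at_bound = cf$c <= lo_c * 1.0001 || cf$c >= hi_c * 0.9999
  ), class = "fourpl_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.fourpl_fit <- function(x, ...) {
  cat(sprintf(
    "4PL fit: IC50 = %.4g, hill = %.3g, top = %.3g, bottom = %.3g (rss %.3g, n %d)\n",
    x$c, x$b, x$a, x$d, x$rss, x$n))
  if (!x$converged) cat("  WARNING: fit did not converge\n")
  if (x$at_bound) cat("  WARNING: IC50 at the search bound\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.fourpl_fit <- function(x, ...) {
  tibble(term = c("top", "bottom", "hill", "ic50"),
         estimate = c(x$a, x$d, x$b, x$c))
}

#' @exportS3Method generics::glance
glance.fourpl_fit <- function(x, ...) {
  tibble(ic50 = x$c, hill = x$b, top = x$a, bottom = x$d, rss = x$rss,
         n = x$n, converged = x$converged, at_bound = x$at_bound)
}

#' Predicted viability from a 4PL fit
#'
#' @param object A `fourpl_fit`.
#' @param newdata Optional tibble with a `dose` column.
#' @param ... Unused.
#' @return Numeric predictions.
#' @export
predict.fourpl_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$data$dose else newdata$dose
  four_pl(x, object$a, object$d, object$b, object$c)
}

#' Classify erlotinib sensitivity from IC50
#'
#' Cutoffs: sensitive below 10 nM, intermediate 10-1000 nM (boundaries
#' inclusive), resistant above 1000 nM.
#'
#' @param ic50 IC50 values in nM.
#' @return Factor with levels sensitive / intermediate / resistant.
#' @export
#' @examples
#' classify_sensitivity(c(5, 10, 500, 2000))
classify_sensitivity <- function(ic50) {
  stopifnot(all(ic50 > 0 | is.na(ic50)))
  out <- dplyr::case_when(
    ic50 < 10 ~ "sensitive",
    ic50 <= 1000 ~ "intermediate",
    TRUE ~ "resistant"
  )
  factor(out, levels = c("sensitive", "intermediate", "resistant"))
}

#' Plot a fitted dose-response curve
#'
#' @param object A `fourpl_fit`.
#' @param ... Unused.
#' @return A ggplot: points on log-dose with the fitted 4PL curve and the
#'   IC50 marked.
#' @exportS3Method ggplot2::autoplot
autoplot.fourpl_fit <- function(object, ...) {
  grid <- tibble(dose = exp(seq(log(min(object$data$dose)),
                                log(max(object$data$dose)),
                                length.out = 200)))
  grid$viability <- predict(object, grid)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$dose,
                                            y = .data$viability)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::geom_vline(xintercept = object$c, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "dose (nM)", y = "viability",
                  title = sprintf("IC50 = %.3g nM", object$c)) +
    ggplot2::theme_minimal()
}
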