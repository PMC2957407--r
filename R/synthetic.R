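#' Simulate a cell-line cohort annotation table
#'
#' Draws a cohort of cell lines with genotype and pathway-activation labels
#' and a ground-truth drug IC50 per line. Defaults mirror a 22-line lung
#' cancer panel with 7 EGFR-mutant, 9 RAS-mutant and 6 MET-activated lines.
#' EGFR mutants draw low IC50 values (TKI-sensitive), RAS mutants high
#' (resistant), per configurable log-normal genotype distributions.
#'
#' @param n_lines Number of cell lines.
#' @param n_egfr_mut Number of EGFR-mutant lines.
#' @param n_ras_mut Number of RAS-mutant lines (one is labelled
#'   `nras_mutant` when `n_ras_mut >= 2`, the rest `kras_mutant`).
#' @param n_met_pos Number of MET-activation-positive lines.
#' @param seed Integer seed; identical inputs give identical tables.
#' @param allow_cooccur If `FALSE` (default) EGFR and RAS mutations are
#'   mutually exclusive and their counts must fit in `n_lines`.
#' @param ic50_meanlog Named numeric: mean of `log(IC50 nM)` for groups
#'   `egfr_mutant`, `ras_mutant`, `other`.
#' @param ic50_sdlog Standard deviation of `log(IC50)` draws.
#' @return A tibble with one row per line: `line_id`, `egfr`, `ras`,
#'   `met_activation`, `true_ic50` (nM), `erlotinib_class`.
#' @export
#' @examples
#' cohort <- make_cohort(22, 7, 9, 6, seed = 1)
#' table(cohort$ras)
make_cohort <- function(n_lines = 22, n_egfr_mut = 7, n_ras_mut = 9,
                        n_met_pos = 6, seed = 1, allow_cooccur = FALSE,
                        ic50_meanlog = c(egfr_mutant = log(5),
                                         ras_mutant = log(3000),
                                         other = log(150)),
                        ic50_sdlog = 0.5) {
  stopifnot(n_lines >= 1, n_egfr_mut >= 0, n_ras_mut >= 0, n_met_pos >= 0)
  if (n_met_pos > n_lines) abort("n_met_pos exceeds n_lines")
  if (!allow_cooccur && n_egfr_mut + n_ras_mut > n_lines) {
    abort("invalid composition: n_egfr_mut + n_ras_mut exceeds n_lines")
  }
  if (max(n_egfr_mut, n_ras_mut) > n_lines) {
    abort("invalid composition: mutant count exceeds n_lines")
  }
  with_seed(seed, {
    line_id <- sprintf("L%02d", seq_len(n_lines))
    egfr <- rep("wt", n_lines)
    egfr[seq_len(n_egfr_mut)] <- "mutant"
    ras <- rep("wt", n_lines)
    if (n_ras_mut > 0) {
      ras_idx <- if (allow_cooccur) {
        seq_len(n_ras_mut)
      } else {
        n_egfr_mut + seq_len(n_ras_mut)
      }
      ras[ras_idx] <- "kras_mutant"
      if (n_ras_mut >= 2) ras[ras_idx[n_ras_mut]] <- "nras_mutant"
    }
    met <- rep("negative", n_lines)
    # MET activation is independent of genotype; spread positives across the
    # panel, and grade a couple of additional lines intermediate
    met_idx <- if (n_met_pos > 0) {
      round(seq(1, n_lines, length.out = n_met_pos))
    } else {
      integer(0)
    }
    met[met_idx] <- "positive"
    inter_pool <- setdiff(seq_len(n_lines), met_idx)
    met[utils::head(inter_pool, min(2, length(inter_pool)))] <- "intermediate"

    grp <- dplyr::case_when(
      egfr == "mutant" ~ "egfr_mutant",
      ras != "wt" ~ "ras_mutant",
      TRUE ~ "other"
    )
    true_ic50 <- exp(stats::rnorm(n_lines, ic50_meanlog[grp], ic50_sdlog))
    tibble(
      line_id = line_id, egfr = egfr, ras = ras, met_activation = met,
      true_ic50 = true_ic50,
      erlotinib_class = classify_sensitivity(true_ic50)
    )
  })
}

#' Ground truth for the synthetic binding-signal generator
#'
#' Encodes the generative model behind [simulate_rosette()],
#' [simulate_lanes()] and [simulate_treatment()]: per-probe baseline binding
#' on the log2 scale, additive log2 effects of cohort labels on named probes,
#' replicate and line-level noise, the far-Western band catalog and the
#' per-family TKI inhibition shifts.
#'
#' Default effects follow the biology the pipeline is built to detect:
#' seven probes (Grb2, ShcA(ptb), Grap2, Brk, Txk, CblB, CblA) are elevated
#' by 2 log2 units in EGFR-mutant lines; MET activation broadly elevates
#' binding; RAS mutation depresses global phosphotyrosine signal by 1 log2
#' unit. TKI treatment shifts RAS-activator, PI3K and Crk family binding
#' down and Nck binding up in sensitive lines.
#'
#' @param panel Probe panel tibble ([sh2_panel()]).
#' @param baseline_log2 Baseline log2 intensity of pTyr-dependent probes.
#' @param background_log2 Background log2 intensity (GST control, negative
#'   control samples).
#' @param egfr_probes Probes elevated in EGFR mutants.
#' @param egfr_delta Log2 effect size on `egfr_probes`.
#' @param ras_delta Global log2 shift applied to every pTyr-dependent probe
#'   in RAS-mutant lines (negative = depressed signal).
#' @param met_delta Log2 elevation in MET-activation-positive lines, applied
#'   to `met_probes` (intermediate lines get half the effect).
#' @param met_probes Probes responding to MET activation; defaults to a broad
#'   set (PI3K family plus Grb2/ShcA and a slice of the remaining panel).
#' @param low_signal_probes Probes with no phosphotyrosine-dependent signal
#'   (background in every sample, controls included), emulating the weak
#'   panel members a control-based filter removes. Default: the GST control
#'   plus the alphabetically last 25 unnamed `"other"`-family probes, so 26
#'   of 96 probes are low-signal and roughly half show a negative
#'   positive-minus-negative control difference. Set `character(0)` to
#'   disable.
#' @param noise_sd Replicate noise sd, log2 units.
#' @param line_sd Sd of the line-level random factor shared across probes
#'   (induces realistic sample clustering); set 0 to disable.
#' @param positive_boost Extra log2 units for the pervanadate-treated
#'   positive-control sample on pTyr-dependent probes.
#' @param inhibition Tibble (`treatment`, `family`, `shift`) of log2
#'   fold-change shifts applied by [simulate_treatment()] in fully sensitive
#'   lines.
#' @param sensitivity_scale Named numeric mapping `erlotinib_class` to the
#'   fraction of the inhibition shift a line experiences; the defaults are
#'   calibrated so a sensitive / intermediate / resistant line shows a
#'   RAS-activator mean log2 fold change of -3.1 / -1.6 / -0.8 under
#'   erlotinib.
#' @return A list of class `"sh2_truth"`.
#' @export
binding_truth <- function(panel = sh2_panel(),
                          baseline_log2 = 10,
                          background_log2 = 4,
                          egfr_probes = c("Grb2", "ShcA(ptb)", "Grap2",
                                          "Brk", "Txk", "CblB", "CblA"),
                          egfr_delta = 2,
                          ras_delta = -1,
                          met_delta = 1.5,
                          met_probes = NULL,
                          low_signal_probes = NULL,
                          noise_sd = 0.5,
                          line_sd = 0.5,
                          positive_boost = 2,
                          inhibition = default_inhibition(),
                          sensitivity_scale = c(sensitive = 1,
                                                intermediate = 1.6 / 3.1,
                                                resistant = 0.8 / 3.1)) {
  validate_panel(panel)
  stopifnot(noise_sd >= 0, line_sd >= 0)
  missing_probes <- setdiff(egfr_probes, panel$probe)
  if (length(missing_probes) > 0) {
    abort(paste("egfr_probes not in panel:", paste(missing_probes, collapse = ", ")))
  }
  if (!all(inhibition$family %in% c(unique(panel$family)))) {
    abort("inhibition table names a probe family absent from the panel")
  }
  dep <- ptyr_dependent(panel)
  if (is.null(low_signal_probes)) {
    named <- unique(c(egfr_probes,
                      panel$probe[panel$family != "other"]))
    pool <- sort(setdiff(dep, named), decreasing = TRUE)
    low_signal_probes <- c(utils::head(pool, 25),
                           panel$probe[panel$probe_class == "GST_control"])
  }
  dep <- setdiff(dep, low_signal_probes)
  if (is.null(met_probes)) {
    pool <- setdiff(dep, egfr_probes)
    met_probes <- unique(c(
      panel$probe[panel$family == "PI3K"], "Grb2", "ShcA",
      utils::head(pool, 25)
    ))
  }
  baseline <- setNames(
    ifelse(panel$probe %in% dep, baseline_log2, background_log2),
    panel$probe
  )
  effects <- dplyr::bind_rows(
    tibble(probe = egfr_probes, label = "egfr_mutant", delta = egfr_delta),
    tibble(probe = dep, label = "ras_mutant", delta = ras_delta),
    tibble(probe = intersect(met_probes, dep), label = "met_positive",
           delta = met_delta),
    tibble(probe = intersect(met_probes, dep), label = "met_intermediate",
           delta = met_delta / 2)
  )
  structure(list(
    panel = panel,
    low_signal = low_signal_probes,
    baseline = baseline,
    background_log2 = background_log2,
    effects = effects,
    noise_sd = noise_sd,
    line_sd = line_sd,
    positive_boost = positive_boost,
    bands = default_band_catalog(panel),
    inhibition = inhibition,
    sensitivity_scale = sensitivity_scale
  ), class = "sh2_truth")
}

#' Default TKI inhibition shifts per probe family
#'
#' Log2 fold-change shifts applied in fully TKI-sensitive lines. RAS-activator
#' binding collapses most (-3.1 log2 units under erlotinib), PI3K and Crk
#' binding decreases, Nck binding increases; dasatinib effects are similar
#' but blunted for RAS activators.
#'
#' @return Tibble with columns `treatment`, `family`, `shift`.
#' @export
default_inhibition <- function() {
  tibble(
    treatment = rep(c("erlotinib", "dasatinib"), each = 5),
    family = rep(c("RAS_activator", "PI3K", "Crk", "Nck", "other"), 2),
    shift = c(-3.1, -1.6, -1.2, 1.0, -0.8,
              -2.0, -1.8, -1.2, 1.0, -0.8)
  )
}

# Far-Western band catalog: each pTyr-dependent probe sees an EGFR-family
# band (185 kDa, responds to EGFR mutation), a MET band (145 kDa, responds
# to MET activation) and a generic mid-MW band. Widths are sds in kDa.
default_band_catalog <- function(panel) {
  dep <- ptyr_dependent(panel)
  dplyr::bind_rows(
    tibble(probe = dep, center_kda = 185, width_kda = 4,
           base_amp_log2 = 6, label = "egfr_mutant", delta = 2),
    tibble(probe = dep, center_kda = 145, width_kda = 4,
           base_amp_log2 = 5, label = "met_positive", delta = 2),
    tibble(probe = dep, center_kda = 100, width_kda = 4,
           base_amp_log2 = 6, label = NA_character_, delta = 0)
  )
}

# log2 mean signal for every (probe, line): baseline + sum of label effects.
line_labels <- function(cohort) {
  tibble(
    line_id = cohort$line_id,
    egfr_mutant = as.numeric(cohort$egfr == "mutant"),
    ras_mutant = as.numeric(cohort$ras != "wt"),
    met_positive = as.numeric(cohort$met_activation == "positive"),
    met_intermediate = as.numeric(cohort$met_activation == "intermediate")
  )
}

effect_log2 <- function(truth, cohort) {
  lab <- line_labels(cohort)
  lab_long <- tidyr::pivot_longer(lab, -"line_id", names_to = "label",
                                  values_to = "on")
  eff <- dplyr::inner_join(truth$effects, lab_long, by = "label",
                           relationship = "many-to-many")
  eff <- dplyr::summarise(
    dplyr::group_by(eff, .data$probe, .data$line_id),
    effect = sum(.data$delta * .data$on), .groups = "drop"
  )
  grid <- tidyr::expand_grid(probe = truth$panel$probe,
                             line_id = cohort$line_id)
  out <- dplyr::left_join(grid, eff, by = c("probe", "line_id"))
  out$effect[is.na(out$effect)] <- 0
  out
}

#' Simulate a replicate-stacked rosette binding matrix
#'
#' Generates spot intensities for every probe x line under a log-normal
#' signal model: `intensity = 2^(baseline + sum(effects * labels) +
#' line_factor + N(0, noise_sd))`. Two control samples are appended:
#' `neg_control` (phosphatase-treated lysate, background-only for
#' pTyr-dependent probes) and `pos_control` (pervanadate-treated mixed
#' lysate, the per-probe maximum effect state plus a boost).
#'
#' @param panel Probe panel ([sh2_panel()]).
#' @param cohort Cohort annotation ([make_cohort()]).
#' @param truth Ground truth ([binding_truth()]).
#' @param n_replicates Replicate spots per probe/sample pair (default 4:
#'   two independent experiments in duplicate).
#' @param seed Integer seed.
#' @return A long tibble: `probe`, `sample`, `replicate`, `intensity`
#'   (nonnegative). Control samples carry `replicate` values like real
#'   samples.
#' @export
simulate_rosette <- function(panel, cohort, truth, n_replicates = 4,
                             seed = 1) {
  stopifnot(n_replicates >= 1)
  validate_panel(panel)
  eff <- effect_log2(truth, cohort)
  dep <- setdiff(ptyr_dependent(panel), truth$low_signal)
  with_seed(seed, {
    line_factor <- setNames(
      stats::rnorm(nrow(cohort), 0, truth$line_sd), cohort$line_id
    )
    base <- truth$baseline[eff$probe]
    mu <- ifelse(eff$probe %in% dep,
                 base + eff$effect + line_factor[eff$line_id],
                 base)
    # positive control sits at the per-probe maximum effect state
    pos_eff <- dplyr::summarise(
      dplyr::group_by(truth$effects, .data$probe),
      best = sum(pmax(.data$delta, 0)), .groups = "drop"
    )
    best <- setNames(pos_eff$best, pos_eff$probe)
    probes <- panel$probe
    mu_pos <- ifelse(
      probes %in% dep,
      truth$baseline[probes] +
        ifelse(is.na(best[probes]), 0, best[probes]) + truth$positive_boost,
      truth$baseline[probes]
    )
    mu_neg <- ifelse(probes %in% dep, truth$background_log2,
                     truth$baseline[probes])
    grid <- dplyr::bind_rows(
      tibble(probe = eff$probe, sample = eff$line_id, mu = mu),
      tibble(probe = probes, sample = "pos_control", mu = mu_pos),
      tibble(probe = probes, sample = "neg_control", mu = mu_neg)
    )
    out <- tidyr::expand_grid(grid, replicate = seq_len(n_replicates))
    out$intensity <- 2^(out$mu + stats::rnorm(nrow(out), 0, truth$noise_sd))
    dplyr::select(out, "probe", "sample", "replicate", "intensity")
  })
}

#' Simulate far-Western lane profiles
#'
#' Builds one migration profile per (probe, line) as a sum of Gaussian bands
#' on the molecular-weight axis plus nonnegative baseline noise, together
#' with a reference anti-phosphotyrosine profile per line for alignment.
#' The migration axis is uniform in log(MW) (standard SDS-PAGE behaviour);
#' band amplitudes follow the same log2 effect model as the rosette signal.
#' The default catalog puts an EGFR-family band at 185 kDa and a
#' MET-associated band at 145 kDa.
#'
#' @inheritParams simulate_rosette
#' @param probes Probes to run lanes for; default all phosphotyrosine-
#'   dependent, non-low-signal probes. The deposited-style far-Western
#'   layout uses the first 36 (36 probes x 20 bins = 720 bands).
#' @param n_positions Number of migration positions per lane.
#' @param mw_range Molecular-weight range (kDa) covered by the gel, given
#'   as `c(top, bottom)`.
#' @param baseline_noise Uniform baseline noise amplitude per position.
#' @return A list with `profiles` (tibble `probe`, `sample`, `position`,
#'   `intensity`), `reference` (tibble `sample`, `position`, `intensity`)
#'   and `ladder` (tibble `position`, `mw`).
#' @export
simulate_lanes <- function(panel, cohort, truth, probes = NULL,
                           n_positions = 200,
                           seed = 1, mw_range = c(320, 15),
                           baseline_noise = 0.05) {
  validate_panel(panel)
  stopifnot(n_positions >= 10, mw_range[1] > mw_range[2])
  positions <- seq_len(n_positions) - 1L
  mw <- exp(seq(log(mw_range[1]), log(mw_range[2]),
                length.out = n_positions))
  ladder_idx <- round(seq(1, n_positions, length.out = 8))
  ladder <- tibble(position = positions[ladder_idx], mw = mw[ladder_idx])

  eff <- effect_log2(truth, cohort)
  eff_lookup <- setNames(eff$effect, paste(eff$probe, eff$line_id))
  lab <- line_labels(cohort)

  bands <- truth$bands
  clamped <- bands$center_kda > max(mw) | bands$center_kda < min(mw)
  if (any(clamped)) {
    warn(sprintf("%d band centers outside the gel range were clamped",
                 sum(clamped)))
    bands$center_kda <- pmin(pmax(bands$center_kda, min(mw)), max(mw))
  }

  with_seed(seed, {
    line_factor <- setNames(
      stats::rnorm(nrow(cohort), 0, truth$line_sd), cohort$line_id
    )
    profile_for <- function(probe, line) {
      b <- bands[bands$probe == probe, , drop = FALSE]
      y <- stats::runif(n_positions, 0, baseline_noise)
      if (nrow(b) > 0) {
        on <- vapply(seq_len(nrow(b)), function(i) {
          if (is.na(b$label[i])) 1 else lab[[b$label[i]]][lab$line_id == line]
        }, numeric(1))
        amp <- 2^(b$base_amp_log2 + b$delta * on + line_factor[line] +
                    stats::rnorm(nrow(b), 0, truth$noise_sd))
        for (i in seq_len(nrow(b))) {
          y <- y + amp[i] * exp(-(mw - b$center_kda[i])^2 /
                                  (2 * b$width_kda[i]^2))
        }
      }
      y
    }
    dep <- probes
    if (is.null(dep)) dep <- setdiff(ptyr_dependent(panel), truth$low_signal)
    grid <- tidyr::expand_grid(probe = dep, sample = cohort$line_id)
    profiles <- dplyr::mutate(grid, data = purrr::map2(
      .data$probe, .data$sample,
      function(p, s) tibble(position = positions,
                            intensity = profile_for(p, s))
    ))
    profiles <- tidyr::unnest(profiles, "data")

    ref <- purrr::map(cohort$line_id, function(line) {
      y <- stats::runif(n_positions, 0, baseline_noise) +
        30 * exp(-(mw - 185)^2 / 32) + 20 * exp(-(mw - 145)^2 / 32) +
        25 * exp(-(mw - 100)^2 / 32)
      tibble(sample = line, position = positions, intensity = y)
    })
    list(profiles = profiles, reference = dplyr::bind_rows(ref),
         ladder = ladder)
  })
}

#' Apply a simulated TKI treatment to untreated binding data
#'
#' Multiplies untreated intensities by `2^(shift + noise)` where the shift
#' is the truth's per-(treatment, family) log2 fold change scaled by the
#' line's drug-sensitivity class. With all shifts zero and no noise the
#' treated data equal the untreated data exactly.
#'
#' @param untreated Long rosette tibble from [simulate_rosette()] (or any
#'   tibble with `probe`, `sample`, `intensity` columns).
#' @param truth Ground truth ([binding_truth()]).
#' @param cohort Cohort annotation (supplies the sensitivity class per line).
#' @param treatment `"erlotinib"` or `"dasatinib"`.
#' @param seed Integer seed (replicate-level fold-change noise).
#' @param fc_noise_sd Log2 noise added on top of the deterministic shift.
#' @param line_response_sd Sd (log2) of a per-(probe, line) response
#'   deviation that is a property of the cell line: it is drawn from
#'   `response_seed`, not `seed`, so both treatments of a line share it.
#'   This is what makes the two TKI conditions of one line cluster together
#'   in fold-change space. Default 0 (pure family-shift responses).
#' @param response_seed Seed for the line response profile; keep it equal
#'   across the treatments of an experiment.
#' @return A tibble shaped like `untreated` with shifted intensities.
#' @export
simulate_treatment <- function(untreated, truth, cohort,
                               treatment = c("erlotinib", "dasatinib"),
                               seed = 1, fc_noise_sd = 0,
                               line_response_sd = 0, response_seed = 1000) {
  treatment <- match.arg(treatment)
  inh <- truth$inhibition[truth$inhibition$treatment == treatment, ]
  shift_of_family <- setNames(inh$shift, inh$family)
  fam <- setNames(truth$panel$family, truth$panel$probe)
  scale <- truth$sensitivity_scale
  cls <- setNames(as.character(cohort$erlotinib_class), cohort$line_id)
  probes <- truth$panel$probe
  dev <- matrix(0, length(probes), nrow(cohort),
                dimnames = list(probes, cohort$line_id))
  if (line_response_sd > 0) {
    dev[] <- with_seed(response_seed,
                       stats::rnorm(length(dev), 0, line_response_sd))
  }
  with_seed(seed, {
    probe_shift <- shift_of_family[fam[untreated$probe]]
    probe_shift[is.na(probe_shift)] <- 0
    line_scale <- scale[cls[untreated$sample]]
    line_scale[is.na(line_scale)] <- 0   # control samples: untouched
    in_cohort <- untreated$sample %in% cohort$line_id
    dev_cell <- numeric(nrow(untreated))
    dev_cell[in_cohort] <- dev[cbind(untreated$probe[in_cohort],
                                     untreated$sample[in_cohort])]
    shift <- unname(probe_shift) * unname(line_scale) + dev_cell +
      stats::rnorm(nrow(untreated), 0, fc_noise_sd)
    dplyr::mutate(untreated, intensity = .data$intensity * 2^shift)
  })
}

#' Simulate a dose-response viability table
#'
#' Draws viability values around a four-parameter logistic curve
#' `y = bottom + (top - bottom) / (1 + (dose / ic50)^hill)` with additive
#' Gaussian noise, clipped at zero.
#'
#' @param true_ic50 IC50 in nM (> 0).
#' @param hill Hill slope.
#' @param top,bottom Upper/lower viability asymptotes (fractions).
#' @param doses Dose levels in nM (> 0).
#' @param noise_sd Sd of additive viability noise.
#' @param n_replicates Replicates per dose.
#' @param seed Integer seed.
#' @param drug Drug name recorded in the table.
#' @return Tibble: `dose`, `replicate`, `viability`, `drug`.
#' @export
simulate_dose_response <- function(true_ic50, hill = 1, top = 1, bottom = 0,
                                   doses = 10^seq(-1, 4, length.out = 8),
                                   noise_sd = 0.05, n_replicates = 3,
                                   seed = 1, drug = "erlotinib") {
  stopifnot(true_ic50 > 0, all(doses > 0), n_replicates >= 1)
  with_seed(seed, {
    grid <- tidyr::expand_grid(dose = doses,
                               replicate = seq_len(n_replicates))
    mu <- four_pl(grid$dose, top, bottom, hill, true_ic50)
    grid$viability <- pmax(0, mu + stats::rnorm(nrow(grid), 0, noise_sd))
    grid$drug <- drug
    grid
  })
}
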