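#' Read a binding matrix from tab-delimited text
#'
#' Expects a header row of sample ids and a first column of feature ids
#' (probe names, or far-Western `"PROBE_binlabel"` ids). Duplicate feature
#' ids and non-numeric cells are reported with their line numbers.
#'
#' @param path TSV path.
#' @return Wide binding tibble.
#' @export
read_binding_tsv <- function(path) {
  if (!file.exists(path)) abort(paste("no such file:", path))
  tbl <- readr::read_tsv(path, show_col_types = FALSE,
                         name_repair = "minimal")
  ids <- tbl[[1]]
  if (anyDuplicated(ids)) {
    dup <- which(duplicated(ids))
    abort(paste0("duplicate feature id(s) at data line(s): ",
                 paste(dup, collapse = ", ")))
  }
  bad <- which(!vapply(tbl[-1], is.numeric, logical(1)))
  if (length(bad) > 0) {
    abort(paste("non-numeric sample column(s):",
                paste(names(tbl)[-1][bad], collapse = ", ")))
  }
  tbl
}

#' Write a binding matrix as tab-delimited text
#'
#' @param mat Wide binding tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_binding_tsv <- function(mat, path) {
  readr::write_tsv(mat, path)
  invisible(path)
}

#' Split far-Western feature ids into probe and bin label
#'
#' Ids follow the grammar `"PROBE_label"` where the label is the bin's
#' upper molecular weight with one decimal (e.g. `"p85A_147.5"`); the probe
#' part may itself contain underscores, so the split is on the last one.
#'
#' @param ids Character vector of feature ids.
#' @return Tibble `feature`, `probe`, `bin_label`.
#' @export
#' @examples
#' split_band_ids("p85A_148.0")
split_band_ids <- function(ids) {
  m <- regmatches(ids, regexpr("_[0-9]+\\.[0-9]+$", ids))
  if (length(m) != length(ids)) {
    bad <- ids[!grepl("_[0-9]+\\.[0-9]+$", ids)]
    abort(paste("malformed band id(s):", paste(bad, collapse = ", ")))
  }
  tibble(
    feature = ids,
    probe = sub("_[0-9]+\\.[0-9]+$", "", ids),
    bin_label = sub("^_", "", m)
  )
}

#' Read/write a cohort annotation table (CSV)
#'
#' @param path CSV path with columns `line_id`, `egfr`, `ras`,
#'   `met_activation` and optionally `true_ic50`, `erlotinib_class`.
#' @return Annotation tibble.
#' @export
read_annotation_csv <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE)
  req <- c("line_id", "egfr", "ras", "met_activation")
  if (!all(req %in% names(tbl))) {
    abort(paste("annotation needs columns:", paste(req, collapse = ", ")))
  }
  if (anyDuplicated(tbl$line_id)) abort("duplicate line_id in annotation")
  tbl
}

#' @rdname read_annotation_csv
#' @param cohort Annotation tibble.
#' @export
write_annotation_csv <- function(cohort, path) {
  readr::write_csv(cohort, path)
  invisible(path)
}

#' Read a lane profile TSV with its JSON ladder sidecar
#'
#' The TSV has columns `position` and `intensity`; the sidecar (same path
#' with extension `.ladder.json`) holds the ladder anchors as
#' `[{"position": p, "mw": m}, ...]`.
#'
#' @param path Profile TSV path.
#' @param ladder_path Optional explicit sidecar path.
#' @return List `profile` (tibble), `ladder` (tibble).
#' @export
read_lane_tsv <- function(path, ladder_path = NULL) {
  prof <- readr::read_tsv(path, show_col_types = FALSE)
  stopifnot(all(c("position", "intensity") %in% names(prof)))
  if (is.null(ladder_path)) {
    ladder_path <- sub("\\.tsv$", ".ladder.json", path)
  }
  if (!file.exists(ladder_path)) abort(paste("no ladder sidecar:", ladder_path))
  ladder <- as_tibble(jsonlite::fromJSON(ladder_path))
  list(profile = prof, ladder = ladder)
}

#' Read the deposited processed-data workbook
#'
#' Parses the two-sheet supplementary workbook layout: sheet 1 the rosette
#' matrix (70 probes x 22 lines), sheet 2 the far-Western matrix (720
#' probe_bin rows x 22 lines). Dimensions are validated and reported. A
#' directory containing `sheet1.tsv` and `sheet2.tsv` is accepted as an
#' equivalent plain-text layout (synthetic stand-ins use this form).
#'
#' @param path Workbook path (`.xls`/`.xlsx`, needs the readxl package) or
#'   a sheet directory.
#' @param expect_dims Expected `(rows, cols)` per sheet; set `NULL` to skip
#'   validation.
#' @return List `rosette`, `far_western` (wide binding tibbles) and `dims`.
#' @export
read_supplementary_workbook <- function(path,
                                        expect_dims = list(c(70, 22),
                                                           c(720, 22))) {
  if (dir.exists(path)) {
    s1 <- file.path(path, "sheet1.tsv")
    s2 <- file.path(path, "sheet2.tsv")
    if (!file.exists(s1) || !file.exists(s2)) {
      abort("sheet directory must contain sheet1.tsv and sheet2.tsv")
    }
    rosette <- read_binding_tsv(s1)
    fw <- read_binding_tsv(s2)
  } else {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      abort("reading spreadsheet workbooks requires the readxl package")
    }
    sheets <- readxl::excel_sheets(path)
    if (length(sheets) < 2) {
      abort(sprintf("expected 2 sheets (rosette, far-Western); found %d",
                    length(sheets)))
    }
    rosette <- as_tibble(readxl::read_excel(path, sheet = 1))
    fw <- as_tibble(readxl::read_excel(path, sheet = 2))
  }
  dims <- list(rosette = dim(binding_as_matrix(rosette)),
               far_western = dim(binding_as_matrix(fw)))
  if (!is.null(expect_dims)) {
    if (!all(dims$rosette == expect_dims[[1]])) {
      abort(sprintf("rosette sheet is %dx%d, expected %dx%d",
                    dims$rosette[1], dims$rosette[2],
                    expect_dims[[1]][1], expect_dims[[1]][2]))
    }
    if (!all(dims$far_western == expect_dims[[2]])) {
      abort(sprintf("far-Western sheet is %dx%d, expected %dx%d",
                    dims$far_western[1], dims$far_western[2],
                    expect_dims[[2]][1], expect_dims[[2]][2]))
    }
  }
  list(rosette = rosette, far_western = fw, dims = dims)
}

#' Default pipeline configuration
#'
#' Collects every stage parameter with its study default: band filter
#' `sd > 5` with `>= 11 of 22` lines above `5.0`; control filter `k_sd`;
#' significance at `q <= 0.1`; `|r| > 0.5` correlation flag; `p <= 0.125`
#' change test; 100,000 enrichment permutations. Round-trips losslessly
#' through JSON.
#'
#' @param seed Master seed for the run.
#' @param out_dir Output directory.
#' @param ... Overrides for any default field.
#' @return A named list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, out_dir = tempfile("sh2run"), ...) {
  cfg <- list(
    seed = seed, out_dir = out_dir,
    n_lines = 22, n_egfr_mut = 7, n_ras_mut = 9, n_met_pos = 6,
    n_replicates = 4,
    k_sd = 2, sd_min = 5, min_lines = 11, min_intensity = 5.0,
    q_max = 0.1, flag_abs_r = 0.5, p_max_change = 0.125,
    n_perm = 100000, cut_k = 4,
    treatment = "erlotinib"
  )
  dots <- list(...)
  cfg[names(dots)] <- dots
  structure(cfg, class = c("pipeline_config", "list"))
}

#' Serialize / restore a pipeline configuration
#'
#' @param config A `pipeline_config`.
#' @param path JSON path.
#' @return `read_config` returns the restored `pipeline_config`.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- jsonlite::fromJSON(path)
  structure(cfg, class = c("pipeline_config", "list"))
}

#' Run the full synthetic analysis pipeline
#'
#' Simulate -> quantify -> preprocess -> cluster -> associate -> perturb,
#' driven by one configuration and one seed, writing every stage product
#' under the configured output directory and returning a manifest with
#' checksums so reruns are verifiable.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress per-stage messages.
#' @return A `run_manifest`: config hash, package version, per-output
#'   checksums, seed.
#' @export
run_pipeline <- function(config = pipeline_config(), quiet = FALSE) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  outputs <- character(0)
  put <- function(tbl, name) {
    p <- file.path(config$out_dir, name)
    readr::write_tsv(tbl, p)
    outputs[[name]] <<- p
    p
  }

  say("[simulate] %d lines, seed %d", config$n_lines, config$seed)
  panel <- sh2_panel()
  cohort <- make_cohort(config$n_lines, config$n_egfr_mut, config$n_ras_mut,
                        config$n_met_pos,
                        seed = derive_seed(config$seed, 1))
  truth <- binding_truth(panel)
  rosette <- simulate_rosette(panel, cohort, truth,
                              n_replicates = config$n_replicates,
                              seed = derive_seed(config$seed, 2))
  write_annotation_csv(cohort, file.path(config$out_dir, "annotation.csv"))
  outputs[["annotation.csv"]] <- file.path(config$out_dir, "annotation.csv")

  say("[preprocess] control filter k_sd=%g; band filter sd>%g, >=%d lines >%g",
      config$k_sd, config$sd_min, config$min_lines, config$min_intensity)
  ctrl_report <- filter_probes_by_controls(rosette, k_sd = config$k_sd)
  averaged <- average_replicates(rosette)
  samples_only <- dplyr::select(
    averaged, -dplyr::any_of(c("pos_control", "neg_control"))
  )
  rosette_mat <- apply_filter(samples_only, ctrl_report)
  put(rosette_mat, "rosette_matrix.tsv")

  lanes <- simulate_lanes(panel, cohort, truth,
                          seed = derive_seed(config$seed, 3))
  fw <- quantify_lanes(lanes)
  band_report <- filter_bands(fw, config$sd_min, config$min_lines,
                              config$min_intensity)
  fw_kept <- apply_filter(fw, band_report)
  put(fw, "far_western_matrix.tsv")
  put(fw_kept, "far_western_filtered.tsv")

  say("[cluster] two-way, uncentered correlation, complete linkage")
  centered <- median_center_rows(rosette_mat)
  row_tree <- hcluster(centered, "features")
  col_tree <- hcluster(centered, "samples")
  export_cdt(centered, row_tree, col_tree,
             file.path(config$out_dir, "rosette_clustered"))
  outputs[["rosette_clustered.cdt"]] <-
    file.path(config$out_dir, "rosette_clustered.cdt")
  cuts <- cut_tree(col_tree, k = config$cut_k)
  put(cuts, "sample_clusters.tsv")

  ras_labels <- setNames(cohort$ras != "wt", cohort$line_id)
  biggest_ras <- names(which.max(table(cuts$cluster[ras_labels[cuts$item]])))
  members <- cuts$item[cuts$cluster == biggest_ras]
  enr <- cluster_enrichment(members, ras_labels, n_perm = config$n_perm,
                            seed = derive_seed(config$seed, 4))
  put(glance(enr), "ras_cluster_enrichment.tsv")

  say("[associate] Mann-Whitney vs EGFR, q<=%g; Pearson vs ln IC50",
      config$q_max)
  egfr_labels <- setNames(cohort$egfr == "mutant", cohort$line_id)
  screen <- mann_whitney_screen(rosette_mat, egfr_labels)
  hits <- significant_features(screen, q_max = config$q_max, pi0 = 1)
  put(attr(hits, "all_records"), "egfr_screen.tsv")
  put(hits, "egfr_hits.tsv")
  ic50 <- setNames(cohort$true_ic50, cohort$line_id)
  corr <- pearson_screen(rosette_mat, ic50,
                         flag_abs_r = config$flag_abs_r)
  put(corr, "ic50_correlation.tsv")

  say("[perturb] %s, log2 fold changes", config$treatment)
  treated <- simulate_treatment(rosette, truth, cohort,
                                treatment = config$treatment,
                                seed = derive_seed(config$seed, 5))
  t_avg <- apply_filter(dplyr::select(
    average_replicates(treated),
    -dplyr::any_of(c("pos_control", "neg_control"))
  ), ctrl_report)
  fc <- log2_fc(t_avg, rosette_mat)
  put(fc, "log2_fc.tsv")
  put(group_summary(fc, panel), "fc_group_summary.tsv")

  checksums <- vapply(outputs, function(p) digest::digest(file = p),
                      character(1))
  manifest <- structure(list(
    config_hash = digest::digest(unclass(config)),
    package_version = as.character(utils::packageVersion("sh2profiler")),
    seed = config$seed,
    outputs = tibble(name = names(outputs), path = unname(unlist(outputs)),
                     sha = unname(checksums)),
    timestamp = format(Sys.time(), tz = "UTC")
  ), class = "run_manifest")
  jsonlite::write_json(
    list(config_hash = manifest$config_hash,
         package_version = manifest$package_version,
         seed = manifest$seed,
         checksums = setNames(as.list(checksums), names(outputs))),
    file.path(config$out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  manifest
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("sh2profiler run manifest\n")
  cat("  config hash:", x$config_hash, "\n")
  cat("  seed:", x$seed, " package:", x$package_version, "\n")
  cat("  outputs:", nrow(x$outputs), "files\n")
  invisible(x)
}
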