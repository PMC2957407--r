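#' The default 96-probe SH2/PTB rosette panel
#'
#' Builds the probe panel used throughout the package: 94 GST-SH2 domain
#' probes, one GST-PTB probe (the ShcA PTB domain) and a GST-alone negative
#' control. Probes belonging to the four functional families tracked in the
#' perturbation analysis are labelled: RAS-pathway activators (Grb2/Shc and
#' close relatives), class IA PI3K regulatory subunits, and the Crk and Nck
#' adaptor families.
#'
#' @param include_antibodies If `TRUE`, append the anti-phosphotyrosine and
#'   anti-actin antibody probes spotted alongside the domain panel.
#' @return A tibble with columns `probe` (unique id), `protein`,
#'   `probe_class` (one of `"SH2"`, `"PTB"`, `"pTyr_antibody"`,
#'   `"actin_antibody"`, `"GST_control"`) and `family` (one of
#'   `"RAS_activator"`, `"PI3K"`, `"Crk"`, `"Nck"`, `"other"`).
#' @export
#' @examples
#' panel <- sh2_panel()
#' dplyr::count(panel, probe_class)
sh2_panel <- function(include_antibodies = FALSE) {
  sh2_names <- c(
    # RAS pathway activators (Grb2/Shc group)
    "Grb2", "Grb2(SH23)", "Grap", "Grap2", "ShcA",
    # PI3K regulatory subunits
    "p85A", "p85B", "p55G",
    # Crk and Nck adaptors
    "Crk", "CrkL", "Nck1", "Nck2",
    # remaining SH2 probes (cytoplasmic kinases, phosphatases, adaptors,
    # regulators); names follow common usage for the human SH2 complement
    "Abl1", "Abl2(Arg)", "Blk", "Blnk", "Bmx", "Brk", "Btk",
    "Bcar3", "Cbl", "CblA", "CblB", "CblC", "Chn2", "Cis1", "Csk",
    "Dapp1", "Eat2", "Emt", "Fer", "Fes", "Fgr", "Frk", "Fyn",
    "Grb7", "Grb10", "Grb14", "Hck", "Hsh2", "Itk", "Jak1", "Jak2",
    "Lck", "Lnk", "Lyn", "Matk", "Nsp1", "Pik3ap1", "Plcg1", "Plcg2",
    "Ptk70/Srms", "Rasa1(N)", "Rasa1(C)", "Sap", "Sh2b", "Sh2d2a",
    "Sh2d3c", "Sh3bp2", "Shb", "Shd", "She", "Shf", "Shp1", "Shp2",
    "Sla", "Sla2", "Slp76", "Socs1", "Socs2", "Socs3", "Socs4",
    "Socs5", "Socs6", "Socs7", "Src", "Stat1", "Stat3", "Stat4",
    "Stat5a", "Stat5b", "Stat6", "Supt6h", "Syk", "Tec", "Tem6",
    "Tns1", "Txk", "Tyk2", "Vav1", "Vav2", "Vav3", "Yes", "Zap70"
  )
  stopifnot(!anyDuplicated(sh2_names), length(sh2_names) == 94)

  families <- list(
    RAS_activator = c("Grb2", "Grb2(SH23)", "Grap", "Grap2", "ShcA",
                      "ShcA(ptb)"),
    PI3K = c("p85A", "p85B", "p55G"),
    Crk = c("Crk", "CrkL"),
    Nck = c("Nck1", "Nck2")
  )
  family_of <- function(p) {
    hit <- names(families)[vapply(families, function(f) p %in% f, logical(1))]
    if (length(hit) == 0) "other" else hit[[1]]
  }

  probes <- c(sh2_names, "ShcA(ptb)", "GST")
  classes <- c(rep("SH2", length(sh2_names)), "PTB", "GST_control")
  panel <- tibble(
    probe = probes,
    protein = sub("\\(.*\\)$", "", probes),
    probe_class = classes,
    family = vapply(probes, family_of, character(1))
  )
  panel$family[panel$probe_class == "GST_control"] <- "other"
  if (include_antibodies) {
    panel <- dplyr::bind_rows(panel, tibble(
      probe = c("anti-pTyr", "anti-actin"),
      protein = c("pTyr", "actin"),
      probe_class = c("pTyr_antibody", "actin_antibody"),
      family = "other"
    ))
  }
  validate_panel(panel)
  panel
}

#' Validate a probe panel table
#'
#' Checks the structural invariants a panel must satisfy: unique probe ids,
#' known class and family labels, and at most one GST control entry.
#'
#' @param panel A panel tibble as returned by [sh2_panel()].
#' @return The panel, invisibly, if valid; otherwise an error.
#' @export
validate_panel <- function(panel) {
  req <- c("probe", "protein", "probe_class", "family")
  if (!all(req %in% names(panel))) {
    abort(paste("panel must have columns:", paste(req, collapse = ", ")))
  }
  if (anyDuplicated(panel$probe)) abort("probe ids must be unique")
  ok_class <- c("SH2", "PTB", "pTyr_antibody", "actin_antibody", "GST_control")
  ok_fam <- c("RAS_activator", "PI3K", "Crk", "Nck", "other")
  if (!all(panel$probe_class %in% ok_class)) abort("unknown probe_class")
  if (!all(panel$family %in% ok_fam)) abort("unknown probe family")
  if (sum(panel$probe_class == "GST_control") > 1) {
    abort("at most one GST_control probe")
  }
  invisible(panel)
}

# Probes whose signal depends on tyrosine phosphorylation (everything except
# the GST and actin controls).
ptyr_dependent <- function(panel) {
  panel$probe[!panel$probe_class %in% c("GST_control", "actin_antibody")]
}
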