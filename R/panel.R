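#' The 17-gene hereditary gynecologic cancer panel
#'
#' Returns the fixed gene panel the pipeline analyses: 17 genes with a
#' definite association to hereditary breast, ovarian and/or endometrial
#' cancer, each with its clinically used RefSeq transcript and the
#' associated cancer phenotype.
#'
#' @return A `data.frame` with columns `gene`, `transcript`, `gene_mim`,
#'   `phenotype` and `disorder_mim`, one row per panel gene.
#' @examples
#' genePanel()
#' @export
genePanel <- function() {
  data.frame(
    gene = c("ATM", "BARD1", "BRCA1", "BRCA2", "BRIP1", "CDH1", "CHEK2",
             "MLH1", "MSH2", "MSH6", "PALB2", "PMS2", "PTEN", "RAD51C",
             "RAD51D", "STK11", "TP53"),
    transcript = c("NM_000051.4", "NM_000465.4", "NM_007294.4", "NM_000059.4",
                   "NM_032043.3", "NM_004360.5", "NM_007194.4", "NM_000249.4",
                   "NM_000251.3", "NM_000179.3", "NM_024675.4", "NM_000535.7",
                   "NM_001304717.5", "NM_058216.3", "NM_002878.4",
                   "NM_000455.5", "NM_000546.5"),
    gene_mim = c("607585", "601593", "113705", "600185", "605882", "192090",
                 "604373", "120436", "609309", "600678", "610355", "600259",
                 "601728", "602774", "602954", "602216", "191170"),
    phenotype = c(
      "Breast cancer susceptibility",
      "Breast cancer susceptibility",
      "Hereditary breast and ovarian cancer",
      "Hereditary breast and ovarian cancer",
      "Breast and ovarian cancer susceptibility",
      "Breast cancer susceptibility",
      "Breast cancer susceptibility",
      "Lynch syndrome (Endometrial and ovarian cancer susceptibility)",
      "Lynch syndrome (Endometrial and ovarian cancer susceptibility)",
      "Lynch syndrome (Endometrial and ovarian cancer susceptibility)",
      "Breast cancer susceptibility",
      "Lynch syndrome (Endometrial and ovarian cancer susceptibility)",
      "Cowden syndrome (Breast and endometrial cancer susceptibility)",
      "Breast and ovarian cancer susceptibility",
      "Breast and ovarian cancer susceptibility",
      "Peutz-Jeghers syndrome (Breast, ovarian, and endometrial cancer susceptibility)",
      "Li-Fraumeni syndrome (Breast cancer susceptibility)"),
    disorder_mim = c("114480", "114480", "604370", "612555", "114480",
                     "114480", "114480", "609310", "120435", "614350",
                     "114480", "614337", "158350", "613399", "614291",
                     "175200", "151623"),
    stringsAsFactors = FALSE
  )
}

#' Panel gene symbols
#'
#' @return Character vector of the 17 panel gene symbols.
#' @export
panelGenes <- function() genePanel()$gene

#' Per-gene classification profiles
#'
#' One row per panel gene with the gene-level knowledge the classification
#' engine consumes: whether loss of function is an established disease
#' mechanism (gates PVS1), the gnomAD-style missense constraint z-score
#' (gates PP2 at z > 3.09), the gene-specific benign allele-frequency
#' cut-off used by BS1, and the homology mask flag (`TRUE` only for PMS2,
#' whose pseudogene-homologous regions are excluded from analysis).
#'
#' The shipped values are editable defaults. The haploinsufficiency flags
#' reflect the dominant loss-of-function mechanism of the panel genes; the
#' z-scores are indicative constraint values whose only downstream effect is
#' which genes clear the 3.09 missense-constraint threshold (TP53 and PTEN
#' with these defaults); the BS1 cut-offs are uniform placeholders --
#' gene-specific calculated cut-offs should be supplied by the user where
#' available.
#'
#' @param overrides Optional `data.frame` with a `gene` column and any subset
#'   of the profile columns; matching cells replace the defaults.
#' @return A `data.frame` with columns `gene`, `haploinsufficient`,
#'   `z_score`, `bs1_cutoff`, `homology_masked`.
#' @examples
#' geneProfiles()
#' geneProfiles(data.frame(gene = "CHEK2", bs1_cutoff = 5e-4))
#' @export
geneProfiles <- function(overrides = NULL) {
  prof <- data.frame(
    gene = panelGenes(),
    haploinsufficient = TRUE,
    z_score = c(ATM = 1.21, BARD1 = -0.46, BRCA1 = -0.75, BRCA2 = -1.30,
                BRIP1 = -0.55, CDH1 = 2.33, CHEK2 = 0.36, MLH1 = 1.16,
                MSH2 = 1.07, MSH6 = 0.30, PALB2 = -0.79, PMS2 = -0.05,
                PTEN = 3.79, RAD51C = 0.37, RAD51D = 0.25, STK11 = 2.28,
                TP53 = 4.23)[panelGenes()],
    bs1_cutoff = 1e-3,
    homology_masked = panelGenes() == "PMS2",
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  if (!is.null(overrides)) {
    stopifnot(is.data.frame(overrides), "gene" %in% names(overrides))
    bad <- setdiff(overrides$gene, prof$gene)
    if (length(bad) > 0)
      stop("unknown gene in profile overrides: ", paste(bad, collapse = ", "))
    for (col in intersect(names(overrides), setdiff(names(prof), "gene"))) {
      prof[[col]][match(overrides$gene, prof$gene)] <- overrides[[col]]
    }
  }
  prof
}

#' Pipeline thresholds
#'
#' Every numeric cut-off used anywhere in the prefilter, the classification
#' engine and the burden statistics, gathered in one place so that no stage
#' carries magic numbers and the audit trail can record every effective
#' value. Call with name = value pairs to override defaults.
#'
#' @param ... Named overrides of the defaults listed below.
#' @return Named list of thresholds:
#' \describe{
#'   \item{splice_score_min}{splice-impact rescue: retained/assessed when
#'     max(ada, rf) exceeds this (default 0.5, strict).}
#'   \item{gnomad_het_max, local_carrier_max, gnomad_hom_max, local_hom_max}{
#'     frequency-filter ceilings (10 / 20 / 3 / 3; variants strictly above
#'     any ceiling are excluded).}
#'   \item{pext_min}{minimum proportion-expressed-across-transcripts for a
#'     null variant to hit a biologically relevant transcript (0.5, strict).}
#'   \item{ba1_af}{stand-alone benign allele frequency (0.05, `>=`).}
#'   \item{pm2_af}{rarity ceiling for PM2_supporting (2e-5, `<=`, or absent
#'     from gnomAD).}
#'   \item{ps4_common_af}{gnomAD allele-frequency boundary between the
#'     case-control and the patient-count PS4 branches (1e-5 = 0.001%).}
#'   \item{ps4_or_min}{case-control odds ratio required for PS4_strong in the
#'     common branch (5, strict).}
#'   \item{ps4_strong_patients, ps4_moderate_patients, ps4_supporting_patients}{
#'     reported-patient counts for the rare-branch PS4 tiers (strict `>`:
#'     4 / 2 / 1).}
#'   \item{pp2_z_min}{missense constraint z-score for PP2 (3.09, strict).}
#'   \item{bp7_phastcons_max}{conservation ceiling for BP7 (0.2, strict `<`).}
#'   \item{strength_points}{pathogenic-side point values per strength
#'     (very_strong 8, strong 4, moderate 2, supporting 1); benign-side
#'     evidence contributes the negative of its strength value.}
#'   \item{class_pathogenic_min, class_lp_min, class_lb_max, class_benign_max}{
#'     point totals mapping to the five tiers (P >= 10, LP 6..9,
#'     VUS 0..5, LB -6..-1, B <= -7).}
#'   \item{chi2_continuity_correction}{Yates correction for the 2x2
#'     chi-square (default FALSE).}
#'   \item{ci_z}{normal quantile for the Woolf odds-ratio CI (1.96).}
#' }
#' @examples
#' th <- pipelineThresholds(pm2_af = 1e-5)
#' th$pm2_af
#' @export
pipelineThresholds <- function(...) {
  defaults <- list(
    splice_score_min = 0.5,
    gnomad_het_max = 10L,
    local_carrier_max = 20L,
    gnomad_hom_max = 3L,
    local_hom_max = 3L,
    pext_min = 0.5,
    ba1_af = 0.05,
    pm2_af = 2e-5,
    ps4_common_af = 1e-5,
    ps4_or_min = 5,
    ps4_strong_patients = 4L,
    ps4_moderate_patients = 2L,
    ps4_supporting_patients = 1L,
    pp2_z_min = 3.09,
    bp7_phastcons_max = 0.2,
    strength_points = c(very_strong = 8, strong = 4, moderate = 2,
                        supporting = 1),
    class_pathogenic_min = 10,
    class_lp_min = 6,
    class_lb_max = -1,
    class_benign_max = -7,
    chi2_continuity_correction = FALSE,
    ci_z = 1.96
  )
  overrides <- list(...)
  if (length(overrides) > 0) {
    if (is.null(names(overrides)) || any(names(overrides) == ""))
      stop("threshold overrides must be named")
    bad <- setdiff(names(overrides), names(defaults))
    if (length(bad) > 0)
      stop("unknown threshold(s): ", paste(bad, collapse = ", "))
    defaults[names(overrides)] <- overrides
  }
  defaults
}
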