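#' @import methods
NULL

# ---- controlled vocabularies ------------------------------------------------

consequenceVocabulary <- function() {
  c("inframe_indel", "frameshift", "missense", "canonical_splice",
    "start_lost", "stop_lost", "stop_gained", "utr_deletion",
    "synonymous", "noncoding", "other")
}

clinvarVocabulary <- function() {
  c("pathogenic_multiple_unanimous", "pathogenic", "likely_pathogenic",
    "vus", "conflicting_blb_vus", "likely_benign", "benign", "absent")
}

classificationTiers <- function() {
  c("pathogenic", "likely_pathogenic", "vus", "likely_benign", "benign")
}

criterionVocabulary <- function() {
  c("PVS1", "PS1", "PS3", "PS4", "PM1", "PM2", "PM4", "PM5",
    "PP1", "PP2", "PP3", "BA1", "BS1", "BS3", "BS4", "BP3", "BP4", "BP7")
}

strengthVocabulary <- function() {
  c("very_strong", "strong", "moderate", "supporting", "stand_alone")
}

# ---- SimulationConfig -------------------------------------------------------

#' @rdname simulationConfig
#' @export
setClass("SimulationConfig", representation(
  cohortSize = "integer",
  perGenePrevalence = "numeric",
  classMix = "numeric",
  controlSize = "integer",
  controlPrevalence = "numeric",
  seed = "integer",
  nDistinctVariants = "integer",
  borderlineFraction = "numeric"
))

setValidity("SimulationConfig", function(object) {
  msgs <- character(0)
  if (object@cohortSize <= 0) msgs <- c(msgs, "cohort_size must be > 0")
  if (object@controlSize <= 0) msgs <- c(msgs, "control_size must be > 0")
  if (object@nDistinctVariants <= 0)
    msgs <- c(msgs, "n_distinct_variants must be > 0")
  panel <- panelGenes()
  badGenes <- setdiff(c(names(object@perGenePrevalence),
                        names(object@controlPrevalence)), panel)
  if (length(badGenes) > 0)
    msgs <- c(msgs, paste0("unknown gene symbol(s): ",
                           paste(unique(badGenes), collapse = ", ")))
  probs <- c(object@perGenePrevalence, object@controlPrevalence,
             object@borderlineFraction)
  if (any(is.na(probs)) || any(probs < 0) || any(probs > 1))
    msgs <- c(msgs, "all probabilities must lie in [0, 1]")
  mix <- object@classMix
  if (!setequal(names(mix), c("P", "LP", "VUS", "LB", "B")))
    msgs <- c(msgs, "class_mix must be named P, LP, VUS, LB, B")
  else if (abs(sum(mix) - 1) > 1e-9)
    msgs <- c(msgs, "class_mix proportions must sum to 1 (within 1e-9)")
  if (any(mix < 0)) msgs <- c(msgs, "class_mix proportions must be >= 0")
  if (length(msgs) > 0) msgs else TRUE
})

#' Simulation configuration for the synthetic cohort generator
#'
#' The defaults describe the study design the package models: a cohort of
#' 7091 exome-sequenced individuals screened against a 134,187-individual
#' non-cancer control population, with per-gene true pathogenic/likely
#' pathogenic carrier prevalences equal to the per-gene carrier frequencies
#' observed in that study, and a five-class mix of distinct variants
#' (pathogenic 60, likely pathogenic 14, VUS 396, likely benign 127,
#' benign 6, of 603 classified variants).
#'
#' @param cohort_size Number of simulated individuals.
#' @param per_gene_prevalence Named vector, gene -> probability that an
#'   individual carries a (truth) P/LP variant in that gene. Genes omitted
#'   get prevalence 0.
#' @param class_mix Named proportions (P, LP, VUS, LB, B) of distinct
#'   generated variants per truth class; must sum to 1.
#' @param control_size Control population size.
#' @param control_prevalence Named vector, gene -> control carrier
#'   probability.
#' @param seed Integer RNG seed; a fixed seed makes generation byte-identical.
#' @param n_distinct_variants Number of distinct variants to generate.
#' @param borderline_fraction Fraction of likely-pathogenic-truth variants
#'   deliberately given borderline annotation bundles (pext just under the
#'   relevant-transcript threshold), which the engine will demote to VUS;
#'   exercises the tolerance of the truth-compatibility contract.
#' @return A validated `SimulationConfig` object.
#' @examples
#' cfg <- simulationConfig(cohort_size = 500, seed = 7)
#' cohortSize(cfg)
#' @export
simulationConfig <- function(cohort_size = 7091L,
                             per_gene_prevalence = studyPrevalences(),
                             class_mix = c(P = 60, LP = 14, VUS = 396,
                                           LB = 127, B = 6) / 603,
                             control_size = 134187L,
                             control_prevalence = controlPrevalences(),
                             seed = 1L,
                             n_distinct_variants = 603L,
                             borderline_fraction = 0.01) {
  new("SimulationConfig",
      cohortSize = as.integer(cohort_size),
      perGenePrevalence = per_gene_prevalence,
      classMix = class_mix,
      controlSize = as.integer(control_size),
      controlPrevalence = control_prevalence,
      seed = as.integer(seed),
      nDistinctVariants = as.integer(n_distinct_variants),
      borderlineFraction = borderline_fraction)
}

#' Default per-gene carrier prevalences
#'
#' Per-gene heterozygote carrier frequencies (as fractions) used as the
#' generator's study-cohort defaults, and the matching control-population
#' frequencies. Genes in which no pathogenic variant was observed carry 0.
#'
#' @return Named numeric vector over the 17 panel genes.
#' @export
studyPrevalences <- function() {
  c(ATM = 0.0051, BARD1 = 0.0006, BRCA1 = 0.0040, BRCA2 = 0.0025,
    BRIP1 = 0.0004, CDH1 = 0.0004, CHEK2 = 0.0031, MLH1 = 0.0004,
    MSH2 = 0.0003, MSH6 = 0.0007, PALB2 = 0.0013, PMS2 = 0.0014,
    PTEN = 0, RAD51C = 0.0013, RAD51D = 0, STK11 = 0, TP53 = 0)
}

#' @rdname studyPrevalences
#' @export
controlPrevalences <- function() {
  c(ATM = 0.0029, BARD1 = 0.0006, BRCA1 = 0.0022, BRCA2 = 0.0030,
    BRIP1 = 0.0009, CDH1 = 0.0001, CHEK2 = 0.0057, MLH1 = 0.0003,
    MSH2 = 0.0001, MSH6 = 0.0009, PALB2 = 0.0015, PMS2 = 0.0012,
    PTEN = 0.0001, RAD51C = 0.0009, RAD51D = 0.0004, STK11 = 0,
    TP53 = 0.0002)
}

# ---- result containers ------------------------------------------------------

#' Synthetic cohort container
#'
#' Holds a generated annotated variant table, the truth records
#' (variant -> intended class), and the generating configuration.
#'
#' @slot variants Annotated variant `data.frame` in the interchange schema.
#' @slot truth `data.frame` with `variant_id`, `gene`, `intended_class`.
#' @slot config The `SimulationConfig` used.
#' @export
setClass("SyntheticCohort", representation(
  variants = "data.frame",
  truth = "data.frame",
  config = "SimulationConfig"
))

#' Prefilter result container
#'
#' @slot retained Variant `data.frame` of retained candidates.
#' @slot decisions One `data.frame` row per input variant: `variant_id`,
#'   `retained`, `stage`, `reason`.
#' @slot cascade Named list of cascade counts (input, per-stage exclusions,
#'   bypass additions, retained totals with and without bypass).
#' @export
setClass("PrefilterResult", representation(
  retained = "data.frame",
  decisions = "data.frame",
  cascade = "list"
))

setValidity("PrefilterResult", function(object) {
  d <- object@decisions
  if (nrow(d) > 0) {
    ok <- d$retained == (d$stage %in% c("retained", "bypass"))
    if (!all(ok)) return("retained flag inconsistent with stage")
  }
  TRUE
})

#' Classified variant set
#'
#' @slot table One row per classified variant: `variant_id`, `gene`,
#'   `criteria` (semicolon-joined `CRITERION@strength`), `points`,
#'   `classification`.
#' @slot audit Named list (by variant_id) of ordered rule-firing records.
#' @slot dropped `data.frame` of variants removed before classification
#'   (PMS2 homology mask), with reasons.
#' @export
setClass("ClassifiedVariants", representation(
  table = "data.frame",
  audit = "list",
  dropped = "data.frame"
))

#' Per-gene carrier summary of a cohort
#'
#' @slot nIndividuals Cohort size.
#' @slot carriers Named integer vector: gene -> distinct heterozygotes
#'   carrying at least one P/LP variant in that gene.
#' @slot variantCounts Named integer vector: gene -> distinct P/LP variants.
#' @export
setClass("CohortSummary", representation(
  nIndividuals = "integer",
  carriers = "integer",
  variantCounts = "integer"
))

setValidity("CohortSummary", function(object) {
  if (any(object@carriers < 0) || any(object@carriers > object@nIndividuals))
    return("carrier counts must lie in [0, nIndividuals]")
  TRUE
})

#' Per-gene burden table
#'
#' @slot table One row per panel gene plus a Sum row, mirroring the burden
#'   comparison: counts, frequencies (percent), odds ratio with 95 percent
#'   CI, chi-square statistic and p-value.
#' @slot nStudy Study cohort size.
#' @slot nControl Control population size.
#' @export
setClass("BurdenTable", representation(
  table = "data.frame",
  nStudy = "integer",
  nControl = "integer"
))

# ---- accessors --------------------------------------------------------------

#' @describeIn simulationConfig Cohort size of a configuration.
#' @param object,x A PanelBurden S4 object.
#' @export
setGeneric("cohortSize", function(object) standardGeneric("cohortSize"))
setMethod("cohortSize", "SimulationConfig", function(object) object@cohortSize)

#' Accessors for PanelBurden containers
#'
#' `variantTable()` returns the annotated variant table of a
#' `SyntheticCohort` or the retained table of a `PrefilterResult`;
#' `truthRecords()` the truth labels; `cohortConfig()` the generating
#' configuration; `filterDecisions()` and `cascadeCounts()` the prefilter
#' audit; `classificationTable()` and `classificationAudit()` the engine
#' output; `carrierCounts()` and `plpVariantCounts()` the per-gene summary;
#' `burdenTable()` the burden comparison `data.frame`.
#'
#' @param object A PanelBurden S4 object.
#' @return The underlying `data.frame`, vector or list.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("variantTable", function(object) standardGeneric("variantTable"))
setMethod("variantTable", "SyntheticCohort", function(object) object@variants)
setMethod("variantTable", "PrefilterResult", function(object) object@retained)

#' @rdname accessors
#' @export
setGeneric("truthRecords", function(object) standardGeneric("truthRecords"))
setMethod("truthRecords", "SyntheticCohort", function(object) object@truth)

#' @rdname accessors
#' @export
setGeneric("cohortConfig", function(object) standardGeneric("cohortConfig"))
setMethod("cohortConfig", "SyntheticCohort", function(object) object@config)

#' @rdname accessors
#' @export
setGeneric("filterDecisions",
           function(object) standardGeneric("filterDecisions"))
setMethod("filterDecisions", "PrefilterResult",
          function(object) object@decisions)

#' @rdname accessors
#' @export
setGeneric("cascadeCounts", function(object) standardGeneric("cascadeCounts"))
setMethod("cascadeCounts", "PrefilterResult", function(object) object@cascade)

#' @rdname accessors
#' @export
setGeneric("classificationTable",
           function(object) standardGeneric("classificationTable"))
setMethod("classificationTable", "ClassifiedVariants",
          function(object) object@table)

#' @rdname accessors
#' @export
setGeneric("classificationAudit",
           function(object) standardGeneric("classificationAudit"))
setMethod("classificationAudit", "ClassifiedVariants",
          function(object) object@audit)

#' @rdname accessors
#' @export
setGeneric("droppedVariants",
           function(object) standardGeneric("droppedVariants"))
setMethod("droppedVariants", "ClassifiedVariants",
          function(object) object@dropped)

#' @rdname accessors
#' @export
setGeneric("carrierCounts", function(object) standardGeneric("carrierCounts"))
setMethod("carrierCounts", "CohortSummary", function(object) object@carriers)
setMethod("cohortSize", "CohortSummary", function(object) object@nIndividuals)

#' @rdname accessors
#' @export
setGeneric("plpVariantCounts",
           function(object) standardGeneric("plpVariantCounts"))
setMethod("plpVariantCounts", "CohortSummary",
          function(object) object@variantCounts)

#' @rdname accessors
#' @export
setGeneric("burdenTable", function(object) standardGeneric("burdenTable"))
setMethod("burdenTable", "BurdenTable", function(object) object@table)

#' @rdname accessors
#' @export
setMethod("as.data.frame", "BurdenTable",
          function(x, ...) x@table)

# ---- show methods -----------------------------------------------------------

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig:", object@cohortSize, "individuals,",
      object@nDistinctVariants, "distinct variants, control N =",
      object@controlSize, "\n")
  cat("  genes with prevalence > 0:",
      sum(object@perGenePrevalence > 0), "| seed:", object@seed, "\n")
})

setMethod("show", "SyntheticCohort", function(object) {
  cat("SyntheticCohort:", nrow(object@variants), "variants across",
      length(unique(object@variants$gene)), "genes;",
      object@config@cohortSize, "individuals\n")
  cat("  truth classes:",
      paste(names(table(object@truth$intended_class)),
            table(object@truth$intended_class), collapse = ", "), "\n")
})

setMethod("show", "PrefilterResult", function(object) {
  cc <- object@cascade
  cat("PrefilterResult:", cc$n_input, "in ->", cc$n_retained, "retained (",
      cc$n_bypass, "via known-pathogenic bypass )\n")
  cat("  excluded: effect", cc$n_excluded_effect,
      "| frequency", cc$n_excluded_frequency,
      "| clinvar", cc$n_excluded_clinvar, "\n")
})

setMethod("show", "ClassifiedVariants", function(object) {
  cat("ClassifiedVariants:", nrow(object@table), "variants\n")
  tt <- table(factor(object@table$classification,
                     levels = classificationTiers()))
  cat(" ", paste(names(tt), tt, collapse = ", "), "\n")
  if (nrow(object@dropped) > 0)
    cat(" ", nrow(object@dropped), "dropped by homology mask\n")
})

setMethod("show", "CohortSummary", function(object) {
  cat("CohortSummary: N =", object@nIndividuals, ";",
      sum(object@carriers), "P/LP heterozygote carriers across",
      sum(object@carriers > 0), "genes\n")
})

setMethod("show", "BurdenTable", function(object) {
  cat("BurdenTable: study N =", object@nStudy,
      ", control N =", object@nControl, "\n")
  print(object@table, row.names = FALSE)
})
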