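#' Run the full burden pipeline
#'
#' Prefilters an annotated variant table, classifies the retained variants,
#' counts per-gene pathogenic/likely pathogenic heterozygote carriers, and
#' builds the burden comparison against a control summary. Outputs are
#' deterministic for fixed inputs. When `out_dir` is given, writes
#' `classification.tsv`, `burden.tsv`, `burden.json` and `audit.json`
#' (cascade counts, per-variant criteria, homology-mask drops and every
#' effective threshold).
#'
#' @param variants Annotated variant `data.frame` (interchange schema).
#' @param control Control summary `data.frame` (`gene`, `n_control`,
#'   `control_count` and/or `control_freq_percent`).
#' @param n_individuals Study cohort size.
#' @param profiles Gene profile table, see [geneProfiles()].
#' @param thresholds Threshold list, see [pipelineThresholds()].
#' @param out_dir Optional output directory (created if needed).
#' @param quiet Suppress progress messages on standard error.
#' @return List with elements `prefilter` ([PrefilterResult-class]),
#'   `classified` ([ClassifiedVariants-class]), `summary`
#'   ([CohortSummary-class]), `burden` ([BurdenTable-class]) and `audit`
#'   (the audit list written as JSON).
#' @examples
#' cohort <- generateCohort(simulationConfig(cohort_size = 300,
#'                                           n_distinct_variants = 60,
#'                                           seed = 11))
#' ctrl <- generateControl(cohortConfig(cohort), mode = "fixed")
#' res <- runPipeline(variantTable(cohort), ctrl, n_individuals = 300)
#' burdenTable(res$burden)
#' @export
runPipeline <- function(variants, control, n_individuals,
                        profiles = geneProfiles(),
                        thresholds = pipelineThresholds(),
                        out_dir = NULL, quiet = TRUE) {
  say <- function(...) if (!quiet) message("[PanelBurden] ", ...)

  say("prefilter: ", nrow(variants), " variants in")
  pf <- runPrefilter(variants, thresholds)
  say("prefilter: ", cascadeCounts(pf)$n_retained, " retained")

  cl <- classifyVariants(variantTable(pf), profiles, thresholds)
  tab <- classificationTable(cl)
  say("classified: ",
      sum(tab$classification %in% c("pathogenic", "likely_pathogenic"),
          na.rm = TRUE), " P/LP")

  summ <- countCarriers(cl, variants, n_individuals)
  burden <- buildBurdenTable(summ, control, thresholds)

  audit <- list(
    cascade = cascadeCounts(pf),
    filter_decisions = filterDecisions(pf),
    homology_mask_dropped = droppedVariants(cl),
    criteria = tab[, c("variant_id", "gene", "criteria", "points",
                       "classification")],
    rule_trace = classificationAudit(cl),
    thresholds = thresholds,
    n_individuals = as.integer(n_individuals)
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(tab, file.path(out_dir, "classification.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "NA")
    utils::write.table(burdenTable(burden),
                       file.path(out_dir, "burden.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, na = "NA")
    jsonlite::write_json(burdenTable(burden),
                         file.path(out_dir, "burden.json"),
                         dataframe = "rows", na = "null", digits = NA)
    jsonlite::write_json(audit, file.path(out_dir, "audit.json"),
                         dataframe = "rows", na = "null", auto_unbox = TRUE,
                         digits = NA)
    say("wrote outputs to ", out_dir)
  }

  list(prefilter = pf, classified = cl, summary = summ, burden = burden,
       audit = audit)
}
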