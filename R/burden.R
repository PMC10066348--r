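#' Carrier-burden statistics
#'
#' Per-gene aggregation of pathogenic/likely pathogenic (P/LP) heterozygote
#' carriers and comparison of study-cohort carrier frequencies to a control
#' population via two-tailed Pearson chi-square tests and odds ratios with
#' Woolf (log-normal) 95 percent confidence intervals.
#'
#' @name burdenStats
NULL

#' Count P/LP heterozygote carriers per gene
#'
#' For each panel gene, counts the distinct individuals carrying at least
#' one variant classified pathogenic or likely pathogenic in that gene; an
#' individual with two P/LP variants in the same gene counts once.
#'
#' @param classified A [ClassifiedVariants-class] object.
#' @param variants Annotated variant `data.frame` carrying the genotype link
#'   (`carrier_ids`, semicolon-separated individual identifiers per
#'   variant); every classified variant must be present.
#' @param n_individuals Cohort size.
#' @param genes Genes to summarise (default: the 17-gene panel).
#' @return A [CohortSummary-class] object.
#' @examples
#' pf <- runPrefilter(exampleVariants())
#' cl <- classifyVariants(variantTable(pf))
#' countCarriers(cl, exampleVariants(), n_individuals = 100)
#' @export
countCarriers <- function(classified, variants, n_individuals,
                          genes = panelGenes()) {
  stopIfNotScalarCount(n_individuals, "n_individuals")
  tab <- classificationTable(classified)
  missing <- setdiff(tab$variant_id, variants$variant_id)
  if (length(missing) > 0)
    stop("classified variant absent from genotype table: ",
         paste(missing, collapse = ", "))
  plp <- tab[!is.na(tab$classification) &
               tab$classification %in% c("pathogenic", "likely_pathogenic"), ,
             drop = FALSE]
  carriers <- stats::setNames(integer(length(genes)), genes)
  nVariants <- stats::setNames(integer(length(genes)), genes)
  idx <- match(plp$variant_id, variants$variant_id)
  carrierList <- strsplit(variants$carrier_ids[idx], ";", fixed = TRUE)
  for (g in unique(plp$gene)) {
    rows <- which(plp$gene == g)
    ids <- unique(unlist(carrierList[rows]))
    ids <- ids[!is.na(ids) & nzchar(ids)]
    carriers[g] <- length(ids)
    nVariants[g] <- length(rows)
  }
  new("CohortSummary", nIndividuals = as.integer(n_individuals),
      carriers = carriers, variantCounts = nVariants)
}

#' Carrier frequency as a display percentage
#'
#' `100 * count / n`, rounded half-up to two decimals, the display
#' convention of the burden table.
#'
#' @param count Carrier count (0 <= count <= n).
#' @param n Cohort size (> 0).
#' @return Numeric percentage with two decimals.
#' @examples
#' prevalencePercent(36, 7091)   # 0.51
#' prevalencePercent(152, 7091)  # 2.14
#' @export
prevalencePercent <- function(count, n) {
  stopIfNotScalarCount(n, "n")
  if (n == 0) stop("n must be > 0")
  if (any(is.na(count)) || any(count < 0) || any(count > n))
    stop("count must lie in [0, n]")
  roundHalfUp(100 * count / n, 2)
}

#' Reconstruct a control carrier count from a published frequency
#'
#' Control populations are often published only as per-gene carrier
#' frequencies with a population size; this inverts the percentage to the
#' nearest integer count (half-up).
#'
#' @param freq_percent Carrier frequency in percent (0-100).
#' @param n Control population size.
#' @return Integer count.
#' @examples
#' controlCountFromFreq(2.10, 134187)  # 2818
#' @export
controlCountFromFreq <- function(freq_percent, n) {
  stopIfNotScalarCount(n, "n")
  if (any(!is.na(freq_percent) & (freq_percent < 0 | freq_percent > 100)))
    stop("freq_percent must lie in [0, 100]")
  as.integer(roundHalfUp(freq_percent / 100 * n, 0))
}

#' Two-tailed Pearson chi-square test on a 2x2 table
#'
#' Pearson chi-square with one degree of freedom, by default without Yates
#' continuity correction, on the table `rbind(c(a, b), c(c, d))` (carriers /
#' non-carriers in study and control). Returns NA with an audit note when a
#' margin is zero.
#'
#' @param a,b,c,d Non-negative cell counts (study carriers, study
#'   non-carriers, control carriers, control non-carriers).
#' @param thresholds Threshold list (uses `chi2_continuity_correction`).
#' @return List with `statistic`, `p_value`, and `note` (NULL unless the
#'   test was not computable).
#' @examples
#' chiSquare2x2(20, 80, 10, 90)
#' @export
chiSquare2x2 <- function(a, b, c, d, thresholds = pipelineThresholds()) {
  cells <- c(a, b, c, d)
  if (any(is.na(cells)) || any(cells < 0))
    stop("all cell counts must be non-negative")
  m <- matrix(cells, nrow = 2, byrow = TRUE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    return(list(statistic = NA_real_, p_value = NA_real_,
                note = "zero margin: chi-square not computable"))
  res <- suppressWarnings(
    stats::chisq.test(m, correct = thresholds$chi2_continuity_correction))
  list(statistic = unname(res$statistic), p_value = unname(res$p.value),
       note = NULL)
}

#' Odds ratio with Woolf 95 percent confidence interval
#'
#' `OR = (a * d) / (b * c)`, with the log-normal (Woolf) interval
#' `exp(log(OR) +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`. Any zero cell yields
#' NA, matching the convention of reporting NA for genes without carriers.
#'
#' @inheritParams chiSquare2x2
#' @param thresholds Threshold list (uses `ci_z`).
#' @return List with `or`, `ci_low`, `ci_high` (all NA when a cell is zero).
#' @examples
#' oddsRatioCI(152, 6939, 2818, 131369)
#' @export
oddsRatioCI <- function(a, b, c, d, thresholds = pipelineThresholds()) {
  cells <- c(a, b, c, d)
  if (any(is.na(cells)) || any(cells < 0))
    stop("all cell counts must be non-negative")
  if (any(cells == 0))
    return(list(or = NA_real_, ci_low = NA_real_, ci_high = NA_real_))
  or <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  z <- thresholds$ci_z
  list(or = or, ci_low = exp(log(or) - z * se),
       ci_high = exp(log(or) + z * se))
}

#' Build the per-gene burden table
#'
#' One row per panel gene plus a `Sum` row comparing study P/LP carrier
#' frequencies to the control population. Control carrier counts are taken
#' from the `control_count` column where present, otherwise reconstructed
#' from `control_freq_percent` with [controlCountFromFreq()]. Genes with
#' zero study carriers (or no usable control entry) carry NA statistics.
#' The `Sum` row totals per-gene carrier counts, so an individual carrying
#' P/LP variants in two genes is counted once per gene.
#'
#' Displayed columns follow the table convention: frequencies and odds
#' ratios rounded half-up to two decimals, chi-square statistics to three;
#' p-values are unrounded.
#'
#' @param study A [CohortSummary-class] for the study cohort.
#' @param control Control summary `data.frame` with columns `gene`,
#'   `n_control` and `control_count` and/or `control_freq_percent`.
#' @param thresholds Threshold list from [pipelineThresholds()].
#' @return A [BurdenTable-class] object.
#' @examples
#' study <- new("CohortSummary", nIndividuals = 7091L,
#'              carriers = stats::setNames(integer(17), panelGenes()),
#'              variantCounts = stats::setNames(integer(17), panelGenes()))
#' ctrl <- data.frame(gene = panelGenes(), control_freq_percent = 0.1,
#'                    n_control = 134187L)
#' buildBurdenTable(study, ctrl)
#' @export
buildBurdenTable <- function(study, control,
                             thresholds = pipelineThresholds()) {
  genes <- panelGenes()
  badGene <- setdiff(control$gene, genes)
  if (length(badGene) > 0)
    stop("control summary contains gene(s) outside the panel: ",
         paste(badGene, collapse = ", "))
  nStudy <- cohortSize(study)
  nControl <- as.integer(max(control$n_control, na.rm = TRUE))

  ctrlIdx <- match(genes, control$gene)
  ctrlCount <- rep(NA_integer_, length(genes))
  for (i in seq_along(genes)) {
    j <- ctrlIdx[i]
    if (is.na(j)) next
    if ("control_count" %in% names(control) &&
        !is.na(control$control_count[j])) {
      ctrlCount[i] <- as.integer(control$control_count[j])
    } else if ("control_freq_percent" %in% names(control) &&
               !is.na(control$control_freq_percent[j])) {
      ctrlCount[i] <- controlCountFromFreq(control$control_freq_percent[j],
                                           control$n_control[j])
    }
  }

  studyCount <- carrierCounts(study)[genes]
  studyCount[is.na(studyCount)] <- 0L
  nPlp <- plpVariantCounts(study)[genes]
  nPlp[is.na(nPlp)] <- 0L

  oneRow <- function(gene, splp, scount, ccount) {
    sfreq <- prevalencePercent(scount, nStudy)
    cfreq <- if (is.na(ccount)) NA_real_ else
      prevalencePercent(ccount, nControl)
    if (scount == 0 || is.na(ccount)) {
      return(data.frame(gene = gene,
                        n_plp_variants = ifelse(scount == 0, NA_integer_,
                                                splp),
                        study_count = ifelse(scount == 0, NA_integer_,
                                             scount),
                        study_freq_percent = ifelse(scount == 0, NA_real_,
                                                    sfreq),
                        control_freq_percent = cfreq,
                        odds_ratio = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, chi2 = NA_real_,
                        p_value = NA_real_, stringsAsFactors = FALSE))
    }
    orci <- oddsRatioCI(scount, nStudy - scount, ccount, nControl - ccount,
                        thresholds)
    chi <- chiSquare2x2(scount, nStudy - scount, ccount, nControl - ccount,
                        thresholds)
    data.frame(gene = gene, n_plp_variants = splp, study_count = scount,
               study_freq_percent = sfreq, control_freq_percent = cfreq,
               odds_ratio = roundHalfUp(orci$or, 2),
               ci_low = roundHalfUp(orci$ci_low, 2),
               ci_high = roundHalfUp(orci$ci_high, 2),
               chi2 = roundHalfUp(chi$statistic, 3),
               p_value = chi$p_value, stringsAsFactors = FALSE)
  }

  rows <- lapply(seq_along(genes), function(i)
    oneRow(genes[i], nPlp[i], studyCount[i], ctrlCount[i]))
  sumRow <- oneRow("Sum", sum(nPlp), sum(studyCount),
                   if (all(is.na(ctrlCount))) NA_integer_ else
                     sum(ctrlCount, na.rm = TRUE))
  new("BurdenTable", table = do.call(rbind, c(rows, list(sumRow))),
      nStudy = nStudy, nControl = nControl)
}
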