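#' Synthetic annotated cohort generation
#'
#' Generates an annotated variant table, cohort genotypes and truth records
#' with the statistical structure the downstream analysis assumes, so the
#' whole pipeline is testable without patient data. Distinct variants are
#' drawn in a configurable five-class truth mix; each truth class maps to an
#' annotation regime:
#'
#' * `P`: null variant (frameshift/stop gain) in a haploinsufficient gene,
#'   NMD-predicted, relevant transcript (pext above threshold), absent from
#'   gnomAD, with a damaging functional study -- very strong + supporting +
#'   strong evidence, classified pathogenic.
#' * `LP`: the same null regime without literature evidence (PVS1 +
#'   PM2_supporting, 9 points, likely pathogenic); a configurable fraction
#'   is deliberately generated borderline (pext just below the relevant
#'   transcript threshold), which the engine demotes to VUS.
#' * `VUS`: rare missense (or occasionally a canonical splice variant whose
#'   frame impact is unassessed) with no domain, constraint, or literature
#'   support -- at most PM2-level evidence.
#' * `LB`: ClinVar likely benign / conflicting-B-LB-VUS missense at modest
#'   gnomAD frequency; removed by the ClinVar prefilter stage.
#' * `B`: common variants (gnomAD heterozygote counts far above the filter
#'   ceiling) and/or ClinVar benign; removed by the frequency or ClinVar
#'   prefilter stage.
#'
#' Cohort carriage: for every gene, each individual is an independent
#' Bernoulli carrier of a truth-P/LP variant with the configured per-gene
#' prevalence; gene carriers are then partitioned uniformly across that
#' gene's P/LP variants, so each individual carries at most one variant per
#' gene. Non-P/LP variants receive background carriers at rates proportional
#' to the same per-gene prevalence (so a zero-prevalence configuration
#' yields a cohort with no carriers at all), drawn from individuals not yet
#' carrying a variant in that gene.
#'
#' @param config A [simulationConfig()] object.
#' @return A [SyntheticCohort-class] holding the variant table (interchange
#'   schema, including `carrier_ids` genotypes), the truth records and the
#'   configuration.
#' @examples
#' cohort <- generateCohort(simulationConfig(cohort_size = 200,
#'                                           n_distinct_variants = 40,
#'                                           seed = 7))
#' cohort
#' @export
generateCohort <- function(config) {
  validObject(config)
  set.seed(config@seed)

  panel <- genePanel()
  profiles <- geneProfiles()
  nVar <- config@nDistinctVariants
  nInd <- config@cohortSize
  individuals <- sprintf("IND%05d", seq_len(nInd))

  prev <- stats::setNames(numeric(nrow(panel)), panel$gene)
  prev[names(config@perGenePrevalence)] <- config@perGenePrevalence

  # largest-remainder apportionment of the class mix
  mix <- config@classMix[c("P", "LP", "VUS", "LB", "B")]
  raw <- mix * nVar
  counts <- floor(raw)
  rem <- nVar - sum(counts)
  if (rem > 0) {
    order <- order(raw - counts, decreasing = TRUE)
    counts[order[seq_len(rem)]] <- counts[order[seq_len(rem)]] + 1
  }
  classes <- rep(names(counts), counts)

  # gene assignment: P/LP variants go to genes in proportion to prevalence
  # (every prevalent gene receives at least one), others uniformly
  prevGenes <- names(prev)[prev > 0]
  genes <- character(nVar)
  isPlp <- classes %in% c("P", "LP")
  nPlp <- sum(isPlp)
  if (nPlp > 0) {
    if (length(prevGenes) == 0)
      stop("class mix requests P/LP variants but all prevalences are 0")
    plpGenes <- prevGenes[seq_len(min(nPlp, length(prevGenes)))]
    if (nPlp > length(prevGenes))
      plpGenes <- c(plpGenes,
                    sample(prevGenes, nPlp - length(prevGenes),
                           replace = TRUE, prob = prev[prevGenes]))
    genes[isPlp] <- sample(plpGenes)  # shuffle so classes mix across genes
  }
  genes[!isPlp] <- sample(panel$gene, nVar - nPlp, replace = TRUE)

  chromOf <- c(ATM = "11", BARD1 = "2", BRCA1 = "17", BRCA2 = "13",
               BRIP1 = "17", CDH1 = "16", CHEK2 = "22", MLH1 = "3",
               MSH2 = "2", MSH6 = "2", PALB2 = "16", PMS2 = "7",
               PTEN = "10", RAD51C = "17", RAD51D = "17", STK11 = "19",
               TP53 = "17")
  pos <- sample.int(150000000L, nVar)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, nVar, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
  variantId <- paste0(chromOf[genes], ":", pos, ":", ref, ":", alt)

  gnomadN <- 2L * config@controlSize  # allele denominator for af bookkeeping

  v <- data.frame(
    variant_id = variantId,
    gene = genes,
    transcript = panel$transcript[match(genes, panel$gene)],
    consequence = "missense",
    splice_ada = NA_real_,
    splice_rf = NA_real_,
    gnomad_het_count = 0L,
    gnomad_hom_count = 0L,
    gnomad_af = 0,
    local_carrier_count = 0L,
    local_hom_count = 0L,
    clinvar_status = "absent",
    clinvar_same_aa_pathogenic = FALSE,
    clinvar_other_aa_change_pathogenic = FALSE,
    pext = round(stats::runif(nVar, 0.6, 1), 3),
    gene_z_score = profiles$z_score[match(genes, profiles$gene)],
    in_functional_domain = FALSE,
    in_repeat_region = FALSE,
    phastcons = round(stats::runif(nVar), 3),
    hsf_splice_impact = FALSE,
    nmd_predicted_by_position = FALSE,
    known_pathogenic_downstream = FALSE,
    splice_frame_disrupted = NA,
    pms2_unique_region = TRUE,
    lit_case_control_or = NA_real_,
    lit_patient_count = 0L,
    lit_functional = "none",
    lit_segregation = "none",
    in_silico_consensus = "mixed",
    carrier_ids = "",
    stringsAsFactors = FALSE
  )

  for (i in seq_len(nVar)) {
    cls <- classes[i]
    if (cls %in% c("P", "LP")) {
      borderline <- cls == "LP" &&
        stats::runif(1) < config@borderlineFraction
      splice <- stats::runif(1) < 0.2
      if (splice) {
        v$consequence[i] <- "canonical_splice"
        v$splice_frame_disrupted[i] <- TRUE
        v$splice_ada[i] <- round(stats::runif(1, 0.8, 1), 3)
        v$splice_rf[i] <- round(stats::runif(1, 0.8, 1), 3)
      } else {
        v$consequence[i] <- sample(c("frameshift", "stop_gained"), 1)
        v$nmd_predicted_by_position[i] <- TRUE
      }
      if (borderline) v$pext[i] <- round(stats::runif(1, 0.3, 0.5), 3)
      if (cls == "P") {
        v$lit_functional[i] <- "damaging"
        v$in_silico_consensus[i] <- "pathogenic"
        v$clinvar_status[i] <- sample(
          c("pathogenic_multiple_unanimous", "pathogenic", "absent"), 1,
          prob = c(0.5, 0.3, 0.2))
        v$lit_patient_count[i] <- sample(0:6, 1)
      } else {
        v$clinvar_status[i] <- sample(c("absent", "likely_pathogenic"), 1,
                                      prob = c(0.8, 0.2))
      }
    } else if (cls == "VUS") {
      if (stats::runif(1) < 0.1) {
        v$consequence[i] <- "canonical_splice"  # frame impact unassessed
        v$splice_ada[i] <- round(stats::runif(1, 0.6, 0.9), 3)
      } else {
        v$consequence[i] <- "missense"
      }
      v$gnomad_af[i] <- sample(c(0, stats::runif(1, 1e-6, 1.5e-5)), 1)
      if (v$gnomad_af[i] > 0) {
        v$gnomad_het_count[i] <-
          max(1L, as.integer(round(v$gnomad_af[i] * gnomadN)))
      }
      v$clinvar_status[i] <- sample(c("absent", "vus"), 1)
    } else if (cls == "LB") {
      v$consequence[i] <- "missense"
      v$gnomad_het_count[i] <- sample(3:10, 1)
      v$gnomad_af[i] <- v$gnomad_het_count[i] / gnomadN
      v$clinvar_status[i] <- sample(c("likely_benign", "conflicting_blb_vus"),
                                    1, prob = c(0.7, 0.3))
      v$in_silico_consensus[i] <- "benign"
    } else { # B
      v$consequence[i] <- sample(c("missense", "synonymous"), 1,
                                 prob = c(0.7, 0.3))
      v$gnomad_het_count[i] <- sample(50:500, 1)
      v$gnomad_hom_count[i] <- sample(0:6, 1)
      v$gnomad_af[i] <- (v$gnomad_het_count[i] + 2 * v$gnomad_hom_count[i]) /
        gnomadN
      v$clinvar_status[i] <- sample(c("benign", "absent"), 1,
                                    prob = c(0.6, 0.4))
      v$phastcons[i] <- round(stats::runif(1, 0, 0.15), 3)
      v$in_silico_consensus[i] <- "benign"
    }
    if (genes[i] == "PMS2" && !(cls %in% c("P", "LP")) &&
        stats::runif(1) < 0.3)
      v$pms2_unique_region[i] <- FALSE
  }

  # cohort carriage, gene by gene; at most one variant per gene per person
  carrierSets <- vector("list", nVar)
  for (g in unique(genes)) {
    geneRows <- which(genes == g)
    available <- individuals
    plpRows <- geneRows[classes[geneRows] %in% c("P", "LP")]
    if (prev[g] > 0 && length(plpRows) > 0) {
      isCarrier <- stats::runif(nInd) < prev[g]
      carriers <- individuals[isCarrier]
      if (length(carriers) > 0) {
        assignment <- sample(seq_along(plpRows), length(carriers),
                             replace = TRUE)
        for (k in seq_along(plpRows))
          carrierSets[[plpRows[k]]] <- carriers[assignment == k]
        available <- setdiff(available, carriers)
      }
    }
    bgScale <- c(P = 0, LP = 0, VUS = 0.5, LB = 0.5, B = 2)
    for (row in geneRows[!(classes[geneRows] %in% c("P", "LP"))]) {
      rate <- prev[g] * bgScale[[classes[row]]]
      if (rate <= 0 || length(available) == 0) next
      nCarr <- min(stats::rbinom(1, nInd, rate), length(available))
      if (nCarr > 0) {
        picked <- sample(available, nCarr)
        carrierSets[[row]] <- picked
        available <- setdiff(available, picked)
      }
    }
  }
  v$carrier_ids <- vapply(carrierSets, function(ids)
    paste(sort(ids), collapse = ";"), character(1))
  v$local_carrier_count <- vapply(carrierSets, length, integer(1))

  truth <- data.frame(variant_id = v$variant_id, gene = v$gene,
                      intended_class = classes, stringsAsFactors = FALSE)
  rownames(v) <- NULL
  new("SyntheticCohort", variants = v, truth = truth, config = config)
}

#' Generate a control-population summary
#'
#' In `"sampled"` mode, per-gene control carrier counts are drawn
#' `Binomial(control_size, control_prevalence[gene])` (an RNG stream derived
#' from `seed + 1`, independent of the cohort stream). In `"fixed"` mode the
#' configured prevalences are emitted exactly as frequencies, with counts
#' reconstructed by half-up rounding -- the form in which published control
#' populations are typically available.
#'
#' @param config A [simulationConfig()] object.
#' @param mode `"sampled"` or `"fixed"`.
#' @return Control summary `data.frame` with columns `gene`,
#'   `control_count`, `control_freq_percent`, `n_control`.
#' @examples
#' generateControl(simulationConfig(seed = 3), mode = "fixed")
#' @export
generateControl <- function(config, mode = c("sampled", "fixed")) {
  validObject(config)
  mode <- match.arg(mode)
  genes <- panelGenes()
  prev <- stats::setNames(numeric(length(genes)), genes)
  prev[names(config@controlPrevalence)] <- config@controlPrevalence
  n <- config@controlSize
  if (mode == "fixed") {
    freq <- prev * 100
    count <- vapply(freq, controlCountFromFreq, integer(1), n = n)
  } else {
    set.seed((config@seed %% .Machine$integer.max) + 1L)
    count <- stats::rbinom(length(genes), n, prev)
    freq <- 100 * count / n
  }
  data.frame(gene = genes, control_count = as.integer(count),
             control_freq_percent = freq, n_control = n,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' A small hand-built annotated variant table
#'
#' Eight variants spanning the annotation regimes (an NMD null, a known
#' pathogenic bypass variant, a frame-disrupting splice variant, rare
#' missense VUS, a likely-benign, a common benign, a silent variant and a
#' PMS2 homology-masked variant), used in examples and quick checks.
#'
#' @return Annotated variant `data.frame` in the interchange schema.
#' @examples
#' exampleVariants()
#' @export
exampleVariants <- function() {
  base <- data.frame(
    variant_id = c("17:43045000:G:A", "13:32340300:T:C", "11:108284000:C:T",
                   "17:43100001:A:T", "16:23635000:G:T", "22:28695000:C:G",
                   "2:215595000:T:A", "7:6003000:G:C"),
    gene = c("BRCA1", "BRCA2", "ATM", "BRCA1", "PALB2", "CHEK2", "BARD1",
             "PMS2"),
    consequence = c("frameshift", "canonical_splice", "stop_gained",
                    "missense", "missense", "missense", "synonymous",
                    "missense"),
    splice_ada = c(NA, 0.97, NA, NA, NA, NA, 0.1, NA),
    splice_rf = c(NA, 0.92, NA, NA, NA, NA, NA, NA),
    gnomad_het_count = c(0L, 3L, 0L, 2L, 8L, 250L, 4L, 1L),
    gnomad_hom_count = 0L,
    gnomad_af = c(0, 1.1e-5, 0, 7e-6, 3e-5, 9.3e-4, 1.5e-5, 4e-6),
    local_carrier_count = c(3L, 2L, 1L, 1L, 2L, 15L, 2L, 1L),
    local_hom_count = 0L,
    clinvar_status = c("absent", "pathogenic_multiple_unanimous", "absent",
                       "vus", "likely_benign", "benign", "vus", "vus"),
    clinvar_same_aa_pathogenic = FALSE,
    clinvar_other_aa_change_pathogenic = FALSE,
    pext = c(0.95, 0.88, 0.91, 0.85, 0.8, 0.75, 0.7, 0.82),
    gene_z_score = c(-0.75, -1.3, 1.21, -0.75, -0.79, 0.36, -0.46, -0.05),
    in_functional_domain = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE,
                             FALSE),
    in_repeat_region = FALSE,
    phastcons = c(0.99, 0.97, 0.98, 0.9, 0.5, 0.2, 0.05, 0.6),
    hsf_splice_impact = FALSE,
    nmd_predicted_by_position = c(TRUE, FALSE, TRUE, FALSE, FALSE, FALSE,
                                  FALSE, FALSE),
    known_pathogenic_downstream = FALSE,
    splice_frame_disrupted = c(NA, TRUE, NA, NA, NA, NA, NA, NA),
    pms2_unique_region = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE),
    lit_case_control_or = NA_real_,
    lit_patient_count = c(0L, 6L, 0L, 0L, 0L, 0L, 0L, 0L),
    lit_functional = c("none", "damaging", "none", "none", "none", "none",
                       "none", "none"),
    lit_segregation = "none",
    in_silico_consensus = c("pathogenic", "pathogenic", "pathogenic",
                            "mixed", "benign", "benign", "benign", "mixed"),
    carrier_ids = c("IND00001;IND00002;IND00003", "IND00004;IND00005",
                    "IND00006", "IND00007", "IND00008;IND00009",
                    paste(sprintf("IND%05d", 10:24), collapse = ";"),
                    "IND00025;IND00026", "IND00027"),
    stringsAsFactors = FALSE
  )
  panel <- genePanel()
  base$transcript <- panel$transcript[match(base$gene, panel$gene)]
  base[, variantColumnOrder()]
}
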