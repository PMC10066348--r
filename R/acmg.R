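#' ACMG/AMP criterion assignment and point-based combination
#'
#' The engine assigns the evidence criteria used in this analysis at their
#' customised strengths from the annotation fields of a single variant plus
#' its gene profile, then combines them into a five-tier classification with
#' a point-based recasting of the combining rules (very strong 8, strong 4,
#' moderate 2, supporting 1; benign evidence negative; pathogenic at >= 10
#' points, likely pathogenic 6-9, VUS 0-5, likely benign -6..-1, benign
#' <= -7; BA1 is stand-alone benign). Under this scale a very strong plus a
#' moderate criterion reach pathogenic, two strong criteria reach likely
#' pathogenic, and PVS1 plus PM2_supporting alone reach likely pathogenic.
#'
#' Individual assigners take one variant (a one-row `data.frame` or a named
#' list) and return a zero-or-more-row criterion `data.frame` with columns
#' `criterion`, `strength`, `rationale`; notes for the audit trail are
#' attached as the `"notes"` attribute.
#'
#' @param v A single annotated variant (named list or one-row `data.frame`).
#' @param profile The variant gene's one-row entry of [geneProfiles()].
#' @param thresholds Threshold list from [pipelineThresholds()].
#' @name acmgEngine
NULL

criterionAssignment <- function(criterion, strength, rationale) {
  data.frame(criterion = criterion, strength = strength,
             rationale = rationale, stringsAsFactors = FALSE)
}

emptyCriteria <- function() {
  data.frame(criterion = character(0), strength = character(0),
             rationale = character(0), stringsAsFactors = FALSE)
}

asVariantList <- function(v) {
  if (is.data.frame(v)) {
    stopifnot(nrow(v) == 1)
    v <- as.list(v)
  }
  v
}

#' @describeIn acmgEngine Loss-of-function criterion (PVS1) via the
#'   decision-tree logic: only in genes where loss of function is the
#'   disease mechanism (haploinsufficient), only for null consequences
#'   (frameshift, stop gain, canonical splice, start loss), and only when
#'   the variant hits a biologically relevant transcript (exon pext above
#'   `pext_min`). Nulls predicted to undergo nonsense-mediated decay
#'   (premature stop 5' of the last 50 nt of the penultimate exon, or known
#'   pathogenic variants downstream) take very strong; NMD-escaping nulls in
#'   a relevant exon take strong. Canonical splice variants use reading-frame
#'   disruption in place of the NMD position rule (frame-disrupting -> very
#'   strong path, frame-preserving -> strong); if frame disruption was not
#'   assessed the evidence is unassessable and a VUS-forcing note is
#'   emitted. Start-loss takes the initiation-codon branch default
#'   (moderate).
#' @export
assignPvs1 <- function(v, profile, thresholds = pipelineThresholds()) {
  v <- asVariantList(v)
  out <- emptyCriteria()
  notes <- character(0)
  nullCons <- c("frameshift", "stop_gained", "canonical_splice", "start_lost")
  if (isTRUE(profile$haploinsufficient) && v$consequence %in% nullCons) {
    if (is.na(v$pext) || v$pext <= thresholds$pext_min) {
      notes <- c(notes, paste0(
        "PVS1 withheld: exon pext ", v$pext %||% NA,
        " does not exceed ", thresholds$pext_min,
        " (not a biologically relevant transcript)"))
    } else if (v$consequence %in% c("frameshift", "stop_gained")) {
      nmd <- isTRUE(v$nmd_predicted_by_position) ||
        isTRUE(v$known_pathogenic_downstream)
      if (nmd) {
        out <- criterionAssignment("PVS1", "very_strong",
          "null variant predicted to undergo nonsense-mediated decay in a haploinsufficient gene")
      } else {
        out <- criterionAssignment("PVS1", "strong",
          "NMD-escaping null variant in a biologically relevant exon of a haploinsufficient gene")
      }
    } else if (v$consequence == "canonical_splice") {
      if (is.na(v$splice_frame_disrupted)) {
        notes <- c(notes, paste0(
          "PVS1 unassessable for canonical splice variant: ",
          "reading-frame disruption not determined; forcing VUS-level caution"))
      } else if (isTRUE(v$splice_frame_disrupted)) {
        out <- criterionAssignment("PVS1", "very_strong",
          "canonical splice variant disrupting the reading frame in a haploinsufficient gene")
      } else {
        out <- criterionAssignment("PVS1", "strong",
          "canonical splice variant preserving the reading frame in a haploinsufficient gene")
      }
    } else if (v$consequence == "start_lost") {
      out <- criterionAssignment("PVS1", "moderate",
        "initiation codon loss in a haploinsufficient gene (decision-tree default strength)")
    }
  }
  attr(out, "notes") <- notes
  out
}

#' @describeIn acmgEngine Case/control and case-count criterion (PS4).
#'   For variants above the `ps4_common_af` gnomAD frequency, strong when a
#'   case-control study reports an odds ratio above `ps4_or_min`. For
#'   extremely rare variants (below that frequency), tiered by previously
#'   reported patients carrying the variant: more than 4 strong, more than
#'   2 moderate, more than 1 supporting. A frequency exactly at the boundary
#'   falls into the common-variant branch.
#' @export
assignPs4 <- function(v, thresholds = pipelineThresholds()) {
  v <- asVariantList(v)
  af <- v$gnomad_af
  if (is.na(af)) return(emptyCriteria())
  if (af >= thresholds$ps4_common_af) {
    or <- v$lit_case_control_or
    if (!is.null(or) && !is.na(or) && or > thresholds$ps4_or_min)
      return(criterionAssignment("PS4", "strong",
        sprintf("case-control odds ratio %.2f > %s", or,
                thresholds$ps4_or_min)))
    return(emptyCriteria())
  }
  np <- v$lit_patient_count
  if (is.null(np) || is.na(np)) np <- 0L
  if (np > thresholds$ps4_strong_patients)
    return(criterionAssignment("PS4", "strong",
      sprintf("extremely rare; %d previously reported patients", np)))
  if (np > thresholds$ps4_moderate_patients)
    return(criterionAssignment("PS4", "moderate",
      sprintf("extremely rare; %d previously reported patients", np)))
  if (np > thresholds$ps4_supporting_patients)
    return(criterionAssignment("PS4", "supporting",
      sprintf("extremely rare; %d previously reported patients", np)))
  emptyCriteria()
}

#' @describeIn acmgEngine Population-frequency criteria: BA1 (stand-alone
#'   benign) at gnomAD allele frequency at or above `ba1_af`; otherwise BS1
#'   (strong benign) above the gene-specific `bs1_cutoff`; otherwise PM2 at
#'   supporting strength when the variant is at or below `pm2_af` or absent
#'   from gnomAD. BA1/BS1 and PM2 are mutually exclusive by construction.
#' @export
assignFrequencyCriteria <- function(v, profile,
                                    thresholds = pipelineThresholds()) {
  v <- asVariantList(v)
  af <- v$gnomad_af
  if (is.na(af)) return(emptyCriteria())
  if (af >= thresholds$ba1_af)
    return(criterionAssignment("BA1", "stand_alone",
      sprintf("gnomAD allele frequency %.3g >= %.3g", af, thresholds$ba1_af)))
  if (af > profile$bs1_cutoff)
    return(criterionAssignment("BS1", "strong",
      sprintf("gnomAD allele frequency %.3g above the gene benign cut-off %.3g",
              af, profile$bs1_cutoff)))
  absent <- af == 0 &&
    isTRUE((v$gnomad_het_count %||% 0) == 0) &&
    isTRUE((v$gnomad_hom_count %||% 0) == 0)
  if (absent || af <= thresholds$pm2_af)
    return(criterionAssignment("PM2", "supporting",
      if (absent) "absent from gnomAD"
      else sprintf("gnomAD allele frequency %.3g <= %.3g", af,
                   thresholds$pm2_af)))
  emptyCriteria()
}

#' @describeIn acmgEngine All remaining criteria from annotation fields:
#'   PP2 (missense in a gene with constraint z above `pp2_z_min`), PS1
#'   (same amino-acid change known pathogenic), PM5 (different change at a
#'   residue with a known pathogenic change, not co-assigned with PS1),
#'   PP3/BP4 (agreement of multiple in silico predictors, taken from the
#'   upstream consensus field), BP7 (synonymous, weakly conserved, no
#'   predicted splice-site impact), PM4 (protein-length change outside a
#'   repeat region), BP3 (inframe indel inside a repeat region), PM1
#'   (missense in an annotated functional domain), PS3/BS3 (published
#'   functional studies), PP1/BS4 (published segregation data).
#' @export
assignRemainingCriteria <- function(v, profile,
                                    thresholds = pipelineThresholds()) {
  v <- asVariantList(v)
  out <- emptyCriteria()
  add <- function(...) rbind(out, criterionAssignment(...))

  if (v$consequence == "missense" && !is.na(profile$z_score) &&
      profile$z_score > thresholds$pp2_z_min)
    out <- add("PP2", "supporting",
               sprintf("missense in constrained gene (z = %.2f > %.2f)",
                       profile$z_score, thresholds$pp2_z_min))
  if (isTRUE(v$clinvar_same_aa_pathogenic))
    out <- add("PS1", "strong",
               "same amino-acid change previously established as pathogenic")
  if (isTRUE(v$clinvar_other_aa_change_pathogenic) &&
      !isTRUE(v$clinvar_same_aa_pathogenic))
    out <- add("PM5", "moderate",
               "different pathogenic missense change at this residue")
  consensus <- v$in_silico_consensus %||% "mixed"
  if (!is.na(consensus) && consensus == "pathogenic")
    out <- add("PP3", "supporting",
               "multiple in silico predictors agree on a deleterious effect")
  if (!is.na(consensus) && consensus == "benign")
    out <- add("BP4", "supporting",
               "multiple in silico predictors agree on a benign effect")
  if (v$consequence == "synonymous" && !is.na(v$phastcons) &&
      v$phastcons < thresholds$bp7_phastcons_max &&
      !isTRUE(v$hsf_splice_impact))
    out <- add("BP7", "supporting",
               sprintf("synonymous, weakly conserved (PhastCons %.2f) and no predicted splice-site impact",
                       v$phastcons))
  if (v$consequence %in% c("inframe_indel", "stop_lost") &&
      !isTRUE(v$in_repeat_region))
    out <- add("PM4", "moderate",
               "protein length change outside a repeat region")
  if (v$consequence == "inframe_indel" && isTRUE(v$in_repeat_region))
    out <- add("BP3", "supporting", "inframe indel within a repeat region")
  if (v$consequence == "missense" && isTRUE(v$in_functional_domain))
    out <- add("PM1", "moderate", "missense within an annotated functional domain")
  lf <- v$lit_functional %||% "none"
  if (!is.na(lf) && lf == "damaging")
    out <- add("PS3", "strong", "functional studies show a damaging effect")
  if (!is.na(lf) && lf == "benign_effect")
    out <- add("BS3", "strong", "functional studies show no damaging effect")
  ls <- v$lit_segregation %||% "none"
  if (!is.na(ls) && ls == "cosegregates")
    out <- add("PP1", "supporting", "variant cosegregates with disease")
  if (!is.na(ls) && ls == "does_not_segregate")
    out <- add("BS4", "strong", "lack of segregation with disease")
  out
}

#' PMS2 homology gate
#'
#' PMS2 classification is confounded by the PMS2CL pseudogene; only variants
#' in uniquely mappable (non-homologous) regions of PMS2 are carried into
#' classification and burden counting. Vectorised over rows; returns `TRUE`
#' for variants that may proceed.
#'
#' @param variants Annotated variant `data.frame`.
#' @return Logical vector over rows.
#' @examples
#' v <- exampleVariants()
#' pms2Gate(v)
#' @export
pms2Gate <- function(variants) {
  !(variants$gene == "PMS2" & !isTRUEvec(variants$pms2_unique_region))
}

isTRUEvec <- function(x) !is.na(x) & x

#' Combine assigned criteria into points and a five-tier class
#'
#' Sums pathogenic-side strengths (very strong 8, strong 4, moderate 2,
#' supporting 1) minus benign-side strengths (strong 4, supporting 1) and
#' maps the total to the five tiers (pathogenic >= 10, likely pathogenic
#' 6-9, VUS 0-5, likely benign -6..-1, benign <= -7). A stand-alone BA1
#' short-circuits to benign whatever else is present.
#'
#' @param criteria Criterion `data.frame` (`criterion`, `strength`,
#'   optionally `rationale`); each criterion may appear at most once.
#' @param thresholds Threshold list from [pipelineThresholds()].
#' @return List with `points` (integer) and `classification` (one of
#'   pathogenic, likely_pathogenic, vus, likely_benign, benign).
#' @examples
#' combineCriteria(data.frame(criterion = c("PVS1", "PM2"),
#'                            strength = c("very_strong", "supporting")))
#' @export
combineCriteria <- function(criteria, thresholds = pipelineThresholds()) {
  if (nrow(criteria) > 0) {
    bad <- setdiff(criteria$criterion, criterionVocabulary())
    if (length(bad) > 0)
      stop("unknown criterion: ", paste(bad, collapse = ", "))
    if (anyDuplicated(criteria$criterion))
      stop("duplicate criterion in evidence set: ",
           paste(criteria$criterion[duplicated(criteria$criterion)],
                 collapse = ", "))
    if (any(criteria$criterion == "BA1"))
      return(list(points = NA_integer_, classification = "benign"))
  }
  pts <- thresholds$strength_points
  benignSide <- startsWith(criteria$criterion, "B")
  val <- unname(pts[criteria$strength])
  if (any(is.na(val)))
    stop("unknown strength: ",
         paste(criteria$strength[is.na(val)], collapse = ", "))
  points <- sum(val[!benignSide]) - sum(val[benignSide])
  cls <- if (points >= thresholds$class_pathogenic_min) "pathogenic"
  else if (points >= thresholds$class_lp_min) "likely_pathogenic"
  else if (points >= 0) "vus"
  else if (points >= thresholds$class_benign_max + 1) "likely_benign"
  else "benign"
  list(points = as.integer(points), classification = cls)
}

classifyMandatoryFields <- function() {
  c("gene", "consequence", "gnomad_af", "gnomad_het_count",
    "gnomad_hom_count", "pext", "clinvar_status",
    "clinvar_same_aa_pathogenic", "clinvar_other_aa_change_pathogenic",
    "in_functional_domain", "in_repeat_region", "phastcons",
    "hsf_splice_impact", "nmd_predicted_by_position",
    "known_pathogenic_downstream", "pms2_unique_region")
}

#' Classify one variant
#'
#' Runs every criterion assigner, combines the evidence and returns the
#' classification together with an ordered audit of every rule consulted.
#' A variant with a missing mandatory annotation field is reported as
#' unclassifiable, naming the field.
#'
#' @param v A single annotated variant (named list or one-row `data.frame`).
#' @param profile One-row gene profile; looked up from `profiles` when
#'   omitted by [classifyVariants()].
#' @param thresholds Threshold list from [pipelineThresholds()].
#' @return List with `variant_id`, `gene`, `criteria` (data.frame),
#'   `points`, `classification`, and `audit` (character vector of rule
#'   firings in order).
#' @examples
#' v <- exampleVariants()
#' classifyVariant(v[1, ], geneProfiles()[geneProfiles()$gene == v$gene[1], ])
#' @export
classifyVariant <- function(v, profile, thresholds = pipelineThresholds()) {
  v <- asVariantList(v)
  audit <- character(0)
  note <- function(x) audit <<- c(audit, x)

  missing <- classifyMandatoryFields()[vapply(classifyMandatoryFields(),
    function(f) is.null(v[[f]]) || is.na(v[[f]]), logical(1))]
  if (length(missing) > 0) {
    return(list(variant_id = v$variant_id, gene = v$gene,
                criteria = emptyCriteria(), points = NA_integer_,
                classification = NA_character_,
                audit = paste0("unclassifiable: missing mandatory field(s) ",
                               paste(missing, collapse = ", "))))
  }

  if (v$clinvar_status == "pathogenic_multiple_unanimous")
    note("retained via known-pathogenic bypass; classification rests on assigned criteria only")

  collect <- function(label, res) {
    for (n in attr(res, "notes") %||% character(0)) note(n)
    if (nrow(res) > 0)
      note(paste0(label, ": ",
                  paste0(res$criterion, "@", res$strength, collapse = ", ")))
    else note(paste0(label, ": none"))
    res
  }

  criteria <- rbind(
    collect("PVS1 decision tree", assignPvs1(v, profile, thresholds)),
    collect("PS4 tiers", assignPs4(v, thresholds)),
    collect("frequency criteria", assignFrequencyCriteria(v, profile,
                                                          thresholds)),
    collect("annotation criteria", assignRemainingCriteria(v, profile,
                                                           thresholds))
  )

  res <- combineCriteria(criteria, thresholds)
  note(sprintf("combined: %s point(s) -> %s",
               res$points %||% NA, res$classification))
  list(variant_id = v$variant_id, gene = v$gene, criteria = criteria,
       points = res$points, classification = res$classification,
       audit = audit)
}

#' Classify a retained variant table
#'
#' Applies the PMS2 homology gate, classifies every remaining variant with
#' [classifyVariant()], and returns a [ClassifiedVariants-class] with the
#' per-variant audit trails.
#'
#' @param variants Retained annotated variant `data.frame` (typically
#'   `variantTable(runPrefilter(...))`).
#' @param profiles Gene profile table from [geneProfiles()].
#' @param thresholds Threshold list from [pipelineThresholds()].
#' @return A [ClassifiedVariants-class] object.
#' @examples
#' pf <- runPrefilter(exampleVariants())
#' classifyVariants(variantTable(pf))
#' @export
classifyVariants <- function(variants, profiles = geneProfiles(),
                             thresholds = pipelineThresholds()) {
  badGene <- setdiff(variants$gene, profiles$gene)
  if (length(badGene) > 0)
    stop("no gene profile for: ", paste(badGene, collapse = ", "))

  keep <- pms2Gate(variants)
  dropped <- data.frame(
    variant_id = variants$variant_id[!keep],
    gene = variants$gene[!keep],
    reason = rep("PMS2 pseudogene-homologous region (excluded from classification and burden)",
                 sum(!keep)),
    stringsAsFactors = FALSE)
  variants <- variants[keep, , drop = FALSE]

  rows <- vector("list", nrow(variants))
  audit <- vector("list", nrow(variants))
  for (i in seq_len(nrow(variants))) {
    v <- variantRow(variants, i)
    profile <- profiles[profiles$gene == v$gene, , drop = FALSE]
    cl <- classifyVariant(v, profile, thresholds)
    rows[[i]] <- data.frame(
      variant_id = cl$variant_id, gene = cl$gene,
      criteria = if (nrow(cl$criteria) > 0)
        paste0(cl$criteria$criterion, "@", cl$criteria$strength,
               collapse = ";") else "",
      points = cl$points %||% NA_integer_,
      classification = cl$classification,
      stringsAsFactors = FALSE)
    audit[[i]] <- cl$audit
  }
  tab <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(variant_id = character(0), gene = character(0),
               criteria = character(0), points = integer(0),
               classification = character(0), stringsAsFactors = FALSE)
  names(audit) <- tab$variant_id
  new("ClassifiedVariants", table = tab, audit = audit, dropped = dropped)
}
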