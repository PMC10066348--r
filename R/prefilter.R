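#' Variant prefilter
#'
#' Three-stage prefiltering of annotated germline variants ahead of
#' criterion-based classification, with a bypass for established pathogenic
#' variants. A variant is retained when it passes all three stages --
#' functional effect, population frequency, and ClinVar status -- or when it
#' is a known pathogenic variant (multiple unanimous pathogenic ClinVar
#' submissions), for which the effect and frequency stages are not enforced.
#'
#' The three predicates are vectorised over the rows of an annotated variant
#' table (see [readVariantTable()] for the schema):
#'
#' * `passesEffectFilter()`: the consequence has moderate or high predicted
#'   impact on the protein (inframe insertion/deletion, frameshift, missense,
#'   canonical splice site, stop/start loss, stop gain, UTR-region deletion)
#'   or the variant has high predicted splice impact (dbscSNV ada or rf score
#'   strictly above `splice_score_min`; an absent score never rescues).
#' * `passesFrequencyFilter()`: excluded when seen in more than
#'   `gnomad_het_max` gnomAD heterozygotes, more than `local_carrier_max`
#'   local-cohort individuals, or more than `gnomad_hom_max` /
#'   `local_hom_max` homozygotes in gnomAD / the local cohort.
#' * `passesClinvarFilter()`: excluded when ClinVar calls it benign, likely
#'   benign, or conflicting between benign/likely benign and VUS; also
#'   excluded when it is a noncoding or synonymous variant without predicted
#'   splice impact that is absent from ClinVar or recorded there as VUS.
#'
#' @param variants Annotated variant `data.frame` (one row per variant).
#' @param thresholds Threshold list from [pipelineThresholds()].
#' @return For the predicates, a logical vector over rows. For
#'   [runPrefilter()], a [PrefilterResult-class] holding the retained table,
#'   one decision per input variant, and the cascade counts.
#' @examples
#' v <- exampleVariants()
#' passesEffectFilter(v)
#' runPrefilter(v)
#' @name prefilter
NULL

#' @rdname prefilter
#' @export
passesEffectFilter <- function(variants, thresholds = pipelineThresholds()) {
  impact <- c("inframe_indel", "frameshift", "missense", "canonical_splice",
              "start_lost", "stop_lost", "stop_gained", "utr_deletion")
  spliceMax <- pmax(naZero(variants$splice_ada), naZero(variants$splice_rf))
  variants$consequence %in% impact | spliceMax > thresholds$splice_score_min
}

#' @rdname prefilter
#' @export
passesFrequencyFilter <- function(variants,
                                  thresholds = pipelineThresholds()) {
  counts <- c("gnomad_het_count", "local_carrier_count",
              "gnomad_hom_count", "local_hom_count")
  for (col in counts) {
    if (any(is.na(variants[[col]])) || any(variants[[col]] < 0))
      stop("negative or missing count in column ", col)
  }
  variants$gnomad_het_count <= thresholds$gnomad_het_max &
    variants$local_carrier_count <= thresholds$local_carrier_max &
    variants$gnomad_hom_count <= thresholds$gnomad_hom_max &
    variants$local_hom_count <= thresholds$local_hom_max
}

#' @rdname prefilter
#' @export
passesClinvarFilter <- function(variants,
                                thresholds = pipelineThresholds()) {
  blb <- variants$clinvar_status %in%
    c("benign", "likely_benign", "conflicting_blb_vus")
  spliceMax <- pmax(naZero(variants$splice_ada), naZero(variants$splice_rf))
  silentUnknown <- variants$consequence %in% c("noncoding", "synonymous") &
    spliceMax <= thresholds$splice_score_min &
    variants$clinvar_status %in% c("absent", "vus")
  !(blb | silentUnknown)
}

#' @rdname prefilter
#' @export
isKnownPathogenic <- function(variants) {
  variants$clinvar_status == "pathogenic_multiple_unanimous"
}

#' @rdname prefilter
#' @export
runPrefilter <- function(variants, thresholds = pipelineThresholds()) {
  if (anyDuplicated(variants$variant_id))
    stop("duplicate variant_id: ",
         paste(unique(variants$variant_id[duplicated(variants$variant_id)]),
               collapse = ", "))

  n <- nrow(variants)
  if (n == 0) {
    cascade <- list(n_input = 0L, n_excluded_effect = 0L,
                    n_excluded_frequency = 0L, n_excluded_clinvar = 0L,
                    n_bypass = 0L, n_retained = 0L,
                    n_retained_standard = 0L)
    return(new("PrefilterResult",
               retained = variants,
               decisions = data.frame(variant_id = character(0),
                                      retained = logical(0),
                                      stage = character(0),
                                      reason = character(0),
                                      stringsAsFactors = FALSE),
               cascade = cascade))
  }

  effectOk <- passesEffectFilter(variants, thresholds)
  freqOk <- passesFrequencyFilter(variants, thresholds)
  clinvarOk <- passesClinvarFilter(variants, thresholds)
  bypass <- isKnownPathogenic(variants)

  standard <- effectOk & freqOk & clinvarOk
  retained <- standard | bypass

  # stage attribution in fixed audit order effect -> frequency -> clinvar;
  # the retained set itself is order-independent
  stage <- rep("retained", n)
  stage[!effectOk] <- "effect"
  stage[effectOk & !freqOk] <- "frequency"
  stage[effectOk & freqOk & !clinvarOk] <- "clinvar"
  stage[bypass & !standard] <- "bypass"
  stage[bypass & standard] <- "retained"

  reason <- character(n)
  reason[stage == "retained"] <- "passed effect, frequency and ClinVar filters"
  reason[stage == "bypass"] <-
    "known pathogenic (multiple unanimous ClinVar submissions); effect and frequency filters not enforced"
  reason[stage == "effect"] <-
    "no moderate/high-impact consequence and no splice score above threshold"
  reason[stage == "frequency"] <-
    "too frequent in gnomAD or the local cohort (het/hom ceilings exceeded)"
  reason[stage == "clinvar"] <-
    "ClinVar benign/likely benign/conflicting B-LB-VUS, or silent variant absent/VUS in ClinVar"

  decisions <- data.frame(variant_id = variants$variant_id,
                          retained = retained,
                          stage = stage,
                          reason = reason,
                          stringsAsFactors = FALSE)

  cascade <- list(
    n_input = n,
    n_excluded_effect = sum(stage == "effect"),
    n_excluded_frequency = sum(stage == "frequency"),
    n_excluded_clinvar = sum(stage == "clinvar"),
    n_bypass = sum(stage == "bypass"),
    n_retained = sum(retained),
    n_retained_standard = sum(standard)
  )

  new("PrefilterResult",
      retained = variants[retained, , drop = FALSE],
      decisions = decisions,
      cascade = cascade)
}
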