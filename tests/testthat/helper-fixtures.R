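# one-row variant builder: a clean rare missense that passes every
# prefilter stage and fires no criterion except PM2, with overridable fields
makeVariant <- function(...) {
  v <- data.frame(
    variant_id = "17:43100001:A:T",
    gene = "BRCA1",
    transcript = "NM_007294.4",
    consequence = "missense",
    splice_ada = NA_real_,
    splice_rf = NA_real_,
    gnomad_het_count = 2L,
    gnomad_hom_count = 0L,
    gnomad_af = 7e-6,
    local_carrier_count = 1L,
    local_hom_count = 0L,
    clinvar_status = "absent",
    clinvar_same_aa_pathogenic = FALSE,
    clinvar_other_aa_change_pathogenic = FALSE,
    pext = 0.9,
    gene_z_score = -0.75,
    in_functional_domain = FALSE,
    in_repeat_region = FALSE,
    phastcons = 0.8,
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
    carrier_ids = "IND00001",
    stringsAsFactors = FALSE
  )
  overrides <- list(...)
  for (nm in names(overrides)) v[[nm]] <- overrides[[nm]]
  v
}

# stack several makeVariant() calls with distinct ids
makeVariants <- function(...) {
  rows <- list(...)
  out <- do.call(rbind, rows)
  out$variant_id <- paste0(out$variant_id, "#", seq_len(nrow(out)))
  out
}

roundHalfUpForTest <- function(x, d) floor(x * 10^d + 0.5) / 10^d

brca1Profile <- function() {
  p <- geneProfiles()
  p[p$gene == "BRCA1", , drop = FALSE]
}

profileFor <- function(gene) {
  p <- geneProfiles()
  p[p$gene == gene, , drop = FALSE]
}
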