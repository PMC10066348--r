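test_that("effect filter admits moderate/high-impact consequences and splice rescues", {
  expect_true(passesEffectFilter(makeVariant(consequence = "frameshift")))
  expect_true(passesEffectFilter(makeVariant(consequence = "missense")))
  expect_true(passesEffectFilter(makeVariant(consequence = "utr_deletion")))
  expect_false(passesEffectFilter(makeVariant(consequence = "noncoding")))
  expect_false(passesEffectFilter(makeVariant(consequence = "synonymous")))
  # splice rescue is strictly > 0.5; an absent score never rescues
  expect_true(passesEffectFilter(
    makeVariant(consequence = "synonymous", splice_ada = 0.8)))
  expect_true(passesEffectFilter(
    makeVariant(consequence = "noncoding", splice_rf = 0.51)))
  expect_false(passesEffectFilter(
    makeVariant(consequence = "synonymous", splice_ada = 0.5,
                splice_rf = 0.5)))
})

test_that("frequency filter excludes strictly above each ceiling", {
  atCeiling <- makeVariant(gnomad_het_count = 10L, local_carrier_count = 20L,
                           gnomad_hom_count = 3L, local_hom_count = 3L,
                           carrier_ids = paste(sprintf("IND%05d", 1:20),
                                               collapse = ";"))
  expect_true(passesFrequencyFilter(atCeiling))
  expect_false(passesFrequencyFilter(makeVariant(gnomad_het_count = 11L)))
  expect_false(passesFrequencyFilter(makeVariant(local_carrier_count = 21L)))
  expect_false(passesFrequencyFilter(makeVariant(gnomad_hom_count = 4L)))
  expect_false(passesFrequencyFilter(makeVariant(local_hom_count = 4L)))
  expect_error(passesFrequencyFilter(makeVariant(gnomad_het_count = -1L)),
               "gnomad_het_count")
})

test_that("ClinVar filter removes benign-side calls and silent unknowns", {
  expect_false(passesClinvarFilter(
    makeVariant(clinvar_status = "likely_benign")))
  expect_false(passesClinvarFilter(makeVariant(clinvar_status = "benign")))
  expect_false(passesClinvarFilter(
    makeVariant(clinvar_status = "conflicting_blb_vus")))
  # silent variants without predicted splice impact, absent or VUS in ClinVar
  expect_false(passesClinvarFilter(
    makeVariant(consequence = "synonymous", splice_ada = 0.2,
                clinvar_status = "absent")))
  expect_false(passesClinvarFilter(
    makeVariant(consequence = "noncoding", clinvar_status = "vus")))
  # splice-predicted silent variants and P/LP-vs-VUS conflicts are kept
  expect_true(passesClinvarFilter(
    makeVariant(consequence = "synonymous", splice_ada = 0.8,
                clinvar_status = "vus")))
  expect_true(passesClinvarFilter(makeVariant(clinvar_status = "absent")))
  expect_true(passesClinvarFilter(makeVariant(clinvar_status = "vus")))
})

test_that("known-pathogenic detection requires multiple unanimous submissions", {
  expect_true(isKnownPathogenic(
    makeVariant(clinvar_status = "pathogenic_multiple_unanimous",
                gnomad_het_count = 300L)))
  expect_false(isKnownPathogenic(makeVariant(clinvar_status = "pathogenic")))
  expect_false(isKnownPathogenic(makeVariant(clinvar_status = "vus")))
})

test_that("prefilter cascade partitions the input and audits each stage", {
  empty <- runPrefilter(makeVariant()[0, ])
  expect_identical(nrow(variantTable(empty)), 0L)
  expect_identical(cascadeCounts(empty)$n_input, 0L)

  # 10 variants: 3 too frequent in gnomAD (non-bypass), 7 clean
  rows <- c(lapply(1:3, function(i) makeVariant(gnomad_het_count = 50L)),
            lapply(4:10, function(i) makeVariant()))
  v <- do.call(makeVariants, rows)
  pf <- runPrefilter(v)
  cc <- cascadeCounts(pf)
  expect_identical(cc$n_retained, 7L)
  expect_identical(cc$n_excluded_frequency, 3L)
  expect_identical(cc$n_excluded_effect + cc$n_excluded_frequency +
                     cc$n_excluded_clinvar + cc$n_retained, cc$n_input)
  d <- filterDecisions(pf)
  expect_setequal(d$variant_id, v$variant_id)
  expect_identical(d$retained, d$stage %in% c("retained", "bypass"))

  # known-pathogenic bypass dominates a frequency failure
  byp <- runPrefilter(makeVariants(
    makeVariant(clinvar_status = "pathogenic_multiple_unanimous",
                gnomad_het_count = 400L)))
  expect_identical(filterDecisions(byp)$stage, "bypass")
  expect_true(filterDecisions(byp)$retained)

  expect_error(runPrefilter(rbind(makeVariant(), makeVariant())),
               "duplicate variant_id")
})

test_that("bypass dominance and frequency monotonicity hold on random variants", {
  set.seed(11)
  consequences <- c("frameshift", "missense", "synonymous", "noncoding",
                    "inframe_indel")
  for (i in 1:60) {
    v <- makeVariant(
      consequence = sample(consequences, 1),
      splice_ada = sample(c(NA, runif(1)), 1),
      gnomad_het_count = sample(0:40, 1),
      local_carrier_count = sample(0:40, 1),
      gnomad_hom_count = sample(0:6, 1),
      local_hom_count = sample(0:6, 1),
      clinvar_status = sample(clinvarStatuses <- c(
        "pathogenic_multiple_unanimous", "pathogenic", "vus",
        "conflicting_blb_vus", "likely_benign", "benign", "absent"), 1))
    pf <- runPrefilter(v)
    if (isKnownPathogenic(v))
      expect_true(filterDecisions(pf)$retained)
    if (filterDecisions(pf)$retained) {
      # decreasing any frequency count can never flip retained -> excluded
      v2 <- v
      v2$gnomad_het_count <- max(0L, v$gnomad_het_count - sample(0:5, 1))
      v2$local_carrier_count <- max(0L, v$local_carrier_count - sample(0:5, 1))
      v2$gnomad_hom_count <- max(0L, v$gnomad_hom_count - 1L)
      expect_true(filterDecisions(runPrefilter(v2))$retained)
    }
  }
})
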