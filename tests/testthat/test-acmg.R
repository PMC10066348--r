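test_that("PVS1 follows the loss-of-function decision tree", {
  p <- brca1Profile()
  # NMD-predicted null in a haploinsufficient gene, relevant transcript
  a <- assignPvs1(makeVariant(consequence = "frameshift",
                              nmd_predicted_by_position = TRUE, pext = 0.9),
                  p)
  expect_identical(a$criterion, "PVS1")
  expect_identical(a$strength, "very_strong")
  # known pathogenic variants downstream also predict decay
  a <- assignPvs1(makeVariant(consequence = "stop_gained",
                              known_pathogenic_downstream = TRUE), p)
  expect_identical(a$strength, "very_strong")
  # NMD-escaping null drops to strong
  a <- assignPvs1(makeVariant(consequence = "stop_gained",
                              nmd_predicted_by_position = FALSE), p)
  expect_identical(a$strength, "strong")
  # low pext: not a biologically relevant transcript
  expect_identical(nrow(assignPvs1(
    makeVariant(consequence = "stop_gained", pext = 0.3,
                nmd_predicted_by_position = TRUE), p)), 0L)
  # gene without a loss-of-function mechanism
  pNoHi <- p; pNoHi$haploinsufficient <- FALSE
  expect_identical(nrow(assignPvs1(
    makeVariant(consequence = "frameshift",
                nmd_predicted_by_position = TRUE), pNoHi)), 0L)
  # canonical splice: frame disruption stands in for the NMD position rule
  a <- assignPvs1(makeVariant(consequence = "canonical_splice",
                              splice_frame_disrupted = TRUE), p)
  expect_identical(a$strength, "very_strong")
  a <- assignPvs1(makeVariant(consequence = "canonical_splice",
                              splice_frame_disrupted = FALSE), p)
  expect_identical(a$strength, "strong")
  # unassessed frame: no criterion, audit note instead
  a <- assignPvs1(makeVariant(consequence = "canonical_splice",
                              splice_frame_disrupted = NA), p)
  expect_identical(nrow(a), 0L)
  expect_match(attr(a, "notes"), "unassessable")
  # start loss takes the initiation-codon default
  a <- assignPvs1(makeVariant(consequence = "start_lost"), p)
  expect_identical(a$strength, "moderate")
  # missense never enters the tree
  expect_identical(nrow(assignPvs1(makeVariant(), p)), 0L)
})

test_that("PS4 branches on frequency and tiers on reported patients", {
  a <- assignPs4(makeVariant(gnomad_af = 2e-5, lit_case_control_or = 6.0))
  expect_identical(a$strength, "strong")
  expect_identical(nrow(assignPs4(
    makeVariant(gnomad_af = 2e-5, lit_case_control_or = 4.0))), 0L)
  expect_identical(nrow(assignPs4(
    makeVariant(gnomad_af = 2e-5, lit_case_control_or = NA_real_))), 0L)
  a <- assignPs4(makeVariant(gnomad_af = 5e-6, lit_patient_count = 5L))
  expect_identical(a$strength, "strong")
  a <- assignPs4(makeVariant(gnomad_af = 5e-6, lit_patient_count = 3L))
  expect_identical(a$strength, "moderate")
  a <- assignPs4(makeVariant(gnomad_af = 5e-6, lit_patient_count = 2L))
  expect_identical(a$strength, "supporting")
  expect_identical(nrow(assignPs4(
    makeVariant(gnomad_af = 5e-6, lit_patient_count = 1L))), 0L)
  # the exact boundary frequency falls into the case-control branch
  expect_identical(nrow(assignPs4(
    makeVariant(gnomad_af = 1e-5, lit_patient_count = 6L))), 0L)
})

test_that("frequency criteria are tiered and mutually exclusive", {
  p <- brca1Profile()
  a <- assignFrequencyCriteria(
    makeVariant(gnomad_af = 0, gnomad_het_count = 0L), p)
  expect_identical(a$criterion, "PM2")
  expect_identical(a$strength, "supporting")
  a <- assignFrequencyCriteria(makeVariant(gnomad_af = 0.06), p)
  expect_identical(a$criterion, "BA1")
  expect_identical(a$strength, "stand_alone")
  a <- assignFrequencyCriteria(makeVariant(gnomad_af = 0.01), p)
  expect_identical(a$criterion, "BS1")
  # between the PM2 ceiling and the BS1 cutoff: nothing fires
  expect_identical(nrow(assignFrequencyCriteria(
    makeVariant(gnomad_af = 3e-5), p)), 0L)
  # at most one frequency criterion over a frequency sweep
  for (af in c(0, 1e-6, 2e-5, 5e-5, 5e-4, 2e-3, 0.02, 0.05, 0.3))
    expect_lte(nrow(assignFrequencyCriteria(
      makeVariant(gnomad_af = af, gnomad_het_count = 1L), p)), 1L)
})

test_that("annotation-driven criteria fire per the customised rules", {
  constrained <- profileFor("TP53")   # z above the missense threshold
  relaxed <- brca1Profile()
  a <- assignRemainingCriteria(
    makeVariant(in_functional_domain = TRUE), constrained)
  expect_setequal(a$criterion, c("PP2", "PM1"))
  expect_identical(nrow(assignRemainingCriteria(makeVariant(), relaxed)), 0L)
  a <- assignRemainingCriteria(
    makeVariant(consequence = "inframe_indel", in_repeat_region = TRUE),
    relaxed)
  expect_identical(a$criterion, "BP3")
  a <- assignRemainingCriteria(
    makeVariant(consequence = "inframe_indel"), relaxed)
  expect_identical(a$criterion, "PM4")
  a <- assignRemainingCriteria(makeVariant(consequence = "stop_lost"),
                               relaxed)
  expect_identical(a$criterion, "PM4")
  a <- assignRemainingCriteria(
    makeVariant(consequence = "synonymous", phastcons = 0.05), relaxed)
  expect_identical(a$criterion, "BP7")
  expect_identical(nrow(assignRemainingCriteria(
    makeVariant(consequence = "synonymous", phastcons = 0.05,
                hsf_splice_impact = TRUE), relaxed)), 0L)
  # PS1 takes precedence over PM5 at the same residue
  a <- assignRemainingCriteria(
    makeVariant(clinvar_same_aa_pathogenic = TRUE,
                clinvar_other_aa_change_pathogenic = TRUE), relaxed)
  expect_identical(a$criterion, "PS1")
  a <- assignRemainingCriteria(
    makeVariant(clinvar_other_aa_change_pathogenic = TRUE), relaxed)
  expect_identical(a$criterion, "PM5")
  # literature evidence
  a <- assignRemainingCriteria(
    makeVariant(lit_functional = "damaging", lit_segregation = "cosegregates",
                in_silico_consensus = "pathogenic"), relaxed)
  expect_setequal(a$criterion, c("PS3", "PP1", "PP3"))
  a <- assignRemainingCriteria(
    makeVariant(lit_functional = "benign_effect",
                lit_segregation = "does_not_segregate",
                in_silico_consensus = "benign"), relaxed)
  expect_setequal(a$criterion, c("BS3", "BS4", "BP4"))
})

test_that("PMS2 homology gate drops only masked PMS2 variants", {
  expect_false(pms2Gate(makeVariant(gene = "PMS2",
                                    pms2_unique_region = FALSE)))
  expect_true(pms2Gate(makeVariant(gene = "PMS2",
                                   pms2_unique_region = TRUE)))
  expect_true(pms2Gate(makeVariant(gene = "MLH1",
                                   pms2_unique_region = FALSE)))
})

test_that("point combination reproduces the customised combining rules", {
  comb <- function(crit, str)
    combineCriteria(data.frame(criterion = crit, strength = str))
  r <- comb(c("PVS1", "PM2"), c("very_strong", "supporting"))
  expect_identical(r$points, 9L)
  expect_identical(r$classification, "likely_pathogenic")
  r <- comb(c("PVS1", "PM5"), c("very_strong", "moderate"))
  expect_identical(r$points, 10L)
  expect_identical(r$classification, "pathogenic")
  r <- comb(c("PS3", "PS4"), c("strong", "strong"))
  expect_identical(r$points, 8L)
  expect_identical(r$classification, "likely_pathogenic")
  r <- combineCriteria(data.frame(criterion = character(0),
                                  strength = character(0)))
  expect_identical(r$points, 0L)
  expect_identical(r$classification, "vus")
  expect_identical(comb("PM2", "supporting")$classification, "vus")
  expect_identical(comb("PVS1", "very_strong")$classification,
                   "likely_pathogenic")
  # BA1 short-circuits whatever else is present
  r <- comb(c("BA1", "PVS1", "PS3"),
            c("stand_alone", "very_strong", "strong"))
  expect_identical(r$classification, "benign")
  expect_error(comb(c("PM2", "PM2"), c("supporting", "supporting")),
               "duplicate")
})

test_that("combination is monotone in evidence and order-independent", {
  set.seed(4)
  pathPool <- data.frame(
    criterion = c("PVS1", "PS1", "PS3", "PS4", "PM1", "PM4", "PM5", "PM2",
                  "PP1", "PP2", "PP3"),
    strength = c("very_strong", "strong", "strong", "strong", "moderate",
                 "moderate", "moderate", "supporting", "supporting",
                 "supporting", "supporting"), stringsAsFactors = FALSE)
  benPool <- data.frame(
    criterion = c("BS1", "BS3", "BS4", "BP3", "BP4", "BP7"),
    strength = c("strong", "strong", "strong", "supporting", "supporting",
                 "supporting"), stringsAsFactors = FALSE)
  tierRank <- c(benign = 1, likely_benign = 2, vus = 3,
                likely_pathogenic = 4, pathogenic = 5)
  for (i in 1:50) {
    base <- rbind(pathPool[sample(nrow(pathPool), sample(0:3, 1)), ],
                  benPool[sample(nrow(benPool), sample(0:2, 1)), ])
    r0 <- combineCriteria(base)
    # permutation invariance
    r0b <- combineCriteria(base[sample(nrow(base)), , drop = FALSE])
    expect_identical(r0b$classification, r0$classification)
    expect_identical(r0b$points, r0$points)
    # adding an unused pathogenic criterion never moves toward benign
    freeP <- pathPool[!pathPool$criterion %in% base$criterion, ]
    if (nrow(freeP) > 0) {
      r1 <- combineCriteria(rbind(base, freeP[sample(nrow(freeP), 1), ]))
      expect_gte(r1$points, r0$points)
      expect_gte(tierRank[[r1$classification]],
                 tierRank[[r0$classification]])
    }
    # adding an unused benign criterion never moves toward pathogenic
    freeB <- benPool[!benPool$criterion %in% base$criterion, ]
    if (nrow(freeB) > 0) {
      r2 <- combineCriteria(rbind(base, freeB[sample(nrow(freeB), 1), ]))
      expect_lte(r2$points, r0$points)
      expect_lte(tierRank[[r2$classification]],
                 tierRank[[r0$classification]])
    }
  }
})

test_that("classification of whole variants assembles criteria and audit", {
  # null-regime variant: PVS1 + PM2 (+PP3) reaches P/LP
  v <- makeVariant(consequence = "frameshift",
                   nmd_predicted_by_position = TRUE, gnomad_af = 0,
                   gnomad_het_count = 0L, in_silico_consensus = "pathogenic")
  cl <- classifyVariant(v, brca1Profile())
  expect_true(cl$classification %in% c("pathogenic", "likely_pathogenic"))
  expect_true("PVS1" %in% cl$criteria$criterion)
  expect_true(any(grepl("combined", cl$audit)))
  # nothing fires -> VUS
  quiet <- makeVariant(gnomad_af = 3e-5)
  cl <- classifyVariant(quiet, brca1Profile())
  expect_identical(cl$classification, "vus")
  expect_identical(cl$points, 0L)
  # missing mandatory annotation -> unclassifiable, field named
  broken <- makeVariant(pext = NA_real_)
  cl <- classifyVariant(broken, brca1Profile())
  expect_true(is.na(cl$classification))
  expect_match(cl$audit, "pext")
  # bypass provenance is flagged in the audit
  byp <- makeVariant(clinvar_status = "pathogenic_multiple_unanimous",
                     gnomad_af = 0.002, gnomad_het_count = 400L)
  cl <- classifyVariant(byp, brca1Profile())
  expect_true(any(grepl("bypass", cl$audit)))
  expect_identical(cl$criteria$criterion, "BS1")
})

test_that("classifyVariants applies the homology gate and keeps audits", {
  v <- makeVariants(
    makeVariant(gene = "PMS2", transcript = "NM_000535.7",
                pms2_unique_region = FALSE, gene_z_score = -0.05),
    makeVariant(gene = "PMS2", transcript = "NM_000535.7",
                pms2_unique_region = TRUE, gene_z_score = -0.05),
    makeVariant())
  cl <- classifyVariants(v)
  expect_identical(nrow(classificationTable(cl)), 2L)
  expect_identical(nrow(droppedVariants(cl)), 1L)
  expect_identical(droppedVariants(cl)$gene, "PMS2")
  expect_named(classificationAudit(cl),
               classificationTable(cl)$variant_id)
  expect_error(classifyVariants(makeVariant(gene = "NOTAGENE")),
               "NOTAGENE")
})
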