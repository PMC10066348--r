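# Independent rule-list classifier used as the oracle for the point engine:
# the classic qualitative combining rules expressed on evidence-strength
# counts, with the three customisations of this analysis applied verbatim
# (very strong + moderate -> pathogenic; two strong -> likely pathogenic;
# PVS1 + PM2_supporting alone -> likely pathogenic). Evidence on both sides
# is treated as conflicting (VUS), as the qualitative rules prescribe.

oracleFixedStrengths <- c(
  PVS1 = "very_strong", PS1 = "strong", PS3 = "strong", PS4 = "strong",
  PM1 = "moderate", PM2 = "supporting", PM4 = "moderate", PM5 = "moderate",
  PP1 = "supporting", PP2 = "supporting", PP3 = "supporting",
  BA1 = "stand_alone", BS1 = "strong", BS3 = "strong", BS4 = "strong",
  BP3 = "supporting", BP4 = "supporting", BP7 = "supporting")

oracleCounts <- function(crit) {
  str <- oracleFixedStrengths[crit]
  ben <- startsWith(crit, "B")
  list(nVS = sum(str == "very_strong" & !ben),
       nST = sum(str == "strong" & !ben),
       nMO = sum(str == "moderate" & !ben),
       nSU = sum(str == "supporting" & !ben),
       nBS = sum(str == "strong" & ben),
       nBP = sum(str == "supporting" & ben))
}

ruleListClassify <- function(crit) {
  if ("BA1" %in% crit) return("benign")
  n <- oracleCounts(crit)
  hasPath <- with(n, nVS + nST + nMO + nSU) > 0
  hasBen <- with(n, nBS + nBP) > 0
  if (hasPath && hasBen) return("vus")
  if (hasPath) with(n, {
    if (nVS >= 1 && (nST >= 1 || nMO >= 1 || nSU >= 2)) return("pathogenic")
    if (nST >= 3) return("pathogenic")
    if (nST == 1 && nMO >= 3) return("pathogenic")
    if (nST == 1 && nMO == 2 && nSU >= 2) return("pathogenic")
    if (nST == 1 && nMO == 1 && nSU >= 4) return("pathogenic")
    if (nVS == 1 && nSU == 1 && nST + nMO == 0) return("likely_pathogenic")
    if (nST == 2) return("likely_pathogenic")
    if (nST == 1 && nMO >= 1 && nMO <= 2) return("likely_pathogenic")
    if (nST == 1 && nSU >= 2) return("likely_pathogenic")
    if (nMO >= 3) return("likely_pathogenic")
    if (nMO == 2 && nSU >= 2) return("likely_pathogenic")
    if (nMO == 1 && nSU >= 4) return("likely_pathogenic")
    "vus"
  })
  else if (hasBen) with(n, {
    if (nBS >= 2) return("benign")
    if (nBS == 1 && nBP >= 1) return("likely_benign")
    if (nBP >= 2) return("likely_benign")
    "vus"
  })
  else "vus"
}

# Whitelist of tolerated point-engine vs rule-list disagreements. Each entry
# is a predicate on (counts, ruleClass, pointClass) with a justification;
# every observed disagreement must match exactly one category.
oracleWhitelist <- list(
  mixed_evidence = list(
    test = function(n, rl, pt)
      with(n, nVS + nST + nMO + nSU > 0 && nBS + nBP > 0) && rl == "vus",
    why = paste("evidence on both sides: the qualitative rules abstain",
                "(conflicting -> VUS) while the point total nets the",
                "two sides, which is the purpose of the point recasting")),
  pvs1_alone = list(
    test = function(n, rl, pt)
      with(n, nVS == 1 && nST + nMO + nSU + nBS + nBP == 0) &&
        pt == "likely_pathogenic",
    why = paste("a lone very-strong criterion is 8 points (likely",
                "pathogenic band); the qualitative list has no",
                "very-strong-alone combination")),
  two_strong_plus = list(
    test = function(n, rl, pt)
      with(n, nVS == 0 && nST == 2 && nBS + nBP == 0 &&
              nMO + nSU > 0) && rl == "likely_pathogenic" &&
        pt == "pathogenic",
    why = paste("the two-strong customisation is stated for the bare pair;",
                "with additional moderate/supporting evidence the point",
                "total reaches the pathogenic band (>= 10)")),
  single_benign = list(
    test = function(n, rl, pt)
      with(n, nVS + nST + nMO + nSU == 0 && nBS + nBP == 1) &&
        rl == "vus" && pt == "likely_benign",
    why = paste("a single benign criterion (-1 or -4 points) falls in the",
                "likely-benign band of the point scale; the qualitative",
                "list requires at least two benign criteria")),
  benign_tier_crossing = list(
    test = function(n, rl, pt)
      with(n, nVS + nST + nMO + nSU == 0 && nBS + nBP >= 2) &&
        rl %in% c("vus", "likely_benign") &&
        pt %in% c("likely_benign", "benign"),
    why = paste("benign-only totals at or below -7 points cross from",
                "likely benign to benign; the qualitative list caps",
                "strong+supporting combinations at likely benign"))
)

whitelistReason <- function(n, rl, pt) {
  for (nm in names(oracleWhitelist))
    if (isTRUE(oracleWhitelist[[nm]]$test(n, rl, pt))) return(nm)
  NA_character_
}
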