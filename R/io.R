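#' Variant-table interchange schema
#'
#' The pipeline's primary interchange format is a tab-separated annotated
#' variant table, one row per variant, with the columns below (order as
#' written by [writeVariantTable()]). Starred columns are optional; missing
#' optional values read back as NA. Unknown extra columns are preserved.
#'
#' @name variantSchema
NULL

# column -> type/mandatory description; single source of truth for reader,
# writer and generator
variantColumnSpec <- function() {
  spec <- list(
    variant_id = list(type = "character", mandatory = TRUE),
    gene = list(type = "character", mandatory = TRUE),
    transcript = list(type = "character", mandatory = TRUE),
    consequence = list(type = "character", mandatory = TRUE,
                       vocab = consequenceVocabulary()),
    splice_ada = list(type = "numeric", mandatory = FALSE),
    splice_rf = list(type = "numeric", mandatory = FALSE),
    gnomad_het_count = list(type = "integer", mandatory = TRUE),
    gnomad_hom_count = list(type = "integer", mandatory = TRUE),
    gnomad_af = list(type = "numeric", mandatory = TRUE),
    local_carrier_count = list(type = "integer", mandatory = TRUE),
    local_hom_count = list(type = "integer", mandatory = TRUE),
    clinvar_status = list(type = "character", mandatory = TRUE,
                          vocab = clinvarVocabulary()),
    clinvar_same_aa_pathogenic = list(type = "logical", mandatory = TRUE),
    clinvar_other_aa_change_pathogenic = list(type = "logical",
                                              mandatory = TRUE),
    pext = list(type = "numeric", mandatory = TRUE),
    gene_z_score = list(type = "numeric", mandatory = FALSE),
    in_functional_domain = list(type = "logical", mandatory = TRUE),
    in_repeat_region = list(type = "logical", mandatory = TRUE),
    phastcons = list(type = "numeric", mandatory = TRUE),
    hsf_splice_impact = list(type = "logical", mandatory = TRUE),
    nmd_predicted_by_position = list(type = "logical", mandatory = TRUE),
    known_pathogenic_downstream = list(type = "logical", mandatory = TRUE),
    splice_frame_disrupted = list(type = "logical", mandatory = FALSE),
    pms2_unique_region = list(type = "logical", mandatory = TRUE),
    lit_case_control_or = list(type = "numeric", mandatory = FALSE),
    lit_patient_count = list(type = "integer", mandatory = TRUE),
    lit_functional = list(type = "character", mandatory = TRUE,
                          vocab = c("damaging", "benign_effect", "none")),
    lit_segregation = list(type = "character", mandatory = TRUE,
                           vocab = c("cosegregates", "does_not_segregate",
                                     "none")),
    in_silico_consensus = list(type = "character", mandatory = TRUE,
                               vocab = c("pathogenic", "benign", "mixed")),
    carrier_ids = list(type = "character", mandatory = TRUE,
                       allow_empty = TRUE)
  )
  spec
}

variantColumnOrder <- function() names(variantColumnSpec())

#' Read and write annotated variant tables
#'
#' [readVariantTable()] reads a tab-separated annotated variant table into
#' a typed `data.frame`, enforcing the schema: mandatory columns must be
#' present and non-missing (errors name the row and column), controlled
#' vocabularies are enforced (errors name the offending token), numeric
#' columns must parse, `variant_id` must be unique, and scores must lie in
#' their stated ranges. Unknown columns are preserved as opaque extras.
#' [writeVariantTable()] writes the same format; a write/read round trip
#' reproduces the records exactly.
#'
#' @param path File path.
#' @param variants Annotated variant `data.frame`.
#' @return `readVariantTable()`: the typed `data.frame`;
#'   `writeVariantTable()`: `path`, invisibly.
#' @examples
#' tmp <- tempfile(fileext = ".tsv")
#' writeVariantTable(exampleVariants(), tmp)
#' v <- readVariantTable(tmp)
#' @export
readVariantTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           colClasses = "character", check.names = FALSE,
                           na.strings = "NA", quote = "")
  spec <- variantColumnSpec()
  mandatory <- names(spec)[vapply(spec, `[[`, logical(1), "mandatory")]
  absent <- setdiff(mandatory, names(raw))
  if (length(absent) > 0)
    stop("variant table is missing mandatory column(s): ",
         paste(absent, collapse = ", "))

  out <- raw
  for (col in intersect(names(spec), names(raw))) {
    s <- spec[[col]]
    x <- raw[[col]]
    if (isTRUE(s$allow_empty)) x[is.na(x)] <- ""
    if (s$mandatory && !isTRUE(s$allow_empty) && any(is.na(x)))
      stop("missing value in mandatory column '", col, "' at row ",
           which(is.na(x))[1])
    if (s$type %in% c("numeric", "integer")) {
      parsed <- suppressWarnings(as.numeric(x))
      bad <- !is.na(x) & is.na(parsed)
      if (any(bad))
        stop("malformed numeric '", x[which(bad)[1]], "' in column '", col,
             "' at row ", which(bad)[1])
      out[[col]] <- if (s$type == "integer") as.integer(parsed) else parsed
    } else if (s$type == "logical") {
      up <- toupper(x)
      bad <- !is.na(x) & !up %in% c("TRUE", "FALSE")
      if (any(bad))
        stop("malformed logical '", x[which(bad)[1]], "' in column '", col,
             "' at row ", which(bad)[1])
      out[[col]] <- up == "TRUE"
    } else {
      out[[col]] <- x
    }
    if (!is.null(s$vocab)) {
      bad <- !is.na(out[[col]]) & !out[[col]] %in% s$vocab
      if (any(bad))
        stop("unknown ", col, " token '", out[[col]][which(bad)[1]],
             "' at row ", which(bad)[1])
    }
  }
  # optional columns absent from the file -> NA defaults
  for (col in setdiff(names(spec), names(out)))
    out[[col]] <- if (spec[[col]]$type == "character") NA_character_
      else if (spec[[col]]$type == "integer") NA_integer_
      else if (spec[[col]]$type == "logical") NA else NA_real_

  if (anyDuplicated(out$variant_id))
    stop("duplicate variant_id: ",
         paste(unique(out$variant_id[duplicated(out$variant_id)]),
               collapse = ", "))
  for (col in c("splice_ada", "splice_rf", "pext", "phastcons")) {
    x <- out[[col]]
    if (any(!is.na(x) & (x < 0 | x > 1)))
      stop("column '", col, "' must lie in [0, 1]")
  }
  if (any(out$gnomad_af < 0 | out$gnomad_af > 1))
    stop("gnomad_af must lie in [0, 1]")
  extras <- setdiff(names(out), names(spec))
  out[, c(variantColumnOrder(), extras), drop = FALSE]
}

#' @rdname readVariantTable
#' @export
writeVariantTable <- function(variants, path) {
  extras <- setdiff(names(variants), variantColumnOrder())
  ordered <- variants[, c(intersect(variantColumnOrder(), names(variants)),
                          extras), drop = FALSE]
  utils::write.table(ordered, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read and write control-population summaries
#'
#' Tab-separated with columns `gene`, `n_control` and at least one of
#' `control_count`, `control_freq_percent`.
#'
#' @param path File path.
#' @param control Control summary `data.frame`.
#' @return The typed `data.frame`, or (writer) `path` invisibly.
#' @examples
#' tmp <- tempfile(fileext = ".tsv")
#' writeControlSummary(generateControl(simulationConfig(), "fixed"), tmp)
#' readControlSummary(tmp)
#' @export
readControlSummary <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ctl <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (!"gene" %in% names(ctl) || !"n_control" %in% names(ctl))
    stop("control summary needs 'gene' and 'n_control' columns")
  if (!any(c("control_count", "control_freq_percent") %in% names(ctl)))
    stop("control summary needs 'control_count' or 'control_freq_percent'")
  ctl
}

#' @rdname readControlSummary
#' @export
writeControlSummary <- function(control, path) {
  utils::write.table(control, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

# ---- VCF convenience adapter ------------------------------------------------

#' VCF convenience adapter
#'
#' [writeVariantVcf()] emits an annotated variant table as a VCF 4.2 file
#' with every annotation field as an INFO key (carrier identifiers
#' comma-joined); [readVariantVcf()] ingests such a file through
#' `VariantAnnotation::readVcf()` and reproduces the same records as the
#' TSV route. The TSV is the primary format; the VCF adapter exists for
#' interoperability with variant-centric tooling and requires the
#' VariantAnnotation package.
#'
#' @param variants Annotated variant `data.frame`.
#' @param path File path (uncompressed `.vcf`).
#' @return `readVariantVcf()`: annotated variant `data.frame`;
#'   `writeVariantVcf()`: `path`, invisibly.
#' @export
writeVariantVcf <- function(variants, path) {
  spec <- variantColumnSpec()
  infoCols <- setdiff(variantColumnOrder(), "variant_id")
  typeOf <- c(character = "String", numeric = "Float", integer = "Integer",
              logical = "String")
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=PanelBurden",
    vapply(infoCols, function(col) {
      sprintf('##INFO=<ID=%s,Number=%s,Type=%s,Description="%s">',
              toupper(col), if (col == "carrier_ids") "." else "1",
              typeOf[[spec[[col]]$type]], col)
    }, character(1)),
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  parts <- strsplit(variants$variant_id, ":", fixed = TRUE)
  bad <- lengths(parts) != 4
  if (any(bad))
    stop("variant_id not in chrom:pos:ref:alt form: ",
         variants$variant_id[which(bad)[1]])
  infoOf <- function(i) {
    vals <- vapply(infoCols, function(col) {
      x <- variants[[col]][i]
      if (col == "carrier_ids")
        return(if (!nzchar(x)) "." else gsub(";", ",", x, fixed = TRUE))
      if (is.na(x)) "." else as.character(x)
    }, character(1))
    paste(paste0(toupper(infoCols), "=", vals), collapse = ";")
  }
  body <- vapply(seq_len(nrow(variants)), function(i) {
    p <- parts[[i]]
    paste(p[1], p[2], variants$variant_id[i], p[3], p[4], ".", "PASS",
          infoOf(i), sep = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname writeVariantVcf
#' @export
readVariantVcf <- function(path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("readVariantVcf() requires the VariantAnnotation package")
  vcf <- VariantAnnotation::readVcf(path)
  info <- VariantAnnotation::info(vcf)
  spec <- variantColumnSpec()
  out <- data.frame(variant_id = rownames(vcf), stringsAsFactors = FALSE)
  for (col in setdiff(variantColumnOrder(), "variant_id")) {
    x <- info[[toupper(col)]]
    if (col == "carrier_ids") {
      x <- vapply(as.list(x), function(ids) {
        ids <- ids[!is.na(ids) & ids != "."]
        paste(ids, collapse = ";")
      }, character(1))
      out[[col]] <- x
      next
    }
    if (is.list(x) || methods::is(x, "List"))
      x <- vapply(as.list(x), function(e)
        if (length(e) == 0) NA_character_ else as.character(e[1]),
        character(1))
    x <- as.character(x)
    x[!is.na(x) & x == "."] <- NA
    s <- spec[[col]]
    out[[col]] <- switch(s$type,
      character = x,
      numeric = as.numeric(x),
      integer = as.integer(as.numeric(x)),
      logical = toupper(x) == "TRUE")
  }
  out
}
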