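#' Read a multi-sample forced-call VCF into a PatientTable
#'
#' Parses a multi-sample VCF carrying FORMAT fields \code{AD}
#' (comma-separated ref,alt depths) and \code{DP} for every sample, and maps
#' samples to roles via a manifest. Multiallelic lines are split into one
#' record per alternate allele (with that allele's AD); non-SNV records
#' (indels, MNVs) are skipped with a counted warning; missing genotype data
#' (\code{./.}) yields an Observation of dp = 0, ad = 0 with a warning.
#' Population allele frequencies are taken from the INFO field named by
#' \code{popAFField} when present.
#'
#' @param vcfPath path to the VCF (plain or bgzipped).
#' @param manifest named character vector or list mapping sample name to
#'   role in tumor/normal/plasma/control/pool, or a path to a YAML/JSON file
#'   with that mapping. Must cover exactly one tumor, one normal, one
#'   plasma, at least one control.
#' @param patientId patient identifier; defaults to the tumor sample name.
#' @param popAFField INFO field holding the population allele frequency
#'   (default "POP_AF"; missing field or value is treated as absent).
#' @return a \linkS4class{PatientTable}.
#' @export
readPatientVcf <- function(vcfPath, manifest, patientId = NULL,
                           popAFField = "POP_AF") {
    manifest <- .readManifest(manifest)
    vcf <- VariantAnnotation::readVcf(vcfPath)
    hdr <- VariantAnnotation::header(vcf)
    fmt <- rownames(VariantAnnotation::geno(hdr))
    if (!all(c("AD", "DP") %in% fmt))
        stop("VCF FORMAT must define both AD and DP")
    vcfSamples <- VariantAnnotation::samples(hdr)
    if (!all(names(manifest) %in% vcfSamples))
        stop("manifest samples absent from VCF header: ",
             paste(setdiff(names(manifest), vcfSamples), collapse = ", "))
    .checkManifestRoles(manifest)

    vcf <- vcf[, names(manifest)]
    snv <- VariantAnnotation::isSNV(vcf, singleAltOnly = FALSE)
    nSkipped <- sum(!snv)
    if (nSkipped > 0L) {
        warning(sprintf("skipped %d non-SNV record(s)", nSkipped))
        vcf <- vcf[snv, ]
    }
    vcf <- VariantAnnotation::expand(vcf)
    # expand() can leave SNV alleles of mixed-type lines; re-check per allele
    keep <- VariantAnnotation::isSNV(vcf, singleAltOnly = FALSE)
    vcf <- vcf[keep, ]

    rr <- SummarizedExperiment::rowRanges(vcf)
    n <- length(rr)
    adArr <- VariantAnnotation::geno(vcf)$AD  # n x samples x (ref, alt)
    dpMat <- VariantAnnotation::geno(vcf)$DP
    if (n > 0L) {
        ad <- matrix(as.integer(adArr[, , 2L]), nrow = n)
        dp <- matrix(as.integer(dpMat), nrow = n)
    } else {
        ad <- dp <- matrix(integer(0), nrow = 0, ncol = length(manifest))
    }
    colnames(ad) <- colnames(dp) <- names(manifest)
    nMissing <- sum(is.na(dp) | is.na(ad))
    if (nMissing > 0L)
        warning(sprintf(
            "%d cell(s) with missing genotype data set to dp = 0, ad = 0",
            nMissing))
    ad[is.na(ad)] <- 0L
    dp[is.na(dp)] <- 0L
    # depth never below what the AD field accounts for
    dp <- pmax(dp, ad)

    info <- VariantAnnotation::info(vcf)
    pa <- rep(NA_real_, n)
    if (popAFField %in% colnames(info)) {
        v <- info[[popAFField]]
        if (is(v, "List") || is.list(v))
            v <- vapply(v, function(e) if (length(e)) as.numeric(e[[1L]])
                        else NA_real_, numeric(1))
        pa <- as.numeric(v)
    }
    if (is.null(patientId))
        patientId <- names(manifest)[manifest == "tumor"][1L]
    tab <- PatientTable(
        patientId = patientId,
        chrom = as.character(GenomicRanges::seqnames(rr)),
        pos = GenomicRanges::start(rr),
        ref = as.character(VariantAnnotation::ref(vcf)),
        alt = as.character(VariantAnnotation::alt(vcf)),
        DP = dp, AD = ad,
        role = unname(manifest), sampleIds = names(manifest), popAF = pa)
    .dedupeKeys(tab)
}

.readManifest <- function(manifest) {
    if (is.character(manifest) && length(manifest) == 1L &&
        file.exists(manifest)) {
        manifest <- if (grepl("\\.json$", manifest, ignore.case = TRUE))
            jsonlite::read_json(manifest, simplifyVector = TRUE)
        else yaml::read_yaml(manifest)
    }
    m <- unlist(manifest)
    if (is.null(names(m)) || any(!nzchar(names(m))))
        stop("manifest must map sample names to roles")
    if (!all(m %in% .ROLES))
        stop("manifest roles must be in: ", paste(.ROLES, collapse = ", "))
    m
}

.checkManifestRoles <- function(manifest) {
    for (r in c("tumor", "normal", "plasma"))
        if (sum(manifest == r) != 1L)
            stop(sprintf("manifest must assign exactly one '%s' sample", r))
    if (sum(manifest == "control") < 1L)
        stop("manifest must assign at least one control sample")
    invisible(TRUE)
}

.dedupeKeys <- function(tab) {
    dup <- duplicated(variantKeys(tab))
    if (any(dup)) {
        warning(sprintf("dropped %d duplicated variant key(s)", sum(dup)))
        tab <- tab[!dup, ]
    }
    tab
}

.tsvColName <- function(role, id) {
    base <- switch(role, tumor = "tumor", normal = "normal",
                   plasma = "plasma", paste0(role, ":", id))
    paste0(base, c(".DP", ".AD"))
}

#' Write a PatientTable to its TSV representation
#'
#' Tab-separated, UTF-8, "." for missing values. Header columns: chrom, pos,
#' ref, alt, pop_af, then DP/AD pairs per sample — \code{tumor.DP tumor.AD
#' normal.DP normal.AD plasma.DP plasma.AD control:<id>.DP control:<id>.AD
#' ... pool:<id>.DP pool:<id>.AD ...}. Integer counts are written bare, so
#' the round trip through \code{\link{readPatientTable}} is bit-exact.
#'
#' @param table a \linkS4class{PatientTable}.
#' @param tsvPath output path.
#' @return the path, invisibly.
#' @export
writePatientTable <- function(table, tsvPath) {
    stopifnot(is(table, "PatientTable"))
    roles <- sampleRoles(table)
    ord <- order(match(roles, .ROLES))
    dp <- dpMatrix(table)[, ord, drop = FALSE]
    ad <- adMatrix(table)[, ord, drop = FALSE]
    ids <- names(roles)[ord]
    cols <- character(0)
    dat <- list(chrom = as.character(GenomicRanges::seqnames(rowRanges(table))),
                pos = GenomicRanges::start(rowRanges(table)),
                ref = mcols(rowRanges(table))$ref,
                alt = mcols(rowRanges(table))$alt,
                pop_af = ifelse(is.na(popAF(table)), ".",
                                vapply(popAF(table), function(p)
                                    format(p, digits = 15, trim = TRUE), "")))
    for (j in seq_along(ids)) {
        nm <- .tsvColName(roles[ord][j], ids[j])
        dat[[nm[1L]]] <- dp[, j]
        dat[[nm[2L]]] <- ad[, j]
    }
    df <- as.data.frame(dat, check.names = FALSE, stringsAsFactors = FALSE)
    con <- file(tsvPath, open = "w", encoding = "UTF-8")
    on.exit(close(con))
    writeLines(paste0("# patient_id=", patientId(table)), con)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(tsvPath)
}

#' Read a PatientTable from its TSV representation
#'
#' Reads the dialect written by \code{\link{writePatientTable}}. VAF is
#' always recomputed from AD/DP; a VAF column in the file would be ignored.
#' Any cell with AD > DP is a validation error naming the offending row.
#'
#' @param tsvPath input path.
#' @param patientId overrides the patient id recorded in the file header.
#' @return a \linkS4class{PatientTable}.
#' @export
readPatientTable <- function(tsvPath, patientId = NULL) {
    lines <- readLines(tsvPath, encoding = "UTF-8")
    pid <- "patient"
    meta <- grepl("^# *patient_id=", lines)
    if (any(meta))
        pid <- sub("^# *patient_id=", "", lines[which(meta)[1L]])
    if (!is.null(patientId)) pid <- patientId
    lines <- lines[!grepl("^#", lines)]
    if (length(lines) == 0L) stop("no header row in ", tsvPath)
    hdr <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
    fixed <- c("chrom", "pos", "ref", "alt", "pop_af")
    if (!identical(hdr[seq_along(fixed)], fixed))
        stop("TSV header must start with: ", paste(fixed, collapse = " "))
    sampleCols <- hdr[-seq_along(fixed)]
    if (length(sampleCols) %% 2L != 0L)
        stop("sample columns must come in .DP/.AD pairs")
    dpCols <- sampleCols[seq(1L, length(sampleCols), by = 2L)]
    adCols <- sampleCols[seq(2L, length(sampleCols), by = 2L)]
    if (!all(grepl("\\.DP$", dpCols)) || !all(grepl("\\.AD$", adCols)) ||
        !identical(sub("\\.DP$", "", dpCols), sub("\\.AD$", "", adCols)))
        stop("sample columns must alternate <sample>.DP, <sample>.AD")
    samples <- sub("\\.DP$", "", dpCols)
    role <- ifelse(grepl("^control:", samples), "control",
            ifelse(grepl("^pool:", samples), "pool", samples))
    if (!all(role %in% .ROLES))
        stop("unrecognised sample columns: ",
             paste(samples[!role %in% .ROLES], collapse = ", "))
    ids <- sub("^(control|pool):", "", samples)

    nSamp <- length(samples)
    if (length(lines) == 1L) {
        return(PatientTable(pid, character(0), integer(0), character(0),
                            character(0),
                            DP = matrix(integer(0), 0, nSamp),
                            AD = matrix(integer(0), 0, nSamp),
                            role = role, sampleIds = ids))
    }
    df <- utils::read.table(text = lines[-1L], sep = "\t", header = FALSE,
                            col.names = hdr, na.strings = ".",
                            colClasses = c("character", "integer", "character",
                                           "character", "numeric",
                                           rep("integer", nSamp * 2L)),
                            check.names = FALSE)
    dp <- as.matrix(df[, dpCols, drop = FALSE])
    ad <- as.matrix(df[, adCols, drop = FALSE])
    if (anyNA(dp) || anyNA(ad))
        stop("missing DP/AD cells; counts must be explicit integers")
    bad <- which(rowSums(ad > dp) > 0L)
    if (length(bad))
        stop(sprintf("AD > DP at data row %d (%s:%d %s>%s)", bad[1L],
                     df$chrom[bad[1L]], df$pos[bad[1L]], df$ref[bad[1L]],
                     df$alt[bad[1L]]))
    PatientTable(pid, df$chrom, df$pos, df$ref, df$alt, DP = dp, AD = ad,
                 role = role, sampleIds = ids, popAF = df$pop_af)
}

#' Read a panel-of-normals site list
#'
#' Accepts either a sites-only VCF or a 4-column TSV (chrom pos ref alt,
#' with or without that header line).
#'
#' @param path input file.
#' @param label provenance label for the resulting \linkS4class{PonSites}.
#' @return a \linkS4class{PonSites}.
#' @export
readPonFile <- function(path, label = basename(path)) {
    if (grepl("\\.vcf(\\.gz|\\.bgz)?$", path, ignore.case = TRUE)) {
        vcf <- VariantAnnotation::expand(VariantAnnotation::readVcf(path))
        rr <- SummarizedExperiment::rowRanges(vcf)
        keys <- paste(GenomicRanges::seqnames(rr), GenomicRanges::start(rr),
                      as.character(VariantAnnotation::ref(vcf)),
                      as.character(VariantAnnotation::alt(vcf)), sep = ":")
    } else {
        df <- utils::read.table(path, sep = "\t", header = FALSE,
                                col.names = c("chrom", "pos", "ref", "alt"),
                                colClasses = c("character", "integer",
                                               "character", "character"))
        if (nrow(df) && identical(tolower(df$chrom[1L]), "chrom"))
            df <- df[-1L, , drop = FALSE]
        keys <- paste(df$chrom, df$pos, df$ref, df$alt, sep = ":")
    }
    new("PonSites", keys = unique(keys), label = label)
}

#' Write a panel-of-normals site list as 4-column TSV
#'
#' @param pon a \linkS4class{PonSites}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writePonFile <- function(pon, path) {
    parts <- strsplit(ponKeys(pon), ":", fixed = TRUE)
    df <- data.frame(chrom = vapply(parts, `[`, "", 1L),
                     pos = vapply(parts, `[`, "", 2L),
                     ref = vapply(parts, `[`, "", 3L),
                     alt = vapply(parts, `[`, "", 4L))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}
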