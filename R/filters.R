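#' Basic tumor/normal threshold filters
#'
#' Evaluates the five basic filters per variant against the original table.
#' All comparisons are inclusive on the keep side: a variant passes
#' \code{ADt} iff tumor AD >= \code{adTMin}, \code{DPt} iff tumor DP >=
#' \code{dpTMin}, \code{VAFt} iff tumor VAF >= \code{vafTMin}, \code{ADn}
#' iff normal AD <= \code{adNMax} (the default 0 keeps only variants with
#' no alternate reads in the matched normal), and \code{DPn} iff normal DP
#' >= \code{dpNMin}.
#'
#' @param table a \linkS4class{PatientTable}.
#' @param cfg a \linkS4class{FilterConfig}.
#' @return logical matrix, variants x labels (ADt, DPt, VAFt, ADn, DPn);
#'   TRUE means the variant FAILS that filter.
#' @export
evaluateBasicFilters <- function(table, cfg = filterConfig()) {
    stopifnot(is(table, "PatientTable"), is(cfg, "FilterConfig"))
    tAD <- roleObs(table, "tumor", "AD")
    tDP <- roleObs(table, "tumor", "DP")
    tVAF <- roleObs(table, "tumor", "VAF")
    nAD <- roleObs(table, "normal", "AD")
    nDP <- roleObs(table, "normal", "DP")
    fails <- cbind(ADt = tAD < cfg@adTMin,
                   DPt = tDP < cfg@dpTMin,
                   VAFt = tVAF < cfg@vafTMin,
                   ADn = nAD > cfg@adNMax,
                   DPn = nDP < cfg@dpNMin)
    rownames(fails) <- variantKeys(table)
    fails
}

.failsGnomad <- function(table, popAFMax) {
    pa <- popAF(table)
    fail <- !is.na(pa) & pa > popAFMax
    names(fail) <- variantKeys(table)
    fail
}

#' Population allele-frequency filter
#'
#' Removes variants whose population allele frequency exceeds
#' \code{popAFMax} (inclusive keep at the threshold). Variants absent from
#' the population database (missing popAF) are kept: a tumor somatic
#' variant is not expected in population catalogues, and absence carries no
#' evidence of germline origin.
#'
#' @param table a \linkS4class{PatientTable}.
#' @param popAFMax maximum tolerated population allele frequency.
#' @return list with \code{kept} (the filtered PatientTable) and
#'   \code{verdicts} (data.frame: key + logical \code{gnomAD} fail flag).
#' @export
applyPopulationAfFilter <- function(table, popAFMax = 1e-5) {
    fail <- .failsGnomad(table, popAFMax)
    verdicts <- data.frame(key = variantKeys(table), gnomAD = unname(fail))
    list(kept = table[!fail, ], verdicts = verdicts)
}

#' Build a panel of normals from normal-sample observations
#'
#' A site enters the PON iff it is observed with AD >= \code{ponMinAd} in at
#' least \code{ponMinSamples} distinct normal samples.
#'
#' @param normals data.frame with columns \code{sample, chrom, pos, ref,
#'   alt, ad} — one row per (normal sample, site) observation, e.g. stacked
#'   \code{\link{normalObservations}} of a cohort's tables.
#' @param ponMinSamples,ponMinAd membership rule knobs.
#' @param label provenance label.
#' @return a \linkS4class{PonSites}.
#' @export
buildPon <- function(normals, ponMinSamples = 2, ponMinAd = 1,
                     label = "self") {
    need <- c("sample", "chrom", "pos", "ref", "alt", "ad")
    if (!all(need %in% names(normals)))
        stop("normals must have columns: ", paste(need, collapse = ", "))
    if (length(unique(normals$sample)) < 1L)
        stop("at least one normal sample required")
    hit <- normals[normals$ad >= ponMinAd, , drop = FALSE]
    key <- paste(hit$chrom, hit$pos, hit$ref, hit$alt, sep = ":")
    nSamp <- tapply(hit$sample, key, function(s) length(unique(s)))
    keys <- names(nSamp)[nSamp >= ponMinSamples]
    new("PonSites", keys = unname(keys), label = label)
}

#' Extract a table's normal-sample observations for PON building
#'
#' @param table a \linkS4class{PatientTable}.
#' @return data.frame in the shape \code{\link{buildPon}} expects.
#' @export
normalObservations <- function(table) {
    rr <- rowRanges(table)
    data.frame(sample = paste0(patientId(table), ".normal"),
               chrom = as.character(GenomicRanges::seqnames(rr)),
               pos = GenomicRanges::start(rr),
               ref = mcols(rr)$ref, alt = mcols(rr)$alt,
               ad = unname(roleObs(table, "normal", "AD")))
}

#' Merge two panels of normals
#'
#' Set union of the site keys; labels are concatenated.
#'
#' @param a,b \linkS4class{PonSites} objects.
#' @return the merged \linkS4class{PonSites}.
#' @export
mergePons <- function(a, b) {
    stopifnot(is(a, "PonSites"), is(b, "PonSites"))
    new("PonSites", keys = union(a@keys, b@keys),
        label = paste(a@label, b@label, sep = "+"))
}

#' Panel-of-normals filter
#'
#' Removes variants whose key is a member of the PON site list.
#'
#' @param table a \linkS4class{PatientTable}.
#' @param pon a \linkS4class{PonSites}.
#' @return list with \code{kept} and \code{verdicts} (key + logical
#'   \code{PON} fail flag).
#' @export
applyPonFilter <- function(table, pon) {
    stopifnot(is(pon, "PonSites"))
    fail <- variantKeys(table) %in% pon@keys
    verdicts <- data.frame(key = variantKeys(table), PON = fail)
    list(kept = table[!fail, ], verdicts = verdicts)
}

.failsPool <- function(table, poolAdGt) {
    poolAd <- roleObs(table, "pool", "AD")
    if (ncol(poolAd) == 0L) {
        fail <- rep(FALSE, nrow(table))
    } else {
        fail <- rowSums(poolAd > poolAdGt) > 0L
    }
    names(fail) <- variantKeys(table)
    fail
}

#' Plasma-pool artefact filter
#'
#' Removes a variant if any plasma-pool sample shows AD strictly greater
#' than \code{poolAdGt} (default 1, i.e. AD >= 2 in at least one pool plasma
#' removes the site). Because pool samples come from other patients, real
#' reads at a patient-specific somatic site mark a position-specific
#' sequencing artefact. Removal drops the variant from the whole record —
#' it is excluded from the patient-plasma signal AND from the control-plasma
#' noise model downstream.
#'
#' @param table a \linkS4class{PatientTable}.
#' @param poolAdGt strict AD bound; a single pool read (AD = 1) never
#'   removes a site at the default.
#' @return list with \code{kept} and \code{verdicts} (key + logical
#'   \code{pool} fail flag).
#' @export
applyPlasmaPoolFilter <- function(table, poolAdGt = 1) {
    fail <- .failsPool(table, poolAdGt)
    verdicts <- data.frame(key = variantKeys(table), pool = unname(fail))
    list(kept = table[!fail, ], verdicts = verdicts)
}

#' Apply a complete filtering method
#'
#' The three method ladders differ only in the noise filters layered on the
#' basic thresholds: Method 1 uses the population-frequency filter plus an
#' external PON (e.g. the 1000-genomes PON); Method 2 swaps in the merged
#' PON (external union self-generated); Method 3 adds the plasma-pool
#' artefact filter on top of Method 2. Every filter is evaluated per
#' variant against the ORIGINAL table and the survivors are the variants
#' failing nothing, so composition order cannot change the result.
#'
#' @param table a \linkS4class{PatientTable}.
#' @param method 1, 2 or 3.
#' @param cfg a \linkS4class{FilterConfig}.
#' @param pon1000g external \linkS4class{PonSites} (may be empty).
#' @param ponSelf self-generated \linkS4class{PonSites} (used by methods 2
#'   and 3; may be empty).
#' @return list with \code{kept} (PatientTable of survivors) and
#'   \code{verdicts}: a data.frame with the variant key columns and one
#'   logical fail column per filter active in the method (pool only for
#'   method 3). A variant is kept iff its whole verdict row is FALSE.
#' @export
applyMethod <- function(table, method, cfg = filterConfig(),
                        pon1000g = emptyPon("1000g"),
                        ponSelf = emptyPon("self")) {
    if (!method %in% 1:3) stop("unknown method id: ", method)
    pon <- if (method == 1L) pon1000g else mergePons(pon1000g, ponSelf)
    basic <- evaluateBasicFilters(table, cfg)
    verdicts <- data.frame(key = variantKeys(table),
                           as.data.frame(basic, row.names = NULL),
                           gnomAD = unname(.failsGnomad(table, cfg@popAFMax)),
                           PON = variantKeys(table) %in% pon@keys)
    if (method == 3L)
        verdicts$pool <- unname(.failsPool(table, cfg@poolAdGt))
    fail <- rowSums(as.matrix(verdicts[, -1L, drop = FALSE])) > 0L
    list(kept = table[!fail, ], verdicts = verdicts)
}

#' An empty panel of normals
#'
#' @param label provenance label.
#' @return a \linkS4class{PonSites} with no sites.
#' @export
emptyPon <- function(label = "empty") new("PonSites", keys = character(0),
                                          label = label)

#' Evaluate a ladder of filter configurations
#'
#' Applies Method 1 under each configuration of an ordered ladder (the
#' progressively more stringent threshold sets) and reports the surviving
#' variant count per rung.
#'
#' @param table a \linkS4class{PatientTable}.
#' @param ladder non-empty list of \linkS4class{FilterConfig}s; names are
#'   used as rung labels.
#' @param pon1000g external PON applied at every rung.
#' @return list with \code{counts} (data.frame rung/nKept) and \code{kept}
#'   (list of survivor PatientTables, one per rung).
#' @export
filterLadder <- function(table, ladder, pon1000g = emptyPon("1000g")) {
    if (length(ladder) == 0L) stop("ladder must be non-empty")
    if (is.null(names(ladder)))
        names(ladder) <- LETTERS[seq_along(ladder)]
    kept <- lapply(ladder, function(cfg)
        applyMethod(table, 1L, cfg, pon1000g = pon1000g)$kept)
    counts <- data.frame(rung = names(ladder),
                         nKept = vapply(kept, nrow, integer(1)),
                         row.names = NULL)
    list(counts = counts, kept = kept)
}
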