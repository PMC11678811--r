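#' Construct a PatientTable
#'
#' Assembles the forced-call matrix of a patient's tumor SNVs across the
#' sample roles the method requires: one tumor, one matched normal, one
#' patient plasma, zero or more control plasmas and zero or more plasma-pool
#' samples.
#'
#' @param patientId patient identifier string.
#' @param chrom chromosome names (character, length n variants).
#' @param pos 1-based positions (integer).
#' @param ref,alt single reference/alternate bases (A/C/G/T).
#' @param DP,AD integer matrices of read depth and alternate allelic depth,
#'   variants x samples; \code{AD <= DP} cellwise.
#' @param role character vector of sample roles, one per column of
#'   \code{DP}/\code{AD}, each in tumor/normal/plasma/control/pool.
#' @param sampleIds sample identifiers (column names); defaults to the role
#'   with a running index for controls and pool samples.
#' @param popAF optional population allele frequency per variant
#'   (NA = absent from the population database).
#' @return a \linkS4class{PatientTable}.
#' @examples
#' tab <- PatientTable("P1",
#'     chrom = "chr1", pos = 100L, ref = "A", alt = "T",
#'     DP = matrix(c(48L, 10L, 52L, 49L, 50L), 1),
#'     AD = matrix(c(8L, 0L, 2L, 0L, 0L), 1),
#'     role = c("tumor", "normal", "plasma", "control", "control"))
#' vafMatrix(tab)
#' @export
PatientTable <- function(patientId, chrom, pos, ref, alt, DP, AD, role,
                         sampleIds = NULL, popAF = NULL) {
    DP <- as.matrix(DP); AD <- as.matrix(AD)
    storage.mode(DP) <- "integer"; storage.mode(AD) <- "integer"
    n <- length(pos)
    if (length(chrom) == 1L) chrom <- rep(chrom, n)
    if (is.null(popAF)) popAF <- rep(NA_real_, n)
    if (is.null(sampleIds)) {
        sampleIds <- role
        for (r in c("control", "pool")) {
            i <- which(role == r)
            if (length(i)) sampleIds[i] <- paste0(r, seq_along(i))
        }
    }
    if (anyDuplicated(sampleIds))
        stop("sample ids must be unique")
    colnames(DP) <- colnames(AD) <- sampleIds
    rr <- GRanges(chrom, IRanges(as.integer(pos), width = 1L),
                  ref = as.character(ref), alt = as.character(alt),
                  popAF = as.numeric(popAF))
    names(rr) <- if (n) paste(chrom, pos, ref, alt, sep = ":") else NULL
    se <- SummarizedExperiment(
        assays = list(DP = DP, AD = AD),
        rowRanges = rr,
        colData = DataFrame(role = as.character(role), row.names = sampleIds),
        metadata = list(patientId = as.character(patientId)))
    new("PatientTable", se)
}

#' @describeIn PatientTable patient identifier.
#' @param x a PatientTable.
#' @export
patientId <- function(x) metadata(x)$patientId

#' @describeIn PatientTable variant keys as "chrom:pos:ref:alt" strings.
#' @export
variantKeys <- function(x) {
    rr <- rowRanges(x)
    if (length(rr) == 0L) return(character(0))
    paste(seqnames(rr), start(rr), mcols(rr)$ref, mcols(rr)$alt, sep = ":")
}

#' @describeIn PatientTable sample roles (named by sample id).
#' @export
sampleRoles <- function(x) {
    r <- as.character(colData(x)$role)
    names(r) <- rownames(colData(x))
    r
}

.roleIdx <- function(x, role) which(as.character(colData(x)$role) %in% role)

#' @describeIn PatientTable read-depth matrix (variants x samples).
#' @export
dpMatrix <- function(x) assay(x, "DP")

#' @describeIn PatientTable alternate allelic-depth matrix.
#' @export
adMatrix <- function(x) assay(x, "AD")

#' Variant allele frequency from counts
#'
#' VAF = AD / DP, with the zero-depth convention VAF = 0 when DP = 0 (a site
#' with no coverage contributes no alternate signal rather than an undefined
#' value; this biases averages toward zero, never upward).
#'
#' @param ad alternate allelic depth(s).
#' @param dp read depth(s).
#' @return numeric vector/matrix of VAFs in [0,1].
#' @examples
#' vafFromCounts(8, 48)   # 1/6
#' vafFromCounts(0, 0)    # 0 by convention
#' @export
vafFromCounts <- function(ad, dp) {
    stopifnot(all(ad >= 0), all(ad <= dp | dp == 0))
    v <- ifelse(dp > 0, ad / dp, 0)
    if (is.matrix(dp)) {
        v <- matrix(v, nrow(dp), ncol(dp), dimnames = dimnames(dp))
    }
    v
}

#' @describeIn PatientTable VAF matrix recomputed from AD/DP.
#' @export
vafMatrix <- function(x) vafFromCounts(adMatrix(x), dpMatrix(x))

#' @describeIn PatientTable population allele frequencies (NA = missing).
#' @export
popAF <- function(x) mcols(rowRanges(x))$popAF

#' Per-role observation slices
#'
#' Extract the DP/AD/VAF observations of the samples holding a given role.
#' For the singleton roles (tumor, normal, plasma) vectors are returned;
#' for control and pool roles matrices (variants x samples).
#'
#' @param x a PatientTable.
#' @param role one of "tumor", "normal", "plasma", "control", "pool".
#' @param what one of "AD", "DP", "VAF".
#' @return vector or matrix of the requested metric.
#' @export
roleObs <- function(x, role = .ROLES, what = c("AD", "DP", "VAF")) {
    role <- match.arg(role)
    what <- match.arg(what)
    idx <- .roleIdx(x, role)
    m <- switch(what, AD = adMatrix(x), DP = dpMatrix(x), VAF = vafMatrix(x))
    out <- m[, idx, drop = FALSE]
    if (role %in% c("tumor", "normal", "plasma")) drop(out[, 1L]) else out
}

#' Subset a PatientTable to a set of variant keys
#'
#' @param x a PatientTable.
#' @param keep logical vector (length nrow) or character vector of keys.
#' @return the subsetted PatientTable.
#' @export
keepVariants <- function(x, keep) {
    if (is.character(keep)) keep <- variantKeys(x) %in% keep
    x[keep, ]
}

setMethod("show", "PatientTable", function(object) {
    roles <- sampleRoles(object)
    cat(sprintf("PatientTable '%s': %d SNVs x %d samples\n",
                patientId(object), nrow(object), ncol(object)))
    cat(sprintf("  roles: tumor/normal/plasma + %d control, %d pool\n",
                sum(roles == "control"), sum(roles == "pool")))
    npa <- sum(!is.na(popAF(object)))
    cat(sprintf("  popAF present for %d/%d variants\n", npa, nrow(object)))
})

setMethod("show", "FilterConfig", function(object) {
    cat("FilterConfig:\n")
    cat(sprintf("  tumor:  AD >= %g, DP >= %g, VAF >= %g\n",
                object@adTMin, object@dpTMin, object@vafTMin))
    cat(sprintf("  normal: AD <= %g, DP >= %g\n", object@adNMax, object@dpNMin))
    cat(sprintf("  popAF <= %g; pool removal at AD > %g\n",
                object@popAFMax, object@poolAdGt))
    cat(sprintf("  PON membership: AD >= %g in >= %g normals\n",
                object@ponMinAd, object@ponMinSamples))
})

setMethod("show", "PonSites", function(object) {
    cat(sprintf("PonSites '%s': %d sites\n", object@label, length(object@keys)))
})

setMethod("show", "NoiseModel", function(object) {
    cat(sprintf("NoiseModel (%s%s): mu = %.4g, sigma = %.4g over %d controls\n",
                object@metric, if (object@pooled) ", pooled" else "",
                object@muNoise, object@sigmaNoise, object@nControls))
})

setMethod("show", "SignalResult", function(object) {
    cat(sprintf(
        "SignalResult (%s): n = %d, aveVarDet = %.4g, S2N = %.4g, z = %.4g\n",
        object@metric, object@nVariantsUsed, object@aveVarDet, object@s2n,
        object@z))
})

setMethod("show", "SimConfig", function(object) {
    cat(sprintf(
        "SimConfig: %d variants, tf = %g, depths T/N/P/C = %g/%g/%g/%g\n",
        object@nVariants, object@tumorFraction, object@tumorDepth,
        object@normalDepth, object@plasmaDepth, object@controlDepth))
    cat(sprintf("  %d controls, %d pool; error %g, artefacts %g @ VAF %g\n",
                object@nControls, object@nPool, object@errorRate,
                object@artefactFraction, object@artefactVaf))
})

#' Construct a FilterConfig
#'
#' @param adTMin,dpTMin,vafTMin,adNMax,dpNMin,popAFMax,poolAdGt,ponMinSamples,ponMinAd
#'   see \linkS4class{FilterConfig}.
#' @return a \linkS4class{FilterConfig}.
#' @export
filterConfig <- function(adTMin = 8, dpTMin = 12, vafTMin = 0.2, adNMax = 0,
                         dpNMin = 10, popAFMax = 1e-5, poolAdGt = 1,
                         ponMinSamples = 2, ponMinAd = 1) {
    new("FilterConfig", adTMin = adTMin, dpTMin = dpTMin, vafTMin = vafTMin,
        adNMax = adNMax, dpNMin = dpNMin, popAFMax = popAFMax,
        poolAdGt = poolAdGt, ponMinSamples = ponMinSamples,
        ponMinAd = ponMinAd)
}

#' Construct a SimConfig
#'
#' @param nVariants,tumorDepth,normalDepth,plasmaDepth,controlDepth,nControls,nPool,tumorFraction,tumorVafMin,tumorVafMax,errorRate,artefactFraction,artefactVaf,germlineLeakFraction,germlineLeakVaf,depthDispersion
#'   see \linkS4class{SimConfig}.
#' @return a \linkS4class{SimConfig}.
#' @export
simConfig <- function(nVariants = 2000, tumorDepth = 24, normalDepth = 17,
                      plasmaDepth = 52, controlDepth = 49, nControls = 9,
                      nPool = 9, tumorFraction = 0.005, tumorVafMin = 0.2,
                      tumorVafMax = 0.8, errorRate = 1e-3,
                      artefactFraction = 0.02, artefactVaf = 0.02,
                      germlineLeakFraction = 0.01, germlineLeakVaf = 0.5,
                      depthDispersion = Inf) {
    new("SimConfig", nVariants = as.integer(nVariants),
        tumorDepth = tumorDepth, normalDepth = normalDepth,
        plasmaDepth = plasmaDepth, controlDepth = controlDepth,
        nControls = as.integer(nControls), nPool = as.integer(nPool),
        tumorFraction = tumorFraction, tumorVafMin = tumorVafMin,
        tumorVafMax = tumorVafMax, errorRate = errorRate,
        artefactFraction = artefactFraction, artefactVaf = artefactVaf,
        germlineLeakFraction = germlineLeakFraction,
        germlineLeakVaf = germlineLeakVaf,
        depthDispersion = depthDispersion)
}

#' Accessors for NoiseModel and SignalResult
#'
#' Plain accessor functions for the statistic containers, so downstream code
#' never reaches into slots.
#'
#' @param x a NoiseModel or SignalResult.
#' @name stat-accessors
NULL

#' @rdname stat-accessors
#' @export
muNoise <- function(x) x@muNoise
#' @rdname stat-accessors
#' @export
sigmaNoise <- function(x) x@sigmaNoise
#' @rdname stat-accessors
#' @export
perControl <- function(x) x@perControl
#' @rdname stat-accessors
#' @export
nControls <- function(x) x@nControls
#' @rdname stat-accessors
#' @export
signalMetric <- function(x) x@metric
#' @rdname stat-accessors
#' @export
aveVarDetValue <- function(x) x@aveVarDet
#' @rdname stat-accessors
#' @export
s2nValue <- function(x) x@s2n
#' @rdname stat-accessors
#' @export
zValue <- function(x) x@z
#' @rdname stat-accessors
#' @export
nVariantsUsed <- function(x) x@nVariantsUsed

#' @rdname stat-accessors
#' @export
ponKeys <- function(x) x@keys
#' @rdname stat-accessors
#' @export
ponLabel <- function(x) x@label
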