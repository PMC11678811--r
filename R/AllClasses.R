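#' @import methods
#' @importFrom stats rbinom rpois runif qt sd rnbinom setNames
#' @importFrom S4Vectors DataFrame metadata metadata<- mcols mcols<-
#' @importFrom IRanges IRanges
#' @importFrom GenomicRanges GRanges seqnames start
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   rowRanges colData
NULL

.FILTER_LABELS <- c("ADt", "DPt", "VAFt", "ADn", "DPn", "gnomAD", "PON", "pool")
.ROLES <- c("tumor", "normal", "plasma", "control", "pool")
.BASES <- c("A", "C", "G", "T")

#' PatientTable: forced-call SNV observations across a patient's samples
#'
#' A \linkS4class{RangedSummarizedExperiment} holding, for every SNV called
#' in a patient's tumor, the read depth (\code{DP}) and alternate allelic
#' depth (\code{AD}) observed by forced calling in each sample of the
#' patient's assay set: the tumor, the matched normal, the patient plasma,
#' each tumor-free control plasma, and each plasma-pool sample (plasma from
#' other cancer patients). Rows are variants (a \code{GRanges} of width-1
#' positions with \code{ref}, \code{alt} and \code{popAF} metadata columns);
#' columns are samples with a \code{role} column in \code{colData}.
#'
#' VAF is never stored: it is recomputed as AD/DP on demand (0 where DP is
#' 0), so the counts remain the single source of truth.
#'
#' @slot .  inherits all slots from \code{RangedSummarizedExperiment}; the
#'   patient identifier lives in \code{metadata(x)$patientId}.
#' @seealso \code{\link{PatientTable}} (constructor),
#'   \code{\link{readPatientVcf}}, \code{\link{readPatientTable}}
#' @export
setClass("PatientTable", contains = "RangedSummarizedExperiment")

.validPatientTable <- function(object) {
    msg <- NULL
    if (!all(c("DP", "AD") %in% names(assays(object))))
        msg <- c(msg, "assays must contain 'DP' and 'AD'")
    cd <- colData(object)
    if (!("role" %in% names(cd)))
        msg <- c(msg, "colData must contain a 'role' column")
    if (!is.null(msg)) return(msg)
    role <- as.character(cd$role)
    if (!all(role %in% .ROLES))
        msg <- c(msg, sprintf("unknown roles: %s",
                              paste(setdiff(role, .ROLES), collapse = ", ")))
    for (r in c("tumor", "normal", "plasma"))
        if (sum(role == r) != 1L)
            msg <- c(msg, sprintf("exactly one '%s' sample required", r))
    rr <- rowRanges(object)
    m <- mcols(rr)
    if (!all(c("ref", "alt") %in% names(m))) {
        msg <- c(msg, "rowRanges must carry 'ref' and 'alt' columns")
        return(if (is.null(msg)) TRUE else msg)
    }
    if (nrow(object) > 0L) {
        if (any(!m$ref %in% .BASES) || any(!m$alt %in% .BASES))
            msg <- c(msg, "ref and alt must be single bases A/C/G/T (SNVs only)")
        if (any(m$ref == m$alt))
            msg <- c(msg, "ref must differ from alt")
        if (any(start(rr) < 1L))
            msg <- c(msg, "positions must be >= 1 (1-based VCF convention)")
        keys <- paste(seqnames(rr), start(rr), m$ref, m$alt, sep = ":")
        if (anyDuplicated(keys))
            msg <- c(msg, "variant keys must be unique within a table")
        dp <- assay(object, "DP"); ad <- assay(object, "AD")
        if (any(dp < 0) || any(ad < 0))
            msg <- c(msg, "DP and AD must be non-negative")
        if (any(ad > dp))
            msg <- c(msg, "AD must not exceed DP in any cell")
        if ("popAF" %in% names(m)) {
            pa <- m$popAF
            if (any(!is.na(pa) & (pa < 0 | pa > 1)))
                msg <- c(msg, "popAF must lie in [0,1] or be NA")
        }
    }
    if (is.null(msg)) TRUE else msg
}
setValidity("PatientTable", .validPatientTable)

#' Filter threshold configuration
#'
#' Thresholds for the basic tumor/normal filters, the population
#' allele-frequency filter, panel-of-normals (PON) construction, and the
#' plasma-pool artefact filter. Defaults are the shipped operating point:
#' keep a variant iff tumor AD >= 8, tumor DP >= 12, tumor VAF >= 0.2,
#' normal AD == 0 and normal DP >= 10; remove it if its population allele
#' frequency exceeds 1e-5 or if any plasma-pool sample shows AD strictly
#' greater than 1.
#'
#' @slot adTMin minimum tumor alternate allelic depth (reads), keep if >=.
#' @slot dpTMin minimum tumor read depth (reads), keep if >=.
#' @slot vafTMin minimum tumor variant allele frequency, keep if >=.
#' @slot adNMax maximum normal alternate allelic depth (reads), keep if <=.
#' @slot dpNMin minimum normal read depth (reads), keep if >=.
#' @slot popAFMax maximum population allele frequency; variants with a known
#'   frequency above this are removed, variants absent from the population
#'   database are kept.
#' @slot poolAdGt strict lower bound on pool AD for removal: a variant is
#'   removed when some pool sample shows AD > \code{poolAdGt}.
#' @slot ponMinSamples number of distinct normal samples that must carry a
#'   site for it to enter a self-generated PON.
#' @slot ponMinAd alternate depth at which a normal sample counts as
#'   carrying a site.
#' @export
setClass("FilterConfig",
    representation(adTMin = "numeric", dpTMin = "numeric", vafTMin = "numeric",
                   adNMax = "numeric", dpNMin = "numeric", popAFMax = "numeric",
                   poolAdGt = "numeric", ponMinSamples = "numeric",
                   ponMinAd = "numeric"),
    prototype(adTMin = 8, dpTMin = 12, vafTMin = 0.2, adNMax = 0, dpNMin = 10,
              popAFMax = 1e-5, poolAdGt = 1, ponMinSamples = 2, ponMinAd = 1))

setValidity("FilterConfig", function(object) {
    vals <- c(object@adTMin, object@dpTMin, object@vafTMin, object@adNMax,
              object@dpNMin, object@popAFMax, object@poolAdGt,
              object@ponMinSamples, object@ponMinAd)
    if (any(!is.finite(vals)) || any(vals < 0))
        return("all thresholds must be finite and >= 0")
    if (object@vafTMin > 1) return("vafTMin must lie in [0,1]")
    if (object@popAFMax > 1) return("popAFMax must lie in [0,1]")
    TRUE
})

#' Panel-of-normals site list
#'
#' A set of SNV keys ("chrom:pos:ref:alt") flagged as recurrent technical
#' artefacts from normal-sample sequencing; membership removes a variant.
#'
#' @slot keys character vector of unique variant keys.
#' @slot label provenance string (e.g. "1000g", "self", or a merge of both).
#' @export
setClass("PonSites",
    representation(keys = "character", label = "character"),
    prototype(keys = character(0), label = "pon"))

setValidity("PonSites", function(object) {
    if (anyDuplicated(object@keys)) "PON keys must be unique (set semantics)"
    else TRUE
})

#' Control-plasma noise model
#'
#' Summarises the background signal of a patient's tumor variants in
#' tumor-free control plasmas. For the VAF and AD metrics each control
#' contributes its mean metric across the kept variants; for the binary
#' metric each control contributes its count of variants detected at or
#' above a detection AD threshold. \code{muNoise} and \code{sigmaNoise} are
#' the mean and sample (n-1) standard deviation of those per-control values.
#'
#' @slot metric one of "VAF", "AD", "binary".
#' @slot perControl numeric vector of one summary value per control sample
#'   (or per variant-control pair when \code{pooled = TRUE}).
#' @slot muNoise mean of \code{perControl}.
#' @slot sigmaNoise sample standard deviation of \code{perControl}.
#' @slot nControls number of control samples.
#' @slot pooled logical; TRUE when mu/sigma were taken over all
#'   (variant, control) pairs instead of per-control means.
#' @export
setClass("NoiseModel",
    representation(metric = "character", perControl = "numeric",
                   muNoise = "numeric", sigmaNoise = "numeric",
                   nControls = "integer", pooled = "logical"),
    prototype(metric = "VAF", perControl = numeric(0), muNoise = NA_real_,
              sigmaNoise = NA_real_, nControls = 0L, pooled = FALSE))

setValidity("NoiseModel", function(object) {
    msg <- NULL
    if (!object@metric %in% c("VAF", "AD", "binary"))
        msg <- c(msg, "metric must be one of VAF, AD, binary")
    if (!is.na(object@muNoise) && object@muNoise < 0)
        msg <- c(msg, "muNoise must be >= 0")
    if (!is.na(object@sigmaNoise) && object@sigmaNoise < 0)
        msg <- c(msg, "sigmaNoise must be >= 0")
    if (is.null(msg)) TRUE else msg
})

#' ctDNA signal statistics for one patient and metric
#'
#' @slot metric one of "VAF", "AD", "binary".
#' @slot nVariantsUsed number of kept variants entering the statistic.
#' @slot aveVarDet average plasma metric over kept variants (for the binary
#'   metric, the count of detected variants).
#' @slot s2n signal-to-noise ratio aveVarDet / muNoise.
#' @slot z standardized score (aveVarDet - muNoise) / sigmaNoise.
#' @export
setClass("SignalResult",
    representation(metric = "character", nVariantsUsed = "integer",
                   aveVarDet = "numeric", s2n = "numeric", z = "numeric"))

setValidity("SignalResult", function(object) {
    msg <- NULL
    if (object@nVariantsUsed < 1L)
        msg <- c(msg, "nVariantsUsed must be >= 1 for a defined result")
    if (!is.na(object@s2n) && object@s2n < 0)
        msg <- c(msg, "s2n must be >= 0")
    if (is.null(msg)) TRUE else msg
})

#' Synthetic cohort generator configuration
#'
#' Parameters of the forced-call count simulator. Defaults mirror the
#' sequencing design the method targets: mean coverage 24x tumor, 17x
#' normal, 52x patient plasma and 49x control plasma, with 9 control and 9
#' pool plasmas. Tumor-tissue VAFs are drawn uniformly on
#' [\code{tumorVafMin}, \code{tumorVafMax}] (high tumor cell fraction);
#' plasma alternate reads arise at probability \code{tumorFraction} x
#' tumor VAF plus a background that is \code{errorRate/3} at clean sites
#' (substitution errors split evenly over the three non-reference bases)
#' and \code{artefactVaf} at recurrent artefact sites shared by every
#' plasma-derived sample — the signature the plasma-pool filter exploits.
#'
#' @slot nVariants tumor SNVs per patient.
#' @slot tumorDepth,normalDepth,plasmaDepth,controlDepth mean read depth per
#'   role (pool samples use \code{controlDepth}).
#' @slot nControls,nPool number of control and pool plasma samples.
#' @slot tumorFraction ctDNA fraction of plasma cfDNA, in [0,1].
#' @slot tumorVafMin,tumorVafMax range of per-variant tumor-tissue VAF.
#' @slot errorRate per-base substitution error rate.
#' @slot artefactFraction fraction of sites given a shared elevated error.
#' @slot artefactVaf alternate-read probability at artefact sites.
#' @slot germlineLeakFraction fraction of variants planted with germline
#'   signal in the matched normal.
#' @slot germlineLeakVaf expected VAF of leaked germline sites in the normal.
#' @slot depthDispersion negative-binomial size for per-site depth;
#'   \code{Inf} gives Poisson depths.
#' @export
setClass("SimConfig",
    representation(nVariants = "integer", tumorDepth = "numeric",
                   normalDepth = "numeric", plasmaDepth = "numeric",
                   controlDepth = "numeric", nControls = "integer",
                   nPool = "integer", tumorFraction = "numeric",
                   tumorVafMin = "numeric", tumorVafMax = "numeric",
                   errorRate = "numeric", artefactFraction = "numeric",
                   artefactVaf = "numeric", germlineLeakFraction = "numeric",
                   germlineLeakVaf = "numeric", depthDispersion = "numeric"),
    prototype(nVariants = 2000L, tumorDepth = 24, normalDepth = 17,
              plasmaDepth = 52, controlDepth = 49, nControls = 9L,
              nPool = 9L, tumorFraction = 0.005, tumorVafMin = 0.2,
              tumorVafMax = 0.8, errorRate = 1e-3, artefactFraction = 0.02,
              artefactVaf = 0.02, germlineLeakFraction = 0.01,
              germlineLeakVaf = 0.5, depthDispersion = Inf))

setValidity("SimConfig", function(object) {
    msg <- NULL
    fr <- c(object@tumorFraction, object@tumorVafMin, object@tumorVafMax,
            object@errorRate, object@artefactFraction, object@artefactVaf,
            object@germlineLeakFraction, object@germlineLeakVaf)
    if (any(fr < 0) || any(fr > 1))
        msg <- c(msg, "all rate/fraction parameters must lie in [0,1]")
    if (object@tumorVafMin > object@tumorVafMax)
        msg <- c(msg, "tumorVafMin must not exceed tumorVafMax")
    dep <- c(object@tumorDepth, object@normalDepth, object@plasmaDepth,
             object@controlDepth)
    if (any(dep <= 0)) msg <- c(msg, "depths must be > 0")
    if (object@nVariants < 1L) msg <- c(msg, "nVariants must be >= 1")
    if (object@nControls < 2L)
        msg <- c(msg, "nControls must be >= 2 (noise model needs a spread)")
    if (object@nPool < 0L) msg <- c(msg, "nPool must be >= 0")
    if (object@depthDispersion <= 0)
        msg <- c(msg, "depthDispersion must be > 0 (Inf for Poisson)")
    if (is.null(msg)) TRUE else msg
})
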