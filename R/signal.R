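#' Average variant signal in patient plasma
#'
#' The arithmetic mean of the plasma VAF (or plasma AD) over the kept
#' variants. With \code{detectedOnly = TRUE} the average runs only over
#' variants detected in plasma (AD >= \code{detectionAdMin}); the default
#' averages all kept variants, which keeps the statistic comparable with a
#' noise model averaged over the same variant set.
#'
#' @param kept a filtered \linkS4class{PatientTable} with >= 1 record.
#' @param metric "VAF" or "AD".
#' @param detectedOnly average only plasma-detected variants.
#' @param detectionAdMin plasma AD at which a variant counts as detected.
#' @return the mean plasma metric (a single number).
#' @export
aveVarDet <- function(kept, metric = c("VAF", "AD"), detectedOnly = FALSE,
                      detectionAdMin = 1L) {
    metric <- match.arg(metric)
    if (nrow(kept) < 1L)
        stop("undefined signal: no variants left after filtering")
    v <- roleObs(kept, "plasma", metric)
    if (detectedOnly) {
        det <- roleObs(kept, "plasma", "AD") >= detectionAdMin
        if (!any(det))
            stop("undefined signal: no variant detected in plasma")
        v <- v[det]
    }
    mean(v)
}

#' Build the control-plasma noise model
#'
#' The noise model is the background of the patient's tumor variants in
#' tumor-free control plasmas. For VAF/AD, each control plasma contributes
#' the mean metric over the kept variants; for the binary metric, each
#' control contributes its count of variants with AD >=
#' \code{detectionAdMin}. \code{muNoise}/\code{sigmaNoise} are the mean and
#' sample (n-1) standard deviation over those per-control values — the
#' per-sample average is the natural null replicate of the patient-plasma
#' statistic. Setting \code{pooled = TRUE} instead takes mu/sigma over all
#' (variant, control) pairs.
#'
#' @param kept a filtered \linkS4class{PatientTable} with >= 1 record and
#'   >= 2 control samples.
#' @param metric "VAF", "AD" or "binary".
#' @param detectionAdMin detection threshold for the binary metric.
#' @param pooled pool all (variant, control) pairs instead of per-control
#'   means (not available for the binary metric).
#' @return a \linkS4class{NoiseModel}.
#' @export
buildNoiseModel <- function(kept, metric = c("VAF", "AD", "binary"),
                            detectionAdMin = 1L, pooled = FALSE) {
    metric <- match.arg(metric)
    if (nrow(kept) < 1L)
        stop("noise model undefined: no variants left after filtering")
    nCtrl <- length(.roleIdx(kept, "control"))
    if (nCtrl < 2L)
        stop("noise model requires >= 2 control samples")
    if (metric == "binary") {
        if (pooled) stop("pooled noise model is undefined for binary counts")
        ctrlAd <- roleObs(kept, "control", "AD")
        per <- colSums(ctrlAd >= detectionAdMin)
    } else {
        m <- roleObs(kept, "control", metric)
        per <- if (pooled) as.numeric(m) else colMeans(m)
    }
    new("NoiseModel", metric = metric, perControl = unname(per),
        muNoise = mean(per), sigmaNoise = sd(per),
        nControls = as.integer(nCtrl), pooled = pooled)
}

#' Signal-to-noise ratio
#'
#' S2N = AveVarDet / muNoise: the mean plasma signal of the kept tumor
#' variants relative to their mean background in control plasmas.
#'
#' @param ave patient-plasma average (from \code{\link{aveVarDet}}).
#' @param noise a \linkS4class{NoiseModel} on the same metric.
#' @return the ratio; \code{+Inf} with a warning when muNoise = 0.
#' @export
s2n <- function(ave, noise) {
    stopifnot(is(noise, "NoiseModel"))
    if (noise@muNoise == 0) {
        if (ave == 0) return(0)
        warning("muNoise = 0: S2N reported as +Inf")
        return(Inf)
    }
    ave / noise@muNoise
}

#' z-score of the plasma signal
#'
#' z = (AveVarDet - muNoise) / sigmaNoise, standardising the plasma signal
#' against the spread of the noise model across control plasmas.
#'
#' @param ave patient-plasma average.
#' @param noise a \linkS4class{NoiseModel} on the same metric.
#' @return the z-score. sigmaNoise = 0 is an error (a degenerate noise
#'   model cannot standardise anything; failing loudly beats an infinite z).
#' @export
zScore <- function(ave, noise) {
    stopifnot(is(noise, "NoiseModel"))
    if (is.na(noise@sigmaNoise) || noise@sigmaNoise == 0)
        stop("degenerate noise model: sigmaNoise = 0, z-score undefined")
    (ave - noise@muNoise) / noise@sigmaNoise
}

#' Binary z-score
#'
#' Ignores VAF/AD magnitudes: the statistic is the COUNT of kept variants
#' detected in patient plasma (AD >= \code{detectionAdMin}); the noise model
#' is the same count per control plasma; z follows the usual
#' standardisation.
#'
#' @param kept a filtered \linkS4class{PatientTable}.
#' @param detectionAdMin plasma AD at which a variant counts as detected.
#' @return a \linkS4class{SignalResult} with metric "binary"
#'   (\code{aveVarDet} holds the patient detected count).
#' @export
binaryZScore <- function(kept, detectionAdMin = 1L) {
    noise <- buildNoiseModel(kept, "binary", detectionAdMin = detectionAdMin)
    count <- sum(roleObs(kept, "plasma", "AD") >= detectionAdMin)
    new("SignalResult", metric = "binary",
        nVariantsUsed = nrow(kept),
        aveVarDet = as.numeric(count),
        s2n = s2n(count, noise),
        z = zScore(count, noise))
}

#' One-sided significance decision for a z-score
#'
#' Compares z to the upper one-sided alpha quantile of a Student t
#' distribution. The shipped default df = 7 reproduces the operating
#' critical value 1.895 at alpha = 0.05.
#'
#' @param z the z-score.
#' @param alpha one-sided significance level in (0,1).
#' @param df degrees of freedom (>= 1).
#' @return list with \code{critical} (the t quantile) and
#'   \code{significant} (TRUE iff z > critical).
#' @examples
#' significance(2.1)              # critical ~ 1.895, significant
#' significance(2.1, alpha = 0.01)
#' @export
significance <- function(z, alpha = 0.05, df = 7) {
    if (!is.finite(alpha) || alpha <= 0 || alpha >= 1)
        stop("alpha must lie in (0,1)")
    if (!is.finite(df) || df < 1) stop("df must be >= 1")
    critical <- qt(1 - alpha, df = df)
    list(critical = critical, significant = z > critical)
}

.configSignature <- function(cfg) {
    s <- vapply(slotNames(cfg), function(n) paste0(n, "=", slot(cfg, n)), "")
    paste(s, collapse = ";")
}

#' Full per-patient signal evaluation
#'
#' Runs a filtering method on the table, then computes the VAF, AD and
#' binary statistics against the control-plasma noise model, plus the
#' one-sided significance decision on the VAF z-score. The returned bundle
#' is a plain (JSON-serialisable) list.
#'
#' @param table a \linkS4class{PatientTable}.
#' @param method 1, 2 or 3 (see \code{\link{applyMethod}}).
#' @param cfg a \linkS4class{FilterConfig}.
#' @param pon1000g,ponSelf \linkS4class{PonSites} used by the method.
#' @param alpha,df significance parameters (see \code{\link{significance}}).
#' @param detectionAdMin binary detection threshold.
#' @param detectedOnly average only plasma-detected variants in aveVarDet.
#' @param pooledNoise use the pooled (variant, control)-pair noise model.
#' @param includeVerdicts attach the per-variant verdict data.frame.
#' @return named list: patient_id, method, n_variants_used, metrics
#'   (VAF/AD: mu, sigma, ave, s2n, z; binary: count, mu, sigma, z),
#'   critical, significant (on the VAF z), config signature, and optionally
#'   verdicts.
#' @export
evaluatePatient <- function(table, method, cfg = filterConfig(),
                            pon1000g = emptyPon("1000g"),
                            ponSelf = emptyPon("self"),
                            alpha = 0.05, df = 7, detectionAdMin = 1L,
                            detectedOnly = FALSE, pooledNoise = FALSE,
                            includeVerdicts = FALSE) {
    res <- applyMethod(table, method, cfg, pon1000g, ponSelf)
    kept <- res$kept
    if (nrow(kept) < 1L)
        stop("undefined signal: no variants survive method ", method)
    metrics <- list()
    for (m in c("VAF", "AD")) {
        noise <- buildNoiseModel(kept, m, pooled = pooledNoise)
        ave <- aveVarDet(kept, m, detectedOnly = detectedOnly,
                         detectionAdMin = detectionAdMin)
        metrics[[m]] <- list(mu = noise@muNoise, sigma = noise@sigmaNoise,
                             ave = ave, s2n = s2n(ave, noise),
                             z = zScore(ave, noise))
    }
    bin <- binaryZScore(kept, detectionAdMin = detectionAdMin)
    binNoise <- buildNoiseModel(kept, "binary",
                                detectionAdMin = detectionAdMin)
    metrics$binary <- list(count = bin@aveVarDet, mu = binNoise@muNoise,
                           sigma = binNoise@sigmaNoise, z = bin@z)
    sig <- significance(metrics$VAF$z, alpha = alpha, df = df)
    out <- list(patient_id = patientId(table), method = method,
                n_variants_used = nrow(kept), metrics = metrics,
                critical = sig$critical, significant = sig$significant,
                alpha = alpha, df = df,
                config = .configSignature(cfg))
    if (includeVerdicts) out$verdicts <- res$verdicts
    out
}
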