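.withSeed <- function(seed, expr) {
    hadSeed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (hadSeed) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (hadSeed) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    expr
}

.subSeed <- function(seed, k) {
    # deterministic substream seed, kept inside 32-bit integer range
    as.integer((as.numeric(seed) * 48271 + as.numeric(k) * 16807) %%
               2147483647)
}

#' Binomially thin a count observation
#'
#' Emulates random read downsampling at the per-site count level: each
#' alternate read is kept independently with probability \code{fraction}
#' (kept alternate count ~ Binomial(ad, fraction)), each reference read
#' likewise; the new depth is the sum of kept reads and VAF is recomputed
#' from the thinned counts. This matches the marginal per-site behaviour of
#' read-level downsampling for SNV counts.
#'
#' @param ad,dp integer vectors of alternate and total depths (ad <= dp).
#' @param fraction keep probability in [0,1].
#' @return list with thinned \code{ad}, \code{dp} and recomputed \code{vaf}.
#' @examples
#' set.seed(1)
#' thinObservation(ad = 8, dp = 48, fraction = 0.4)
#' @export
thinObservation <- function(ad, dp, fraction) {
    if (!is.numeric(fraction) || length(fraction) != 1L ||
        is.na(fraction) || fraction < 0 || fraction > 1)
        stop("fraction must be a single probability in [0,1]")
    stopifnot(all(ad >= 0), all(ad <= dp))
    n <- length(ad)
    keptAlt <- rbinom(n, ad, fraction)
    keptRef <- rbinom(n, dp - ad, fraction)
    newDp <- keptAlt + keptRef
    list(ad = keptAlt, dp = newDp, vaf = vafFromCounts(keptAlt, newDp))
}

#' Downsample plasma observations of a PatientTable
#'
#' Thins every observation in the scoped sample roles by independent
#' binomial read-thinning (see \code{\link{thinObservation}}), leaving all
#' other roles untouched. Each scoped sample column draws from its own
#' deterministic substream derived from \code{seed}, so the output is
#' bit-exact reproducible and independent of evaluation order. The global
#' RNG state is left unchanged.
#'
#' @param table a \linkS4class{PatientTable}.
#' @param fraction keep probability in [0,1] (the operating point of
#'   interest is 0.4, taking ~52x plasma to ~21x).
#' @param seed integer seed.
#' @param scope character vector of roles to thin (default: patient plasma
#'   only; controls in the study design are used at their native depth).
#' @return the thinned \linkS4class{PatientTable}.
#' @export
downsamplePlasma <- function(table, fraction, seed, scope = "plasma") {
    stopifnot(is(table, "PatientTable"), all(scope %in% .ROLES))
    dp <- dpMatrix(table); ad <- adMatrix(table)
    cols <- which(as.character(colData(table)$role) %in% scope)
    for (j in cols) {
        thin <- .withSeed(.subSeed(seed, j), {
            thinObservation(ad[, j], dp[, j], fraction)
        })
        ad[, j] <- thin$ad
        dp[, j] <- thin$dp
    }
    out <- table
    SummarizedExperiment::assay(out, "DP") <- dp
    SummarizedExperiment::assay(out, "AD") <- ad
    validObject(out)
    out
}
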