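.simDepth <- function(n, meanDepth, dispersion) {
    if (is.finite(dispersion))
        rnbinom(n, size = dispersion, mu = meanDepth)
    else
        rpois(n, meanDepth)
}

.randomSites <- function(n, artefactFraction) {
    pos <- sample.int(240000000L, n)
    ref <- sample(.BASES, n, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(.BASES, r), 1L), "")
    data.frame(chrom = "chr1", pos = pos, ref = ref, alt = unname(alt),
               isArtefact = runif(n) < artefactFraction)
}

.simObs <- function(n, meanDepth, altProb, dispersion) {
    dp <- .simDepth(n, meanDepth, dispersion)
    ad <- rbinom(n, dp, pmin(altProb, 1))
    list(dp = dp, ad = ad)
}

#' Simulate one patient's forced-call table
#'
#' Generates a \linkS4class{PatientTable} under the model the detection
#' method assumes. Per variant site: the tumor-tissue VAF v_t is uniform on
#' [\code{tumorVafMin}, \code{tumorVafMax}]; tumor reads are
#' Binomial(DP, v_t) at Poisson (or negative-binomial) depth; the matched
#' normal sees only sequencing error except at germline-leak sites, where it
#' sees reads at \code{germlineLeakVaf}; patient plasma draws alternate
#' reads at probability \code{tumorFraction * v_t + background}; every
#' control and pool plasma draws at \code{background} alone. The background
#' is \code{errorRate/3} at clean sites and \code{artefactVaf} at artefact
#' sites — artefact sites are SHARED by all plasma-derived samples (patient
#' plasma, controls, pool), which is exactly the signature the plasma-pool
#' filter exploits.
#'
#' @param cfg a \linkS4class{SimConfig}.
#' @param seed integer seed (the global RNG state is left untouched).
#' @param patientId identifier for the generated table.
#' @param sites optional data.frame (chrom, pos, ref, alt, isArtefact) of
#'   pre-assigned variant sites, used by \code{\link{simulateCohort}} to
#'   share one artefact-site universe across patients.
#' @return list with \code{table} (the \linkS4class{PatientTable}) and
#'   \code{truth} (per-variant data.frame: key, isArtefact, isGermlineLeak,
#'   vT; plus attribute-free columns \code{tumorFraction} repeated).
#' @export
simulatePatient <- function(cfg = simConfig(), seed = 1L, patientId = "P1",
                            sites = NULL) {
    stopifnot(is(cfg, "SimConfig"))
    validObject(cfg)
    .withSeed(seed, {
        n <- cfg@nVariants
        if (is.null(sites)) sites <- .randomSites(n, cfg@artefactFraction)
        stopifnot(nrow(sites) == n)
        vT <- runif(n, cfg@tumorVafMin, cfg@tumorVafMax)
        isLeak <- runif(n) < cfg@germlineLeakFraction
        background <- ifelse(sites$isArtefact, cfg@artefactVaf,
                             cfg@errorRate / 3)

        tum <- .simObs(n, cfg@tumorDepth, vT, cfg@depthDispersion)
        normProb <- ifelse(isLeak, cfg@germlineLeakVaf, cfg@errorRate / 3)
        nor <- .simObs(n, cfg@normalDepth, normProb, cfg@depthDispersion)
        pla <- .simObs(n, cfg@plasmaDepth,
                       cfg@tumorFraction * vT + background,
                       cfg@depthDispersion)

        nCol <- 3L + cfg@nControls + cfg@nPool
        dp <- matrix(0L, n, nCol)
        ad <- matrix(0L, n, nCol)
        dp[, 1L] <- tum$dp; ad[, 1L] <- tum$ad
        dp[, 2L] <- nor$dp; ad[, 2L] <- nor$ad
        dp[, 3L] <- pla$dp; ad[, 3L] <- pla$ad
        for (j in seq_len(cfg@nControls + cfg@nPool)) {
            o <- .simObs(n, cfg@controlDepth, background, cfg@depthDispersion)
            dp[, 3L + j] <- o$dp
            ad[, 3L + j] <- o$ad
        }
        role <- c("tumor", "normal", "plasma",
                  rep("control", cfg@nControls), rep("pool", cfg@nPool))
        tab <- PatientTable(patientId, sites$chrom, sites$pos, sites$ref,
                            sites$alt, DP = dp, AD = ad, role = role)
        truth <- data.frame(
            key = variantKeys(tab),
            isArtefact = sites$isArtefact,
            isGermlineLeak = isLeak,
            vT = vT,
            tumorFraction = cfg@tumorFraction)
        list(table = tab, truth = truth)
    })
}

#' Simulate a cohort of patients
#'
#' Generates \code{nPatients} forced-call tables under one
#' \linkS4class{SimConfig}. All patients share a single cohort-level site
#' universe whose artefact flags are drawn once, and the same control/pool
#' manifest, mirroring a study where every plasma is sequenced and
#' force-called identically. Per-patient substreams are derived
#' deterministically from the master seed, so a cohort is reproducible
#' file-for-file.
#'
#' @param cfg a \linkS4class{SimConfig}.
#' @param nPatients number of patients.
#' @param seed master integer seed.
#' @param outDir optional directory; when given, writes one TSV table per
#'   patient (\code{\link{writePatientTable}} dialect), a
#'   \code{manifest.yaml} of sample roles and a \code{truth.json}.
#' @return list with \code{patients} (list of \code{list(table, truth)}),
#'   \code{cfg} and \code{seed}.
#' @export
simulateCohort <- function(cfg = simConfig(), nPatients = 9L, seed = 1L,
                           outDir = NULL) {
    stopifnot(is(cfg, "SimConfig"), nPatients >= 1L)
    allSites <- .withSeed(.subSeed(seed, 0L), {
        .randomSites(nPatients * cfg@nVariants, cfg@artefactFraction)
    })
    patients <- vector("list", nPatients)
    ids <- sprintf("P%d", seq_len(nPatients))
    for (i in seq_len(nPatients)) {
        rows <- ((i - 1L) * cfg@nVariants + 1L):(i * cfg@nVariants)
        patients[[i]] <- simulatePatient(cfg, seed = .subSeed(seed, i),
                                         patientId = ids[i],
                                         sites = allSites[rows, , drop = FALSE])
    }
    names(patients) <- ids
    if (!is.null(outDir)) {
        dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
        for (i in seq_len(nPatients))
            writePatientTable(patients[[i]]$table,
                              file.path(outDir, paste0(ids[i], ".tsv")))
        roles <- sampleRoles(patients[[1L]]$table)
        yaml::write_yaml(as.list(roles), file.path(outDir, "manifest.yaml"))
        truth <- lapply(patients, `[[`, "truth")
        jsonlite::write_json(truth, file.path(outDir, "truth.json"),
                             dataframe = "columns", digits = NA)
    }
    list(patients = patients, cfg = cfg, seed = seed)
}

#' Recovery report against simulation ground truth
#'
#' Summarises how well the pipeline recovers a simulated cohort: per-patient
#' VAF z and S2N under methods 2 and 3 with the one-sided detection flag,
#' the plasma-pool filter's precision and recall against the true artefact
#' sites, and the empirical type-I error across null (tumorFraction = 0)
#' patients.
#'
#' @param cohort output of \code{\link{simulateCohort}}.
#' @param results named list (one entry per patient id) of lists with
#'   elements \code{method2} and \code{method3}, each an
#'   \code{\link{evaluatePatient}} bundle for that method.
#' @param alpha,df significance parameters for the detection flag.
#' @param poolAdGt pool-filter bound used for the precision/recall audit.
#' @return list with \code{perPatient} (data.frame), \code{poolPrecision},
#'   \code{poolRecall}, \code{typeIError} (NA if no null patients) and
#'   \code{critical}.
#' @export
recoveryReport <- function(cohort, results, alpha = 0.05, df = 7,
                           poolAdGt = 1) {
    ids <- names(cohort$patients)
    if (!all(ids %in% names(results)))
        stop("results missing for patient(s): ",
             paste(setdiff(ids, names(results)), collapse = ", "))
    critical <- significance(0, alpha = alpha, df = df)$critical
    rows <- lapply(ids, function(id) {
        r2 <- results[[id]]$method2
        r3 <- results[[id]]$method3
        data.frame(patient = id,
                   tumorFraction = cohort$patients[[id]]$truth$tumorFraction[1L],
                   z2 = r2$metrics$VAF$z, z3 = r3$metrics$VAF$z,
                   s2n2 = r2$metrics$VAF$s2n, s2n3 = r3$metrics$VAF$s2n,
                   detected2 = r2$metrics$VAF$z > critical,
                   detected3 = r3$metrics$VAF$z > critical)
    })
    perPatient <- do.call(rbind, rows)
    removed <- truth <- logical(0)
    for (id in ids) {
        tab <- cohort$patients[[id]]$table
        removed <- c(removed, unname(.failsPool(tab, poolAdGt)))
        truth <- c(truth, cohort$patients[[id]]$truth$isArtefact)
    }
    poolPrecision <- if (any(removed)) mean(truth[removed]) else NA_real_
    poolRecall <- if (any(truth)) mean(removed[truth]) else NA_real_
    nullIdx <- perPatient$tumorFraction == 0
    typeIError <- if (any(nullIdx)) mean(perPatient$detected3[nullIdx])
                  else NA_real_
    list(perPatient = perPatient, poolPrecision = poolPrecision,
         poolRecall = poolRecall, typeIError = typeIError,
         critical = critical)
}
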