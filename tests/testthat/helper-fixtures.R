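# In-code fixtures and independent oracles shared across test files.

# A small hand-built table: 4 variants, 3 controls, 2 pool samples.
makeToyTable <- function() {
    PatientTable(
        patientId = "toy",
        chrom = "chr1",
        pos = c(100L, 200L, 300L, 400L),
        ref = c("A", "C", "G", "T"),
        alt = c("T", "G", "A", "C"),
        #      tumor normal plasma c1 c2 c3 p1 p2
        DP = rbind(c(48L, 10L, 52L, 49L, 50L, 48L, 50L, 50L),
                   c(12L, 10L, 41L, 50L, 51L, 49L, 50L, 50L),
                   c(30L, 12L, 45L, 48L, 47L, 50L, 50L, 50L),
                   c(25L, 11L, 40L, 50L, 49L, 47L, 50L, 50L)),
        AD = rbind(c(8L, 0L, 2L, 0L, 1L, 0L, 0L, 1L),
                   c(8L, 0L, 1L, 0L, 0L, 1L, 2L, 0L),
                   c(15L, 0L, 0L, 1L, 0L, 0L, 0L, 0L),
                   c(10L, 0L, 3L, 0L, 0L, 0L, 1L, 1L)),
        role = c("tumor", "normal", "plasma", rep("control", 3L),
                 rep("pool", 2L)),
        popAF = c(NA, 2e-5, 1e-5, NA))
}

# Random valid table with configurable size; counts cover threshold
# boundaries on both sides.
randomTable <- function(seed, nVar = NULL, nCtrl = NULL, nPool = NULL) {
    set.seed(seed)
    if (is.null(nVar)) nVar <- sample(1:200, 1L)
    if (is.null(nCtrl)) nCtrl <- sample(2:9, 1L)
    if (is.null(nPool)) nPool <- sample(0:9, 1L)
    nSamp <- 3L + nCtrl + nPool
    dp <- matrix(rpois(nVar * nSamp, lambda = 20) , nVar, nSamp)
    ad <- matrix(rbinom(nVar * nSamp, dp, 0.25), nVar, nSamp)
    ref <- sample(c("A", "C", "G", "T"), nVar, replace = TRUE)
    alt <- vapply(ref, function(r)
        sample(setdiff(c("A", "C", "G", "T"), r), 1L), "")
    popAF <- ifelse(runif(nVar) < 0.3, runif(nVar, 0, 5e-5), NA_real_)
    PatientTable("rnd", "chr1", pos = sample.int(1e6, nVar), ref = ref,
                 alt = unname(alt), DP = dp, AD = ad,
                 role = c("tumor", "normal", "plasma",
                          rep("control", nCtrl), rep("pool", nPool)),
                 popAF = popAF)
}

# Brute-force verdict oracle: direct per-variant boolean expressions,
# no shared code with the implementation's matrix path.
oracleVerdicts <- function(table, method, cfg, pon1000g, ponSelf) {
    dp <- dpMatrix(table); ad <- adMatrix(table)
    roles <- unname(sampleRoles(table))
    iT <- which(roles == "tumor"); iN <- which(roles == "normal")
    iPool <- which(roles == "pool")
    keys <- variantKeys(table)
    pon <- if (method == 1) ponKeys(pon1000g) else
        union(ponKeys(pon1000g), ponKeys(ponSelf))
    pa <- popAF(table)
    out <- NULL
    for (i in seq_len(nrow(table))) {
        tdp <- dp[i, iT]; tad <- ad[i, iT]
        tvaf <- if (tdp > 0) tad / tdp else 0
        row <- c(ADt = tad < cfg@adTMin,
                 DPt = tdp < cfg@dpTMin,
                 VAFt = tvaf < cfg@vafTMin,
                 ADn = ad[i, iN] > cfg@adNMax,
                 DPn = dp[i, iN] < cfg@dpNMin,
                 gnomAD = !is.na(pa[i]) && pa[i] > cfg@popAFMax,
                 PON = keys[i] %in% pon)
        if (method == 3) {
            hit <- FALSE
            for (j in iPool) if (ad[i, j] > cfg@poolAdGt) hit <- TRUE
            row <- c(row, pool = hit)
        }
        out <- rbind(out, row)
    }
    rownames(out) <- NULL
    out
}

# Loop-based oracle for the noise model and the two signal formulas:
# per-control means, sample sd, ratio and standardisation written as
# explicit scalar loops.
oracleSignal <- function(table, metric) {
    dp <- dpMatrix(table); ad <- adMatrix(table)
    roles <- unname(sampleRoles(table))
    iP <- which(roles == "plasma"); iC <- which(roles == "control")
    val <- function(i, j) {
        if (metric == "AD") ad[i, j]
        else if (dp[i, j] > 0) ad[i, j] / dp[i, j] else 0
    }
    n <- nrow(table)
    ave <- 0
    for (i in seq_len(n)) ave <- ave + val(i, iP)
    ave <- ave / n
    per <- numeric(length(iC))
    for (k in seq_along(iC)) {
        s <- 0
        for (i in seq_len(n)) s <- s + val(i, iC[k])
        per[k] <- s / n
    }
    mu <- 0
    for (k in seq_along(per)) mu <- mu + per[k]
    mu <- mu / length(per)
    ss <- 0
    for (k in seq_along(per)) ss <- ss + (per[k] - mu)^2
    sigma <- sqrt(ss / (length(per) - 1))
    list(ave = ave, mu = mu, sigma = sigma,
         s2n = if (mu > 0) ave / mu else if (ave == 0) 0 else Inf,
         z = if (sigma > 0) (ave - mu) / sigma else NA_real_)
}

# Random verdict table over the full label set.
randomVerdicts <- function(seed, nVar = NULL) {
    set.seed(seed)
    if (is.null(nVar)) nVar <- sample(1:500, 1L)
    labs <- c("ADt", "DPt", "VAFt", "ADn", "DPn", "gnomAD", "PON", "pool")
    m <- matrix(runif(nVar * length(labs)) < 0.15, nVar, length(labs),
                dimnames = list(NULL, labs))
    data.frame(key = sprintf("chr1:%d:A:T", seq_len(nVar)),
               as.data.frame(m))
}

# Frozen-set oracle for exclusive intersection counts.
oracleExclusive <- function(membership) {
    labs <- colnames(membership)
    sets <- apply(membership, 1L, function(r) paste(labs[r], collapse = "&"))
    as.list(table(sets))
}

writeToyVcf <- function(path) {
    writeLines(c(
        "##fileformat=VCFv4.2",
        '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
        '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">',
        '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
        '##INFO=<ID=POP_AF,Number=1,Type=Float,Description="Population AF">',
        "##contig=<ID=chr1,length=248956422>",
        paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
              "FORMAT", "TUM", "NORM", "PLAS", "C1", "C2", sep = "\t"),
        paste("chr1", 100, ".", "A", "T", ".", "PASS", "POP_AF=0.00002",
              "GT:AD:DP", "0/1:40,8:48", "0/0:10,0:10", "0/1:50,2:52",
              "0/0:49,0:49", "0/0:48,1:49", sep = "\t"),
        paste("chr1", 200, ".", "C", "G,T", ".", "PASS", ".",
              "GT:AD:DP", "0/1:20,5,3:28", "0/0:12,0,0:12", "0/1:40,1,0:41",
              "0/0:50,0,0:50", "0/0:50,0,1:51", sep = "\t"),
        paste("chr1", 300, ".", "G", "GA", ".", "PASS", ".",
              "GT:AD:DP", "0/1:20,9:29", "0/0:11,0:11", "0/1:40,1:41",
              "0/0:50,0:50", "0/0:50,0:50", sep = "\t"),
        paste("chr1", 400, ".", "T", "C", ".", "PASS", ".",
              "GT:AD:DP", "./.:.:.", "0/0:12,0:12", "0/1:30,3:33",
              "0/0:40,0:40", "0/0:40,0:40", sep = "\t")), path)
    path
}

toyManifest <- c(TUM = "tumor", NORM = "normal", PLAS = "plasma",
                 C1 = "control", C2 = "control")
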