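cfgDefault <- filterConfig()

test_that("basic filters are inclusive on the keep side at the boundary", {
    tab <- PatientTable("b", "chr1", c(1L, 2L, 3L),
                        ref = c("A", "C", "G"), alt = c("T", "A", "C"),
                        # exactly at threshold / one below / normal ad = 1
                        DP = rbind(c(12L, 10L, 50L, 50L, 50L),
                                   c(12L, 10L, 50L, 50L, 50L),
                                   c(12L, 10L, 50L, 50L, 50L)),
                        AD = rbind(c(8L, 0L, 0L, 0L, 0L),
                                   c(7L, 0L, 0L, 0L, 0L),
                                   c(8L, 1L, 0L, 0L, 0L)),
                        role = c("tumor", "normal", "plasma", "control",
                                 "control"))
    f <- evaluateBasicFilters(tab, cfgDefault)
    # tumor(dp=12, ad=8, vaf=8/12), normal(dp=10, ad=0): all boundaries pass
    expect_false(any(f[1, ]))
    # tumor ad = 7 fails only ADt (vaf 7/12 still >= 0.2)
    expect_identical(which(f[2, ]), c(ADt = 1L))
    # normal ad = 1 fails only ADn
    expect_identical(which(f[3, ]), c(ADn = 4L))
})

test_that("VAFt boundary uses the recomputed tumor VAF", {
    tab <- PatientTable("v", "chr1", c(1L, 2L), ref = c("A", "A"),
                        alt = c("T", "G"),
                        DP = rbind(c(40L, 10L, 50L, 50L, 50L),
                                   c(40L, 10L, 50L, 50L, 50L)),
                        AD = rbind(c(8L, 0L, 0L, 0L, 0L),   # vaf 0.2
                                   c(7L, 0L, 0L, 0L, 0L)),  # vaf 0.175
                        role = c("tumor", "normal", "plasma", "control",
                                 "control"))
    f <- evaluateBasicFilters(tab, cfgDefault)
    expect_false(f[1, "VAFt"])
    expect_true(f[2, "VAFt"])
})

test_that("population AF filter keeps the threshold and missing values", {
    tab <- makeToyTable()  # popAF: NA, 2e-5, 1e-5, NA
    res <- applyPopulationAfFilter(tab, 1e-5)
    expect_identical(res$verdicts$gnomAD, c(FALSE, TRUE, FALSE, FALSE))
    expect_setequal(variantKeys(res$kept),
                    variantKeys(tab)[c(1, 3, 4)])
})

test_that("PON membership rule counts distinct carrying normals", {
    normals <- data.frame(
        sample = c("n1", "n2", "n3", "n1", "n1"),
        chrom = "chr1",
        pos = c(10L, 10L, 20L, 30L, 30L),
        ref = "A", alt = "T",
        ad = c(1L, 1L, 2L, 3L, 5L))
    pon <- buildPon(normals)                      # defaults: ad>=1 in >=2
    expect_setequal(ponKeys(pon), "chr1:10:A:T")  # site 30 seen in 1 sample
    pon1 <- buildPon(normals, ponMinSamples = 1)
    expect_setequal(ponKeys(pon1),
                    c("chr1:10:A:T", "chr1:20:A:T", "chr1:30:A:T"))
    ponHi <- buildPon(normals, ponMinAd = 2)
    expect_length(ponKeys(ponHi), 0L)
})

test_that("PON merge is a set union with no duplicates", {
    a <- buildPon(data.frame(sample = c("x", "y"), chrom = "chr1",
                             pos = 1L, ref = "A", alt = "T", ad = 1L),
                  label = "a")
    b <- buildPon(data.frame(sample = c("x", "y"), chrom = "chr1",
                             pos = c(1L, 1L), ref = "A", alt = "T",
                             ad = 1L), label = "b")
    c2 <- buildPon(data.frame(sample = c("x", "y"), chrom = "chr2",
                              pos = 5L, ref = "C", alt = "G", ad = 1L))
    m <- mergePons(a, c2)
    expect_setequal(ponKeys(m), c("chr1:1:A:T", "chr2:5:C:G"))
    expect_setequal(ponKeys(mergePons(a, b)), "chr1:1:A:T")
    expect_setequal(ponKeys(mergePons(a, emptyPon())), ponKeys(a))
})

test_that("PON filter removes exactly the member keys", {
    tab <- makeToyTable()
    pon <- readPonFromKeys <- new("PonSites",
                                  keys = c("chr1:100:A:T", "chr9:9:A:T"),
                                  label = "x")
    res <- applyPonFilter(tab, pon)
    expect_identical(res$verdicts$PON, c(TRUE, FALSE, FALSE, FALSE))
    res0 <- applyPonFilter(tab, emptyPon())
    expect_identical(nrow(res0$kept), nrow(tab))
})

test_that("plasma pool filter removes at AD strictly above the bound", {
    # pool ADs per variant (2 pool samples): (0,1), (2,0), (0,0), (1,1)
    tab <- makeToyTable()
    res <- applyPlasmaPoolFilter(tab, poolAdGt = 1)
    expect_identical(res$verdicts$pool, c(FALSE, TRUE, FALSE, FALSE))
    # all pool ADs <= 1 are kept even when several samples show one read
    expect_true("chr1:400:T:C" %in% variantKeys(res$kept))
    # idempotence
    twice <- applyPlasmaPoolFilter(res$kept, poolAdGt = 1)
    expect_identical(variantKeys(twice$kept), variantKeys(res$kept))
    # empty pool list: identity
    noPool <- tab[, unname(sampleRoles(tab)) != "pool"]
    resNP <- applyPlasmaPoolFilter(noPool, 1)
    expect_identical(nrow(resNP$kept), nrow(noPool))
})

test_that("method ladder composition: pool only bites in method 3", {
    set.seed(42)
    tab <- makeToyTable()
    pon <- emptyPon("1000g")
    # variant 2 (chr1:200:C:G) fails pool and gnomAD; variant at 100 fails
    # nothing basic; craft a clean table where one variant fails ONLY pool
    clean <- PatientTable("m", "chr1", c(1L, 2L), ref = c("A", "C"),
                          alt = c("T", "G"),
                          DP = rbind(c(20L, 12L, 50L, 50L, 50L, 50L),
                                     c(20L, 12L, 50L, 50L, 50L, 50L)),
                          AD = rbind(c(10L, 0L, 1L, 0L, 0L, 2L),
                                     c(10L, 0L, 1L, 0L, 0L, 0L)),
                          role = c("tumor", "normal", "plasma", "control",
                                   "control", "pool"))
    m1 <- applyMethod(clean, 1)
    m2 <- applyMethod(clean, 2)
    m3 <- applyMethod(clean, 3)
    expect_identical(nrow(m1$kept), 2L)
    expect_identical(nrow(m2$kept), 2L)
    expect_identical(variantKeys(m3$kept), "chr1:2:C:G")
    expect_error(applyMethod(clean, 4), "unknown method")
})

test_that("kept <=> empty failed-set, and verdicts match the brute-force oracle", {
    ponA <- new("PonSites", keys = character(0), label = "1000g")
    for (seed in 101:130) {
        tab <- randomTable(seed, nVar = sample(1:60, 1))
        set.seed(seed + 5000)
        keys <- variantKeys(tab)
        pon1 <- new("PonSites", keys = sample(keys, min(3, length(keys))),
                    label = "1000g")
        ponS <- new("PonSites", keys = sample(keys, min(2, length(keys))),
                    label = "self")
        cfg <- filterConfig(adTMin = sample(0:8, 1), dpTMin = sample(0:15, 1),
                            vafTMin = runif(1, 0, 0.4),
                            adNMax = sample(0:2, 1), dpNMin = sample(0:15, 1))
        for (method in 1:3) {
            res <- applyMethod(tab, method, cfg, pon1, ponS)
            got <- as.matrix(res$verdicts[, -1, drop = FALSE])
            want <- oracleVerdicts(tab, method, cfg, pon1, ponS)
            expect_identical(unname(got), unname(want))
            expect_identical(variantKeys(res$kept),
                             res$verdicts$key[rowSums(got) == 0])
        }
    }
})

test_that("survivors nest: method 3 within method 2 within gnomAD/PON", {
    for (seed in 201:220) {
        tab <- randomTable(seed)
        keys <- variantKeys(tab)
        set.seed(seed)
        pon1 <- new("PonSites", keys = sample(keys, min(5, length(keys))),
                    label = "1000g")
        ponS <- new("PonSites", keys = sample(keys, min(5, length(keys))),
                    label = "self")
        s1 <- variantKeys(applyMethod(tab, 1, pon1000g = pon1,
                                      ponSelf = ponS)$kept)
        s2 <- variantKeys(applyMethod(tab, 2, pon1000g = pon1,
                                      ponSelf = ponS)$kept)
        s3 <- variantKeys(applyMethod(tab, 3, pon1000g = pon1,
                                      ponSelf = ponS)$kept)
        expect_true(all(s3 %in% s2))
        expect_true(all(s2 %in% s1))
    }
})

test_that("pool filter commutes with PON application", {
    for (seed in 301:310) {
        tab <- randomTable(seed)
        set.seed(seed)
        pon <- new("PonSites",
                   keys = sample(variantKeys(tab),
                                 min(5, nrow(tab))), label = "pon")
        poolFirst <- applyPonFilter(applyPlasmaPoolFilter(tab, 1)$kept,
                                    pon)$kept
        ponFirst <- applyPlasmaPoolFilter(applyPonFilter(tab, pon)$kept,
                                          1)$kept
        expect_identical(variantKeys(poolFirst), variantKeys(ponFirst))
        expect_identical(adMatrix(poolFirst), adMatrix(ponFirst))
    }
})

test_that("raising any keep-side threshold never adds a survivor", {
    base <- filterConfig(adTMin = 4, dpTMin = 8, vafTMin = 0.1, adNMax = 1,
                         dpNMin = 5)
    bumps <- list(filterConfig(adTMin = 6, dpTMin = 8, vafTMin = 0.1,
                               adNMax = 1, dpNMin = 5),
                  filterConfig(adTMin = 4, dpTMin = 12, vafTMin = 0.1,
                               adNMax = 1, dpNMin = 5),
                  filterConfig(adTMin = 4, dpTMin = 8, vafTMin = 0.3,
                               adNMax = 1, dpNMin = 5),
                  filterConfig(adTMin = 4, dpTMin = 8, vafTMin = 0.1,
                               adNMax = 0, dpNMin = 5),
                  filterConfig(adTMin = 4, dpTMin = 8, vafTMin = 0.1,
                               adNMax = 1, dpNMin = 9))
    for (seed in 401:410) {
        tab <- randomTable(seed)
        s0 <- variantKeys(applyMethod(tab, 1, base)$kept)
        for (cfg in bumps) {
            s1 <- variantKeys(applyMethod(tab, 1, cfg)$kept)
            expect_true(all(s1 %in% s0))
        }
    }
})

test_that("filterLadder reports non-increasing survivor counts on a monotone ladder", {
    ladder <- list(A = filterConfig(adTMin = 0, dpTMin = 0, vafTMin = 0,
                                    adNMax = 5, dpNMin = 0),
                   B = filterConfig(adTMin = 2, dpTMin = 5, vafTMin = 0.05,
                                    adNMax = 2, dpNMin = 3),
                   C = filterConfig(adTMin = 4, dpTMin = 8, vafTMin = 0.1,
                                    adNMax = 1, dpNMin = 6),
                   D = filterConfig(adTMin = 6, dpTMin = 10, vafTMin = 0.15,
                                    adNMax = 0, dpNMin = 8),
                   E = filterConfig())
    for (seed in 501:505) {
        tab <- randomTable(seed)
        res <- filterLadder(tab, ladder)
        expect_identical(res$counts$rung, names(ladder))
        expect_true(all(diff(res$counts$nKept) <= 0))
        # singleton ladder equals a direct method-1 run
        one <- filterLadder(tab, ladder["E"])
        expect_identical(one$counts$nKept,
                         nrow(applyMethod(tab, 1, ladder$E)$kept))
    }
    expect_error(filterLadder(randomTable(1), list()), "non-empty")
})
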