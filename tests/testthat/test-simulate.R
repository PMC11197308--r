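test_that("config validation guards rates, fractions and separability", {
    expect_error(simConfig(), "seed is mandatory")
    expect_error(simConfig(seed = 1, mu = 0))
    expect_error(simConfig(seed = 1,
                           te_placement = list(p_beyond = 1.2,
                                               p_inside = 0)),
                 "\\[0, 1\\]")
    # effect too small for the fold-change threshold under the noise
    expect_error(simConfig(seed = 1, effect_log2fc = 1.6,
                           noise_sigma = 0.1), "separation")
    # noise alone could cross thresholds
    expect_error(simConfig(seed = 1, noise_sigma = 0.5), "noise")
    expect_error(simConfig(seed = 1, hi_tpm_level = 33), "hi_tpm_level")
    expect_error(simConfig(seed = 1, lo_tpm_base = 7.9), "lo_tpm_base")
})

test_that("age zero yields identical LTR copies", {
    cfg <- simConfig(seed = 2, n_intact_ltr = 20,
                     age_distribution = ageDistUniform(0, 1e-9))
    comp <- simulateTEComplement(cfg)
    s <- as.character(comp$ltr_seqs)
    ids <- comp$truth$te_id
    expect_true(all(s[paste0(ids, "__5ltr")] == s[paste0(ids, "__3ltr")]))
})

test_that("observed mismatch fraction matches the binomial oracle", {
    # one element, T = 1 MY, mu = 4e-9, L = 1e6: p ~ 2 mu T = 0.008
    cfg <- simConfig(seed = 3, n_intact_ltr = 1, ltr_length = 1e6,
                     internal_length = 1000L, chrom_length = 1e7,
                     n_chromosomes = 1L,
                     age_distribution = ageDistUniform(1 - 1e-9, 1))
    comp <- simulateTEComplement(cfg)
    d <- pairwiseDivergence(comp$ltr_seqs[[1]], comp$ltr_seqs[[2]])
    p <- 2 * 4e-9 * 1e6
    tol <- 3 * sqrt(p * (1 - p) / 1e6)
    expect_lt(abs(d$p_distance - p), tol)
})

test_that("divergence is calibrated and monotone in age", {
    # 1000 elements at fixed T = 2 MY: mean raw divergence within 3 SE
    # of 2 mu T minus the same-site collision term (4/3) q^2
    cfg <- simConfig(seed = 4, n_intact_ltr = 1000, ltr_length = 1000,
                     age_distribution = ageDistUniform(2 - 1e-9, 2))
    comp <- simulateTEComplement(cfg)
    d <- dateLTRPairs(comp$ltr_seqs)
    q <- 4e-9 * 2e6
    p_exp <- 2 * q - (4 / 3) * q^2
    se <- sqrt(p_exp * (1 - p_exp) / (1000 * 1000))
    expect_lt(abs(mean(d$p_distance) - p_exp), 3 * se)
    # monotone in T
    meanDiv <- function(t, seed) {
        cfg <- simConfig(seed = seed, n_intact_ltr = 150,
                         age_distribution = ageDistUniform(t - 1e-9, t))
        mean(dateLTRPairs(simulateTEComplement(cfg)$ltr_seqs)$p_distance)
    }
    divs <- vapply(c(1, 3, 6), meanDiv, 1, seed = 12)
    expect_true(all(diff(divs) > 0))
})

test_that("saturated divergence regimes are refused", {
    cfg <- simConfig(seed = 5, n_intact_ltr = 5,
                     age_distribution = ageDistUniform(70, 71))
    expect_error(simulateTEComplement(cfg), "0.25")
})

test_that("solo LTR count is the deterministic configured multiple", {
    cfg <- simConfig(seed = 6, n_intact_ltr = 100,
                     solo_to_intact_ratio = 5.0)
    comp <- simulateTEComplement(cfg)
    expect_equal(comp$solo$n_solo, 500L)
    expect_equal(comp$solo$n_intact, 100L)
    expect_equal(soloIntactRatio(comp$solo$n_solo, comp$solo$n_intact), 5.00)
})

test_that("identical configs give identical output", {
    cfg <- simConfig(seed = 8, n_intact_ltr = 50, n_genes = 32,
                     n_period = 10, n_cultivar = 10, n_null = 20)
    a <- simulateTEComplement(cfg); b <- simulateTEComplement(cfg)
    expect_identical(as.character(a$ltr_seqs), as.character(b$ltr_seqs))
    expect_identical(a$truth, b$truth)
    la <- simulateGeneTELandscape(cfg); lb <- simulateGeneTELandscape(cfg)
    expect_identical(la$truth, lb$truth)
    expect_identical(start(la$tesA), start(lb$tesA))
    ea <- simulateExpressionCourse(cfg); eb <- simulateExpressionCourse(cfg)
    expect_identical(tpmMatrix(ea$matA), tpmMatrix(eb$matA))
})

test_that("landscape truth covers the 16 configurations and its decoys", {
    cfg <- simConfig(seed = 13, n_genes = 48)
    land <- simulateGeneTELandscape(cfg)
    expect_equal(nrow(land$truth), 48L)
    expect_equal(length(unique(land$truth$subtype)), 16L)
    # decoys beyond the radius or inside gene bodies never reach the
    # proximity records
    recA <- assignTEProximity(land$genesA, land$tesA)
    decoyA <- teID(land$tesA)[mcols(land$tesA)$decoy != "none"]
    expect_length(intersect(recA$te_id, decoyA), 0L)
    # placed flank TEs land at their intended distances (< 5000)
    expect_true(all(recA$distance >= 0 & recA$distance < 5000))
    # ages attached for young/old analysis on the same landscape
    expect_true(all(!is.na(teAge(land$tesA))))
    lab <- youngOldSplit(setNames(teAge(land$tesA), teID(land$tesA)))
    expect_equal(length(lab), length(land$tesA))
})

test_that("synteny retention controls the anchor fraction", {
    cfg <- simConfig(seed = 14, n_genes = 200, synteny_retention = 0.5)
    land <- simulateGeneTELandscape(cfg)
    expect_equal(nrow(land$anchors), sum(land$truth$anchored))
    expect_gt(nrow(land$anchors), 60)
    expect_lt(nrow(land$anchors), 140)
})

test_that("gene placements beyond chromosome capacity are refused", {
    cfg <- simConfig(seed = 15, n_genes = 5000, n_chromosomes = 1L,
                     chrom_length = 1e6)
    expect_error(simulateGeneTELandscape(cfg), "capacity")
})

test_that("expression injections sit where the thresholds expect them", {
    cfg <- simConfig(seed = 16, n_period = 15, n_cultivar = 15,
                     n_null = 30, noise_sigma = 0)
    ex <- simulateExpressionCourse(cfg)
    A <- tpmMatrix(ex$matA); B <- tpmMatrix(ex$matB)
    tr <- ex$truth
    # null genes with zero noise: identical constant profiles
    nul <- tr$pattern == "null"
    expect_true(all(A[tr$gene_a[nul], ] == cfg$base_tpm))
    expect_true(all(A[tr$gene_a[nul], ] == B[tr$gene_b[nul], ]))
    # cultivar-specific: above 32 in A, below 8 in B
    cv <- tr$pattern == "cultivar_specific"
    expect_true(all(apply(A[tr$gene_a[cv], , drop = FALSE], 1, max) > 32))
    expect_true(all(apply(B[tr$gene_b[cv], , drop = FALSE], 1, max) < 8))
    # period-specific: some adjacent |log2FC| >= 1.5 in A only
    fc <- function(x) max(abs(diff(log2(x + 1))))
    pd <- tr$pattern == "period_specific"
    expect_true(all(apply(A[tr$gene_a[pd], , drop = FALSE], 1, fc) >= 1.5))
    expect_true(all(apply(B[tr$gene_b[pd], , drop = FALSE], 1, fc) < 1.5))
})

test_that("the pipeline writes a consistent, reloadable input set", {
    cfg <- simConfig(seed = 17, n_intact_ltr = 40, n_genes = 32,
                     n_period = 8, n_cultivar = 8, n_null = 16)
    out <- withr::local_tempdir()
    files <- runSyntheticPipeline(cfg, out)
    expect_true(all(file.exists(files)))
    te <- readTEGFF3(files["te_gff"])
    expect_equal(length(te), 40L)
    seqs <- readLTRFasta(files["fasta"])
    expect_equal(length(seqs), 80L)
    genes <- readGeneGFF3(files["genes_a"])
    expect_equal(length(genes), 32L)
    anchors <- readAnchors(files["anchors"])
    expect_true(all(anchors$gene_a %in% mcols(genes)$gene_id))
    se <- readExpressionTSV(files["tpm_a"])
    expect_equal(ncol(tpmMatrix(se)), cfg$n_timepoints)
})
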