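test_that("pair classification follows the count discrepancy", {
    alpha <- classifyPair("NONE", "NONE", 0, 0)
    expect_equal(alpha$main_type, "III")
    expect_equal(alpha$subtype, "NONE|NONE")
    expect_true(alpha$iii_alpha)

    t1 <- classifyPair("UP", "NONE", 1, 0)
    expect_equal(t1$main_type, "I")
    expect_equal(t1$subtype, "UP|NONE")
    expect_false(t1$iii_alpha)

    # equal states but unequal counts still discriminate
    t2 <- classifyPair("UP", "UP", 1, 3)
    expect_equal(t2$main_type, "II")
    expect_equal(t2$subtype, "UP|UP")

    # equal nonzero counts are Type III but not IIIa
    t3 <- classifyPair("UP", "DOWN", 2, 2)
    expect_equal(t3$main_type, "III")
    expect_false(t3$iii_alpha)

    expect_error(classifyPair("NONE", "UP", 1, 1), "inconsistent")
    expect_error(classifyPair("LEFT", "UP", 1, 1), "NONE/UP/DOWN/BOTH")
})

test_that("classification is total and antisymmetric under cultivar swap", {
    states <- c("NONE", "UP", "DOWN", "BOTH")
    cnt <- function(s) if (s == "NONE") 0L else sample(1:4, 1)
    set.seed(16)
    seen <- character()
    for (sa in states) for (sb in states) for (rep in 1:5) {
        na <- cnt(sa); nb <- cnt(sb)
        cls <- classifyPair(sa, sb, na, nb)
        expect_true(cls$main_type %in% c("I", "II", "III"))
        seen <- union(seen, cls$subtype)
        swp <- classifyPair(sb, sa, nb, na)
        expect_equal(swp$subtype,
                     paste(rev(strsplit(cls$subtype, "|",
                                        fixed = TRUE)[[1]]),
                           collapse = "|"))
        expect_equal(swp$main_type,
                     c(I = "II", II = "I", III = "III")[[cls$main_type]])
        expect_equal(swp$iii_alpha, cls$iii_alpha)
    }
    expect_equal(length(seen), 16L)   # the full 4x4 subtype grid
})

test_that("classifyAllPairs reproduces the simulated ground truth", {
    cfg <- simConfig(seed = 9, n_genes = 160)
    land <- simulateGeneTELandscape(cfg)
    pairs <- land$truth[, c("gene_a", "gene_b")]
    res <- classifyAllPairs(land$genesA, land$genesB,
                            land$tesA, land$tesB, pairs)
    expect_equal(res$pairs$main_type, land$truth$main_type)
    expect_equal(res$pairs$subtype, land$truth$subtype)
    expect_equal(res$pairs$n_a, land$truth$n_a)
    expect_equal(res$pairs$iii_alpha, land$truth$iii_alpha)
    # conservation: type and subtype counts each sum to the input size
    expect_equal(sum(res$summary$by_type), nrow(pairs))
    expect_equal(sum(res$summary$by_subtype), nrow(pairs))
    # Type III count equals the brute n_a == n_b count
    expect_equal(unname(res$summary$by_type["III"]),
                 sum(res$pairs$n_a == res$pairs$n_b))
    expect_equal(res$summary$n_iii_alpha,
                 sum(res$pairs$n_a == 0 & res$pairs$n_b == 0))
})

test_that("classifyAllPairs handles empty input and bad ids", {
    cfg <- simConfig(seed = 10, n_genes = 20)
    land <- simulateGeneTELandscape(cfg)
    none <- data.frame(gene_a = character(), gene_b = character())
    res <- classifyAllPairs(land$genesA, land$genesB,
                            land$tesA, land$tesB, none)
    expect_equal(nrow(res$pairs), 0L)
    expect_equal(sum(res$summary$by_type), 0L)
    expect_error(classifyAllPairs(land$genesA, land$genesB,
        land$tesA, land$tesB,
        data.frame(gene_a = "nope", gene_b = land$truth$gene_b[1])),
        "unresolvable.*nope")
})

test_that("ltr_only restricts the counted TE orders", {
    genes <- makeGenes(100001L, 103000L, "gA")
    tes <- makeTEs(c(96000L, 104001L), c(96500L, 104500L),
                   order = c("LTR", "MITE"),
                   superfamily = c("RLC", "DTT"))
    genesB <- makeGenes(100001L, 103000L, "gB", chrom = "chrB")
    tesB <- makeTEs(1L, 100L, "tb", chrom = "chrB")  # far away
    pairs <- data.frame(gene_a = "gA", gene_b = "gB")
    full <- classifyAllPairs(genes, genesB, tes, tesB, pairs)
    expect_equal(full$pairs$n_a, 2L)
    expect_equal(full$pairs$state_a, "BOTH")
    ltr <- classifyAllPairs(genes, genesB, tes, tesB, pairs,
                            ltr_only = TRUE)
    expect_equal(ltr$pairs$n_a, 1L)
    expect_equal(ltr$pairs$state_a, "UP")
})
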