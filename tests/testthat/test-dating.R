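test_that("pairwise divergence counts mismatches over retained columns", {
    a <- strrep("A", 100)
    expect_equal(pairwiseDivergence(a, a),
                 list(aligned_length = 100L, mismatches = 0L,
                      p_distance = 0))
    b <- paste0(strrep("A", 98), "CC")
    d <- pairwiseDivergence(a, b)
    expect_equal(d$aligned_length, 100L)
    expect_equal(d$mismatches, 2L)
    expect_equal(d$p_distance, 0.02)
    # one gapped column excluded, 2 mismatches elsewhere -> 2/99
    a2 <- paste0("-", strrep("A", 99))
    b2 <- paste0("A", strrep("A", 97), "CC")
    d2 <- pairwiseDivergence(a2, b2)
    expect_equal(d2$aligned_length, 99L)
    expect_equal(d2$p_distance, 2 / 99)
    # N columns are excluded like gaps
    expect_equal(pairwiseDivergence("ANCT", "AGCT")$aligned_length, 3L)
})

test_that("pairwise divergence rejects degenerate input", {
    expect_error(pairwiseDivergence("ACGT", "ACG"), "equal length")
    expect_error(pairwiseDivergence("----", "ACGT"), "no alignment columns")
    expect_error(pairwiseDivergence("ACGX", "ACGT"), "alphabet")
})

test_that("divergence is invariant to swapping the two LTRs", {
    set.seed(7)
    for (i in 1:20) {
        s1 <- paste(sample(c("A", "C", "G", "T", "-", "N"), 80, TRUE,
                           prob = c(.23, .23, .23, .23, .04, .04)),
                    collapse = "")
        s2 <- paste(sample(c("A", "C", "G", "T", "-", "N"), 80, TRUE,
                           prob = c(.23, .23, .23, .23, .04, .04)),
                    collapse = "")
        expect_identical(pairwiseDivergence(s1, s2),
                         pairwiseDivergence(s2, s1))
    }
})

test_that("Jukes-Cantor correction matches the closed form", {
    expect_equal(jcCorrect(0), 0)
    # frozen: -(3/4) * log(1 - 4*0.02/3)
    expect_equal(jcCorrect(0.02), 0.0202715, tolerance = 1e-6)
    expect_error(jcCorrect(0.75), "0.75")
    expect_error(jcCorrect(-0.01), "0.75")
})

test_that("Jukes-Cantor correction is monotone and at least identity", {
    p <- seq(0, 0.74, by = 0.01)
    K <- jcCorrect(p)
    expect_true(all(diff(K) > 0))
    expect_true(all(K >= p))
})

test_that("insertion time is K / (2 mu) in million years", {
    expect_equal(insertionTime(0), 0)
    expect_equal(insertionTime(0.008, mu = 4e-9), 1.0)
    expect_equal(insertionTime(0.02, mu = 4e-9), 2.5)
    expect_error(insertionTime(-0.1), "non-negative")
})

test_that("solo:intact ratio divides and reports to 2 decimals", {
    expect_equal(soloIntactRatio(10, 2), 5.00)
    expect_equal(soloIntactRatio(1132, 100), 11.32)
    expect_equal(soloIntactRatio(0, 5), 0.00)
    expect_error(soloIntactRatio(10, 0), "zero")
})

test_that("dateLTRPairs pairs sequences by name and is swap-invariant", {
    seqs <- c(e1__5ltr = strrep("ACGT", 25),
              e1__3ltr = paste0(strrep("ACGT", 24), "ACGA"),
              e2__5ltr = strrep("A", 100),
              e2__3ltr = strrep("A", 100))
    d <- dateLTRPairs(seqs, mu = 4e-9)
    expect_equal(d$element_id, c("e1", "e2"))
    expect_equal(d$p_distance, c(0.01, 0))
    expect_equal(d$age_my, c(jcCorrect(0.01) / (2 * 4e-9) / 1e6, 0))
    # raw mode skips the correction
    expect_equal(dateLTRPairs(seqs, model = "raw")$K, c(0.01, 0))
    # swapping the 5' and 3' labels changes nothing
    swapped <- seqs
    names(swapped) <- c("e1__3ltr", "e1__5ltr", "e2__3ltr", "e2__5ltr")
    expect_equal(dateLTRPairs(swapped)$age_my, d$age_my)
    expect_warning(dateLTRPairs(seqs[1:3]), "unpaired")
})

test_that("simulated ages are recovered without bias and shrink with L", {
    cfg_long <- simConfig(seed = 11, n_intact_ltr = 300, ltr_length = 4000,
                          age_distribution = ageDistUniform(0, 5))
    cfg_short <- simConfig(seed = 11, n_intact_ltr = 300, ltr_length = 500)
    err <- function(cfg) {
        comp <- simulateTEComplement(cfg)
        d <- dateLTRPairs(comp$ltr_seqs, mu = cfg$mu)
        d$age_my - comp$truth$true_age_my[match(d$element_id,
                                                comp$truth$te_id)]
    }
    e_long <- err(cfg_long); e_short <- err(cfg_short)
    expect_lt(abs(mean(e_long)), 0.15)           # unbiased
    expect_lt(mean(abs(e_long)), mean(abs(e_short)))  # error ~ 1/sqrt(L)
})
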