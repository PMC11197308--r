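## Synthetic genome-annotation and expression simulator with ground
## truth: the validation backbone for every analysis stage.

#' @importFrom stats runif rnorm rbinom
NULL

.BASES <- c("A", "C", "G", "T")

#' Age-distribution descriptors for the simulator
#'
#' `ageDistUniform(lo, hi)` draws ages uniformly; `ageDistBurst(mean,
#' sd)` draws a normal transposition burst truncated at zero. Components
#' can be combined into a weighted mixture by passing a list of them as
#' `age_distribution`.
#'
#' @param lo,hi Uniform bounds in million years.
#' @param mean_my,sd_my Burst centre and spread in million years.
#' @param weight Mixture weight (normalized across components).
#' @return A list descriptor consumed by [simConfig()].
#' @export
ageDistUniform <- function(lo = 0, hi = 5, weight = 1) {
    stopifnot(lo >= 0, hi > lo, weight > 0)
    list(kind = "uniform", lo = lo, hi = hi, weight = weight)
}

#' @rdname ageDistUniform
#' @export
ageDistBurst <- function(mean_my, sd_my, weight = 1) {
    stopifnot(mean_my >= 0, sd_my > 0, weight > 0)
    list(kind = "burst", mean_my = mean_my, sd_my = sd_my, weight = weight)
}

.sampleAges <- function(n, dist) {
    if (!is.null(dist$kind)) dist <- list(dist)
    w <- vapply(dist, `[[`, 1, "weight")
    comp <- sample.int(length(dist), n, replace = TRUE, prob = w / sum(w))
    ages <- numeric(n)
    for (k in seq_along(dist)) {
        i <- which(comp == k)
        if (!length(i)) next
        d <- dist[[k]]
        ages[i] <- switch(d$kind,
            uniform = runif(length(i), d$lo, d$hi),
            burst = pmax(0, rnorm(length(i), d$mean_my, d$sd_my)),
            stop("unknown age distribution kind: ", d$kind))
    }
    ages
}

#' Simulation configuration
#'
#' Collects and validates every knob of the synthetic-data generator.
#' Defaults describe a realistic mid-size plant-genome TE complement:
#' 2000 intact LTR elements with 1-kb LTRs mutating at the Rosaceae rate
#' mu = 4e-9 per site per year, ages uniform on 0--5 MY, a moderate
#' solo:intact ratio of 8, 500 gene pairs with TEs placed at controlled
#' flanking distances, and a 9-timepoint two-cultivar fruit-development
#' TPM course with 200 period-specific, 200 cultivar-specific and 600
#' null gene pairs.
#'
#' Expression effect sizes are validated against the caller thresholds
#' at construction: with truncated (+-3 sigma) log-normal noise, an
#' injected log2 effect of `effect_log2fc` must still clear the 1.5
#' fold-change threshold and null noise must not reach it, so injected
#' patterns are recoverable exactly.
#'
#' @param seed Integer RNG seed (mandatory; same config => identical
#'   output).
#' @param n_chromosomes,chrom_length Genome layout for placements (bp).
#' @param n_intact_ltr Number of intact LTR elements to simulate.
#' @param age_distribution An [ageDistUniform()]/[ageDistBurst()]
#'   descriptor or a list of them (weighted mixture).
#' @param ltr_length,internal_length LTR and internal-region lengths (bp).
#' @param mu Per-site per-year mutation rate (> 0).
#' @param solo_to_intact_ratio Solo LTRs recorded per intact element.
#' @param n_genes Gene pairs in the two-cultivar landscape.
#' @param te_placement List with `p_beyond` (fraction of genes given a
#'   decoy TE beyond the 5-kb radius) and `p_inside` (decoy fully inside
#'   the gene body).
#' @param synteny_retention Fraction of gene pairs emitted as anchors.
#' @param n_timepoints Timepoints per cultivar (>= 2).
#' @param n_period,n_cultivar,n_null Injected DE pattern counts.
#' @param effect_log2fc Injected adjacent-timepoint log2 effect for
#'   period-specific genes (default 2.0 > the 1.5 threshold).
#' @param base_tpm Background expression level (TPM).
#' @param hi_tpm_level,lo_tpm_base Cultivar-specific injected levels
#'   (must straddle the TPM > 32 / < 8 thresholds).
#' @param noise_sigma SD of the truncated log-normal TPM noise.
#' @param fc_threshold,hi_threshold,lo_threshold Caller thresholds the
#'   injections must straddle (1.5 / 32 / 8).
#' @return A validated list of class `"SimConfig"`.
#' @export
simConfig <- function(seed,
                      n_chromosomes = 2L, chrom_length = 2e7,
                      n_intact_ltr = 2000L,
                      age_distribution = ageDistUniform(0, 5),
                      ltr_length = 1000L, internal_length = 4000L,
                      mu = 4e-9,
                      solo_to_intact_ratio = 8,
                      n_genes = 500L,
                      te_placement = list(p_beyond = 0.2, p_inside = 0.1),
                      synteny_retention = 1.0,
                      n_timepoints = 9L,
                      n_period = 200L, n_cultivar = 200L, n_null = 600L,
                      effect_log2fc = 2.0, base_tpm = 5,
                      hi_tpm_level = 64, lo_tpm_base = 2,
                      noise_sigma = 0.05,
                      fc_threshold = 1.5, hi_threshold = 32,
                      lo_threshold = 8) {
    if (missing(seed)) stop("seed is mandatory")
    stopifnot(mu > 0, ltr_length >= 10, n_timepoints >= 2,
              solo_to_intact_ratio >= 0, noise_sigma >= 0)
    if (te_placement$p_beyond < 0 || te_placement$p_beyond > 1 ||
        te_placement$p_inside < 0 || te_placement$p_inside > 1 ||
        synteny_retention < 0 || synteny_retention > 1)
        stop("fractions must lie in [0, 1]")
    # threshold-separation guarantee under +-3 sigma truncated noise:
    # adjacent log2 fold changes shift by at most 6 sigma / ln 2
    margin <- 6 * noise_sigma / log(2)
    if (effect_log2fc - margin < fc_threshold)
        stop("effect_log2fc cannot guarantee separation from the ",
             fc_threshold, " fold-change threshold under the noise level")
    if (margin >= fc_threshold)
        stop("noise_sigma large enough to push null genes over the ",
             "fold-change threshold")
    if (hi_tpm_level * exp(-3 * noise_sigma) <= hi_threshold)
        stop("hi_tpm_level cannot guarantee TPM > ", hi_threshold,
             " under the noise level")
    if (lo_tpm_base * exp(3 * noise_sigma) >= lo_threshold)
        stop("lo_tpm_base cannot guarantee TPM < ", lo_threshold,
             " under the noise level")
    period_peak <- (base_tpm + 1) * 2^effect_log2fc - 1
    if (period_peak * exp(3 * noise_sigma) >= hi_threshold)
        stop("period-specific peak would cross the cultivar hi threshold")
    structure(as.list(environment()), class = "SimConfig")
}

## TE complement ---------------------------------------------------------

# mutate one LTR copy: each site substituted independently with
# probability q, replacement drawn uniformly among the 3 alternatives
# (so repeated hits across copies can coincide, exercising the JC
# correction non-trivially)
.mutateCopy <- function(anc, q) {
    hit <- which(runif(length(anc)) < q)
    if (length(hit)) {
        shift <- sample.int(3L, length(hit), replace = TRUE)
        anc[hit] <- .BASES[(match(anc[hit], .BASES) - 1L + shift) %% 4L + 1L]
    }
    anc
}

#' Simulate an intact-LTR complement with age-encoding LTR pairs
#'
#' Inverts the dating model: every element starts with two identical
#' LTR copies and each copy accrues substitutions independently, each
#' site with probability mu * T (T = true age in years), replacements
#' uniform over the three alternative bases. Expected raw pairwise
#' divergence is therefore ~ 2 mu T before multiple-hit correction.
#' Solo LTRs are recorded deterministically at the configured ratio.
#'
#' @param config A [simConfig()].
#' @return A list with `te` ([TEAnnotation] of placed intact elements),
#'   `ltr_seqs` (DNAStringSet named `<id>__5ltr`/`<id>__3ltr`), `solo`
#'   (a solo-count row), and `truth` (data.frame `te_id`,
#'   `true_age_my`).
#' @export
simulateTEComplement <- function(config) {
    stopifnot(inherits(config, "SimConfig"))
    set.seed(config$seed)
    n <- config$n_intact_ltr
    L <- config$ltr_length
    ages <- .sampleAges(n, config$age_distribution)
    q <- config$mu * ages * 1e6
    if (any(q >= 0.25))
        stop("mu * T >= 0.25 per copy: divergence saturated beyond the ",
             "regime the Jukes-Cantor dating supports")

    ids <- sprintf("LTRRT%05d", seq_len(n))
    seqs <- vector("character", 2L * n)
    for (i in seq_len(n)) {
        anc <- sample(.BASES, L, replace = TRUE)
        seqs[2L * i - 1L] <- paste(.mutateCopy(anc, q[i]), collapse = "")
        seqs[2L * i] <- paste(.mutateCopy(anc, q[i]), collapse = "")
    }
    names(seqs) <- as.vector(rbind(paste0(ids, "__5ltr"),
                                   paste0(ids, "__3ltr")))

    # tile elements across chromosomes with random jitter
    elem_w <- 2L * L + config$internal_length
    per_chrom <- ceiling(n / config$n_chromosomes)
    slot_w <- floor(config$chrom_length / per_chrom)
    if (slot_w < elem_w + 2L)
        stop("chromosome capacity exceeded: elements do not fit")
    chrom <- rep(seq_len(config$n_chromosomes), each = per_chrom)[seq_len(n)]
    slot <- sequence(rle(chrom)$lengths)
    start <- (slot - 1L) * slot_w + 1L +
        floor(runif(n) * (slot_w - elem_w))
    gr <- GRanges(paste0("chr", chrom),
                  IRanges(start, width = elem_w), strand = "+")
    mcols(gr)$te_id <- ids
    mcols(gr)$te_order <- "LTR"
    mcols(gr)$superfamily <- sample(c("RLC", "RLG", "RLU"), n,
                                    replace = TRUE, prob = c(.45, .45, .1))
    mcols(gr)$ltr5_start <- start
    mcols(gr)$ltr5_end <- start + L - 1L
    mcols(gr)$ltr3_start <- start + elem_w - L
    mcols(gr)$ltr3_end <- start + elem_w - 1L
    te <- TEAnnotation(sort(gr, ignore.strand = TRUE))

    n_solo <- as.integer(round(config$solo_to_intact_ratio * n))
    list(te = te,
         ltr_seqs = DNAStringSet(seqs),
         solo = data.frame(label = "simulated", n_solo = n_solo,
                           n_intact = n),
         truth = data.frame(te_id = ids, true_age_my = ages))
}

## Gene/TE landscape -----------------------------------------------------

.placeFlankTE <- function(gene_start, gene_end, side, gap, te_len) {
    if (side == "upstream") {
        e <- gene_start - gap - 1L   # nearest-edge gap = `gap` bp exactly
        c(e - te_len + 1L, e)
    } else {
        s <- gene_end + gap + 1L
        c(s, s + te_len - 1L)
    }
}

#' Simulate a two-cultivar gene/TE landscape with known configurations
#'
#' Places `n_genes` syntenic gene pairs on matching coordinates of two
#' cultivars and gives each pair a known positional configuration: the
#' 16 (state A, state B) combinations of NONE/UP/DOWN/BOTH are cycled so
#' all are covered, with per-side TE counts drawn 1--3, flanking gaps
#' drawn strictly inside the 5-kb radius, plus decoy TEs beyond the
#' radius and fully inside gene bodies (both excluded by the proximity
#' rules, and marked so in the ground truth). Decoy and flank TEs carry
#' ages drawn from the configured age distribution so young/old splits
#' can be tested on the same landscape.
#'
#' @param config A [simConfig()].
#' @return A list with `genesA`, `genesB` (GRanges with `gene_id`),
#'   `tesA`, `tesB` ([TEAnnotation]), `anchors` (retained synteny
#'   pairs), and `truth` (per-pair intended states, counts, main type,
#'   subtype, IIIa flag, anchored flag).
#' @export
simulateGeneTELandscape <- function(config) {
    stopifnot(inherits(config, "SimConfig"))
    set.seed(config$seed + 1L)
    n <- config$n_genes
    gene_len <- 3000L
    te_len <- 500L
    spacing <- 30000L
    radius <- 5000L
    per_chrom <- floor(config$chrom_length / spacing)
    if (per_chrom < 1L || n > per_chrom * config$n_chromosomes)
        stop("chromosome capacity exceeded: gene placements overlap")

    states <- c("NONE", "UP", "DOWN", "BOTH")
    grid <- expand.grid(a = states, b = states,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    conf_idx <- rep(seq_len(16L), length.out = n)[sample.int(n)]

    chrom <- rep(seq_len(config$n_chromosomes),
                 each = per_chrom)[seq_len(n)]
    slot <- sequence(rle(chrom)$lengths)
    gstart <- (slot - 1L) * spacing + 10000L
    gend <- gstart + gene_len - 1L

    makeGenes <- function(tag)
        GRanges(paste0("chr", tag, chrom),
                IRanges(gstart, gend), strand = "+",
                gene_id = sprintf("g%04d_%s", seq_len(n), tag))
    genesA <- makeGenes("A")
    genesB <- makeGenes("B")

    countFor <- function(state)
        switch(state, NONE = c(0L, 0L),
               UP = c(sample(1:3, 1L), 0L),
               DOWN = c(0L, sample(1:3, 1L)),
               BOTH = c(sample(1:3, 1L), sample(1:3, 1L)))

    placeCultivar <- function(genes, state_vec, tag) {
        s <- start(genes); e <- end(genes)
        chr <- as.character(seqnames(genes))
        rows <- list(); counts <- matrix(0L, length(genes), 2L)
        k <- 0L
        for (i in seq_along(genes)) {
            cnt <- countFor(state_vec[i])
            counts[i, ] <- cnt
            for (side in c("upstream", "downstream")) {
                m <- if (side == "upstream") cnt[1L] else cnt[2L]
                for (j in seq_len(m)) {
                    gap <- sample(0:(radius - 1L), 1L)
                    pos <- .placeFlankTE(s[i], e[i], side, gap, te_len)
                    k <- k + 1L
                    rows[[k]] <- data.frame(chr = chr[i], s = pos[1L],
                                            e = pos[2L], decoy = "none")
                }
            }
            if (runif(1) < config$te_placement$p_beyond) {
                gap <- sample(radius:(radius + 2000L), 1L)
                side <- sample(c("upstream", "downstream"), 1L)
                pos <- .placeFlankTE(s[i], e[i], side, gap, te_len)
                k <- k + 1L
                rows[[k]] <- data.frame(chr = chr[i], s = pos[1L],
                                        e = pos[2L], decoy = "beyond")
            }
            if (runif(1) < config$te_placement$p_inside) {
                off <- sample.int(gene_len - te_len - 2L, 1L)
                k <- k + 1L
                rows[[k]] <- data.frame(chr = chr[i], s = s[i] + off,
                                        e = s[i] + off + te_len - 1L,
                                        decoy = "inside")
            }
        }
        df <- do.call(rbind, rows)
        gr <- GRanges(df$chr, IRanges(df$s, df$e), strand = "+")
        nte <- length(gr)
        mcols(gr)$te_id <- sprintf("TE%s%05d", tag, seq_len(nte))
        mcols(gr)$te_order <- sample(c("LTR", "TIR", "MITE"), nte,
                                     replace = TRUE, prob = c(.7, .2, .1))
        mcols(gr)$superfamily <- ifelse(mcols(gr)$te_order == "LTR",
            sample(c("RLC", "RLG"), nte, replace = TRUE),
            sample(c("DTA", "DTT"), nte, replace = TRUE))
        mcols(gr)$age_my <- .sampleAges(nte, config$age_distribution)
        mcols(gr)$decoy <- df$decoy
        list(te = TEAnnotation(sort(gr, ignore.strand = TRUE)),
             counts = counts)
    }

    state_a <- grid$a[conf_idx]
    state_b <- grid$b[conf_idx]
    plA <- placeCultivar(genesA, state_a, "A")
    plB <- placeCultivar(genesB, state_b, "B")

    n_a <- rowSums(plA$counts); n_b <- rowSums(plB$counts)
    cls <- Map(classifyPair, state_a, state_b, n_a, n_b)
    anchored <- runif(n) < config$synteny_retention
    truth <- data.frame(
        gene_a = mcols(genesA)$gene_id, gene_b = mcols(genesB)$gene_id,
        state_a = state_a, state_b = state_b, n_a = n_a, n_b = n_b,
        main_type = vapply(cls, `[[`, "", "main_type"),
        subtype = vapply(cls, `[[`, "", "subtype"),
        iii_alpha = vapply(cls, `[[`, NA, "iii_alpha"),
        anchored = anchored, stringsAsFactors = FALSE)
    anchors <- truth[anchored, c("gene_a", "gene_b")]
    rownames(anchors) <- NULL
    list(genesA = genesA, genesB = genesB,
         tesA = plA$te, tesB = plB$te,
         anchors = anchors, truth = truth)
}

## Expression time courses -----------------------------------------------

.truncNoise <- function(n, sigma) {
    if (sigma == 0) return(rep(1, n))
    exp(pmin(3 * sigma, pmax(-3 * sigma, rnorm(n, 0, sigma))))
}

#' Simulate two-cultivar expression time courses with injected DE
#'
#' Generates TPM matrices for cultivars A and B over a shared ordered
#' timepoint axis, injecting three ground-truth patterns:
#' period-specific genes (one adjacent-timepoint log2 fold change of
#' `effect_log2fc` in A, flat partner in B), cultivar-specific genes
#' (constant `hi_tpm_level` in A, `lo_tpm_base` in B), and null genes
#' (background level in both). Multiplicative log-normal noise is
#' truncated at +-3 sigma so injected patterns cannot cross the caller
#' thresholds (validated by [simConfig()]).
#'
#' @param config A [simConfig()].
#' @param pairs Optional data.frame of gene pairs to use as feature ids
#'   (first `n_period + n_cultivar + n_null` rows); defaults to
#'   generated ids.
#' @return A list with `matA`, `matB` (SummarizedExperiments, assay
#'   `tpm`) and `truth` (data.frame `gene_a`, `gene_b`, `pattern`).
#' @export
simulateExpressionCourse <- function(config, pairs = NULL) {
    stopifnot(inherits(config, "SimConfig"))
    set.seed(config$seed + 2L)
    nt <- config$n_timepoints
    ng <- config$n_period + config$n_cultivar + config$n_null
    if (is.null(pairs)) {
        pairs <- data.frame(gene_a = sprintf("g%04d_A", seq_len(ng)),
                            gene_b = sprintf("g%04d_B", seq_len(ng)))
    } else if (nrow(pairs) < ng)
        stop("need at least ", ng, " gene pairs")
    pairs <- pairs[seq_len(ng), ]
    pattern <- sample(rep(c("period_specific", "cultivar_specific", "null"),
                          c(config$n_period, config$n_cultivar,
                            config$n_null)))

    A <- matrix(config$base_tpm, ng, nt)
    B <- matrix(config$base_tpm, ng, nt)
    peak <- (config$base_tpm + 1) * 2^config$effect_log2fc - 1
    for (i in which(pattern == "period_specific"))
        A[i, sample.int(nt, 1L)] <- peak
    cv <- pattern == "cultivar_specific"
    A[cv, ] <- config$hi_tpm_level
    B[cv, ] <- config$lo_tpm_base

    A <- A * matrix(.truncNoise(ng * nt, config$noise_sigma), ng, nt)
    B <- B * matrix(.truncNoise(ng * nt, config$noise_sigma), ng, nt)
    tps <- paste0("t", seq_len(nt))
    dimnames(A) <- list(pairs$gene_a, tps)
    dimnames(B) <- list(pairs$gene_b, tps)

    mkSE <- function(m) {
        se <- SummarizedExperiment(assays = list(tpm = m))
        metadata(se)$sample_role <- "timepoint-days"
        se
    }
    list(matA = mkSE(A), matB = mkSE(B),
         truth = data.frame(gene_a = pairs$gene_a, gene_b = pairs$gene_b,
                            pattern = pattern, stringsAsFactors = FALSE))
}

## Full pipeline ---------------------------------------------------------

#' Run the full synthetic pipeline and write every output file
#'
#' Simulates the TE complement, the two-cultivar gene/TE landscape and
#' the expression courses from one configuration, and writes the
#' complete input set (TE GFF3 x3, gene GFF3 x2, LTR FASTA, solo-count
#' TSV, expression TSV x2, anchors TSV) plus ground-truth TSVs to a
#' directory. Output is a pure function of the configuration: the same
#' config (including seed) produces byte-identical files.
#'
#' @param config A [simConfig()].
#' @param outdir Output directory (created if absent).
#' @return Named character vector of written file paths, invisibly.
#' @export
runSyntheticPipeline <- function(config, outdir) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    p <- function(f) file.path(outdir, f)

    comp <- simulateTEComplement(config)
    land <- simulateGeneTELandscape(config)
    ng <- config$n_period + config$n_cultivar + config$n_null
    expr <- simulateExpressionCourse(
        config, if (nrow(land$truth) >= ng) land$truth else NULL)

    writeTEGFF3(comp$te, p("te_complement.gff3"))
    writeLTRFasta(comp$ltr_seqs, p("ltr_pairs.fa"))
    writeSoloCounts(comp$solo, p("solo_counts.tsv"))
    write.table(comp$truth, p("truth_ages.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    writeGeneGFF3(land$genesA, p("genes_A.gff3"))
    writeGeneGFF3(land$genesB, p("genes_B.gff3"))
    writeTEGFF3(land$tesA, p("tes_A.gff3"))
    writeTEGFF3(land$tesB, p("tes_B.gff3"))
    writeAnchors(land$anchors, p("anchors.tsv"))
    write.table(land$truth, p("truth_pairs.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    writeExpressionTSV(expr$matA, p("tpm_A.tsv"))
    writeExpressionTSV(expr$matB, p("tpm_B.tsv"))
    write.table(expr$truth, p("truth_expression.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)

    files <- c(te_gff = p("te_complement.gff3"), fasta = p("ltr_pairs.fa"),
               solo = p("solo_counts.tsv"), truth_ages = p("truth_ages.tsv"),
               genes_a = p("genes_A.gff3"), genes_b = p("genes_B.gff3"),
               tes_a = p("tes_A.gff3"), tes_b = p("tes_B.gff3"),
               anchors = p("anchors.tsv"), truth_pairs = p("truth_pairs.tsv"),
               tpm_a = p("tpm_A.tsv"), tpm_b = p("tpm_B.tsv"),
               truth_expression = p("truth_expression.tsv"))
    invisible(files)
}
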