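# Shared fixture builders and independent oracles.

suppressPackageStartupMessages({
    library(GenomicRanges)
    library(S4Vectors)
})

makeGenes <- function(starts, ends, ids = NULL, chrom = "chr1") {
    if (is.null(ids)) ids <- sprintf("g%03d", seq_along(starts))
    GRanges(chrom, IRanges(starts, ends), strand = "+", gene_id = ids)
}

makeTEs <- function(starts, ends, ids = NULL, chrom = "chr1",
                    order = "LTR", superfamily = "RLC") {
    if (is.null(ids)) ids <- sprintf("te%03d", seq_along(starts))
    gr <- GRanges(chrom, IRanges(starts, ends), strand = "+")
    mcols(gr)$te_id <- ids
    mcols(gr)$te_order <- rep(order, length.out = length(gr))
    mcols(gr)$superfamily <- rep(superfamily, length.out = length(gr))
    gr
}

# Exhaustive all-pairs proximity scan: plain integer arithmetic,
# independent of the interval-structure implementation under test.
bruteProximity <- function(genes, tes, radius = 5000) {
    out <- list(); k <- 0L
    gch <- as.character(seqnames(genes)); tch <- as.character(seqnames(tes))
    gs <- start(genes); ge <- end(genes)
    ts <- start(tes); te <- end(tes)
    gid <- mcols(genes)$gene_id; tid <- mcols(tes)$te_id
    for (i in seq_along(genes)) for (j in seq_along(tes)) {
        if (gch[i] != tch[j]) next
        if (ts[j] >= gs[i] && te[j] <= ge[i]) next   # fully inside
        if (te[j] < gs[i]) { d <- gs[i] - te[j] - 1L; side <- "upstream" }
        else if (ts[j] > ge[i]) { d <- ts[j] - ge[i] - 1L; side <- "downstream" }
        else {
            d <- 0L
            side <- if ((ts[j] + te[j]) / 2 <= (gs[i] + ge[i]) / 2)
                "upstream" else "downstream"
        }
        if (d < radius) {
            k <- k + 1L
            out[[k]] <- data.frame(gene_id = gid[i], te_id = tid[j],
                                   side = side, distance = d,
                                   stringsAsFactors = FALSE)
        }
    }
    if (!k) return(data.frame(gene_id = character(), te_id = character(),
                              side = character(), distance = integer()))
    df <- do.call(rbind, out)
    df[order(df$gene_id, df$distance, df$te_id), , drop = FALSE]
}

randomLandscape <- function(n_genes, n_tes, chrom_len = 2e6,
                            n_chrom = 2) {
    g_start <- sample.int(chrom_len - 3000L, n_genes)
    genes <- makeGenes(g_start, g_start + sample(500:3000, n_genes, TRUE),
                       chrom = paste0("chr", sample.int(n_chrom, n_genes,
                                                        TRUE)))
    t_start <- sample.int(chrom_len - 1000L, n_tes)
    tes <- makeTEs(t_start, t_start + sample(100:1000, n_tes, TRUE),
                   chrom = paste0("chr", sample.int(n_chrom, n_tes, TRUE)))
    list(genes = genes, tes = tes)
}

proximityEqual <- function(a, b) {
    rownames(a) <- rownames(b) <- NULL
    isTRUE(all.equal(a, b, check.attributes = FALSE))
}
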