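## Threshold-rule DEG calling between two cultivars over shared fruit
## development time courses, through synteny anchors.

# max over adjacent timepoints of |log2 fold change| with +1 pseudocount
.maxAdjacentFC <- function(x, signed = FALSE) {
    l <- log2(x + 1)
    fc <- diff(l)
    if (signed) max(fc) else max(abs(fc))
}

.resolvePairs <- function(matA, matB, pairs) {
    missA <- setdiff(pairs$gene_a, rownames(matA))
    missB <- setdiff(pairs$gene_b, rownames(matB))
    if (length(missA) || length(missB))
        stop("unresolvable gene id(s) in pairs: ",
             paste(c(missA, missB), collapse = ", "))
}

#' Call period-specific syntenic DEG pairs
#'
#' A syntenic pair is period-specific when cultivar A's gene shows a
#' log2 fold change of at least `fc` between some two adjacent
#' timepoints while cultivar B's partner stays below `fc` between every
#' adjacent pair. Fold changes use a +1 TPM pseudocount and are absolute
#' by default (`signed = TRUE` restricts to increases).
#'
#' @param matA,matB Expression containers ([tpmMatrix()]-compatible)
#'   with the same number of ordered timepoints (>= 2).
#' @param pairs A data.frame of synteny anchors (`gene_a`, `gene_b`).
#' @param fc log2 fold-change threshold (default 1.5; `>=` in A,
#'   strict `<` in B).
#' @param signed Use signed (increase-only) fold changes instead of
#'   absolute values.
#' @return The subset of `pairs` that is called, with supporting columns
#'   `max_fc_a`, `max_fc_b`, `pattern = "period_specific"`.
#' @export
callPeriodSpecific <- function(matA, matB, pairs, fc = 1.5,
                               signed = FALSE) {
    mA <- tpmMatrix(matA); mB <- tpmMatrix(matB)
    if (ncol(mA) != ncol(mB))
        stop("cultivar matrices must share the timepoint axis")
    if (ncol(mA) < 2L) stop("need at least 2 timepoints")
    .resolvePairs(mA, mB, pairs)
    fa <- apply(mA[pairs$gene_a, , drop = FALSE], 1L,
                .maxAdjacentFC, signed = signed)
    fb <- apply(mB[pairs$gene_b, , drop = FALSE], 1L,
                .maxAdjacentFC, signed = signed)
    keep <- fa >= fc & fb < fc
    out <- pairs[keep, , drop = FALSE]
    out$max_fc_a <- unname(fa[keep])
    out$max_fc_b <- unname(fb[keep])
    out$pattern <- rep("period_specific", sum(keep))
    rownames(out) <- NULL
    out
}

#' Call cultivar-specific syntenic DEG pairs
#'
#' A syntenic pair is cultivar-specific when cultivar A's gene exceeds
#' `hi` TPM at some timepoint (strict `>`) while cultivar B's partner
#' stays below `lo` TPM at every timepoint (strict `<`). With
#' `all_timepoints = TRUE`, A must exceed `hi` at every timepoint
#' instead.
#'
#' @param matA,matB Expression containers with the same timepoint axis.
#' @param pairs A data.frame of synteny anchors (`gene_a`, `gene_b`).
#' @param hi High-expression TPM threshold for A (default 32).
#' @param lo Low-expression TPM threshold for B (default 8).
#' @param all_timepoints Require A above `hi` at all timepoints.
#' @return The subset of `pairs` called, with `max_tpm_a`, `max_tpm_b`,
#'   `pattern = "cultivar_specific"`.
#' @export
callCultivarSpecific <- function(matA, matB, pairs, hi = 32, lo = 8,
                                 all_timepoints = FALSE) {
    mA <- tpmMatrix(matA); mB <- tpmMatrix(matB)
    if (ncol(mA) != ncol(mB))
        stop("cultivar matrices must share the timepoint axis")
    .resolvePairs(mA, mB, pairs)
    xa <- mA[pairs$gene_a, , drop = FALSE]
    xb <- mB[pairs$gene_b, , drop = FALSE]
    okA <- if (all_timepoints) apply(xa > hi, 1L, all)
           else apply(xa > hi, 1L, any)
    okB <- apply(xb < lo, 1L, all)
    keep <- okA & okB
    out <- pairs[keep, , drop = FALSE]
    out$max_tpm_a <- unname(apply(xa, 1L, max))[keep]
    out$max_tpm_b <- unname(apply(xb, 1L, max))[keep]
    out$pattern <- rep("cultivar_specific", sum(keep))
    rownames(out) <- NULL
    out
}
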