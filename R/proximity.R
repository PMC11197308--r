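## TE-to-gene proximity within a flanking radius, and per-gene
## positional states.

#' @importFrom GenomicRanges findOverlaps distance granges
#' @importFrom S4Vectors queryHits subjectHits
NULL

#' Assign TEs to genes within a flanking radius
#'
#' A TE is assigned to a gene when the gap between their nearest edges
#' is strictly less than `radius` (default 5000 bp) and the TE is not
#' fully contained in the gene body (a boundary-straddling insertion is
#' not "inside" the gene and counts as proximal at distance 0). Sides
#' are coordinate-order based and strand-agnostic: upstream = TE entirely
#' before the gene start, downstream = TE entirely after the gene end;
#' for partial overlaps the side follows the TE midpoint relative to the
#' gene midpoint (ties upstream). One TE may be assigned to several
#' genes.
#'
#' @param genes GRanges of gene bodies with a `gene_id` metadata column.
#' @param tes GRanges (or [TEAnnotation]) of TEs; element ids taken from
#'   `te_id` metadata column, else from names.
#' @param radius Flanking radius in bp (default 5000, strict `<`).
#' @return A data.frame with columns `gene_id`, `te_id`, `side`
#'   (`"upstream"`/`"downstream"`), `distance` (bp gap, 0 when touching
#'   or overlapping).
#' @export
assignTEProximity <- function(genes, tes, radius = 5000) {
    if (radius <= 0) stop("radius must be positive")
    gene_id <- mcols(genes)$gene_id
    if (is.null(gene_id)) stop("genes need a gene_id metadata column")
    te_id <- mcols(tes)$te_id
    if (is.null(te_id)) te_id <- names(tes)
    if (is.null(te_id)) stop("tes need te_id metadata or names")

    hits <- findOverlaps(granges(tes), granges(genes),
                         maxgap = radius - 1L, ignore.strand = TRUE)
    if (!length(hits))
        return(data.frame(gene_id = character(), te_id = character(),
                          side = character(), distance = integer()))
    q <- queryHits(hits); s <- subjectHits(hits)
    ts <- start(tes)[q]; te <- end(tes)[q]
    gs <- start(genes)[s]; ge <- end(genes)[s]

    contained <- ts >= gs & te <= ge       # fully inside the gene body
    d <- integer(length(q))
    up <- te < gs
    down <- ts > ge
    d[up] <- gs[up] - te[up] - 1L
    d[down] <- ts[down] - ge[down] - 1L    # overlap/touching stay 0
    side <- ifelse(up, "upstream",
            ifelse(down, "downstream",
                   ifelse((ts + te) / 2 <= (gs + ge) / 2,
                          "upstream", "downstream")))
    keep <- !contained & d < radius
    out <- data.frame(gene_id = gene_id[s][keep],
                      te_id = te_id[q][keep],
                      side = side[keep],
                      distance = d[keep],
                      stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out[order(out$gene_id, out$distance, out$te_id), , drop = FALSE]
}

#' Per-gene positional state of proximal TEs
#'
#' Summarizes a gene's proximity records into upstream/downstream counts
#' and one of four positional states: `NONE` (no proximal TEs), `UP`,
#' `DOWN`, or `BOTH`.
#'
#' @param gene_ids Character vector of genes to summarize.
#' @param records Proximity records from [assignTEProximity()].
#' @return A data.frame with columns `gene_id`, `n_up`, `n_down`,
#'   `state`.
#' @export
positionalState <- function(gene_ids, records) {
    n_up <- integer(length(gene_ids))
    n_down <- integer(length(gene_ids))
    if (nrow(records)) {
        upt <- table(records$gene_id[records$side == "upstream"])
        dnt <- table(records$gene_id[records$side == "downstream"])
        n_up <- as.integer(upt[gene_ids]); n_up[is.na(n_up)] <- 0L
        n_down <- as.integer(dnt[gene_ids]); n_down[is.na(n_down)] <- 0L
    }
    state <- ifelse(n_up == 0L & n_down == 0L, "NONE",
             ifelse(n_up > 0L & n_down > 0L, "BOTH",
             ifelse(n_up > 0L, "UP", "DOWN")))
    data.frame(gene_id = gene_ids, n_up = n_up, n_down = n_down,
               state = state, stringsAsFactors = FALSE)
}
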