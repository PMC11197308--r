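#' @import methods
#' @importFrom S4Vectors mcols mcols<- DataFrame metadata metadata<-
#' @importFrom GenomicRanges GRanges seqnames start end width strand
#' @importFrom IRanges IRanges
NULL

## Controlled vocabularies -----------------------------------------------

#' Superfamily, order, and protein-domain vocabularies
#'
#' Constants used throughout the package: the nine three-letter TE
#' superfamily codes (RLC = Copia LTR-RT, RLG = Gypsy LTR-RT, RLU =
#' unknown LTR-RT, DTA = hAT, DTC = CACTA, DTH = PIF-Harbinger, DTM =
#' Mutator, DTT = Tc1-Mariner, DHH = Helitron), the TE orders they belong
#' to, and the five protein domains of an autonomous LTR retrotransposon
#' (capsid protein GAG, aspartic proteinase AP, integrase INT, reverse
#' transcriptase RT, RNase H RH).
#'
#' @format Character vectors.
#' @name vocabularies
NULL

#' @rdname vocabularies
#' @export
TE_SUPERFAMILIES <- c("RLC", "RLG", "RLU",
                      "DTA", "DTC", "DTH", "DTM", "DTT", "DHH")

#' @rdname vocabularies
#' @export
TE_ORDERS <- c("LTR", "TIR", "MITE", "Helitron", "LINE")

#' @rdname vocabularies
#' @export
LTR_DOMAINS <- c("GAG", "AP", "INT", "RT", "RH")

## TEAnnotation ----------------------------------------------------------

#' TEAnnotation: a set of annotated transposable elements
#'
#' A \linkS4class{GRanges} subclass holding one range per element with
#' required metadata columns `te_id` (unique element identifier),
#' `te_order` (one of `r paste(TE_ORDERS, collapse = ", ")`) and
#' `superfamily` (one of the nine three-letter codes, or `"unknown"`).
#' Optional columns: `family`, `age_my` (non-negative insertion age in
#' million years), and for LTR-order elements the 1-based closed
#' sub-coordinates of the two terminal repeats, `ltr5_start`, `ltr5_end`,
#' `ltr3_start`, `ltr3_end` (5' LTR preceding the 3' LTR, both inside the
#' element range).
#'
#' @slot .  Inherits all GRanges slots.
#' @seealso [TEAnnotation()], [readTEGFF3()]
#' @export
setClass("TEAnnotation", contains = "GRanges")

.validTEAnnotation <- function(object) {
    msg <- character()
    mc <- mcols(object)
    req <- c("te_id", "te_order", "superfamily")
    miss <- setdiff(req, colnames(mc))
    if (length(miss))
        return(paste("missing metadata column(s):",
                     paste(miss, collapse = ", ")))
    if (anyDuplicated(mc$te_id))
        msg <- c(msg, "duplicated te_id values")
    bad_order <- setdiff(unique(mc$te_order), TE_ORDERS)
    if (length(bad_order))
        msg <- c(msg, paste("unknown te_order:",
                            paste(bad_order, collapse = ", ")))
    bad_sf <- setdiff(unique(mc$superfamily), c(TE_SUPERFAMILIES, "unknown"))
    if (length(bad_sf))
        msg <- c(msg, paste("superfamily outside the nine-code vocabulary:",
                            paste(bad_sf, collapse = ", ")))
    if ("age_my" %in% colnames(mc)) {
        a <- mc$age_my
        if (any(!is.na(a) & a < 0))
            msg <- c(msg, "negative age_my")
    }
    if (all(c("ltr5_start", "ltr5_end", "ltr3_start", "ltr3_end") %in%
            colnames(mc))) {
        i <- which(mc$te_order == "LTR" & !is.na(mc$ltr5_start))
        if (length(i)) {
            ok <- mc$ltr5_start[i] <= mc$ltr5_end[i] &
                  mc$ltr5_end[i] < mc$ltr3_start[i] &
                  mc$ltr3_start[i] <= mc$ltr3_end[i] &
                  mc$ltr5_start[i] >= start(object)[i] &
                  mc$ltr3_end[i] <= end(object)[i]
            if (!all(ok, na.rm = TRUE))
                msg <- c(msg,
                    "LTR sub-coordinates must satisfy 5' before 3', both within the element")
        }
    }
    if (length(msg)) msg else TRUE
}
setValidity("TEAnnotation", .validTEAnnotation)

#' Construct a TEAnnotation
#'
#' @param gr A GRanges with at least `te_id`, `te_order` and `superfamily`
#'   metadata columns (see \linkS4class{TEAnnotation}).
#' @return A `TEAnnotation` object.
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1001, 9000),
#'     te_id = "TE1", te_order = "LTR", superfamily = "RLC")
#' TEAnnotation(gr)
#' @export
TEAnnotation <- function(gr) {
    stopifnot(is(gr, "GRanges"))
    new("TEAnnotation", gr)
}

#' @describeIn TEAnnotation-class element identifiers.
#' @param x,object A `TEAnnotation`.
#' @export
setGeneric("teID", function(x) standardGeneric("teID"))

#' @rdname TEAnnotation-class
#' @export
setMethod("teID", "TEAnnotation", function(x) mcols(x)$te_id)

#' @describeIn TEAnnotation-class TE order per element.
#' @export
setGeneric("teOrder", function(x) standardGeneric("teOrder"))

#' @rdname TEAnnotation-class
#' @export
setMethod("teOrder", "TEAnnotation", function(x) mcols(x)$te_order)

#' @describeIn TEAnnotation-class superfamily code per element.
#' @export
setGeneric("superfamily", function(x) standardGeneric("superfamily"))

#' @rdname TEAnnotation-class
#' @export
setMethod("superfamily", "TEAnnotation", function(x) mcols(x)$superfamily)

#' @describeIn TEAnnotation-class insertion age (million years) per
#'   element, `NA` where not estimated.
#' @export
setGeneric("teAge", function(x) standardGeneric("teAge"))

#' @rdname TEAnnotation-class
#' @export
setMethod("teAge", "TEAnnotation", function(x) {
    if ("age_my" %in% colnames(mcols(x))) mcols(x)$age_my
    else rep(NA_real_, length(x))
})

#' @rdname TEAnnotation-class
#' @export
setMethod("show", "TEAnnotation", function(object) {
    cat("TEAnnotation with", length(object), "elements\n")
    tab <- table(mcols(object)$superfamily)
    cat("  superfamilies:",
        paste(names(tab), tab, sep = ":", collapse = " "), "\n")
    if ("age_my" %in% colnames(mcols(object)) &&
        any(!is.na(mcols(object)$age_my)))
        cat("  dated elements:", sum(!is.na(mcols(object)$age_my)), "\n")
    callNextMethod()
})

## RateProfile -----------------------------------------------------------

#' RateProfile: binned transposition and accumulation profile
#'
#' Holds per-bin counts of dated elements over a fixed time window
#' (default 0--10 million years in 0.1-MY bins, left-closed right-open,
#' last bin closed), the transposition rate (per-bin fraction of
#' in-window elements, summing to 1 when the window is non-empty) and the
#' accumulation profile (fraction of in-window elements at least as old
#' as each bin's left edge; equals 1 at the present-day boundary).
#'
#' @slot binEdges numeric, bin boundaries in million years (length bins+1).
#' @slot binCounts integer counts per bin.
#' @slot transpositionRate numeric per-bin fractions.
#' @slot accumulation numeric cumulative fractions at each left edge.
#' @slot ages numeric, the in-window ages retained for burst statistics.
#' @slot nWindow integer, elements inside the window.
#' @slot nOlder integer, elements beyond the window (excluded from
#'   normalization but reported).
#' @seealso [buildRateProfile()], [estimateBurst()]
#' @export
setClass("RateProfile",
    representation(binEdges = "numeric",
                   binCounts = "integer",
                   transpositionRate = "numeric",
                   accumulation = "numeric",
                   ages = "numeric",
                   nWindow = "integer",
                   nOlder = "integer"))

.validRateProfile <- function(object) {
    msg <- character()
    nb <- length(object@binEdges) - 1L
    if (length(object@binCounts) != nb ||
        length(object@transpositionRate) != nb ||
        length(object@accumulation) != nb)
        msg <- c(msg, "bin vectors must all have length(binEdges) - 1")
    if (sum(object@binCounts) != object@nWindow)
        msg <- c(msg, "binCounts must sum to nWindow")
    if (object@nWindow > 0L &&
        abs(sum(object@transpositionRate) - 1) > 1e-9)
        msg <- c(msg, "transpositionRate must sum to 1 when window non-empty")
    if (length(msg)) msg else TRUE
}
setValidity("RateProfile", .validRateProfile)

#' @describeIn RateProfile-class per-bin transposition-rate fractions.
#' @param x,object A `RateProfile`.
#' @export
setGeneric("transpositionRate", function(x) standardGeneric("transpositionRate"))

#' @rdname RateProfile-class
#' @export
setMethod("transpositionRate", "RateProfile", function(x) x@transpositionRate)

#' @describeIn RateProfile-class cumulative accumulation fractions.
#' @export
setGeneric("accumulation", function(x) standardGeneric("accumulation"))

#' @rdname RateProfile-class
#' @export
setMethod("accumulation", "RateProfile", function(x) x@accumulation)

#' @describeIn RateProfile-class integer counts per bin.
#' @export
setGeneric("binCounts", function(x) standardGeneric("binCounts"))

#' @rdname RateProfile-class
#' @export
setMethod("binCounts", "RateProfile", function(x) x@binCounts)

#' @describeIn RateProfile-class bin boundaries (million years).
#' @export
setGeneric("binEdges", function(x) standardGeneric("binEdges"))

#' @rdname RateProfile-class
#' @export
setMethod("binEdges", "RateProfile", function(x) x@binEdges)

#' @rdname RateProfile-class
#' @export
setMethod("show", "RateProfile", function(object) {
    nb <- length(object@binCounts)
    cat("RateProfile:", nb, "bins over [",
        object@binEdges[1], ",", object@binEdges[nb + 1L], "] MY\n")
    cat("  in-window elements:", object@nWindow,
        " beyond window:", object@nOlder, "\n")
    if (object@nWindow > 0L) {
        i <- which.max(object@binCounts)
        cat("  modal bin: [", object@binEdges[i], ",",
            object@binEdges[i + 1L], ") MY, count", object@binCounts[i], "\n")
    }
})

#' Export a RateProfile as a data.frame
#'
#' One row per bin with columns `bin_start_my`, `bin_end_my`, `count`,
#' `transposition_rate`, `accumulation`.
#'
#' @param x A `RateProfile`.
#' @param row.names,optional,... Passed for S3 consistency; unused.
#' @return A data.frame with one row per bin.
#' @export
as.data.frame.RateProfile <- function(x, row.names = NULL,
                                      optional = FALSE, ...) {
    nb <- length(x@binCounts)
    data.frame(bin_start_my = x@binEdges[seq_len(nb)],
               bin_end_my = x@binEdges[seq_len(nb) + 1L],
               count = x@binCounts,
               transposition_rate = x@transpositionRate,
               accumulation = x@accumulation)
}

setMethod("as.data.frame", "RateProfile",
    function(x, row.names = NULL, optional = FALSE, ...)
        as.data.frame.RateProfile(x, row.names, optional, ...))
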