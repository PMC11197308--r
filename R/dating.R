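## LTR-pair dating: insertion age T = K / (2 mu) from the divergence of
## an element's two terminal repeats, which were identical at insertion.

#' Per-site divergence between two aligned LTR copies
#'
#' Compares two equal-length aligned sequences over \{A, C, G, T, N, -\},
#' excluding every column that contains a gap or an N in either sequence,
#' and returns the number of retained columns, the mismatch count, and
#' the uncorrected p-distance.
#'
#' @param ltr5,ltr3 Aligned sequences (character scalars, DNAString, or
#'   anything `as.character()` turns into one). Must have equal length.
#' @param gap_policy Column-handling policy; only `"exclude-columns"` is
#'   implemented (gap/N columns dropped before counting).
#' @return A list with `aligned_length` (retained columns), `mismatches`
#'   and `p_distance`.
#' @examples
#' pairwiseDivergence("ACGTACGTAC", "ACGTACGTAC")$p_distance  # 0
#' pairwiseDivergence("AAAA", "AAAT")$p_distance              # 0.25
#' @export
pairwiseDivergence <- function(ltr5, ltr3, gap_policy = "exclude-columns") {
    gap_policy <- match.arg(gap_policy)
    a <- charToRaw(toupper(as.character(ltr5)))
    b <- charToRaw(toupper(as.character(ltr3)))
    if (length(a) != length(b))
        stop("aligned sequences must have equal length (",
             length(a), " vs ", length(b), ")")
    ok <- charToRaw("ACGTN-")
    if (!all(a %in% ok) || !all(b %in% ok))
        stop("sequences must be over the alphabet {A,C,G,T,N,-}")
    excl <- charToRaw("N-")
    keep <- !(a %in% excl | b %in% excl)
    n <- sum(keep)
    if (n == 0L)
        stop("no alignment columns retained after gap/N exclusion")
    mm <- sum(a[keep] != b[keep])
    list(aligned_length = n, mismatches = mm, p_distance = mm / n)
}

#' Jukes-Cantor correction of a p-distance
#'
#' K = -(3/4) * log(1 - 4p/3), the expected number of substitutions per
#' site under the one-parameter model, correcting the raw mismatch
#' fraction for multiple hits. Defined for 0 <= p < 0.75.
#'
#' @param p Numeric vector of p-distances.
#' @return Numeric vector of corrected distances K (substitutions/site).
#' @examples
#' jcCorrect(0)      # 0
#' jcCorrect(0.02)   # ~0.020271
#' @export
jcCorrect <- function(p) {
    if (any(p < 0 | p >= 0.75))
        stop("Jukes-Cantor correction is defined for 0 <= p < 0.75")
    -0.75 * log1p(-4 * p / 3)
}

#' Insertion time from LTR-pair divergence
#'
#' T = K / (2 mu), reported in million years: the two LTRs were
#' identical at insertion and each has accumulated substitutions at the
#' per-site per-year rate mu since, so their divergence K corresponds to
#' 2 mu T.
#'
#' @param K Substitutions per site (vector).
#' @param mu Per-site per-year mutation rate; the default 4e-9 is the
#'   approximate Rosaceae rate.
#' @return Insertion age(s) in million years.
#' @examples
#' insertionTime(0.008)  # 1 MY at mu = 4e-9
#' @export
insertionTime <- function(K, mu = 4e-9) {
    stopifnot(mu > 0)
    if (any(K < 0)) stop("K must be non-negative")
    K / (2 * mu) / 1e6
}

#' Date a set of LTR pairs
#'
#' Takes paired aligned LTR sequences named `<element_id>__5ltr` /
#' `<element_id>__3ltr`, computes per-element p-distance (gap/N columns
#' excluded), applies the Jukes-Cantor correction (or keeps the raw
#' p-distance with `model = "raw"`), and converts to age in million
#' years via T = K/(2 mu).
#'
#' @param seqs A named DNAStringSet or named character vector of aligned
#'   LTR sequences.
#' @param mu Per-site per-year mutation rate (default 4e-9).
#' @param model `"JC69"` (default) or `"raw"` (diagnostic; K = p).
#' @return A data.frame with columns `element_id`, `aligned_length`,
#'   `mismatches`, `p_distance`, `K`, `age_my`.
#' @export
dateLTRPairs <- function(seqs, mu = 4e-9, model = c("JC69", "raw")) {
    model <- match.arg(model)
    nm <- names(seqs)
    if (is.null(nm)) stop("sequences must be named <element_id>__5ltr/__3ltr")
    is5 <- grepl("__5ltr$", nm)
    is3 <- grepl("__3ltr$", nm)
    if (!all(is5 | is3))
        stop("sequence names must end in __5ltr or __3ltr")
    ids5 <- sub("__5ltr$", "", nm[is5])
    ids3 <- sub("__3ltr$", "", nm[is3])
    ids <- intersect(ids5, ids3)
    orphan <- c(setdiff(ids5, ids3), setdiff(ids3, ids5))
    if (length(orphan))
        warning("unpaired LTR sequence(s) skipped: ",
                paste(orphan, collapse = ", "))
    s <- as.character(seqs)
    names(s) <- nm
    res <- lapply(ids, function(id) {
        d <- pairwiseDivergence(s[paste0(id, "__5ltr")],
                                s[paste0(id, "__3ltr")])
        K <- if (model == "JC69") jcCorrect(d$p_distance) else d$p_distance
        data.frame(element_id = id,
                   aligned_length = d$aligned_length,
                   mismatches = d$mismatches,
                   p_distance = d$p_distance,
                   K = K,
                   age_my = insertionTime(K, mu))
    })
    do.call(rbind, res)
}

#' Solo-LTR to intact-element ratio
#'
#' The abundance of solo LTRs (single terminal repeats left by unequal
#' homologous recombination) relative to intact elements measures the
#' propensity of recombination-mediated LTR-RT removal in a genome.
#'
#' @param n_solo,n_intact Non-negative counts (vectors recycle).
#' @param digits Decimal places in the reported ratio (default 2).
#' @return `n_solo / n_intact`, rounded to `digits`.
#' @examples
#' soloIntactRatio(1132, 100)  # 11.32
#' @export
soloIntactRatio <- function(n_solo, n_intact, digits = 2) {
    if (any(n_solo < 0)) stop("n_solo must be non-negative")
    if (any(n_intact == 0))
        stop("n_intact is zero: no intact elements in this genome, ",
             "ratio undefined")
    if (any(n_intact < 0)) stop("n_intact must be positive")
    round(n_solo / n_intact, digits)
}
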