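## Transposition dynamics: binned age profiles, burst statistics,
## young/old splits, and TE-count vs genome-size correlations.

#' @importFrom stats median cor.test
NULL

#' Build a binned transposition/accumulation profile
#'
#' Bins element ages into 0.1-MY intervals over a 0--10 MY window
#' (left-closed right-open bins; the last bin additionally includes ages
#' exactly at the window edge). The transposition rate of a bin is the
#' fraction of in-window elements dated to it — the net increase in
#' surviving elements per 0.1 MY relative to the in-window total — and
#' the accumulation profile gives, at each bin's left edge t, the
#' fraction of in-window elements at least t MY old (1 at t = 0).
#' Elements older than the window are excluded from normalization but
#' counted in `nOlder`.
#'
#' @param ages Numeric vector of non-negative element ages (million years).
#' @param window_my Window length in MY (default 10).
#' @param bin_my Bin width in MY (default 0.1).
#' @param cumulative Accumulation reported as `"fraction"` (default) of
#'   in-window elements or as raw `"count"`.
#' @return A [RateProfile] object.
#' @examples
#' p <- buildRateProfile(c(0.05, 0.05, 0.15))
#' binCounts(p)[1:2]            # 2, 1
#' sum(transpositionRate(p))    # 1
#' @export
buildRateProfile <- function(ages, window_my = 10, bin_my = 0.1,
                             cumulative = c("fraction", "count")) {
    cumulative <- match.arg(cumulative)
    stopifnot(window_my > 0, bin_my > 0)
    ages <- as.numeric(ages)
    if (any(ages < 0, na.rm = TRUE)) stop("ages must be non-negative")
    ages <- ages[!is.na(ages)]
    nb <- as.integer(round(window_my / bin_my))
    # round the edge grid so ages printed at bin boundaries (0.1, 0.3,
    # 0.7, ...) land in their left-closed bin despite binary rounding
    edges <- round((0:nb) * bin_my, 10)
    inwin <- ages[ages <= window_my]
    older <- length(ages) - length(inwin)

    # findInterval: left-closed right-open bins, window edge into last bin
    idx <- findInterval(inwin, edges, rightmost.closed = TRUE)
    counts <- tabulate(idx, nbins = nb)
    n <- length(inwin)
    rate <- if (n > 0L) counts / n else rep(0, nb)
    acc_count <- rev(cumsum(rev(counts)))  # elements with age >= left edge
    acc <- if (cumulative == "fraction") {
        if (n > 0L) acc_count / n else rep(0, nb)
    } else as.numeric(acc_count)

    new("RateProfile", binEdges = edges, binCounts = as.integer(counts),
        transpositionRate = rate, accumulation = acc,
        ages = inwin, nWindow = as.integer(n), nOlder = as.integer(older))
}

#' Burst statistics of a rate profile
#'
#' The estimated transposition burst is summarized by the median
#' in-window age and by the midpoint of the modal 0.1-MY bin (ties
#' broken toward the younger bin).
#'
#' @param profile A [RateProfile] with a non-empty window.
#' @return A list with `median_age_my` and `modal_bin_midpoint_my`.
#' @examples
#' estimateBurst(buildRateProfile(c(1, 2, 3)))$median_age_my  # 2
#' @export
estimateBurst <- function(profile) {
    stopifnot(is(profile, "RateProfile"))
    if (profile@nWindow == 0L)
        stop("empty window: no elements dated within the profile window")
    i <- which.max(profile@binCounts)  # first max = youngest on ties
    list(median_age_my = median(profile@ages),
         modal_bin_midpoint_my =
             (profile@binEdges[i] + profile@binEdges[i + 1L]) / 2)
}

#' Split elements into young and old halves by insertion age
#'
#' Elements at or below the median age (the top 50% of the insertion-time
#' range, i.e. the most recent insertions) are labeled `young`, the rest
#' `old`. Ties at the median go to `young`.
#'
#' @param ages Named (or unnamed) numeric vector of ages; at least 2.
#' @return A character vector of `"young"`/`"old"` labels, named like
#'   `ages`.
#' @examples
#' youngOldSplit(c(a = 1, b = 2, c = 3, d = 4))
#' @export
youngOldSplit <- function(ages) {
    if (length(ages) < 2L) stop("need at least 2 elements to split")
    if (any(ages < 0)) stop("ages must be non-negative")
    med <- median(ages)
    lab <- ifelse(ages <= med, "young", "old")
    if (length(unique(ages)) == 1L)
        warning("all ages identical; every element labeled young")
    names(lab) <- names(ages)
    lab
}

#' Correlate TE category counts with genome size
#'
#' Spearman rank correlation (average-rank tie handling, two-sided
#' asymptotic p-values) of each TE category's copy number against genome
#' size across genomes. Constant categories have undefined rank
#' correlation and are reported as `NA` with a warning.
#'
#' @param counts Numeric matrix, genomes x TE categories (column names =
#'   category labels). At least 4 genomes.
#' @param genome_sizes Numeric vector of genome sizes, one per row of
#'   `counts`.
#' @return A data.frame with one row per category: `category`, `rho`,
#'   `p_value`, `n`.
#' @examples
#' m <- cbind(retro = c(1, 2, 3, 5, 4))
#' correlateGenomeSize(m, 1:5)$rho  # 0.9
#' @export
correlateGenomeSize <- function(counts, genome_sizes) {
    counts <- as.matrix(counts)
    if (nrow(counts) < 4L) stop("need at least 4 genomes")
    if (length(genome_sizes) != nrow(counts))
        stop("genome_sizes must match rows of counts")
    if (any(counts < 0)) stop("category counts must be non-negative")
    cats <- colnames(counts)
    if (is.null(cats)) cats <- paste0("category", seq_len(ncol(counts)))
    res <- lapply(seq_len(ncol(counts)), function(j) {
        x <- counts[, j]
        if (length(unique(x)) == 1L) {
            warning("category '", cats[j],
                    "' is constant; rank correlation undefined")
            return(data.frame(category = cats[j], rho = NA_real_,
                              p_value = NA_real_, n = length(x)))
        }
        ct <- suppressWarnings(
            cor.test(x, genome_sizes, method = "spearman",
                     alternative = "two.sided", exact = FALSE))
        data.frame(category = cats[j], rho = unname(ct$estimate),
                   p_value = ct$p.value, n = length(x))
    })
    do.call(rbind, res)
}
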