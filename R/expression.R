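## Domain-completeness and expression-behaviour classification of
## LTR retrotransposons.

#' Classify elements by protein-domain completeness
#'
#' An autonomous LTR retrotransposon encodes five protein domains (GAG,
#' AP, INT, RT, RH). Elements retaining all five are `structure_intact`,
#' those retaining at least one are `domain_existent`, and those with
#' none are `no_domain`. Every structure-intact element therefore also
#' satisfies the domain-existent criterion.
#'
#' @param domain_table A data.frame with `element_id` and `domain`
#'   columns (see [readDomainTable()]).
#' @param element_ids Character vector of all annotated element ids;
#'   elements absent from the table are `no_domain`. Table rows whose
#'   element is not annotated trigger a warning and are reported, not
#'   classified.
#' @return A data.frame with columns `element_id`, `n_domains`, `status`.
#' @examples
#' tab <- data.frame(element_id = c(rep("e1", 5), "e2"),
#'                   domain = c("GAG", "AP", "INT", "RT", "RH", "RT"))
#' classifyDomainStatus(tab, c("e1", "e2", "e3"))$status
#' @export
classifyDomainStatus <- function(domain_table, element_ids) {
    bad <- which(!domain_table$domain %in% LTR_DOMAINS)
    if (length(bad))
        stop("invalid domain name(s): ",
             paste(unique(domain_table$domain[bad]), collapse = ", "))
    unknown <- setdiff(unique(domain_table$element_id), element_ids)
    if (length(unknown))
        warning("domain-table element(s) absent from the annotation: ",
                paste(unknown, collapse = ", "))
    tab <- domain_table[domain_table$element_id %in% element_ids, ]
    # one domain counts once however many rows repeat it
    nd <- vapply(split(tab$domain, tab$element_id),
                 function(d) length(unique(d)), integer(1))
    n <- nd[match(element_ids, names(nd))]
    n[is.na(n)] <- 0L
    status <- rep("no_domain", length(element_ids))
    status[n >= 1L] <- "domain_existent"
    status[n == 5L] <- "structure_intact"
    data.frame(element_id = element_ids, n_domains = unname(n),
               status = status)
}

#' Filter features that are ever expressed
#'
#' Keeps features whose expression exceeds `min_tpm` in at least one
#' sample (strict inequality), the selection rule for elements expressed
#' anywhere across conditions. `mode = "all"` instead requires every
#' sample to exceed the threshold.
#'
#' @param x Expression container ([tpmMatrix()]-compatible).
#' @param min_tpm TPM threshold (default 1, strict `>`).
#' @param mode `"any"` (default) or `"all"` sample rule.
#' @return Character vector of retained feature ids.
#' @export
filterExpressed <- function(x, min_tpm = 1, mode = c("any", "all")) {
    mode <- match.arg(mode)
    m <- tpmMatrix(x)
    keep <- if (mode == "any") apply(m > min_tpm, 1L, any)
            else apply(m > min_tpm, 1L, all)
    rownames(m)[keep]
}

#' Flag highly expressed cells
#'
#' A cell is highly expressed when log2(TPM + 1) >= `threshold_log2`
#' (default 3.5, i.e. TPM >= 2^3.5 - 1 ~ 10.31; inclusive).
#'
#' @param x Expression container ([tpmMatrix()]-compatible).
#' @param threshold_log2 Threshold on log2(TPM + 1) (default 3.5).
#' @return A logical matrix with the dimensions of the input.
#' @examples
#' flagHighExpression(matrix(c(0, 2^3.5 - 1, 10, 50), 2,
#'                    dimnames = list(c("a", "b"), c("s1", "s2"))))
#' @export
flagHighExpression <- function(x, threshold_log2 = 3.5) {
    m <- tpmMatrix(x)
    if (any(m < 0)) stop("TPM must be non-negative")
    log2(m + 1) >= threshold_log2
}

#' Expression specificity (tau) of a feature
#'
#' tau = sum(1 - x_i / max(x)) / (n - 1) computed on log2(TPM + 1)
#' values: 0 for a uniform profile, 1 when exactly one sample is
#' non-zero. A feature is called specific when tau meets the threshold.
#' tau is invariant to global scaling of the row and only defined for
#' expressed features with at least two samples.
#'
#' @param tpm Numeric vector of TPM values across samples (>= 2).
#' @param threshold Specificity call threshold on tau (default 0.85;
#'   a package default, not a literature constant).
#' @return A list with `tau` and `specific`.
#' @examples
#' expressionSpecificity(c(100, 0, 0, 0))$tau   # 1
#' expressionSpecificity(c(5, 5, 5, 5))$tau     # 0
#' @export
expressionSpecificity <- function(tpm, threshold = 0.85) {
    if (length(tpm) < 2L) stop("tau needs at least 2 samples")
    if (any(tpm < 0)) stop("TPM must be non-negative")
    x <- log2(tpm + 1)
    mx <- max(x)
    if (mx == 0) stop("feature is not expressed; tau undefined")
    tau <- sum(1 - x / mx) / (length(x) - 1L)
    list(tau = tau, specific = tau >= threshold)
}

#' Per-element expression summary table
#'
#' Combines domain status, expressed/high flags and specificity into
#' one row per element: the per-element classification used downstream.
#'
#' @param x Expression container ([tpmMatrix()]-compatible), features x
#'   samples.
#' @param domain_table Optional domain table (see [readDomainTable()]).
#' @param min_tpm Expressed threshold (strict `>`, default 1).
#' @param threshold_log2 High-expression threshold on log2(TPM+1).
#' @param tau_threshold Specificity threshold on tau.
#' @return A data.frame with one row per feature: `element_id`,
#'   `status` (if domains supplied), `expressed`, `n_high_samples`,
#'   `tau`, `specific` (tau columns `NA` for unexpressed features).
#' @export
classifyExpression <- function(x, domain_table = NULL, min_tpm = 1,
                               threshold_log2 = 3.5, tau_threshold = 0.85) {
    m <- tpmMatrix(x)
    ids <- rownames(m)
    expressed <- ids %in% filterExpressed(m, min_tpm)
    high <- flagHighExpression(m, threshold_log2)
    tau <- rep(NA_real_, length(ids))
    spec <- rep(NA, length(ids))
    for (i in which(expressed & ncol(m) >= 2L)) {
        s <- expressionSpecificity(m[i, ], tau_threshold)
        tau[i] <- s$tau
        spec[i] <- s$specific
    }
    out <- data.frame(element_id = ids,
                      expressed = expressed,
                      n_high_samples = rowSums(high),
                      tau = tau, specific = spec)
    if (!is.null(domain_table)) {
        ds <- classifyDomainStatus(domain_table, ids)
        out$status <- ds$status[match(ids, ds$element_id)]
        out <- out[, c("element_id", "status", "expressed",
                       "n_high_samples", "tau", "specific")]
    }
    rownames(out) <- NULL
    out
}
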