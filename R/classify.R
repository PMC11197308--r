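## Classification of syntenic DEG pairs by the discrepancy and position
## of TEs within the flanking radius of each gene: three main types and
## sixteen positional subtypes.

.POSITIONAL_STATES <- c("NONE", "UP", "DOWN", "BOTH")

#' Classify one syntenic DEG pair
#'
#' The main type compares total proximal-TE counts between the two
#' cultivars: Type I when cultivar A's gene has more proximal TEs than
#' its partner, Type II when fewer, Type III when the counts are equal.
#' The subtype is the ordered pair of positional states
#' (NONE/UP/DOWN/BOTH for each side), one of 16. Type IIIa is the
#' no-TEs-on-either-side case, subtype (NONE, NONE).
#'
#' @param state_a,state_b Positional states of the two genes.
#' @param n_a,n_b Total proximal-TE counts (must be consistent with the
#'   states: 0 iff NONE).
#' @return A list with `main_type` (`"I"`, `"II"`, `"III"`), `subtype`
#'   (`"UP|NONE"` etc.), `iii_alpha`.
#' @examples
#' classifyPair("UP", "NONE", 1, 0)   # Type I
#' classifyPair("UP", "UP", 1, 3)     # Type II despite equal states
#' @export
classifyPair <- function(state_a, state_b, n_a, n_b) {
    if (!state_a %in% .POSITIONAL_STATES ||
        !state_b %in% .POSITIONAL_STATES)
        stop("states must be one of NONE/UP/DOWN/BOTH")
    if ((state_a == "NONE") != (n_a == 0L) ||
        (state_b == "NONE") != (n_b == 0L))
        stop("positional state inconsistent with TE count")
    main <- if (n_a > n_b) "I" else if (n_a < n_b) "II" else "III"
    list(main_type = main,
         subtype = paste(state_a, state_b, sep = "|"),
         iii_alpha = n_a == 0L && n_b == 0L)
}

#' Classify all syntenic DEG pairs of a two-cultivar landscape
#'
#' Runs [assignTEProximity()] on each cultivar, derives per-gene
#' positional states, and classifies every DEG pair by [classifyPair()].
#'
#' @param genesA,genesB GRanges of gene bodies (`gene_id` column) for
#'   the two cultivars.
#' @param tesA,tesB GRanges/[TEAnnotation] of TEs per cultivar.
#' @param deg_pairs A data.frame with `gene_a`, `gene_b` (DEG pairs
#'   through synteny anchors).
#' @param radius Flanking radius in bp (default 5000, strict `<`).
#' @param ltr_only Count only LTR-order TEs toward the states (default
#'   `FALSE`: all TE orders count).
#' @return A list with `pairs` (one classified row per DEG pair:
#'   states, counts, `main_type`, `subtype`, `iii_alpha`) and `summary`
#'   (a list with `by_type` and `by_subtype` count tables).
#' @export
classifyAllPairs <- function(genesA, genesB, tesA, tesB, deg_pairs,
                             radius = 5000, ltr_only = FALSE) {
    missA <- setdiff(deg_pairs$gene_a, mcols(genesA)$gene_id)
    missB <- setdiff(deg_pairs$gene_b, mcols(genesB)$gene_id)
    if (length(missA) || length(missB))
        stop("unresolvable gene id(s) in DEG pairs: ",
             paste(c(missA, missB), collapse = ", "))
    if (ltr_only) {
        tesA <- tesA[mcols(tesA)$te_order == "LTR"]
        tesB <- tesB[mcols(tesB)$te_order == "LTR"]
    }
    recA <- assignTEProximity(genesA, tesA, radius)
    recB <- assignTEProximity(genesB, tesB, radius)
    stA <- positionalState(deg_pairs$gene_a, recA)
    stB <- positionalState(deg_pairs$gene_b, recB)

    n <- nrow(deg_pairs)
    out <- data.frame(gene_a = deg_pairs$gene_a,
                      gene_b = deg_pairs$gene_b,
                      state_a = stA$state, state_b = stB$state,
                      n_a = stA$n_up + stA$n_down,
                      n_b = stB$n_up + stB$n_down,
                      stringsAsFactors = FALSE)
    cls <- Map(classifyPair, out$state_a, out$state_b, out$n_a, out$n_b)
    out$main_type <- vapply(cls, `[[`, "", "main_type")
    out$subtype <- vapply(cls, `[[`, "", "subtype")
    out$iii_alpha <- vapply(cls, `[[`, NA, "iii_alpha")

    subtypes <- as.vector(outer(.POSITIONAL_STATES, .POSITIONAL_STATES,
                                function(a, b) paste(a, b, sep = "|")))
    by_type <- vapply(c("I", "II", "III"),
                      function(t) sum(out$main_type == t), integer(1))
    by_subtype <- vapply(subtypes,
                         function(s) sum(out$subtype == s), integer(1))
    list(pairs = out,
         summary = list(by_type = by_type, by_subtype = by_subtype,
                        n_pairs = n,
                        n_iii_alpha = sum(out$iii_alpha)))
}
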