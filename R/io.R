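#' @importFrom utils read.delim write.table count.fields
#' @importFrom Biostrings readDNAStringSet writeXStringSet DNAStringSet
#' @importFrom rtracklayer import export
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
NULL

## Classification mapping ------------------------------------------------

#' Map a GFF3 Classification attribute to order and superfamily
#'
#' Translates EDTA-style classification strings (`LTR/Copia`,
#' `DNA/DTA`, `MITE/DTT`, `DNA/Helitron`, ...) and bare three-letter
#' codes into the package's controlled vocabulary. Anything outside the
#' nine-code vocabulary is mapped to superfamily `"RLU"` when the record
#' is LTR-like and `"unknown"` otherwise, with a warning; records are
#' never dropped for an unrecognized classification.
#'
#' @param classification Character vector of classification strings.
#' @return A data.frame with columns `te_order` and `superfamily`.
#' @examples
#' classifyTEType(c("LTR/Copia", "DNA/DTA", "MITE/DTT", "DNA/Helitron"))
#' @export
classifyTEType <- function(classification) {
    cls <- as.character(classification)
    n <- length(cls)
    ord <- rep("TIR", n)
    sf <- rep("unknown", n)

    is_mite <- grepl("^MITE", cls, ignore.case = TRUE)
    is_ltr <- grepl("^LTR", cls, ignore.case = TRUE) |
        cls %in% c("RLC", "RLG", "RLU")
    is_line <- grepl("LINE", cls, ignore.case = TRUE)
    is_hel <- grepl("Helitron|DHH", cls, ignore.case = TRUE)

    ord[is_ltr] <- "LTR"
    ord[is_mite] <- "MITE"
    ord[is_hel] <- "Helitron"
    ord[is_line] <- "LINE"

    sf[is_ltr] <- "RLU"
    sf[grepl("Copia", cls, ignore.case = TRUE) | cls == "RLC"] <- "RLC"
    sf[grepl("Gypsy", cls, ignore.case = TRUE) | cls == "RLG"] <- "RLG"
    sf[is_hel] <- "DHH"
    for (code in c("DTA", "DTC", "DTH", "DTM", "DTT")) {
        hit <- grepl(code, cls, fixed = TRUE)
        sf[hit] <- code
        ord[hit & !is_mite] <- "TIR"
        ord[hit & is_mite] <- "MITE"
    }
    sf[grepl("hAT", cls)] <- "DTA"
    sf[grepl("CACTA", cls, ignore.case = TRUE)] <- "DTC"
    sf[grepl("Harbinger|PIF", cls, ignore.case = TRUE)] <- "DTH"
    sf[grepl("Mutator", cls, ignore.case = TRUE)] <- "DTM"
    sf[grepl("Tc1|Mariner", cls, ignore.case = TRUE)] <- "DTT"

    unknown <- sf == "unknown" & !is_line
    if (any(unknown))
        warning("classification(s) outside the nine-code vocabulary ",
                "mapped to 'unknown': ",
                paste(unique(cls[unknown]), collapse = ", "))
    data.frame(te_order = ord, superfamily = sf,
               stringsAsFactors = FALSE)
}

## GFF3 ------------------------------------------------------------------

.GFF3_LTR_ATTRS <- c("ltr5_start", "ltr5_end", "ltr3_start", "ltr3_end")

# Validate raw GFF3 lines; drop records with end < start (warning),
# stop on malformed lines naming the line number. Returns a path to a
# cleaned temporary copy (or the original when untouched).
.precheckGFF3 <- function(path) {
    lines <- readLines(path)
    body <- !startsWith(lines, "#") & nzchar(lines)
    fields <- strsplit(lines[body], "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf != 9L)) {
        bad <- which(body)[which(nf != 9L)[1L]]
        stop("malformed GFF3 line ", bad, " in ", path,
             ": expected 9 tab-separated fields, found ", nf[nf != 9L][1L])
    }
    starts <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 4L)))
    ends <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 5L)))
    if (anyNA(starts) || anyNA(ends)) {
        bad <- which(body)[which(is.na(starts) | is.na(ends))[1L]]
        stop("malformed GFF3 line ", bad, " in ", path,
             ": non-numeric start/end")
    }
    drop <- ends < starts
    if (any(drop)) {
        warning(sum(drop), " GFF3 record(s) with end < start rejected")
        keep <- rep(TRUE, length(lines))
        keep[which(body)[drop]] <- FALSE
        tmp <- tempfile(fileext = ".gff3")
        writeLines(lines[keep], tmp)
        return(tmp)
    }
    path
}

#' Read a TE annotation from GFF3
#'
#' Parses an EDTA-style TE GFF3: one record per element carrying a
#' `Classification` attribute (e.g. `LTR/Copia`), with LTR
#' sub-coordinates supplied either as `ltr5_start`/`ltr5_end`/
#' `ltr3_start`/`ltr3_end` attributes on the element record or as child
#' records of type `long_terminal_repeat` pointing at the element via
#' `Parent`. Coordinates follow the GFF3 convention (1-based closed) and
#' are stored unchanged in the returned GRanges-based object.
#'
#' @param path Path to a GFF3 file.
#' @return A [TEAnnotation] object.
#' @seealso [writeTEGFF3()] for the inverse; read-write-read round trips
#'   are identity on the record set.
#' @export
readTEGFF3 <- function(path) {
    gr <- rtracklayer::import(.precheckGFF3(path), format = "gff3")
    mc <- mcols(gr)
    is_child <- !is.na(mc$type) & mc$type == "long_terminal_repeat"
    main <- gr[!is_child]
    mm <- mcols(main)

    te_id <- if ("ID" %in% colnames(mm)) as.character(mm$ID) else NULL
    if (is.null(te_id) || anyNA(te_id))
        stop("every TE record needs an ID attribute")
    cls_col <- intersect(c("Classification", "classification"), colnames(mm))
    if (!length(cls_col))
        stop("TE records must carry a Classification attribute")
    typed <- classifyTEType(as.character(mm[[cls_col[1L]]]))

    out <- GRanges(seqnames(main), IRanges(start(main), end(main)),
                   strand = strand(main))
    mcols(out)$te_id <- te_id
    mcols(out)$te_order <- typed$te_order
    mcols(out)$superfamily <- typed$superfamily
    if ("family" %in% colnames(mm))
        mcols(out)$family <- as.character(mm$family)

    for (a in .GFF3_LTR_ATTRS)
        mcols(out)[[a]] <- if (a %in% colnames(mm))
            suppressWarnings(as.integer(mm[[a]])) else NA_integer_

    children <- gr[is_child]
    if (length(children)) {
        parent <- vapply(mcols(children)$Parent, `[`, "", 1L)
        for (id in unique(parent)) {
            kids <- children[parent == id]
            kids <- kids[order(start(kids))]
            if (length(kids) != 2L) {
                warning("element ", id, " has ", length(kids),
                        " long_terminal_repeat children; expected 2 - skipped")
                next
            }
            i <- match(id, te_id)
            if (is.na(i)) next
            mcols(out)$ltr5_start[i] <- start(kids)[1L]
            mcols(out)$ltr5_end[i] <- end(kids)[1L]
            mcols(out)$ltr3_start[i] <- start(kids)[2L]
            mcols(out)$ltr3_end[i] <- end(kids)[2L]
        }
    }
    if (all(is.na(mcols(out)$ltr5_start)))
        for (a in .GFF3_LTR_ATTRS) mcols(out)[[a]] <- NULL
    if ("age_my" %in% colnames(mm))
        mcols(out)$age_my <- suppressWarnings(as.numeric(mm$age_my))
    TEAnnotation(sort(out, ignore.strand = TRUE))
}

.ORDER_TO_SOTYPE <- c(LTR = "LTR_retrotransposon",
                      TIR = "terminal_inverted_repeat_element",
                      MITE = "MITE",
                      Helitron = "helitron",
                      LINE = "LINE_element")
.SF_TO_CLASSIFICATION <- c(RLC = "LTR/Copia", RLG = "LTR/Gypsy",
                           RLU = "LTR/unknown", DTA = "DNA/DTA",
                           DTC = "DNA/DTC", DTH = "DNA/DTH",
                           DTM = "DNA/DTM", DTT = "DNA/DTT",
                           DHH = "DNA/Helitron", unknown = "Unknown")

#' Write a TE annotation to GFF3
#'
#' Emits one record per element with `ID`, `Classification` and (where
#' present) LTR sub-coordinate and `age_my` attributes, so that
#' [readTEGFF3()] recovers the identical record set.
#'
#' @param x A [TEAnnotation].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeTEGFF3 <- function(x, path) {
    stopifnot(is(x, "TEAnnotation"))
    out <- GRanges(seqnames(x), IRanges(start(x), end(x)),
                   strand = strand(x))
    mc <- mcols(x)
    mcols(out)$source <- "TEdynamics"
    mcols(out)$type <- .ORDER_TO_SOTYPE[mc$te_order]
    mcols(out)$ID <- mc$te_id
    cls <- .SF_TO_CLASSIFICATION[mc$superfamily]
    cls[mc$superfamily == "unknown" & mc$te_order == "MITE"] <- "MITE/unknown"
    cls[mc$te_order == "MITE" & mc$superfamily != "unknown"] <-
        paste0("MITE/", mc$superfamily[mc$te_order == "MITE" &
                                       mc$superfamily != "unknown"])
    cls[mc$te_order == "LINE"] <- "LINE/unknown"
    mcols(out)$Classification <- unname(cls)
    for (a in c("family", .GFF3_LTR_ATTRS, "age_my"))
        if (a %in% colnames(mc)) mcols(out)[[a]] <- mc[[a]]
    rtracklayer::export(out, path, format = "gff3")
    invisible(path)
}

#' Read gene models from GFF3
#'
#' Keeps records of type `gene`; the gene body is treated as a single
#' interval (no intron/exon structure).
#'
#' @param path Path to a GFF3 file.
#' @return A GRanges with a `gene_id` metadata column.
#' @export
readGeneGFF3 <- function(path) {
    gr <- rtracklayer::import(.precheckGFF3(path), format = "gff3")
    genes <- gr[!is.na(mcols(gr)$type) & mcols(gr)$type == "gene"]
    id <- as.character(mcols(genes)$ID)
    if (anyNA(id)) stop("gene records need an ID attribute")
    out <- GRanges(seqnames(genes), IRanges(start(genes), end(genes)),
                   strand = strand(genes))
    mcols(out)$gene_id <- id
    sort(out, ignore.strand = TRUE)
}

#' Write gene models to GFF3
#'
#' @param genes A GRanges with a `gene_id` column.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeGeneGFF3 <- function(genes, path) {
    out <- granges(genes)
    mcols(out)$source <- "TEdynamics"
    mcols(out)$type <- "gene"
    mcols(out)$ID <- mcols(genes)$gene_id
    rtracklayer::export(out, path, format = "gff3")
    invisible(path)
}

## Expression matrices ---------------------------------------------------

#' Read a TPM expression matrix from TSV
#'
#' Expects a header row of sample identifiers and a first column of
#' feature identifiers. Values must be numeric and non-negative (TPM).
#'
#' @param path Path to a tab-separated file.
#' @param role Optional sample-axis role tag (`"tissue"`,
#'   `"timepoint-days"`, `"treatment-hours"`); stored as metadata.
#' @return A [SummarizedExperiment::SummarizedExperiment] with a single
#'   assay `"tpm"`.
#' @export
readExpressionTSV <- function(path, role = NA_character_) {
    nf <- count.fields(path, sep = "\t", quote = "")
    if (length(unique(nf)) != 1L)
        stop("ragged expression table: rows have differing field counts")
    df <- read.delim(path, header = TRUE, sep = "\t", quote = "",
                     check.names = FALSE, colClasses = "character")
    feats <- df[[1L]]
    if (anyDuplicated(feats))
        stop("duplicated feature id(s): ",
             paste(unique(feats[duplicated(feats)]), collapse = ", "))
    samples <- colnames(df)[-1L]
    if (anyDuplicated(samples))
        stop("duplicated sample id(s)")
    m <- suppressWarnings(
        matrix(as.numeric(as.matrix(df[, -1L, drop = FALSE])),
               nrow = nrow(df),
               dimnames = list(feats, samples)))
    if (anyNA(m)) stop("non-numeric expression value(s)")
    if (any(m < 0)) stop("negative TPM value(s); TPM must be >= 0")
    se <- SummarizedExperiment(assays = list(tpm = m))
    metadata(se)$sample_role <- role
    se
}

#' Write a TPM matrix to TSV
#'
#' @param x A SummarizedExperiment with a `tpm` assay, or a numeric matrix.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeExpressionTSV <- function(x, path) {
    m <- tpmMatrix(x)
    df <- data.frame(feature_id = rownames(m), m, check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Extract the TPM matrix from an expression container
#'
#' @param x A SummarizedExperiment (assay `"tpm"`) or a numeric matrix.
#' @return A numeric matrix, features x samples.
#' @export
tpmMatrix <- function(x) {
    if (is(x, "SummarizedExperiment")) x <- assay(x, "tpm")
    stopifnot(is.matrix(x), is.numeric(x))
    x
}

## Anchors, domain tables, counts ----------------------------------------

#' Read synteny anchors
#'
#' Two-column TSV pairing gene identifiers of cultivar A with their
#' syntenic counterparts in cultivar B. Repeated pairs and repeated
#' genes are deduplicated keeping the first occurrence, so each gene
#' appears in at most one pair.
#'
#' @param path Path to a two-column TSV (no header).
#' @return A data.frame with columns `gene_a`, `gene_b`.
#' @export
readAnchors <- function(path) {
    df <- read.delim(path, header = FALSE, sep = "\t", quote = "",
                     colClasses = "character")
    if (ncol(df) < 2L) stop("anchors file needs two columns")
    df <- data.frame(gene_a = df[[1L]], gene_b = df[[2L]],
                     stringsAsFactors = FALSE)
    keep <- !duplicated(df$gene_a) & !duplicated(df$gene_b)
    df[keep, , drop = FALSE]
}

#' Write synteny anchors
#'
#' @param pairs A data.frame with columns `gene_a`, `gene_b`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeAnchors <- function(pairs, path) {
    write.table(pairs[, c("gene_a", "gene_b")], path, sep = "\t",
                quote = FALSE, row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Read a per-element protein-domain table
#'
#' TSV with header columns `element_id`, `domain` and optionally
#' `clade` (TEsorter-style). Domain names outside the five-name
#' vocabulary (GAG, AP, INT, RT, RH) raise an error naming the rows.
#'
#' @param path Path to the TSV.
#' @return A data.frame with columns `element_id`, `domain`, `clade`.
#' @export
readDomainTable <- function(path) {
    df <- read.delim(path, header = TRUE, sep = "\t", quote = "",
                     colClasses = "character")
    if (!all(c("element_id", "domain") %in% colnames(df)))
        stop("domain table needs element_id and domain columns")
    bad <- which(!df$domain %in% LTR_DOMAINS)
    if (length(bad))
        stop("domain name(s) outside the GAG/AP/INT/RT/RH vocabulary at row(s) ",
             paste(bad, collapse = ", "), ": ",
             paste(unique(df$domain[bad]), collapse = ", "))
    if (!"clade" %in% colnames(df)) df$clade <- NA_character_
    df[, c("element_id", "domain", "clade")]
}

#' Write a protein-domain table
#'
#' @param df A data.frame with `element_id`, `domain` (and optionally
#'   `clade`) columns.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeDomainTable <- function(df, path) {
    if (!"clade" %in% colnames(df)) df$clade <- NA_character_
    write.table(df[, c("element_id", "domain", "clade")], path,
                sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read solo-LTR / intact-element counts
#'
#' TSV with header columns `label`, `n_solo`, `n_intact` (one row per
#' genome or sequence).
#'
#' @param path Path to the TSV.
#' @return A data.frame with the three columns, counts as integers.
#' @export
readSoloCounts <- function(path) {
    df <- read.delim(path, header = TRUE, sep = "\t", quote = "")
    if (!all(c("label", "n_solo", "n_intact") %in% colnames(df)))
        stop("solo-count table needs label, n_solo, n_intact columns")
    df$n_solo <- as.integer(df$n_solo)
    df$n_intact <- as.integer(df$n_intact)
    if (any(df$n_solo < 0 | df$n_intact < 0, na.rm = TRUE) ||
        anyNA(df$n_solo) || anyNA(df$n_intact))
        stop("counts must be non-negative integers")
    df[, c("label", "n_solo", "n_intact")]
}

#' Write solo-LTR / intact-element counts
#'
#' @param df A data.frame with `label`, `n_solo`, `n_intact` columns.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeSoloCounts <- function(df, path) {
    write.table(df[, c("label", "n_solo", "n_intact")], path,
                sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read LTR sequences from FASTA
#'
#' Sequences are uppercased (DNAStringSet normalization). Paired LTRs
#' follow the `<element_id>__5ltr` / `<element_id>__3ltr` naming used by
#' [dateLTRPairs()].
#'
#' @param path Path to an uncompressed FASTA file.
#' @return A [Biostrings::DNAStringSet].
#' @export
readLTRFasta <- function(path) {
    readDNAStringSet(path)
}

#' Write LTR sequences to FASTA
#'
#' @param seqs A named DNAStringSet (or named character vector).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeLTRFasta <- function(seqs, path) {
    if (!is(seqs, "DNAStringSet")) seqs <- DNAStringSet(seqs)
    writeXStringSet(seqs, path)
    invisible(path)
}
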