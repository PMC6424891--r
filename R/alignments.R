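#' @include AllClasses.R AllGenerics.R
#' @importFrom GenomeInfoDb seqlengths seqlengths<- seqlevels
NULL

# Alignment records are represented as a GRanges with metadata columns
# `read_id` (character) and `unique` (logical, never NA): reference,
# 1-based inclusive interval along the reference-consuming span, strand
# from the SAM flag. One range per primary mapped record.

.alignmentGRanges <- function(reference, start, end, strand, read_id,
                              unique) {
    gr <- GRanges(reference, IRanges(start = start, end = end),
                  strand = strand)
    mcols(gr)$read_id <- as.character(read_id)
    mcols(gr)$unique <- as.logical(unique)
    if (anyNA(mcols(gr)$unique))
        stop("uniqueness flag must be definite (no missing values)")
    gr
}

#' Read alignments from SAM or a simplified alignment TSV
#'
#' Reads mapped alignment records into a `GRanges` with metadata columns
#' `read_id` and `unique`. For SAM input, one record is returned per
#' primary mapped alignment; unmapped, secondary and supplementary
#' records are never yielded (secondary mappings inform uniqueness only,
#' through the aligner-reported `NH` tag). Intervals span the
#' reference-consuming length of the alignment (CIGAR M/D/N/=/X), 1-based
#' inclusive.
#'
#' A read is considered uniquely mapped under the default policy
#' (`"nh-mapq"`) iff its record is primary, not supplementary, the `NH`
#' tag is absent or 1, and `MAPQ > 0`. Policies `"nh"` and `"mapq"` use
#' only the respective criterion.
#'
#' The TSV dialect (for small text fixtures) has columns `read_id`,
#' `reference`, `start`, `end`, `unique` (0/1) and optionally `strand`,
#' with 1-based inclusive coordinates and a header line.
#'
#' @param path Path to a SAM (`.sam`) or TSV (`.tsv`/`.txt`) file.
#' @param format `"auto"` (by extension), `"sam"` or `"tsv"`.
#' @param uniquePolicy Uniqueness policy for SAM input; see Details.
#' @return A `GRanges` with metadata columns `read_id` and `unique`.
#' @seealso [filterAlignments()], [writeSam()], [writeAlignmentsTsv()]
#' @export
readAlignments <- function(path, format = c("auto", "sam", "tsv"),
                           uniquePolicy = c("nh-mapq", "nh", "mapq")) {
    format <- match.arg(format)
    uniquePolicy <- match.arg(uniquePolicy)
    if (!file.exists(path)) stop("alignment file not found: ", path)
    if (format == "auto")
        format <- if (grepl("\\.sam$", path, ignore.case = TRUE)) "sam"
                  else "tsv"
    if (format == "tsv") return(.readAlignmentsTsv(path))
    .readAlignmentsSam(path, uniquePolicy)
}

.readAlignmentsSam <- function(path, uniquePolicy) {
    hdr <- grep("^@", readLines(path, n = 1000L), value = TRUE)
    if (!any(startsWith(hdr, "@SQ")))
        stop("SAM format error in ", path,
             ": missing header (@SQ reference lines required)")
    bam <- tryCatch(
        Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                         indexDestination = FALSE),
        error = function(e) stop("SAM format error in ", path, ": ",
                                 conditionMessage(e), call. = FALSE))
    on.exit(unlink(bam))
    p <- Rsamtools::ScanBamParam(
        what = c("qname", "flag", "rname", "pos", "mapq", "cigar"),
        tag = "NH")
    rec <- Rsamtools::scanBam(bam, param = p)[[1]]
    flag <- rec$flag
    mapped <- bitwAnd(flag, 0x4L) == 0L
    secondary <- bitwAnd(flag, 0x100L) != 0L
    supplementary <- bitwAnd(flag, 0x800L) != 0L
    nh <- rec$tag$NH
    if (is.null(nh)) nh <- rep(NA_integer_, length(flag))
    mapq <- rec$mapq
    mapqOk <- !is.na(mapq) & mapq > 0L
    uniq <- switch(uniquePolicy,
        "nh-mapq" = !secondary & !supplementary &
                    (is.na(nh) | nh == 1L) & mapqOk,
        "nh"      = !secondary & !supplementary & (is.na(nh) | nh == 1L),
        "mapq"    = !secondary & !supplementary & mapqOk)
    keep <- mapped & !secondary & !supplementary
    if (!any(keep))
        return(.alignmentGRanges(character(), integer(), integer(),
                                 character(), character(), logical()))
    refwidth <- GenomicAlignments::cigarWidthAlongReferenceSpace(
        rec$cigar[keep])
    .alignmentGRanges(
        reference = as.character(rec$rname[keep]),
        start = rec$pos[keep],
        end = rec$pos[keep] + refwidth - 1L,
        strand = ifelse(bitwAnd(flag[keep], 0x10L) != 0L, "-", "+"),
        read_id = rec$qname[keep],
        unique = uniq[keep])
}

.readAlignmentsTsv <- function(path) {
    df <- utils::read.delim(path, comment.char = "#",
                            stringsAsFactors = FALSE)
    need <- c("read_id", "reference", "start", "end", "unique")
    if (!all(need %in% colnames(df)))
        stop("alignment TSV ", path, " needs columns: ",
             paste(need, collapse = ", "))
    if (any(df$end < df$start))
        stop("end < start for read_id: ",
             paste(df$read_id[df$end < df$start], collapse = ", "))
    .alignmentGRanges(df$reference, df$start, df$end,
                      if ("strand" %in% colnames(df)) df$strand else "*",
                      df$read_id, df$unique == 1 | df$unique == TRUE)
}

#' Write alignment records as SAM
#'
#' Emits a minimal valid SAM file (header plus one record per range) for
#' alignment records as returned by [readAlignments()] or
#' [simulateAlignments()]. Non-unique records are written with `MAPQ 0`
#' and `NH:i:2` so that re-reading restores the uniqueness flag;
#' unique records get `MAPQ 60` and `NH:i:1`.
#'
#' @param alignments `GRanges` with metadata columns `read_id`, `unique`.
#' @param referenceLengths Named integer vector of reference lengths for
#'   the `@SQ` header lines.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeSam <- function(alignments, referenceLengths, path) {
    refs <- as.character(seqnames(alignments))
    missing <- setdiff(unique(refs), names(referenceLengths))
    if (length(missing))
        stop("no reference length for: ", paste(missing, collapse = ", "))
    hdr <- c("@HD\tVN:1.6\tSO:unknown",
             sprintf("@SQ\tSN:%s\tLN:%d", names(referenceLengths),
                     as.integer(referenceLengths)))
    uniq <- mcols(alignments)$unique
    flag <- ifelse(as.character(strand(alignments)) == "-", 16L, 0L)
    body <- sprintf("%s\t%d\t%s\t%d\t%d\t%dM\t*\t0\t0\t*\t*\tNH:i:%d",
                    mcols(alignments)$read_id, flag, refs,
                    start(alignments), ifelse(uniq, 60L, 0L),
                    width(alignments), ifelse(uniq, 1L, 2L))
    writeLines(c(hdr, body), path)
    invisible(path)
}

#' Write alignment records as the simplified TSV dialect
#'
#' @param alignments `GRanges` with metadata columns `read_id`, `unique`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeAlignmentsTsv <- function(alignments, path) {
    df <- data.frame(read_id = mcols(alignments)$read_id,
                     reference = as.character(seqnames(alignments)),
                     start = start(alignments), end = end(alignments),
                     unique = as.integer(mcols(alignments)$unique),
                     strand = as.character(strand(alignments)))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Apply the read-level filters
#'
#' Removes, in this order, (a) records that do not map to a unique
#' position and (b) records overlapping any rRNA or tRNA feature by at
#' least one nucleotide. All other records pass through unchanged. The
#' returned [FilterStats-class] accounts for every input record exactly
#' once; applying the order deterministically means a non-unique read
#' overlapping an rRNA is counted as non-unique.
#'
#' @param alignments `GRanges` with metadata columns `read_id`, `unique`.
#' @param annotation A [GenomeAnnotation-class] providing the rRNA/tRNA
#'   features.
#' @param stranded If `TRUE`, only same-strand overlaps with rRNA/tRNA
#'   features trigger removal. Default `FALSE` (unstranded).
#' @return A list with elements `alignments` (the retained `GRanges`)
#'   and `stats` (a [FilterStats-class]).
#' @examples
#' ann <- GenomeAnnotation(data.frame(
#'     feature_id = c("orfA", "rrn1"), reference = "chr",
#'     start = c(101, 1001), end = c(700, 2500),
#'     feature_class = c("CDS", "rRNA")))
#' aln <- GenomicRanges::GRanges("chr", IRanges::IRanges(
#'     start = c(150, 990, 300), width = 50))
#' S4Vectors::mcols(aln)$read_id <- c("r1", "r2", "r3")
#' S4Vectors::mcols(aln)$unique <- c(TRUE, TRUE, FALSE)
#' filterAlignments(aln, ann)$stats
#' @export
filterAlignments <- function(alignments, annotation, stranded = FALSE) {
    nIn <- length(alignments)
    uniq <- mcols(alignments)$unique
    if (is.null(uniq))
        stop("alignments must carry a 'unique' metadata column")
    afterUnique <- alignments[uniq]
    excl <- excludedRegions(annotation)
    hit <- IRanges::overlapsAny(afterUnique, excl, minoverlap = 1L,
                                ignore.strand = !stranded)
    retained <- afterUnique[!hit]
    list(alignments = retained,
         stats = FilterStats(
             nInput = nIn,
             nNonUniqueRemoved = nIn - length(afterUnique),
             nRrnaTrnaRemoved = sum(hit),
             nRetained = length(retained)))
}
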