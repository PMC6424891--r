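#' @include AllClasses.R AllGenerics.R
NULL

#' Count reads overlapping each ORF
#'
#' Assigns filtered reads to protein-coding features by the overlap rule:
#' a read counts towards an ORF when its reference interval overlaps the
#' ORF by at least one nucleotide (mapping entirely within or partially
#' covering the ORF). A read overlapping k ORFs increments each of the k
#' counts; the mRNA total `N` counts each read once, as the number of
#' distinct retained reads overlapping at least one protein-coding
#' feature. With `multiOrf = "discard"`, reads overlapping more than one
#' ORF are dropped from both the counts and `N` (a strict mode for
#' sensitivity analysis).
#'
#' @param alignments Filtered `GRanges` of alignment records (see
#'   [filterAlignments()]).
#' @param annotation A [GenomeAnnotation-class].
#' @param sampleId Sample identifier stored in the result.
#' @param multiOrf `"count-each"` (default) or `"discard"`; see Details.
#' @param stranded If `TRUE`, only same-strand overlaps count.
#' @param filterStats Optional [FilterStats-class] carried through into
#'   the result for reporting.
#' @return An [OrfCountTable-class] with a count for every
#'   protein-coding feature (zeros explicit).
#' @examples
#' ann <- GenomeAnnotation(data.frame(
#'     feature_id = "orfA", reference = "chr",
#'     start = 1001, end = 2000, feature_class = "CDS"))
#' aln <- GenomicRanges::GRanges("chr",
#'     IRanges::IRanges(start = c(995, 2001), end = c(1001, 2050)))
#' S4Vectors::mcols(aln)$read_id <- c("r1", "r2")
#' S4Vectors::mcols(aln)$unique <- TRUE
#' counts(countReads(aln, ann, sampleId = "s1"))  # 1-nt overlap counts
#' @export
countReads <- function(alignments, annotation, sampleId = "sample",
                       multiOrf = c("count-each", "discard"),
                       stranded = FALSE, filterStats = NULL) {
    multiOrf <- match.arg(multiOrf)
    cds <- proteinCoding(annotation)
    refs <- unique(as.character(seqnames(alignments)))
    known <- unique(as.character(seqnames(features(annotation))))
    bad <- setdiff(refs, known)
    if (length(bad))
        stop("alignment record(s) on reference absent from annotation: ",
             paste(bad, collapse = ", "))
    hits <- GenomicRanges::findOverlaps(alignments, cds, minoverlap = 1L,
                                        ignore.strand = !stranded)
    perRead <- tabulate(S4Vectors::queryHits(hits), length(alignments))
    if (multiOrf == "discard") {
        keep <- S4Vectors::queryHits(hits) %in% which(perRead == 1L)
        hits <- hits[keep]
        n <- sum(perRead == 1L)
    } else {
        n <- sum(perRead > 0L)
    }
    cvec <- tabulate(S4Vectors::subjectHits(hits), length(cds))
    names(cvec) <- names(cds)
    if (is.null(filterStats))
        filterStats <- FilterStats(length(alignments), 0L, 0L,
                                   length(alignments))
    OrfCountTable(sampleId = sampleId, counts = cvec, totalMrna = n,
                  filterStats = filterStats)
}

#' Relative transcript abundance
#'
#' Computes `r_i = c_i / N` for every protein-coding feature: the number
#' of reads mapping in the ORF divided by the total number of reads
#' mapping within any protein-coding region of the same sample. This is
#' the cross-sample normalization of the pipeline (gene length is
#' constant across samples, but the mRNA total varies with sequencing
#' depth).
#'
#' @param countTable An [OrfCountTable-class] with `totalMrna > 0`.
#' @return Named numeric vector of relative abundances.
#' @export
relativeAbundance <- function(countTable) {
    n <- totalMrnaCounts(countTable)
    if (n == 0L)
        stop("no mRNA-mapping reads in sample ",
             sQuote(sampleId(countTable)))
    counts(countTable) / n
}

#' Hits per kilobase
#'
#' Computes `h_i = c_i * 1000 / L_i`, the ORF's read count normalized by
#' ORF length: the within-sample scale on which transcript levels of
#' different genes are comparable.
#'
#' @param countTable An [OrfCountTable-class].
#' @param annotation The [GenomeAnnotation-class] providing ORF lengths.
#' @return Named numeric vector of hits per kilobase.
#' @export
hitsPerKilobase <- function(countTable, annotation) {
    cvec <- counts(countTable)
    len <- featureLengths(annotation)[names(cvec)]
    if (anyNA(len))
        stop("missing feature length for feature_id: ",
             paste(names(cvec)[is.na(len)], collapse = ", "))
    cvec * 1000 / len
}

#' Both normalizations as an OrfAbundanceTable
#'
#' @param countTable An [OrfCountTable-class].
#' @param annotation The [GenomeAnnotation-class] providing ORF lengths.
#' @return An [OrfAbundanceTable-class] with the relative abundances and
#'   hits per kilobase of the sample.
#' @export
orfAbundance <- function(countTable, annotation) {
    new("OrfAbundanceTable",
        sampleId = sampleId(countTable),
        relAbundance = relativeAbundance(countTable),
        hitsPerKb = hitsPerKilobase(countTable, annotation))
}

#' Serialize a sample's counts and abundances to TSV
#'
#' Writes the per-sample table (columns `feature_id`, `count`,
#' `relative_abundance`, `hits_per_kb`) with `#key=value` header
#' comments carrying the sample id, mRNA total and filter statistics.
#'
#' @param countTable An [OrfCountTable-class].
#' @param annotation The matching [GenomeAnnotation-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeCountTable <- function(countTable, annotation, path) {
    ab <- orfAbundance(countTable, annotation)
    fs <- as.list(filterStats(countTable))
    hdr <- c(sprintf("#sample_id=%s", sampleId(countTable)),
             sprintf("#total_mrna_counts=%d", totalMrnaCounts(countTable)),
             sprintf("#%s=%d", names(fs), unlist(fs)))
    df <- data.frame(feature_id = names(counts(countTable)),
                     count = unname(counts(countTable)),
                     relative_abundance =
                         .fmtNum(unname(relAbundance(ab))),
                     hits_per_kb = .fmtNum(unname(hitsPerKb(ab))))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(hdr, con)
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read a serialized count table back
#'
#' @param path Path written by [writeCountTable()].
#' @return A list with elements `countTable` (an [OrfCountTable-class])
#'   and `table` (the full data frame).
#' @export
readCountTable <- function(path) {
    lines <- readLines(path)
    meta <- grep("^#", lines, value = TRUE)
    kv <- sub("^#", "", meta)
    keys <- sub("=.*$", "", kv)
    vals <- sub("^[^=]*=", "", kv)
    meta <- stats::setNames(as.list(vals), keys)
    df <- utils::read.delim(text = lines[!startsWith(lines, "#")],
                            stringsAsFactors = FALSE)
    fs <- FilterStats(as.integer(meta$n_input),
                      as.integer(meta$n_non_unique_removed),
                      as.integer(meta$n_rrna_trna_removed),
                      as.integer(meta$n_retained))
    ct <- OrfCountTable(meta$sample_id,
                        stats::setNames(df$count, df$feature_id),
                        as.integer(meta$total_mrna_counts), fs)
    list(countTable = ct, table = df)
}

# Deterministic numeric formatting for byte-stable TSV output.
.fmtNum <- function(x) {
    out <- formatC(x, digits = 12, format = "g")
    out[!is.finite(x)] <- "NA"
    out
}
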