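#' @include AllClasses.R AllGenerics.R
NULL

#' Build a GenomeAnnotation from a GRanges or data frame
#'
#' @param features A `GRanges` named by feature_id with a `featureClass`
#'   metadata column, or a data frame with columns `feature_id`,
#'   `reference`, `start`, `end`, and optionally `strand` and
#'   `feature_class`. Coordinates are 1-based inclusive.
#' @return A [GenomeAnnotation-class] object.
#' @examples
#' df <- data.frame(feature_id = c("orfA", "rrn1"), reference = "chr",
#'                  start = c(101, 901), end = c(700, 2400),
#'                  feature_class = c("CDS", "rRNA"))
#' GenomeAnnotation(df)
#' @export
GenomeAnnotation <- function(features) {
    if (is.data.frame(features)) {
        df <- features
        need <- c("feature_id", "reference", "start", "end")
        if (!all(need %in% colnames(df)))
            stop("annotation data frame needs columns: ",
                 paste(need, collapse = ", "))
        if (any(df$end < df$start))
            stop("end < start for feature_id: ",
                 paste(df$feature_id[df$end < df$start], collapse = ", "))
        gr <- GRanges(df$reference,
                      IRanges(start = df$start, end = df$end),
                      strand = if ("strand" %in% colnames(df))
                          df$strand else "*")
        names(gr) <- df$feature_id
        mcols(gr)$featureClass <-
            if ("feature_class" %in% colnames(df))
                as.character(df$feature_class) else "CDS"
        features <- gr
    }
    new("GenomeAnnotation", features = features)
}

# Feature-type aliases mapping GFF3 'type' values onto the three classes
# the pipeline distinguishes; anything unmatched becomes "other".
.defaultTypeAliases <- function() {
    list(CDS = c("CDS", "ORF", "protein_coding_gene"),
         rRNA = c("rRNA", "rRNA_gene"),
         tRNA = c("tRNA", "tRNA_gene"))
}

#' Read a GFF3 genome annotation
#'
#' Parses a GFF3 file into a [GenomeAnnotation-class]. Feature types are
#' mapped onto the classes `CDS`, `rRNA` and `tRNA` via `typeAliases`;
#' unknown types become class `other`. Coordinates are kept 1-based
#' inclusive exactly as in the file. Feature identifiers are taken from
#' the `ID` attribute, falling back to `locus_tag` then `Name`.
#'
#' @param path Path to a GFF3 file.
#' @param typeAliases Named list mapping each of `CDS`, `rRNA`, `tRNA`
#'   to the GFF3 `type` strings that should count as that class.
#' @return A [GenomeAnnotation-class] object.
#' @examples
#' gff <- tempfile(fileext = ".gff3")
#' writeLines(c("##gff-version 3",
#'   "chr\tsim\tCDS\t101\t700\t.\t+\t0\tID=orfA",
#'   "chr\tsim\trRNA\t901\t2400\t.\t+\t.\tID=rrn1"), gff)
#' readAnnotation(gff)
#' @export
readAnnotation <- function(path, typeAliases = .defaultTypeAliases()) {
    if (!file.exists(path)) stop("annotation file not found: ", path)
    lines <- readLines(path)
    body <- !startsWith(lines, "#") & nzchar(trimws(lines))
    nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
    if (any(nf != 9L)) {
        bad <- which(body)[which(nf != 9L)[1]]
        stop(sprintf("unparseable GFF3 line %d in %s: expected 9 tab-separated fields, found %d",
                     bad, path, nf[nf != 9L][1]))
    }
    fields <- strsplit(lines[body], "\t", fixed = TRUE)
    starts <- suppressWarnings(as.numeric(vapply(fields, `[`,
                                                 character(1), 4L)))
    ends <- suppressWarnings(as.numeric(vapply(fields, `[`,
                                               character(1), 5L)))
    if (anyNA(starts) || anyNA(ends)) {
        bad <- which(body)[which(is.na(starts) | is.na(ends))[1]]
        stop(sprintf("unparseable GFF3 line %d in %s: non-numeric coordinates",
                     bad, path))
    }
    if (any(ends < starts)) {
        i <- which(ends < starts)[1]
        attr9 <- fields[[i]][9]
        id <- sub("^.*ID=([^;]+).*$", "\\1", attr9)
        stop(sprintf("end < start for feature_id: %s (line %d)",
                     id, which(body)[i]))
    }
    gr <- rtracklayer::import(path, format = "gff3")
    ids <- as.character(mcols(gr)$ID)
    if ("locus_tag" %in% colnames(mcols(gr))) {
        lt <- as.character(mcols(gr)$locus_tag)
        ids[is.na(ids)] <- lt[is.na(ids)]
    }
    if ("Name" %in% colnames(mcols(gr))) {
        nm <- as.character(mcols(gr)$Name)
        ids[is.na(ids)] <- nm[is.na(ids)]
    }
    if (anyNA(ids))
        stop("feature(s) without ID/locus_tag/Name attribute in ", path)
    if (anyDuplicated(ids))
        stop("duplicate feature_id: ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    type <- as.character(mcols(gr)$type)
    cls <- rep("other", length(gr))
    for (k in c("CDS", "rRNA", "tRNA"))
        cls[type %in% typeAliases[[k]]] <- k
    out <- granges(gr, use.mcols = FALSE)
    names(out) <- ids
    mcols(out)$featureClass <- cls
    GenomeAnnotation(out)
}

#' Write a GenomeAnnotation to GFF3
#'
#' @param annotation A [GenomeAnnotation-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeAnnotation <- function(annotation, path) {
    gr <- features(annotation)
    cls <- mcols(gr)$featureClass
    out <- granges(gr, use.mcols = FALSE)
    mcols(out)$type <- ifelse(cls == "other", "misc_feature", cls)
    mcols(out)$ID <- names(gr)
    mcols(out)$source <- "orfprop"
    mcols(out)$phase <- ifelse(cls == "CDS", 0L, NA_integer_)
    rtracklayer::export(out, path, format = "gff3")
    invisible(path)
}
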