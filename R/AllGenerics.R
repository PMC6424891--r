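#' @include AllClasses.R
NULL

#' Accessors for pipeline objects
#'
#' Accessor generics for the package's S4 containers: feature sets of a
#' [GenomeAnnotation-class], count/abundance vectors, sample and
#' condition identifiers, and filter statistics.
#'
#' @param x An orfprop S4 object.
#' @return The requested slot content; see the individual methods.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("features", function(x) standardGeneric("features"))

#' @rdname accessors
#' @export
setGeneric("proteinCoding", function(x) standardGeneric("proteinCoding"))

#' @rdname accessors
#' @export
setGeneric("excludedRegions", function(x) standardGeneric("excludedRegions"))

#' @rdname accessors
#' @export
setGeneric("featureLengths", function(x) standardGeneric("featureLengths"))

#' @rdname accessors
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))

#' @rdname accessors
#' @export
setGeneric("conditionId", function(x) standardGeneric("conditionId"))

#' @rdname accessors
#' @export
setGeneric("totalMrnaCounts", function(x) standardGeneric("totalMrnaCounts"))

#' @rdname accessors
#' @export
setGeneric("filterStats", function(x) standardGeneric("filterStats"))

#' @rdname accessors
#' @export
setGeneric("relAbundance", function(x) standardGeneric("relAbundance"))

#' @rdname accessors
#' @export
setGeneric("hitsPerKb", function(x) standardGeneric("hitsPerKb"))

#' @rdname accessors
#' @export
setGeneric("isReplicated", function(x) standardGeneric("isReplicated"))

#' @rdname accessors
#' @export
setGeneric("regulons", function(x) standardGeneric("regulons"))

# -- GenomeAnnotation ---------------------------------------------------

#' @rdname accessors
#' @export
setMethod("features", "GenomeAnnotation", function(x) x@features)

#' @rdname accessors
#' @export
setMethod("proteinCoding", "GenomeAnnotation", function(x)
    x@features[mcols(x@features)$featureClass == "CDS"])

#' @rdname accessors
#' @export
setMethod("excludedRegions", "GenomeAnnotation", function(x)
    x@features[mcols(x@features)$featureClass %in% c("rRNA", "tRNA")])

#' @rdname accessors
#' @export
setMethod("featureLengths", "GenomeAnnotation", function(x)
    stats::setNames(width(x@features), names(x@features)))

setMethod("show", "GenomeAnnotation", function(object) {
    cls <- table(factor(mcols(object@features)$featureClass,
                        levels = .FEATURE_CLASSES))
    cat("GenomeAnnotation with", length(object@features), "features on",
        length(unique(as.character(seqnames(object@features)))),
        "reference(s)\n")
    cat(sprintf("  CDS: %d | rRNA: %d | tRNA: %d | other: %d\n",
                cls["CDS"], cls["rRNA"], cls["tRNA"], cls["other"]))
})

# -- FilterStats --------------------------------------------------------

setMethod("show", "FilterStats", function(object) {
    cat("FilterStats:", object@nInput, "input |",
        object@nNonUniqueRemoved, "non-unique removed |",
        object@nRrnaTrnaRemoved, "rRNA/tRNA removed |",
        object@nRetained, "retained\n")
})

#' Convert FilterStats to a named list (e.g. for JSON reports)
#'
#' @param x A [FilterStats-class] object.
#' @param ... Unused.
#' @return A named list with the four counters.
#' @export
setMethod("as.list", "FilterStats", function(x, ...) {
    list(n_input = x@nInput,
         n_non_unique_removed = x@nNonUniqueRemoved,
         n_rrna_trna_removed = x@nRrnaTrnaRemoved,
         n_retained = x@nRetained)
})

# -- OrfCountTable ------------------------------------------------------

#' @rdname accessors
#' @importFrom BiocGenerics counts
#' @export
setMethod("counts", "OrfCountTable", function(object) object@counts)

#' @rdname accessors
#' @export
setMethod("sampleId", "OrfCountTable", function(x) x@sampleId)

#' @rdname accessors
#' @export
setMethod("totalMrnaCounts", "OrfCountTable", function(x) x@totalMrna)

#' @rdname accessors
#' @export
setMethod("filterStats", "OrfCountTable", function(x) x@filterStats)

setMethod("show", "OrfCountTable", function(object) {
    cat("OrfCountTable for sample", sQuote(object@sampleId), "\n")
    cat("  ", length(object@counts), "ORFs;", object@totalMrna,
        "mRNA-mapping reads (N);", sum(object@counts), "assigned hits\n")
})

# -- OrfAbundanceTable --------------------------------------------------

#' @rdname accessors
#' @export
setMethod("sampleId", "OrfAbundanceTable", function(x) x@sampleId)

#' @rdname accessors
#' @export
setMethod("relAbundance", "OrfAbundanceTable", function(x) x@relAbundance)

#' @rdname accessors
#' @export
setMethod("hitsPerKb", "OrfAbundanceTable", function(x) x@hitsPerKb)

setMethod("show", "OrfAbundanceTable", function(object) {
    cat("OrfAbundanceTable for sample", sQuote(object@sampleId), "\n")
    cat("  ", length(object@relAbundance), "ORFs; sum(r) =",
        format(sum(object@relAbundance), digits = 12), "\n")
})

# -- SampleGroup --------------------------------------------------------

#' @rdname accessors
#' @export
setMethod("conditionId", "SampleGroup", function(x) x@conditionId)

#' @rdname accessors
#' @export
setMethod("isReplicated", "SampleGroup", function(x)
    length(x@samples) >= 2L)

#' @rdname accessors
#' @export
setMethod("length", "SampleGroup", function(x) length(x@samples))

setMethod("show", "SampleGroup", function(object) {
    cat("SampleGroup", sQuote(object@conditionId), "with",
        length(object@samples), "sample(s)",
        if (length(object@samples) >= 2L) "(replicated)" else "", "\n")
})

# -- TruthTable ---------------------------------------------------------

#' @rdname accessors
#' @export
setMethod("regulons", "TruthTable", function(x) x@regulons)

setMethod("show", "TruthTable", function(object) {
    cat("TruthTable:", nrow(object@abundance), "features x",
        ncol(object@abundance), "conditions\n")
    cat("  conditions:", paste(colnames(object@abundance), collapse = ", "),
        "\n")
    if (length(object@regulons))
        cat("  regulons:", paste(sprintf("%s (%d)", names(object@regulons),
            lengths(object@regulons)), collapse = ", "), "\n")
})

setMethod("show", "SimulationConfig", function(object) {
    cat("SimulationConfig:", object@nOrfs, "ORFs on a",
        object@referenceLength, "nt reference;",
        nrow(object@conditions), "conditions; depth",
        format(object@depth, big.mark = ","), "reads/sample\n")
    cat(sprintf("  rRNA fraction %.3g | non-unique fraction %.3g | read length %d | seed %d\n",
                object@rrnaFraction, object@nonUniqueFraction,
                object@readLength, object@seed))
})

setMethod("show", "ThresholdScheme", function(object) {
    cat("ThresholdScheme: up", paste0(object@upLevels, "x", collapse = ", "),
        "| down", paste0(100 * (1 - object@downLevels), "%", collapse = ", "),
        "reduction |", if (object@boundaryInclusive) "inclusive" else
        "exclusive", "boundaries\n")
})
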