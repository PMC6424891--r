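#' @import methods
#' @importFrom S4Vectors mcols mcols<- DataFrame
#' @importFrom GenomicRanges GRanges granges seqnames start end width strand
#' @importFrom IRanges IRanges
NULL

#' GenomeAnnotation: genomic features of a bacterial genome
#'
#' Holds the annotated features of a genome as a [GenomicRanges::GRanges]
#' with one metadata column, `featureClass`, taking values `"CDS"`,
#' `"rRNA"`, `"tRNA"` or `"other"`. Feature identifiers are the names of
#' the `GRanges` and must be unique. Coordinates are 1-based inclusive on
#' both ends, as in GFF3.
#'
#' The protein-coding subset (`featureClass == "CDS"`) is the counting
#' universe of the pipeline; rRNA and tRNA features define the regions
#' whose reads are removed before counting.
#'
#' @slot features A `GRanges` with unique names and a `featureClass`
#'   metadata column.
#' @seealso [readAnnotation()], [proteinCoding()], [excludedRegions()]
#' @export
setClass("GenomeAnnotation", slots = c(features = "GRanges"))

.FEATURE_CLASSES <- c("CDS", "rRNA", "tRNA", "other")

setValidity("GenomeAnnotation", function(object) {
    gr <- object@features
    msg <- character()
    if (is.null(names(gr)) && length(gr) > 0L)
        msg <- c(msg, "features must be named by feature_id")
    if (anyDuplicated(names(gr)))
        msg <- c(msg, sprintf("duplicate feature_id: %s",
            paste(unique(names(gr)[duplicated(names(gr))]), collapse = ", ")))
    if (!"featureClass" %in% colnames(mcols(gr)))
        msg <- c(msg, "features must carry a 'featureClass' metadata column")
    else if (!all(mcols(gr)$featureClass %in% .FEATURE_CLASSES))
        msg <- c(msg, sprintf("featureClass values must be one of: %s",
                              paste(.FEATURE_CLASSES, collapse = ", ")))
    if (length(gr) > 0L && any(start(gr) < 1L))
        msg <- c(msg, sprintf("start < 1 for feature_id: %s",
            paste(names(gr)[start(gr) < 1L], collapse = ", ")))
    if (length(gr) > 0L && any(end(gr) < start(gr)))
        msg <- c(msg, sprintf("end < start for feature_id: %s",
            paste(names(gr)[end(gr) < start(gr)], collapse = ", ")))
    if (length(msg)) msg else TRUE
})

#' FilterStats: read-level filter accounting
#'
#' Accounts for every alignment record entering [filterAlignments()]
#' exactly once: removed as non-uniquely mapping, removed for overlapping
#' an rRNA/tRNA feature, or retained. The uniqueness filter is applied
#' first, so a non-unique rRNA-overlapping read counts as non-unique.
#'
#' @slot nInput Number of input records.
#' @slot nNonUniqueRemoved Records removed because they do not map to a
#'   unique position.
#' @slot nRrnaTrnaRemoved Unique records removed because they overlap an
#'   rRNA or tRNA feature by at least one nucleotide.
#' @slot nRetained Records passing both filters.
#' @export
setClass("FilterStats", slots = c(
    nInput = "integer",
    nNonUniqueRemoved = "integer",
    nRrnaTrnaRemoved = "integer",
    nRetained = "integer"
))

setValidity("FilterStats", function(object) {
    v <- c(object@nInput, object@nNonUniqueRemoved,
           object@nRrnaTrnaRemoved, object@nRetained)
    if (length(v) != 4L || anyNA(v))
        return("all four counters must be single non-missing integers")
    if (any(v < 0L))
        return("counters must be non-negative")
    if (object@nInput !=
        object@nNonUniqueRemoved + object@nRrnaTrnaRemoved + object@nRetained)
        return("conservation violated: nInput != nNonUniqueRemoved + nRrnaTrnaRemoved + nRetained")
    TRUE
})

#' FilterStats constructor
#'
#' @param nInput,nNonUniqueRemoved,nRrnaTrnaRemoved,nRetained Single
#'   non-negative counts; they must satisfy
#'   `nInput == nNonUniqueRemoved + nRrnaTrnaRemoved + nRetained`.
#' @return A [FilterStats-class] object.
#' @examples
#' FilterStats(10, 1, 2, 7)
#' @export
FilterStats <- function(nInput = 0L, nNonUniqueRemoved = 0L,
                        nRrnaTrnaRemoved = 0L, nRetained = 0L) {
    new("FilterStats",
        nInput = as.integer(nInput),
        nNonUniqueRemoved = as.integer(nNonUniqueRemoved),
        nRrnaTrnaRemoved = as.integer(nRrnaTrnaRemoved),
        nRetained = as.integer(nRetained))
}

#' OrfCountTable: per-ORF read counts for one sample
#'
#' Per-ORF read counts `c_i` over the protein-coding features of an
#' annotation, for a single sample. A read overlapping k ORFs contributes
#' 1 to each of the k counts but only 1 to `totalMrna`, the number of
#' distinct retained reads overlapping at least one protein-coding
#' feature. `totalMrna` is the denominator N of the relative-abundance
#' normalization ("total number of mRNA counts").
#'
#' @slot sampleId Sample identifier.
#' @slot counts Named integer vector over all protein-coding feature_ids
#'   (zero counts explicit).
#' @slot totalMrna Number of distinct reads overlapping any CDS.
#' @slot filterStats A [FilterStats-class] describing the read filtering
#'   that produced the input records.
#' @seealso [countReads()], [relativeAbundance()], [hitsPerKilobase()]
#' @export
setClass("OrfCountTable", slots = c(
    sampleId = "character",
    counts = "integer",
    totalMrna = "integer",
    filterStats = "FilterStats"
))

setValidity("OrfCountTable", function(object) {
    msg <- character()
    if (length(object@sampleId) != 1L)
        msg <- c(msg, "sampleId must be a single string")
    if (is.null(names(object@counts)) && length(object@counts) > 0L)
        msg <- c(msg, "counts must be named by feature_id")
    if (anyNA(object@counts) || any(object@counts < 0L))
        msg <- c(msg, "counts must be non-negative and non-missing")
    if (length(object@totalMrna) != 1L || is.na(object@totalMrna))
        msg <- c(msg, "totalMrna must be a single count")
    else {
        if (object@totalMrna > sum(as.numeric(object@counts)))
            msg <- c(msg, "totalMrna exceeds the count sum")
        if (object@totalMrna > object@filterStats@nRetained &&
            object@filterStats@nInput > 0L)
            msg <- c(msg, "totalMrna exceeds the number of retained reads")
    }
    if (length(msg)) msg else TRUE
})

#' OrfCountTable constructor
#'
#' @param sampleId Sample identifier.
#' @param counts Named integer vector of per-ORF counts.
#' @param totalMrna Number of distinct reads overlapping any CDS (N).
#' @param filterStats Optional [FilterStats-class]; defaults to an empty
#'   record (all zero), used when counts were produced without read-level
#'   filtering (e.g. by [simulateCounts()]).
#' @return An [OrfCountTable-class] object.
#' @export
OrfCountTable <- function(sampleId, counts, totalMrna,
                          filterStats = FilterStats()) {
    counts <- stats::setNames(as.integer(counts), names(counts))
    new("OrfCountTable", sampleId = as.character(sampleId), counts = counts,
        totalMrna = as.integer(totalMrna), filterStats = filterStats)
}

#' OrfAbundanceTable: normalized per-ORF abundances for one sample
#'
#' Carries the two normalizations of the pipeline for one sample:
#' relative transcript abundance `r_i = c_i / N` (an ORF's count divided
#' by the total number of reads mapping within any protein-coding
#' region), and hits per kilobase `h_i = c_i * 1000 / L_i` (the
#' within-sample, length-corrected scale).
#'
#' @slot sampleId Sample identifier.
#' @slot relAbundance Named numeric vector, each value in \[0, 1\].
#' @slot hitsPerKb Named numeric vector, non-negative.
#' @export
setClass("OrfAbundanceTable", slots = c(
    sampleId = "character",
    relAbundance = "numeric",
    hitsPerKb = "numeric"
))

setValidity("OrfAbundanceTable", function(object) {
    msg <- character()
    if (anyNA(object@relAbundance) ||
        any(object@relAbundance < 0) || any(object@relAbundance > 1))
        msg <- c(msg, "relative abundances must lie in [0, 1]")
    if (anyNA(object@hitsPerKb) || any(object@hitsPerKb < 0))
        msg <- c(msg, "hits per kilobase must be non-negative")
    if (!identical(names(object@relAbundance), names(object@hitsPerKb)))
        msg <- c(msg, "relAbundance and hitsPerKb must share feature_ids")
    if (length(msg)) msg else TRUE
})

#' SampleGroup: one or more count tables sharing a condition
#'
#' Groups the replicate count tables of one experimental condition. A
#' group is replicated when it holds two or more samples; replication of
#' the baseline group decides the test dispatched by
#' [compareConditions()] (z-test for replicated baselines, chi-square
#' otherwise).
#'
#' @slot conditionId Condition identifier.
#' @slot samples List of [OrfCountTable-class] objects sharing one
#'   feature universe.
#' @export
setClass("SampleGroup", slots = c(
    conditionId = "character",
    samples = "list"
))

setValidity("SampleGroup", function(object) {
    if (length(object@samples) < 1L)
        return("a SampleGroup needs at least one sample")
    if (!all(vapply(object@samples, is, logical(1), "OrfCountTable")))
        return("samples must all be OrfCountTable objects")
    universes <- lapply(object@samples, function(s) names(s@counts))
    if (length(universes) > 1L &&
        !all(vapply(universes[-1], identical, logical(1), universes[[1]])))
        return("all samples in a group must share the same feature universe")
    TRUE
})

#' SampleGroup constructor
#'
#' @param conditionId Condition identifier.
#' @param samples A list of [OrfCountTable-class] objects (or a single
#'   one) sharing the same feature universe.
#' @return A [SampleGroup-class] object.
#' @export
SampleGroup <- function(conditionId, samples) {
    if (is(samples, "OrfCountTable")) samples <- list(samples)
    new("SampleGroup", conditionId = as.character(conditionId),
        samples = samples)
}

#' ThresholdScheme: fold-change classification thresholds
#'
#' The fold thresholds used to classify per-ORF condition ratios, as
#' drawn on the pipeline's scatter plots: ordered increase factors
#' (default 2-fold and 10-fold) and ordered remaining fractions for
#' decreases (default 0.5, i.e. a 50% reduction, and 0.1, a 90%
#' reduction). Boundaries are inclusive by default (a ratio of exactly
#' 2 is classified as a 2-fold increase).
#'
#' @slot upLevels Strictly increasing fold factors, all > 1.
#' @slot downLevels Strictly decreasing remaining fractions in (0, 1).
#' @slot boundaryInclusive Whether a ratio exactly at a threshold takes
#'   that class.
#' @seealso [thresholdScheme()], [classifyChange()]
#' @export
setClass("ThresholdScheme", slots = c(
    upLevels = "numeric",
    downLevels = "numeric",
    boundaryInclusive = "logical"
))

setValidity("ThresholdScheme", function(object) {
    msg <- character()
    up <- object@upLevels; down <- object@downLevels
    if (length(up) < 1L || any(up <= 1) || is.unsorted(up, strictly = TRUE))
        msg <- c(msg, "upLevels must be strictly increasing and all > 1")
    if (length(down) < 1L || any(down <= 0) || any(down >= 1) ||
        is.unsorted(rev(down), strictly = TRUE))
        msg <- c(msg, "downLevels must be strictly decreasing, in (0, 1)")
    if (length(object@boundaryInclusive) != 1L ||
        is.na(object@boundaryInclusive))
        msg <- c(msg, "boundaryInclusive must be TRUE or FALSE")
    if (length(msg)) msg else TRUE
})

#' Create a ThresholdScheme
#'
#' @param up Fold-increase thresholds, strictly increasing, all > 1.
#'   Default `c(2, 10)`.
#' @param down Remaining fractions for decreases, strictly decreasing, in
#'   (0, 1). Default `c(0.5, 0.1)` (50% and 90% reductions).
#' @param boundaryInclusive Logical; whether a ratio exactly at a
#'   threshold is assigned that class. Default `TRUE`.
#' @return A [ThresholdScheme-class] object.
#' @examples
#' thresholdScheme()                 # Fig-style 2x/10x up, 50%/90% down
#' thresholdScheme(up = 2, down = 0.5)
#' @export
thresholdScheme <- function(up = c(2, 10), down = c(0.5, 0.1),
                            boundaryInclusive = TRUE) {
    new("ThresholdScheme", upLevels = as.numeric(up),
        downLevels = as.numeric(down),
        boundaryInclusive = isTRUE(boundaryInclusive))
}

#' RegulonSpec: a co-regulated gene set for the simulator
#'
#' A named set of protein-coding features sharing condition-dependent
#' multiplicative expression factors in the simulator's truth model. A
#' factor entry may be a single number (the same factor for every member)
#' or a range `c(lo, hi)` from which per-member factors are drawn
#' log-uniformly when the genome is built. Conditions not listed keep
#' factor 1.
#'
#' @slot name Regulon name.
#' @slot members Feature identifiers of the member ORFs.
#' @slot foldFactors Named list, condition_id -> factor (length 1) or
#'   range (length 2), all values > 0.
#' @slot baselineScale Multiplier applied to the members' drawn baseline
#'   weights (e.g. 10 for genes highly expressed under baseline
#'   conditions). Default 1.
#' @slot baselineAbundance Optional fixed baseline relative abundance per
#'   member (overrides the drawn weight; `NA` to disable). Used for gene
#'   sets that are nearly silent at baseline, where the induced fold is
#'   defined from a small, controlled starting abundance.
#' @export
setClass("RegulonSpec", slots = c(
    name = "character",
    members = "character",
    foldFactors = "list",
    baselineScale = "numeric",
    baselineAbundance = "numeric"
))

setValidity("RegulonSpec", function(object) {
    msg <- character()
    if (length(object@name) != 1L || !nzchar(object@name))
        msg <- c(msg, "name must be a single non-empty string")
    ff <- object@foldFactors
    if (length(ff) && (is.null(names(ff)) || any(!nzchar(names(ff)))))
        msg <- c(msg, "foldFactors must be named by condition_id")
    ok <- vapply(ff, function(x)
        is.numeric(x) && length(x) %in% 1:2 && all(x > 0), logical(1))
    if (length(ff) && !all(ok))
        msg <- c(msg, "each fold factor must be a positive scalar or range")
    if (length(msg)) msg else TRUE
})

#' RegulonSpec constructor
#'
#' @param name Regulon name.
#' @param members Character vector of member feature_ids.
#' @param foldFactors Named list of per-condition factors or ranges.
#' @param baselineScale,baselineAbundance See [RegulonSpec-class].
#' @return A [RegulonSpec-class] object.
#' @export
regulonSpec <- function(name, members, foldFactors = list(),
                        baselineScale = 1, baselineAbundance = NA_real_) {
    new("RegulonSpec", name = name, members = as.character(members),
        foldFactors = foldFactors, baselineScale = as.numeric(baselineScale),
        baselineAbundance = as.numeric(baselineAbundance))
}

#' SimulationConfig: layout and sampling parameters for a simulated study
#'
#' Everything needed to regenerate a simulated study deterministically:
#' genome layout (number and length range of ORFs, reference length),
#' regulon structure, the baseline abundance law, the per-condition
#' replicate design, sequencing depth, contamination fractions (rRNA
#' reads, non-uniquely-mapping reads), optional Dirichlet-multinomial
#' overdispersion, read length and seed.
#'
#' @slot nOrfs Number of protein-coding ORFs to place.
#' @slot orfLengthRange Length-2 integer range of ORF lengths (nt).
#' @slot referenceLength Length of the single reference sequence (nt).
#' @slot regulons List of [RegulonSpec-class] objects (disjoint members).
#' @slot baselineLaw List: `law` (`"lognormal"` or `"uniform"`) and
#'   `sigma` (log-sd of the log-normal).
#' @slot conditions Data frame with columns `condition_id`, `replicates`.
#' @slot depth Reads per sample.
#' @slot rrnaFraction Proportion of reads drawn from rRNA features.
#' @slot nonUniqueFraction Proportion of reads flagged non-unique.
#' @slot overdispersion Dirichlet concentration scale (NA = pure
#'   multinomial).
#' @slot readLength Simulated read length (nt).
#' @slot seed Base seed; per-sample streams are derived from
#'   (seed, condition, replicate).
#' @seealso [simulationConfig()], [defaultStudyScenario()],
#'   [buildGenome()]
#' @export
setClass("SimulationConfig", slots = c(
    nOrfs = "integer",
    orfLengthRange = "integer",
    referenceLength = "integer",
    regulons = "list",
    baselineLaw = "list",
    conditions = "data.frame",
    depth = "numeric",
    rrnaFraction = "numeric",
    nonUniqueFraction = "numeric",
    overdispersion = "numeric",
    readLength = "integer",
    seed = "integer"
))

setValidity("SimulationConfig", function(object) {
    msg <- character()
    if (object@nOrfs < 1L) msg <- c(msg, "nOrfs must be >= 1")
    if (length(object@orfLengthRange) != 2L ||
        object@orfLengthRange[1] < 1L ||
        object@orfLengthRange[2] < object@orfLengthRange[1])
        msg <- c(msg, "orfLengthRange must be an increasing length-2 range")
    if (object@depth < 1) msg <- c(msg, "depth must be >= 1")
    for (f in c("rrnaFraction", "nonUniqueFraction")) {
        v <- slot(object, f)
        if (length(v) != 1L || is.na(v) || v < 0 || v >= 1)
            msg <- c(msg, sprintf("%s must lie in [0, 1)", f))
    }
    if (!all(c("condition_id", "replicates") %in% colnames(object@conditions)))
        msg <- c(msg, "conditions needs columns condition_id, replicates")
    else if (anyDuplicated(object@conditions$condition_id))
        msg <- c(msg, "condition_ids must be unique")
    if (!all(vapply(object@regulons, is, logical(1), "RegulonSpec")))
        msg <- c(msg, "regulons must be RegulonSpec objects")
    else {
        mem <- unlist(lapply(object@regulons, slot, "members"))
        if (anyDuplicated(mem))
            msg <- c(msg, "regulon memberships may not overlap")
    }
    if (object@readLength < 1L) msg <- c(msg, "readLength must be >= 1")
    if (length(msg)) msg else TRUE
})

#' TruthTable: ground-truth abundance profiles of a simulated study
#'
#' Per-condition true relative abundances (each condition's column sums
#' to 1) after applying regulon fold factors to the baseline profile and
#' renormalizing. Because induction changes the composition, the expected
#' observable ratio of a gene differs from its raw fold factor; the
#' expected ratios reported by [expectedRatios()] are the
#' post-renormalization values, which are what the pipeline's
#' relative-abundance ratios estimate.
#'
#' @slot abundance Numeric matrix, features x conditions; columns sum
#'   to 1.
#' @slot regulons Named list, regulon name -> member feature_ids.
#' @slot factors Numeric matrix, features x conditions, of the applied
#'   (pre-renormalization) fold factors.
#' @seealso [buildGenome()], [expectedRatios()], [simulateCounts()]
#' @export
setClass("TruthTable", slots = c(
    abundance = "matrix",
    regulons = "list",
    factors = "matrix"
))

setValidity("TruthTable", function(object) {
    ab <- object@abundance
    if (is.null(rownames(ab)) || is.null(colnames(ab)))
        return("abundance matrix needs feature_ids as rownames and condition_ids as colnames")
    if (any(ab < 0)) return("abundances must be non-negative")
    s <- colSums(ab)
    if (any(abs(s - 1) > 1e-12))
        return("each condition's abundances must sum to 1 (1e-12)")
    TRUE
})
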