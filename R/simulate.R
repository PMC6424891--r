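#' @include AllClasses.R AllGenerics.R
#' @importFrom stats rbinom rmultinom rlnorm runif rgamma qbinom
#' @importFrom Biostrings DNAStringSet writeXStringSet
NULL

# Run expr with a temporarily seeded RNG, restoring the caller's RNG
# state afterwards, so simulation never perturbs user code.
.withRNG <- function(seed, expr) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
        get(".Random.seed", globalenv()) else NULL
    on.exit({
        if (is.null(old)) {
            if (exists(".Random.seed", globalenv(), inherits = FALSE))
                rm(".Random.seed", envir = globalenv())
        } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
    expr
}

# Derive a deterministic sub-stream seed from (seed, labels...): one
# pseudo-random stream per sample, so adding a condition or replicate
# never perturbs the draws of another.
.streamSeed <- function(seed, ...) {
    h <- as.numeric(seed) %% 2147483647
    for (tok in as.character(c(...))) {
        for (b in utf8ToInt(tok)) h <- (h * 31 + b) %% 2147483647
        h <- (h * 131 + 7) %% 2147483647
    }
    as.integer(h)
}

#' Create a SimulationConfig
#'
#' @param nOrfs Number of protein-coding ORFs.
#' @param orfLengthRange Range of ORF lengths (nt), length 2.
#' @param referenceLength Reference sequence length (nt).
#' @param regulons List of [RegulonSpec-class] objects.
#' @param baselineLaw List with `law` (`"lognormal"` or `"uniform"`) and
#'   `sigma` (log-sd for the log-normal law).
#' @param conditions Data frame with columns `condition_id`,
#'   `replicates`.
#' @param depth Reads per sample.
#' @param rrnaFraction Proportion of reads drawn from rRNA features.
#' @param nonUniqueFraction Proportion of reads flagged non-unique.
#' @param overdispersion Dirichlet concentration scale; `NA` (default)
#'   for pure multinomial sampling.
#' @param readLength Simulated read length (nt).
#' @param seed Base seed for all derived streams.
#' @return A [SimulationConfig-class] object.
#' @export
simulationConfig <- function(nOrfs, orfLengthRange = c(300L, 1800L),
                             referenceLength = 9000000L,
                             regulons = list(),
                             baselineLaw = list(law = "lognormal",
                                                sigma = 1),
                             conditions = data.frame(
                                 condition_id = "cond1",
                                 replicates = 1L),
                             depth = 2e6, rrnaFraction = 0.05,
                             nonUniqueFraction = 0.02,
                             overdispersion = NA_real_,
                             readLength = 100L, seed = 1L) {
    new("SimulationConfig", nOrfs = as.integer(nOrfs),
        orfLengthRange = as.integer(orfLengthRange),
        referenceLength = as.integer(referenceLength),
        regulons = regulons, baselineLaw = baselineLaw,
        conditions = conditions, depth = as.numeric(depth),
        rrnaFraction = as.numeric(rrnaFraction),
        nonUniqueFraction = as.numeric(nonUniqueFraction),
        overdispersion = as.numeric(overdispersion),
        readLength = as.integer(readLength), seed = as.integer(seed))
}

#' The default study scenario
#'
#' A packaged simulation design mirroring a far-red-light (FRL)
#' photoacclimation profiling experiment on a cyanobacterial genome:
#'
#' * Conditions: `WT_WL` (triplicate baseline, white light), `WT_FRL`,
#'   `WT_WL_Em`, `WT_FRL_Em` (erythromycin added), and the regulator
#'   knockouts `rfpA_FRL`, `rfpB_FRL`, `rfpC_FRL` (single libraries).
#' * `farlip_cluster`: a 20-gene regulon, nearly silent in white light
#'   (fixed baseline relative abundance 6e-5 per gene), induced
#'   1,000- to 43,500-fold in `WT_FRL`; induction abolished (factor 1)
#'   in `rfpB_FRL`/`rfpC_FRL`, weak (2- to 5-fold) in `rfpA_FRL`, and
#'   attenuated by erythromycin in `WT_FRL_Em`.
#' * `pbp_psi_wl`: 15 phycobiliprotein/photosystem-I-like genes, highly
#'   expressed at baseline (10x weight), repressed to 5-50% of baseline
#'   in every FRL condition and to 1-10% under erythromycin.
#' * `em_response`: 4 antibiotic-response genes induced 50- to 670-fold
#'   whenever erythromycin is present.
#' * 5% of reads from rRNA features, 2% flagged non-unique, read length
#'   100 nt, 2e6 reads per sample, 6,700 ORFs on a 9-Mb reference.
#'
#' @param seed Base seed.
#' @return A [SimulationConfig-class].
#' @examples
#' cfg <- defaultStudyScenario(seed = 1)
#' cfg
#' @export
defaultStudyScenario <- function(seed = 1L) {
    orfIds <- sprintf("ORF_%04d", seq_len(6700L))
    farlip <- orfIds[101:120]
    pbp <- orfIds[501:515]
    em <- orfIds[1001:1004]
    frlInduction <- c(1e3, 4.35e4)
    regulons <- list(
        regulonSpec("farlip_cluster", farlip,
            foldFactors = list(
                WT_FRL = frlInduction,
                WT_FRL_Em = 0.075 * frlInduction,
                rfpA_FRL = c(2, 5),
                rfpB_FRL = 1,
                rfpC_FRL = 1),
            baselineAbundance = 6e-5),
        regulonSpec("pbp_psi_wl", pbp,
            foldFactors = list(
                WT_FRL = c(0.05, 0.5),
                WT_WL_Em = c(0.01, 0.1),
                WT_FRL_Em = c(0.01, 0.1),
                rfpA_FRL = c(0.05, 0.5),
                rfpB_FRL = c(0.05, 0.5),
                rfpC_FRL = c(0.05, 0.5)),
            baselineScale = 10),
        regulonSpec("em_response", em,
            foldFactors = list(
                WT_WL_Em = c(50, 670),
                WT_FRL_Em = c(50, 670))))
    simulationConfig(
        nOrfs = 6700L,
        orfLengthRange = c(300L, 1800L),
        referenceLength = 9000000L,
        regulons = regulons,
        conditions = data.frame(
            condition_id = c("WT_WL", "WT_FRL", "WT_WL_Em", "WT_FRL_Em",
                             "rfpA_FRL", "rfpB_FRL", "rfpC_FRL"),
            replicates = c(3L, 1L, 1L, 1L, 1L, 1L, 1L)),
        depth = 2e6,
        rrnaFraction = 0.05,
        nonUniqueFraction = 0.02,
        readLength = 100L,
        seed = seed)
}

.drawFactors <- function(range, n) {
    if (length(range) == 1L) rep(range, n)
    else exp(runif(n, log(range[1]), log(range[2])))
}

#' Build the simulated genome and truth table
#'
#' Places `nOrfs` non-overlapping ORFs (plus two rRNA and two tRNA
#' features) on a single reference, draws baseline abundances from the
#' configured law, applies each regulon's per-condition fold factors and
#' renormalizes each condition's profile to sum to 1. Because induction
#' changes the composition, the expected observable ratios differ from
#' the raw factors; [expectedRatios()] reports the post-renormalization
#' values, which are what the pipeline estimates. Deterministic for a
#' fixed config seed.
#'
#' @param config A [SimulationConfig-class].
#' @return A list with elements `annotation`
#'   (a [GenomeAnnotation-class]) and `truth` (a [TruthTable-class]).
#' @export
buildGenome <- function(config) {
    stopifnot(is(config, "SimulationConfig"))
    .withRNG(.streamSeed(config@seed, "genome"), {
        n <- config@nOrfs
        ids <- sprintf("ORF_%04d", seq_len(n))
        lens <- sample(seq(config@orfLengthRange[1],
                           config@orfLengthRange[2]), n, replace = TRUE)
        gaps <- sample(seq(config@readLength + 10L, 250L), n,
                       replace = TRUE)
        starts <- cumsum(c(1L, lens[-n] + gaps[-n]))
        ends <- starts + lens - 1L
        # non-coding features in the tail, behind a gap
        tailPos <- ends[n] + gaps[n]
        ncLens <- c(1500L, 2900L, 75L, 85L)
        ncIds <- c("rrn16S", "rrn23S", "trnA", "trnB")
        ncCls <- c("rRNA", "rRNA", "tRNA", "tRNA")
        ncStarts <- tailPos + cumsum(c(0L, utils::head(ncLens, -1) + 200L))
        ncEnds <- ncStarts + ncLens - 1L
        if (ncEnds[length(ncEnds)] > config@referenceLength)
            stop("capacity error: features do not fit within referenceLength (",
                 config@referenceLength, " nt; need ",
                 ncEnds[length(ncEnds)], ")")
        gr <- GRanges("chr",
                      IRanges(start = c(starts, ncStarts),
                              end = c(ends, ncEnds)),
                      strand = sample(c("+", "-"), n + 4L,
                                      replace = TRUE))
        names(gr) <- c(ids, ncIds)
        mcols(gr)$featureClass <- c(rep("CDS", n), ncCls)
        seqlengths(gr) <- c(chr = config@referenceLength)
        annotation <- GenomeAnnotation(gr)

        w <- switch(config@baselineLaw$law,
            lognormal = rlnorm(n, meanlog = 0,
                               sdlog = config@baselineLaw$sigma),
            uniform = runif(n, 0.5, 1.5),
            stop("unknown baseline law: ", config@baselineLaw$law))
        names(w) <- ids
        condIds <- config@conditions$condition_id
        for (reg in config@regulons) {
            miss <- setdiff(reg@members, ids)
            if (length(miss))
                stop("regulon ", reg@name,
                     " references unknown ORFs: ",
                     paste(miss, collapse = ", "))
            w[reg@members] <- w[reg@members] * reg@baselineScale
        }
        # fixed-baseline regulons: pin the members' baseline relative
        # abundance, leaving the rest of the composition proportional
        fixedMask <- rep(FALSE, n); names(fixedMask) <- ids
        fixedA <- 0
        for (reg in config@regulons) {
            if (!is.na(reg@baselineAbundance)) {
                fixedMask[reg@members] <- TRUE
                fixedA <- fixedA +
                    reg@baselineAbundance * length(reg@members)
            }
        }
        if (fixedA >= 1)
            stop("fixed baseline abundances sum to >= 1")
        if (any(fixedMask)) {
            restW <- sum(w[!fixedMask])
            for (reg in config@regulons)
                if (!is.na(reg@baselineAbundance))
                    w[reg@members] <-
                        reg@baselineAbundance * restW / (1 - fixedA)
        }

        fac <- matrix(1, n, length(condIds),
                      dimnames = list(ids, condIds))
        for (reg in config@regulons) {
            for (cond in names(reg@foldFactors)) {
                if (!cond %in% condIds)
                    stop("regulon ", reg@name,
                         " names unknown condition: ", cond)
                fac[reg@members, cond] <-
                    .drawFactors(reg@foldFactors[[cond]],
                                 length(reg@members))
            }
        }
        ab <- sweep(fac, 1, w, `*`)
        ab <- sweep(ab, 2, colSums(ab), `/`)
        truth <- new("TruthTable", abundance = ab,
                     regulons = stats::setNames(
                         lapply(config@regulons, slot, "members"),
                         vapply(config@regulons, slot, character(1),
                                "name")),
                     factors = fac)
        list(annotation = annotation, truth = truth)
    })
}

#' Expected post-renormalization condition ratios
#'
#' @param truth A [TruthTable-class].
#' @param baseline,other Condition identifiers.
#' @return Named numeric vector: true abundance under `other` divided by
#'   true abundance under `baseline` (`NA` where the baseline abundance
#'   is zero).
#' @export
expectedRatios <- function(truth, baseline, other) {
    ab <- truth@abundance
    for (cond in c(baseline, other))
        if (!cond %in% colnames(ab))
            stop("unknown condition: ", cond)
    foldRatio(ab[, baseline], ab[, other])
}

#' Simulate a count table for one sample
#'
#' Draws per-ORF counts multinomially (Dirichlet-multinomially when
#' `overdispersion` is set) from the condition's true abundance vector
#' at the given depth. `totalMrna` equals the depth. Deterministic for a
#' fixed (seed, condition, replicate) triple.
#'
#' @param truth A [TruthTable-class].
#' @param conditionId Condition to draw from.
#' @param depth Number of reads (>= 1).
#' @param seed Base seed.
#' @param replicate Replicate index (distinct streams per replicate).
#' @param overdispersion Dirichlet concentration scale; `NA` for pure
#'   multinomial.
#' @return An [OrfCountTable-class] with
#'   `sampleId = "<condition>_rep<replicate>"`.
#' @export
simulateCounts <- function(truth, conditionId, depth, seed = 1L,
                           replicate = 1L, overdispersion = NA_real_) {
    if (!conditionId %in% colnames(truth@abundance))
        stop("unknown condition: ", conditionId)
    if (depth < 1) stop("depth must be >= 1")
    p <- truth@abundance[, conditionId]
    .withRNG(.streamSeed(seed, conditionId, replicate, "counts"), {
        if (!is.na(overdispersion)) {
            g <- rgamma(length(p), shape = p * overdispersion)
            p <- g / sum(g)
        }
        cvec <- as.integer(rmultinom(1, size = depth, prob = p))
        names(cvec) <- rownames(truth@abundance)
        OrfCountTable(sprintf("%s_rep%d", conditionId, replicate),
                      cvec, as.integer(depth),
                      FilterStats(as.integer(depth), 0L, 0L,
                                  as.integer(depth)))
    })
}

#' Simulate alignment records for one sample
#'
#' Generates `depth` fixed-length ungapped reads: a binomial
#' `rrnaFraction` share placed uniformly within rRNA features, the rest
#' assigned to ORFs by the condition's true abundances and placed
#' uniformly within their source ORF (fully contained; with
#' `jitter = TRUE` reads may extend past the ORF boundary, retaining at
#' least one nucleotide of overlap, to exercise the boundary-overlap
#' counting rule). A binomial `nonUniqueFraction` share of all reads is
#' flagged non-unique. Deterministic for a fixed (seed, condition,
#' replicate).
#'
#' @param truth A [TruthTable-class].
#' @param conditionId Condition to draw from.
#' @param config The [SimulationConfig-class] (depth, fractions, read
#'   length, seed).
#' @param annotation The matching [GenomeAnnotation-class] from
#'   [buildGenome()].
#' @param replicate Replicate index.
#' @param depth Override of `config@depth` (e.g. for smaller runs).
#' @param jitter Allow partial boundary overlaps (default `FALSE`).
#' @param samPath If non-`NULL`, also write the records as SAM.
#' @return A `GRanges` of alignment records (metadata columns `read_id`,
#'   `unique`).
#' @export
simulateAlignments <- function(truth, conditionId, config, annotation,
                               replicate = 1L, depth = config@depth,
                               jitter = FALSE, samPath = NULL) {
    if (!conditionId %in% colnames(truth@abundance))
        stop("unknown condition: ", conditionId)
    if (depth < 1) stop("depth must be >= 1")
    rl <- config@readLength
    cds <- proteinCoding(annotation)
    rrna <- features(annotation)[
        mcols(features(annotation))$featureClass == "rRNA"]
    if (any(width(cds) < rl) || any(width(rrna) < rl))
        stop("read length (", rl,
             ") exceeds a target feature; shortest target is ",
             min(width(cds), width(rrna)), " nt")
    p <- truth@abundance[, conditionId]
    sampleName <- sprintf("%s_rep%d", conditionId, replicate)
    .withRNG(.streamSeed(config@seed, conditionId, replicate,
                         "alignments"), {
        nRrna <- rbinom(1, depth, config@rrnaFraction)
        nMrna <- depth - nRrna
        orfOfRead <- sample.int(length(p), nMrna, replace = TRUE,
                                prob = p)
        src <- c(cds[orfOfRead],
                 rrna[sample.int(length(rrna), nRrna, replace = TRUE)])
        if (jitter) {
            lo <- pmax(1L, start(src) - rl + 1L)
            hi <- end(src)
        } else {
            lo <- start(src)
            hi <- end(src) - rl + 1L
        }
        starts <- lo + floor(runif(depth) * (hi - lo + 1L))
        gr <- GRanges(seqnames(src),
                      IRanges(start = starts, width = rl),
                      strand = sample(c("+", "-"), depth,
                                      replace = TRUE))
        GenomeInfoDb::seqlevels(gr) <-
            GenomeInfoDb::seqlevels(features(annotation))
        seqlengths(gr) <- seqlengths(features(annotation))
        mcols(gr)$read_id <- sprintf("%s_r%07d", sampleName,
                                     seq_len(depth))
        mcols(gr)$unique <- runif(depth) >= config@nonUniqueFraction
        if (!is.null(samPath))
            writeSam(gr, seqlengths(features(annotation)), samPath)
        gr
    })
}

#' Simulate every sample of a scenario as count tables
#'
#' Convenience wrapper: builds the genome and truth for `config` and
#' draws one [OrfCountTable-class] per (condition, replicate) at the
#' configured depth, grouped into [SampleGroup-class] objects.
#'
#' @param config A [SimulationConfig-class].
#' @param depth Optional depth override.
#' @return A list with `annotation`, `truth`, and `groups` (a named list
#'   of [SampleGroup-class], one per condition).
#' @export
simulateScenario <- function(config, depth = config@depth) {
    g <- buildGenome(config)
    groups <- lapply(seq_len(nrow(config@conditions)), function(i) {
        cond <- config@conditions$condition_id[i]
        reps <- config@conditions$replicates[i]
        SampleGroup(cond, lapply(seq_len(reps), function(r)
            simulateCounts(g$truth, cond, depth, seed = config@seed,
                           replicate = r,
                           overdispersion = config@overdispersion)))
    })
    names(groups) <- config@conditions$condition_id
    list(annotation = g$annotation, truth = g$truth, groups = groups)
}

#' Exact binomial interval for an observed condition ratio
#'
#' The interval within which the pipeline's estimated ratio
#' `(c2/N2) / (c1/N1)` should fall, at the given joint level, when the
#' counts are drawn binomially at the true abundances: each margin gets
#' an exact binomial quantile interval at level `1 - (1 - level)/2`
#' (Bonferroni, so the joint coverage is at least `level`), and the
#' ratio bounds are formed from the opposite extremes of the two
#' margins.
#'
#' @param N1,N2 mRNA totals of the baseline and comparison samples.
#' @param p1,p2 True relative abundances (vectors allowed).
#' @param level Joint coverage level (default 0.99).
#' @return A two-column matrix `lo`, `hi` of ratio bounds.
#' @export
ratioRecoveryInterval <- function(N1, p1, N2, p2, level = 0.99) {
    alpha <- (1 - level) / 2          # per-margin error budget
    lo1 <- qbinom(alpha / 2, N1, p1) / N1
    hi1 <- qbinom(1 - alpha / 2, N1, p1) / N1
    lo2 <- qbinom(alpha / 2, N2, p2) / N2
    hi2 <- qbinom(1 - alpha / 2, N2, p2) / N2
    cbind(lo = lo2 / hi1, hi = hi2 / pmax(lo1, .Machine$double.xmin))
}

#' Write the truth table as TSV
#'
#' @param truth A [TruthTable-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeTruthTable <- function(truth, path) {
    ab <- truth@abundance
    df <- data.frame(feature_id = rownames(ab),
                     apply(ab, 2, .fmtNum))
    colnames(df) <- c("feature_id", colnames(ab))
    reg <- rep("", nrow(ab))
    for (nm in names(truth@regulons))
        reg[rownames(ab) %in% truth@regulons[[nm]]] <- nm
    df$regulon <- reg
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Write a random reference FASTA consistent with an annotation
#'
#' Generates a random nucleotide sequence of the annotated reference
#' length (synthetic sequence; reads are placed by coordinate, so the
#' sequence content is only needed for SAM-header/FASTA consistency of
#' exported files).
#'
#' @param annotation A [GenomeAnnotation-class] with seqlengths set.
#' @param path Output FASTA path.
#' @param seed Seed for the synthetic sequence.
#' @return `path`, invisibly.
#' @export
writeReferenceFasta <- function(annotation, path, seed = 1L) {
    sl <- seqlengths(features(annotation))
    if (anyNA(sl)) stop("annotation has no reference lengths")
    .withRNG(.streamSeed(seed, "fasta"), {
        seqs <- Biostrings::DNAStringSet(vapply(sl, function(n)
            paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                  collapse = ""), character(1)))
        names(seqs) <- names(sl)
        Biostrings::writeXStringSet(seqs, path)
    })
    invisible(path)
}
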