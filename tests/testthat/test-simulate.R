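test_that("buildGenome lays out the genome and truth as configured", {
    cfg <- smallConfig(seed = 21L)
    g <- buildGenome(cfg)
    ann <- g$annotation

    expect_length(proteinCoding(ann), 40L)
    cls <- S4Vectors::mcols(features(ann))$featureClass
    expect_gte(sum(cls == "rRNA"), 1L)
    expect_gte(sum(cls == "tRNA"), 1L)
    # features are non-overlapping and inside the reference
    expect_identical(
        length(GenomicRanges::reduce(features(ann),
                                     ignore.strand = TRUE)),
        length(features(ann)))
    expect_lte(max(GenomicRanges::end(features(ann))),
               cfg@referenceLength)

    # truth: columns sum to one, regulon bookkeeping intact
    ab <- g$truth@abundance
    expect_equal(unname(colSums(ab)), rep(1, ncol(ab)),
                 tolerance = 1e-12)
    expect_identical(regulons(g$truth)$boost, sprintf("ORF_%04d", 1:5))

    # capacity error when the reference cannot hold the features
    tiny <- smallConfig(seed = 21L)
    tiny@referenceLength <- 10000L
    expect_error(buildGenome(tiny), "capacity")
})

test_that("unit fold factors give unit expected ratios; factors renormalize", {
    flat <- smallConfig(regulons = list())
    g <- buildGenome(flat)
    er <- expectedRatios(g$truth, "base", "induced")
    expect_equal(unname(er), rep(1, 40), tolerance = 1e-12)

    cfg <- smallConfig()
    g2 <- buildGenome(cfg)
    er2 <- expectedRatios(g2$truth, "base", "induced")
    boosted <- sprintf("ORF_%04d", 1:5)
    # composition shift: induced members land below their raw factor,
    # the rest below 1, and the renormalization is self-consistent
    expect_true(all(er2[boosted] > 1 & er2[boosted] < 20))
    expect_true(all(er2[setdiff(names(er2), boosted)] < 1))
    fac <- g2$truth@factors[, "induced"]
    expect_equal(unname(er2 / fac),
                 rep(unname(er2[6] / fac[6]), 40), tolerance = 1e-12)

    expect_error(expectedRatios(g$truth, "base", "nope"),
                 "unknown condition")
})

test_that("genome generation is deterministic under a fixed seed", {
    g1 <- buildGenome(smallConfig(seed = 5L))
    g2 <- buildGenome(smallConfig(seed = 5L))
    expect_identical(g1$truth@abundance, g2$truth@abundance)
    expect_identical(GenomicRanges::start(features(g1$annotation)),
                     GenomicRanges::start(features(g2$annotation)))
    g3 <- buildGenome(smallConfig(seed = 6L))
    expect_false(identical(g1$truth@abundance, g3$truth@abundance))
})

test_that("simulated counts follow the truth at binomial precision", {
    cfg <- smallConfig(regulons = list(), nOrfs = 10L)
    g <- buildGenome(cfg)
    # near-uniform truth, deep sample: every count within 4 binomial sd
    depth <- 1e6
    ct <- simulateCounts(g$truth, "base", depth, seed = 31L)
    expect_identical(totalMrnaCounts(ct), as.integer(depth))
    expect_identical(sum(counts(ct)), as.integer(depth))
    p <- g$truth@abundance[, "base"]
    expected <- depth * p
    sd <- sqrt(depth * p * (1 - p))
    expect_true(all(abs(counts(ct) - expected) <= 4 * sd))

    expect_identical(counts(simulateCounts(g$truth, "base", 1e4,
                                           seed = 8L)),
                     counts(simulateCounts(g$truth, "base", 1e4,
                                           seed = 8L)))
    expect_error(simulateCounts(g$truth, "base", 0), "depth")
    expect_error(simulateCounts(g$truth, "zzz", 10),
                 "unknown condition")
})

test_that("simulated alignments hit the contamination targets", {
    cfg <- smallConfig(seed = 13L, rrnaFraction = 0.05,
                       nonUniqueFraction = 0.02)
    g <- buildGenome(cfg)
    depth <- 50000
    aln <- simulateAlignments(g$truth, "base", cfg, g$annotation,
                              depth = depth)
    expect_length(aln, depth)

    rrna <- features(g$annotation)[
        S4Vectors::mcols(features(g$annotation))$featureClass == "rRNA"]
    fracR <- mean(IRanges::overlapsAny(aln, rrna,
                                       ignore.strand = TRUE))
    sdR <- sqrt(0.05 * 0.95 / depth)
    expect_lt(abs(fracR - 0.05), 4 * sdR)

    fracNU <- mean(!S4Vectors::mcols(aln)$unique)
    sdNU <- sqrt(0.02 * 0.98 / depth)
    expect_lt(abs(fracNU - 0.02), 4 * sdNU)

    # determinism of the whole generation path
    aln2 <- simulateAlignments(g$truth, "base", cfg, g$annotation,
                               depth = depth)
    expect_identical(GenomicRanges::start(aln),
                     GenomicRanges::start(aln2))
    expect_identical(S4Vectors::mcols(aln)$unique,
                     S4Vectors::mcols(aln2)$unique)
})

test_that("alignment-path counts are distributed like direct counts", {
    cfg <- smallConfig(seed = 17L, nOrfs = 25L, rrnaFraction = 0.04,
                       nonUniqueFraction = 0.02)
    g <- buildGenome(cfg)
    depth <- 60000
    aln <- simulateAlignments(g$truth, "base", cfg, g$annotation,
                              depth = depth)
    flt <- filterAlignments(aln, g$annotation)
    ct <- countReads(flt$alignments, g$annotation,
                     filterStats = flt$stats)
    # goodness of fit of the recovered composition against the truth
    p <- g$truth@abundance[, "base"]
    gof <- suppressWarnings(
        chisq.test(counts(ct), p = p / sum(p)))
    expect_gt(gof$p.value, 0.01)

    # boundary jitter keeps every read overlapping its source ORF
    alnJ <- simulateAlignments(g$truth, "base", cfg, g$annotation,
                               depth = 5000, jitter = TRUE)
    cds <- proteinCoding(g$annotation)
    expect_true(all(IRanges::overlapsAny(alnJ, features(g$annotation),
                                         ignore.strand = TRUE)))
    touching <- alnJ[IRanges::overlapsAny(alnJ, cds,
                                          ignore.strand = TRUE)]
    partial <- sum(!IRanges::overlapsAny(touching, cds,
                                         type = "within",
                                         ignore.strand = TRUE))
    expect_gt(partial, 0)  # jitter produces partial boundary overlaps
})

test_that("read length exceeding a feature is rejected", {
    cfg <- smallConfig(readLength = 2000L)
    g <- buildGenome(smallConfig())
    expect_error(
        simulateAlignments(g$truth, "base", cfg, g$annotation,
                           depth = 10),
        "read length")
})

test_that("the default study scenario encodes the experimental design", {
    cfg <- defaultStudyScenario(seed = 2L)
    expect_identical(nrow(cfg@conditions), 7L)
    expect_identical(
        cfg@conditions$replicates[cfg@conditions$condition_id ==
                                  "WT_WL"], 3L)
    regs <- stats::setNames(cfg@regulons,
                            vapply(cfg@regulons, slot, character(1),
                                   "name"))
    expect_length(regs$farlip_cluster@members, 20L)
    # induction abolished in the regulator knockouts
    expect_identical(regs$farlip_cluster@foldFactors$rfpB_FRL, 1)
    expect_identical(regs$farlip_cluster@foldFactors$rfpC_FRL, 1)
    # weak residual activation in the sensor knockout
    expect_true(all(regs$farlip_cluster@foldFactors$rfpA_FRL <= 5))
    expect_identical(max(regs$farlip_cluster@foldFactors$WT_FRL),
                     43500)
    expect_identical(max(regs$em_response@foldFactors$WT_WL_Em), 670)
})
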