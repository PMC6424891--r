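# Fixtures and independent oracles, built in code at test time.

# Small fixed annotation: 3 ORFs, one rRNA, one tRNA on one reference.
tinyAnnotation <- function() {
    GenomeAnnotation(data.frame(
        feature_id = c("orfA", "orfB", "orfC", "rrn1", "trn1"),
        reference = "chr",
        start = c(1001, 3001, 5001, 7001, 9501),
        end = c(2000, 4500, 5600, 9000, 9580),
        strand = c("+", "-", "+", "+", "-"),
        feature_class = c("CDS", "CDS", "CDS", "rRNA", "tRNA")))
}

# Build alignment records from a compact spec.
makeReads <- function(start, end, unique = TRUE, reference = "chr",
                      strand = "*", read_id = NULL) {
    n <- length(start)
    gr <- GenomicRanges::GRanges(rep_len(reference, n),
        IRanges::IRanges(start = start, end = end),
        strand = rep_len(strand, n))
    S4Vectors::mcols(gr)$read_id <-
        if (is.null(read_id)) sprintf("r%04d", seq_len(n)) else read_id
    S4Vectors::mcols(gr)$unique <- rep_len(unique, n)
    gr
}

# Independent brute-force oracle for ORF counting: an exhaustive
# read x ORF overlap scan on plain vectors, no interval machinery.
bruteForceCounts <- function(reads, annotation) {
    cds <- proteinCoding(annotation)
    rs <- GenomicRanges::start(reads); re <- GenomicRanges::end(reads)
    rref <- as.character(GenomicRanges::seqnames(reads))
    os <- GenomicRanges::start(cds); oe <- GenomicRanges::end(cds)
    oref <- as.character(GenomicRanges::seqnames(cds))
    counts <- integer(length(cds))
    hitAny <- logical(length(reads))
    for (j in seq_along(cds)) {
        ov <- rref == oref[j] & rs <= oe[j] & re >= os[j]
        counts[j] <- sum(ov)
        hitAny <- hitAny | ov
    }
    names(counts) <- names(cds)
    list(counts = counts, N = sum(hitAny))
}

# Random counting instance: ORFs may overlap each other and reads may
# span several ORFs, which exercises the multi-ORF semantics.
randomInstance <- function(seed, maxOrfs = 50L, maxReads = 5000L,
                           refLen = 100000L) {
    set.seed(seed)
    nOrfs <- sample.int(maxOrfs, 1L)
    nReads <- sample.int(maxReads, 1L)
    os <- sample.int(refLen - 2000L, nOrfs)
    ol <- sample(200:2000, nOrfs, replace = TRUE)
    ann <- GenomeAnnotation(data.frame(
        feature_id = sprintf("g%03d", seq_len(nOrfs)),
        reference = "chr", start = os, end = os + ol - 1L,
        feature_class = "CDS"))
    rs <- sample.int(refLen, nReads, replace = TRUE)
    rl <- sample(30:150, nReads, replace = TRUE)
    reads <- makeReads(rs, rs + rl - 1L)
    list(annotation = ann, reads = reads)
}

# Hand-written SAM fixture exercising header, unmapped, secondary,
# multi-mapping (NH=2, MAPQ 0) and gapped records.
writeSamFixture <- function(path) {
    writeLines(c(
        "@HD\tVN:1.6\tSO:unknown",
        "@SQ\tSN:chr\tLN:100000",
        # 50-nt ungapped alignment at 101 -> [101, 150]
        "read1\t0\tchr\t101\t60\t50M\t*\t0\t0\t*\t*\tNH:i:1",
        # gapped: 30M5D20M consumes 55 reference nt -> [1001, 1055]
        "read2\t16\tchr\t1001\t60\t30M5D20M\t*\t0\t0\t*\t*\tNH:i:1",
        # multi-mapper: primary with NH=2, MAPQ 0 -> unique = FALSE
        "read3\t0\tchr\t2001\t0\t50M\t*\t0\t0\t*\t*\tNH:i:2",
        # its secondary record: never yielded
        "read3\t256\tchr\t5001\t0\t50M\t*\t0\t0\t*\t*\tNH:i:2",
        # unmapped record: skipped
        "read4\t4\t*\t0\t0\t*\t*\t0\t0\t*\t*",
        # soft-clipped: 10S40M consumes 40 nt -> [3001, 3040]
        "read5\t0\tchr\t3001\t60\t10S40M\t*\t0\t0\t*\t*\tNH:i:1"),
        path)
    path
}

# A small GFF3 fixture as text lines.
gff3Lines <- function() {
    c("##gff-version 3",
      "chr\tsim\tCDS\t1001\t2000\t.\t+\t0\tID=orfA",
      "chr\tsim\tCDS\t3001\t4500\t.\t-\t0\tID=orfB",
      "chr\tsim\tCDS\t5001\t5600\t.\t+\t0\tID=orfC",
      "chr\tsim\trRNA\t7001\t9000\t.\t+\t.\tID=rrn1",
      "chr\tsim\ttRNA\t9501\t9580\t.\t-\t.\tID=trn1",
      "chr\tsim\tregulatory_region\t9800\t9900\t.\t+\t.\tID=reg1")
}

# Small simulation config for fast end-to-end tests.
smallConfig <- function(seed = 11L, nOrfs = 40L, depth = 20000,
                        conditions = data.frame(
                            condition_id = c("base", "induced"),
                            replicates = c(2L, 1L)),
                        regulons = list(
                            regulonSpec("boost",
                                sprintf("ORF_%04d", 1:5),
                                foldFactors = list(induced = 20))),
                        ...) {
    simulationConfig(nOrfs = nOrfs, orfLengthRange = c(300L, 900L),
                     referenceLength = 200000L, regulons = regulons,
                     conditions = conditions, depth = depth,
                     seed = seed, ...)
}
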