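test_that("SAM records are read with correct intervals and uniqueness", {
    sam <- withr::local_tempfile(fileext = ".sam")
    writeSamFixture(sam)
    aln <- readAlignments(sam)

    # unmapped and secondary records are not yielded
    expect_length(aln, 4L)
    expect_identical(S4Vectors::mcols(aln)$read_id,
                     c("read1", "read2", "read3", "read5"))
    # 50-nt ungapped alignment starting at 101 spans [101, 150]
    expect_identical(GenomicRanges::start(aln)[1], 101L)
    expect_identical(GenomicRanges::end(aln)[1], 150L)
    # deletions consume reference space, soft clips do not
    expect_identical(GenomicRanges::end(aln)[2], 1055L)
    expect_identical(GenomicRanges::end(aln)[4], 3040L)
    # NH=2 / MAPQ 0 marks the multi-mapper, flags are definite
    expect_identical(S4Vectors::mcols(aln)$unique,
                     c(TRUE, TRUE, FALSE, TRUE))
    expect_identical(as.character(GenomicRanges::strand(aln)[2]), "-")
})

test_that("headerless SAM input is rejected", {
    sam <- withr::local_tempfile(fileext = ".sam")
    writeLines("read1\t0\tchr\t101\t60\t50M\t*\t0\t0\t*\t*", sam)
    expect_error(readAlignments(sam), "header")
})

test_that("the TSV alignment dialect round-trips", {
    reads <- makeReads(c(100, 500), c(149, 549),
                       unique = c(TRUE, FALSE))
    tsv <- withr::local_tempfile(fileext = ".tsv")
    writeAlignmentsTsv(reads, tsv)
    back <- readAlignments(tsv)
    expect_identical(GenomicRanges::start(back),
                     GenomicRanges::start(reads))
    expect_identical(GenomicRanges::end(back), GenomicRanges::end(reads))
    expect_identical(S4Vectors::mcols(back)$unique, c(TRUE, FALSE))
})

test_that("filtering removes non-unique then rRNA/tRNA-overlapping reads", {
    ann <- tinyAnnotation()
    reads <- makeReads(
        start = c(1100,  # unique, inside orfA -> retained
                  6952,  # unique, overlaps rrn1 [7001,9000] by exactly 1 nt
                  8000,  # unique, inside rrn1 -> removed
                  9580,  # unique, overlaps trn1 end by 1 nt -> removed
                  1200,  # non-unique over a CDS -> non-unique removal
                  8100), # non-unique AND rRNA: counted as non-unique
        end = c(1149, 7001, 8049, 9629, 1249, 8149),
        unique = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE))
    res <- filterAlignments(reads, ann)
    st <- res$stats

    expect_identical(st@nInput, 6L)
    expect_identical(st@nNonUniqueRemoved, 2L)
    expect_identical(st@nRrnaTrnaRemoved, 3L)
    expect_identical(st@nRetained, 1L)
    expect_identical(S4Vectors::mcols(res$alignments)$read_id, "r0001")
    # conservation is enforced by the class validity
    expect_true(validObject(st))
})

test_that("filtering is idempotent and tolerates empty input", {
    ann <- tinyAnnotation()
    set.seed(42)
    starts <- sample.int(9500, 300)
    reads <- makeReads(starts, starts + 49L,
                       unique = runif(300) > 0.1)
    once <- filterAlignments(reads, ann)
    twice <- filterAlignments(once$alignments, ann)
    expect_identical(twice$stats@nNonUniqueRemoved, 0L)
    expect_identical(twice$stats@nRrnaTrnaRemoved, 0L)
    expect_identical(length(twice$alignments), length(once$alignments))

    empty <- filterAlignments(makeReads(integer(), integer()), ann)
    expect_identical(empty$stats@nInput, 0L)
    expect_identical(empty$stats@nRetained, 0L)
})

test_that("retained reads round-trip through SAM with identical intervals", {
    ann <- tinyAnnotation()
    set.seed(7)
    starts <- sample.int(9000, 200)
    reads <- makeReads(starts, starts + 74L, unique = runif(200) > 0.2,
                       strand = sample(c("+", "-"), 200, TRUE))
    kept <- filterAlignments(reads, ann)$alignments
    sam <- withr::local_tempfile(fileext = ".sam")
    writeSam(kept, c(chr = 100000L), sam)
    back <- readAlignments(sam)
    expect_identical(GenomicRanges::start(back),
                     GenomicRanges::start(kept))
    expect_identical(GenomicRanges::end(back), GenomicRanges::end(kept))
    expect_identical(S4Vectors::mcols(back)$read_id,
                     S4Vectors::mcols(kept)$read_id)
    expect_identical(S4Vectors::mcols(back)$unique,
                     S4Vectors::mcols(kept)$unique)
})
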