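#' @include AllClasses.R AllGenerics.R
#' @importFrom stats pnorm pchisq p.adjust setNames
NULL

#' Condition ratio of relative abundances
#'
#' The per-ORF condition ratio: relative transcript abundance under the
#' comparison condition divided by the relative transcript abundance
#' under the baseline condition. When the baseline abundance is zero the
#' ratio is undefined and returned as `NA` (never printed as infinity);
#' the Haldane option instead shifts both underlying counts by +0.5
#' before forming abundances, which is handled in [compareConditions()].
#'
#' @param r1 Baseline relative abundance(s), non-negative.
#' @param r2 Comparison relative abundance(s), non-negative.
#' @return `r2 / r1`, with `NA` where `r1 == 0`.
#' @examples
#' foldRatio(0.001, 0.02)  # 20
#' foldRatio(0, 0.01)      # NA: undefined
#' @export
foldRatio <- function(r1, r2) {
    if (any(r1 < 0, na.rm = TRUE) || any(r2 < 0, na.rm = TRUE))
        stop("relative abundances must be non-negative")
    out <- r2 / r1
    out[r1 == 0] <- NA_real_
    out
}

#' Pooled two-proportion z-test for equal transcription
#'
#' Tests, for one ORF, whether the proportion of mRNA-mapping reads
#' falling in the ORF is the same in two conditions, using the pooled
#' two-proportion z statistic on (replicate-summed) counts:
#' \deqn{z = \frac{c_1/N_1 - c_2/N_2}
#'   {\sqrt{\hat p (1-\hat p)(1/N_1 + 1/N_2)}},\quad
#'   \hat p = \frac{c_1 + c_2}{N_1 + N_2}}
#' with a two-sided p-value from the standard normal. Degenerate tables
#' (pooled proportion 0 or 1) give `z = 0`, `p = 1`. All arguments are
#' vectorized over ORFs.
#'
#' @param c1,c2 ORF counts under conditions 1 and 2.
#' @param N1,N2 mRNA totals under conditions 1 and 2 (both > 0).
#' @return A list with numeric vectors `statistic` (z) and `p_value`.
#' @examples
#' zTestEqualTranscription(100, 1e5, 50, 1e5)  # z ~ 4.08, p ~ 4.4e-5
#' @export
zTestEqualTranscription <- function(c1, N1, c2, N2) {
    if (any(N1 <= 0) || any(N2 <= 0))
        stop("mRNA totals N1 and N2 must be positive")
    phat <- (c1 + c2) / (N1 + N2)
    se <- sqrt(phat * (1 - phat) * (1 / N1 + 1 / N2))
    z <- (c1 / N1 - c2 / N2) / se
    degenerate <- phat <= 0 | phat >= 1
    z[degenerate] <- 0
    p <- 2 * pnorm(-abs(z))
    p[degenerate] <- 1
    list(statistic = z, p_value = pmin(p, 1))
}

#' Pearson 2x2 chi-square test for equal transcription
#'
#' Tests equal transcription of one ORF between two single libraries via
#' the Pearson chi-square statistic (1 df, no continuity correction) on
#' the 2x2 table `[[c1, N1 - c1], [c2, N2 - c2]]`, with the p-value from
#' the upper tail of the chi-square(1) distribution. Without a
#' continuity correction the statistic equals the square of the pooled
#' two-proportion z statistic on the same counts. Degenerate tables (any
#' expected cell zero, i.e. `c1 + c2 == 0` or `c1 + c2 == N1 + N2`) give
#' `chi2 = 0`, `p = 1` with a warning. Vectorized over ORFs.
#'
#' @param c1,c2 ORF counts under conditions 1 and 2 (`c1 <= N1`,
#'   `c2 <= N2`).
#' @param N1,N2 mRNA totals under conditions 1 and 2 (both > 0).
#' @return A list with numeric vectors `statistic` (chi-square) and
#'   `p_value`.
#' @examples
#' chiSquareEqualTranscription(30, 1e4, 10, 1e4)  # chi2 ~ 10.02
#' @export
chiSquareEqualTranscription <- function(c1, N1, c2, N2) {
    if (any(N1 <= 0) || any(N2 <= 0))
        stop("mRNA totals N1 and N2 must be positive")
    if (any(c1 > N1) || any(c2 > N2))
        stop("counts cannot exceed their mRNA totals")
    c1 <- as.numeric(c1); c2 <- as.numeric(c2)   # avoid integer overflow
    N1 <- as.numeric(N1); N2 <- as.numeric(N2)
    tot <- N1 + N2
    m <- c1 + c2
    degenerate <- m == 0 | m == tot
    if (any(degenerate))
        warning(sum(degenerate),
                " degenerate 2x2 table(s): statistic set to 0, p to 1")
    num <- tot * (c1 * (N2 - c2) - c2 * (N1 - c1))^2
    den <- m * (tot - m) * N1 * N2
    stat <- ifelse(degenerate, 0, num / den)
    p <- pchisq(stat, df = 1, lower.tail = FALSE)
    p[degenerate] <- 1
    list(statistic = stat, p_value = p)
}

#' Classify a condition ratio against fold thresholds
#'
#' Assigns each ratio to a change class using the scheme's thresholds,
#' highest matching class first: with the default scheme, ratio >= 10 is
#' `up_10x`, >= 2 `up_2x`, <= 0.1 `down_90pct`, <= 0.5 `down_50pct`,
#' anything between `unchanged`. Undefined (`NA`) ratios map to
#' `undefined`. Boundaries are inclusive when the scheme says so.
#'
#' @param ratio Numeric vector of condition ratios (`NA` = undefined).
#' @param scheme A [ThresholdScheme-class].
#' @return Character vector of change classes; the classes partition
#'   `[0, Inf)` plus `undefined`.
#' @examples
#' classifyChange(c(12, 1.5, 0.08, NA))
#' @export
classifyChange <- function(ratio, scheme = thresholdScheme()) {
    stopifnot(is(scheme, "ThresholdScheme"))
    if (any(ratio < 0, na.rm = TRUE))
        stop("ratios must be non-negative")
    up <- scheme@upLevels
    down <- scheme@downLevels
    upLab <- sprintf("up_%gx", up)
    downLab <- sprintf("down_%gpct", round(100 * (1 - down)))
    out <- rep("unchanged", length(ratio))
    cmpUp <- if (scheme@boundaryInclusive) `>=` else `>`
    cmpDown <- if (scheme@boundaryInclusive) `<=` else `<`
    for (i in seq_along(up))          # ascending: strongest wins last
        out[!is.na(ratio) & cmpUp(ratio, up[i])] <- upLab[i]
    for (i in seq_along(down))        # most extreme reduction wins last
        out[!is.na(ratio) & cmpDown(ratio, down[i])] <- downLab[i]
    out[is.na(ratio)] <- "undefined"
    out
}

#' All change classes of a scheme, in display order
#'
#' @param scheme A [ThresholdScheme-class].
#' @return Character vector of class labels, strongest increase first.
#' @export
changeClasses <- function(scheme = thresholdScheme()) {
    c(rev(sprintf("up_%gx", scheme@upLevels)), "unchanged",
      sprintf("down_%gpct", round(100 * (1 - scheme@downLevels))),
      "undefined")
}

.pooledCounts <- function(group) {
    cs <- lapply(group@samples, counts)
    list(counts = Reduce(`+`, cs),
         N = sum(vapply(group@samples, totalMrnaCounts, numeric(1))))
}

#' Compare two conditions ORF by ORF
#'
#' Produces one row per protein-coding ORF: pooled counts and relative
#' abundances of the two groups, the condition ratio (comparison over
#' baseline), the equal-transcription test, a Benjamini-Hochberg
#' q-value over all ORFs, and the fold-threshold change class.
#' Replicate counts are summed within each group before abundances are
#' formed. The z-test is used when the baseline group is replicated;
#' with a single baseline library the 2x2 chi-square test is applied.
#' Undefined ratios (baseline abundance zero) are still tested, since
#' the counts permit testing; with `pseudocount = "haldane"` all counts
#' are shifted by +0.5 before abundances and ratios are formed, giving
#' finite ratios.
#'
#' @param baseline A [SampleGroup-class]: the basis of the comparison
#'   (condition 1).
#' @param other A [SampleGroup-class]: the comparison condition
#'   (condition 2).
#' @param scheme A [ThresholdScheme-class] for classification.
#' @param pseudocount `"none"` (default) or `"haldane"`.
#' @return A `data.frame` with columns `feature_id`, `c_baseline`,
#'   `c_other`, `N_baseline`, `N_other`, `r_baseline`, `r_other`,
#'   `ratio`, `statistic`, `test_used`, `p_value`, `q_value`,
#'   `change_class`, in annotation (feature universe) order.
#' @examples
#' ct <- function(id, c1, c2) OrfCountTable(id,
#'     c(gA = c1, gB = c2), c1 + c2)
#' base <- SampleGroup("ctrl", list(ct("c1", 50, 50), ct("c2", 45, 55)))
#' trt <- SampleGroup("trt", ct("t1", 90, 10))
#' compareConditions(base, trt)
#' @export
compareConditions <- function(baseline, other,
                              scheme = thresholdScheme(),
                              pseudocount = c("none", "haldane")) {
    stopifnot(is(baseline, "SampleGroup"), is(other, "SampleGroup"))
    pseudocount <- match.arg(pseudocount)
    u1 <- names(baseline@samples[[1]]@counts)
    u2 <- names(other@samples[[1]]@counts)
    if (!identical(u1, u2)) {
        off <- c(setdiff(u1, u2), setdiff(u2, u1))
        stop("mismatched feature universes between groups; offending feature_ids: ",
             paste(utils::head(off, 10L), collapse = ", "),
             if (length(off) > 10L) ", ..." else "")
    }
    p1 <- .pooledCounts(baseline)
    p2 <- .pooledCounts(other)
    c1 <- p1$counts; N1 <- p1$N
    c2 <- p2$counts; N2 <- p2$N
    if (pseudocount == "haldane") {
        r1 <- (c1 + 0.5) / (N1 + 0.5 * length(c1))
        r2 <- (c2 + 0.5) / (N2 + 0.5 * length(c2))
        ratio <- r2 / r1
    } else {
        r1 <- c1 / N1
        r2 <- c2 / N2
        ratio <- foldRatio(r1, r2)
    }
    if (isReplicated(baseline)) {
        testUsed <- "z_test"
        tst <- zTestEqualTranscription(c1, N1, c2, N2)
    } else {
        testUsed <- "chi_square"
        tst <- suppressWarnings(
            chiSquareEqualTranscription(c1, N1, c2, N2))
    }
    data.frame(
        feature_id = names(c1),
        c_baseline = unname(c1),
        c_other = unname(c2),
        N_baseline = N1,
        N_other = N2,
        r_baseline = unname(r1),
        r_other = unname(r2),
        ratio = unname(ratio),
        statistic = unname(tst$statistic),
        test_used = testUsed,
        p_value = unname(tst$p_value),
        q_value = p.adjust(unname(tst$p_value), method = "BH"),
        change_class = unname(classifyChange(ratio, scheme)),
        row.names = NULL, stringsAsFactors = FALSE)
}

#' Write a comparison result table to TSV
#'
#' @param results Data frame from [compareConditions()].
#' @param path Output path.
#' @param baselineId,otherId Optional condition identifiers recorded as
#'   `#key=value` header comments.
#' @return `path`, invisibly.
#' @export
writeComparison <- function(results, path, baselineId = NULL,
                            otherId = NULL) {
    con <- file(path, "w")
    on.exit(close(con))
    if (!is.null(baselineId))
        writeLines(sprintf("#baseline=%s", baselineId), con)
    if (!is.null(otherId))
        writeLines(sprintf("#other=%s", otherId), con)
    out <- results
    for (col in c("r_baseline", "r_other", "ratio", "statistic",
                  "p_value", "q_value"))
        out[[col]] <- .fmtNum(results[[col]])
    utils::write.table(out, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
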