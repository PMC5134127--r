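# Fixture builders and the independent Smith-Waterman oracle used to
# cross-check the seed-and-extend engine. The oracle path goes through
# Biostrings::pairwiseAlignment and shares nothing with the package's
# alignment code beyond the decision thresholds.

randSeq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                             collapse = "")

mutateSeq <- function(s, rate) {
    v <- strsplit(s, "")[[1]]
    n <- rbinom(1, length(v), rate)
    if (n > 0) {
        pos <- sample.int(length(v), n)
        for (p in pos) v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1)
    }
    paste(v, collapse = "")
}

## best local alignment under match +1 / mismatch -2 / linear gap -2
oracleAlign <- function(q, t) {
    aln <- Biostrings::pairwiseAlignment(q, t, type = "local",
        substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
            match = 1, mismatch = -2, baseOnly = TRUE),
        gapOpening = 0, gapExtension = 2)
    len <- Biostrings::nchar(aln)
    list(score = Biostrings::score(aln), length = len,
         identity = if (len > 0) Biostrings::nmatch(aln) / len else 0)
}

## same decision contract as the engine, computed from oracle alignments
oracleHitMatrix <- function(qseqs, tseqs, params = homologyParams()) {
    dbLen <- sum(nchar(tseqs))
    out <- matrix(FALSE, length(qseqs), length(tseqs))
    for (i in seq_along(qseqs)) for (j in seq_along(tseqs)) {
        a <- oracleAlign(qseqs[i], tseqs[j])
        ev <- 0.621 * nchar(qseqs[i]) * dbLen * exp(-1.33 * a$score)
        out[i, j] <- a$length >= params@minAlignmentLength &&
            a$identity >= params@minIdentity && ev <= params@evalueThreshold
    }
    out
}

## engine-side per-pair hit booleans in the same matrix layout
engineHitMatrix <- function(qseqs, tseqs, params = homologyParams()) {
    names(qseqs) <- paste0("q", seq_along(qseqs))
    names(tseqs) <- paste0("t", seq_along(tseqs))
    idx <- buildHomologyIndex(tseqs, params)
    hits <- viroshare:::.queryIndex(qseqs, idx)
    ok <- viroshare:::.applyThresholds(hits, params)
    out <- matrix(FALSE, length(qseqs), length(tseqs))
    out[cbind(hits$query[ok], hits$target[ok])] <- TRUE
    out
}

## a minimal hand-built cohort: n subjects x timepoints at one site, with a
## caller-supplied list of per-sample contig character vectors
makeCohort <- function(samples, contigs) {
    ViromeCohort(samples, lapply(contigs, function(x)
        Biostrings::DNAStringSet(x)))
}

## two-household + control skeleton used across tests
smallDesign <- function(tps = c("day0", "day3")) {
    subj <- data.frame(
        subject_id = c("S01", "S02", "S03", "S04", "C01"),
        household_id = c("H01", "H01", "H02", "H02", "HC01"),
        treatment = c("amoxicillin", "placebo", "azithromycin", "placebo", "none"))
    do.call(rbind, lapply(seq_len(nrow(subj)), function(i)
        data.frame(subj[i, ], body_site = "feces", timepoint = tps,
                   row.names = NULL)))
}
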