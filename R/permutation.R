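## Resampling test for individual- and household-specific virome overlap.
##
## Per iteration a "within" shared fraction is drawn from a random pair of
## the unit's own samples and a "between" fraction from a random pair of
## samples of two distinct other units; the empirical p-value is the
## fraction of iterations in which the between draw reaches the within draw
## (ties count against significance, making the test conservative).

#' One resampled shared-homologue percentage
#'
#' Samples `nContigs` contigs from the source virome (without replacement if
#' the virome has at least that many contigs, with replacement otherwise)
#' and returns 100 times the fraction carrying a significant homologue in
#' the target, given the per-contig hit flags of the ordered pair.
#'
#' @param flags logical vector: per-source-contig homologue flags against
#'   the target (one entry of a [computeHitFlags()] object).
#' @param nContigs number of contigs to sample.
#' @return percentage in [0, 100].
#' @export
drawSharedFraction <- function(flags, nContigs = 1000L) {
    if (!length(flags)) stop("empty virome")
    100 * mean(flags[sample.int(length(flags), nContigs,
                                replace = length(flags) < nContigs)])
}

.permResult <- function(unit, w, b, params) {
    p <- mean(b >= w)
    data.frame(unit_id = unit,
               within_mean = mean(w), within_sd = stats::sd(w),
               between_mean = mean(b), between_sd = stats::sd(b),
               p_value = p,
               p_label = if (p == 0)
                   sprintf("<%g", 1 / params@nIterations) else
                   format(p, digits = 4),
               n_iterations = params@nIterations,
               n_contigs_per_draw = params@nContigsPerDraw,
               stringsAsFactors = FALSE)
}

#' Individual-specific virome overlap test
#'
#' Per iteration, a within draw takes two distinct random time points of the
#' subject and resamples the shared fraction between them; a between draw
#' does the same for random time points of two distinct randomly chosen
#' subjects (the inter-subject null). p is the fraction of iterations with
#' between >= within; a p of 0 is reported as `<1/n` in `p_label` and stored
#' as 0.
#'
#' @param subject subject id.
#' @param hitFlags a [computeHitFlags()] object.
#' @param params a [PermutationParams-class].
#' @return one-row data.frame: `unit_id`, `within_mean`, `within_sd`,
#'   `between_mean`, `between_sd`, `p_value`, `p_label`, parameter echo.
#'   Means and SDs are percentages.
#' @export
subjectOverlapTest <- function(subject, hitFlags, params = permutationParams()) {
    sm <- hitFlags$samples
    own <- sm$sample_id[sm$subject_id == subject]
    if (length(own) < 2L)
        stop("subject ", subject, " has fewer than 2 usable time points")
    allSubj <- unique(sm$subject_id)
    if (length(allSubj) < 2L) stop("need at least one other subject")
    bySubj <- split(sm$sample_id, sm$subject_id)[allSubj]
    set.seed(params@seed)
    N <- params@nIterations
    w <- b <- numeric(N)
    for (i in seq_len(N)) {
        pair <- own[sample.int(length(own), 2L)]
        w[i] <- drawSharedFraction(hitFlags$flags[[pair[1]]][[pair[2]]],
                                   params@nContigsPerDraw)
        ss <- allSubj[sample.int(length(allSubj), 2L)]
        s1 <- bySubj[[ss[1]]]; s2 <- bySubj[[ss[2]]]
        q <- s1[sample.int(length(s1), 1L)]
        t <- s2[sample.int(length(s2), 1L)]
        b[i] <- drawSharedFraction(hitFlags$flags[[q]][[t]],
                                   params@nContigsPerDraw)
    }
    .permResult(subject, w, b, params)
}

#' Household-specific virome overlap test
#'
#' Within draws resample shared fractions between samples of the two
#' housemates; null draws use cross-subject pairs from two distinct other
#' households (controls included).
#'
#' @param household household id of a two-person household.
#' @inheritParams subjectOverlapTest
#' @return one-row data.frame as for [subjectOverlapTest()].
#' @export
householdOverlapTest <- function(household, hitFlags,
                                 params = permutationParams()) {
    sm <- hitFlags$samples
    members <- unique(sm$subject_id[sm$household_id == household])
    if (length(members) != 2L)
        stop("household ", household, " is not a usable two-person household")
    bySubj <- split(sm$sample_id, sm$subject_id)
    hhOf <- vapply(split(sm$household_id, sm$subject_id), `[`, "", 1)
    allSubj <- names(bySubj)
    set.seed(params@seed)
    N <- params@nIterations
    w <- b <- numeric(N)
    for (i in seq_len(N)) {
        d <- if (stats::runif(1) < 0.5) members else rev(members)
        s1 <- bySubj[[d[1]]]; s2 <- bySubj[[d[2]]]
        q <- s1[sample.int(length(s1), 1L)]
        t <- s2[sample.int(length(s2), 1L)]
        w[i] <- drawSharedFraction(hitFlags$flags[[q]][[t]],
                                   params@nContigsPerDraw)
        repeat {
            ss <- allSubj[sample.int(length(allSubj), 2L)]
            if (hhOf[ss[1]] != hhOf[ss[2]] &&
                !all(ss %in% members)) break
        }
        s1 <- bySubj[[ss[1]]]; s2 <- bySubj[[ss[2]]]
        q <- s1[sample.int(length(s1), 1L)]
        t <- s2[sample.int(length(s2), 1L)]
        b[i] <- drawSharedFraction(hitFlags$flags[[q]][[t]],
                                   params@nContigsPerDraw)
    }
    .permResult(household, w, b, params)
}

#' Overlap tests for every subject or two-person household
#'
#' Runs [subjectOverlapTest()] (or [householdOverlapTest()]) for each
#' eligible unit, deriving one seed per unit from `params@seed` so the table
#' is reproducible as a whole.
#'
#' @param hitFlags a [computeHitFlags()] object.
#' @param params a [PermutationParams-class].
#' @param unit `"subject"` or `"household"`.
#' @return data.frame with one row per unit, mirroring the per-unit tests.
#' @export
overlapTestTable <- function(hitFlags, params = permutationParams(),
                             unit = c("subject", "household")) {
    unit <- match.arg(unit)
    sm <- hitFlags$samples
    if (unit == "subject") {
        units <- names(which(table(sm$subject_id) >= 2))
        fun <- subjectOverlapTest
    } else {
        cnt <- vapply(split(sm$subject_id, sm$household_id),
                      function(x) length(unique(x)), 1L)
        units <- names(which(cnt == 2L))
        fun <- householdOverlapTest
    }
    res <- lapply(seq_along(units), function(i) {
        pi <- permutationParams(params@nIterations, params@nContigsPerDraw,
                                params@seed + i)
        fun(units[i], hitFlags, pi)
    })
    do.call(rbind, res)
}
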