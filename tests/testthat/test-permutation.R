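test_that("resampled shared fractions hit the exact extremes and midpoints", {
    set.seed(30)
    expect_equal(drawSharedFraction(rep(TRUE, 20), 1000), 100)
    expect_equal(drawSharedFraction(rep(FALSE, 20), 1000), 0)
    ## 4 contigs, 2 with homologues, draw of 4 without replacement covers all
    expect_equal(drawSharedFraction(c(TRUE, TRUE, FALSE, FALSE), 4), 50)
    expect_error(drawSharedFraction(logical(0), 10), "empty")
})

## a small cohort with complete separation: every within-subject pair shares
## everything, every between-subject pair shares nothing
separatedCohort <- function(nSubj = 4, tps = c("day0", "day3", "day7")) {
    subj <- sprintf("S%02d", seq_len(nSubj))
    sm <- expand.grid(timepoint = tps, subject_id = subj,
                      stringsAsFactors = FALSE)[, 2:1]
    sm$household_id <- paste0("H", sm$subject_id)
    sm$body_site <- "feces"; sm$treatment <- "none"
    own <- lapply(subj, function(s)
        setNames(replicate(3, randSeq(400)), paste0("c", 1:3)))
    names(own) <- subj
    makeCohort(sm, lapply(seq_len(nrow(sm)), function(i) own[[sm$subject_id[i]]]))
}

test_that("complete separation drives p to the resolution floor", {
    set.seed(31)
    co <- separatedCohort()
    hf <- computeHitFlags(co, "feces")
    r <- subjectOverlapTest("S01", hf, permutationParams(nIterations = 500, seed = 1))
    expect_equal(r$within_mean, 100)
    expect_lt(r$between_mean, 100 / 3) # between draws can involve S01 itself
    expect_identical(r$p_value, 0)
    expect_identical(r$p_label, "<0.002")
    ## identical seeds reproduce the result exactly; the floor holds under
    ## any relabelling of the other subjects
    r2 <- subjectOverlapTest("S01", hf, permutationParams(nIterations = 500, seed = 1))
    expect_identical(r, r2)
})

test_that("the exhaustible tiny cohort matches enumeration within Monte Carlo error", {
    set.seed(32)
    shared <- setNames(c(randSeq(400), randSeq(400)), c("c1", "c2"))
    subjB <- setNames(c(shared[[1]], randSeq(400)), c("c1", "c2"))
    sm <- expand.grid(timepoint = c("day0", "day3"),
                      subject_id = c("S01", "S02"),
                      stringsAsFactors = FALSE)[, 2:1]
    sm$household_id <- paste0("H", sm$subject_id)
    sm$body_site <- "feces"; sm$treatment <- "none"
    co <- makeCohort(sm, list(shared, shared, subjB, subjB))
    hf <- computeHitFlags(co, "feces")
    ## enumeration oracle: within pairs of each subject share fraction 1;
    ## every cross-subject ordered pair shares 1/2; a full draw (n = 2,
    ## without replacement) makes every draw deterministic, so
    ## p(S01) = P(b >= w) where w = 100 always and b = 50 always -> 0...
    ## except iterations whose two random subjects are both S01 or both S02
    ## are impossible (subjects are distinct), so p = 0 exactly; for S02 the
    ## within pair is also 1, same enumeration
    pp <- permutationParams(nIterations = 400, nContigsPerDraw = 2, seed = 9)
    expect_identical(subjectOverlapTest("S01", hf, pp)$p_value, 0)
    ## now make S02's two time points share nothing with each other:
    ## within(S02) = 0 always, between draws >= 0 always -> p = 1
    co2 <- makeCohort(sm, list(shared, shared,
                               setNames(c(shared[[1]], randSeq(400)), c("c1", "c2")),
                               setNames(c(randSeq(400), randSeq(400)), c("c1", "c2"))))
    hf2 <- computeHitFlags(co2, "feces")
    expect_identical(subjectOverlapTest("S02", hf2, pp)$p_value, 1)
})

test_that("household test separates sharing households from strangers", {
    set.seed(33)
    tps <- c("day0", "day3")
    sm <- smallDesign(tps)
    hhSeqs <- setNames(replicate(3, randSeq(500)), paste0("c", 1:3))
    strangers <- function() setNames(replicate(3, randSeq(500)), paste0("c", 1:3))
    ctg <- lapply(seq_len(nrow(sm)), function(i)
        if (sm$household_id[i] == "H01") hhSeqs else strangers())
    ## H01's members share everything; everyone else is unrelated
    co <- makeCohort(sm, ctg)
    hf <- computeHitFlags(co, "feces")
    pp <- permutationParams(nIterations = 300, seed = 2)
    r <- householdOverlapTest("H01", hf, pp)
    expect_equal(r$within_mean, 100)
    expect_identical(r$p_value, 0)
    expect_error(householdOverlapTest("HC01", hf, pp), "two-person")
    ## deterministic given the seed
    expect_identical(r, householdOverlapTest("H01", hf, pp))
})

test_that("under an iid null the test is centred and never anticonservative", {
    ## the within and between draws are exchangeable when viromes are iid,
    ## so p concentrates near 1/2 and the rejection rate at 0.05 must not
    ## exceed nominal (the test is conservative under its own design; see
    ## the methods vignette for why p is not uniform)
    nC <- 12
    ps <- numeric(0)
    for (k in seq_len(nC)) {
        sim <- simulateCohort(nullPoolConfig(seed = 100 + k))
        hf <- suppressMessages(computeHitFlags(sim$cohort, "feces"))
        tab <- overlapTestTable(hf, permutationParams(nIterations = 200,
                                                      seed = k))
        ps <- c(ps, tab$p_value)
    }
    expect_gte(length(ps), 40)
    expect_gt(mean(ps), 0.35)
    expect_lt(mean(ps), 0.65)
    ## empirical type-I error at 0.05 stays at or below nominal + 3 SE
    expect_lte(mean(ps <= 0.05), 0.05 + 3 * sqrt(0.05 * 0.95 / length(ps)))
})

test_that("overlap table runs one test per eligible unit", {
    set.seed(34)
    co <- separatedCohort(3)
    hf <- computeHitFlags(co, "feces")
    tab <- overlapTestTable(hf, permutationParams(nIterations = 100, seed = 5))
    expect_identical(tab$unit_id, c("S01", "S02", "S03"))
    expect_true(all(tab$p_value == 0))
})
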