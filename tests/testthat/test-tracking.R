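# helper: one subject sampled at several time points with given contig sets
subjectCohort <- function(contigsByTp, subject = "S01", site = "feces") {
    tps <- names(contigsByTp)
    sm <- data.frame(subject_id = subject, household_id = paste0("H", subject),
                     body_site = site, timepoint = tps, treatment = "none")
    makeCohort(sm, unname(contigsByTp))
}

# helper: a two-person household with per-subject, per-timepoint contigs
householdCohort <- function(bySubject, treatments = c("placebo", "amoxicillin"),
                            missing = character(0)) {
    rows <- list(); ctg <- list()
    for (i in seq_along(bySubject)) {
        s <- names(bySubject)[i]
        for (tp in names(bySubject[[i]])) {
            rows[[length(rows) + 1L]] <- data.frame(
                subject_id = s, household_id = "H01", body_site = "feces",
                timepoint = tp, treatment = treatments[i],
                missing = sampleId(s, "feces", tp) %in% missing)
            ctg[[length(ctg) + 1L]] <- if (sampleId(s, "feces", tp) %in% missing)
                character(0) else bySubject[[i]][[tp]]
        }
    }
    makeCohort(do.call(rbind, rows), ctg)
}

test_that("clustering merges identical contigs and splits unrelated ones", {
    set.seed(40)
    a <- randSeq(600); b <- randSeq(500)
    co <- subjectCohort(list(day0 = c(x = a, y = b),
                             day3 = c(x = a, z = randSeq(700))))
    gv <- clusterGlobalViruses(co, "subject", "S01", "feces")
    expect_identical(length(unique(gv$members$virus_id)), 3L)
    ## the virus carrying the identical contig is present at both time points
    both <- table(gv$presence$virus_id)
    expect_identical(sum(both == 2), 1L)
    expect_identical(sum(both == 1), 2L)
    expect_error(clusterGlobalViruses(co, "subject", "nobody", "feces"),
                 "no non-missing")
})

test_that("single linkage chains a~b~c into one virus and ids ignore input order", {
    set.seed(41)
    g <- randSeq(1200)
    a <- substr(g, 1, 700)     # a overlaps b, b overlaps c, a does not meet c
    b <- substr(g, 350, 1050)
    c3 <- substr(g, 701, 1200)
    ## connected-components oracle over brute-force pairwise alignments
    lens <- nchar(c(a, b, c3))
    link <- matrix(FALSE, 3, 3)
    for (i in 1:3) for (j in 1:3) {
        if (i == j) next
        al <- oracleAlign(c(a, b, c3)[i], c(a, b, c3)[j])
        link[i, j] <- al$identity >= 0.98 && al$length >= 0.5 * min(lens[c(i, j)])
    }
    expect_true(link[1, 2] && link[2, 3] && !link[1, 3])
    co <- subjectCohort(list(day0 = c(a = a), day3 = c(b = b), day7 = c(c = c3)))
    gv <- clusterGlobalViruses(co, "subject", "S01", "feces")
    expect_identical(length(unique(gv$members$virus_id)), 1L)
    ## permutation invariance: shuffled contig input order, same clusters
    co2 <- subjectCohort(list(day0 = c(a = a), day3 = c(b = b), day7 = c(c = c3)))
    perm <- subjectCohort(list(day7 = c(c = c3), day0 = c(a = a), day3 = c(b = b)))
    gvp <- clusterGlobalViruses(perm, "subject", "S01", "feces")
    ord <- function(x) x$members[order(x$members$sample_id, x$members$contig_id), ]
    expect_identical(ord(gvp)$virus_id, ord(gv)$virus_id)
})

test_that("persistence spans use day offsets and thresholds are nested", {
    set.seed(42)
    v1 <- randSeq(500); v2 <- randSeq(500); v3 <- randSeq(500)
    co <- subjectCohort(list(
        day0 = c(a = v1, b = v2, c = v3),
        day3 = c(a = v1),
        day7 = c(a = v1, b = v2),
        week8 = c(a = v1),
        month6 = c(a = v1)))
    gv <- clusterGlobalViruses(co, "subject", "S01", "feces")
    ps <- persistenceSummary(gv)
    expect_identical(ps$n_viruses, 3L)
    expect_identical(sort(unname(ps$spans)), c(0, 7, 182))
    expect_equal(ps$fraction_ge_4_days, 2 / 3)  # spans 7 and 182
    expect_equal(ps$fraction_ge_150_days, 1 / 3) # span 182 only
    expect_gte(ps$fraction_ge_4_days, ps$fraction_ge_150_days)
})

test_that("household sharing partitions viruses by carrier and arm", {
    set.seed(43)
    shared <- replicate(3, randSeq(400))
    uP <- replicate(4, randSeq(400)); uA <- replicate(3, randSeq(400))
    co <- householdCohort(list(
        P = list(day0 = setNames(c(shared, uP), paste0("p", 1:7))),
        A = list(day0 = setNames(c(shared, uA), paste0("a", 1:6)))))
    gv <- clusterGlobalViruses(co, "household", "H01", "feces")
    hs <- householdSharing(gv, co)
    expect_identical(hs$n_viruses_total, 10L)
    expect_identical(hs$n_shared, 3L)
    expect_identical(hs$n_unique_placebo, 4L)
    expect_identical(hs$n_unique_antibiotic, 3L)
    expect_identical(hs$n_shared + hs$n_unique_placebo + hs$n_unique_antibiotic,
                     hs$n_viruses_total)
})

test_that("the transmission rule fires only on late reappearance in >= 2 time points", {
    set.seed(44)
    v <- randSeq(600); filler <- function() setNames(randSeq(400), "f")
    tps <- timepointLevels()
    mk <- function(donorTps, recipTps, missing = character(0)) {
        P <- lapply(setNames(tps, tps), function(tp)
            if (tp %in% donorTps) c(v = v, filler()) else filler())
        A <- lapply(setNames(tps, tps), function(tp)
            if (tp %in% recipTps) c(v = v, filler()) else filler())
        householdCohort(list(P = P, A = A), missing = missing)
    }
    ## textbook case: donor always positive, recipient turns positive late
    co <- mk(tps, c("week8", "month6"))
    calls <- callTransmissions(clusterGlobalViruses(co, "household", "H01", "feces"), co)
    expect_identical(nrow(calls), 1L)
    expect_identical(calls$donor, "P")
    expect_identical(calls$recipient, "A")
    expect_identical(calls$donor_first, "day0")
    expect_identical(calls$recipient_first, "week8")
    expect_identical(calls$direction_class, "placebo_to_antibiotic")
    ## both housemates positive throughout: never absent, no call
    co <- mk(tps, tps)
    expect_identical(nrow(callTransmissions(
        clusterGlobalViruses(co, "household", "H01", "feces"), co)), 0L)
    ## a single late reappearance is not enough
    co <- mk(tps, "month6")
    expect_identical(nrow(callTransmissions(
        clusterGlobalViruses(co, "household", "H01", "feces"), co)), 0L)
    ## a missing recipient specimen in the pre-window blocks the call
    co <- mk(tps, c("week8", "month6"), missing = "A_feces_day0")
    expect_identical(nrow(callTransmissions(
        clusterGlobalViruses(co, "household", "H01", "feces"), co)), 0L)
    ## equal first presence: shared but directionless, no call
    co <- mk(tps, tps[c(1, 4, 5)])
    expect_identical(nrow(callTransmissions(
        clusterGlobalViruses(co, "household", "H01", "feces"), co)), 0L)
})

test_that("directionality summary partitions transmissions and handles zero calls", {
    sharing <- data.frame(household_id = c("H01", "H02"),
                          n_viruses_total = c(10L, 20L), n_shared = c(3L, 5L),
                          n_unique_placebo = c(4L, 10L),
                          n_unique_antibiotic = c(3L, 5L))
    noCalls <- callTransmissions0 <- data.frame(
        household_id = character(), direction_class = character())
    d0 <- directionalitySummary(sharing, noCalls)
    expect_equal(d0$summary$mean_pct,
                 c(100 * mean(c(3 / 10, 5 / 20)), 0, 0, 0))
    calls <- data.frame(
        household_id = c("H01", "H01", "H02"),
        direction_class = c("placebo_to_antibiotic", "placebo_to_antibiotic",
                            "antibiotic_to_placebo"))
    d <- directionalitySummary(sharing, calls)
    ph <- d$per_household
    expect_equal(ph$p2a_pct + ph$a2p_pct, ph$transmitted_pct)
    expect_equal(ph$transmitted_pct, c(20, 5))
})

test_that("planted transmissions with directional bias never go the other way", {
    cfg <- simulationConfig(nHouseholdsTwoPerson = 3, nControls = 0,
        bodySites = "feces", transmissionRate = 2,
        transmissionDirectionBias = 1, missingSampleProb = 0,
        nBackgroundPool = 0, dropLastHouseholdMonth6 = FALSE, seed = 45)
    sim <- simulateCohort(cfg)
    tr <- sim$truth$transmissions
    expect_gt(nrow(tr), 0)
    sm <- unique(as.data.frame(sampleData(sim$cohort))[, c("subject_id", "treatment")])
    expect_true(all(sm$treatment[match(tr$donor, sm$subject_id)] == "placebo"))
    calls <- do.call(rbind, lapply(unique(tr$household_id), function(h)
        callTransmissions(clusterGlobalViruses(sim$cohort, "household", h,
                                               "feces"), sim$cohort)))
    expect_true(all(calls$direction_class == "placebo_to_antibiotic"))
})
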