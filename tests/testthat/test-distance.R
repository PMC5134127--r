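test_that("Sorensen similarity follows the reciprocal-hit formula", {
    rec <- function(q, t, n, h) data.frame(query_sample = q, target_sample = t,
                                           n_query = n, n_hit = h)
    ## identical viromes: everything reciprocally hit
    expect_equal(sorensenSimilarity(rec("A", "B", 4, 4), rec("B", "A", 4, 4)), 1)
    ## no sharing either way
    expect_equal(sorensenSimilarity(rec("A", "B", 4, 0), rec("B", "A", 3, 0)), 0)
    ## 3 + 3 contigs, one reciprocal pair: (1 + 1) / 6
    expect_equal(sorensenSimilarity(rec("A", "B", 3, 1), rec("B", "A", 3, 1)), 1 / 3)
    expect_error(sorensenSimilarity(rec("A", "B", 3, 1), rec("C", "A", 3, 1)),
                 "same unordered pair")
})

test_that("similarity and distance matrices are exact complements", {
    set.seed(20)
    sm <- smallDesign()[c(1, 3, 5, 9), ] # one sample for each of 4 subjects
    shared <- randSeq(600)
    ctg <- list(c(a1 = shared, a2 = randSeq(400), a3 = randSeq(500)),
                c(b1 = shared, b2 = randSeq(450), b3 = randSeq(350)),
                c(c1 = randSeq(500), c2 = randSeq(400)),
                c(d1 = randSeq(300)))
    co <- makeCohort(sm, ctg)
    tab <- allPairsShared(co, "feces")
    S <- sorensenMatrix(tab)
    D <- brayCurtisMatrix(tab)
    expect_true(isSymmetric(S) && isSymmetric(D))
    expect_equal(unname(D), unname(1 - S) - diag(diag(1 - S)))
    expect_equal(diag(S), setNames(rep(1, 4), rownames(S)))
    expect_equal(diag(D), setNames(rep(0, 4), rownames(D)))
    ## the one reciprocally shared contig pair: (1+1)/(3+3)
    expect_equal(S["S01_feces_day0", "S02_feces_day0"], 1 / 3)
    expect_equal(D["S01_feces_day0", "S02_feces_day0"], 2 / 3)
    ## disjoint viromes sit at maximum distance
    expect_equal(D["S03_feces_day0", "C01_feces_day0"], 1)
    expect_error(brayCurtisMatrix(tab[-2, ]), "incomplete")
})

test_that("PCoA reproduces distances of planar configurations", {
    set.seed(21)
    X <- matrix(rnorm(10), 5, 2)
    D <- as.matrix(dist(X))
    ord <- pcoaOrdination(D, nAxes = 2)
    expect_equal(as.matrix(dist(ord$coordinates)), D, ignore_attr = TRUE,
                 tolerance = 1e-8)
    expect_true(all(diff(ord$eigenvalues) <= 1e-8)) # non-increasing
    expect_lte(sum(ord$proportion_explained), 1 + 1e-12)
    ## three equidistant points: an equilateral triangle, first two axes tie
    D3 <- 1 - diag(3)
    ord3 <- pcoaOrdination(D3, nAxes = 2)
    expect_equal(ord3$eigenvalues[1], ord3$eigenvalues[2])
    expect_equal(as.vector(dist(ord3$coordinates)), rep(1, 3))
    ## degenerate all-zero input: all coordinates zero
    ordz <- pcoaOrdination(matrix(0, 4, 4), nAxes = 2)
    expect_true(all(ordz$coordinates == 0))
    expect_error(pcoaOrdination(matrix(c(0, 1, 0.5, 0), 2, 2), 1), "symmetric")
})

test_that("household comparison groups cross-subject pairs and matches wilcox", {
    ids <- c("S01_feces_day0", "S01_feces_day3", "S02_feces_day0",
             "S03_feces_day0", "S04_feces_day0", "C01_feces_day0")
    sm <- data.frame(sample_id = ids,
                     subject_id = substr(ids, 1, 3),
                     household_id = c("H01", "H01", "H01", "H02", "H02", "HC01"))
    n <- length(ids)
    set.seed(22)
    M <- matrix(0, n, n, dimnames = list(ids, ids))
    vals <- runif(n * (n - 1) / 2)
    M[upper.tri(M)] <- vals
    M <- M + t(M); diag(M) <- 1
    ## the same-subject pair S01 day0/day3 gets an extreme value that must
    ## not leak into either group
    M["S01_feces_day0", "S01_feces_day3"] <- 42
    M["S01_feces_day3", "S01_feces_day0"] <- 42
    r <- householdDistanceComparison(M, sm)
    subj <- sm$subject_id; hh <- sm$household_id
    w <- b <- numeric(0)
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
        if (subj[i] == subj[j]) next
        if (hh[i] == hh[j]) w <- c(w, M[i, j]) else b <- c(b, M[i, j])
    }
    expect_identical(r$n_within, length(w))
    expect_identical(r$n_between, length(b))
    expect_equal(r$within_mean, mean(w))
    expect_lt(max(w, b), 2) # the 42 was excluded
    ref <- wilcox.test(w, b, exact = FALSE)
    expect_equal(r$p, ref$p.value)
    expect_equal(r$U, unname(ref$statistic))
})

test_that("small tie-free groups get an exact Mann-Whitney p", {
    ## 2 households x 2 subjects, 1 sample each: within = {1, 2} (the two
    ## intra-household pairs), between = {3, 4, 5, 6} (the four cross ones)
    ids <- paste0("S0", 1:4, "_feces_day0")
    sm <- data.frame(sample_id = ids, subject_id = substr(ids, 1, 3),
                     household_id = c("H01", "H01", "H02", "H02"))
    M <- matrix(0, 4, 4, dimnames = list(ids, ids))
    M[1, 2] <- 1; M[3, 4] <- 2
    M[1, 3] <- 3; M[1, 4] <- 4; M[2, 3] <- 5; M[2, 4] <- 6
    M <- M + t(M); diag(M) <- 1
    r <- householdDistanceComparison(M, sm)
    expect_identical(r$U, 0)
    ## enumeration oracle: U over every assignment of 2 of the 6 values to
    ## the within group; two-sided p doubles the lower tail of U = 0
    vals <- 1:6
    Us <- apply(combn(6, 2), 2, function(ix) {
        w <- vals[ix]; b <- vals[-ix]
        sum(outer(w, b, ">"))
    })
    pExact <- min(1, 2 * mean(Us <= 0))
    expect_equal(r$p, pExact)
})
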