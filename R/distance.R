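## Sorensen similarity, Bray-Curtis distance, PCoA ordination, and the
## within- vs between-household comparison.

#' Sorensen similarity of one virome pair
#'
#' Computed from the reciprocal homologue-hit counts of the ordered pair:
#' (n_hit(A->B) + n_hit(B->A)) / (n_A + n_B). On a scale of 0 to 1, where 0
#' is no sharing and 1 identical viromes; reduces to the classic Sorensen
#' coefficient 2C/(S1+S2) when hits are reciprocal.
#'
#' @param recAB,recBA one-row data.frames (rows of an [allPairsShared()]
#'   table) for the two orientations of the same unordered pair.
#' @return numeric similarity in [0, 1].
#' @export
sorensenSimilarity <- function(recAB, recBA) {
    if (!identical(sort(c(recAB$query_sample, recAB$target_sample)),
                   sort(c(recBA$query_sample, recBA$target_sample))))
        stop("records do not refer to the same unordered pair")
    if (recAB$n_query == 0 || recBA$n_query == 0)
        stop("both viromes must be non-empty")
    (recAB$n_hit + recBA$n_hit) / (recAB$n_query + recBA$n_query)
}

.pairMatrix <- function(table, complement) {
    ids <- unique(c(table$query_sample, table$target_sample))
    n <- length(ids)
    key <- paste(table$query_sample, table$target_sample)
    grid <- expand.grid(q = ids, t = ids, stringsAsFactors = FALSE)
    missing <- setdiff(paste(grid$q, grid$t), key)
    if (length(missing))
        stop("incomplete table; missing ordered pair(s): ",
             paste(utils::head(missing, 5), collapse = ", "))
    hit <- matrix(table$n_hit[match(paste(rep(ids, each = n), rep(ids, n)), key)],
                  n, n, byrow = TRUE, dimnames = list(ids, ids))
    nq <- table$n_query[match(paste(ids, ids), key)]
    sim <- (hit + t(hit)) / outer(nq, nq, `+`)
    m <- if (complement) 1 - sim else sim
    diag(m) <- if (complement) 0 else 1
    m
}

#' Sorensen similarity matrix from a shared-fraction table
#'
#' @param table an [allPairsShared()] table (complete over ordered pairs).
#' @return square symmetric matrix of similarities, diagonal 1.
#' @export
sorensenMatrix <- function(table) .pairMatrix(table, complement = FALSE)

#' Bray-Curtis distance matrix (1 minus Sorensen)
#'
#' @param table an [allPairsShared()] table.
#' @return square symmetric matrix of distances in [0, 1], diagonal 0.
#' @export
brayCurtisMatrix <- function(table) .pairMatrix(table, complement = TRUE)

#' Principal coordinates analysis (classical metric MDS)
#'
#' Double-centers -D^2/2 and eigendecomposes (via [stats::cmdscale]).
#' Coordinates are eigenvectors scaled by the square root of their
#' eigenvalues; axes with negative eigenvalues are dropped (and reported),
#' so ordinations are always real-valued.
#'
#' @param dm square symmetric distance matrix.
#' @param nAxes number of axes to retain (< number of samples).
#' @return list with `coordinates` (samples x axes), `eigenvalues` (all,
#'   including any negative ones), and `proportion_explained` (per retained
#'   axis, relative to the positive eigenvalue total).
#' @export
pcoaOrdination <- function(dm, nAxes = 2L) {
    dm <- as.matrix(dm)
    if (!isSymmetric(unname(dm), tol = 1e-8))
        stop("distance matrix must be symmetric")
    n <- nrow(dm)
    if (nAxes >= n) stop("nAxes must be < number of samples")
    fit <- suppressWarnings(stats::cmdscale(dm, k = n - 1L, eig = TRUE))
    eig <- fit$eig
    pos <- which(eig > sqrt(.Machine$double.eps) * max(abs(eig), 1))
    keep <- pos[seq_len(min(nAxes, length(pos)))]
    coords <- if (length(keep)) fit$points[, keep, drop = FALSE] else
        matrix(0, n, nAxes) # degenerate (e.g. all-zero) input
    colnames(coords) <- paste0("PCo", seq_len(ncol(coords)))
    rownames(coords) <- rownames(dm)
    nNeg <- sum(eig < 0)
    if (nNeg) message(nNeg, " negative eigenvalue(s) dropped")
    list(coordinates = coords, eigenvalues = eig,
         proportion_explained = eig[keep] / sum(eig[eig > 0]))
}

#' Within- vs between-household similarity comparison
#'
#' Compares Sorensen similarities of all cross-subject sample pairs inside a
#' household against cross-subject pairs across households, by a two-sided
#' Mann-Whitney U test (exact enumeration when both groups have at most 8
#' values and no ties; tie-corrected normal approximation otherwise).
#' Same-subject pairs (two time points of one subject) are excluded from
#' both groups: the comparison is between subjects, not within them.
#'
#' @param simMatrix a [sorensenMatrix()] (samples x samples similarity).
#' @param samples metadata data.frame with `sample_id`, `subject_id`,
#'   `household_id` covering the matrix labels (e.g. the `samples` element
#'   of a `hitFlags` object).
#' @return list: `within_mean`, `within_se`, `between_mean`, `between_se`,
#'   `U`, `p`, `n_within`, `n_between`.
#' @export
householdDistanceComparison <- function(simMatrix, samples) {
    ids <- rownames(simMatrix)
    i <- match(ids, samples$sample_id)
    if (anyNA(i)) stop("matrix labels missing from sample metadata")
    subj <- samples$subject_id[i]
    hh <- samples$household_id[i]
    n <- length(ids)
    ut <- which(upper.tri(simMatrix), arr.ind = TRUE)
    cross <- subj[ut[, 1]] != subj[ut[, 2]]
    sameHH <- hh[ut[, 1]] == hh[ut[, 2]]
    within <- simMatrix[ut][cross & sameHH]
    between <- simMatrix[ut][cross & !sameHH]
    if (!length(within) || !length(between))
        stop("a comparison group is empty")
    exact <- length(within) <= 8 && length(between) <= 8 &&
        !anyDuplicated(c(within, between))
    wt <- suppressWarnings(stats::wilcox.test(within, between,
        alternative = "two.sided", exact = exact))
    se <- function(x) stats::sd(x) / sqrt(length(x))
    list(within_mean = mean(within), within_se = se(within),
         between_mean = mean(between), between_se = se(between),
         U = unname(wt$statistic), p = wt$p.value,
         n_within = length(within), n_between = length(between))
}
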