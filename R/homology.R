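## Pairwise virome homology: R surface over the seed-and-extend engine.

## Karlin-Altschul parameters for ungapped nucleotide scoring +1/-2
.KA_LAMBDA <- 1.33
.KA_K <- 0.621

.evalue <- function(score, qlen, dbLen)
    .KA_K * as.numeric(qlen) * as.numeric(dbLen) * exp(-.KA_LAMBDA * score)

#' Homology index over a target virome
#'
#' Exact-word index of a virome's contigs used as the target ("database")
#' side of homology searches; the analogue of building one BLAST database
#' per virome.
#'
#' @slot ptr external pointer to the word table.
#' @slot contigNames contig ids in index order.
#' @slot totalLength total target length (the database size used in E-value
#'   computation).
#' @slot wordSize seed word length.
#' @export
setClass("HomologyIndex", representation(
    ptr = "externalptr", contigNames = "character",
    totalLength = "numeric", wordSize = "integer"))

setMethod("show", "HomologyIndex", function(object) {
    cat("HomologyIndex:", length(object@contigNames), "contigs,",
        object@totalLength, "nt, word size", object@wordSize, "\n")
})

.asSeqChar <- function(x) {
    if (length(x) == 0L) return(character(0))
    if (is(x, "DNAStringSet")) {
        s <- as.character(x)
        if (is.null(names(s))) names(s) <- paste0("contig", seq_along(s))
        s
    } else if (is.character(x)) {
        if (is.null(names(x))) names(x) <- paste0("contig", seq_along(x))
        x
    } else stop("contigs must be a DNAStringSet or named character vector")
}

#' Build a homology index for one virome
#'
#' @param contigs [Biostrings::DNAStringSet] (or named character vector) of
#'   the target virome's contigs; must be non-empty.
#' @param params a [HomologyParams-class].
#' @return a [HomologyIndex-class].
#' @examples
#' idx <- buildHomologyIndex(Biostrings::DNAStringSet(
#'     c(a = paste(rep("ACGT", 100), collapse = ""))))
#' idx
#' @export
buildHomologyIndex <- function(contigs, params = homologyParams()) {
    s <- .asSeqChar(contigs)
    if (!length(s)) stop("cannot index an empty virome")
    ptr <- .cpp_build_index(unname(s), names(s), params@wordSize)
    new("HomologyIndex", ptr = ptr, contigNames = names(s),
        totalLength = sum(nchar(s)), wordSize = params@wordSize)
}

## raw per-(query contig, target contig) best ungapped alignments, with
## E-value and identity columns appended; rows only for seeded pairs
.queryIndex <- function(qseqs, index) {
    hits <- .cpp_query_index(unname(qseqs), index@ptr)
    hits$identity <- ifelse(hits$length > 0, hits$matches / hits$length, 0)
    hits$evalue <- .evalue(hits$score, nchar(qseqs)[hits$query],
                           index@totalLength)
    hits$target_id <- index@contigNames[hits$target]
    hits
}

.applyThresholds <- function(hits, params) {
    hits$length >= params@minAlignmentLength &
        hits$identity >= params@minIdentity &
        hits$evalue <= params@evalueThreshold
}

#' Test one contig for a homologue in an indexed virome
#'
#' A contig has a homologue when its best-scoring local alignment against
#' some target contig passes the length, identity and E-value thresholds of
#' `params`.
#'
#' @param contig a single sequence (character scalar or length-1
#'   DNAStringSet).
#' @param index a [HomologyIndex-class].
#' @param params a [HomologyParams-class].
#' @return list with `hit` (logical) and, when seeded, the best-hit summary
#'   (`target_id`, `alignment_length`, `identity`, `evalue`, `score`).
#' @export
contigHasHomologue <- function(contig, index, params = homologyParams()) {
    s <- .asSeqChar(contig)
    stopifnot(length(s) == 1L)
    hits <- .queryIndex(s, index)
    if (!nrow(hits))
        return(list(hit = FALSE, target_id = NA_character_,
                    alignment_length = NA_integer_, identity = NA_real_,
                    evalue = NA_real_, score = NA_integer_))
    best <- hits[which.max(hits$score), ]
    ok <- .applyThresholds(hits, params)
    list(hit = any(ok), target_id = best$target_id,
         alignment_length = best$length, identity = best$identity,
         evalue = best$evalue, score = best$score)
}

## per-query-contig hit flags of a query contig set against an index
.hitFlagsFor <- function(qseqs, index, params) {
    flags <- logical(length(qseqs))
    hits <- .queryIndex(qseqs, index)
    if (nrow(hits)) {
        ok <- .applyThresholds(hits, params)
        flags[unique(hits$query[ok])] <- TRUE
    }
    flags
}

#' Fraction of query contigs with a homologue in a target virome
#'
#' @param query,target [Biostrings::DNAStringSet] (or named character)
#'   contig sets; both non-empty.
#' @param params a [HomologyParams-class].
#' @return one-row data.frame: `n_query_contigs`, `n_query_with_hit`,
#'   `fraction`.
#' @export
sharedFraction <- function(query, target, params = homologyParams()) {
    q <- .asSeqChar(query)
    if (!length(q)) stop("empty query virome")
    idx <- buildHomologyIndex(target, params)
    flags <- .hitFlagsFor(q, idx, params)
    data.frame(n_query_contigs = length(q), n_query_with_hit = sum(flags),
               fraction = mean(flags))
}

#' Per-contig homologue flags for every ordered virome pair at a body site
#'
#' The workhorse of the pipeline: builds one index per non-missing,
#' non-empty sample at `bodySite` and records, for every ordered pair of
#' samples, which query contigs have a significant homologue in the target.
#' Everything downstream (shared-fraction tables, Sorensen distances, the
#' resampling tests) reuses these flags.
#'
#' @param cohort a [ViromeCohort-class].
#' @param bodySite `"feces"` or `"saliva"`.
#' @param params a [HomologyParams-class].
#' @return an object of class `hitFlags`: list with `samples` (metadata
#'   data.frame of the samples in scope) and `flags` (nested list,
#'   `flags[[query_id]][[target_id]]` = logical vector over the query's
#'   contigs). Self pairs are included (and are all-TRUE by construction).
#' @seealso [allPairsShared()], [subjectOverlapTest()]
#' @export
computeHitFlags <- function(cohort, bodySite, params = homologyParams()) {
    stopifnot(is(cohort, "ViromeCohort"))
    rows <- .siteSamples(cohort, bodySite)
    if (length(rows) < 2L)
        stop("need >= 2 non-missing viromes at body site ", bodySite)
    sm <- as.data.frame(sampleData(cohort))[rows, , drop = FALSE]
    skipped <- missingSamples(cohort)
    skipped <- skipped[grepl(paste0("_", bodySite, "_"), skipped)]
    if (length(skipped))
        message("excluding ", length(skipped), " missing sample(s) at ", bodySite)
    seqs <- lapply(rows, function(i) .asSeqChar(cohort@contigs[[i]]))
    names(seqs) <- sm$sample_id
    idx <- lapply(seqs, buildHomologyIndex, params = params)
    flags <- lapply(seqs, function(q)
        lapply(idx, function(ix) .hitFlagsFor(q, ix, params)))
    structure(list(samples = sm, flags = flags, params = params,
                   body_site = bodySite),
              class = "hitFlags")
}

#' @export
print.hitFlags <- function(x, ...) {
    cat("hitFlags:", nrow(x$samples), "samples at", x$body_site, "->",
        nrow(x$samples)^2, "ordered pairs\n")
    invisible(x)
}

#' Shared-fraction table over all ordered virome pairs at a body site
#'
#' For every ordered pair of samples (self pairs included) the fraction of
#' query contigs with a significant homologue in the target virome. The
#' table is asymmetric in general; self fractions are 1 for non-empty
#' viromes.
#'
#' @param x a [ViromeCohort-class] or a precomputed `hitFlags` object.
#' @param bodySite body site (ignored when `x` is already a `hitFlags`).
#' @param params a [HomologyParams-class].
#' @return data.frame with columns `query_sample`, `target_sample`,
#'   `query_subject`, `query_timepoint`, `target_subject`,
#'   `target_timepoint`, `body_site`, `n_query`, `n_hit`, `fraction`.
#' @export
allPairsShared <- function(x, bodySite = "feces", params = homologyParams()) {
    hf <- if (inherits(x, "hitFlags")) x else
        computeHitFlags(x, bodySite, params)
    sm <- hf$samples
    ids <- sm$sample_id
    grid <- expand.grid(target = ids, query = ids, stringsAsFactors = FALSE)[, 2:1]
    nHit <- mapply(function(q, t) sum(hf$flags[[q]][[t]]), grid$query, grid$target)
    nQ <- vapply(hf$flags[grid$query], function(f) length(f[[1]]), 1L)
    qi <- match(grid$query, ids); ti <- match(grid$target, ids)
    data.frame(query_sample = grid$query, target_sample = grid$target,
               query_subject = sm$subject_id[qi],
               query_timepoint = sm$timepoint[qi],
               target_subject = sm$subject_id[ti],
               target_timepoint = sm$timepoint[ti],
               body_site = hf$body_site, n_query = nQ, n_hit = unname(nHit),
               fraction = unname(nHit) / nQ, row.names = NULL)
}
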