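## Global viruses: single-linkage contig clustering across time points (and
## housemates), persistence, household sharing, and the putative-transmission
## caller.

#' Cluster contigs into global viruses
#'
#' Pools all contigs of one subject (or of both members of one household) at
#' a body site across time points and single-linkage clusters them: two
#' contigs are linked when a local alignment covers at least
#' `params@minOverlap` of the shorter contig at `params@minIdentity`
#' identity or better. Connected components are the "global viruses" -- the
#' same role the per-subject/per-household global assemblies play in
#' presence/absence tracking. Virus ids are deterministic, ordered by
#' earliest member time point then lexicographic member id, and invariant to
#' contig input order.
#'
#' @param cohort a [ViromeCohort-class].
#' @param scope `"subject"` or `"household"`.
#' @param id the subject or household id.
#' @param bodySite body site to cluster.
#' @param params a [ClusterParams-class].
#' @return an object of class `globalViruses`: list with `members`
#'   (data.frame: virus_id, sample_id, contig_id, subject_id, timepoint,
#'   day_offset), `presence` (data.frame: virus_id, subject_id, timepoint,
#'   day_offset; one row per virus presence in a sampled specimen), `scope`,
#'   `id`, `body_site`.
#' @export
clusterGlobalViruses <- function(cohort, scope = c("subject", "household"),
                                 id, bodySite = "feces",
                                 params = clusterParams()) {
    scope <- match.arg(scope)
    stopifnot(is(cohort, "ViromeCohort"))
    sm <- as.data.frame(sampleData(cohort))
    rows <- .siteSamples(cohort, bodySite)
    col <- if (scope == "subject") "subject_id" else "household_id"
    rows <- rows[sm[[col]][rows] == id]
    if (!length(rows)) stop("no non-missing viromes for ", scope, " ", id)
    seqs <- character(0); meta <- list()
    for (i in rows) {
        cs <- .asSeqChar(cohort@contigs[[i]])
        lab <- paste(sm$sample_id[i], names(cs), sep = ":")
        meta[[length(meta) + 1L]] <- data.frame(
            label = lab, sample_id = sm$sample_id[i], contig_id = names(cs),
            subject_id = sm$subject_id[i], timepoint = sm$timepoint[i],
            stringsAsFactors = FALSE)
        names(cs) <- lab
        seqs <- c(seqs, cs)
    }
    meta <- do.call(rbind, meta)
    meta$day_offset <- dayOffset(meta$timepoint)
    ## pairwise linkage via the seed-and-extend engine
    idx <- buildHomologyIndex(seqs, homologyParams())
    hits <- .queryIndex(seqs, idx)
    hits <- hits[hits$query != hits$target, , drop = FALSE]
    lens <- nchar(seqs)
    shorter <- pmin(lens[hits$query], lens[hits$target])
    link <- hits$identity >= params@minIdentity &
        hits$length >= params@minOverlap * shorter
    g <- igraph::graph_from_data_frame(
        data.frame(from = names(seqs)[hits$query[link]],
                   to = names(seqs)[hits$target[link]]),
        directed = FALSE,
        vertices = data.frame(name = names(seqs)))
    comp <- igraph::components(g)$membership[names(seqs)]
    ## deterministic ids: order clusters by earliest member time point, then
    ## lexicographically smallest member label
    groups <- split(seq_along(seqs), comp)
    key <- t(vapply(groups, function(ix)
        c(min(meta$day_offset[ix]), min(meta$label[ix])), c("", "")))
    rank <- order(as.numeric(key[, 1]), key[, 2])
    vid <- sprintf("GV%04d", match(as.character(comp), names(groups)[rank]))
    members <- cbind(virus_id = vid,
                     meta[, setdiff(colnames(meta), "label"), drop = FALSE])
    members <- members[order(members$virus_id, members$sample_id,
                             members$contig_id), ]
    rownames(members) <- NULL
    presence <- unique(members[, c("virus_id", "subject_id", "timepoint",
                                   "day_offset")])
    presence <- presence[order(presence$virus_id, presence$subject_id,
                               presence$day_offset), ]
    rownames(presence) <- NULL
    structure(list(members = members, presence = presence, scope = scope,
                   id = id, body_site = bodySite),
              class = "globalViruses")
}

#' @export
print.globalViruses <- function(x, ...) {
    cat("globalViruses:", length(unique(x$members$virus_id)), "viruses from",
        nrow(x$members), "contigs (", x$scope, x$id, ",", x$body_site, ")\n")
    invisible(x)
}

#' Persistence of a subject's global viruses
#'
#' For each virus the span is the difference between the latest and earliest
#' day offsets at which it is present; the summary reports the fractions of
#' viruses with span at least 4 days (re-detected across the first antibiotic
#' week or later) and at least 150 days (still identifiable at 5-6 months),
#' plus the span histogram.
#'
#' @param gv a subject-scope [clusterGlobalViruses()] result.
#' @return list: `n_viruses`, `fraction_ge_4_days`, `fraction_ge_150_days`,
#'   `spans` (named integer vector per virus).
#' @export
persistenceSummary <- function(gv) {
    pres <- gv$presence
    spans <- vapply(split(pres$day_offset, pres$virus_id),
                    function(d) max(d) - min(d), 1)
    list(n_viruses = length(spans),
         fraction_ge_4_days = mean(spans >= 4),
         fraction_ge_150_days = mean(spans >= 150),
         spans = spans)
}

.householdArms <- function(cohort, householdId) {
    sm <- as.data.frame(sampleData(cohort))
    sub <- unique(sm[sm$household_id == householdId,
                     c("subject_id", "treatment")])
    if (nrow(sub) != 2L)
        stop("household ", householdId, " is not a two-person household")
    sub
}

#' Household sharing of global viruses
#'
#' A virus is shared when present at one or more time points of each
#' housemate; viruses carried by a single housemate are attributed to that
#' subject's treatment arm. The partition identity
#' shared + unique_placebo + unique_antibiotic = total holds by
#' construction.
#'
#' @param gv a household-scope [clusterGlobalViruses()] result.
#' @param cohort the [ViromeCohort-class] (for treatment arms).
#' @return one-row data.frame: `household_id`, `n_viruses_total`,
#'   `n_shared`, `n_unique_placebo`, `n_unique_antibiotic`.
#' @export
householdSharing <- function(gv, cohort) {
    stopifnot(gv$scope == "household")
    arms <- .householdArms(cohort, gv$id)
    placebo <- arms$subject_id[arms$treatment == "placebo"]
    bySubj <- split(gv$presence$subject_id, gv$presence$virus_id)
    carriers <- lapply(bySubj, unique)
    nShared <- sum(vapply(carriers, length, 1L) == 2L)
    solo <- unlist(carriers[vapply(carriers, length, 1L) == 1L])
    data.frame(household_id = gv$id,
               n_viruses_total = length(carriers),
               n_shared = nShared,
               n_unique_placebo = sum(solo == placebo),
               n_unique_antibiotic = sum(solo != placebo),
               stringsAsFactors = FALSE)
}

#' Call putative transmissions within a household
#'
#' A virus is a putative transmission when it was present in one housemate
#' (the donor), absent from the other at every sampled time point up to and
#' including the donor's first presence, and later appeared in at least two
#' of the recipient's time points. Missing recipient specimens are unknown,
#' not absent: one in the pre-window disqualifies the call. Equal first
#' presences give no call (no direction assignable).
#'
#' @param gv a household-scope [clusterGlobalViruses()] result.
#' @param cohort the [ViromeCohort-class] (for arms and missing samples).
#' @return data.frame with one row per call: `household_id`, `body_site`,
#'   `virus_id`, `donor`, `recipient`, `donor_first`, `recipient_first`,
#'   `recipient_presence_count`, `direction_class`.
#' @export
callTransmissions <- function(gv, cohort) {
    stopifnot(gv$scope == "household")
    arms <- .householdArms(cohort, gv$id)
    sm <- as.data.frame(sampleData(cohort))
    sampledOffsets <- function(s) {
        ok <- sm$subject_id == s & sm$body_site == gv$body_site & !sm$missing
        dayOffset(sm$timepoint[ok])
    }
    missingOffsets <- function(s) {
        ok <- sm$subject_id == s & sm$body_site == gv$body_site & sm$missing
        dayOffset(sm$timepoint[ok])
    }
    tpl <- timepointLevels()
    calls <- list()
    for (vid in unique(gv$presence$virus_id)) {
        pv <- gv$presence[gv$presence$virus_id == vid, ]
        for (d in arms$subject_id) {
            r <- setdiff(arms$subject_id, d)
            dOff <- pv$day_offset[pv$subject_id == d]
            rOff <- pv$day_offset[pv$subject_id == r]
            if (!length(dOff) || length(rOff) < 2L) next
            fD <- min(dOff); fR <- min(rOff)
            if (!(fR > fD)) next
            ## (a) recipient absent at all sampled offsets <= fD, with no
            ## unknown (missing) recipient specimen in that window
            if (any(rOff <= fD)) next
            if (any(missingOffsets(r) <= fD)) next
            if (!any(sampledOffsets(r) <= fD)) next # nothing observed pre-fD
            dir <- if (arms$treatment[arms$subject_id == d] == "placebo")
                "placebo_to_antibiotic"
            else if (arms$treatment[arms$subject_id == r] == "placebo")
                "antibiotic_to_placebo"
            else "involving_control_na"
            calls[[length(calls) + 1L]] <- data.frame(
                household_id = gv$id, body_site = gv$body_site,
                virus_id = vid, donor = d, recipient = r,
                donor_first = tpl[match(fD, dayOffset(tpl))],
                recipient_first = tpl[match(fR, dayOffset(tpl))],
                recipient_presence_count = length(rOff),
                direction_class = dir, stringsAsFactors = FALSE)
        }
    }
    if (!length(calls))
        return(data.frame(household_id = character(), body_site = character(),
                          virus_id = character(), donor = character(),
                          recipient = character(), donor_first = character(),
                          recipient_first = character(),
                          recipient_presence_count = integer(),
                          direction_class = character()))
    do.call(rbind, calls)
}

#' Cohort-level sharing and transmission directionality summary
#'
#' Per household, the proportions (percent of all that household's global
#' viruses) that are shared between housemates, that look transmitted, and
#' that were transmitted in each direction; then the mean and standard error
#' of each proportion across households. Directional parts sum to the
#' transmission total per household.
#'
#' @param sharingTable row-bound [householdSharing()] results.
#' @param calls row-bound [callTransmissions()] results.
#' @return list: `per_household` (data.frame of percentages) and `summary`
#'   (data.frame: quantity, mean_pct, se_pct).
#' @export
directionalitySummary <- function(sharingTable, calls) {
    ph <- sharingTable
    cnt <- function(hh, dir = NULL) {
        k <- calls$household_id == hh
        if (!is.null(dir)) k <- k & calls$direction_class == dir
        sum(k)
    }
    ph$n_transmitted <- vapply(ph$household_id, cnt, 1L)
    ph$n_p2a <- vapply(ph$household_id, cnt, 1L, dir = "placebo_to_antibiotic")
    ph$n_a2p <- vapply(ph$household_id, cnt, 1L, dir = "antibiotic_to_placebo")
    tot <- ph$n_viruses_total
    ph$shared_pct <- 100 * ph$n_shared / tot
    ph$transmitted_pct <- 100 * ph$n_transmitted / tot
    ph$p2a_pct <- 100 * ph$n_p2a / tot
    ph$a2p_pct <- 100 * ph$n_a2p / tot
    se <- function(x) stats::sd(x) / sqrt(length(x))
    qty <- c("shared_pct", "transmitted_pct", "p2a_pct", "a2p_pct")
    summary <- data.frame(
        quantity = c("shared", "transmitted", "transmitted_placebo_to_antibiotic",
                     "transmitted_antibiotic_to_placebo"),
        mean_pct = vapply(qty, function(q) mean(ph[[q]]), 1),
        se_pct = vapply(qty, function(q) se(ph[[q]]), 1),
        row.names = NULL, stringsAsFactors = FALSE)
    list(per_household = ph, summary = summary)
}
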