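## Household-cohort simulator with planted ground truth.
##
## Presence of each virus in each subject evolves as a two-state Markov chain
## over the five sampling time points; genomes are uniform-random sequences
## that accumulate substitutions per time step along each carrier lineage and
## are emitted re-fragmented per sample, so downstream clustering has real
## work to do. Planted transmissions copy a donor-exclusive virus into the
## housemate at a later time point and are floored to two recipient
## presences, making them recoverable by the presence/absence rule.

.BASES <- c("A", "C", "G", "T")

.randGenome <- function(len) sample.int(4L, len, replace = TRUE)

.mutateGenome <- function(g, rate) {
    if (rate <= 0) return(g)
    n <- stats::rbinom(1L, length(g), rate)
    if (n == 0L) return(g)
    pos <- sample.int(length(g), n)
    ## substitute with one of the three other bases
    g[pos] <- ((g[pos] - 1L + sample.int(3L, n, replace = TRUE)) %% 4L) + 1L
    g
}

.genomeToChar <- function(g) paste(.BASES[g], collapse = "")

## stars-and-bars composition: k fragment lengths >= 200 summing to L
.fragmentLengths <- function(L, k) {
    if (k == 1L) return(L)
    extra <- L - 200L * k
    bars <- sort(sample.int(extra + k - 1L, k - 1L))
    parts <- diff(c(0L, bars, extra + k)) - 1L
    200L + parts
}

## Markov presence path over nT time points
.presencePath <- function(nT, p0, retain, acquire) {
    pres <- logical(nT)
    pres[1] <- stats::runif(1) < p0
    for (k in seq_len(nT - 1L))
        pres[k + 1L] <- stats::runif(1) <
            (if (pres[k]) retain else acquire)
    pres
}

#' Study-design-like simulation configuration
#'
#' The default generator configuration: 8 two-person households plus 4
#' singleton controls, five time points, feces and saliva, the last household
#' lost to follow-up at month 6. Dynamics parameters were tuned once, by
#' simulation, so that realized fecal shared-homologue fractions land in the
#' regimes the analysis assumes: within-subject means around 20-75% and
#' between-subject means around 1-17%.
#'
#' @param seed integer RNG seed.
#' @return a [SimulationConfig-class].
#' @examples
#' defaultSimulationConfig(seed = 42)
#' @export
defaultSimulationConfig <- function(seed = 1L) simulationConfig(seed = seed)

#' Null-pool configuration for calibration runs
#'
#' A cohort with no subject-specific structure: no core viruses, background
#' pool only, and retention equal to acquisition so that presence is iid
#' Bernoulli across every (subject, time point) sample. Mutation is off so
#' all carriers hold identical pool sequences. Used to study the null
#' behaviour of the overlap resampling test.
#'
#' @param seed integer RNG seed.
#' @param poolSize background pool size.
#' @param presenceProb per-sample presence probability (retention =
#'   acquisition = this value).
#' @return a [SimulationConfig-class].
#' @export
nullPoolConfig <- function(seed = 1L, poolSize = 40L, presenceProb = 0.3) {
    simulationConfig(nHouseholdsTwoPerson = 2L, nControls = 0L,
        bodySites = "feces", nCoreVirusesPerSubject = 0L,
        nHouseholdSharedViruses = 0L, nBackgroundPool = as.integer(poolSize),
        retentionProb = presenceProb, reacquisitionProb = 0,
        backgroundAcquisitionProb = presenceProb, transmissionRate = 0,
        mutationRate = 0, genomeLengthRange = c(400L, 1200L),
        contigsPerVirus = 1L, missingSampleProb = 0,
        dropLastHouseholdMonth6 = FALSE, seed = seed)
}

.designTable <- function(config) {
    nh <- config@nHouseholdsTwoPerson
    nc <- config@nControls
    rows <- list()
    for (h in seq_len(nh)) {
        abx <- if (h %% 2L == 1L) "amoxicillin" else "azithromycin"
        who <- sample(1:2, 1L) # which member takes the antibiotic
        tr <- if (who == 1L) c(abx, "placebo") else c("placebo", abx)
        rows[[h]] <- data.frame(
            subject_id = sprintf("S%02d", 2L * h - 1:0),
            household_id = sprintf("H%02d", h),
            treatment = tr, stringsAsFactors = FALSE)
    }
    if (nc > 0)
        rows[[nh + 1L]] <- data.frame(
            subject_id = sprintf("C%02d", seq_len(nc)),
            household_id = sprintf("HC%02d", seq_len(nc)),
            treatment = "none", stringsAsFactors = FALSE)
    do.call(rbind, rows)
}

#' Simulate a household virome cohort with planted ground truth
#'
#' Deterministic given `config@seed` (identical configs yield byte-identical
#' FASTA output). Returns the cohort plus a truth table recording every
#' virus, its per-(subject, time point) presence, and all planted
#' transmission events.
#'
#' @param config a [SimulationConfig-class].
#' @return a list with elements:
#' \describe{
#'   \item{cohort}{a [ViromeCohort-class];}
#'   \item{truth}{a list of data.frames `viruses` (virus_id, body_site, type,
#'     household_id, founder_subjects, genome_length), `presence` (virus_id,
#'     body_site, subject_id, timepoint, sampled) with one row per
#'     virus-presence, and `transmissions` (household_id, body_site,
#'     virus_id, donor, recipient, donor_first, recipient_first).}
#' }
#' @examples
#' sim <- simulateCohort(nullPoolConfig(seed = 3, poolSize = 10))
#' sim$cohort
#' @export
simulateCohort <- function(config) {
    stopifnot(is(config, "SimulationConfig"))
    validObject(config)
    oldseed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(oldseed)) assign(".Random.seed", oldseed, .GlobalEnv))
    set.seed(config@seed)

    design <- .designTable(config)
    tps <- timepointLevels()
    nT <- length(tps)
    nSubj <- nrow(design)
    twoPerson <- unique(design$household_id[duplicated(design$household_id) |
        duplicated(design$household_id, fromLast = TRUE)])

    ## missing specimens: per (subject, tp, site), plus the lost household
    missKey <- character()
    for (site in config@bodySites)
        for (s in design$subject_id)
            for (tp in tps)
                if (stats::runif(1) < config@missingSampleProb)
                    missKey <- c(missKey, sampleId(s, site, tp))
    if (config@dropLastHouseholdMonth6 && length(twoPerson)) {
        lostSubj <- design$subject_id[design$household_id ==
                                      twoPerson[length(twoPerson)]]
        for (site in config@bodySites)
            missKey <- c(missKey, sampleId(lostSubj, site, "month6"))
    }
    missKey <- unique(missKey)

    virusRows <- list(); presRows <- list(); transRows <- list()
    seqsBySample <- list()   # sample_id -> named character vector

    for (site in config@bodySites) {
        ## ---- virus universe -------------------------------------------------
        vtab <- list(); vn <- 0L
        newVirus <- function(type, hh, founders) {
            vn <<- vn + 1L
            len <- sample(config@genomeLengthRange[1]:config@genomeLengthRange[2], 1L)
            vtab[[vn]] <<- list(
                virus_id = sprintf("%s_V%04d", site, vn), type = type,
                household_id = hh, founders = founders,
                genome = .randGenome(len))
            vn
        }
        coreOf <- vector("list", nSubj); names(coreOf) <- design$subject_id
        exclOf <- coreOf
        for (hh in twoPerson) {
            pair <- design$subject_id[design$household_id == hh]
            for (k in seq_len(config@nHouseholdSharedViruses)) {
                i <- newVirus("core_shared", hh, paste(pair, collapse = ","))
                for (s in pair) coreOf[[s]] <- c(coreOf[[s]], i)
            }
        }
        for (s in design$subject_id) {
            hh <- design$household_id[design$subject_id == s]
            nExcl <- config@nCoreVirusesPerSubject -
                (if (hh %in% twoPerson) config@nHouseholdSharedViruses else 0L)
            for (k in seq_len(max(0L, nExcl))) {
                i <- newVirus("core_exclusive", hh, s)
                coreOf[[s]] <- c(coreOf[[s]], i)
                exclOf[[s]] <- c(exclOf[[s]], i)
            }
        }
        bgIdx <- integer(0)
        for (k in seq_len(config@nBackgroundPool))
            bgIdx <- c(bgIdx, newVirus("background", NA_character_, NA_character_))

        ## ---- presence dynamics ---------------------------------------------
        ## presence[[subject]][virus, tp]
        presence <- lapply(seq_len(nSubj), function(i) {
            matrix(FALSE, nrow = vn, ncol = nT)
        })
        names(presence) <- design$subject_id
        for (s in design$subject_id) {
            for (v in coreOf[[s]]) {
                pres <- logical(nT); pres[1] <- TRUE
                for (k in seq_len(nT - 1L))
                    pres[k + 1L] <- stats::runif(1) <
                        (if (pres[k]) config@retentionProb else config@reacquisitionProb)
                presence[[s]][v, ] <- pres
            }
            for (v in bgIdx)
                presence[[s]][v, ] <- .presencePath(nT,
                    config@backgroundAcquisitionProb, config@retentionProb,
                    config@backgroundAcquisitionProb)
        }

        ## ---- planted transmissions -----------------------------------------
        transModel <- list() # virus_id -> list(recipient, tstar)
        for (hh in twoPerson) {
            pair <- design$subject_id[design$household_id == hh]
            plc <- pair[design$treatment[match(pair, design$subject_id)] == "placebo"]
            abx <- setdiff(pair, plc)
            nEv <- stats::rpois(1L, config@transmissionRate)
            avail <- list(); avail[[plc]] <- exclOf[[plc]]; avail[[abx]] <- exclOf[[abx]]
            for (e in seq_len(nEv)) {
                donor <- if (stats::runif(1) < config@transmissionDirectionBias) plc else abx
                recip <- setdiff(pair, donor)
                if (!length(avail[[donor]])) next
                v <- avail[[donor]][sample.int(length(avail[[donor]]), 1L)]
                avail[[donor]] <- setdiff(avail[[donor]], v)
                ## transmit at day3/day7/week8 so >= 2 recipient time points remain
                tstar <- sample(2:(nT - 1L), 1L)
                pres <- logical(nT)
                pres[tstar] <- TRUE; pres[tstar + 1L] <- TRUE
                k <- tstar + 1L
                while (k < nT) {
                    pres[k + 1L] <- stats::runif(1) <
                        (if (pres[k]) config@retentionProb else 0)
                    k <- k + 1L
                }
                presence[[recip]][v, ] <- pres
                vid <- vtab[[v]]$virus_id
                transModel[[vid]] <- list(v = v, donor = donor,
                                          recipient = recip, tstar = tstar)
                transRows[[length(transRows) + 1L]] <- data.frame(
                    household_id = hh, body_site = site, virus_id = vid,
                    donor = donor, recipient = recip,
                    donor_first = tps[1], recipient_first = tps[tstar],
                    stringsAsFactors = FALSE)
            }
        }

        ## ---- lineage evolution ----------------------------------------------
        ## genomes[[subject]][[virus key]][[k]]: the carrier's genome at time
        ## point k. Ordinary lineages found at day0 from the ancestral genome;
        ## a transmitted lineage founds at its first recipient presence as a
        ## copy of the donor's current genome with one extra round of
        ## divergence, then evolves independently.
        genomes <- stats::setNames(vector("list", nSubj), design$subject_id)
        for (s in design$subject_id) {
            carried <- which(rowSums(presence[[s]]) > 0)
            genomes[[s]] <- list()
            for (v in carried) {
                tm <- transModel[[vtab[[v]]$virus_id]]
                if (!is.null(tm) && identical(tm$recipient, s)) next
                gl <- vector("list", nT)
                gl[[1]] <- vtab[[v]]$genome
                for (k in seq_len(nT - 1L))
                    gl[[k + 1L]] <- .mutateGenome(gl[[k]], config@mutationRate)
                genomes[[s]][[as.character(v)]] <- gl
            }
        }
        for (vid in names(transModel)) {
            tm <- transModel[[vid]]
            gl <- vector("list", nT)
            gl[[tm$tstar]] <- .mutateGenome(genomes[[tm$donor]][[as.character(tm$v)]][[tm$tstar]],
                                            config@mutationRate)
            if (tm$tstar < nT)
                for (k in tm$tstar:(nT - 1L))
                    gl[[k + 1L]] <- .mutateGenome(gl[[k]], config@mutationRate)
            genomes[[tm$recipient]][[as.character(tm$v)]] <- gl
        }

        ## ---- emission --------------------------------------------------------
        for (s in design$subject_id) {
            carried <- which(rowSums(presence[[s]]) > 0)
            for (k in seq_len(nT)) {
                tp <- tps[k]
                sid <- sampleId(s, site, tp)
                sampled <- !(sid %in% missKey)
                out <- character(0)
                for (v in carried) {
                    if (!presence[[s]][v, k]) next
                    vid <- vtab[[v]]$virus_id
                    presRows[[length(presRows) + 1L]] <- data.frame(
                        virus_id = vid, body_site = site, subject_id = s,
                        timepoint = tp, sampled = sampled,
                        stringsAsFactors = FALSE)
                    if (!sampled) next
                    g <- genomes[[s]][[as.character(v)]][[k]]
                    lens <- .fragmentLengths(length(g), config@contigsPerVirus)
                    ends <- cumsum(lens); starts <- c(1L, utils::head(ends, -1L) + 1L)
                    frag <- vapply(seq_along(lens), function(fi)
                        .genomeToChar(g[starts[fi]:ends[fi]]), "")
                    names(frag) <- sprintf("%s.f%d", vid, seq_along(lens))
                    out <- c(out, frag)
                }
                if (sampled) seqsBySample[[sid]] <- out
            }
        }

        virusRows[[site]] <- data.frame(
            virus_id = vapply(vtab, `[[`, "", "virus_id"),
            body_site = site,
            type = vapply(vtab, `[[`, "", "type"),
            household_id = vapply(vtab, `[[`, "", "household_id"),
            founder_subjects = vapply(vtab, `[[`, "", "founders"),
            genome_length = vapply(vtab, function(x) length(x$genome), 1L),
            stringsAsFactors = FALSE)
    }

    ## ---- assemble cohort ----------------------------------------------------
    grid <- expand.grid(timepoint = tps, body_site = config@bodySites,
                        subject_id = design$subject_id,
                        stringsAsFactors = FALSE)[, 3:1]
    grid$household_id <- design$household_id[match(grid$subject_id, design$subject_id)]
    grid$treatment <- design$treatment[match(grid$subject_id, design$subject_id)]
    grid$sample_id <- sampleId(grid$subject_id, grid$body_site, grid$timepoint)
    grid$missing <- grid$sample_id %in% missKey
    contigs <- lapply(seq_len(nrow(grid)), function(i) {
        if (grid$missing[i]) return(Biostrings::DNAStringSet())
        sq <- seqsBySample[[grid$sample_id[i]]]
        if (is.null(sq)) sq <- character(0)
        Biostrings::DNAStringSet(sq)
    })
    cohort <- ViromeCohort(grid, contigs)
    truth <- list(
        viruses = do.call(rbind, unname(virusRows)),
        presence = if (length(presRows)) do.call(rbind, presRows) else
            data.frame(virus_id = character(), body_site = character(),
                       subject_id = character(), timepoint = character(),
                       sampled = logical()),
        transmissions = if (length(transRows)) do.call(rbind, transRows) else
            data.frame(household_id = character(), body_site = character(),
                       virus_id = character(), donor = character(),
                       recipient = character(), donor_first = character(),
                       recipient_first = character()))
    list(cohort = cohort, truth = truth)
}
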