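#' @useDynLib viroshare, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
#' @importFrom S4Vectors DataFrame SimpleList
#' @importClassesFrom S4Vectors DataFrame SimpleList
#' @importFrom Biostrings DNAStringSet readDNAStringSet writeXStringSet width
#'   alphabetFrequency
NULL

## ---- time conventions -------------------------------------------------------

.TIMEPOINT_OFFSETS <- c(day0 = 0L, day3 = 3L, day7 = 7L, week8 = 56L, month6 = 182L)

#' Sampling time points
#'
#' The study design samples each subject five times: the day before treatment
#' starts (`day0`), on treatment (`day3`), at its end (`day7`), and at two
#' follow-ups (`week8`, `month6`). `timepointLevels()` returns the labels in
#' chronological order; `dayOffset()` converts labels to days since `day0`
#' (week8 = 56 d, month6 = 182 d, calendar-typical conventions).
#'
#' @return `timepointLevels()`: character vector of the five labels.
#' @examples
#' timepointLevels()
#' dayOffset(c("day3", "month6"))
#' @export
timepointLevels <- function() names(.TIMEPOINT_OFFSETS)

#' @param labels character vector of time point labels.
#' @return `dayOffset()`: integer days since day 0.
#' @rdname timepointLevels
#' @export
dayOffset <- function(labels) {
    bad <- setdiff(unique(labels), names(.TIMEPOINT_OFFSETS))
    if (length(bad))
        stop("unknown time point label(s): ", paste(bad, collapse = ", "))
    unname(.TIMEPOINT_OFFSETS[labels])
}

.BODY_SITES <- c("feces", "saliva")
.TREATMENTS <- c("placebo", "amoxicillin", "azithromycin", "none")
.ANTIBIOTICS <- c("amoxicillin", "azithromycin")

#' Sample identifier
#'
#' One specimen is identified by subject, body site and time point; the
#' canonical sample id is the underscore-joined triple.
#'
#' @param subject_id,body_site,timepoint character vectors (recycled).
#' @return character vector of sample ids.
#' @examples
#' sampleId("CA05", "feces", "day0")
#' @export
sampleId <- function(subject_id, body_site, timepoint) {
    paste(subject_id, body_site, timepoint, sep = "_")
}

## ---- classes ----------------------------------------------------------------

#' ViromeCohort: per-sample contig sets plus cohort metadata
#'
#' Container for a longitudinal household virome cohort. `samples` is a
#' [S4Vectors::DataFrame] with one row per planned specimen (columns
#' `sample_id`, `subject_id`, `household_id`, `body_site`, `timepoint`,
#' `treatment`, `missing`); `contigs` is a [S4Vectors::SimpleList] of
#' [Biostrings::DNAStringSet], parallel to the rows, holding each specimen's
#' assembled contigs. Missing specimens (e.g. a household lost to follow-up)
#' keep their metadata row, carry an empty contig set and are flagged
#' `missing = TRUE`.
#'
#' Validity enforces the study-design invariants: unique sample keys;
#' households of one or two subjects; in a two-person household exactly one
#' member on an antibiotic and the other on placebo; `treatment == "none"`
#' only in singleton (control) households; contigs at least 200 nt with no
#' ambiguous characters (shorter or ambiguous contigs are excluded at read
#' time, mirroring the assembly filter).
#'
#' @slot samples DataFrame of sample metadata.
#' @slot contigs SimpleList of DNAStringSet, one per sample row.
#' @export
setClass("ViromeCohort",
    representation(samples = "DataFrame", contigs = "SimpleList"))

.validViromeCohort <- function(object) {
    msg <- character()
    sm <- object@samples
    need <- c("sample_id", "subject_id", "household_id", "body_site",
              "timepoint", "treatment", "missing")
    miss <- setdiff(need, colnames(sm))
    if (length(miss))
        return(paste("samples lacks column(s):", paste(miss, collapse = ", ")))
    if (length(object@contigs) != nrow(sm))
        msg <- c(msg, "contigs list is not parallel to sample rows")
    if (anyDuplicated(sm$sample_id))
        msg <- c(msg, "duplicate sample keys")
    if (!all(sm$body_site %in% .BODY_SITES))
        msg <- c(msg, "body_site must be 'feces' or 'saliva'")
    if (!all(sm$timepoint %in% timepointLevels()))
        msg <- c(msg, "invalid timepoint label")
    if (!all(sm$treatment %in% .TREATMENTS))
        msg <- c(msg, "invalid treatment label")
    ## subject-level consistency and household composition
    subj <- unique(as.data.frame(sm[, c("subject_id", "household_id", "treatment")]))
    if (anyDuplicated(subj$subject_id))
        msg <- c(msg, "a subject maps to more than one household or treatment")
    hh <- split(subj, subj$household_id)
    for (h in hh) {
        n <- nrow(h)
        if (n > 2) {
            msg <- c(msg, sprintf("household %s has %d subjects", h$household_id[1], n))
        } else if (n == 2) {
            tr <- sort(h$treatment)
            if (!(tr[1] %in% .ANTIBIOTICS && tr[2] == "placebo") &&
                !(tr[2] %in% .ANTIBIOTICS && tr[1] == "placebo"))
                msg <- c(msg, sprintf(
                    "two-person household %s must pair one antibiotic with one placebo",
                    h$household_id[1]))
        } else if (h$treatment[1] == "none" && FALSE) {
            ## singleton with 'none' is fine
        }
        if (n == 1 && !(h$treatment[1] %in% .TREATMENTS))
            msg <- c(msg, "invalid control treatment")
        if (n == 2 && any(h$treatment == "none"))
            msg <- c(msg, "treatment 'none' only allowed in singleton households")
    }
    for (i in seq_len(nrow(sm))) {
        cs <- object@contigs[[i]]
        if (!is(cs, "DNAStringSet")) {
            msg <- c(msg, "contig entries must be DNAStringSet"); break
        }
        if (sm$missing[i] && length(cs) > 0)
            msg <- c(msg, sprintf("missing sample %s carries contigs", sm$sample_id[i]))
        if (length(cs)) {
            if (anyDuplicated(names(cs)))
                msg <- c(msg, sprintf("duplicate contig ids in %s", sm$sample_id[i]))
            if (any(Biostrings::width(cs) < 200L))
                msg <- c(msg, sprintf("contig < 200 nt in %s", sm$sample_id[i]))
            af <- Biostrings::alphabetFrequency(cs, baseOnly = TRUE)
            if (any(af[, "other"] > 0))
                msg <- c(msg, sprintf("ambiguous characters in %s", sm$sample_id[i]))
        }
    }
    if (length(msg)) msg else TRUE
}
setValidity("ViromeCohort", .validViromeCohort)

#' Homology search parameters
#'
#' Controls the seed-and-extend nucleotide search that stands in for
#' per-virome BLASTN comparisons. A query contig has a homologue in a target
#' virome when its best local alignment against some target contig reaches
#' `minAlignmentLength` nucleotides, `minIdentity` fractional identity and a
#' Karlin-Altschul E-value at most `evalueThreshold` (database size = total
#' target length; match +1 / mismatch -2 scoring). The E-value bound of
#' 1e-10 is the decision criterion of the original comparisons; word size,
#' alignment length and identity defaults are engine conventions chosen to be
#' permissive at the divergence scales of persistent viruses.
#'
#' @slot wordSize integer exact-seed length (default 11).
#' @slot minAlignmentLength integer minimum alignment length, nt (default 50).
#' @slot minIdentity numeric minimum fractional identity (default 0.90).
#' @slot evalueThreshold numeric significance bound (default 1e-10).
#' @export
setClass("HomologyParams", representation(
    wordSize = "integer", minAlignmentLength = "integer",
    minIdentity = "numeric", evalueThreshold = "numeric"))

setValidity("HomologyParams", function(object) {
    msg <- character()
    if (object@wordSize < 8L) msg <- c(msg, "wordSize must be >= 8")
    if (object@minIdentity <= 0 || object@minIdentity > 1)
        msg <- c(msg, "minIdentity must be in (0, 1]")
    if (object@evalueThreshold <= 0) msg <- c(msg, "evalueThreshold must be > 0")
    if (object@minAlignmentLength < 1L) msg <- c(msg, "minAlignmentLength must be >= 1")
    if (length(msg)) msg else TRUE
})

#' @param wordSize,minAlignmentLength,minIdentity,evalueThreshold see slots.
#' @return `homologyParams()` returns a validated `HomologyParams` object.
#' @rdname HomologyParams-class
#' @examples
#' homologyParams()
#' @export
homologyParams <- function(wordSize = 11L, minAlignmentLength = 50L,
                           minIdentity = 0.90, evalueThreshold = 1e-10) {
    new("HomologyParams", wordSize = as.integer(wordSize),
        minAlignmentLength = as.integer(minAlignmentLength),
        minIdentity = minIdentity, evalueThreshold = evalueThreshold)
}

#' Resampling-test parameters
#'
#' @slot nIterations integer number of paired resampling iterations
#'   (default 10000).
#' @slot nContigsPerDraw integer contigs sampled per draw (default 1000;
#'   drawn without replacement when the virome is at least that large, with
#'   replacement otherwise).
#' @slot seed integer RNG seed.
#' @export
setClass("PermutationParams", representation(
    nIterations = "integer", nContigsPerDraw = "integer", seed = "integer"))

setValidity("PermutationParams", function(object) {
    msg <- character()
    if (object@nIterations < 1L) msg <- c(msg, "nIterations must be >= 1")
    if (object@nContigsPerDraw < 1L) msg <- c(msg, "nContigsPerDraw must be >= 1")
    if (length(msg)) msg else TRUE
})

#' @param nIterations,nContigsPerDraw,seed see slots.
#' @return `permutationParams()` returns a validated `PermutationParams`.
#' @rdname PermutationParams-class
#' @examples
#' permutationParams(nIterations = 500)
#' @export
permutationParams <- function(nIterations = 10000L, nContigsPerDraw = 1000L,
                              seed = 1L) {
    new("PermutationParams", nIterations = as.integer(nIterations),
        nContigsPerDraw = as.integer(nContigsPerDraw), seed = as.integer(seed))
}

#' Global-virus clustering parameters
#'
#' Contigs are linked when a local alignment covers at least `minOverlap` of
#' the shorter contig at `minIdentity` identity or better; global viruses are
#' the connected components under single linkage. Defaults (98% identity,
#' 50% overlap) mirror the assembly criteria used to discriminate highly
#' related viruses.
#'
#' @slot minIdentity numeric in (0, 1], default 0.98.
#' @slot minOverlap numeric fraction of the shorter contig, default 0.50.
#' @export
setClass("ClusterParams",
    representation(minIdentity = "numeric", minOverlap = "numeric"))

setValidity("ClusterParams", function(object) {
    msg <- character()
    if (object@minIdentity <= 0 || object@minIdentity > 1)
        msg <- c(msg, "minIdentity must be in (0, 1]")
    if (object@minOverlap <= 0 || object@minOverlap > 1)
        msg <- c(msg, "minOverlap must be in (0, 1]")
    if (length(msg)) msg else TRUE
})

#' @param minIdentity,minOverlap see slots.
#' @return `clusterParams()` returns a validated `ClusterParams`.
#' @rdname ClusterParams-class
#' @examples
#' clusterParams()
#' @export
clusterParams <- function(minIdentity = 0.98, minOverlap = 0.50) {
    new("ClusterParams", minIdentity = minIdentity, minOverlap = minOverlap)
}

#' Cohort simulation configuration
#'
#' Parameters of the household-cohort generator. Each subject carries a set
#' of core viruses (a subset shared with the housemate as common founders), a
#' cohort-wide background pool supplies environmentally acquired viruses, and
#' presence evolves along the five sampling time points as a Markov chain:
#' a present virus persists to the next time point with `retentionProb`, an
#' absent core virus reappears with `reacquisitionProb`, and an absent
#' background virus is acquired with `backgroundAcquisitionProb`. Genomes are
#' uniform-random sequences that accumulate substitutions at `mutationRate`
#' per base per time step and are emitted re-fragmented into
#' `contigsPerVirus` non-overlapping contigs per sample. Planted
#' transmissions copy a donor-exclusive virus into the housemate at a random
#' later time point (with one extra round of divergence) and are floored to
#' at least two recipient presences so the presence/absence transmission rule
#' can in principle recover them.
#'
#' @slot nHouseholdsTwoPerson integer two-person households (default 8).
#' @slot nControls integer singleton control households (default 4).
#' @slot bodySites character subset of feces/saliva.
#' @slot nCoreVirusesPerSubject integer core viruses per subject.
#' @slot nHouseholdSharedViruses integer of the core viruses that are common
#'   founders of both housemates.
#' @slot nBackgroundPool integer cohort-wide background viruses.
#' @slot retentionProb,reacquisitionProb,backgroundAcquisitionProb numeric
#'   per-time-step presence dynamics, all in [0, 1].
#' @slot transmissionRate numeric expected planted transmissions per
#'   two-person household (Poisson, capped by available donor-exclusive
#'   viruses).
#' @slot transmissionDirectionBias numeric probability that the donor of a
#'   planted transmission is the placebo-taking housemate.
#' @slot mutationRate numeric per-base substitution probability per time step.
#' @slot genomeLengthRange integer length-2, genome length bounds (nt).
#' @slot contigsPerVirus integer fragments emitted per present virus per
#'   sample.
#' @slot missingSampleProb numeric probability a (subject, time point, site)
#'   specimen is missing.
#' @slot dropLastHouseholdMonth6 logical; drop the last two-person
#'   household's month-6 specimens (a household lost to follow-up).
#' @slot seed integer RNG seed.
#' @export
setClass("SimulationConfig", representation(
    nHouseholdsTwoPerson = "integer", nControls = "integer",
    bodySites = "character", nCoreVirusesPerSubject = "integer",
    nHouseholdSharedViruses = "integer", nBackgroundPool = "integer",
    retentionProb = "numeric", reacquisitionProb = "numeric",
    backgroundAcquisitionProb = "numeric", transmissionRate = "numeric",
    transmissionDirectionBias = "numeric", mutationRate = "numeric",
    genomeLengthRange = "integer", contigsPerVirus = "integer",
    missingSampleProb = "numeric", dropLastHouseholdMonth6 = "logical",
    seed = "integer"))

setValidity("SimulationConfig", function(object) {
    msg <- character()
    pr <- c(object@retentionProb, object@reacquisitionProb,
            object@backgroundAcquisitionProb, object@missingSampleProb,
            object@mutationRate, object@transmissionDirectionBias)
    if (any(pr < 0 | pr > 1)) msg <- c(msg, "probabilities must be in [0, 1]")
    cnt <- c(object@nHouseholdsTwoPerson, object@nControls,
             object@nCoreVirusesPerSubject, object@nHouseholdSharedViruses,
             object@nBackgroundPool)
    if (any(cnt < 0L)) msg <- c(msg, "counts must be >= 0")
    if (object@transmissionRate < 0) msg <- c(msg, "transmissionRate must be >= 0")
    if (object@nHouseholdSharedViruses > object@nCoreVirusesPerSubject)
        msg <- c(msg, "nHouseholdSharedViruses cannot exceed nCoreVirusesPerSubject")
    if (!all(object@bodySites %in% .BODY_SITES) || !length(object@bodySites))
        msg <- c(msg, "bodySites must be a non-empty subset of feces/saliva")
    if (length(object@genomeLengthRange) != 2L ||
        object@genomeLengthRange[1] > object@genomeLengthRange[2])
        msg <- c(msg, "genomeLengthRange must be an increasing length-2 integer")
    if (object@contigsPerVirus < 1L) msg <- c(msg, "contigsPerVirus must be >= 1")
    if (object@genomeLengthRange[1] < 200L * object@contigsPerVirus)
        msg <- c(msg, "min genome length must be >= 200 * contigsPerVirus")
    if (length(msg)) msg else TRUE
})

#' Construct a simulation configuration
#'
#' @param nHouseholdsTwoPerson,nControls,bodySites,nCoreVirusesPerSubject,nHouseholdSharedViruses,nBackgroundPool,retentionProb,reacquisitionProb,backgroundAcquisitionProb,transmissionRate,transmissionDirectionBias,mutationRate,genomeLengthRange,contigsPerVirus,missingSampleProb,dropLastHouseholdMonth6,seed
#'   see the corresponding [SimulationConfig-class] slots.
#' @return a validated `SimulationConfig`.
#' @seealso [defaultSimulationConfig()], [nullPoolConfig()]
#' @examples
#' simulationConfig(nHouseholdsTwoPerson = 2, nControls = 1, seed = 7)
#' @export
simulationConfig <- function(nHouseholdsTwoPerson = 8L, nControls = 4L,
        bodySites = c("feces", "saliva"), nCoreVirusesPerSubject = 12L,
        nHouseholdSharedViruses = 5L, nBackgroundPool = 40L,
        retentionProb = 0.78, reacquisitionProb = 0.05,
        backgroundAcquisitionProb = 0.04, transmissionRate = 2.5,
        transmissionDirectionBias = 0.75, mutationRate = 0.001,
        genomeLengthRange = c(500L, 3000L), contigsPerVirus = 2L,
        missingSampleProb = 0.02, dropLastHouseholdMonth6 = TRUE, seed = 1L) {
    new("SimulationConfig",
        nHouseholdsTwoPerson = as.integer(nHouseholdsTwoPerson),
        nControls = as.integer(nControls), bodySites = bodySites,
        nCoreVirusesPerSubject = as.integer(nCoreVirusesPerSubject),
        nHouseholdSharedViruses = as.integer(nHouseholdSharedViruses),
        nBackgroundPool = as.integer(nBackgroundPool),
        retentionProb = retentionProb, reacquisitionProb = reacquisitionProb,
        backgroundAcquisitionProb = backgroundAcquisitionProb,
        transmissionRate = transmissionRate,
        transmissionDirectionBias = transmissionDirectionBias,
        mutationRate = mutationRate,
        genomeLengthRange = as.integer(genomeLengthRange),
        contigsPerVirus = as.integer(contigsPerVirus),
        missingSampleProb = missingSampleProb,
        dropLastHouseholdMonth6 = dropLastHouseholdMonth6,
        seed = as.integer(seed))
}
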