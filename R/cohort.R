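## ViromeCohort construction, accessors and TSV/FASTA round-trip.

#' Construct a ViromeCohort
#'
#' @param samples a data.frame or DataFrame with columns `subject_id`,
#'   `household_id`, `body_site`, `timepoint`, `treatment` and optionally
#'   `missing` (default `FALSE`); `sample_id` is derived if absent.
#' @param contigs a list of [Biostrings::DNAStringSet], one per sample row
#'   (named contigs, unique within a sample). Missing samples get empty sets.
#' @return a validated [ViromeCohort-class].
#' @examples
#' sm <- data.frame(subject_id = "S1", household_id = "H1",
#'                  body_site = "feces", timepoint = "day0",
#'                  treatment = "none")
#' ctg <- Biostrings::DNAStringSet(c(c1 = paste(rep("ACGT", 60), collapse = "")))
#' ViromeCohort(sm, list(ctg))
#' @export
ViromeCohort <- function(samples, contigs) {
    samples <- as.data.frame(samples)
    if (is.null(samples$missing))
        samples[["missing"]] <- logical(nrow(samples))
    if (is.null(samples$sample_id))
        samples$sample_id <- sampleId(samples$subject_id, samples$body_site,
                                      samples$timepoint)
    canon <- setdiff(.META_COLS, "fasta_file")
    samples <- samples[, c(canon, setdiff(colnames(samples), canon)),
                       drop = FALSE]
    rownames(samples) <- NULL
    samples <- S4Vectors::DataFrame(samples)
    contigs <- S4Vectors::SimpleList(lapply(contigs, function(x) {
        if (is.character(x)) x <- Biostrings::DNAStringSet(x)
        x
    }))
    names(contigs) <- samples$sample_id
    new("ViromeCohort", samples = samples, contigs = contigs)
}

#' @describeIn ViromeCohort sample metadata as a DataFrame.
#' @param object,x a `ViromeCohort`.
#' @export
setGeneric("sampleData", function(object) standardGeneric("sampleData"))

#' @rdname ViromeCohort-class
#' @export
setMethod("sampleData", "ViromeCohort", function(object) object@samples)

#' @describeIn ViromeCohort contig sets; optionally for one sample id.
#' @param sample optional sample id (character scalar).
#' @export
setGeneric("viromeContigs", function(object, sample = NULL)
    standardGeneric("viromeContigs"))

#' @rdname ViromeCohort-class
#' @export
setMethod("viromeContigs", "ViromeCohort", function(object, sample = NULL) {
    if (is.null(sample)) return(object@contigs)
    i <- match(sample, object@samples$sample_id)
    if (is.na(i)) stop("unknown sample id: ", sample)
    object@contigs[[i]]
})

#' @describeIn ViromeCohort ids of samples flagged missing.
#' @export
setGeneric("missingSamples", function(object) standardGeneric("missingSamples"))

#' @rdname ViromeCohort-class
#' @export
setMethod("missingSamples", "ViromeCohort", function(object)
    object@samples$sample_id[object@samples$missing])

#' @describeIn ViromeCohort distinct subject ids.
#' @export
setGeneric("subjects", function(object) standardGeneric("subjects"))

#' @rdname ViromeCohort-class
#' @export
setMethod("subjects", "ViromeCohort", function(object)
    unique(object@samples$subject_id))

#' @describeIn ViromeCohort distinct household ids.
#' @export
setGeneric("households", function(object) standardGeneric("households"))

#' @rdname ViromeCohort-class
#' @export
setMethod("households", "ViromeCohort", function(object)
    unique(object@samples$household_id))

#' @rdname ViromeCohort-class
#' @export
setMethod("show", "ViromeCohort", function(object) {
    sm <- object@samples
    cat("ViromeCohort:", nrow(sm), "samples (", sum(sm$missing), "missing ),",
        length(unique(sm$subject_id)), "subjects,",
        length(unique(sm$household_id)), "households\n")
    cat("  body sites:", paste(unique(sm$body_site), collapse = ", "), "\n")
    cat("  contigs:", sum(vapply(object@contigs, length, 1L)), "total\n")
})

## internal: rows of non-missing samples at a site, with >= 1 contig
.siteSamples <- function(cohort, bodySite) {
    sm <- sampleData(cohort)
    keep <- !sm$missing & sm$body_site == bodySite &
        vapply(cohort@contigs, length, 1L) > 0
    which(keep)
}

## ---- readers / writers ------------------------------------------------------

.META_COLS <- c("sample_id", "subject_id", "household_id", "body_site",
                "timepoint", "treatment", "missing", "fasta_file")

#' Read a cohort from a metadata table plus per-sample FASTA files
#'
#' The metadata is a tab-delimited table with header columns `subject_id`,
#' `household_id`, `body_site`, `timepoint`, `treatment`, `fasta_file`
#' (and optionally `sample_id`, `missing`). A row whose `fasta_file` is empty
#' or NA, or whose `missing` flag is true, is loaded as a missing specimen.
#' Contigs shorter than 200 nt or containing ambiguous characters are dropped
#' (with a message reporting the count), mirroring the contig filter applied
#' after assembly.
#'
#' @param metadataPath path to the TSV metadata table.
#' @param fastaDir directory that `fasta_file` entries are relative to.
#' @return a validated [ViromeCohort-class].
#' @seealso [writeCohort()]
#' @export
readCohort <- function(metadataPath, fastaDir = dirname(metadataPath)) {
    if (!file.exists(metadataPath)) stop("metadata not found: ", metadataPath)
    md <- utils::read.delim(metadataPath, stringsAsFactors = FALSE,
                            colClasses = "character")
    need <- c("subject_id", "household_id", "body_site", "timepoint",
              "treatment", "fasta_file")
    miss <- setdiff(need, colnames(md))
    if (length(miss))
        stop("metadata lacks column(s): ", paste(miss, collapse = ", "))
    for (j in need[1:5]) {
        bad <- which(is.na(md[[j]]) | md[[j]] == "")
        if (length(bad))
            stop(sprintf("malformed metadata row %d: empty %s", bad[1], j))
    }
    md$missing <- if (is.null(md$missing)) rep(FALSE, nrow(md)) else
        as.logical(md$missing) %in% TRUE
    md$missing <- md$missing | is.na(md$fasta_file) | md$fasta_file == ""
    if (is.null(md$sample_id))
        md$sample_id <- sampleId(md$subject_id, md$body_site, md$timepoint)
    dup <- which(duplicated(md$sample_id))
    if (length(dup))
        stop("duplicate sample key in metadata row ", dup[1], ": ",
             md$sample_id[dup[1]])
    nDropped <- 0L
    contigs <- vector("list", nrow(md))
    for (i in seq_len(nrow(md))) {
        if (md$missing[i]) {
            contigs[[i]] <- Biostrings::DNAStringSet()
            next
        }
        f <- file.path(fastaDir, md$fasta_file[i])
        if (!file.exists(f))
            stop(sprintf("malformed metadata row %d: FASTA not found: %s", i, f))
        cs <- Biostrings::readDNAStringSet(f)
        names(cs) <- sub("\\s.*$", "", names(cs))
        af <- Biostrings::alphabetFrequency(cs, baseOnly = TRUE)
        keep <- Biostrings::width(cs) >= 200L & af[, "other"] == 0
        nDropped <- nDropped + sum(!keep)
        contigs[[i]] <- cs[keep]
    }
    if (nDropped > 0)
        message(nDropped, " contig(s) dropped (< 200 nt or ambiguous characters)")
    ViromeCohort(md[, setdiff(.META_COLS, "fasta_file")], contigs)
}

#' Write a cohort as a metadata TSV plus one FASTA per sample
#'
#' The inverse of [readCohort()]: `readCohort(writeCohort(x))` reproduces the
#' cohort exactly (same keys, same sequences). Missing samples get a metadata
#' row with an empty `fasta_file` and no FASTA on disk. FASTA records are
#' wrapped at 80 columns.
#'
#' @param cohort a [ViromeCohort-class].
#' @param outDir output directory (created if needed).
#' @param overwrite logical; allow clobbering existing files.
#' @return (invisibly) named list with `metadata` path and `fasta` paths.
#' @export
writeCohort <- function(cohort, outDir, overwrite = FALSE) {
    stopifnot(is(cohort, "ViromeCohort"))
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    sm <- as.data.frame(sampleData(cohort))
    sm$fasta_file <- ifelse(sm$missing, "", paste0(sm$sample_id, ".fasta"))
    metaPath <- file.path(outDir, "metadata.tsv")
    paths <- file.path(outDir, sm$fasta_file[!sm$missing])
    clash <- c(metaPath, paths)[file.exists(c(metaPath, paths))]
    if (length(clash) && !overwrite)
        stop("output exists (use overwrite = TRUE): ", clash[1])
    utils::write.table(sm[, .META_COLS], metaPath, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    for (i in which(!sm$missing))
        Biostrings::writeXStringSet(cohort@contigs[[i]],
            file.path(outDir, sm$fasta_file[i]), width = 80L)
    invisible(list(metadata = metaPath, fasta = paths))
}
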