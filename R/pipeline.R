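## End-to-end orchestration: simulate/read -> homology -> distances/PCoA ->
## overlap tests -> global-virus tracking -> transmission directionality,
## with every stage's output serialized and a checksum manifest.

.cfgGet <- function(config, name, default) {
    v <- config[[name]]
    if (is.null(v)) default else v
}

#' Read a pipeline configuration from YAML
#'
#' The configuration holds either a `simulation` block (arguments of
#' [simulationConfig()], snake_case accepted) or an `input` block
#' (`metadata`, `fasta_dir`), never both, plus optional `body_sites`,
#' `homology`, `permutation`, `cluster` parameter blocks and a `seed`.
#'
#' @param path YAML file path.
#' @return a validated config list.
#' @export
readPipelineConfig <- function(path) {
    if (!file.exists(path)) stop("config file not found: ", path)
    validatePipelineConfig(yaml::read_yaml(path))
}

#' @rdname readPipelineConfig
#' @param config a config list.
#' @export
validatePipelineConfig <- function(config) {
    has <- c(!is.null(config$simulation), !is.null(config$input))
    if (sum(has) != 1L)
        stop("config must supply exactly one of 'simulation' or 'input'")
    config
}

.snakeToCamel <- function(x) {
    names(x) <- gsub("_(\\w)", "\\U\\1", names(x), perl = TRUE)
    x
}

.cfgSimulation <- function(config, seed) {
    args <- .snakeToCamel(config$simulation)
    if (is.null(args$seed)) args$seed <- seed
    do.call(simulationConfig, args)
}

.cfgHomology <- function(config)
    do.call(homologyParams, .snakeToCamel(.cfgGet(config, "homology", list())))

.cfgCluster <- function(config)
    do.call(clusterParams, .snakeToCamel(.cfgGet(config, "cluster", list())))

.cfgPermutation <- function(config, seed) {
    args <- .snakeToCamel(.cfgGet(config, "permutation", list()))
    if (is.null(args$seed)) args$seed <- seed
    do.call(permutationParams, args)
}

.writeTSV <- function(d, path) {
    utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
}

.writeJSON <- function(x, path) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    path
}

#' Run the full household-virome analysis pipeline
#'
#' Executes, in order: cohort simulation (or reading), all-pairs homology,
#' Sorensen/Bray-Curtis distances with PCoA and the within- vs
#' between-household comparison, subject and household overlap resampling
#' tests, per-subject global-virus clustering with persistence summaries,
#' and per-household clustering with sharing, transmission calls and the
#' directionality summary. All stage outputs are written under `outDir` and
#' recorded, with MD5 checksums, in `manifest.json`; runs are deterministic
#' given the seed.
#'
#' @param config a config list ([readPipelineConfig()]).
#' @param outDir output directory.
#' @param seed integer seed (overridden by an explicit seed in `config`).
#' @return (invisibly) the manifest list.
#' @export
runPipeline <- function(config, outDir, seed = 1L) {
    config <- validatePipelineConfig(config)
    seed <- as.integer(.cfgGet(config, "seed", seed))
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    outputs <- character(0)
    emit <- function(p) { outputs[[length(outputs) + 1L]] <<- p; p }
    stage <- function(name, expr) {
        tryCatch(expr, error = function(e)
            stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
                 call. = FALSE))
    }

    ## stage 1: cohort
    truth <- NULL
    if (!is.null(config$simulation)) {
        simCfg <- .cfgSimulation(config, seed)
        sim <- stage("simulate", simulateCohort(simCfg))
        cohort <- sim$cohort
        truth <- sim$truth
        emit(.writeJSON(truth, file.path(outDir, "truth.json")))
    } else {
        cohort <- stage("read_cohort",
            readCohort(config$input$metadata, config$input$fasta_dir))
    }
    cohortDir <- file.path(outDir, "cohort")
    stage("write_cohort", writeCohort(cohort, cohortDir, overwrite = TRUE))
    emit(file.path(cohortDir, "metadata.tsv"))
    yaml::write_yaml(config, emit(file.path(outDir, "config.yaml")))

    hp <- .cfgHomology(config)
    pp <- .cfgPermutation(config, seed)
    cp <- .cfgCluster(config)
    sites <- .cfgGet(config, "body_sites",
                     unique(as.data.frame(sampleData(cohort))$body_site))
    sm <- as.data.frame(sampleData(cohort))

    for (site in sites) {
        ## stage 2: homology
        hf <- stage("homology", computeHitFlags(cohort, site, hp))
        tab <- allPairsShared(hf)
        emit(.writeTSV(tab, file.path(outDir,
            sprintf("shared_fractions_%s.tsv", site))))

        ## stage 3: distances, ordination, household comparison
        sim <- stage("distance", sorensenMatrix(tab))
        bc <- brayCurtisMatrix(tab)
        emit(.writeTSV(data.frame(sample_id = rownames(sim), sim,
                                  check.names = FALSE),
            file.path(outDir, sprintf("sorensen_%s.tsv", site))))
        emit(.writeTSV(data.frame(sample_id = rownames(bc), bc,
                                  check.names = FALSE),
            file.path(outDir, sprintf("bray_curtis_%s.tsv", site))))
        ord <- stage("pcoa", pcoaOrdination(bc, nAxes = 2L))
        emit(.writeTSV(data.frame(sample_id = rownames(ord$coordinates),
                                  ord$coordinates),
            file.path(outDir, sprintf("pcoa_%s.tsv", site))))
        emit(.writeJSON(list(eigenvalues = ord$eigenvalues,
                             proportion_explained = ord$proportion_explained),
            file.path(outDir, sprintf("pcoa_%s.json", site))))
        hhcmp <- stage("household_comparison",
            householdDistanceComparison(sim, hf$samples))
        emit(.writeJSON(hhcmp, file.path(outDir,
            sprintf("household_comparison_%s.json", site))))

        ## stage 4: overlap resampling tests
        emit(.writeTSV(stage("permtest_subject",
                overlapTestTable(hf, pp, unit = "subject")),
            file.path(outDir, sprintf("subject_overlap_%s.tsv", site))))
        emit(.writeTSV(stage("permtest_household",
                overlapTestTable(hf, pp, unit = "household")),
            file.path(outDir, sprintf("household_overlap_%s.tsv", site))))

        ## stage 5: per-subject tracking and persistence
        pers <- list()
        for (s in unique(hf$samples$subject_id)) {
            gv <- stage("track", clusterGlobalViruses(cohort, "subject", s,
                                                      site, cp))
            ps <- persistenceSummary(gv)
            pers[[s]] <- ps[c("n_viruses", "fraction_ge_4_days",
                              "fraction_ge_150_days")]
        }
        emit(.writeJSON(pers, file.path(outDir,
            sprintf("persistence_%s.json", site))))

        ## stage 6: per-household sharing and transmissions
        hhs <- names(which(vapply(split(sm$subject_id, sm$household_id),
                                  function(x) length(unique(x)), 1L) == 2L))
        sharing <- list(); calls <- list(); presence <- list()
        for (h in hhs) {
            gv <- stage("transmit", clusterGlobalViruses(cohort, "household",
                                                         h, site, cp))
            sharing[[h]] <- householdSharing(gv, cohort)
            calls[[h]] <- callTransmissions(gv, cohort)
            presence[[h]] <- cbind(household_id = h, gv$presence)
        }
        emit(.writeTSV(do.call(rbind, c(presence, list(make.row.names = FALSE))),
            file.path(outDir, sprintf("global_virus_presence_%s.tsv", site))))
        sharing <- do.call(rbind, sharing)
        calls <- do.call(rbind, c(calls, list(make.row.names = FALSE)))
        emit(.writeTSV(sharing, file.path(outDir,
            sprintf("sharing_%s.tsv", site))))
        emit(.writeTSV(calls, file.path(outDir,
            sprintf("transmissions_%s.tsv", site))))

        ## stage 7: directionality
        dirs <- stage("directionality", directionalitySummary(sharing, calls))
        emit(.writeJSON(dirs, file.path(outDir,
            sprintf("directionality_%s.json", site))))
    }

    fasta <- list.files(cohortDir, pattern = "\\.fasta$", full.names = TRUE)
    files <- c(outputs, fasta)
    manifest <- list(
        seed = seed,
        parameters = list(
            homology = list(word_size = hp@wordSize,
                min_alignment_length = hp@minAlignmentLength,
                min_identity = hp@minIdentity,
                evalue_threshold = hp@evalueThreshold),
            permutation = list(n_iterations = pp@nIterations,
                n_contigs_per_draw = pp@nContigsPerDraw, seed = pp@seed),
            cluster = list(min_identity = cp@minIdentity,
                min_overlap = cp@minOverlap),
            body_sites = sites),
        checksums = {
            ck <- tools::md5sum(sort(files))
            names(ck) <- sub(paste0("^", normalizePath(outDir), "/?"), "",
                             normalizePath(names(ck)))
            as.list(ck)
        })
    .writeJSON(manifest, file.path(outDir, "manifest.json"))
    invisible(manifest)
}
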