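#' Load a run configuration
#'
#' YAML or JSON file describing one analysis run. Recognized fields:
#' `cohort` (contour JSON path), `levels` (contour JSON of level boxes or
#' directory of NIfTI masks), `landmarks` (landmark JSON),
#' `aliases` (alias CSV), `ptv` (PTV structure name, default PTV1),
#' `threshold` (inclusion threshold, default 0.70), `cranial_landmark`,
#' `caudal_landmark`, `width_z` (numeric vector, mm), `width_axis`,
#' `out` (output directory), `seed` (for simulate), `log` (log file).
#'
#' @param path config file (.yaml/.yml or .json).
#' @return list of class `"runConfig"`.
#' @export
loadRunConfig <- function(path) {
    cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
           else jsonlite::fromJSON(path, simplifyVector = TRUE)
    cfg$ptv <- cfg$ptv %||% "PTV1"
    cfg$threshold <- cfg$threshold %||% 0.70
    if (cfg$threshold <= 0 || cfg$threshold >= 1)
        stop("config error: threshold must lie in (0, 1)")
    cfg$width_axis <- cfg$width_axis %||% "x"
    cfg$out <- cfg$out %||% "."
    cfg$logFile <- cfg$log
    class(cfg) <- "runConfig"
    cfg
}

resolveCohort <- function(config) {
    if (is(config$cohort, "ObserverCohort")) return(config$cohort)
    if (is.null(config$cohort)) stop("config error: no cohort input given")
    aliases <- if (!is.null(config$aliases)) readAliasTable(config$aliases)
               else readAliasTable()
    readContours(config$cohort, "json", aliases)
}

#' Volume-statistics and agreement report
#'
#' The variability-table stage of the pipeline: per structure, the
#' observer count N, mean/SD/range of volumes, CoV, CIpairs and the mean
#' pairwise DSC and MASD, written as one CSV row per structure sorted
#' most-to-least variable by CoV. Undefined cells (single-observer
#' structures) are blank, not 0. Volumes are printed to 3 significant
#' figures and CoV to 2 decimals, half away from zero.
#'
#' @param config a `"runConfig"` (or list with the same fields). The
#'   cohort may be given directly as an [ObserverCohort-class] in
#'   `config$cohort`.
#' @param computeMASD passed to [cohortAgreement()].
#' @return invisibly, the unrounded [agreementTable()] data.frame. Side
#'   effect: `metrics.csv` in `config$out`.
#' @export
runMetrics <- function(config, computeMASD = TRUE) {
    cohort <- resolveCohort(config)
    ns <- structureCount(cohort)
    if (!any(ns >= 2L))
        stop("no structure is shared by at least 2 observers")
    for (s in names(ns)[ns == 1L])
        iovLog(config, "warning: structure '", s,
               "' has a single observer; CoV/CIpairs left blank")
    agr <- cohortAgreement(cohort, computeMASD = computeMASD)
    tab <- agreementTable(agr)
    out <- data.frame(structure = tab$structure, n = tab$n,
                      mean_cc = fmtVolume(tab$mean_cc),
                      sd_cc = fmtVolume(tab$sd_cc),
                      cov = fmtCov(tab$cov),
                      min_cc = fmtVolume(tab$min_cc),
                      max_cc = fmtVolume(tab$max_cc),
                      ci_pairs = fmtCov(tab$ci_pairs),
                      dsc_mean = fmtCov(tab$dsc_mean),
                      masd_mean_mm = fmtVolume(tab$masd_mean_mm))
    dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
    path <- file.path(config$out, "metrics.csv")
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
    iovLog(config, "wrote ", path, " (", nrow(out), " structures)")
    invisible(tab)
}

resolveLevels <- function(config, grid) {
    lv <- config$levels
    if (is.list(lv) && all(vapply(lv, is, logical(1), "BinaryVolume")))
        return(lv)
    if (is.null(lv)) stop("config error: no level masks given")
    if (dir.exists(lv)) {
        files <- list.files(lv, pattern = "\\.nii(\\.gz)?$", full.names = TRUE)
        if (length(files) == 0L)
            stop("missing level masks: no NIfTI files in ", lv)
        out <- lapply(files, readMaskNifti, grid = grid)
        names(out) <- sub("\\.nii(\\.gz)?$", "", basename(files))
        return(out)
    }
    # level names are arbitrary by design; skip vocabulary warnings
    atlas <- suppressWarnings(readContours(lv, "json"))
    obs <- cohortObservers(atlas)[1]
    out <- lapply(structureNames(atlas), function(s)
        rasterize(getDelineation(atlas, obs, s), grid))
    names(out) <- structureNames(atlas)
    out
}

#' Lymph-node-level inclusion report
#'
#' Applies the strict >70% (configurable) overlap rule per observer and
#' level and writes the coverage table plus the covered-by-all /
#' covered-by-no-observer lists.
#'
#' @inheritParams runMetrics
#' @return invisibly, the [levelCoverageTable()] data.frame. Side effect:
#'   `levels.csv` in `config$out`.
#' @export
runLevels <- function(config) {
    cohort <- resolveCohort(config)
    levels <- resolveLevels(config, cohort@grid)
    tab <- withCallingHandlers(
        levelCoverageTable(cohort, levels, ptvName = config$ptv,
                           threshold = config$threshold),
        warning = function(w) {
            iovLog(config, "warning: ", conditionMessage(w))
            invokeRestart("muffleWarning")
        })
    out <- tab
    for (cn in grep("^frac_", names(out), value = TRUE))
        out[[cn]] <- fmtCov(out[[cn]])
    dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
    path <- file.path(config$out, "levels.csv")
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
    iovLog(config, "wrote ", path, "; covered by all: ",
           paste(tab$level[tab$covered_by_all], collapse = ", "),
           "; covered by none: ",
           paste(tab$level[tab$covered_by_none], collapse = ", "))
    invisible(tab)
}

#' Landmark-referenced border and width report
#'
#' Per-observer cranial/caudal borders, landmark offsets and axial widths
#' plus cohort spread/mean rows, written as CSV.
#'
#' @inheritParams runMetrics
#' @return invisibly, the [borderReport()] list. Side effects:
#'   `landmarks_observers.csv` and `landmarks_cohort.csv` in `config$out`.
#' @export
runLandmarks <- function(config) {
    cohort <- resolveCohort(config)
    if (is.null(config$landmarks)) stop("config error: no landmark file given")
    lm <- if (is.numeric(config$landmarks)) config$landmarks
          else readLandmarks(config$landmarks, cohort@grid)
    pick <- function(nm) {
        if (!is.null(config[[nm]])) {
            if (!config[[nm]] %in% names(lm))
                stop("config error: unknown landmark '", config[[nm]], "'")
            config[[nm]]
        } else NA
    }
    rep <- borderReport(cohort, structure = config$ptv, landmarks = lm,
                        cranialLandmark = pick("cranial_landmark"),
                        caudalLandmark = pick("caudal_landmark"),
                        widthZ = config$width_z %||% numeric(),
                        axis = config$width_axis)
    dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
    p1 <- file.path(config$out, "landmarks_observers.csv")
    p2 <- file.path(config$out, "landmarks_cohort.csv")
    utils::write.csv(rep$perObserver, p1, row.names = FALSE, quote = FALSE)
    utils::write.csv(rep$cohort, p2, row.names = FALSE, quote = FALSE)
    iovLog(config, "wrote ", p1, " and ", p2)
    invisible(rep)
}

#' Generate and persist a synthetic cohort
#'
#' Runs [generateCohort()] under `config$seed` and writes the cohort in
#' the JSON contour dialect, the nodal-level boxes as a single-observer
#' contour file, the landmark file, and the ground truth (realized
#' margins, truncations, omissions, analytic volumes) as JSON.
#'
#' @inheritParams runMetrics
#' @param spec optional [cohortSpec()]; defaults to
#'   [defaultCohortSpec()] under `config$seed`.
#' @return invisibly, the [generateCohort()] result. Side effects:
#'   `cohort.json`, `levels.json`, `landmarks.json`, `ground_truth.json`
#'   in `config$out`.
#' @export
runSimulate <- function(config, spec = NULL) {
    seed <- config$seed %||% 1L
    if (is.null(spec)) spec <- defaultCohortSpec(seed = seed)
    gen <- generateCohort(spec)
    dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
    writeContours(gen$cohort, file.path(config$out, "cohort.json"))
    # level boxes as a one-observer contour file on the same grid
    lvlDel <- lapply(names(spec$levels), function(nm)
        structureDelineation("atlas", nm,
                             shapeContours(spec$levels[[nm]], 0, NULL,
                                           spec$grid)))
    writeContours(observerCohort(spec$grid, lvlDel, "atlas"),
                  file.path(config$out, "levels.json"))
    jsonlite::write_json(as.list(gen$landmarks),
                         file.path(config$out, "landmarks.json"),
                         auto_unbox = TRUE, digits = NA)
    truth <- list(
        observers = gen$truth$observers,
        omitted = gen$truth$omitted,
        analytic_volumes_cc = lapply(gen$truth$structures,
                                     function(s) s$volume_cc))
    jsonlite::write_json(truth, file.path(config$out, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
    iovLog(config, "simulated cohort (seed ", seed, ") written to ",
           config$out)
    invisible(gen)
}
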