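#' Controlled structure vocabulary
#'
#' Canonical names for the structures of a head-and-neck contouring study:
#' the two planning target volumes and the standard organs at risk.
#' Arbitrary additional names (e.g. nodal level labels) are allowed
#' everywhere; they are simply preserved verbatim.
#'
#' @return character vector of canonical names.
#' @export
canonicalNames <- function() {
    c("PTV1", "PTV2", "brainstem", "pituitary",
      "inner_ear_L", "inner_ear_R", "optic_chiasm", "spinal_canal",
      "optic_nerve_L", "optic_nerve_R", "eye_lens_L", "eye_lens_R",
      "TMJ_L", "TMJ_R", "parotid_L", "parotid_R",
      "submandibular_L", "submandibular_R")
}

#' Read a structure-name alias table
#'
#' A two-column CSV (`raw_name, canonical_name`) mapping planning-system ROI
#' labels onto the controlled vocabulary. A default table covering common
#' spellings ships in `inst/extdata/aliases.csv`.
#'
#' @param path CSV path; default = the packaged table.
#' @return data.frame with columns `raw_name`, `canonical_name`.
#' @export
readAliasTable <- function(path = system.file("extdata", "aliases.csv",
                                              package = "contourIOV")) {
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!all(c("raw_name", "canonical_name") %in% names(tab)))
        stop("alias table must have columns raw_name, canonical_name")
    tab
}

# Map one raw ROI name to the vocabulary. Matching is case-insensitive on
# trimmed names; unmapped names are kept verbatim with a warning.
mapStructureName <- function(raw, aliases) {
    key <- tolower(trimws(raw))
    canon <- canonicalNames()
    if (raw %in% canon) return(raw)
    hit <- match(key, tolower(trimws(aliases$raw_name)))
    if (!is.na(hit)) return(aliases$canonical_name[hit])
    hit2 <- match(key, tolower(canon))
    if (!is.na(hit2)) return(canon[hit2])
    warning("structure name '", raw,
            "' not in vocabulary or alias table; kept verbatim", call. = FALSE)
    raw
}

#' Read a multi-observer contour set
#'
#' Ingests the package's portable JSON contour dialect:
#' \preformatted{
#' {"grid": {"origin": [x,y,z], "spacing": [dx,dy,dz], "size": [nx,ny,nz]},
#'  "observers": [{"id": "...", "structures": [
#'     {"name": "...", "contours": [
#'        {"z": mm, "role": "outer"|"hole", "vertices": [[x,y], ...]}]}]}]}
#' }
#' All lengths are millimetres. ROI names are mapped to the controlled
#' vocabulary through the alias table; unmapped names are preserved
#' verbatim with a warning. DICOM-RT STRUCT input is not supported by this
#' build; export to the JSON dialect first.
#'
#' @param path input file.
#' @param dialect `"json"` (the native dialect). `"dicom-rt"` raises an
#'   informative error.
#' @param aliases alias table data.frame, see [readAliasTable()].
#' @return An [ObserverCohort-class].
#' @seealso [writeContours()] for the inverse.
#' @export
readContours <- function(path, dialect = c("json", "dicom-rt"),
                         aliases = readAliasTable()) {
    dialect <- match.arg(dialect)
    if (dialect == "dicom-rt")
        stop("DICOM-RT STRUCT reading is not supported by this build; ",
             "convert to the JSON contour dialect")
    if (!file.exists(path)) stop("file not found: ", path)
    doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    if (is.null(doc$grid) || is.null(doc$observers))
        stop("parse error: top-level 'grid' and 'observers' required in ", path)
    g <- doc$grid
    grid <- imageGrid(origin = unlist(g$origin), spacing = unlist(g$spacing),
                      size = unlist(g$size))
    dels <- list()
    for (ob in doc$observers) {
        if (is.null(ob$id)) stop("parse error: observer without id")
        for (st in ob$structures) {
            if (is.null(st$name) || !nzchar(st$name))
                stop("parse error: unnamed structure for observer ", ob$id)
            name <- mapStructureName(st$name, aliases)
            contours <- lapply(st$contours, function(ct) {
                v <- do.call(rbind, lapply(ct$vertices, unlist))
                if (is.null(v) || nrow(v) < 3L)
                    stop("parse error: ROI '", st$name, "' (observer ",
                         ob$id, ") has a degenerate polygon at z = ",
                         ct$z, " mm (< 3 vertices)")
                role <- if (is.null(ct$role)) "outer" else ct$role
                planarContour(ct$z, v, role)
            })
            # validate slice matching up front so bad files fail at ingest
            for (ct in contours)
                sliceIndex(ct@z, grid, paste0("ROI '", st$name, "'"))
            dels[[length(dels) + 1L]] <-
                structureDelineation(ob$id, name, contours)
        }
    }
    obsIds <- vapply(doc$observers, function(o) as.character(o$id), character(1))
    observerCohort(grid, dels, observers = obsIds)
}

#' Write a cohort to the JSON contour dialect
#'
#' Round-trips with [readContours()]: every vertex is preserved to better
#' than 1e-6 mm and every label exactly.
#'
#' @param cohort an [ObserverCohort-class] (contour-based delineations only).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeContours <- function(cohort, path) {
    g <- cohort@grid
    obsList <- lapply(cohort@observers, function(oid) {
        dels <- Filter(function(d) d@observer == oid, cohort@delineations)
        list(id = oid, structures = lapply(dels, function(d) {
            if (is.null(d@contours) || length(d@contours) == 0L)
                stop("cannot serialize mask-based delineation '",
                     d@structure, "' to the contour dialect")
            list(name = d@structure, contours = lapply(d@contours, function(ct)
                list(z = ct@z, role = ct@role,
                     vertices = lapply(seq_len(nrow(ct@vertices)),
                                       function(i) ct@vertices[i, ]))))
        }))
    })
    doc <- list(grid = list(origin = g@origin, spacing = g@spacing,
                            size = g@size),
                observers = obsList)
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' Read a landmark definition file
#'
#' Landmarks are user-declared z positions (mm) of named anatomical
#' reference points, e.g. the floor of the sphenoid sinus (cranial PTV1
#' reference) and the sternoclavicular joints (caudal reference). Format:
#' JSON object `{"name": z_mm, ...}`.
#'
#' @param path JSON file.
#' @param grid optional [ImageGrid-class]; when given, landmarks outside
#'   the grid z extent are an error.
#' @return named numeric vector of z positions, mm.
#' @export
readLandmarks <- function(path, grid = NULL) {
    lm <- unlist(jsonlite::fromJSON(path))
    if (is.null(names(lm)) || any(!nzchar(names(lm))) || anyDuplicated(names(lm)))
        stop("landmark file must be a JSON object of unique name: z_mm pairs")
    if (!is.null(grid)) {
        zr <- range(sliceZ(grid)) + c(-0.5, 0.5) * grid@spacing[3]
        bad <- lm < zr[1] | lm > zr[2]
        if (any(bad))
            stop("landmark(s) outside grid z extent: ",
                 paste(names(lm)[bad], collapse = ", "))
    }
    lm
}
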