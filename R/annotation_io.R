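# LabelMe-style annotation JSON and flat measurement tables.
#
# Only the "shapes[].label/points/shape_type" subset of the LabelMe
# schema is consumed; "imageData" is ignored when present, since
# annotation coordinates, not pixels, drive all computation. The label
# vocabulary is the package's documented protocol:
#   polygons: acetabulum_L / acetabulum_R, femoral_head_L / femoral_head_R
#   points:   fhc_L / fhc_R (femoral head centers), rim_L / rim_R
#             (cranial effective acetabular rim)

POLY_LABELS <- c("acetabulum_L", "acetabulum_R",
                 "femoral_head_L", "femoral_head_R")
POINT_LABELS <- c("fhc_L", "fhc_R", "rim_L", "rim_R")

MEAS_REQUIRED <- c("dog_id", "side", "examiner", "session",
                   "aa_px2", "aaofh_px2", "hci")
MEAS_OPTIONAL <- c("norberg_deg", "fci_grade")

.side_of <- function(label) {
  if (grepl("_L$", label)) "left" else "right"
}

#' Read a LabelMe-style annotation file
#'
#' Parses one radiograph's annotation JSON and pairs the labeled shapes
#' into per-side [hip_annotation()] objects. Shapes with labels outside
#' the controlled vocabulary raise a warning and are skipped; a side
#' whose acetabulum or femoral head outline is missing raises an error
#' listing what is absent (it is never silently dropped).
#'
#' @param path path to a LabelMe-style JSON file.
#' @param dog_id subject identifier; defaults to the file's image
#'   identifier (or the file name) without extension.
#' @return list of `hip_annotation` objects, one per annotated side.
#' @export
read_annotation <- function(path, dog_id = NULL) {
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e)
                    abort_hci(sprintf("cannot parse %s: %s", path,
                                      conditionMessage(e)), "hci_io_error"))
  if (is.null(doc$shapes))
    abort_hci(sprintf("%s has no \"shapes\" array", path),
              "hci_invalid_annotation")
  if (is.null(dog_id)) {
    base <- doc$imagePath %||% basename(path)
    dog_id <- tools::file_path_sans_ext(basename(base))
  }
  flags <- doc$flags %||% list()

  polys <- list(); pts <- list()
  for (sh in doc$shapes) {
    lab <- sh$label %||% "<unlabeled>"
    p <- sh$points
    coords <- if (length(p))
      do.call(rbind, lapply(p, function(q) as.numeric(unlist(q))))
    else matrix(numeric(0), 0, 2)
    if (lab %in% POLY_LABELS) {
      if (nrow(coords) < 3L)
        abort_hci(sprintf("shape \"%s\" in %s has %d points; a polygon needs at least 3",
                          lab, basename(path), nrow(coords)),
                  "hci_invalid_annotation")
      polys[[lab]] <- coords
    } else if (lab %in% POINT_LABELS) {
      if (nrow(coords) != 1L)
        abort_hci(sprintf("point shape \"%s\" in %s must have exactly 1 point",
                          lab, basename(path)), "hci_invalid_annotation")
      pts[[lab]] <- as.numeric(coords[1L, ])
    } else {
      warn_hci(sprintf("skipping shape with unknown label \"%s\" in %s",
                       lab, basename(path)), "hci_unknown_label")
    }
  }

  out <- list()
  for (suffix in c("L", "R")) {
    side_labels <- paste0(c("acetabulum_", "femoral_head_", "fhc_", "rim_"),
                          suffix)
    present <- c(names(polys), names(pts))
    if (!any(side_labels %in% present)) next
    missing <- setdiff(side_labels[1:2], names(polys))
    if (length(missing))
      abort_hci(sprintf("side %s in %s is incomplete: missing %s",
                        suffix, basename(path),
                        paste(missing, collapse = ", ")),
                "hci_incomplete_side")
    out[[length(out) + 1L]] <- hip_annotation(
      dog_id = dog_id, side = .side_of(side_labels[1L]),
      acetabulum = polys[[side_labels[1L]]],
      femoral_head = polys[[side_labels[2L]]],
      femoral_head_center = pts[[side_labels[3L]]],
      cranial_rim = pts[[side_labels[4L]]],
      examiner = flags$examiner, session = flags$session,
      fci_grade = flags$fci_grade)
  }
  out
}

#' Write annotations as a LabelMe-style JSON file
#'
#' Inverse of [read_annotation()]: coordinates round-trip losslessly.
#' Examiner, session and FCI grade (taken from the first annotation)
#' are stored in the file's `flags` object, which standard LabelMe
#' tooling ignores.
#'
#' @param annotations list of [hip_annotation()] objects (at most one
#'   per side), or an empty list.
#' @param path output file path.
#' @param image_path image identifier recorded in the file.
#' @param image_width,image_height image dimensions in pixels.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(annotations, path, image_path = NULL,
                             image_width = 0L, image_height = 0L) {
  shapes <- list()
  add_shape <- function(label, coords, type) {
    pts <- lapply(seq_len(nrow(coords)),
                  function(i) as.numeric(coords[i, ]))
    shapes[[length(shapes) + 1L]] <<- list(
      label = label, points = pts, group_id = NULL,
      shape_type = type, flags = structure(list(), names = character(0)))
  }
  flags <- structure(list(), names = character(0))
  for (ann in annotations) {
    if (!inherits(ann, "hip_annotation"))
      abort_hci("annotations must be hip_annotation objects",
                "hci_invalid_annotation")
    sfx <- if (ann$side == "left") "L" else "R"
    add_shape(paste0("acetabulum_", sfx), ann$acetabulum, "polygon")
    add_shape(paste0("femoral_head_", sfx), ann$femoral_head, "polygon")
    if (!is.null(ann$femoral_head_center))
      add_shape(paste0("fhc_", sfx), rbind(ann$femoral_head_center), "point")
    if (!is.null(ann$cranial_rim))
      add_shape(paste0("rim_", sfx), rbind(ann$cranial_rim), "point")
  }
  if (length(annotations)) {
    a1 <- annotations[[1L]]
    if (!is.null(a1$examiner)) flags$examiner <- a1$examiner
    if (!is.null(a1$session)) flags$session <- a1$session
    if (!is.null(a1$fci_grade)) flags$fci_grade <- a1$fci_grade
  }
  if (is.null(image_path) && length(annotations))
    image_path <- paste0(annotations[[1L]]$dog_id, ".png")
  doc <- list(version = "4.5.13", flags = flags, shapes = shapes,
              imagePath = image_path %||% "", imageData = NULL,
              imageHeight = as.integer(image_height),
              imageWidth = as.integer(image_width))
  json <- jsonlite::toJSON(doc, digits = NA, auto_unbox = TRUE,
                           null = "null", pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}

.validate_measurements <- function(df, where = "measurements") {
  unknown <- setdiff(names(df), c(MEAS_REQUIRED, MEAS_OPTIONAL))
  if (length(unknown))
    abort_hci(sprintf("%s: unknown column(s) %s", where,
                      paste(unknown, collapse = ", ")), "hci_column_error")
  missing <- setdiff(MEAS_REQUIRED, names(df))
  if (length(missing))
    abort_hci(sprintf("%s: missing required column(s) %s", where,
                      paste(missing, collapse = ", ")), "hci_column_error")
  for (col in c("aa_px2", "aaofh_px2", "hci", "norberg_deg")) {
    if (!col %in% names(df)) next
    v <- df[[col]]
    if (is.character(v)) v[v %in% c("", "NA")] <- NA
    vn <- suppressWarnings(as.numeric(v))
    if (any(is.na(vn) & !is.na(v)))
      abort_hci(sprintf("%s: non-numeric value in column %s", where, col),
                "hci_invalid_measurement")
    df[[col]] <- vn
  }
  bad <- !is.na(df$hci) & (df$hci < 0 | df$hci > 1)
  if (any(bad))
    abort_hci(sprintf("%s: hci outside [0, 1] in row(s) %s", where,
                      paste(which(bad), collapse = ", ")),
              "hci_invalid_measurement")
  if ("fci_grade" %in% names(df)) {
    g <- df$fci_grade
    bad <- !is.na(g) & g != "" & !g %in% FCI_GRADES
    if (any(bad))
      abort_hci(sprintf("%s: fci_grade outside A-E in row(s) %s", where,
                        paste(which(bad), collapse = ", ")),
                "hci_invalid_measurement")
  } else df$fci_grade <- NA_character_
  if (!"norberg_deg" %in% names(df)) df$norberg_deg <- NA_real_
  df[, c(MEAS_REQUIRED, MEAS_OPTIONAL)]
}

#' Read and write per-hip measurement tables
#'
#' Header-first CSV with one row per hip and columns `dog_id`, `side`,
#' `examiner`, `session`, `aa_px2`, `aaofh_px2`, `hci`, `norberg_deg`,
#' `fci_grade` (the last two optional on read). Numeric fields are
#' serialized at full precision (17 significant digits), so a
#' write/read cycle reproduces the values exactly.
#'
#' @param records data frame of measurement records.
#' @param path CSV file path.
#' @return `read_measurements()` returns the validated data frame;
#'   `write_measurements()` returns `path` invisibly.
#' @export
write_measurements <- function(records, path) {
  df <- .validate_measurements(as.data.frame(records))
  out <- df
  for (col in c("aa_px2", "aaofh_px2", "hci", "norberg_deg"))
    out[[col]] <- ifelse(is.na(df[[col]]), "",
                         sprintf("%.17g", df[[col]]))
  out$fci_grade <- ifelse(is.na(df$fci_grade), "", df$fci_grade)
  utils::write.table(out, path, sep = ",", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_measurements
#' @export
read_measurements <- function(path) {
  if (!file.exists(path))
    abort_hci(sprintf("no such file: %s", path), "hci_io_error")
  df <- utils::read.csv(path, colClasses = "character",
                        check.names = FALSE)
  df <- .validate_measurements(df, where = basename(path))
  df$fci_grade[df$fci_grade == ""] <- NA_character_
  df
}
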