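# The two measurement constructs: Hip Congruency Index and Norberg
# angle, plus the per-hip annotation container they operate on.

FCI_GRADES <- c("A", "B", "C", "D", "E")

#' Per-hip annotation container
#'
#' Bundles one hip's acetabular and femoral-head outlines with optional
#' point landmarks and identity metadata.
#'
#' @param dog_id subject identifier.
#' @param side `"left"` or `"right"`.
#' @param acetabulum polygon outlining the projected acetabular
#'   coverage area (the margo acetabuli outline).
#' @param femoral_head polygon outlining the proximal femur.
#' @param femoral_head_center optional (x, y) landmark: center of the
#'   femoral head.
#' @param cranial_rim optional (x, y) landmark: cranial effective
#'   acetabular rim.
#' @param examiner,session optional identifiers for reliability
#'   studies.
#' @param fci_grade optional FCI screening grade, one of `"A"`--`"E"`.
#' @return object of class `hip_annotation`.
#' @export
hip_annotation <- function(dog_id, side, acetabulum, femoral_head,
                           femoral_head_center = NULL, cranial_rim = NULL,
                           examiner = NULL, session = NULL,
                           fci_grade = NULL) {
  side <- as.character(side)
  if (length(side) != 1L || !side %in% c("left", "right"))
    abort_hci("side must be \"left\" or \"right\"", "hci_invalid_annotation")
  if (!is.null(fci_grade)) {
    fci_grade <- as.character(fci_grade)
    if (length(fci_grade) != 1L || !fci_grade %in% FCI_GRADES)
      abort_hci("fci_grade must be one of A, B, C, D, E",
                "hci_invalid_annotation")
  }
  check_pt <- function(p, what) {
    if (is.null(p)) return(NULL)
    p <- as.numeric(p)
    if (length(p) != 2L || !all(is.finite(p)))
      abort_hci(sprintf("%s must be a finite (x, y) pair", what),
                "hci_invalid_annotation")
    p
  }
  structure(
    list(dog_id = as.character(dog_id), side = side,
         acetabulum = as_polygon(acetabulum, "acetabulum"),
         femoral_head = as_polygon(femoral_head, "femoral_head"),
         femoral_head_center = check_pt(femoral_head_center,
                                        "femoral_head_center"),
         cranial_rim = check_pt(cranial_rim, "cranial_rim"),
         examiner = if (is.null(examiner)) NULL else as.character(examiner),
         session = if (is.null(session)) NULL else as.character(session),
         fci_grade = fci_grade),
    class = "hip_annotation")
}

#' @export
print.hip_annotation <- function(x, ...) {
  cat(sprintf("<hip_annotation> dog %s, %s hip\n", x$dog_id, x$side))
  cat(sprintf("  acetabulum: %d vertices; femoral head: %d vertices\n",
              nrow(x$acetabulum), nrow(x$femoral_head)))
  if (!is.null(x$fci_grade)) cat("  FCI grade:", x$fci_grade, "\n")
  if (!is.null(x$examiner) || !is.null(x$session))
    cat(sprintf("  examiner %s, session %s\n",
                x$examiner %||% "-", x$session %||% "-"))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Hip Congruency Index from two annotation polygons
#'
#' HCI is the fraction of the projected acetabular coverage area (AA)
#' occupied by the femoral head: the overlap area AAOFH divided by AA.
#' Because the femoral-head outline always extends beyond the
#' acetabular outline on a ventrodorsal hip-extended view, only the
#' overlap counts; no containment is assumed. Being a ratio of two
#' areas measured on the same projection, HCI is invariant to image
#' magnification and rigid motion.
#'
#' @param acetabulum,femoral_head polygons (see [as_polygon()]).
#' @return object of class `hci_measurement` with fields `aa`, `aaofh`
#'   (square pixels) and `hci` (dimensionless in \[0, 1\]).
#' @export
compute_hci <- function(acetabulum, femoral_head) {
  acetabulum <- as_polygon(acetabulum, "acetabulum")
  femoral_head <- as_polygon(femoral_head, "femoral_head")
  aa <- abs(signed_area(acetabulum))
  if (aa <= 0)
    abort_hci("acetabulum polygon has zero area", "hci_degenerate_annotation")
  aaofh <- intersection_area(acetabulum, femoral_head)
  aaofh <- min(aaofh, aa)               # clip float overshoot
  structure(list(aa = aa, aaofh = aaofh, hci = aaofh / aa),
            class = "hci_measurement")
}

#' @export
print.hci_measurement <- function(x, ...) {
  cat(sprintf("HCI = %.4f  (AA = %.1f px^2, AAOFH = %.1f px^2)\n",
              x$hci, x$aa, x$aaofh))
  invisible(x)
}

#' Norberg angle from point landmarks
#'
#' The Norberg angle is measured at the femoral head center, between
#' the ray toward the contralateral femoral head center and the ray
#' toward the cranial effective acetabular rim. Values around 105
#' degrees or more are conventionally associated with normal hips; the
#' angle is returned as an unsigned magnitude in \[0, 180\].
#'
#' @param own_center (x, y) center of the femoral head being measured.
#' @param contralateral_center (x, y) center of the opposite femoral
#'   head.
#' @param cranial_rim (x, y) cranial effective acetabular rim landmark.
#' @return angle in degrees, in \[0, 180\].
#' @export
norberg_angle <- function(own_center, contralateral_center, cranial_rim) {
  u <- as.numeric(contralateral_center) - as.numeric(own_center)
  v <- as.numeric(cranial_rim) - as.numeric(own_center)
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (!is.finite(nu) || !is.finite(nv) || nu == 0 || nv == 0)
    abort_hci("landmark points must be distinct from the femoral head center",
              "hci_degenerate_landmark")
  cosang <- sum(u * v) / (nu * nv)
  acos(min(1, max(-1, cosang))) * 180 / pi
}

#' Measure one annotated hip
#'
#' Per-hip driver combining both metrics: the HCI is always computed;
#' the Norberg angle only when the annotation carries both landmarks
#' and the caller supplies the contralateral femoral head center
#' (obtained by pairing the left and right annotations of a dog).
#'
#' @param annotation a [hip_annotation()].
#' @param contralateral_center optional (x, y) center of the opposite
#'   femoral head.
#' @return list with elements `hci` (an `hci_measurement`) and
#'   `norberg` (degrees, or `NULL` when landmarks are unavailable).
#' @export
measure_hip <- function(annotation, contralateral_center = NULL) {
  if (!inherits(annotation, "hip_annotation"))
    abort_hci("annotation must be a hip_annotation object",
              "hci_invalid_annotation")
  hci <- compute_hci(annotation$acetabulum, annotation$femoral_head)
  na <- NULL
  if (!is.null(annotation$femoral_head_center) &&
      !is.null(annotation$cranial_rim) &&
      !is.null(contralateral_center)) {
    na <- norberg_angle(annotation$femoral_head_center,
                        contralateral_center, annotation$cranial_rim)
  }
  list(hci = hci, norberg = na)
}
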