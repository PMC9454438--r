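# Synthetic hip cohorts with known ground-truth HCI.
#
# The generative model is deliberately minimal: the acetabular coverage
# region is a "cup" (disc of radius R cut by a half-plane chord whose
# position is set by an opening half-angle), and the femoral head is a
# disc of radius r displaced laterally by d from the acetabular center.
# Lateral displacement is the only subluxation axis, which matches the
# projection argument for the ventrodorsal hip-extended view: the
# relevant structures lie approximately in one anatomical plane, and
# increasing subluxation monotonically increases acetabular free space
# (and so decreases HCI). Ground truth is computed by the brute-force
# grid oracle, never by the polygon-clipping path under test.

#' Shape parameters of one synthetic hip
#'
#' @param acetabular_radius radius R of the acetabular cup, pixels.
#' @param femoral_radius radius r of the femoral head, pixels; must be
#'   smaller than `acetabular_radius`.
#' @param displacement lateral subluxation d of the femoral head
#'   center, pixels, non-negative.
#' @param opening_halfangle half-angle of the cup opening in degrees,
#'   in (0, 90]. 90 gives a half-disc cup; smaller values close the
#'   cup around the head.
#' @param n_vertices polygon discretization, at least 64 vertices per
#'   outline.
#' @param pixel_scale global magnification applied to all coordinates.
#' @return validated parameter list of class `hip_shape_params`.
#' @export
hip_shape_params <- function(acetabular_radius = 100,
                             femoral_radius = 90,
                             displacement = 0,
                             opening_halfangle = 70,
                             n_vertices = 128,
                             pixel_scale = 1) {
  chk <- function(cond, msg) if (!cond) abort_hci(msg, "hci_parameter_error")
  chk(is.finite(acetabular_radius) && acetabular_radius > 0,
      "acetabular_radius must be positive")
  chk(is.finite(femoral_radius) && femoral_radius > 0 &&
        femoral_radius < acetabular_radius,
      "femoral_radius must be positive and smaller than acetabular_radius")
  chk(is.finite(displacement) && displacement >= 0,
      "displacement must be non-negative")
  chk(is.finite(opening_halfangle) && opening_halfangle > 0 &&
        opening_halfangle <= 90,
      "opening_halfangle must be in (0, 90] degrees")
  chk(is.finite(n_vertices) && n_vertices >= 64,
      "n_vertices must be at least 64")
  chk(is.finite(pixel_scale) && pixel_scale > 0,
      "pixel_scale must be positive")
  structure(list(acetabular_radius = acetabular_radius,
                 femoral_radius = femoral_radius,
                 displacement = displacement,
                 opening_halfangle = opening_halfangle,
                 n_vertices = as.integer(n_vertices),
                 pixel_scale = pixel_scale),
            class = "hip_shape_params")
}

# cup area: disc of radius R minus the circular segment beyond the
# chord at signed distance R*cos(theta) from the center
.cup_area <- function(R, theta) R^2 * (pi - theta + sin(theta) * cos(theta))

#' Generate one synthetic hip with known ground truth
#'
#' Builds the acetabular cup and femoral head polygons for the given
#' shape parameters, emits landmarks (femoral head center and the
#' cranial chord endpoint of the cup as the effective rim), and
#' computes the true HCI with the grid oracle at the requested
#' resolution.
#'
#' @param params a [hip_shape_params()] object.
#' @param center (x, y) acetabular center in image coordinates
#'   (before `pixel_scale`).
#' @param side `"left"` or `"right"`; lateral displacement points away
#'   from the midline (+x for left hips, -x for right hips in image
#'   coordinates).
#' @param dog_id,fci_grade identity metadata passed through to the
#'   annotation.
#' @param truth_resolution grid-oracle resolution for the ground-truth
#'   HCI, at least 2000 cells per axis.
#' @return list with elements `annotation` (a [hip_annotation()]) and
#'   `truth` (list with `true_hci` and `true_displacement` in pixels).
#' @export
make_hip <- function(params, center = c(0, 0), side = "left",
                     dog_id = "synthetic", fci_grade = NULL,
                     truth_resolution = 2000) {
  if (!inherits(params, "hip_shape_params"))
    params <- do.call(hip_shape_params, as.list(params))
  if (truth_resolution < 2000)
    abort_hci("truth_resolution must be at least 2000", "hci_parameter_error")
  geo <- .hip_polygons(params, center, side)

  s <- geo$s
  sc <- params$pixel_scale
  R <- params$acetabular_radius
  th <- params$opening_halfangle * pi / 180
  d <- params$displacement
  cup_region <- function(x, y) {
    lx <- s * (x / sc - center[1L]); ly <- y / sc - center[2L]
    (lx^2 + ly^2 <= R^2) & (lx <= R * cos(th))
  }
  head_region <- disc_region(geo$head_center, params$femoral_radius * sc)
  pad <- 1.05 * (R + params$femoral_radius + d) * sc
  bbox <- c(center[1L] * sc - pad, center[1L] * sc + pad,
            center[2L] * sc - pad, center[2L] * sc + pad)
  overlap <- grid_overlap_oracle(cup_region, head_region, bbox,
                                 truth_resolution)
  true_hci <- min(1, as.numeric(overlap) / (.cup_area(R, th) * sc^2))

  ann <- hip_annotation(dog_id = dog_id, side = side,
                        acetabulum = geo$cup, femoral_head = geo$head,
                        femoral_head_center = geo$head_center,
                        cranial_rim = geo$rim, fci_grade = fci_grade)
  list(annotation = ann,
       truth = list(true_hci = true_hci, true_displacement = d * sc))
}

# Bare polygon construction for one hip (no ground truth): cup outline
# is the major arc from theta to 2*pi - theta in the lateral-signed
# frame, closed by the chord; the head is a regular n-gon disc.
.hip_polygons <- function(params, center = c(0, 0), side = "left") {
  s <- if (identical(side, "left")) 1 else -1
  sc <- params$pixel_scale
  R <- params$acetabular_radius
  r <- params$femoral_radius
  d <- params$displacement
  th <- params$opening_halfangle * pi / 180
  n <- params$n_vertices
  phi <- seq(th, 2 * pi - th, length.out = n)
  cup <- cbind(x = center[1L] + s * R * cos(phi),
               y = center[2L] + R * sin(phi)) * sc
  head_c <- c(center[1L] + s * d, center[2L])
  head <- .regular_polygon(head_c, r, n) * sc
  rim <- c(center[1L] + s * R * cos(th), center[2L] - R * sin(th)) * sc
  list(cup = cup, head = head, head_center = head_c * sc, rim = rim, s = s)
}

#' Perturb polygon vertices with examiner noise
#'
#' Adds independent isotropic Gaussian noise to every vertex, emulating
#' the per-vertex placement variability of a human examiner re-drawing
#' an outline. If the jittered polygon self-intersects, the draw is
#' repeated (up to 100 times) before failing.
#'
#' @param p polygon (see [as_polygon()]).
#' @param sd noise standard deviation per coordinate, pixels.
#' @return jittered, validated vertex matrix. Uses the current R
#'   random-number stream.
#' @export
jitter_polygon <- function(p, sd) {
  m <- as_polygon(p)
  if (length(sd) != 1L || !is.finite(sd) || sd < 0)
    abort_hci("sd must be a single non-negative number", "hci_parameter_error")
  if (sd == 0) return(m)
  for (k in seq_len(100L)) {
    j <- m + matrix(stats::rnorm(length(m), 0, sd), ncol = 2L)
    j <- snap_coords(j)
    if (cpp_is_simple(j[, 1L], j[, 2L])) {
      colnames(j) <- c("x", "y")
      return(j)
    }
  }
  abort_hci("jittered polygon still self-intersects after 100 redraws",
            "hci_generation_error")
}

#' Cohort design for the synthetic study
#'
#' Default displacement distributions (as a fraction of the acetabular
#' radius) increase monotonically across the five FCI-like grades, so
#' that simulated grade mean HCIs are ordered A > B > C > D > E. The
#' defaults are configuration, not constants.
#'
#' @param dogs_per_grade named integer vector, dogs per grade A-E; each
#'   dog contributes a left and a right hip of that grade.
#' @param grade_displacement_mean named numeric vector, mean d/R per
#'   grade.
#' @param grade_displacement_sd standard deviation of d/R (common to
#'   all grades); draws are truncated at 0.
#' @param jitter_sd examiner noise SD in pixels (per vertex, per
#'   replicate).
#' @param n_examiners,n_sessions replication design; every hip is
#'   annotated once per examiner-session combination.
#' @param seed integer seed for the cohort's random stream.
#' @param shape base [hip_shape_params()] shared by all hips (its
#'   `displacement` field is overridden per hip).
#' @return validated specification of class `cohort_spec`.
#' @export
cohort_spec <- function(dogs_per_grade = c(A = 60, B = 78, C = 34,
                                           D = 19, E = 9),
                        grade_displacement_mean = c(A = 0.05, B = 0.15,
                                                    C = 0.25, D = 0.40,
                                                    E = 0.60),
                        grade_displacement_sd = 0.05,
                        jitter_sd = 1,
                        n_examiners = 2L,
                        n_sessions = 2L,
                        seed = 1L,
                        shape = hip_shape_params()) {
  chk <- function(cond, msg) if (!cond) abort_hci(msg, "hci_parameter_error")
  chk(all(FCI_GRADES %in% names(dogs_per_grade)),
      "dogs_per_grade must be named with grades A-E")
  chk(all(dogs_per_grade >= 0), "dogs_per_grade must be non-negative")
  chk(all(FCI_GRADES %in% names(grade_displacement_mean)),
      "grade_displacement_mean must be named with grades A-E")
  chk(grade_displacement_sd >= 0, "grade_displacement_sd must be >= 0")
  chk(jitter_sd >= 0, "jitter_sd must be >= 0")
  chk(n_examiners >= 1 && n_sessions >= 1,
      "need at least one examiner and one session")
  if (!inherits(shape, "hip_shape_params"))
    shape <- do.call(hip_shape_params, as.list(shape))
  structure(list(dogs_per_grade = dogs_per_grade[FCI_GRADES],
                 grade_displacement_mean = grade_displacement_mean[FCI_GRADES],
                 grade_displacement_sd = grade_displacement_sd,
                 jitter_sd = jitter_sd,
                 n_examiners = as.integer(n_examiners),
                 n_sessions = as.integer(n_sessions),
                 seed = as.integer(seed),
                 shape = shape),
            class = "cohort_spec")
}

#' Generate a synthetic cohort
#'
#' Draws per-hip displacements from the grade distributions, builds
#' both hips of every dog, and replicates each annotation across
#' examiners and sessions with independent per-vertex jitter. A single
#' global stream keyed by `spec$seed` derives one sub-seed per dog, so
#' the cohort is reproducible (also under partial regeneration).
#'
#' @param spec a [cohort_spec()].
#' @param truth_resolution grid-oracle resolution for ground truth.
#' @return list of class `hip_cohort` with elements `truth` (data
#'   frame: dog_id, side, fci_grade, true_displacement, true_hci) and
#'   `annotations` (list of [hip_annotation()], one per hip x examiner
#'   x session).
#' @export
make_cohort <- function(spec = cohort_spec(), truth_resolution = 2000) {
  if (!inherits(spec, "cohort_spec"))
    abort_hci("spec must be a cohort_spec", "hci_parameter_error")
  shape <- spec$shape
  R <- shape$acetabular_radius
  grades <- rep(FCI_GRADES, times = spec$dogs_per_grade)
  n_dogs <- length(grades)
  set.seed(spec$seed)
  dog_seeds <- sample.int(.Machine$integer.max - 1L, n_dogs)

  centers <- list(right = c(750, 600), left = c(1250, 600))
  truth <- vector("list", 2L * n_dogs)
  anns <- list()
  dmax <- (R + shape$femoral_radius) / R

  for (i in seq_len(n_dogs)) {
    set.seed(dog_seeds[i])
    g <- grades[i]
    dog_id <- sprintf("dog%03d", i)
    for (side in c("right", "left")) {
      frac <- stats::rnorm(1, spec$grade_displacement_mean[[g]],
                           spec$grade_displacement_sd)
      frac <- min(max(frac, 0), dmax)
      p <- shape
      p$displacement <- frac * R
      hip <- make_hip(p, center = centers[[side]], side = side,
                      dog_id = dog_id, fci_grade = g,
                      truth_resolution = truth_resolution)
      truth[[2L * (i - 1L) + (side == "left") + 1L]] <-
        data.frame(dog_id = dog_id, side = side, fci_grade = g,
                   true_displacement = hip$truth$true_displacement,
                   true_hci = hip$truth$true_hci)
      base <- hip$annotation
      for (e in seq_len(spec$n_examiners)) {
        for (s in seq_len(spec$n_sessions)) {
          a <- base
          a$examiner <- paste0("E", e)
          a$session <- paste0("S", s)
          if (spec$jitter_sd > 0) {
            a$acetabulum <- jitter_polygon(base$acetabulum, spec$jitter_sd)
            a$femoral_head <- jitter_polygon(base$femoral_head, spec$jitter_sd)
            a$femoral_head_center <- base$femoral_head_center +
              stats::rnorm(2, 0, spec$jitter_sd)
            a$cranial_rim <- base$cranial_rim +
              stats::rnorm(2, 0, spec$jitter_sd)
          }
          anns[[length(anns) + 1L]] <- a
        }
      }
    }
  }
  structure(list(truth = do.call(rbind, truth), annotations = anns,
                 spec = spec),
            class = "hip_cohort")
}

#' Measure a set of hip annotations
#'
#' Computes HCI for every annotation and the Norberg angle for every
#' annotation whose contralateral femoral head center is available in
#' the same dog / examiner / session group.
#'
#' @param annotations list of [hip_annotation()] objects.
#' @return measurement-record data frame (see [write_measurements()]).
#' @export
measure_annotations <- function(annotations) {
  n <- length(annotations)
  rows <- vector("list", n)
  key <- vapply(annotations, function(a)
    paste(a$dog_id, a$examiner %||% "", a$session %||% "", sep = "\r"),
    character(1))
  sides <- vapply(annotations, `[[`, character(1), "side")
  for (i in seq_len(n)) {
    a <- annotations[[i]]
    mate <- which(key == key[i] & sides != sides[i])
    contra <- if (length(mate) == 1L)
      annotations[[mate]]$femoral_head_center else NULL
    m <- measure_hip(a, contralateral_center = contra)
    rows[[i]] <- data.frame(
      dog_id = a$dog_id, side = a$side,
      examiner = a$examiner %||% NA_character_,
      session = a$session %||% NA_character_,
      aa_px2 = m$hci$aa, aaofh_px2 = m$hci$aaofh, hci = m$hci$hci,
      norberg_deg = m$norberg %||% NA_real_,
      fci_grade = a$fci_grade %||% NA_character_)
  }
  do.call(rbind, rows)
}

#' Write a synthetic cohort to disk
#'
#' Emits one LabelMe-style JSON per dog / examiner / session plus a
#' `ground_truth.csv` (dog_id, side, fci_grade, true_displacement,
#' true_hci).
#'
#' @param cohort a [make_cohort()] result.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!inherits(cohort, "hip_cohort"))
    abort_hci("cohort must be a hip_cohort", "hci_parameter_error")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  key <- vapply(cohort$annotations, function(a)
    paste(a$dog_id, a$examiner %||% "E1", a$session %||% "S1", sep = "_"),
    character(1))
  for (k in unique(key)) {
    write_annotation(cohort$annotations[key == k],
                     file.path(dir, paste0(k, ".json")),
                     image_path = paste0(k, ".png"),
                     image_width = 2000L, image_height = 1200L)
  }
  tr <- cohort$truth
  tr$true_displacement <- sprintf("%.17g", tr$true_displacement)
  tr$true_hci <- sprintf("%.17g", tr$true_hci)
  utils::write.table(tr, file.path(dir, "ground_truth.csv"), sep = ",",
                     row.names = FALSE, quote = FALSE)
  invisible(dir)
}
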