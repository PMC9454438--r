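# LabelMe-dialect JSON and measurement-table round trips.

make_two_sided_dog <- function(dog_id = "dogA", jitter = 0) {
  params <- hip_shape_params(100, 90, 12, 70, 64)
  list(
    make_hip(params, center = c(750, 600), side = "right",
             dog_id = dog_id, fci_grade = "B")$annotation,
    make_hip(params, center = c(1250, 600), side = "left",
             dog_id = dog_id, fci_grade = "B")$annotation)
}

test_that("annotation JSON round-trips losslessly", {
  anns <- make_two_sided_dog()
  f <- withr::local_tempfile(fileext = ".json")
  write_annotation(anns, f, image_width = 2000, image_height = 1200)
  back <- read_annotation(f)
  expect_length(back, 2L)
  back_sides <- vapply(back, `[[`, character(1), "side")
  for (i in 1:2) {
    j <- which(back_sides == anns[[i]]$side)
    expect_length(j, 1L)
    expect_equal(back[[j]]$acetabulum, anns[[i]]$acetabulum)
    expect_equal(back[[j]]$femoral_head, anns[[i]]$femoral_head)
    expect_equal(back[[j]]$femoral_head_center, anns[[i]]$femoral_head_center)
    expect_equal(back[[j]]$cranial_rim, anns[[i]]$cranial_rim)
    expect_identical(back[[j]]$fci_grade, "B")
  }
})

test_that("minimal one-sided file, empty file, and label handling", {
  f <- withr::local_tempfile(fileext = ".json")
  ann <- hip_annotation("d", "right",
                        acetabulum = unit_square(0, 0, 100),
                        femoral_head = unit_square(50, 50, 100))
  write_annotation(list(ann), f)
  back <- read_annotation(f)
  expect_length(back, 1L)
  expect_identical(back[[1]]$side, "right")
  expect_null(back[[1]]$femoral_head_center)

  # empty annotation list -> file with empty shapes array
  write_annotation(list(), f)
  doc <- jsonlite::fromJSON(f, simplifyVector = FALSE)
  expect_length(doc$shapes, 0L)
  expect_length(read_annotation(f), 0L)

  # unknown label: warning + skip, known shapes still read
  doc <- list(version = "4.5.13", flags = structure(list(), names = character(0)),
              shapes = list(
                list(label = "femur_shaft", points = list(c(0, 0), c(1, 1), c(2, 0)),
                     shape_type = "polygon"),
                list(label = "acetabulum_R",
                     points = list(c(0, 0), c(100, 0), c(100, 100), c(0, 100)),
                     shape_type = "polygon"),
                list(label = "femoral_head_R",
                     points = list(c(50, 50), c(150, 50), c(150, 150), c(50, 150)),
                     shape_type = "polygon")),
              imagePath = "x.png", imageHeight = 200, imageWidth = 200)
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA), f)
  expect_warning(back <- read_annotation(f), class = "hci_unknown_label")
  expect_length(back, 1L)
})

test_that("reader error contracts: short polygons and incomplete sides", {
  f <- withr::local_tempfile(fileext = ".json")
  doc <- list(shapes = list(
    list(label = "femoral_head_L", points = list(c(0, 0), c(1, 1)),
         shape_type = "polygon")))
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA), f)
  err <- tryCatch(read_annotation(f), error = function(e) e)
  expect_s3_class(err, "hci_invalid_annotation")
  expect_match(conditionMessage(err), "femoral_head_L")

  # side present but missing its femoral head
  doc <- list(shapes = list(
    list(label = "acetabulum_L",
         points = list(c(0, 0), c(10, 0), c(10, 10)), shape_type = "polygon")))
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA), f)
  err <- tryCatch(read_annotation(f), error = function(e) e)
  expect_s3_class(err, "hci_incomplete_side")
  expect_match(conditionMessage(err), "femoral_head_L")
})

test_that("reader is insensitive to shape order", {
  anns <- make_two_sided_dog()
  f <- withr::local_tempfile(fileext = ".json")
  write_annotation(anns, f)
  doc <- jsonlite::fromJSON(f, simplifyVector = FALSE)
  set.seed(3)
  doc$shapes <- doc$shapes[sample(length(doc$shapes))]
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                              null = "null"), f)
  back <- read_annotation(f)
  sides <- vapply(back, `[[`, character(1), "side")
  for (i in 1:2) {
    j <- which(sides == anns[[i]]$side)
    expect_equal(back[[j]]$acetabulum, anns[[i]]$acetabulum)
  }
})

test_that("round-trip law holds across many randomized files", {
  set.seed(29)
  f <- withr::local_tempfile(fileext = ".json")
  for (rep in 1:100) {
    side <- sample(c("left", "right"), 1)
    g <- random_hip_polygons()
    ann <- hip_annotation(sprintf("dog%02d", rep), side,
                          acetabulum = g$cup, femoral_head = g$head,
                          femoral_head_center =
                            if (runif(1) < 0.5) g$head_center else NULL,
                          cranial_rim = if (runif(1) < 0.5) g$rim else NULL,
                          examiner = sample(c("E1", "E2"), 1),
                          session = sample(c("S1", "S2"), 1))
    write_annotation(list(ann), f)
    back <- read_annotation(f)
    expect_length(back, 1L)
    expect_equal(back[[1]]$acetabulum, ann$acetabulum)
    expect_equal(back[[1]]$femoral_head, ann$femoral_head)
    expect_identical(back[[1]]$examiner, ann$examiner)
    expect_identical(back[[1]]$session, ann$session)
  }
})

test_that("measurement CSV round-trips and enforces its schema", {
  rec <- data.frame(dog_id = c("d1", "d1", "d2"),
                    side = c("left", "right", "left"),
                    examiner = "E1", session = "S1",
                    aa_px2 = c(31415.92653589793, 28000.1, 30000),
                    aaofh_px2 = c(25000.123456789, 21000, 2.5e4),
                    hci = c(0.7957747154594767, 0.75, 5 / 6),
                    norberg_deg = c(105.123456789, NA, 95),
                    fci_grade = c("A", "A", NA))
  f <- withr::local_tempfile(fileext = ".csv")
  write_measurements(rec, f)
  back <- read_measurements(f)
  expect_identical(back$hci, rec$hci)          # bit-exact numeric round trip
  expect_identical(back$aa_px2, rec$aa_px2)
  expect_identical(back$norberg_deg, rec$norberg_deg)
  expect_identical(back$fci_grade, rec$fci_grade)

  # grade column absent -> NA grades
  rec2 <- rec[, setdiff(names(rec), c("fci_grade", "norberg_deg"))]
  write_measurements(rec2, f)
  back2 <- read_measurements(f)
  expect_true(all(is.na(back2$fci_grade)))

  # invariant enforcement and column contracts
  bad <- rec; bad$hci[2] <- 1.2
  expect_error(write_measurements(bad, f), class = "hci_invalid_measurement")
  unk <- rec; unk$extra <- 1
  expect_error(write_measurements(unk, f), class = "hci_column_error")
  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines("dog_id,side,examiner\nd1,left,E1", f2)
  expect_error(read_measurements(f2), class = "hci_column_error")
  f3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(paste0("dog_id,side,examiner,session,aa_px2,aaofh_px2,hci\n",
                    "d1,left,E1,S1,100,90,1.4"), f3)
  expect_error(read_measurements(f3), class = "hci_invalid_measurement")
})
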