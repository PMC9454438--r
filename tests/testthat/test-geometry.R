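# Polygon kernel: shoelace area, simple-polygon intersection, circle
# discretizer, and the analytic/grid oracles it is checked against.

test_that("polygon_area matches closed forms and is representation-invariant", {
  sq <- unit_square()
  expect_equal(polygon_area(sq), 1)
  expect_equal(polygon_area(rbind(c(0, 0), c(4, 0), c(0, 3))), 6)

  # regular n-gon closed form: n/2 * R^2 * sin(2*pi/n)
  n <- 1024; R <- 100
  # 1e-7 coordinate snapping bounds the achievable agreement (~1e-10)
  expect_equal(polygon_area(circle_polygon(c(-37, 12), R, n)),
               0.5 * n * R^2 * sin(2 * pi / n), tolerance = 1e-9)

  set.seed(11)
  for (rep in 1:20) {
    p <- star_polygon(sample(5:40, 1), 500, 700, 100, 300)
    a0 <- polygon_area(p)
    rot <- sample(nrow(p), 1)
    p_rot <- p[c(rot:nrow(p), seq_len(rot - 1)), ]
    expect_equal(polygon_area(p_rot), a0, tolerance = 1e-12)
    expect_equal(polygon_area(p[rev(seq_len(nrow(p))), ]), a0,
                 tolerance = 1e-12)
    s <- runif(1, 0.2, 25)
    expect_equal(polygon_area(p * s), s^2 * a0, tolerance = 1e-9)
  }
})

test_that("invalid polygons are rejected, not repaired", {
  expect_error(polygon_area(rbind(c(0, 0), c(1, 0))),
               class = "hci_invalid_polygon")
  expect_error(polygon_area(rbind(c(0, 0), c(1, NA), c(1, 1))),
               class = "hci_invalid_polygon")
  expect_error(polygon_area(rbind(c(0, 0), c(0, 0), c(1, 1), c(0, 1))),
               class = "hci_invalid_polygon")
  bowtie <- rbind(c(0, 0), c(1, 1), c(1, 0), c(0, 1))
  expect_error(polygon_area(bowtie), class = "hci_invalid_polygon")
  expect_error(intersection_area(bowtie, unit_square()),
               class = "hci_invalid_polygon")
})

test_that("polygon_intersection handles overlap, disjoint and lens cases", {
  a <- unit_square()
  pieces <- polygon_intersection(a, unit_square(0.5, 0.5))
  expect_length(pieces, 1L)
  expect_equal(abs(hcindex:::signed_area(pieces[[1]])), 0.25,
               tolerance = 1e-7)

  expect_length(polygon_intersection(a, unit_square(5, 5)), 0L)

  # 2048-gon circles, centers 1 apart: lens area 2*acos(1/2) - sqrt(3)/2
  lens <- 2 * acos(0.5) - sqrt(3) / 2
  pieces <- polygon_intersection(circle_polygon(c(0, 0), 1, 2048),
                                 circle_polygon(c(1, 0), 1, 2048))
  expect_length(pieces, 1L)
  expect_equal(abs(hcindex:::signed_area(pieces[[1]])), lens,
               tolerance = 1e-4)

  # deterministic output for identical inputs
  p1 <- polygon_intersection(a, unit_square(0.25, -0.25))
  p2 <- polygon_intersection(a, unit_square(0.25, -0.25))
  expect_identical(p1, p2)
})

test_that("intersection_area identities: self, disjoint, half overlap", {
  set.seed(21)
  p <- star_polygon(17, 300, 300, 50, 150)
  expect_equal(intersection_area(p, p), polygon_area(p),
               tolerance = 1e-7)
  expect_equal(intersection_area(unit_square(), unit_square(3, 0)), 0)
  expect_equal(intersection_area(unit_square(), unit_square(0.5, 0)), 0.5,
               tolerance = 1e-7)
  # boundary-only contact counts as empty
  expect_equal(intersection_area(unit_square(), unit_square(1, 0)), 0)
})

test_that("intersection_area is symmetric, bounded and scales as s^2", {
  set.seed(31)
  for (rep in 1:60) {
    a <- star_polygon(sample(5:30, 1), runif(1, 400, 600),
                      runif(1, 400, 600), 100, 350)
    b <- star_polygon(sample(5:30, 1), runif(1, 400, 600),
                      runif(1, 400, 600), 100, 350)
    i1 <- intersection_area(a, b)
    i2 <- intersection_area(b, a)
    amin <- min(polygon_area(a), polygon_area(b))
    expect_lt(abs(i1 - i2), 1e-9 * max(1, i1))
    expect_lte(i1, amin + 1e-9 * amin)
    if (rep <= 10 && i1 > 0) {
      s <- runif(1, 0.5, 20)
      expect_lt(abs(intersection_area(a * s, b * s) - s^2 * i1),
                1e-9 * s^2 * i1 + 1e-12)
    }
  }
})

test_that("discretized circles agree with the analytic lens oracle", {
  set.seed(41)
  for (rep in 1:25) {
    r1 <- runif(1, 0.5, 2); r2 <- runif(1, 0.5, 2)
    d <- runif(1, 0.05, 0.95 * (r1 + r2))
    poly <- intersection_area(circle_polygon(c(0, 0), r1, 512),
                              circle_polygon(c(d, 0), r2, 512))
    exact <- circle_circle_overlap_area(c(0, 0), r1, c(d, 0), r2)
    expect_lt(abs(poly - exact), 0.01 * exact)
  }
})

test_that("circle_polygon contract: first vertex, equivariance, area limit", {
  p <- circle_polygon(c(2, 3), 5, 64)
  expect_equal(p[1, ], c(x = 7, y = 3))
  expect_equal(nrow(p), 64L)
  expect_true(all(abs(sqrt(rowSums(sweep(p, 2, c(2, 3))^2)) - 5) < 1e-7))

  shift <- circle_polygon(c(12, -4), 5, 64)
  expect_equal(unname(shift - p),
               matrix(rep(c(10, -7), each = 64), ncol = 2),
               tolerance = 1e-7)

  expect_error(circle_polygon(c(0, 0), 5, 7), class = "hci_parameter_error")
  expect_error(circle_polygon(c(0, 0), -1, 64), class = "hci_parameter_error")

  # relaxed-precondition path used for oracle shapes
  sq4 <- hcindex:::.regular_polygon(c(0, 0), 1, 4)
  expect_true(all(abs(sqrt(rowSums(sq4^2)) - 1) < 1e-7))

  areas <- vapply(c(8, 16, 64, 256, 1024), function(n)
    polygon_area(circle_polygon(c(0, 0), 1, n)), numeric(1))
  expect_true(all(diff(areas) > 0))
  expect_true(all(areas < pi))
  expect_lt(pi - areas[5], 1e-4)
})

test_that("circle_circle_overlap_area closed form", {
  expect_equal(circle_circle_overlap_area(c(1, 2), 3, c(1, 2), 3), 9 * pi)
  expect_equal(circle_circle_overlap_area(c(0, 0), 1, c(3, 0), 1.5), 0)
  expect_equal(circle_circle_overlap_area(c(0, 0), 1, c(1, 0), 1),
               2 * acos(0.5) - sqrt(3) / 2, tolerance = 1e-12)
  # containment
  expect_equal(circle_circle_overlap_area(c(0, 0), 2, c(0.3, 0), 0.5),
               0.25 * pi)
  expect_error(circle_circle_overlap_area(c(0, 0), 0, c(1, 0), 1),
               class = "hci_parameter_error")
})

test_that("grid_overlap_oracle: exact cases, convergence, errors", {
  sq_region <- function(x, y) x >= 0 & x <= 1 & y >= 0 & y <= 1
  est <- grid_overlap_oracle(sq_region, sq_region, c(-0.2, 1.2, -0.2, 1.2),
                             1000)
  expect_lt(abs(est - 1), 0.01)

  far <- function(x, y) (x - 10)^2 + y^2 <= 1
  expect_equal(as.numeric(
    grid_overlap_oracle(sq_region, far, c(-2, 12, -2, 2), 500)), 0)

  lens <- 2 * acos(0.5) - sqrt(3) / 2
  bbox <- c(-1.1, 2.1, -1.1, 1.1)
  e500 <- abs(as.numeric(grid_overlap_oracle(disc_region(c(0, 0), 1),
                                             disc_region(c(1, 0), 1),
                                             bbox, 500)) - lens)
  e2000 <- abs(as.numeric(grid_overlap_oracle(disc_region(c(0, 0), 1),
                                              disc_region(c(1, 0), 1),
                                              bbox, 2000)) - lens)
  expect_lt(e2000, 0.005 * lens)
  expect_lt(e2000, e500 / 2)   # error at least halves from 500 -> 2000

  expect_error(grid_overlap_oracle(sq_region, sq_region, c(0, 0, 0, 1), 500),
               class = "hci_parameter_error")
  expect_error(grid_overlap_oracle(sq_region, sq_region, c(0, 1, 0, 1), 50),
               class = "hci_parameter_error")
})
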