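test_that("eye surface area follows the half-ellipsoid formula", {
  # r = (2 + 4/2)/2 = 2 -> 2*pi*4
  expect_equal(eye_surface_area(2, 4), 8 * pi)
  expect_equal(eye_surface_area(1, 2), 2 * pi)
  # whenever height = 2 * width the radius equals the width
  for (w in c(0.5, 3, 120, 431.7)) {
    expect_equal(eye_surface_area(w, 2 * w), 2 * pi * w^2)
  }
  # alternative radius convention halves the width contribution
  expect_equal(eye_surface_area(2, 4, convention = "halfwidth-halfheight"),
               2 * pi * ((1 + 2) / 2)^2)
  expect_error(eye_surface_area(-1, 2), "invalid measurement")
  expect_error(eye_surface_area(1, 0), "invalid measurement")
})

test_that("funiculus surface area is the ovoid surface minus the base disc", {
  expect_equal(funiculus_surface_area(2, 2), 3 * pi)       # 4pi - pi
  expect_equal(funiculus_surface_area(4, 2), 8 * pi)       # 9pi - pi
  # quadratic scaling in the linear dimensions
  expect_equal(funiculus_surface_area(20, 20),
               100 * funiculus_surface_area(2, 2))
  # half-surface option
  expect_equal(funiculus_surface_area(2, 2, surface = "half"), pi)
  # the full ovoid always dominates its base circle ...
  expect_gt(funiculus_surface_area(0.1, 10), 0)
  # ... but the half surface can be eaten by it when width >> length
  expect_error(funiculus_surface_area(0.1, 10, surface = "half"),
               "geometry error")
  expect_error(funiculus_surface_area(0, 1), "invalid measurement")
})

test_that("surface areas scale as c^2 under linear rescaling", {
  set.seed(11)
  for (i in 1:20) {
    w <- runif(1, 50, 500); h <- runif(1, 50, 500); c0 <- runif(1, 0.1, 10)
    expect_equal(eye_surface_area(c0 * w, c0 * h),
                 c0^2 * eye_surface_area(w, h))
    l <- runif(1, 100, 400); fw <- runif(1, 20, 90)
    expect_equal(funiculus_surface_area(c0 * l, c0 * fw),
                 c0^2 * funiculus_surface_area(l, fw))
  }
})

test_that("EF ratio composes the two area operations and is scale-free", {
  expect_equal(ef_ratio(50, 25), 2)
  expect_equal(ef_ratio(7.3, 7.3), 1)
  expect_equal(ef_ratio(eye_surface_area(2, 4), funiculus_surface_area(2, 2)),
               8 / 3)
  set.seed(21)
  for (i in 1:20) {
    a <- runif(1, 1, 100); b <- runif(1, 1, 100); c0 <- runif(1, 0.01, 100)
    expect_equal(ef_ratio(c0 * a, c0 * b), ef_ratio(a, b))
  }
  expect_error(ef_ratio(-1, 1), "invalid measurement")
})

test_that("sensillum density divides the count by half the surface", {
  expect_equal(sensilla_density(100, 200), 1)
  expect_equal(sensilla_density(0, 123.4), 0)
  expect_equal(sensilla_density(36, 1800), 0.04)
  expect_error(sensilla_density(10, 0), "invalid measurement")
  expect_error(sensilla_density(-1, 10), "invalid measurement")
})

test_that("disc and volume ratios behave as ratios", {
  expect_equal(disc_ratio(10, 5), 2)
  expect_equal(disc_ratio(3.3, 3.3), 1)
  expect_equal(disc_ratio(5, 10), 1 / disc_ratio(10, 5))
  vr <- volume_ratios(4, 2, 8)
  expect_equal(vr, list(ol_al = 2, ol_central = 0.5, al_central = 0.25))
  expect_equal(volume_ratios(3, 3, 3), list(ol_al = 1, ol_central = 1,
                                            al_central = 1))
  set.seed(31)
  for (i in 1:20) {
    v <- runif(3, 1, 100)
    r <- volume_ratios(v[1], v[2], v[3])
    expect_equal(r$ol_al, r$ol_central / r$al_central)
    c0 <- runif(1, 0.1, 10)
    expect_equal(volume_ratios(c0 * v[1], c0 * v[2], c0 * v[3]), r)
  }
  expect_error(volume_ratios(1, -1, 1), "invalid measurement")
})

test_that("attraction index is the symmetric two-choice preference", {
  expect_equal(attraction_index(15, 15), 0)
  expect_equal(attraction_index(30, 0), 1)
  expect_equal(attraction_index(0, 30), -1)
  expect_equal(attraction_index(30, 10), 0.5)
  # count-scale invariance
  expect_equal(attraction_index(6, 2), attraction_index(30, 10))
  expect_error(attraction_index(0, 0), "undefined")
  expect_error(attraction_index(-1, 5), "non-negative")
})
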