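test_that("pure-birth trees are ultrametric, seeded and correctly sized", {
  t2 <- simulate_tree(2, seed = 40)
  expect_equal(length(t2$tip.label), 2L)
  V <- vcv_from_tree(t2)
  expect_equal(V[1, 1], V[2, 2])           # cherry: equal depths
  tr <- simulate_tree(20, seed = 41)
  expect_true(ape::is.ultrametric(tr, tol = 1e-8))
  expect_equal(max(vcv_from_tree(tr)), 1)  # rescaled to unit depth
  expect_identical(write_newick(simulate_tree(20, seed = 41)),
                   write_newick(tr))
  expect_false(identical(write_newick(simulate_tree(20, seed = 42)),
                         write_newick(tr)))
  expect_error(simulate_tree(1, seed = 1), ">= 2")
  unscaled <- simulate_tree(10, seed = 43, rescale = FALSE)
  expect_gt(abs(max(vcv_from_tree(unscaled)) - 1), 1e-6)
})

test_that("lineage growth matches the Yule expectation", {
  # with rescale off, the expected depth of an n-tip Yule tree with rate b
  # is sum_{k=2}^{n} 1/(k b); compare the mean simulated depth
  n <- 12; b <- 2
  depths <- vapply(1:300, function(i)
    max(vcv_from_tree(simulate_tree(n, b, seed = 5000 + i,
                                    rescale = FALSE))), numeric(1))
  expected <- sum(1 / (b * (2:n)))
  expect_equal(mean(depths), expected, tolerance = 0.1)
})

test_that("Brownian trait simulation honours its covariance", {
  tr <- simulate_tree(5, seed = 44)
  V <- vcv_from_tree(tr)
  s2 <- 1.7
  draws <- vapply(1:2000, function(i)
    simulate_bm_trait(tr, sigma2 = s2, seed = 6000 + i), numeric(5))
  emp <- cov(t(draws))
  expect_equal(emp, s2 * V, tolerance = 0.1 * s2 * max(V),
               ignore_attr = TRUE)
  # zero rate gives the constant root state
  expect_equal(unname(simulate_bm_trait(tr, sigma2 = 0, root = 2.5,
                                        seed = 1)), rep(2.5, 5))
  expect_identical(simulate_bm_trait(tr, seed = 7),
                   simulate_bm_trait(tr, seed = 7))
})

test_that("binary traits hit their target prevalence", {
  tr <- simulate_tree(50, seed = 45)
  expect_equal(unname(simulate_binary_trait(tr, 0, seed = 1)), rep(0, 50))
  expect_equal(unname(simulate_binary_trait(tr, 1, seed = 1)), rep(1, 50))
  prev <- vapply(1:100, function(i)
    mean(simulate_binary_trait(tr, 0.4, seed = 7000 + i)), numeric(1))
  expect_lt(abs(mean(prev) - 0.4), 0.05)
})

test_that("PGLS datasets are deterministic and carry their design", {
  tr <- simulate_tree(30, seed = 46)
  d1 <- simulate_pgls_dataset(tr, beta_true = c(1, 0.5), seed = 47)
  d2 <- simulate_pgls_dataset(tr, beta_true = c(1, 0.5), seed = 47)
  expect_identical(d1, d2)
  expect_equal(colnames(d1$X), c("intercept", "predictor"))
  expect_true(all(d1$X[, "predictor"] %in% c(0, 1)))
})

test_that("morphometric tables close the generator/analyzer round trip", {
  cfg <- synthetic_config(seed = 48, n_species = 40)
  spec <- simulate_morphometric_table(cfg)
  expect_equal(nrow(spec), 40 * cfg$n_replicates_per_species)
  expect_identical(spec, simulate_morphometric_table(cfg))
  tab <- aggregate_species(spec)
  hw <- tapply(spec$head_width, spec$species, mean)[tab$species_id]
  fit <- allometry_fit(hw, tab$eye_area, expected_slope = 2)
  expect_lt(abs(fit$slope - 2), 0.3)
  # no replicate noise, no allocation axis: EF identical across species
  cfg0 <- synthetic_config(seed = 49, n_species = 10, ef_log_sd = 0,
                           measurement_cv = 0)
  tab0 <- aggregate_species(simulate_morphometric_table(cfg0))
  expect_lt(diff(range(tab0$ef_ratio)) / mean(tab0$ef_ratio), 1e-6)
})

test_that("disc data honour group means and the disc/adult correlation", {
  d0 <- simulate_disc_data(n_species = 10, group_means = c(1.5, 2.5),
                           sd = 0, rho_adult = 0.5, seed = 50)
  r0 <- with(d0$discs, disc_ratio(eye_portion_area, antennal_portion_area))
  expect_equal(sort(unique(round(r0, 9))), c(1.5, 2.5))
  d1 <- simulate_disc_data(n_species = 30, sd = 0.1, rho_adult = 1,
                           seed = 51)
  dr <- tapply(with(d1$discs,
                    disc_ratio(eye_portion_area, antennal_portion_area)),
               d1$discs$species, mean)
  expect_equal(cor(log(dr[names(d1$adult_ef)]), log(d1$adult_ef)), 1,
               tolerance = 1e-9)
  rs <- vapply(1:200, function(i) {
    d <- simulate_disc_data(n_species = 60, sd = 0.1, rho_adult = 0.8,
                            seed = 8000 + i)
    dr <- tapply(with(d$discs,
                      disc_ratio(eye_portion_area, antennal_portion_area)),
                 d$discs$species, mean)
    cor(log(dr[names(d$adult_ef)]), log(d$adult_ef))
  }, numeric(1))
  expect_lt(abs(mean(rs) - 0.8), 0.1)
})

test_that("EF ratio is independent of size by construction", {
  hits <- 0
  for (i in 1:100) {
    cfg <- synthetic_config(seed = 9000 + i, n_species = 62)
    spec <- simulate_morphometric_table(cfg)
    tab <- aggregate_species(spec)
    bl <- tapply(spec$body_length, spec$species, mean)[tab$species_id]
    ci <- allometry_fit(bl, tab$ef_ratio, expected_slope = 0)$slope_ci
    hits <- hits + (ci[1] <= 0 && 0 <= ci[2])
  }
  expect_gte(hits / 100, 0.90)
})
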