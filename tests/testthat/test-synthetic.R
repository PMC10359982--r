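# Synthetic-fixture generator and the perturbation noise model

test_that("toy construction inverts the (d, alpha) specification exactly", {
  for (spec in list(toy_geometry_spec(3.0, 10),
                    toy_geometry_spec(3.2, 0),
                    toy_geometry_spec(2.95, 24, dihedral_phi = 40),
                    toy_geometry_spec(3.3, 15, acceptor_context = "sidechain-O"),
                    toy_geometry_spec(3.4, 5, acceptor_context = "sidechain-S"))) {
    s <- build_toy_chb(spec)
    det <- detect_chbs(s)
    expect_equal(nrow(det), 1)
    expect_equal(det$d, spec$d, tolerance = 1e-9)
    expect_equal(det$alpha_min, spec$alpha, tolerance = 1e-9)
    expect_equal(det$acceptor_element, spec$acceptor_element)
  }
})

test_that("boundary specs pass at (3.41, 25) and fail at (3.43, 10)", {
  expect_equal(nrow(detect_chbs(build_toy_chb(toy_geometry_spec(3.41, 25)))), 1)
  expect_equal(nrow(detect_chbs(build_toy_chb(toy_geometry_spec(3.43, 10)))), 0)
})

test_that("specs that force atom clashes are infeasible", {
  expect_error(build_toy_chb(toy_geometry_spec(d = 3.0, alpha = 180)),
               class = "chalcogenr_infeasible_spec")
})

test_that("perturbation is deterministic, seed-controlled and null at sigma 0", {
  s <- build_toy_chb(toy_geometry_spec(3.0, 10))
  expect_identical(perturb_structure(s, 0, seed = 1)$atoms[, c("x", "y", "z")],
                   s$atoms[, c("x", "y", "z")])
  a <- perturb_structure(s, 0.3, seed = 42)
  b <- perturb_structure(s, 0.3, seed = 42)
  c <- perturb_structure(s, 0.3, seed = 43)
  expect_identical(a$atoms, b$atoms)
  expect_false(identical(a$atoms$x, c$atoms$x))
  expect_equal(a$metadata$source, "predicted")
  expect_equal(nrow(a$metadata$ssbonds), 0) # predicted files carry no SSBOND
})

test_that("perturbation does not disturb the global RNG state", {
  s <- build_toy_chb(toy_geometry_spec(3.0, 10))
  set.seed(123)
  before <- .Random.seed
  invisible(perturb_structure(s, 0.2, seed = 7))
  expect_identical(.Random.seed, before)
})

test_that("mean |delta-d| under small noise follows sigma * sqrt(2) * sqrt(2/pi)", {
  # distance between two points, each coordinate perturbed with sd sigma:
  # delta-d is asymptotically N(0, 2 sigma^2), so E|delta-d| = sigma*sqrt(2)*sqrt(2/pi)
  sigma <- 0.046
  n <- 10000
  set.seed(99)
  p1 <- cbind(rnorm(n, 0, sigma), rnorm(n, 0, sigma), rnorm(n, 0, sigma))
  p2 <- cbind(3 + rnorm(n, 0, sigma), rnorm(n, 0, sigma), rnorm(n, 0, sigma))
  dd <- sqrt(rowSums((p1 - p2)^2)) - 3
  expected <- sigma * sqrt(2) * sqrt(2 / pi)
  mc_se <- sd(abs(dd)) / sqrt(n)
  expect_lt(abs(mean(abs(dd)) - expected), 3 * mc_se + 0.1 * expected)
})

test_that("the truth table matches the pipeline recovery exactly", {
  ds <- generate_paired_dataset(paired_dataset_spec(n_entries = 40,
                                                    noise_sigma = 0.3,
                                                    seed = 31))
  cmps <- expect_quiet(
    purrr::map2(ds$experimental, ds$models, compare_structures))
  sv <- pool_comparisons(cmps)
  expect_equal(nrow(sv$matched), 40)
  expect_identical(sv$matched$recovered, ds$truth$recovered_truth)
  expect_equal(recovery_fraction(sv$matched),
               mean(ds$truth$recovered_truth))
})

test_that("an unperturbed dataset is fully recovered", {
  ds <- generate_paired_dataset(paired_dataset_spec(n_entries = 15,
                                                    noise_sigma = 0,
                                                    seed = 3))
  expect_true(all(ds$truth$recovered_truth))
  cmps <- expect_quiet(
    purrr::map2(ds$experimental, ds$models, compare_structures))
  sv <- pool_comparisons(cmps)
  expect_equal(recovery_fraction(sv$matched), 1.0)
})

test_that("threshold-straddling d samples recover exactly the in-threshold set", {
  ds <- generate_paired_dataset(
    paired_dataset_spec(n_entries = 50, d_range = c(3.30, 3.55),
                        alpha_range = c(5, 5), noise_sigma = 0, seed = 17))
  expect_equal(mean(ds$truth$recovered_truth),
               mean(ds$truth$d_true <= 3.42))
  cmps <- expect_quiet(
    purrr::map2(ds$experimental, ds$models, compare_structures))
  # experimental detection only reports passing bonds, so the number of
  # matched bonds equals the number of d samples inside the threshold
  sv <- pool_comparisons(cmps)
  expect_equal(nrow(sv$matched), sum(ds$truth$d_true <= 3.42))
  expect_true(all(sv$matched$recovered))
})

test_that("generated datasets round-trip through PDB files unchanged in meaning", {
  ds <- generate_paired_dataset(paired_dataset_spec(n_entries = 5,
                                                    noise_sigma = 0.2,
                                                    seed = 13))
  dir <- withr::local_tempdir()
  for (i in seq_along(ds$experimental)) {
    fe <- file.path(dir, paste0("e", i, ".pdb"))
    fm <- file.path(dir, paste0("m", i, ".pdb"))
    write_structure(ds$experimental[[i]], fe)
    write_structure(ds$models[[i]], fm)
    e2 <- expect_quiet(read_structure(fe))
    m2 <- expect_quiet(read_structure(fm))
    cmp <- expect_quiet(compare_structures(e2, m2))
    expect_equal(cmp$matched$recovered, ds$truth$recovered_truth[i])
    expect_equal(cmp$matched$exp_d, ds$truth$d_true[i], tolerance = 2e-3)
    expect_equal(cmp$matched$model_d,
                 if (ds$truth$recovered_truth[i] ||
                       ds$truth$ss_perturbed[i] <= 2.5)
                   ds$truth$d_perturbed[i] else NA_real_,
                 tolerance = 2e-3)
  }
})
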