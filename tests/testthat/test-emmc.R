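hyrax <- species_profile("rock hyrax", 2.95, 11)
human <- species_profile("human", 58.7, 55)
elephant <- species_profile("African elephant", 3940, 65)
colorectal <- cancer_spec("colorectal", 2e8, 73, 4)

test_that("cancer_risk evaluates the closed form and guards its domain", {
  expect_equal(cancer_risk(C = 5, u = 0.1, k = 1, T_years = 1, M = 2), 0.05)
  expect_equal(cancer_risk(C = 7, u = 0, k = 3, T_years = 2, M = 2), 0)
  expect_warning(cancer_risk(C = 1e6, u = 1e-2, k = 10, T_years = 10, M = 1),
                 "small-p")
  expect_error(cancer_risk(C = -1, u = 1e-6, k = 1, T_years = 1, M = 2),
               "positive")
  expect_error(cancer_risk(C = 1, u = 1e-6, k = 0, T_years = 1, M = 2))
})

test_that("stem-cell scaling is proportional to body mass", {
  expect_equal(scale_C(colorectal, elephant, human), 2e8 * 3940 / 58.7)
  expect_equal(scale_C(colorectal, human, human), 2e8)
  expect_equal(scale_C(colorectal, hyrax, human), 2e8 * 2.95 / 58.7,
               tolerance = 1e-12)
})

test_that("metabolic scaling of the division rate uses the chained anchor", {
  off <- metabolic_mode(FALSE)
  on_ <- metabolic_mode(TRUE)
  expect_equal(effective_k(colorectal, elephant, off, human), 73)
  expect_equal(effective_k(colorectal, human, on_, human), 73)
  expect_equal(effective_k(colorectal, hyrax, on_, human),
               73 * (2.95 / 58.7)^-0.15, tolerance = 1e-12)
  # explicit exponent 0 when enabled reproduces the disabled mode exactly
  zero <- metabolic_mode(TRUE, exponent = 0)
  expect_identical(effective_k(colorectal, elephant, zero, human),
                   effective_k(colorectal, elephant, off, human))
})

test_that("calibration pins the reference species risk at the target", {
  for (ca in default_cancers()) for (mode in list(metabolic_mode(FALSE),
                                                  metabolic_mode(TRUE))) {
    u <- calibrate_u(ca, hyrax, mode, tab_species = human)
    C_h <- scale_C(ca, hyrax, human)
    k_h <- effective_k(ca, hyrax, mode, human)
    expect_equal(cancer_risk(C_h, u, k_h, 11, ca$M_base), ca$p_target,
                 tolerance = 1e-12)
  }
})

test_that("solve_M recovers the baseline M for the reference species", {
  u <- calibrate_u(colorectal, hyrax, tab_species = human)
  res <- solve_M(colorectal, hyrax, u, tab_species = human)
  expect_equal(res$M_total, 4, tolerance = 1e-9)
  expect_equal(res$M_add, 0, tolerance = 1e-9)
  expect_equal(solve_u_fold(colorectal, hyrax, u, tab_species = human)$fold,
               1, tolerance = 1e-9)
})

test_that("required suppression increases with body mass and lifespan", {
  u <- calibrate_u(colorectal, hyrax, tab_species = human)
  weights <- c(3, 30, 300, 3000)
  Ms <- vapply(weights, function(w)
    solve_M(colorectal, species_profile("x", w, 40), u,
            tab_species = human)$M_total, numeric(1))
  expect_true(all(diff(Ms) > 0))
  folds <- vapply(weights, function(w)
    solve_u_fold(colorectal, species_profile("x", w, 40), u,
                 tab_species = human)$fold, numeric(1))
  expect_true(all(diff(folds) > 0))
  lifespans <- c(10, 20, 40, 80)
  Ms_T <- vapply(lifespans, function(tt)
    solve_M(colorectal, species_profile("x", 500, tt), u,
            tab_species = human)$M_total, numeric(1))
  expect_true(all(diff(Ms_T) > 0))
})

test_that("the two adaptive routes are mutually consistent", {
  for (ca in default_cancers()) {
    u0 <- calibrate_u(ca, hyrax, tab_species = human)
    res <- solve_u_fold(ca, elephant, u0, tab_species = human)
    C_e <- scale_C(ca, elephant, human)
    expect_equal(cancer_risk(C_e, u0 / res$fold, ca$k_ref, 65, ca$M_base),
                 ca$p_target, tolerance = 1e-9)
  }
})

test_that("solve_M rejects parameter regions where risk is not decreasing in M", {
  expect_error(solve_M(colorectal, elephant, u = 1, tab_species = human),
               "not decreasing")
})

test_that("the full table covers every cancer x species x mode combination", {
  tab <- build_emmc_table()
  expect_equal(nrow(tab), 3 * 4 * 2)
  ref_rows <- tab[tab$species == "rock hyrax", ]
  expect_equal(ref_rows$M_add, rep(0, nrow(ref_rows)), tolerance = 1e-9)
  expect_equal(ref_rows$u_fold, rep(1, nrow(ref_rows)), tolerance = 1e-9)
  expect_error(build_emmc_table(reference = "mouse"), "not in species list")
})

test_that("a YAML parameter file reproduces the default table", {
  cfg_file <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(
    cancers = list(colorectal = list(C_ref = 2e8, k_ref = 73, M_base = 4)),
    species = list(hyrax = list(weight_kg = 2.95, T_years = 11),
                   elephant = list(weight_kg = 3940, T_years = 65),
                   human = list(weight_kg = 58.7, T_years = 55)),
    reference = "hyrax", tab_species = "human"), cfg_file)
  pars <- read_emmc_config(cfg_file)
  tab <- do.call(build_emmc_table, pars)
  full <- build_emmc_table()
  for (sp in c("hyrax", "elephant", "human")) {
    got <- tab[tab$cancer == "colorectal" & tab$species == sp & !tab$mr, ]
    ref <- full[full$cancer == "colorectal" &
                  full$species == default_species()[[sp]]$name & !full$mr, ]
    expect_equal(got$M_add, ref$M_add, tolerance = 1e-12)
  }
})
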