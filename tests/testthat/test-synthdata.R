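test_that("in vitro fixtures are reproducible triplicates on the 2-min grid", {
  sc <- list(default_scenario(2))
  pp <- list(default_release_params(2))
  fx <- generate_invitro_fixtures(sc, pp, noise_sd = 2, seed = 3)
  expect_equal(sort(unique(fx$replicate)), 1:3)
  expect_true(all(fx$dissolved_pct >= 0 & fx$dissolved_pct <= 100))
  expect_true(all(diff(sort(unique(fx$time_min))) == 2))

  fx2 <- generate_invitro_fixtures(sc, pp, noise_sd = 2, seed = 3)
  expect_identical(fx, fx2)

  clean <- generate_invitro_fixtures(sc, pp, noise_sd = 0, seed = 1)
  r1 <- clean$dissolved_pct[clean$replicate == 1]
  r3 <- clean$dissolved_pct[clean$replicate == 3]
  expect_identical(r1, r3)
  expect_error(generate_invitro_fixtures(sc, pp, noise_sd = -1), ">= 0")
})

test_that("the virtual trial carries ground truth and obeys its switches", {
  spec <- virtual_trial_spec(n = 6, seed = 2)
  out <- generate_virtual_trial(spec)
  expect_equal(nrow(out$truth), 6)
  expect_setequal(names(out$pk),
                  c("subject", "time_h", "conc_mg_L", "formulation",
                    "dose_mg"))
  expect_equal(nrow(out$pk), 6 * 2 * length(clinical_times()))
  expect_true(all(out$truth$group %in% 1:6))

  # same seed: identical tables (and identical written CSV)
  out2 <- generate_virtual_trial(spec)
  expect_identical(out$pk, out2$pk)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_plasma_csv(out$pk, f1)
  write_plasma_csv(out2$pk, f2)
  expect_identical(readLines(f1), readLines(f2))

  # noise off, single fixed-kge group, no variability: identical capsule
  # profiles
  pop0 <- default_poppk("capsule")
  pop0$bsv[] <- 0
  uni <- generate_virtual_trial(
    virtual_trial_spec(n = 3, prevalences = c(0, 1, 0, 0, 0, 0),
                       noise = FALSE, seed = 1),
    pop = pop0)
  caps <- uni$pk[uni$pk$formulation == "capsule", ]
  m <- matrix(caps$conc_mg_L, ncol = 3)
  expect_equal(m[, 1], m[, 2])
  expect_equal(m[, 1], m[, 3])
})

test_that("default config files encode the study design and regenerate identically", {
  d1 <- file.path(tempdir(), "cfg1")
  d2 <- file.path(tempdir(), "cfg2")
  make_default_configs(d1)
  make_default_configs(d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }

  g1 <- read_scenario_config(file.path(d1, "scenario_group1.yaml"))
  expect_equal(g1$get_min, 15)
  expect_equal(nrow(g1$stresses), 0)

  g2 <- read_scenario_config(file.path(d1, "scenario_group2.yaml"))
  expect_equal(g2$stresses$time_min, c(10, 13))
  expect_equal(g2$stresses$mbar, c(300, 300))

  g3 <- read_scenario_config(file.path(d1, "scenario_group3.yaml"))
  expect_equal(g3$stresses$time_min, 5)
  expect_equal(g3$stresses$mbar, 200)

  # round trips into the defining types without loss
  pop <- read_poppk_config(file.path(d1, "poppk.yaml"), "tablet")
  expect_equal(pop$theta, default_poppk("tablet")$theta)
  expect_equal(pop$bsv, default_poppk("tablet")$bsv)
  cfg <- read_gi_config(file.path(d1, "gi_default.yaml"))
  expect_equal(cfg, default_gi_config())
  rel <- read_release_config(file.path(d1, "release_group6.yaml"))
  p6 <- default_release_params(6)
  expect_equal(rel[c("kind", "tlag", "tau", "b", "z", "cs", "x0")],
               p6[c("kind", "tlag", "tau", "b", "z", "cs", "x0")])
})

test_that("shipped package configs match the in-code defaults", {
  ext <- system.file("extdata", package = "gastroPK")
  expect_equal(read_gi_config(file.path(ext, "gi_default.yaml")),
               default_gi_config())
  expect_equal(read_poppk_config(file.path(ext, "poppk.yaml"), "capsule")$theta,
               default_poppk("capsule")$theta)
})
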