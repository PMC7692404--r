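small_cfg <- function(seed = 3, ...) {
  args <- utils::modifyList(
    list(seed = seed, n_normal = 25, n_tumor = 30, n_pathways = 4,
         genes_per_pathway = 8, perturbed_pathways = c("PW01", "PW02"),
         survival_pathways = "PW01"),
    list(...))
  do.call(sim_config, args)
}

test_that("identical configs give identical cohorts; different seeds differ", {
  a <- simulate_cohort(small_cfg())
  b <- simulate_cohort(small_cfg())
  expect_identical(a$expression$values, b$expression$values)
  expect_identical(a$clinical, b$clinical)
  expect_identical(a$truth, b$truth)
  c <- simulate_cohort(small_cfg(seed = 4))
  expect_false(identical(a$expression$values, c$expression$values))

  # regeneration on disk is byte-identical under the same seed
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_cohort(a, d1); write_cohort(b, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
})

test_that("simulation does not disturb the caller's RNG stream", {
  set.seed(99); before <- rnorm(1)
  set.seed(99); invisible(simulate_cohort(small_cfg())); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("normal-sample within-block correlation realizes near rho", {
  co <- simulate_cohort(sim_config(seed = 1, n_normal = 50, n_tumor = 10,
                                   n_pathways = 6, genes_per_pathway = 10,
                                   perturbed_pathways = "PW01",
                                   survival_pathways = "PW01"))
  expect_true(all(abs(co$truth$pathways$realized_normal_rho - 0.8) <= 0.1))
  # carriers on a decorrelated block realize near-zero correlation
  carr <- co$truth$samples
  carr <- carr$sample_id[carr$pathway == "PW01" & carr$is_perturbed]
  genes <- unique(as.vector(co$edges$PW01))
  cm <- stats::cor(t(co$expression$values[genes, carr]))
  expect_lt(abs(mean(cm[upper.tri(cm)])), 0.25)
})

test_that("truth tables, survival plant and expression sign obey the config", {
  co <- simulate_cohort(small_cfg())
  expect_true(all(co$expression$values >= 0))
  tr <- co$truth
  expect_identical(sort(unique(tr$samples$pathway)),
                   sprintf("PW%02d", 1:4))
  expect_true(all(!tr$samples$is_perturbed[tr$samples$pathway == "PW03"]))
  n_carr <- sum(tr$samples$is_perturbed[tr$samples$pathway == "PW01"])
  expect_identical(n_carr, 15L)  # half of 30 tumors
  expect_identical(tr$pathways$is_survival_pathway,
                   c(TRUE, FALSE, FALSE, FALSE))
  expect_identical(nrow(co$clinical), 30L)
  expect_true(all(co$clinical$time >= 0))
  expect_true(all(co$clinical$event %in% 0:1))

  # null configuration: no carriers anywhere
  co0 <- simulate_cohort(small_cfg(fraction_tumors_perturbed = 0,
                                   perturbed_pathways = character(0),
                                   survival_pathways = character(0)))
  expect_false(any(co0$truth$samples$is_perturbed))
})

test_that("sign-flip perturbation flips cross-loading edge correlations", {
  co <- simulate_cohort(small_cfg(perturbation_mode = "sign_flip",
                                  fraction_tumors_perturbed = 1,
                                  n_tumor = 60))
  carr <- unique(co$truth$samples$sample_id[co$truth$samples$is_perturbed &
                                              co$truth$samples$pathway == "PW01"])
  genes <- sort(unique(as.vector(co$edges$PW01)))
  cm <- stats::cor(t(co$expression$values[genes, carr]))
  off <- cm[upper.tri(cm)]
  # roughly half the pairs flip to strongly negative correlation
  expect_gt(mean(off < -0.4), 0.3)
  expect_gt(mean(off > 0.4), 0.3)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(rho = 1), "rho")
  expect_error(sim_config(censoring_fraction = 1))
  expect_error(sim_config(perturbed_pathways = "PW99"), "outside")
  expect_error(sim_config(survival_pathways = "PW03",
                          perturbed_pathways = "PW01"), "subset")
  expect_error(sim_config(hazard_ratio_strong = 0))
})

test_that("the fixture suite round-trips through the package readers", {
  dir <- withr::local_tempdir()
  write_fixture_suite(dir, seed = 3)
  toy <- file.path(dir, "toy_cohort")
  x <- read_expression(file.path(toy, "expression.tsv"),
                       file.path(toy, "annotation.tsv"))
  pw <- read_pathways(file.path(toy, "pathways.tsv"), rownames(x$values))
  cl <- read_clinical(file.path(toy, "clinical.tsv"))
  expect_identical(length(pw), 3L)
  expect_identical(nrow(cl), 12L)
  expect_identical(sum(x$sample_group == "normal"), 12L)

  # the written hand fixture reproduces the documented reference correlation
  hd <- file.path(dir, "hand_edges")
  hx <- read_expression(file.path(hd, "expression.tsv"),
                        file.path(hd, "annotation.tsv"))
  expect_equal(stats::cor(hx$values["GX", ], hx$values["GY", ]), 0.5,
               tolerance = 1e-12)

  # regeneration with the same seed is byte-identical; another seed differs
  dir2 <- withr::local_tempdir()
  write_fixture_suite(dir2, seed = 3)
  f <- file.path("toy_cohort", "expression.tsv")
  expect_identical(readLines(file.path(dir, f)), readLines(file.path(dir2, f)))
  dir3 <- withr::local_tempdir()
  write_fixture_suite(dir3, seed = 4)
  expect_false(identical(readLines(file.path(dir, f)),
                         readLines(file.path(dir3, f))))
})
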