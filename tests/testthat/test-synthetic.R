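test_that("the simulation design is reproduced verbatim", {
  sc <- table2_scenarios()
  expect_length(sc, 8)
  expect_equal(sum(vapply(sc, function(s) s$n_sims, integer(1))), 16L)

  g1 <- sc[[1]]
  expect_equal(g1$weights, c(0.25, 0.75))
  expect_equal(g1$true_means, c(0.100, 0.120))
  expect_equal(g1$true_sd, 0.020)
  expect_equal(g1$n, 200L)

  g5 <- sc[[5]]
  expect_equal(g5$n, 500L)
  expect_equal(g5$k, 4L)
  expect_equal(g5$weights, c(0.10, 0.35, 0.35, 0.20))

  g8 <- sc[[8]]
  expect_equal(g8$true_means, c(0.080, 0.100, 0.120, 0.140))

  # 12 two-component and 4 four-component samples
  expect_equal(sum(vapply(sc, function(s) (s$k == 2) * s$n_sims,
                          numeric(1))), 12)
  expect_equal(sum(vapply(sc, function(s) (s$k == 4) * s$n_sims,
                          numeric(1))), 4)
})

test_that("thickness samples honor labels, weights, and seeds", {
  sc <- table2_scenarios()[[5]]
  s <- simulate_thickness_sample(sc, 31)
  expect_length(s$values, 500)
  expect_true(all(s$true_labels %in% 1:4))

  # empirical label fractions near the design weights (3 SE binomial band)
  big <- simulate_thickness_sample(
    structure(list(group = 5L, n_sims = 1L, n = 20000L, k = 4L,
                   weights = sc$weights, true_means = sc$true_means,
                   true_sd = sc$true_sd), class = "scenario"), 8)
  frac <- tabulate(big$true_labels, 4) / 20000
  for (j in 1:4) {
    se <- sqrt(sc$weights[j] * (1 - sc$weights[j]) / 20000)
    expect_lt(abs(frac[j] - sc$weights[j]), 3 * se + 1e-9)
  }

  # per-component sample means within 3 SD / sqrt(n_j) of truth
  for (j in 1:4) {
    xj <- big$values[big$true_labels == j]
    expect_lt(abs(mean(xj) - sc$true_means[j]),
              3 * sc$true_sd / sqrt(length(xj)))
  }

  expect_identical(simulate_thickness_sample(sc, 31), s)
  expect_false(identical(simulate_thickness_sample(sc, 32)$values,
                         s$values))
})

test_that("field samples have the structure the pipeline assumes", {
  spec <- field_sample_spec(n_coccoliths = 200, mass_noise_sd = 0)
  gen <- simulate_field_sample(spec, seed = 5)
  expect_equal(nrow(gen$sem), 200)
  expect_equal(nrow(gen$lm), 200)
  expect_equal(gen$meta$cell_density_l, 41003)

  # with zero mass noise the generated mass IS the volumetric formula
  expect_equal(gen$lm$mass_pg,
               coccolith_mass(gen$lm$length_um,
                              gen$lm$length_um / spec$aspect_mean,
                              gen$lm$mean_thickness_um))

  # only overcalcified Type A is light-microscope distinguishable
  expect_true(all(gen$lm$central_area == "open"))
  spec_oa <- field_sample_spec(morphotypes = c("OA", "B"),
                               proportions = c(0.3, 0.7),
                               length_mean = c(3.0, 2.95),
                               length_sd = c(0.2, 0.2),
                               thickness_mean = c(0.128, 0.097),
                               thickness_sd = c(0.012, 0.018))
  gen_oa <- simulate_field_sample(spec_oa, seed = 6)
  oa_rows <- gen_oa$sem$morphotype == "OA"
  expect_equal(gen_oa$lm$central_area[oa_rows] == "overcalcified",
               rep(TRUE, sum(oa_rows)))

  # zero-variance spec collapses each morphotype to identical records
  spec0 <- field_sample_spec(morphotypes = "A", proportions = 1,
                             length_mean = 3.3, length_sd = 0,
                             thickness_mean = 0.13, thickness_sd = 0,
                             ct_l_sd = 0, mass_noise_sd = 0,
                             n_coccoliths = 20)
  gen0 <- simulate_field_sample(spec0, seed = 9)
  expect_equal(length(unique(gen0$lm$mean_thickness_um)), 1)
  expect_equal(length(unique(gen0$sem$length_um)), 1)

  expect_identical(simulate_field_sample(spec, 5), gen)
})

test_that("generated abundances feed the preprocess module coherently", {
  gen <- simulate_field_sample(field_sample_spec(n_coccoliths = 300),
                               seed = 20)
  counts <- table(gen$sem$morphotype)
  ab <- relative_abundance(setNames(as.integer(counts), names(counts)))
  pA <- ab$relative_abundance[ab$morphotype == "A"]
  expect_lt(abs(pA - 0.77), 3 * sqrt(0.77 * 0.23 / 300))
})
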