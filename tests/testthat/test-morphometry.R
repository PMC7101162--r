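test_that("volumetric mass matches worked examples", {
  # overcalcified Type A quality-control case: prints as 2.1 pg
  m <- coccolith_mass(3.00, 2.51, 0.128, 2.71)
  expect_equal(round(m, 1), 2.1)
  expect_equal(m, pi * 1.5 * 1.255 * 0.128 * 2.71)
  # independent arithmetic
  expect_equal(coccolith_mass(2.0, 2.0, 0.1, 2.71), pi * 0.1 * 2.71)
  expect_equal(coccolith_mass(3.0, 2.5, 0), 0)
  expect_error(coccolith_mass(2.0, 2.5, 0.1), "length")
  expect_error(coccolith_mass(3.0, 2.5, -0.1), "thickness")
})

test_that("mass scales linearly in thickness/density and quadratically in size", {
  base <- coccolith_mass(3.2, 2.6, 0.12, 2.71)
  expect_equal(coccolith_mass(3.2, 2.6, 0.24, 2.71), 2 * base)
  expect_equal(coccolith_mass(3.2, 2.6, 0.12, 5.42), 2 * base)
  expect_equal(coccolith_mass(6.4, 5.2, 0.12, 2.71), 4 * base)
})

test_that("every printed calcite-budget cell is reproduced to 2 decimals", {
  cd <- c(41003, 11983, 16632, 1228)
  mass <- c(2.4, 2.7, 1.7, 1.7)
  printed <- rbind(c(2.26, 0.98, 4.72),
                   c(0.74, 0.32, 1.55),
                   c(0.65, 0.28, 1.36),
                   c(0.05, 0.02, 0.10))
  for (i in seq_along(cd)) {
    got <- calcite_concentration(cd[i], mass[i], c(23, 10, 48))
    expect_equal(round(got, 2), printed[i, ])
  }
  expect_equal(calcite_concentration(0, 2.4, 23), 0)
  # exact ratio between the extreme coccoliths-per-cell assumptions
  expect_equal(calcite_concentration(5000, 2.2, 48) /
                 calcite_concentration(5000, 2.2, 10), 4.8)
})

test_that("central-tube and aspect ratios follow their definitions", {
  expect_equal(ct_l_ratio(0.24, 0.22, 3.36), 0.23 / 3.36)
  expect_equal(round(ct_l_ratio(0.24, 0.22, 3.36), 2), 0.07)
  expect_equal(ct_l_ratio(0, 0, 3.0), 0)
  expect_equal(ct_l_ratio(0.2, 0.2, 4.0), 0.05)

  expect_equal(aspect_ratio(3.36, 2.79), 3.36 / 2.79)
  expect_equal(round(aspect_ratio(3.36, 2.79), 2), 1.20)
  expect_equal(aspect_ratio(2.5, 2.5), 1)
  expect_error(aspect_ratio(2.5, 3.0), "length")
  set.seed(4)
  l <- runif(50, 2, 4)
  w <- l / runif(50, 1, 1.4)
  expect_true(all(aspect_ratio(l, w) >= 1))
})

test_that("per-morphotype mass tables join sizes with posterior thickness", {
  sem <- data.frame(morphotype = c("A", "OA", "M"),
                    mean_length_um = c(3.14, 3.00, 2.98),
                    mean_width_um = c(2.61, 2.51, 2.39))
  post <- data.frame(morphotype = c("A", "OA"),
                     thickness_um = c(0.098, 0.128))
  tab <- morphotype_mass_table(sem, post)
  expect_equal(round(tab$mass_pg[tab$morphotype == "OA"], 1), 2.1)
  # a morphotype without a posterior stays visible but not estimable
  expect_false(tab$estimable[tab$morphotype == "M"])
  expect_true(is.na(tab$mass_pg[tab$morphotype == "M"]))

  post2 <- post
  post2$thickness_um <- post2$thickness_um * 2
  tab2 <- morphotype_mass_table(sem, post2)
  expect_equal(tab2$mass_pg[tab2$estimable], 2 * tab$mass_pg[tab$estimable])
})

test_that("the calcite budget table carries one TC column per assumption", {
  meta <- data.frame(sample_id = "s1", station = "Coastal",
                     month = "January", depth_m = 10,
                     cell_density_l = 41003)
  out <- calcite_budget(meta, 2.4)
  expect_equal(round(out$TC_23, 2), 2.26)
  expect_equal(round(out$TC_10, 2), 0.98)
  expect_equal(round(out$TC_48, 2), 4.72)
})
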