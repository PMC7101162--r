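test_that("SEM rows parse into validated records", {
  path <- sem_csv(c("s1,A,3.36,2.79,0.24,0.22", "s1,B,3.18,2.66,,"))
  rec <- read_sem_table(path)
  expect_equal(nrow(rec), 2)
  expect_equal(rec$morphotype, c("A", "B"))
  expect_equal(rec$length_um, c(3.36, 3.18))
  expect_equal(rec$width_um[1], 2.79)
  expect_true(is.na(rec$ct_left_um[2]))
})

test_that("invalid SEM rows are rejected with 1-based row diagnostics", {
  expect_error(read_sem_table(sem_csv("s1,X,3.0,2.5,,")),
               "row 1.*morphotype code 'X'")
  expect_error(read_sem_table(sem_csv(c("s1,A,3.0,2.5,,",
                                        "s1,A,abc,2.5,,"))),
               "row 2.*non-numeric")
  # inverted axes violate the distal-shield convention
  expect_error(read_sem_table(sem_csv("s1,A,2.5,3.0,,")), "row 1.*axis")
  # one diagnostic per bad row
  err <- tryCatch(read_sem_table(sem_csv(c("s1,Q,3,2,,", "s1,A,2,3,,"))),
                  error = conditionMessage)
  expect_equal(lengths(regmatches(err, gregexpr("row [0-9]+", err))), 2)
})

test_that("LM rows parse, default central_area, and enforce invariants", {
  rec <- read_lm_table(lm_csv("s1,3.1,2.0,0.124,overcalcified"))
  expect_equal(rec$mass_pg, 2.0)
  expect_equal(rec$mean_thickness_um, 0.124)
  # column absent -> unknown
  p <- write_lines_tmp(c("sample_id,length_um,mass_pg,mean_thickness_um",
                         "s1,3.1,2.0,0.124"))
  expect_equal(read_lm_table(p)$central_area, "unknown")
  expect_error(read_lm_table(lm_csv("s1,3.1,2.0,3.5,open")),
               "row 1.*mean_thickness")
})

test_that("write/read round-trips SEM and LM tables exactly", {
  spec <- field_sample_spec(n_coccoliths = 40)
  gen <- simulate_field_sample(spec, seed = 11)
  sp <- tempfile(fileext = ".csv")
  lp <- tempfile(fileext = ".csv")
  write_sem_table(gen$sem, sp)
  write_lm_table(gen$lm, lp)
  expect_equal(read_sem_table(sp), gen$sem, tolerance = 1e-12)
  expect_equal(read_lm_table(lp), gen$lm, tolerance = 1e-12)
})

test_that("config loading applies defaults, overrides, and rejects unknowns", {
  empty <- tempfile(fileext = ".json")
  writeLines("{}", empty)
  cfg <- load_config(empty)
  expect_equal(cfg$mixture$iterations, 500000L)
  expect_equal(cfg$mixture$burn_in, 50000L)
  expect_equal(cfg$mixture$thinning, 100L)
  expect_equal(cfg$pipeline$outlier_multiplier, 1.5)
  expect_equal(cfg$pipeline$coccoliths_per_cell, c(10L, 23L, 48L))

  over <- tempfile(fileext = ".json")
  writeLines('{"mixture": {"gamma_floor": 0.02, "k": 4,
               "alpha": [10, 35, 35, 20], "sort_means": true}}', over)
  expect_equal(load_config(over)$mixture$gamma_floor, 0.02)

  bad <- tempfile(fileext = ".json")
  writeLines('{"mixture": {"k": 4, "alpha": [20, 80], "sort_means": true}}',
             bad)
  expect_error(load_config(bad), "alpha")

  unk <- tempfile(fileext = ".json")
  writeLines('{"mixture": {"iterationz": 10}}', unk)
  expect_error(load_config(unk), "iterationz")
})
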