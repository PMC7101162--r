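# shared fixtures: tiny CSV writers and a light sampler profile for tests

write_lines_tmp <- function(lines) {
  path <- tempfile(fileext = ".csv")
  writeLines(lines, path)
  path
}

sem_csv <- function(rows) {
  write_lines_tmp(c("sample_id,morphotype,length_um,width_um,ct_left_um,ct_right_um",
                    rows))
}

lm_csv <- function(rows) {
  write_lines_tmp(c("sample_id,length_um,mass_pg,mean_thickness_um,central_area",
                    rows))
}

# fast sampler schedule for unit tests (acceptance uses the desk profile)
test_config <- function(k = 2, alpha = NULL, seed = 1L, ...) {
  mixture_config(k = k, alpha = alpha, iterations = 6000L, burn_in = 1000L,
                 thinning = 5L, chains = 3L, seed = seed, ...)
}
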