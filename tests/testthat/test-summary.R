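classified_toy <- function(...) {
  rows <- list(...)
  dplyr::bind_rows(lapply(seq_along(rows), function(i) {
    tibble::tibble(particle_id = paste0("p", i),
                   sws_total = rows[[i]]$sws_total,
                   sws_sample_length = rows[[i]]$sl %||% 50,
                   viable = TRUE,
                   class = factor(rows[[i]]$class, levels = c(
                     "background", "unclassified", "hyphae", "small_clump",
                     "large_clump", "pellet")))
  }))
}

test_that("SWS fractions are shares of the summed SWS total", {
  cl <- classified_toy(list(class = "pellet", sws_total = 8e4),
                       list(class = "hyphae", sws_total = 2e4))
  fr <- sws_fractions(cl)
  expect_equal(fr$sws_fraction[fr$class == "pellet"], 80)
  expect_equal(fr$sws_fraction[fr$class == "hyphae"], 20)
  expect_equal(fr$sws_fraction[fr$class == "small_clump"], 0)
  expect_equal(sum(fr$sws_fraction), 100)

  single <- sws_fractions(classified_toy(list(class = "large_clump",
                                              sws_total = 123)))
  expect_equal(single$sws_fraction[single$class == "large_clump"], 100)
})

test_that("fractions close to 100 and match a brute-force sum on simulated runs", {
  run <- simulate_run(sim_params(n = 1200), seed = 4)
  cl <- classify_particles(extract_features(run$pulses))
  fr <- sws_fractions(cl)
  expect_equal(sum(fr$sws_fraction), 100, tolerance = 1e-12)
  # brute force per class
  keep <- as.character(cl$class) %in% c("hyphae", "small_clump",
                                        "large_clump", "pellet")
  denom <- sum(cl$sws_total[keep])
  for (cls in c("hyphae", "small_clump", "large_clump", "pellet")) {
    expect_equal(fr$sws_fraction[fr$class == cls],
                 100 * sum(cl$sws_total[keep & cl$class == cls]) / denom,
                 tolerance = 1e-12)
  }
})

test_that("unclassified particles enter the denominator only on request", {
  cl <- classified_toy(list(class = "pellet", sws_total = 6e4),
                       list(class = "unclassified", sws_total = 2e4))
  fr_default <- sws_fractions(cl)
  expect_equal(fr_default$sws_fraction[fr_default$class == "pellet"], 100)
  fr_incl <- sws_fractions(cl, include_unclassified = TRUE)
  expect_equal(fr_incl$sws_fraction[fr_incl$class == "pellet"], 75)
  expect_equal(sum(fr_incl$sws_fraction), 100)
})

test_that("degenerate inputs to the fractions are rejected", {
  cl <- classified_toy(list(class = "hyphae", sws_total = 0))
  expect_error(sws_fractions(cl), "positive SWS total")
})

test_that("concentration arithmetic follows count / volume x dilution", {
  m <- measurement_meta(um_per_sample = 1, pump_speed = 15, duration = 80,
                        dilution_factor = 1000)
  # 1200 ul measured: 40 counts -> 40 / 1.2 ml * 1000
  out <- class_concentrations(tibble::tibble(class = "pellet", n = 40), m)
  expect_equal(out$concentration, 40 / 1.2 * 1000)
  expect_equal(out$volume_ml, 1.2)
  # 120 counts in 15 ul/s x 80 s (1.2 ml) at 1:1000 -> exactly 1e5 per ml
  out2 <- class_concentrations(c(pellet = 120), m)
  expect_equal(out2$concentration, 1e5)
  out3 <- class_concentrations(c(pellet = 0), m)
  expect_equal(out3$concentration, 0)
})

test_that("concentration is linear in counts and dilution", {
  set.seed(5)
  for (i in 1:10) {
    n <- sample(0:500, 1); k <- sample(1:7, 1); dil <- runif(1, 1, 2000)
    m1 <- measurement_meta(um_per_sample = 1, dilution_factor = dil)
    base <- class_concentrations(c(x = n), m1)$concentration
    expect_equal(class_concentrations(c(x = k * n), m1)$concentration,
                 k * base)
    m2 <- measurement_meta(um_per_sample = 1, dilution_factor = k * dil)
    expect_equal(class_concentrations(c(x = n), m2)$concentration, k * base)
  }
  expect_error(measurement_meta(um_per_sample = 1, duration = 0), "positive")
})

test_that("replicates pool by volume weighting with an SD alongside", {
  m1 <- measurement_meta(um_per_sample = 1, duration = 60)   # 900 ul
  m2 <- measurement_meta(um_per_sample = 1, duration = 120)  # 1800 ul
  r1 <- class_concentrations(c(pellet = 45), m1)
  r2 <- class_concentrations(c(pellet = 108), m2)
  pooled <- pool_replicates(list(r1, r2))
  expect_equal(pooled$n_replicates, 2)
  w <- c(0.9, 1.8)
  expect_equal(pooled$concentration,
               sum(c(r1$concentration, r2$concentration) * w) / sum(w))
  expect_equal(pooled$concentration_sd,
               sd(c(r1$concentration, r2$concentration)))
  expect_error(pool_replicates(list(r1)), "two replicate")
})

test_that("size histograms are relative and respect class unions", {
  cl <- classified_toy(list(class = "small_clump", sws_total = 1, sl = 55),
                       list(class = "large_clump", sws_total = 1, sl = 150),
                       list(class = "pellet", sws_total = 1, sl = 250),
                       list(class = "hyphae", sws_total = 1, sl = 40))
  h_all <- size_distribution(cl, "hyphal_aggregates",
                             breaks = c(0, 100, 200, 300))
  expect_equal(sum(h_all$freq), 1)
  expect_equal(h_all$n, c(1L, 1L, 1L))
  h_large <- size_distribution(cl, "large_elements",
                               breaks = c(0, 100, 200, 300))
  expect_equal(h_large$n, c(0L, 1L, 1L))  # hyphae and small clumps excluded
  one_bin <- size_distribution(cl, "large_elements", breaks = c(0, 1000))
  expect_equal(one_bin$freq, 1)
  expect_equal(nrow(size_distribution(cl[0, ], "hyphal_aggregates")), 0)
  expect_error(size_distribution(cl, "nonsense_union"), "unknown class")
})

test_that("uniform sizes split evenly across two equal bins", {
  set.seed(8)
  n <- 1e4
  cl <- tibble::tibble(particle_id = as.character(seq_len(n)),
                       sws_total = 1,
                       sws_sample_length = runif(n, 0, 200),
                       viable = TRUE, class = factor("pellet"))
  h <- size_distribution(cl, "pellet", breaks = c(0, 100, 200))
  expect_equal(sum(h$freq), 1)
  expect_equal(h$freq[1], 0.5, tolerance = 0.03)
})

test_that("run summaries stack into a tidy time course", {
  p <- sim_params(n = 400)
  runs <- simulate_timecourse(
    tibble::tibble(timepoint = c(10, 20),
                   hyphae = c(0.5, 0.5), small_clump = c(0.2, 0.2),
                   large_clump = c(0.2, 0.2), pellet = c(0.1, 0.1)),
    p, seed = 6)
  summaries <- lapply(runs, function(r) {
    cl <- classify_particles(extract_features(r$pulses))
    pm <- pellet_metrics(r$pulses, particles = cl)
    summarize_run(cl, pulse_meta(r$pulses), pellets = pm)
  })
  tc <- morphology_timecourse(summaries)
  expect_equal(nrow(tc), 8)  # 2 timepoints x 4 classes
  expect_equal(unique(tc$timepoint), c(10, 20))
  expect_true(all(tc$concentration >= 0))
  pellet_rows <- tc[tc$class == "pellet", ]
  expect_true(all(is.finite(pellet_rows$mean_rad)))
  expect_true(all(pellet_rows$mean_compactness <= 1))
  expect_equal(nrow(morphology_timecourse(list())), 0)
})

test_that("replicate error reports mean, SD and percent CV per parameter", {
  reps <- tibble::tibble(conc = c(90, 110), rad = c(0.3, 0.3))
  err <- replicate_error(reps)
  conc_row <- err[err$parameter == "conc", ]
  expect_equal(conc_row$mean, 100)
  expect_equal(conc_row$cv_pct, sd(c(90, 110)) / 100 * 100)
  expect_equal(conc_row$cv_pct, 14.14, tolerance = 1e-3)
  expect_equal(err$cv_pct[err$parameter == "rad"], 0)
  expect_error(replicate_error(reps[1, ]), "two replicates")
  # scale invariance of the percent CV
  err10 <- replicate_error(dplyr::mutate(reps, conc = conc * 10))
  expect_equal(err10$cv_pct[err10$parameter == "conc"], conc_row$cv_pct)
})
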