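cfg <- gate_config()

test_that("the viability prefilter is strict at the green-fluorescence threshold", {
  expect_true(is_viable(feature_row(fl_green_total = 31), cfg))
  expect_false(is_viable(feature_row(fl_green_total = 30), cfg))
  expect_false(is_viable(feature_row(fl_green_total = 29.9), cfg))
  # missing channel: background under the default, viable when not required
  row_nofl <- feature_row()[setdiff(names(feature_row()), "fl_green_total")]
  expect_warning(v <- is_viable(row_nofl, cfg), "background")
  expect_false(v)
  cfg_opt <- gate_config(require_fl = FALSE)
  expect_true(is_viable(row_nofl, cfg_opt))
})

# feature rows sitting squarely inside each gate
pellet_row <- function(...) {
  do.call(feature_row, utils::modifyList(
    list(sws_total = 1.5e5, sws_sample_length = 150, fws_length = 250,
         fws_maximum = 1e4, fws_fill_factor = 0.9, fws_sample_length = 250),
    list(...)))
}
large_clump_row <- function(...) {
  do.call(feature_row, utils::modifyList(
    list(sws_total = 1.5e5, sws_sample_length = 150, fws_length = 250,
         fws_maximum = 9e3, fws_fill_factor = 0.9), list(...)))
}

class_of <- function(row, config = cfg) {
  as.character(classify_particles(row, config)$class)
}

test_that("the documented gate examples classify as published", {
  # all pellet criteria met
  expect_equal(class_of(pellet_row()), "pellet")
  # unsaturated FWS: a core is required, so this is a large clump
  expect_equal(class_of(large_clump_row()), "large_clump")
  # small element below the small-clump SWS interval: hyphae
  expect_equal(class_of(feature_row(sws_sample_length = 50, sws_total = 1e4,
                                    fws_length = 100)), "hyphae")
  # overlap region 1.8e4-4e4: the small-clump gate takes precedence
  expect_equal(class_of(feature_row(sws_sample_length = 50, sws_total = 3e4,
                                    fws_length = 100)), "small_clump")
  # non-viable particles are background regardless of geometry
  expect_equal(class_of(pellet_row(fl_green_total = 10)), "background")
})

test_that("particles on strict-inequality boundaries fall to the documented side", {
  eps <- 1e-9
  # pellet gate bounds (boundary -> large clump)
  expect_equal(class_of(pellet_row(sws_total = 4e4)), "large_clump")
  # note: within the pellet gate the SWS-total bound 4e4 is implied by the
  # ratio rule (total/sample length > 8e2 with sample length > 120 forces
  # total > 9.6e4), so crossing 4e4 alone cannot produce a pellet:
  expect_equal(class_of(pellet_row(sws_total = 4e4 + 1)), "large_clump")
  expect_equal(class_of(pellet_row(sws_sample_length = 120)), "large_clump")
  expect_equal(class_of(pellet_row(sws_sample_length = 120 + eps)), "pellet")
  expect_equal(class_of(pellet_row(fws_maximum = 7.5e3 * 1,
                                   fws_fill_factor = 1)), "large_clump")
  expect_equal(class_of(pellet_row(fws_maximum = 1e4,
                                   fws_fill_factor = 1e4 / 7.5e3)),
               "large_clump")  # ratio exactly 7.5e3
  r <- pellet_row(sws_total = 121 * 8e2, sws_sample_length = 121)
  expect_equal(r$sws_total_over_sample_length, 8e2)
  expect_equal(class_of(r), "large_clump")  # ratio exactly 8e2
  expect_equal(class_of(pellet_row(sws_total = 121 * 8e2 + 1,
                                   sws_sample_length = 121)), "pellet")
  # FWS saturation is >= the level
  expect_equal(class_of(pellet_row(fws_maximum = 1e4 - eps)), "large_clump")

  # large-element gate: both conditions must hold strictly (companion values
  # chosen outside every small gate so the boundary side is observable)
  expect_equal(class_of(feature_row(sws_total = 2e4, sws_sample_length = 160,
                                    fws_length = 200)),
               "unclassified")  # on the SWS-total boundary: small side
  expect_equal(class_of(feature_row(sws_total = 2e4 + 1,
                                    sws_sample_length = 160,
                                    fws_length = 200, fws_maximum = 5e3)),
               "large_clump")
  expect_equal(class_of(feature_row(sws_total = 9.5e4,
                                    sws_sample_length = 100,
                                    fws_length = 200)),
               "unclassified")  # on the sample-length boundary: small side
  expect_equal(class_of(feature_row(sws_total = 9.5e4,
                                    sws_sample_length = 100 + eps,
                                    fws_length = 200, fws_maximum = 5e3)),
               "large_clump")

  # hyphae bounds (strict on all four)
  expect_equal(class_of(feature_row(sws_sample_length = 10)), "unclassified")
  expect_equal(class_of(feature_row(sws_sample_length = 10 + eps)), "hyphae")
  expect_equal(class_of(feature_row(sws_sample_length = 150)), "unclassified")
  # hyphae SWS bound probed at FWS length 17 (outside the small-clump gate)
  expect_equal(class_of(feature_row(sws_total = 4e4 - 1, fws_length = 17,
                                    sws_sample_length = 99)), "hyphae")
  expect_equal(class_of(feature_row(sws_total = 4e4, fws_length = 17,
                                    sws_sample_length = 99)), "unclassified")
  expect_equal(class_of(feature_row(fws_length = 190)), "unclassified")
  expect_equal(class_of(feature_row(fws_length = 190 - eps)), "hyphae")

  # small-clump interval is open at both SWS ends and at FWS length 18
  expect_equal(class_of(feature_row(sws_total = 1.8e4, fws_length = 100,
                                    sws_sample_length = 50)), "hyphae")
  expect_equal(class_of(feature_row(sws_total = 1.8e4 + 1, fws_length = 100,
                                    sws_sample_length = 50)), "small_clump")
  expect_equal(class_of(feature_row(sws_total = 9e4, fws_length = 100,
                                    sws_sample_length = 50)), "unclassified")
  # at FWS length exactly 18 the small-clump gate closes; the element still
  # satisfies the hyphae row and falls there
  expect_equal(class_of(feature_row(sws_total = 3e4, fws_length = 18,
                                    sws_sample_length = 50)), "hyphae")
  expect_equal(class_of(feature_row(sws_total = 3e4, fws_length = 18 + eps,
                                    sws_sample_length = 50)), "small_clump")
})

test_that("undefined ratios route particles to unclassified", {
  expect_equal(class_of(pellet_row(fws_fill_factor = 0)), "unclassified")
  expect_equal(class_of(feature_row(sws_sample_length = 0)), "unclassified")
})

test_that("fallback_small = hyphae adopts leftover small elements", {
  cfg_h <- gate_config(fallback_small = "hyphae")
  row <- feature_row(sws_sample_length = 5, fws_length = 100)  # below hyphae SL
  expect_equal(class_of(row), "unclassified")
  expect_equal(class_of(row, cfg_h), "hyphae")
})

test_that("explicit gate polygons override the rectangular defaults", {
  # a polygon large gate that catches a low-SWS but very long particle
  poly <- matrix(c(100, 0, 400, 0, 400, 3e5, 100, 3e5), ncol = 2, byrow = TRUE)
  cfg_poly <- gate_config(large_gate = list(polygon = poly))
  row <- feature_row(sws_total = 1e4, sws_sample_length = 200,
                     fws_length = 210, fws_maximum = 5e3)
  expect_equal(class_of(row), "unclassified")    # rectangle: not large
  expect_equal(class_of(row, cfg_poly), "large_clump")
})

test_that("every viable particle receives exactly one class and counts add up", {
  run <- simulate_run(sim_params(n = 1500), seed = 9)
  out <- classify_run(run$pulses)
  expect_equal(nrow(out$particles), 1500)
  expect_false(any(is.na(out$particles$class)))
  expect_equal(sum(out$counts$n), sum(out$particles$viable))
  expect_equal(nlevels(out$particles$class), 6)
})

test_that("raising SWS total never demotes a qualifying pellet", {
  for (mult in c(1, 2, 5, 10, 100)) {
    expect_equal(class_of(pellet_row(sws_total = 1.5e5 * mult)), "pellet")
  }
})

test_that("simulated particles with gate margins recover their labels", {
  run <- simulate_run(sim_params(n = 3000), seed = 21)
  cl <- classify_particles(extract_features(run$pulses))
  joined <- dplyr::inner_join(run$truth, cl[c("particle_id", "class")],
                              by = "particle_id",
                              suffix = c("_truth", "_gate"))
  recovery <- mean(as.character(joined$class_gate) == joined$class_truth)
  expect_gte(recovery, 0.99)
})

test_that("empty runs classify to empty tables with zero counts", {
  run <- simulate_run(sim_params(n = 0), seed = 1)
  out <- classify_run(run$pulses)
  expect_equal(nrow(out$particles), 0)
  expect_true(all(out$counts$n == 0))
})

test_that("hierarchical 2-cluster refinement reproduces the small/large split", {
  run <- simulate_run(sim_params(n = 500), seed = 33)
  cl <- classify_particles(extract_features(run$pulses))
  ref <- refine_gates(cl, "hierarchical_average_euclidean", k = 2)
  expect_gte(group_concordance(ref), 0.95)
})

test_that("3-means separates pellets from large clumps on raw magnitudes", {
  run <- simulate_run(sim_params(n = 600), seed = 17)
  cl <- classify_particles(extract_features(run$pulses))
  ref <- refine_gates(cl, "kmeans", k = 3, transform = "identity", seed = 4)
  tab <- ref$contingency
  majority <- colnames(tab)[apply(tab, 1, which.max)]
  expect_true("pellet" %in% majority)
  expect_true("large_clump" %in% majority)
  # reproducible under the same seed
  ref2 <- refine_gates(cl, "kmeans", k = 3, transform = "identity", seed = 4)
  expect_identical(ref$cluster, ref2$cluster)
})

test_that("cluster counts outside 2..5 are rejected", {
  run <- simulate_run(sim_params(n = 50), seed = 2)
  cl <- classify_particles(extract_features(run$pulses))
  expect_error(refine_gates(cl, "kmeans", k = 6), "between 2 and 5")
  expect_error(refine_gates(cl, "kmeans", k = 1), "between 2 and 5")
})

test_that("tidy and glance summarize a refinement", {
  run <- simulate_run(sim_params(n = 200), seed = 3)
  cl <- classify_particles(extract_features(run$pulses))
  ref <- refine_gates(cl, "hierarchical_average_euclidean", k = 2)
  td <- tidy(ref)
  expect_true(all(c("cluster", "class", "n", "cluster_fraction") %in% names(td)))
  expect_equal(sum(td$n), ref$n)
  gl <- glance(ref)
  expect_equal(gl$k, 2)
  expect_true(gl$concordance >= 0 && gl$concordance <= 1)
})
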