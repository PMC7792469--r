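test_that("personalization uses the record and distributes resistances", {
  g <- make_coronary_tree(seed = 1)
  rec <- ref_record()
  m <- personalize(g, rec)
  expect_equal(max(m$waveform$samples_mmHg), 133.39, tolerance = 1e-3)
  expect_equal(min(m$waveform$samples_mmHg), 84.03)
  expect_equal(m$waveform$period, 60 / 65.19)
  # MAP and target coronary flow
  expect_equal(m$map_mmHg, 84.03 + (133.39 - 84.03) / 3)
  expect_gt(m$q_coronary_ml_s, 1)

  # two terminals with identical diameters get identical resistances
  gb <- graph_with_vein()
  gb$segments <- gb$segments[gb$segments$label != "vein", ]
  mb <- personalize(gb, rec)
  expect_equal(mb$terminals$R_mmHg_s_ml[1], mb$terminals$R_mmHg_s_ml[2])
  # Murray weighting: parallel combination equals total / target flow
  r_eq <- 1 / sum(1 / mb$terminals$R_mmHg_s_ml)
  expect_equal(r_eq, (mb$map_mmHg - 8) / mb$q_coronary_ml_s, tolerance = 1e-9)

  expect_error(patient_record("x", age = 60, sbp = 120, dbp = 80, hr = NA),
               "HR")
  expect_error(patient_record("x", age = 60, sbp = NA, dbp = 80, hr = 60),
               "SBP")
  # age brackets map to increasing wall stiffness
  cfg <- personalize_config()
  young <- personalize(g, patient_record("y", age = 40, sbp = 120, dbp = 80,
                                         hr = 60), cfg)
  old <- personalize(g, patient_record("o", age = 70, sbp = 120, dbp = 80,
                                       hr = 60), cfg)
  expect_lt(young$graph$segments$wall_speed_m_s[1],
            old$graph$segments$wall_speed_m_s[1])
})

test_that("hyperemia divides terminal resistances", {
  g <- make_coronary_tree(seed = 1)
  m <- personalize(g, ref_record())
  m1 <- induce_hyperemia(m, 1)
  expect_equal(m1$terminals$R_mmHg_s_ml, m$terminals$R_mmHg_s_ml)
  m$terminals$R_mmHg_s_ml[1] <- 70
  m2 <- induce_hyperemia(m, 3.5)
  expect_equal(m2$terminals$R_mmHg_s_ml[1], 20)
  expect_error(induce_hyperemia(m, 0.5), "factor")
})

test_that("FFR is the distal/aortic pressure ratio at the marked site", {
  # steady series circuit: stenotic tube resistance = R_t/4, P_out = 0
  mu <- 0.004
  r_s <- 128 * mu * 8e-3 / (pi * (1.2e-3)^4) / 133.322e6
  g <- single_segment_graph(diameter_mm = 1.2, length_mm = 8)
  g$segments$ffr_site <- TRUE
  term <- terminal_outlets(g, R = 4 * r_s, p_out = 0)
  sol <- solve_steady(g, term, p_in_mmHg = 100, mu = mu)
  expect_equal(compute_ffr(sol, "s1"), 0.8, tolerance = 1e-9)

  expect_error(compute_ffr(sol, "missing"), "unknown")
  g2 <- g; g2$segments$ffr_site <- FALSE
  sol2 <- solve_steady(g2, term, 100, mu = mu)
  expect_error(compute_ffr(sol2, "s1"), "not marked")
})

test_that("sequential stenoses: distal site FFR below proximal, same aorta", {
  rec <- ref_record()
  g <- make_coronary_tree(seed = 2)
  g <- apply_stenosis(g, stenosis_spec("s_LAD", 0.55, 0.3))
  g <- apply_stenosis(g, stenosis_spec("s_LADa", 0.55, 0.3))
  m <- induce_hyperemia(personalize(g, rec), 3.5)
  sol <- run_model(m, "steady")
  f_prox <- compute_ffr(sol, "s_LAD")
  f_dist <- compute_ffr(sol, "s_LADa")
  expect_lt(f_dist, f_prox)
  res <- ffr_result(sol)
  expect_equal(nrow(res$per_site), 2)
})

test_that("classification follows the strict 0.80 rule", {
  expect_true(classify_vessel(0.58))      # the worked Discussion case
  expect_false(classify_vessel(0.80))     # exactly at threshold: negative
  expect_true(classify_patient(c(0.41, 0.88, 0.81)))
  expect_false(classify_patient(c(0.85, 0.92)))
  expect_error(classify_patient(numeric(0)), "empty")
  expect_error(classify_vessel(1.5), "0, 1.2")
  expect_error(classify_vessel(0), "0, 1.2")
  # threshold consistency over a grid
  xs <- seq(0.05, 1.15, by = 0.05)
  expect_identical(classify_vessel(xs), xs < 0.8)
})

test_that("FFR monotonicity and hyperemia direction (steady fast mode)", {
  rec <- ref_record()
  ffr_at <- function(red, factor = 3.5) {
    g <- make_coronary_tree(seed = 2)
    g <- apply_stenosis(g, stenosis_spec("s_LAD", max(red, 1e-9), 0.3))
    m <- induce_hyperemia(personalize(g, rec), factor)
    compute_ffr(run_model(m, "steady"), "s_LAD")
  }
  f <- vapply(seq(0, 0.9, by = 0.1), ffr_at, 1)
  expect_true(all(diff(f) < 0))
  expect_true(all(f > 0 & f <= 1.02))
  # stronger hyperemia lowers FFR of a stenosed tree
  expect_lt(ffr_at(0.6, 3.5), ffr_at(0.6, 1.5))
})
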