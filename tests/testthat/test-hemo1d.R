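test_that("inflow waveform has the prescribed extremes, period and mean", {
  w <- build_inflow_waveform(120, 80, 60)
  expect_equal(w$period, 1.0)
  expect_equal(max(w$samples_mmHg), 120, tolerance = 1e-3)
  expect_equal(min(w$samples_mmHg), 80)
  # time mean ~ DBP + PP/3 within 1%
  expect_lt(abs(mean(w$samples_mmHg) - (80 + 40 / 3)) / (80 + 40 / 3), 0.01)

  # study-population heart rate
  w2 <- build_inflow_waveform(133.39, 84.03, 65.19)
  expect_equal(w2$period, 60 / 65.19, tolerance = 1e-12)
  expect_equal(w2$period, 0.9204, tolerance = 1e-4)

  expect_error(build_inflow_waveform(80, 80, 60), "sbp")
  expect_error(build_inflow_waveform(120, 80, 0), "hr")
})

test_that("steady network solve matches the Poiseuille closed form", {
  g <- single_segment_graph(diameter_mm = 3, length_mm = 10)
  # fix both end pressures via a huge-resistance-free construction:
  # terminal R chosen so the end-to-end drop is exactly 10 mmHg
  mu <- 0.004
  r_seg <- 128 * mu * 10e-3 / (pi * (3e-3)^4) / 133.322e6   # mmHg s/mL
  q_expect <- 10 / r_seg                                     # end-to-end 10
  term <- terminal_outlets(g, R = r_seg * 8.2, p_out = 8)    # arbitrary R
  sol <- solve_steady(g, term, p_in_mmHg = 100, mu = mu)
  drop <- sol$node_pressure_mmHg[["n_root"]] - sol$node_pressure_mmHg[["n_tip"]]
  expect_equal(unname(sol$seg_flow_ml_s["s1"]), drop / r_seg,
               tolerance = 1e-9)

  # symmetric bifurcation: equal daughter flows
  gb <- graph_with_vein()
  gb$segments <- gb$segments[gb$segments$label != "vein", ]
  term <- terminal_outlets(gb, R = 50, p_out = 8)
  sb <- solve_steady(gb, term, 100)
  expect_equal(unname(sb$seg_flow_ml_s["b1"]), unname(sb$seg_flow_ml_s["b2"]),
               tolerance = 1e-9)
  # Kirchhoff balance at the junction
  expect_equal(unname(sb$seg_flow_ml_s["trunk"]),
               unname(sb$seg_flow_ml_s["b1"] + sb$seg_flow_ml_s["b2"]),
               tolerance = 1e-9)

  # inflow pressure equal to every outflow pressure -> zero flow
  s0 <- solve_steady(gb, terminal_outlets(gb, R = 50, p_out = 8), 8)
  expect_true(all(abs(s0$seg_flow_ml_s) < 1e-12))
})

test_that("unsteady solve under constant inflow matches the steady oracle", {
  rec <- ref_record()
  for (sd in c(2, 9)) {
    g <- make_coronary_tree(seed = sd)
    m <- personalize(g, rec)
    st <- run_model(m, "steady")
    un <- solve_unsteady(m$graph, m$terminals, m$map_mmHg,
                         numerical_config(n_cycles = 10))
    nodes <- names(un$node_pressure_mmHg)
    rel <- abs(st$node_pressure_mmHg[nodes] - un$node_pressure_mmHg) /
      st$node_pressure_mmHg[nodes]
    expect_lt(max(rel), 0.02)
    expect_lt(un$mass_residual, 1e-6)
    # conservation: inflow equals total terminal outflow over the cycle
    qin <- sum(un$seg_flow_ml_s[m$graph$segments$id[
      m$graph$segments$from %in% m$graph$ostia]])
    qout <- sum(un$seg_flow_ml_s[m$graph$segments$id[
      m$graph$segments$to %in% m$terminals$node]])
    expect_lt(abs(qin - qout) / qin, 0.005)
  }
})

test_that("pressures stay within physical bounds under pulsatile inflow", {
  rec <- ref_record()
  g <- make_coronary_tree(seed = 3)
  m <- personalize(g, rec)
  un <- run_model(m, "unsteady", numerical_config(n_cycles = 8))
  pmax_in <- rec$sbp
  for (sg in un$segments) {
    expect_true(all(is.finite(sg$p_mmHg)))
    expect_lt(max(sg$p_mmHg), pmax_in * 1.05)
    expect_gt(min(sg$p_mmHg), 0)
    expect_true(all(sg$A_mm2 > 0))
  }
})

test_that("numerical contracts are enforced", {
  expect_error(numerical_config(cfl = 1.2), "CFL")
  expect_error(numerical_config(cfl = 0), "CFL")
  g <- single_segment_graph()
  gz <- g; gz$segments$effective_diameter_mm <- 0
  expect_error(solve_steady(gz, terminal_outlets(g, 50), 100), "singular|diameter")
  # non-convergence is reported, not silent
  term <- terminal_outlets(g, 50, 8)
  w <- build_inflow_waveform(120, 80, 60)
  expect_warning(solve_unsteady(g, term, w,
                                numerical_config(n_cycles = 1,
                                                 tolerance_mmHg = 1e-9)),
                 "convergence")
})

test_that("flow solutions roundtrip through the array export", {
  g <- single_segment_graph(3, 15)
  sol <- solve_unsteady(g, terminal_outlets(g, 60, 8),
                        build_inflow_waveform(120, 80, 70),
                        numerical_config(n_cycles = 6))
  tp <- withr::local_tempfile()
  write_flow_solution(sol, tp)
  back <- read_flow_solution(tp)
  expect_equal(back$segments[[1]]$p_mean_mmHg, sol$segments$s1$p_mean_mmHg,
               tolerance = 1e-6)
  expect_lt(max(abs(back$segments[[1]]$p_mmHg - sol$segments$s1$p_mmHg)),
            1e-3)
})
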