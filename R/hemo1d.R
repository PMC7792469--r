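#' @useDynLib coroflow, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# 1 mmHg in Pa
.MMHG <- 133.322
# 1 mmHg*s/mL in Pa*s/m^3
.RUNIT <- .MMHG * 1e6

#' Aortic inflow pressure waveform
#'
#' Periodic two-phase template: a smooth squared-sine systolic ejection
#' occupying two thirds of the cycle, followed by a diastolic baseline at
#' DBP.  By construction the maximum is SBP, the minimum DBP, and the time
#' mean equals the classical estimate DBP + (SBP - DBP)/3.
#'
#' @param sbp,dbp systolic / diastolic pressure, mmHg (sbp > dbp > 0).
#' @param hr heart rate, beats per minute.
#' @param n_samples samples per period.
#' @return object of class `waveform`: `period` (s), `samples_mmHg`
#'   (pressure at uniformly spaced phases), and the generating parameters.
#' @examples
#' w <- build_inflow_waveform(120, 80, 60)
#' w$period            # 1.0 s
#' mean(w$samples_mmHg)  # ~93.3 mmHg
#' @export
build_inflow_waveform <- function(sbp, dbp, hr, n_samples = 200) {
  if (!is.finite(sbp) || !is.finite(dbp) || !is.finite(hr))
    stop("sbp, dbp and hr must be finite numbers")
  if (dbp <= 0) stop("dbp must be positive")
  if (sbp <= dbp) stop("sbp must exceed dbp")
  if (hr <= 0) stop("hr must be positive")
  fs <- 2 / 3                      # systolic fraction; mean shape = fs/2 = 1/3
  phi <- (seq_len(n_samples) - 1) / n_samples
  shape <- ifelse(phi < fs, sin(pi * phi / fs)^2, 0)
  structure(list(period = 60 / hr,
                 samples_mmHg = dbp + (sbp - dbp) * shape,
                 sbp = sbp, dbp = dbp, hr = hr),
            class = "waveform")
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform> period %.4f s, %g/%g mmHg, mean %.2f mmHg\n",
              x$period, x$sbp, x$dbp, mean(x$samples_mmHg)))
  invisible(x)
}

#' Numerical configuration for the unsteady solver
#'
#' @param dx_mm target grid spacing along each segment, mm.
#' @param cfl Courant number, must lie in (0, 1).
#' @param n_cycles maximum number of cardiac cycles to run.
#' @param rho blood density, kg/m^3.
#' @param mu dynamic viscosity, Pa s.
#' @param p_out_mmHg default venous outflow pressure.
#' @param tolerance_mmHg periodic-convergence tolerance on the
#'   cycle-to-cycle change of pointwise cycle-mean pressure.
#' @param n_out number of output phases per cycle.
#' @return list of class `numerical_config`.
#' @export
numerical_config <- function(dx_mm = 1, cfl = 0.8, n_cycles = 5, rho = 1060,
                             mu = 0.004, p_out_mmHg = 8,
                             tolerance_mmHg = 0.1, n_out = 64) {
  if (!is.finite(cfl) || cfl <= 0 || cfl >= 1)
    stop("CFL number must lie strictly inside (0, 1)")
  if (dx_mm <= 0) stop("dx_mm must be positive")
  if (n_cycles < 1) stop("n_cycles must be >= 1")
  structure(list(dx_mm = dx_mm, cfl = cfl, n_cycles = as.integer(n_cycles),
                 rho = rho, mu = mu, p_out_mmHg = p_out_mmHg,
                 tolerance_mmHg = tolerance_mmHg, n_out = as.integer(n_out)),
            class = "numerical_config")
}

#' Terminal outlet table
#'
#' One resistive (Windkessel-type) outlet per terminal node:
#' `Q = (p - p_out) / R`.
#'
#' @param graph a `vessel_graph` (used to locate terminal nodes).
#' @param R terminal resistance(s), mmHg s/mL; recycled over terminals.
#' @param p_out outflow pressure, mmHg.
#' @return data.frame with columns `node`, `R_mmHg_s_ml`, `p_out_mmHg`.
#' @export
terminal_outlets <- function(graph, R, p_out = 8) {
  tn <- .terminal_nodes(graph)
  if (any(R <= 0)) stop("terminal resistance must be positive")
  data.frame(node = tn, R_mmHg_s_ml = rep(R, length.out = length(tn)),
             p_out_mmHg = rep(p_out, length.out = length(tn)),
             stringsAsFactors = FALSE)
}

.model_segments <- function(graph) {
  sg <- graph$segments[graph$segments$label != "vein", , drop = FALSE]
  if (!nrow(sg)) stop("graph has no arterial segments")
  sg
}

.terminal_nodes <- function(graph) {
  sg <- .model_segments(graph)
  ids <- unique(c(sg$from, sg$to))
  ids[!(ids %in% sg$from) & !(ids %in% graph$ostia)]
}

#' Steady Poiseuille network solve
#'
#' Linear resistive-network model used both as a fast FFR mode and as an
#' independent oracle for the unsteady solver: each segment carries a
#' Poiseuille conductance g = pi D^4 / (128 mu L), terminals are resistive
#' outlets, and nodal pressures solve the Kirchhoff balance exactly.
#'
#' @param graph a validated `vessel_graph`.
#' @param terminals a [terminal_outlets()] table covering every terminal.
#' @param p_in_mmHg inflow pressure prescribed at the ostia.
#' @param mu blood viscosity, Pa s.
#' @return object of class `c("steady_solution", "flow_solution")` with
#'   named `node_pressure_mmHg` and `seg_flow_ml_s`.
#' @export
solve_steady <- function(graph, terminals, p_in_mmHg, mu = 0.004) {
  sg <- .model_segments(graph)
  nodes <- unique(c(sg$from, sg$to, graph$ostia))
  ni <- stats::setNames(seq_along(nodes), nodes)
  D <- sg$effective_diameter_mm * 1e-3
  L <- sg$length_mm * 1e-3
  if (any(D <= 0)) stop("singular network: zero-diameter segment")
  g <- pi * D^4 / (128 * mu * L)                    # m^3 s^-1 Pa^-1
  n <- length(nodes)
  A <- matrix(0, n, n)
  b <- numeric(n)
  for (i in seq_len(nrow(sg))) {
    a <- ni[[sg$from[i]]]; z <- ni[[sg$to[i]]]
    A[a, a] <- A[a, a] + g[i]; A[z, z] <- A[z, z] + g[i]
    A[a, z] <- A[a, z] - g[i]; A[z, a] <- A[z, a] - g[i]
  }
  tn <- .terminal_nodes(graph)
  miss <- setdiff(tn, terminals$node)
  if (length(miss)) stop("terminal node(s) without outlet: ",
                         paste(miss, collapse = ", "))
  for (i in seq_len(nrow(terminals))) {
    k <- ni[[terminals$node[i]]]
    if (is.null(k)) next
    gt <- 1 / (terminals$R_mmHg_s_ml[i] * .RUNIT)
    A[k, k] <- A[k, k] + gt
    b[k] <- b[k] + gt * terminals$p_out_mmHg[i] * .MMHG
  }
  for (o in graph$ostia) {
    k <- ni[[o]]
    A[k, ] <- 0; A[k, k] <- 1
    b[k] <- rep(p_in_mmHg, length.out = length(graph$ostia))[
      match(o, graph$ostia)] * .MMHG
  }
  p <- tryCatch(solve(A, b), error = function(e) stop("singular network"))
  q <- g * (p[ni[sg$from]] - p[ni[sg$to]]) * 1e6     # mL/s
  structure(list(graph = graph,
                 node_pressure_mmHg = stats::setNames(p / .MMHG, nodes),
                 seg_flow_ml_s = stats::setNames(q, sg$id),
                 p_in_mmHg = p_in_mmHg, terminals = terminals,
                 converged = TRUE, method = "steady"),
            class = c("steady_solution", "flow_solution"))
}

#' Unsteady 1D pulse-wave solve
#'
#' Advances the 1D mass/momentum equations of an elastic-tube network
#' (linear tube law `p = p_ext + rho c0^2 (A/A0 - 1)`, Poiseuille wall
#' friction) with an explicit second-order MacCormack scheme and
#' characteristic boundary treatment: prescribed pressure at the ostia,
#' resistive terminals, and junction coupling enforcing mass conservation
#' and continuity of total pressure.  The run stops at periodic convergence
#' (cycle-to-cycle change of pointwise cycle-mean pressure below tolerance)
#' or after `n_cycles` cycles, in which case non-convergence is reported
#' with a warning and flagged on the result.
#'
#' @param graph a validated `vessel_graph`; edges oriented ostium-outward.
#' @param terminals a [terminal_outlets()] table.
#' @param waveform a [build_inflow_waveform()] result, or a single number
#'   (mmHg) for constant inflow pressure.
#' @param config a [numerical_config()].
#' @return object of class `flow_solution`: cycle-mean `node_pressure_mmHg`,
#'   per-segment cycle-mean profiles and final-cycle snapshots of pressure
#'   (mmHg), velocity (m/s) and area (mm^2), plus `converged`,
#'   `mass_residual` and timing diagnostics.
#' @export
solve_unsteady <- function(graph, terminals, waveform,
                           config = numerical_config()) {
  if (!inherits(config, "numerical_config"))
    stop("config must be created by numerical_config()")
  ok <- validate_graph(graph)
  if (!ok$pass) stop("invalid graph: ", paste(ok$violations, collapse = "; "))
  sg <- .model_segments(graph)
  nodes <- unique(c(sg$from, sg$to, graph$ostia))
  ni <- stats::setNames(seq_along(nodes), nodes)
  if (is.numeric(waveform) && length(waveform) == 1) {
    wf_samples <- waveform
    period <- 1.0
  } else if (inherits(waveform, "waveform")) {
    wf_samples <- waveform$samples_mmHg
    period <- waveform$period
  } else stop("waveform must be a waveform object or a single pressure")
  node_type <- integer(length(nodes)) + 1L          # default junction
  node_type[ni[graph$ostia]] <- 0L
  tn <- .terminal_nodes(graph)
  node_type[ni[tn]] <- 2L
  miss <- setdiff(tn, terminals$node)
  if (length(miss)) stop("terminal node(s) without outlet: ",
                         paste(miss, collapse = ", "))
  if (any(sg$to %in% graph$ostia) || any(sg$from %in% tn))
    stop("edges must be oriented from ostium outward")
  term_R <- term_P <- rep(NA_real_, length(nodes))
  for (i in seq_len(nrow(terminals))) {
    k <- ni[[terminals$node[i]]]
    if (is.null(k)) next
    term_R[k] <- terminals$R_mmHg_s_ml[i] * .RUNIT
    term_P[k] <- terminals$p_out_mmHg[i] * .MMHG
  }
  if (any(node_type == 2L & !is.finite(term_R)))
    stop("terminal resistance missing")
  L <- sg$length_mm * 1e-3
  A0 <- pi * (sg$effective_diameter_mm * 1e-3)^2 / 4
  nx <- pmax(3L, as.integer(ceiling(sg$length_mm / config$dx_mm)) + 1L)
  res <- cf_solve1d(
    seg_from = ni[sg$from] - 1L, seg_to = ni[sg$to] - 1L,
    seg_L = L, seg_A0 = A0, seg_c0 = sg$wall_speed_m_s, seg_nx = nx,
    node_type = node_type, term_R = term_R, term_Pout = term_P,
    inflow = wf_samples * .MMHG, period = period, rho = config$rho,
    mu = config$mu, pext = min(wf_samples) * .MMHG, cfl = config$cfl,
    n_cycles = config$n_cycles, conv_tol = config$tolerance_mmHg * .MMHG,
    n_out = config$n_out)
  if (!res$converged)
    warning(sprintf(paste0("unsteady solve did not reach periodic ",
                           "convergence in %d cycles (last cycle-mean ",
                           "pressure change %.3g mmHg)"),
                    res$cycles_run, res$cycle_delta_p / .MMHG))
  seg_out <- lapply(seq_len(nrow(sg)), function(s) list(
    p_mean_mmHg = res$seg_p_mean[[s]] / .MMHG,
    u_mean_m_s = res$seg_u_mean[[s]],
    A_mean_mm2 = res$seg_A_mean[[s]] * 1e6,
    p_mmHg = res$snap_p[[s]] / .MMHG,
    u_m_s = res$snap_u[[s]],
    A_mm2 = res$snap_A[[s]] * 1e6,
    x_mm = seq(0, sg$length_mm[s], length.out = nx[s])))
  names(seg_out) <- sg$id
  q <- vapply(seq_len(nrow(sg)), function(s) {
    pr <- seg_out[[s]]
    mean(pr$u_mean_m_s * pr$A_mean_mm2) * 1e-6 * 1e6  # m/s * m^2 -> mL/s
  }, 1)
  structure(list(graph = graph,
                 node_pressure_mmHg = stats::setNames(res$node_p_mean / .MMHG,
                                                      nodes),
                 seg_flow_ml_s = stats::setNames(q, sg$id),
                 segments = seg_out,
                 phase = seq(0, period, length.out = config$n_out + 1)[
                   seq_len(config$n_out)],
                 converged = res$converged, cycles_run = res$cycles_run,
                 mass_residual = res$mass_residual, dt_min = res$dt_min,
                 cycle_delta_p_mmHg = res$cycle_delta_p / .MMHG,
                 n_steps = res$n_steps, method = "unsteady"),
            class = "flow_solution")
}

#' Export / import a flow solution
#'
#' Final-cycle snapshot arrays are written as raw float32 (gzip) with a
#' JSON index describing segments, grids and units; cycle-mean summaries
#' live in the index itself.
#'
#' @param sol an unsteady `flow_solution`.
#' @param path output prefix; writes `<path>.json` and `<path>.bin.gz`.
#' @return the path (write) or a list with the index and arrays (read).
#' @export
write_flow_solution <- function(sol, path) {
  stopifnot(inherits(sol, "flow_solution"), !is.null(sol$segments))
  index <- list(schema_version = 1,
                node_pressure_mmHg = as.list(sol$node_pressure_mmHg),
                phase_s = sol$phase, converged = sol$converged,
                segments = lapply(names(sol$segments), function(id) {
                  sg <- sol$segments[[id]]
                  list(id = id, nx = length(sg$x_mm), x_mm = sg$x_mm,
                       p_mean_mmHg = sg$p_mean_mmHg,
                       u_mean_m_s = sg$u_mean_m_s)
                }),
                arrays = c("p_mmHg", "u_m_s", "A_mm2"),
                dtype = "float32")
  con <- gzfile(paste0(path, ".bin.gz"), "wb")
  for (sg in sol$segments)
    for (nm in c("p_mmHg", "u_m_s", "A_mm2"))
      writeBin(as.numeric(sg[[nm]]), con, size = 4)
  close(con)
  jsonlite::write_json(index, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_flow_solution
#' @export
read_flow_solution <- function(path) {
  index <- jsonlite::fromJSON(paste0(path, ".json"), simplifyVector = FALSE)
  con <- gzfile(paste0(path, ".bin.gz"), "rb")
  on.exit(close(con))
  n_out <- length(index$phase_s)
  segs <- lapply(index$segments, function(si) {
    out <- list(id = si$id, x_mm = unlist(si$x_mm),
                p_mean_mmHg = unlist(si$p_mean_mmHg),
                u_mean_m_s = unlist(si$u_mean_m_s))
    for (nm in unlist(index$arrays))
      out[[nm]] <- matrix(readBin(con, "numeric", n_out * si$nx, size = 4),
                          n_out, si$nx)
    out
  })
  list(index = index, segments = segs)
}

#' @export
print.flow_solution <- function(x, ...) {
  cat(sprintf("<flow_solution: %s> %d nodes, %d segments%s\n",
              x$method, length(x$node_pressure_mmHg),
              length(x$seg_flow_ml_s),
              if (identical(x$method, "unsteady"))
                sprintf(", %s after %d cycle(s)",
                        if (x$converged) "converged" else "NOT converged",
                        x$cycles_run) else ""))
  invisible(x)
}
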