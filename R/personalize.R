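#' Patient record
#'
#' The routine clinical fields used to personalize the model: brachial
#' pressures and heart rate measured at the time of the CT scan, plus
#' anthropometrics for the cardiac-output estimate.
#'
#' @param id patient identifier.
#' @param age years.
#' @param sex `"m"` or `"f"` (informational).
#' @param height_cm,weight_kg anthropometrics; may be `NA`.
#' @param sbp,dbp systolic/diastolic pressure, mmHg; required, sbp > dbp.
#' @param hr heart rate, bpm; required, > 0.
#' @param history named list of flags (`mi`, `pci`, `smoking`).
#' @return list of class `patient_record` (includes derived `bmi`).
#' @export
patient_record <- function(id, age, sex = NA, height_cm = NA, weight_kg = NA,
                           sbp, dbp, hr,
                           history = list(mi = FALSE, pci = FALSE,
                                          smoking = FALSE)) {
  if (missing(sbp) || missing(dbp) || is.na(sbp) || is.na(dbp))
    stop("patient record missing SBP/DBP")
  if (missing(hr) || is.na(hr)) stop("patient record missing HR")
  if (sbp <= dbp) stop("SBP must exceed DBP")
  if (hr <= 0) stop("HR must be positive")
  bmi <- if (is.na(height_cm) || is.na(weight_kg)) NA_real_
         else weight_kg / (height_cm / 100)^2
  structure(list(id = as.character(id), age = age, sex = sex,
                 height_cm = height_cm, weight_kg = weight_kg, bmi = bmi,
                 sbp = sbp, dbp = dbp, hr = hr, history = history),
            class = "patient_record")
}

#' Read patient records from CSV
#'
#' Columns: `id, age, sex, height_cm, weight_kg, sbp, dbp, hr` and optional
#' flag columns `mi, pci, smoking` (0/1).
#'
#' @param path CSV file.
#' @return list of [patient_record()] objects.
#' @export
read_patient_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(i) {
    r <- df[i, ]
    gv <- function(nm, default = NA) if (nm %in% names(r)) r[[nm]] else default
    patient_record(id = r$id, age = gv("age"), sex = gv("sex"),
                   height_cm = gv("height_cm"), weight_kg = gv("weight_kg"),
                   sbp = r$sbp, dbp = r$dbp, hr = r$hr,
                   history = list(mi = isTRUE(gv("mi", 0) == 1),
                                  pci = isTRUE(gv("pci", 0) == 1),
                                  smoking = isTRUE(gv("smoking", 0) == 1)))
  })
}

#' Personalization configuration
#'
#' @param c0_by_age wall characteristic speed (m/s) per age bracket:
#'   under 50, 50-65, over 65.  Arterial stiffness rises with age; the
#'   defaults span the range typical of muscular arteries.
#' @param coronary_flow_fraction fraction of cardiac output perfusing the
#'   coronary circulation at baseline (default 0.04).
#' @param cardiac_index_l_min_m2 cardiac index used with the Du Bois body
#'   surface area when height/weight are available.
#' @param default_co_l_min fallback cardiac output when anthropometrics are
#'   missing (scaled by HR/70).
#' @param hyperemia_factor default microvascular resistance drop under
#'   papaverine-level hyperemia.
#' @param p_out_mmHg venous outflow pressure.
#' @param murray_exponent exponent of the diameter law used to distribute
#'   terminal resistances.
#' @return list of class `personalize_config`.
#' @export
personalize_config <- function(c0_by_age = c(under50 = 8, age50to65 = 10,
                                             over65 = 12),
                               coronary_flow_fraction = 0.04,
                               cardiac_index_l_min_m2 = 3.0,
                               default_co_l_min = 5.0,
                               hyperemia_factor = 3.5,
                               p_out_mmHg = 8, murray_exponent = 3) {
  structure(as.list(environment()), class = "personalize_config")
}

.c0_for_age <- function(age, cfg) {
  if (is.na(age)) return(cfg$c0_by_age[["age50to65"]])
  if (age < 50) cfg$c0_by_age[["under50"]]
  else if (age <= 65) cfg$c0_by_age[["age50to65"]]
  else cfg$c0_by_age[["over65"]]
}

#' Personalize the haemodynamic model for a patient
#'
#' Builds the inflow waveform from SBP/DBP/HR, assigns the wall
#' characteristic speed from the age bracket, and closes the terminals:
#' resistances are distributed in proportion to D^-murray_exponent of the
#' terminal segment diameters (so flow splits follow Murray's law) and
#' scaled so that total baseline coronary flow at mean arterial pressure
#' equals `coronary_flow_fraction` of the estimated cardiac output.
#'
#' @param graph a validated arterial `vessel_graph`.
#' @param record a [patient_record()].
#' @param config a [personalize_config()].
#' @return object of class `ffr_model`: the graph (with personalized wall
#'   speeds), waveform, terminal table, target flows and the configuration.
#' @export
personalize <- function(graph, record, config = personalize_config()) {
  stopifnot(inherits(record, "patient_record"),
            inherits(config, "personalize_config"))
  ok <- validate_graph(graph)
  if (!ok$pass) stop("invalid graph: ", paste(ok$violations, collapse = "; "))
  wf <- build_inflow_waveform(record$sbp, record$dbp, record$hr)
  c0 <- .c0_for_age(record$age, config)
  graph$segments$wall_speed_m_s <- c0
  map <- record$dbp + (record$sbp - record$dbp) / 3
  co_l_min <- if (!is.na(record$height_cm) && !is.na(record$weight_kg)) {
    bsa <- 0.007184 * record$height_cm^0.725 * record$weight_kg^0.425
    config$cardiac_index_l_min_m2 * bsa
  } else {
    config$default_co_l_min * record$hr / 70
  }
  q_cor <- config$coronary_flow_fraction * co_l_min * 1000 / 60   # mL/s
  tn <- .terminal_nodes(graph)
  sg <- .model_segments(graph)
  d_term <- sg$reference_diameter_mm[match(tn, sg$to)]
  w <- d_term^config$murray_exponent
  w <- w / sum(w)
  r_total <- (map - config$p_out_mmHg) / q_cor                    # mmHg s/mL
  terminals <- data.frame(node = tn, R_mmHg_s_ml = r_total / w,
                          p_out_mmHg = config$p_out_mmHg,
                          stringsAsFactors = FALSE)
  structure(list(graph = graph, record = record, waveform = wf,
                 terminals = terminals, map_mmHg = map,
                 q_coronary_ml_s = q_cor, config = config,
                 hyperemia_factor = 1),
            class = "ffr_model")
}

#' @export
print.ffr_model <- function(x, ...) {
  cat(sprintf(paste0("<ffr_model> patient %s: MAP %.1f mmHg, target flow ",
                     "%.2f mL/s, %d terminal(s), hyperemia x%.2g\n"),
              x$record$id, x$map_mmHg, x$q_coronary_ml_s,
              nrow(x$terminals), x$hyperemia_factor))
  invisible(x)
}

#' Induce hyperemia
#'
#' Models maximal microvascular vasodilation (clinically: intracoronary
#' papaverine) by dividing every terminal resistance by `factor`.
#'
#' @param model an [personalize()] result.
#' @param factor resistance drop, >= 1 (default 3.5).
#' @return the modified `ffr_model`.
#' @export
induce_hyperemia <- function(model, factor = 3.5) {
  stopifnot(inherits(model, "ffr_model"))
  if (!is.finite(factor) || factor < 1) stop("hyperemia factor must be >= 1")
  model$terminals$R_mmHg_s_ml <- model$terminals$R_mmHg_s_ml / factor
  model$hyperemia_factor <- model$hyperemia_factor * factor
  model
}

#' Run the haemodynamic model
#'
#' @param model an `ffr_model`.
#' @param method `"unsteady"` (1D pulse-wave solve) or `"steady"`
#'   (Poiseuille network at mean arterial pressure; fast mode).
#' @param config a [numerical_config()] for the unsteady method.
#' @return a `flow_solution`.
#' @export
run_model <- function(model, method = c("unsteady", "steady"),
                      config = numerical_config()) {
  stopifnot(inherits(model, "ffr_model"))
  method <- match.arg(method)
  if (method == "steady")
    solve_steady(model$graph, model$terminals, model$map_mmHg,
                 mu = config$mu)
  else
    solve_unsteady(model$graph, model$terminals, model$waveform, config)
}

#' Compute FFR at a marked site
#'
#' FFR is the ratio of the cycle-averaged pressure at the distal end of the
#' stenotic edge to the cycle-averaged aortic (ostial) pressure, both under
#' hyperemia.  Sites are the graph edges flagged `ffr_site`; each site is
#' assessed individually (sequential stenoses each get their own value
#' against the same aortic numerator).
#'
#' @param solution a converged `flow_solution`.
#' @param site segment id of a marked stenotic edge.
#' @return the FFR value.
#' @export
compute_ffr <- function(solution, site) {
  stopifnot(inherits(solution, "flow_solution"))
  if (!isTRUE(solution$converged))
    stop("solution not converged; cannot compute FFR")
  g <- solution$graph
  i <- match(site, g$segments$id)
  if (is.na(i)) stop("unknown segment id: ", site)
  if (!isTRUE(g$segments$ffr_site[i]))
    stop("site not marked as FFR site: ", site)
  distal <- g$segments$to[i]
  root <- .component_root(g, distal)
  pa <- solution$node_pressure_mmHg[[root]]
  pd <- solution$node_pressure_mmHg[[distal]]
  pd / pa
}

.component_root <- function(graph, node) {
  sg <- .model_segments(graph)
  v <- node
  repeat {
    up <- sg$from[sg$to == v]
    if (!length(up)) break
    v <- up[1]
  }
  if (!(v %in% graph$ostia)) stop("site not connected to an ostium")
  v
}

#' FFR results for all marked sites
#'
#' @param solution a converged `flow_solution` on a graph with marked sites.
#' @param threshold ischemia threshold (strict `<`).
#' @return object of class `ffr_result`: per-site table (site, vessel,
#'   ffr), per-vessel table (minimum FFR over the vessel's sites and the
#'   ischemia call), and the per-patient call.
#' @export
ffr_result <- function(solution, threshold = 0.8) {
  g <- solution$graph
  sites <- g$segments$id[g$segments$ffr_site]
  if (!length(sites)) stop("no FFR sites marked on graph")
  vessel <- g$segments$vessel[g$segments$ffr_site]
  vessel[is.na(vessel)] <- sites[is.na(vessel)]
  ffr <- vapply(sites, function(s) compute_ffr(solution, s), 1)
  per_site <- data.frame(site = sites, vessel = vessel, ffr = ffr,
                         stringsAsFactors = FALSE, row.names = NULL)
  agg <- stats::aggregate(ffr ~ vessel, per_site, min)
  agg$ischemic <- vapply(agg$ffr, classify_vessel, TRUE, threshold = threshold)
  structure(list(per_site = per_site, per_vessel = agg,
                 patient_ischemic = classify_patient(agg$ffr, threshold),
                 threshold = threshold),
            class = "ffr_result")
}

#' @export
print.ffr_result <- function(x, ...) {
  cat(sprintf("<ffr_result> threshold %.2f, patient %s\n", x$threshold,
              if (x$patient_ischemic) "ISCHEMIC" else "non-ischemic"))
  print(x$per_vessel, row.names = FALSE)
  invisible(x)
}

#' Ischemia classification
#'
#' A vessel is called ischemic iff its FFR is strictly below the threshold
#' (an FFR of exactly 0.80 is negative); a patient is ischemic iff at least
#' one vessel is.
#'
#' @param ffr vessel FFR value(s) in (0, 1.2].
#' @param threshold decision threshold (default 0.80).
#' @return logical.
#' @export
classify_vessel <- function(ffr, threshold = 0.8) {
  if (any(!is.finite(ffr)) || any(ffr <= 0) || any(ffr > 1.2))
    stop("FFR values must lie in (0, 1.2]")
  ffr < threshold
}

#' @rdname classify_vessel
#' @param vessel_ffrs FFR values of all interrogated vessels of one patient.
#' @export
classify_patient <- function(vessel_ffrs, threshold = 0.8) {
  if (!length(vessel_ffrs)) stop("empty vessel list for patient")
  any(classify_vessel(vessel_ffrs, threshold))
}

#' End-to-end virtual FFR for one patient
#'
#' [personalize()] then [induce_hyperemia()] then [run_model()] then
#' [ffr_result()].
#'
#' @param graph arterial `vessel_graph` with marked stenosis sites.
#' @param record a [patient_record()].
#' @param method solver mode, see [run_model()].
#' @param hyperemia_factor resistance drop under hyperemia.
#' @param config [numerical_config()] for the unsteady mode.
#' @param pconfig [personalize_config()].
#' @param threshold ischemia threshold.
#' @return an `ffr_result`.
#' @export
ffr_pipeline <- function(graph, record, method = "steady",
                         hyperemia_factor = 3.5,
                         config = numerical_config(),
                         pconfig = personalize_config(), threshold = 0.8) {
  model <- personalize(graph, record, pconfig)
  model <- induce_hyperemia(model, hyperemia_factor)
  sol <- run_model(model, method, config)
  ffr_result(sol, threshold)
}
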