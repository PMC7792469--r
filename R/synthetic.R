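# Synthetic world: coronary trees, CTA-like voxel phantoms with the
# artefacts real scans show (vein contamination, calcification), and paired
# virtual/invasive cohorts.  All generators are pure functions of their
# arguments and a seed; the global RNG state is preserved.

.with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Generate a synthetic coronary tree
#'
#' A planar-fan binary tree emulating a left coronary system: the trunk
#' (left main) leaves the ostium, then bifurcates; daughter diameters
#' follow Murray's law, `d_parent^m = d_1^m + d_2^m` with a random flow
#' split, so every junction satisfies the diameter law exactly.  Branching
#' stops at `n_generations` or when a daughter would fall below
#' `min_diameter_mm` (the minimum calibre the method models).  Daughter
#' directions partition the parent's angular sector, which keeps branches
#' from colliding when rasterized.
#'
#' @param seed integer seed; identical seeds give identical graphs.
#' @param n_generations maximum bifurcation depth (>= 1; 1 = trunk only).
#' @param murray_exponent exponent of the diameter law (default 3).
#' @param root_diameter_mm trunk diameter (default 4).
#' @param root_length_mm trunk length (default 22).
#' @param min_diameter_mm smallest modelled diameter (default 2).
#' @param c0 wall characteristic speed assigned to all segments, m/s.
#' @return a `vessel_graph` passing [validate_graph()], rooted at node
#'   `"n1"`; segments carry anatomical vessel names (LM, LAD, LCX, ...).
#' @export
make_coronary_tree <- function(seed = 1, n_generations = 3,
                               murray_exponent = 3, root_diameter_mm = 4,
                               root_length_mm = 22, min_diameter_mm = 2,
                               c0 = 10) {
  if (n_generations < 1) stop("n_generations must be >= 1")
  if (root_diameter_mm < min_diameter_mm)
    stop("parameters yield a sub-", min_diameter_mm, " mm root")
  .with_seed(seed, {
    nodes <- data.frame(id = "n1", kind = "ostium", x = 0, y = 0, z = 0,
                        stringsAsFactors = FALSE)
    segs <- NULL
    nid <- 1L
    new_node <- function(pos, kind) {
      nid <<- nid + 1L
      id <- paste0("n", nid)
      nodes <<- rbind(nodes, data.frame(id = id, kind = kind, x = pos[1],
                                        y = pos[2], z = pos[3],
                                        stringsAsFactors = FALSE))
      id
    }
    add_seg <- function(id, from, to, len, d, vessel) {
      segs <<- rbind(segs, data.frame(
        id = id, from = from, to = to, length_mm = len,
        reference_diameter_mm = d, effective_diameter_mm = d,
        wall_speed_m_s = c0, label = "artery", ffr_site = FALSE,
        vessel = vessel, stringsAsFactors = FALSE))
    }
    # recursive growth: each branch owns an angular sector in the xy plane;
    # daughters also tilt out of plane in opposite directions, giving
    # realistic (30-70 degree) 3D bifurcation angles without collisions
    grow <- function(from_id, pos, theta, sector, depth, d, len, vessel,
                     zsign = 0) {
      zjit <- if (depth == 1) 0 else zsign * stats::runif(1, 0.2, 0.4)
      dir <- c(cos(theta), sin(theta), zjit)
      dir <- dir / sqrt(sum(dir^2))
      tip <- pos + len * dir
      leaf <- depth >= n_generations
      if (!leaf) {
        f <- stats::runif(1, 0.38, 0.62)
        d1 <- d * f^(1 / murray_exponent)
        d2 <- d * (1 - f)^(1 / murray_exponent)
        if (d1 < min_diameter_mm || d2 < min_diameter_mm) leaf <- TRUE
      }
      to_id <- new_node(tip, if (leaf) "terminal" else "junction")
      add_seg(paste0("s_", vessel), from_id, to_id, len, d, vessel)
      if (leaf) return(invisible(NULL))
      half <- (sector[2] - sector[1]) / 2
      s1 <- c(sector[1], sector[1] + half)
      s2 <- c(sector[1] + half, sector[2])
      th1 <- mean(s1) + stats::runif(1, -0.08, 0.08) * half
      th2 <- mean(s2) + stats::runif(1, -0.08, 0.08) * half
      lfac <- stats::runif(2, 0.72, 0.95)
      nm <- if (depth == 1) c("LAD", "LCX")
            else paste0(vessel, c("a", "b"))
      # larger daughter continues the parent's name lineage first
      grow(to_id, tip, th2, s2, depth + 1, d1, len * lfac[1], nm[1], +1)
      grow(to_id, tip, th1, s1, depth + 1, d2, len * lfac[2], nm[2], -1)
    }
    grow("n1", c(0, 0, 0), 0, c(-1.1, 1.1), 1, root_diameter_mm,
         root_length_mm, "LM")
    g <- vessel_graph(nodes, segs, "n1")
    ok <- validate_graph(g)
    if (!ok$pass) stop("generated tree invalid: ",
                       paste(ok$violations, collapse = "; "))
    g
  })
}

#' Rasterize a vessel graph into a CTA-like voxel phantom
#'
#' Lumen voxels are those whose centre lies within the local segment radius
#' of the centerline; the aortic root is added as a large tube tangent to
#' the ostium so that ostium detection has a real contact surface.
#' Optional artefacts reproduce what contrast scans show: a vein (separate
#' bright tube near, but by default not touching, the arterial tree) and
#' calcifications (bright blobs >= 800 HU adjacent to the lumen).
#' Gaussian noise is added after rasterization.
#'
#' @param graph source `vessel_graph` (the ground truth).
#' @param spacing_mm isotropic voxel size (default 0.5, the minimum slice
#'   thickness of the emulated acquisition).
#' @param lumen_hu,background_hu intensity levels (defaults 400 / 0).
#' @param noise_sd Gaussian noise standard deviation (HU).
#' @param vein add a vein tube (`FALSE`, `TRUE` = non-touching).
#' @param calcification add 1-3 bright blobs adjacent to the lumen.
#' @param distractor add a bright blob far from the coronary region (used
#'   to exercise preprocessing).
#' @param aorta add the aortic-root tube (default TRUE).
#' @param aorta_diameter_mm,aorta_length_mm aortic tube geometry.
#' @param pad_mm empty margin around the tree.
#' @param seed RNG seed for noise and artefact placement.
#' @return list with `volume` (a [voxel_volume()]), `graph` (the arterial
#'   ground truth), `aorta_seed` (a world point inside the aorta), and
#'   `artefacts` (what was added where).
#' @export
make_voxel_phantom <- function(graph, spacing_mm = 0.5, lumen_hu = 400,
                               background_hu = 0, noise_sd = 0,
                               vein = FALSE, calcification = FALSE,
                               distractor = FALSE, aorta = TRUE,
                               aorta_diameter_mm = 10, aorta_length_mm = 30,
                               pad_mm = 8, seed = 1) {
  stopifnot(inherits(graph, "vessel_graph"))
  sg <- graph$segments
  if (min(sg$effective_diameter_mm) / spacing_mm < 2)
    stop("spacing too coarse: thinnest segment under 2 voxels across")
  nd <- graph$nodes
  pos <- as.matrix(nd[, c("x", "y", "z")])
  rmax <- max(sg$reference_diameter_mm) / 2
  lo <- apply(pos, 2, min) - rmax - pad_mm
  hi <- apply(pos, 2, max) + rmax + pad_mm
  root <- as.numeric(nd[match(graph$ostia[1], nd$id), c("x", "y", "z")])
  ar <- aorta_diameter_mm / 2
  aorta_axis <- NULL
  if (aorta) {
    # vertical tube whose surface passes through the ostium
    ax <- root - c(ar, 0, 0)
    aorta_axis <- rbind(ax - c(0, 0, aorta_length_mm / 2),
                        ax + c(0, 0, aorta_length_mm / 2))
    lo <- pmin(lo, apply(aorta_axis, 2, min) - ar - pad_mm)
    hi <- pmax(hi, apply(aorta_axis, 2, max) + ar + pad_mm)
  }
  if (distractor) hi[2] <- hi[2] + 70   # room well outside the ROI
  dims <- as.integer(ceiling((hi - lo) / spacing_mm)) + 1L
  vol <- array(background_hu, dim = dims)
  spacing <- rep(spacing_mm, 3)
  origin <- lo
  add <- function(p0, p1, r, value)
    cf_add_capsule(vol, dims, spacing, origin, as.numeric(p0),
                   as.numeric(p1), r, value)
  if (aorta) add(aorta_axis[1, ], aorta_axis[2, ], ar, lumen_hu)
  for (i in seq_len(nrow(sg))) {
    p0 <- as.numeric(nd[match(sg$from[i], nd$id), c("x", "y", "z")])
    p1 <- as.numeric(nd[match(sg$to[i], nd$id), c("x", "y", "z")])
    add(p0, p1, sg$effective_diameter_mm[i] / 2, lumen_hu)
  }
  artefacts <- list()
  .with_seed(seed + 1, {
    if (vein) {
      # straight tube floating above the tree plane, separate component
      zoff <- max(pos[, 3]) + rmax + 4
      v0 <- c(lo[1] + pad_mm, mean(pos[, 2]), zoff)
      v1 <- c(hi[1] - pad_mm, mean(pos[, 2]) + 5, zoff)
      add(v0, v1, 1.5, lumen_hu)
      artefacts$vein <- rbind(v0, v1)
    }
    if (calcification) {
      nb <- sample(1:3, 1)
      ctr <- matrix(0, nb, 3)
      for (b in seq_len(nb)) {
        i <- sample(nrow(sg), 1)
        p0 <- as.numeric(nd[match(sg$from[i], nd$id), c("x", "y", "z")])
        p1 <- as.numeric(nd[match(sg$to[i], nd$id), c("x", "y", "z")])
        t <- stats::runif(1, 0.3, 0.7)
        u <- c(0, 0, 1)
        c0 <- p0 + t * (p1 - p0) +
          u * (sg$effective_diameter_mm[i] / 2 + 0.6)
        add(c0, c0 + 1e-6, 1.0, 900)
        ctr[b, ] <- c0
      }
      artefacts$calcification <- ctr
    }
    if (distractor) {
      dc <- c((lo[1] + hi[1]) / 2, hi[2] - 6, root[3])
      add(dc, dc + 1e-6, 3, lumen_hu)
      artefacts$distractor <- dc
    }
    if (noise_sd > 0)
      vol <- vol + stats::rnorm(length(vol), 0, noise_sd)
  })
  aorta_seed <- if (aorta) aorta_axis[1, ] + c(0, 0, aorta_length_mm / 2)
                else root
  list(volume = voxel_volume(vol, spacing, origin), graph = graph,
       aorta_seed = aorta_seed, artefacts = artefacts)
}

#' Sample synthetic patient records
#'
#' Draws records with the marginal moments of the study population: age
#' 63.6 +- 9 years, SBP 133.4 +- 9.4 mmHg, DBP 84.0 +- 5.3 mmHg, HR
#' 65.2 +- 5 bpm, height 170.7 +- 8.5 cm, weight 81.6 +- 11 kg.
#'
#' @param n number of patients.
#' @param seed RNG seed.
#' @return list of [patient_record()] objects.
#' @export
make_patient_records <- function(n, seed = 1) {
  .with_seed(seed, lapply(seq_len(n), function(i) {
    sbp <- stats::rnorm(1, 133.4, 9.4)
    dbp <- min(stats::rnorm(1, 84.0, 5.3), sbp - 20)
    patient_record(id = sprintf("P%03d", i),
                   age = stats::rnorm(1, 63.6, 9),
                   sex = sample(c("m", "f"), 1, prob = c(0.71, 0.29)),
                   height_cm = stats::rnorm(1, 170.7, 8.5),
                   weight_kg = stats::rnorm(1, 81.6, 11),
                   sbp = sbp, dbp = dbp,
                   hr = max(45, stats::rnorm(1, 65.2, 5)))
  }))
}

#' Cohort specification
#'
#' @param n_patients cohort size (>= 1).
#' @param vessels_per_patient candidate counts of diseased vessels per
#'   patient (sampled uniformly; default 1-3).
#' @param severity_range percent-diameter stenosis range, as fractions
#'   (default 45-75\%, the study's inclusion range).
#' @param bias expected virtual-minus-invasive difference (the Bland-Altman
#'   calibration target, default 0.09238).
#' @param sd total standard deviation of the difference (default 0.1908),
#'   split evenly between a per-patient offset and per-vessel noise.
#' @param seed integer seed.
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients, vessels_per_patient = 1:3,
                        severity_range = c(0.45, 0.75), bias = 0.09238,
                        sd = 0.1908, seed = 1) {
  if (n_patients < 1) stop("n_patients must be >= 1")
  if (sd < 0) stop("sd must be >= 0")
  structure(list(n_patients = as.integer(n_patients),
                 vessels_per_patient = vessels_per_patient,
                 severity_range = severity_range, bias = bias, sd = sd,
                 seed = as.integer(seed)), class = "cohort_spec")
}

#' Generate a paired virtual/invasive cohort
#'
#' For each patient: sample a record and a coronary tree, place 1-3
#' stenoses (45-75\% diameter) on distinct vessels, run the personalized
#' model under hyperemia for the virtual FFR, and emulate the invasive
#' reference as `virtual - bias + patient_offset + noise`, clipped to
#' (0.05, 1].  Deterministic for a fixed spec.
#'
#' @param spec a [cohort_spec()].
#' @param runner function(graph, record) returning an `ffr_result`;
#'   defaults to the steady-mode [ffr_pipeline()].
#' @return a [paired_ffr()] table with one row per (patient, vessel).
#' @export
make_cohort <- function(spec, runner = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (is.null(runner))
    runner <- function(graph, record) ffr_pipeline(graph, record,
                                                   method = "steady")
  records <- make_patient_records(spec$n_patients, seed = spec$seed)
  sd_pat <- spec$sd / sqrt(2)
  sd_res <- spec$sd / sqrt(2)
  rows <- .with_seed(spec$seed + 1000L, {
    out <- vector("list", spec$n_patients)
    for (i in seq_len(spec$n_patients)) {
      g <- make_coronary_tree(seed = spec$seed * 1000L + i,
                              n_generations = 3)
      vessels <- unique(g$segments$vessel)
      nles <- sample(spec$vessels_per_patient, 1)
      nles <- min(nles, length(vessels))
      target_vessels <- sample(vessels, nles)
      for (v in target_vessels) {
        cand <- g$segments$id[g$segments$vessel == v &
                                !g$segments$ffr_site]
        sid <- if (length(cand) == 1) cand else sample(cand, 1)
        g <- apply_stenosis(g, stenosis_spec(
          sid,
          diameter_reduction = stats::runif(1, spec$severity_range[1],
                                            spec$severity_range[2]),
          extent_fraction = stats::runif(1, 0.2, 0.45)))
      }
      res <- tryCatch(runner(g, records[[i]]), error = function(e)
        stop("model runner failed for patient ", records[[i]]$id, ": ",
             conditionMessage(e)))
      pv <- res$per_vessel
      offset <- stats::rnorm(1, 0, sd_pat)
      inv <- pv$ffr - spec$bias + offset + stats::rnorm(nrow(pv), 0, sd_res)
      inv <- pmin(pmax(inv, 0.051), 1)
      out[[i]] <- data.frame(patient_id = records[[i]]$id,
                             vessel_id = pv$vessel,
                             virtual_ffr = pv$ffr, invasive_ffr = inv,
                             stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  })
  paired_ffr(rows$patient_id, rows$vessel_id, rows$virtual_ffr,
             rows$invasive_ffr)
}
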