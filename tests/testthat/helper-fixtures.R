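# Shared fixture builders.  Everything is generated in code; no data files.

# reference patient: the study population means (SBP/DBP/HR at scan time)
ref_record <- function(id = "ref") {
  patient_record(id, age = 63.61, sex = "m", height_cm = 170.74,
                 weight_kg = 81.58, sbp = 133.39, dbp = 84.03, hr = 65.19)
}

# hand-built two-branch tree with an explicit vein edge bridging branches
graph_with_vein <- function() {
  nodes <- data.frame(
    id = c("o", "j", "t1", "t2"),
    kind = c("ostium", "junction", "terminal", "terminal"),
    x = c(0, 20, 40, 40), y = c(0, 0, 10, -10), z = 0,
    stringsAsFactors = FALSE)
  segs <- data.frame(
    id = c("trunk", "b1", "b2", "vein1"),
    from = c("o", "j", "j", "t1"),
    to = c("j", "t1", "t2", "t2"),
    length_mm = c(20, 22.4, 22.4, 20),
    reference_diameter_mm = c(4, 3, 3, 2.5),
    effective_diameter_mm = c(4, 3, 3, 2.5),
    wall_speed_m_s = 10,
    label = c("artery", "artery", "artery", "vein"),
    ffr_site = FALSE, stringsAsFactors = FALSE)
  vessel_graph(nodes, segs, "o")
}

# analytic cylinder mask: radius r_mm along z, n_z slices, isotropic spacing
cylinder_mask <- function(r_mm = 2, spacing = 0.5, half_width = 12,
                          n_z = 80) {
  xs <- (seq_len(2 * half_width) - half_width - 0.5) * spacing
  sl <- outer(xs, xs, function(x, y) x^2 + y^2 <= r_mm^2)
  array(rep(sl, n_z), dim = c(length(xs), length(xs), n_z))
}

# match each true segment to the extracted segment with the closest pair of
# endpoints; returns per-segment absolute diameter and relative length errors
recovery_errors <- function(truth, extracted) {
  tn <- truth$nodes; en <- extracted$nodes
  npos <- function(df, id) as.numeric(df[match(id, df$id), c("x", "y", "z")])
  out <- data.frame(id = truth$segments$id, d_err = NA_real_,
                    l_err_rel = NA_real_)
  for (i in seq_len(nrow(truth$segments))) {
    ts <- truth$segments[i, ]
    p0 <- npos(tn, ts$from); p1 <- npos(tn, ts$to)
    best <- NA; bd <- Inf
    for (j in seq_len(nrow(extracted$segments))) {
      es <- extracted$segments[j, ]
      d <- sqrt(sum((p0 - npos(en, es$from))^2)) +
        sqrt(sum((p1 - npos(en, es$to))^2))
      if (d < bd) { bd <- d; best <- j }
    }
    es <- extracted$segments[best, ]
    out$d_err[i] <- abs(es$reference_diameter_mm - ts$reference_diameter_mm)
    out$l_err_rel[i] <- abs(es$length_mm - ts$length_mm) / ts$length_mm
  }
  out
}

# 43-vessel / 31-patient paired-FFR fixture built backwards from the
# reconstructed overall confusion tables: per-vessel (tp 16, fp 4, fn 8,
# tn 15) and per-patient (tp 16, fp 1, fn 7, tn 7).
reference_cohort_fixture <- function() {
  rows <- list()
  add <- function(pid, vid, virt, inv)
    rows[[length(rows) + 1]] <<- data.frame(patient_id = pid, vessel_id = vid,
                                            virtual_ffr = virt,
                                            invasive_ffr = inv)
  jit <- function(k, base) base + 0.003 * (k %% 7)
  # 16 TP patients, one true-positive vessel each
  for (k in 1:16) add(sprintf("TP%02d", k), "v1", jit(k, 0.60), jit(k, 0.68))
  # extra vessels on TP patients that do not change the patient call:
  add("TP01", "v2", 0.86, 0.70)            # vessel FN (8th)
  for (k in 2:4) add(sprintf("TP%02d", k), "v2", jit(k, 0.70), jit(k, 0.84))  # vessel FPs
  for (k in 5:12) add(sprintf("TP%02d", k), "v2", jit(k, 0.90), jit(k, 0.88)) # vessel TNs
  # 7 FN patients (invasive positive, virtual negative)
  for (k in 1:7) add(sprintf("FN%02d", k), "v1", jit(k, 0.85), jit(k, 0.71))
  # 1 FP patient
  add("FP01", "v1", 0.74, 0.86)
  # 7 TN patients
  for (k in 1:7) add(sprintf("TN%02d", k), "v1", jit(k, 0.92), jit(k, 0.89))
  df <- do.call(rbind, rows)
  paired_ffr(df$patient_id, df$vessel_id, df$virtual_ffr, df$invasive_ffr)
}
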