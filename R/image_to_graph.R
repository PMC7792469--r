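#' Voxel volumes
#'
#' A `voxel_volume` holds a 3D intensity array on an HU-like scale together
#' with its voxel spacing (mm) and world origin (mm).  Arrays are native R
#' arrays, 1-based, axis order (x, y, z); the world position of voxel
#' (i, j, k) is `origin + (c(i, j, k) - 1) * spacing`.
#'
#' @param intensities 3D numeric array.
#' @param spacing numeric(3), mm per voxel, all > 0.
#' @param origin numeric(3), mm.
#' @return object of class `voxel_volume`.
#' @export
voxel_volume <- function(intensities, spacing, origin = c(0, 0, 0)) {
  if (length(dim(intensities)) != 3 || !length(intensities))
    stop("intensities must be a non-empty 3D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three positive numbers")
  structure(list(intensities = intensities, spacing = spacing,
                 origin = as.numeric(origin)),
            class = "voxel_volume")
}

#' @export
print.voxel_volume <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("<voxel_volume> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

.vol_dims <- function(vol) as.integer(dim(vol$intensities))

.world_to_index <- function(vol, xyz) {
  round((as.numeric(xyz) - vol$origin) / vol$spacing) + 1L
}

.index_to_world <- function(vol, ijk) {
  vol$origin + (as.numeric(ijk) - 1) * vol$spacing
}

.lin0 <- function(ijk, dims) {
  (ijk[1] - 1L) + dims[1] * ((ijk[2] - 1L) + dims[2] * (ijk[3] - 1L))
}

# --- NIfTI-1 and raw I/O ---------------------------------------------------

#' Read and write volumes
#'
#' `nifti_write`/`nifti_read` implement a minimal NIfTI-1 interface
#' (single-file `.nii`, optionally gzipped `.nii.gz`; float32 data, spacing
#' from `pixdim`, origin from the q-offset fields).  `write_volume_raw` /
#' `read_volume_raw` store the array as raw float32 plus a JSON sidecar with
#' the grid metadata, a header-free route convenient for testing.
#'
#' @param vol a [voxel_volume()].
#' @param path output path (`.nii` or `.nii.gz` for NIfTI; any prefix for the
#'   raw route, which appends `.raw` and `.json`).
#' @return the path (write) or a `voxel_volume` (read).
#' @export
nifti_write <- function(vol, path) {
  stopifnot(inherits(vol, "voxel_volume"))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  d <- .vol_dims(vol)
  writeBin(348L, con, size = 4)                      # sizeof_hdr
  writeBin(raw(36), con)                             # unused
  writeBin(c(3L, d, 1L, 1L, 1L, 1L), con, size = 2)  # dim[8]
  writeBin(raw(14), con)                             # intent etc.
  writeBin(16L, con, size = 2)                       # datatype: float32
  writeBin(32L, con, size = 2)                       # bitpix
  writeBin(0L, con, size = 2)                        # slice_start
  writeBin(c(1, vol$spacing, 0, 0, 0, 0), con, size = 4)  # pixdim[8]
  writeBin(352, con, size = 4)                       # vox_offset (float)
  writeBin(c(1, 0), con, size = 4)                   # scl_slope, scl_inter
  writeBin(raw(4), con)                              # slice_end/code/units
  writeBin(c(0, 0), con, size = 4)                   # cal_max/min
  writeBin(c(0, 0), con, size = 4)                   # slice_duration, toffset
  writeBin(c(0L, 0L), con, size = 4)                 # glmax/glmin
  writeBin(raw(104), con)                            # descrip + aux_file
  writeBin(c(1L, 0L), con, size = 2)                 # qform_code, sform_code
  writeBin(c(0, 0, 0, vol$origin), con, size = 4)    # quatern b,c,d + offsets
  writeBin(rep(0, 12), con, size = 4)                # srow
  writeBin(raw(16), con)                             # intent_name
  writeChar("n+1", con, nchars = 3, eos = NULL)
  writeBin(raw(1), con)                              # magic terminator -> 348
  writeBin(raw(4), con)                              # pad to vox_offset 352
  writeBin(as.numeric(vol$intensities), con, size = 4)
  invisible(path)
}

#' @rdname nifti_write
#' @export
nifti_read <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 348)
  sz <- readBin(hdr[1:4], "integer", 1, size = 4)
  if (sz != 348) stop("not a NIfTI-1 file: ", path)
  dimv <- readBin(hdr[41:56], "integer", 8, size = 2)
  d <- dimv[2:4]
  datatype <- readBin(hdr[71:72], "integer", 1, size = 2)
  pixdim <- readBin(hdr[77:108], "numeric", 8, size = 4)
  vox_offset <- readBin(hdr[109:112], "numeric", 1, size = 4)
  slope <- readBin(hdr[113:116], "numeric", 1, size = 4)
  inter <- readBin(hdr[117:120], "numeric", 1, size = 4)
  origin <- readBin(hdr[269:280], "numeric", 3, size = 4)
  skip <- vox_offset - 348
  if (skip > 0) readBin(con, "raw", skip)
  n <- prod(d)
  dat <- switch(as.character(datatype),
                "2" = as.numeric(readBin(con, "integer", n, size = 1, signed = FALSE)),
                "4" = as.numeric(readBin(con, "integer", n, size = 2)),
                "8" = as.numeric(readBin(con, "integer", n, size = 4)),
                "16" = readBin(con, "numeric", n, size = 4),
                "64" = readBin(con, "numeric", n, size = 8),
                stop("unsupported NIfTI datatype: ", datatype))
  if (slope != 0 && !(slope == 1 && inter == 0)) dat <- dat * slope + inter
  voxel_volume(array(dat, dim = d), pixdim[2:4], origin)
}

#' @rdname nifti_write
#' @export
write_volume_raw <- function(vol, path) {
  stopifnot(inherits(vol, "voxel_volume"))
  con <- file(paste0(path, ".raw"), "wb")
  writeBin(as.numeric(vol$intensities), con, size = 4)
  close(con)
  jsonlite::write_json(list(dim = .vol_dims(vol), spacing = vol$spacing,
                            origin = vol$origin, dtype = "float32",
                            order = "xyz-column-major"),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname nifti_write
#' @export
read_volume_raw <- function(path) {
  meta <- jsonlite::fromJSON(paste0(path, ".json"))
  con <- file(paste0(path, ".raw"), "rb")
  dat <- readBin(con, "numeric", prod(meta$dim), size = 4)
  close(con)
  voxel_volume(array(dat, dim = meta$dim), meta$spacing, meta$origin)
}

# --- preprocessing ---------------------------------------------------------

#' Preprocess a contrast-enhanced volume
#'
#' Two clean-up steps used before segmentation: (1) the first `drop_slices`
#' axial (z) slices, which often have a narrowed visibility scope, are
#' removed; (2) bright structures far from the main contrast-filled region
#' (lung vessels, unrelated enhancement) are suppressed to background by a
#' morphological criterion: only structures that survive an opening with
#' radius `opening_radius_mm` (i.e. contain a ball of that radius - in
#' practice the aorta and heart chambers) define the region of interest,
#' which is then grown by `roi_margin_mm`; bright voxels outside it are set
#' to `background`.
#'
#' @param vol a [voxel_volume()].
#' @param config list with elements `drop_slices` (default 0),
#'   `opening_radius_mm` (4), `roi_margin_mm` (80), `threshold` (200),
#'   `background` (0).
#' @return the cleaned `voxel_volume`.
#' @export
preprocess_volume <- function(vol, config = list()) {
  stopifnot(inherits(vol, "voxel_volume"))
  cfg <- utils::modifyList(list(drop_slices = 0L, opening_radius_mm = 4,
                                roi_margin_mm = 80, threshold = 200,
                                background = 0), config)
  d <- .vol_dims(vol)
  k <- as.integer(cfg$drop_slices)
  if (k >= d[3]) stop("drop_slices (", k, ") >= number of slices (", d[3], ")")
  arr <- vol$intensities
  origin <- vol$origin
  if (k > 0) {
    arr <- arr[, , (k + 1):d[3], drop = FALSE]
    origin[3] <- origin[3] + k * vol$spacing[3]
    d <- dim(arr)
  }
  bright <- arr > cfg$threshold
  if (any(bright)) {
    edt <- cf_edt(as.logical(bright), as.integer(d), vol$spacing)
    core <- edt > cfg$opening_radius_mm
    if (any(core)) {
      d2core <- cf_edt(!core, as.integer(d), vol$spacing)
      roi <- array(d2core <= cfg$roi_margin_mm, dim = d)
      arr[bright & !roi] <- cfg$background
    } else {
      arr[bright] <- cfg$background
    }
  }
  voxel_volume(arr, vol$spacing, origin)
}

# --- segmentation ----------------------------------------------------------

#' Segment aorta and coronary arteries, find ostia
#'
#' Fixed-threshold segmentation with 26-connected region growth from seed
#' points, followed by a scale-based split of the seed component into aorta
#' (the part within `aorta_core_radius_mm` of voxels whose distance
#' transform exceeds that radius, i.e. the large-calibre structure) and
#' arteries (the rest).  Ostia are the contact loci between the aorta mask
#' and each artery component: the centroid of the artery voxels adjacent to
#' the aorta.
#'
#' @param vol a [voxel_volume()].
#' @param hu_threshold segmentation threshold on the HU-like scale.
#' @param seeds matrix (n x 3) of world positions (mm) inside bright
#'   structures; at least one required.
#' @param aorta_core_radius_mm scale separating aorta from arteries.
#' @return list with `aorta_mask`, `artery_mask` (logical arrays),
#'   `ostia` (matrix of world positions, one row per artery component in
#'   contact with the aorta), and `artery_labels` (integer array).
#' @export
segment_vessels <- function(vol, hu_threshold = 200, seeds,
                            aorta_core_radius_mm = 3) {
  stopifnot(inherits(vol, "voxel_volume"))
  d <- .vol_dims(vol)
  seeds <- matrix(as.numeric(seeds), ncol = 3)
  mask <- vol$intensities >= hu_threshold
  if (!any(mask)) stop("empty segmentation: no voxel reaches the threshold")
  seed_lin <- integer(nrow(seeds))
  for (i in seq_len(nrow(seeds))) {
    ijk <- .world_to_index(vol, seeds[i, ])
    if (any(ijk < 1) || any(ijk > d)) stop("seed outside volume")
    if (!mask[ijk[1], ijk[2], ijk[3]])
      stop("seed below threshold at (", paste(seeds[i, ], collapse = ", "), ")")
    seed_lin[i] <- .lin0(ijk, d)
  }
  lab <- cf_label(as.logical(mask), d, 26L)
  keep <- unique(lab[seed_lin + 1L])
  comp <- array(lab %in% keep & mask, dim = d)
  if (!any(comp)) stop("empty segmentation")
  edt <- cf_edt(as.logical(comp), d, vol$spacing)
  core <- edt >= aorta_core_radius_mm
  if (any(core)) {
    # one voxel diagonal of slack so the aorta shell is not left behind as
    # spurious "artery" fragments
    d2core <- cf_edt(!core, d, vol$spacing)
    aorta <- array(comp &
                     d2core <= aorta_core_radius_mm +
                       sqrt(3) * max(vol$spacing), dim = d)
  } else {
    aorta <- array(FALSE, dim = d)
  }
  artery <- comp & !aorta
  art_lab <- array(cf_label(as.logical(artery), d, 26L), dim = d)
  # despeckle: tiny fragments at the aorta boundary are not arteries
  sizes <- tabulate(art_lab[art_lab > 0])
  small <- which(sizes < 50)
  if (length(small)) {
    artery[art_lab %in% small] <- FALSE
    art_lab <- array(cf_label(as.logical(artery), d, 26L), dim = d)
  }
  ostia <- NULL
  if (any(aorta)) {
    # contact voxels: artery voxels with an aorta voxel among 26 neighbours
    d2a <- cf_edt(!aorta, d, vol$spacing)
    contact <- artery & d2a <= max(vol$spacing) * sqrt(3) + 1e-9
    comps <- sort(unique(art_lab[contact]))
    comps <- comps[comps > 0]
    if (length(comps)) {
      # the aorta mask was grown by one voxel diagonal; pull the contact
      # centroid back by that margin toward the aorta so the ostium sits on
      # the true aortic surface
      margin <- sqrt(3) * max(vol$spacing)
      core_idx <- which(core)
      core_pos <- sweep(sweep(arrayInd(core_idx, d) - 1, 2, vol$spacing, "*"),
                        2, vol$origin, "+")
      ostia <- t(vapply(comps, function(cc) {
        w <- which(contact & art_lab == cc)
        ijk <- arrayInd(w, d)
        ctr <- colMeans(sweep(sweep(ijk - 1, 2, vol$spacing, "*"), 2,
                              vol$origin, "+"))
        dd <- colSums((t(core_pos) - ctr)^2)
        dirv <- core_pos[which.min(dd), ] - ctr
        nv <- sqrt(sum(dirv^2))
        if (nv > 1e-9) ctr + dirv / nv * margin else ctr
      }, numeric(3)))
    }
  }
  list(aorta_mask = aorta, artery_mask = array(artery, dim = d),
       ostia = ostia, artery_labels = art_lab)
}

# --- skeletonization -------------------------------------------------------

#' Extract centerlines and radii from a binary vessel mask
#'
#' Centerlines are traced geodesically: a Dijkstra front is propagated from
#' the root through the mask with a cost that penalizes voxels far from the
#' medial axis (weight 1/(EDT + half voxel)), then branches are peeled off
#' iteratively - the voxel with the largest geodesic distance to the current
#' skeleton in excess of its own radius starts a new branch, which is traced
#' back along the Dijkstra parents until it meets the skeleton.  The
#' per-voxel radius estimate is the Euclidean distance transform value (mm).
#'
#' @param mask logical 3D array (or a `voxel_volume` of 0/1).
#' @param spacing numeric(3), mm.
#' @param origin numeric(3), mm.
#' @param roots optional matrix of world positions used as tracing roots
#'   (one per connected component to trace); defaults to the voxel with the
#'   largest distance-transform value.
#' @param min_branch_mm branches shorter than this are not peeled.
#' @return object of class `skeleton`: list of `chains` (each with `ijk`
#'   voxel matrix, `radius_mm`, and `attach` = c(chain, index) or NA),
#'   plus `spacing`, `origin`.
#' @export
skeletonize_and_measure <- function(mask, spacing, origin = c(0, 0, 0),
                                    roots = NULL, min_branch_mm = 3) {
  if (inherits(mask, "voxel_volume")) {
    spacing <- mask$spacing; origin <- mask$origin
    mask <- mask$intensities > 0
  }
  d <- as.integer(dim(mask))
  spacing <- rep(as.numeric(spacing), length.out = 3)
  nvox <- sum(mask)
  if (nvox < 2) stop("mask reduced to fewer than 2 voxels")
  edt <- cf_edt(as.logical(mask), d, spacing)
  eps <- 0.5 * min(spacing)
  w <- 1 / (edt + eps)
  if (is.null(roots)) {
    root_lin <- which.max(edt) - 1L
  } else {
    roots <- matrix(as.numeric(roots), ncol = 3)
    root_lin <- integer(nrow(roots))
    mask_idx <- which(mask)
    ijk_all <- arrayInd(mask_idx, d)
    wpos <- sweep(sweep(ijk_all - 1, 2, spacing, "*"), 2, origin, "+")
    for (i in seq_len(nrow(roots))) {
      dd <- colSums((t(wpos) - roots[i, ])^2)
      root_lin[i] <- mask_idx[which.min(dd)] - 1L
    }
  }
  g <- cf_geodesic(as.logical(mask), d, spacing, as.integer(root_lin), w)
  parent <- g$parent
  chains <- list()
  member <- integer(prod(d))   # 0 = not on skeleton, else chain id
  # first chain(s): farthest voxel from each root
  skel <- integer(0)
  trace_up <- function(from_lin) {
    path <- integer(0)
    v <- from_lin
    while (v >= 0 && member[v + 1L] == 0L) {
      path <- c(path, v)
      v <- parent[v + 1L]
    }
    list(path = rev(path), hit = v)
  }
  repeat {
    if (length(skel) == 0) {
      h <- g$dist
    } else {
      h <- cf_geodesic(as.logical(mask), d, spacing, as.integer(skel),
                       numeric(0))$dist
    }
    excess <- h - edt
    excess[!is.finite(excess)] <- -Inf
    cand <- which.max(excess) - 1L
    if (!is.finite(excess[cand + 1L])) break
    if (length(skel) > 0 &&
        excess[cand + 1L] < max(min_branch_mm, 2 * min(spacing))) break
    tr <- trace_up(cand)
    if (length(tr$path) < 2 && length(skel) > 0) break
    vox <- tr$path
    attach <- NA
    if (tr$hit >= 0) {
      # Inside a wide parent vessel, the new trace can run parallel to the
      # existing centerline before the Dijkstra trees merge.  Trim leading
      # voxels that still lie inside the lumen tube of the skeleton (closer
      # to some skeleton voxel than that voxel's radius) and attach where
      # the branch actually leaves the parent vessel.
      spos <- arrayInd(skel + 1L, d)
      ppos <- arrayInd(vox + 1L, d)
      sw <- sweep(spos - 1, 2, spacing, "*")
      pw <- sweep(ppos - 1, 2, spacing, "*")
      nearest <- function(i) {
        dd <- colSums((t(sw) - pw[i, ])^2)
        j <- which.min(dd)
        c(sqrt(dd[j]), j)
      }
      keep_from <- length(vox) + 1L
      for (i in seq_along(vox)) {
        nj <- nearest(i)
        if (nj[1] >= edt[skel[nj[2]] + 1L]) { keep_from <- i; break }
      }
      if (keep_from > length(vox)) next   # spur entirely inside the lumen
      # the true bifurcation is where the daughter centerline, extended
      # backwards, meets the parent centerline: back-project the initial
      # branch direction onto the nearby skeleton voxels
      nkeep <- length(vox) - keep_from + 1L
      pstart <- pw[keep_from, ]
      hit_vox <- skel[nearest(keep_from)[2]]
      # clearance: stay outside the junction bulge before fitting the axis
      clear <- max(1.5, 1.1 * edt[hit_vox + 1L])
      darc <- c(0, cumsum(sqrt(rowSums(
        diff(pw[keep_from:length(vox), , drop = FALSE])^2))))
      iw <- which(darc >= clear & darc <= clear + 7)
      skip <- if (length(iw)) iw[1] - 1L else min(3L, max(nkeep - 4L, 0L))
      iwin <- (keep_from + skip):min(keep_from + skip +
                                       max(length(iw) - 1L, 11L),
                                     length(vox))
      if (length(iwin) >= 4) {
        # total-least-squares direction of the straight part of the branch
        W <- pw[iwin, , drop = FALSE]
        ctr <- colMeans(W)
        dirv <- svd(sweep(W, 2, ctr, "-"))$v[, 1]
        if (sum(dirv * (W[nrow(W), ] - W[1, ])) < 0) dirv <- -dirv
        rel <- sweep(sw, 2, ctr, "-")
        along <- drop(rel %*% dirv)
        perp2 <- rowSums(rel^2) - along^2
        # the junction lies behind the window, close to the extended line
        cand2 <- which(rowSums(sweep(sw, 2, pstart, "-")^2) < 100 & along < 2)
        if (length(cand2))
          hit_vox <- skel[cand2[which.min(perp2[cand2])]]
        # refine: the junction is the closest approach of the parent axis
        # (fitted upstream of the bifurcation bulge) and the daughter axis
        pc0 <- member[hit_vox + 1L]
        cvox <- chains[[pc0]]$lin0
        cidx <- match(hit_vox, cvox)
        if (!is.na(cidx) && length(cvox) >= 4) {
          cw <- (arrayInd(cvox + 1L, d) - 1) %*% diag(spacing)
          step <- c(0, sqrt(rowSums(diff(cw)^2)))
          arc <- cumsum(step)
          fit_line <- function(W) {
            c0 <- colMeans(W)
            list(c = c0, d = svd(sweep(W, 2, c0, "-"))$v[, 1])
          }
          s0 <- arc[cidx]
          for (pass in 1:2) {
            win <- which(arc >= s0 - clear - 7 & arc <= s0 - clear)
            if (length(win) < 4) win <- which(arc >= s0 - 10 & arc <= s0 - 0.5)
            win_dn <- which(arc >= s0 + clear & arc <= s0 + clear + 7)
            lines <- list(list(c = ctr, d = dirv))
            if (length(win) >= 4) lines <- c(lines, list(fit_line(cw[win, , drop = FALSE])))
            if (length(win_dn) >= 4) lines <- c(lines, list(fit_line(cw[win_dn, , drop = FALSE])))
            if (length(lines) < 2) break
            # least-squares intersection of the fitted axes
            A <- matrix(0, 3, 3); bb <- numeric(3)
            for (ln in lines) {
              P <- diag(3) - tcrossprod(ln$d)
              A <- A + P
              bb <- bb + P %*% ln$c
            }
            pj <- tryCatch(drop(solve(A, bb)), error = function(e) NULL)
            if (is.null(pj)) break
            dd2 <- rowSums(sweep(cw, 2, pj, "-")^2)
            j2 <- which.min(dd2)
            if (dd2[j2] < 36) {
              hit_vox <- cvox[j2]
              s0 <- arc[j2]
            } else break
          }
        }
      }
      vox <- vox[keep_from:length(vox)]
      pc <- member[hit_vox + 1L]
      idx <- match(hit_vox, chains[[pc]]$lin0)
      attach <- c(pc, idx)
      vox_full <- c(hit_vox, vox)
    } else {
      vox_full <- vox
    }
    cid <- length(chains) + 1L
    ijk <- arrayInd(vox_full + 1L, d)
    skel_idx <- if (length(vox_full) > length(vox))
      c(match(vox_full[1], skel), length(skel) + seq_along(vox))
    else length(skel) + seq_along(vox)
    chains[[cid]] <- list(lin0 = vox_full, ijk = ijk,
                          radius_mm = .local_max_radius(edt, vox_full, d),
                          attach = attach, skel_idx = skel_idx)
    member[vox + 1L] <- cid
    skel <- c(skel, vox)
    if (length(chains) > 200) break
  }
  # volumetric radius: each lumen voxel drains to its geodesically nearest
  # skeleton voxel; cross-sectional area = claimed volume / local step.
  # This is subvoxel-accurate where the raw EDT radius is biased by the
  # centerline's offset within its voxel.
  if (length(skel)) {
    lab <- cf_geodesic(as.logical(mask), d, spacing, as.integer(skel),
                       numeric(0))$label
    counts <- tabulate(lab[lab >= 0] + 1L, nbins = length(skel))
    voxvol <- prod(spacing)
    # subvoxel centerline: move each skeleton voxel to the centroid of the
    # lumen voxels it claims (the cross-sectional slab), which removes the
    # lattice quantization of the traced path
    claimed <- which(lab >= 0)
    cw_all <- sweep(sweep(arrayInd(claimed, d) - 1, 2, spacing, "*"), 2,
                    origin, "+")
    li <- lab[claimed] + 1L
    cent <- cbind(rowsum(cw_all[, 1], li), rowsum(cw_all[, 2], li),
                  rowsum(cw_all[, 3], li))   # rows follow sort(unique(li))
    uli <- sort(unique(li))
    centroid <- matrix(NA_real_, length(skel), 3)
    centroid[uli, ] <- cent / counts[uli]
    for (ci in seq_along(chains)) {
      ch <- chains[[ci]]
      pos <- sweep(sweep(ch$ijk - 1, 2, spacing, "*"), 2, origin, "+")
      okv0 <- !is.na(ch$skel_idx)
      pref <- pos
      pref[okv0, ] <- centroid[ch$skel_idx[okv0], , drop = FALSE]
      bad <- !is.finite(pref[, 1])
      pref[bad, ] <- pos[bad, , drop = FALSE]
      # consecutive territories alternate sides of the axis; a moving
      # average cancels the resulting zigzag while keeping subvoxel accuracy
      if (nrow(pref) > 5) {
        sm <- apply(pref, 2, function(v)
          stats::filter(v, rep(1 / 5, 5), sides = 2))
        keep <- !is.na(sm[, 1])
        pref[keep, ] <- sm[keep, ]
      }
      chains[[ci]]$pos_mm <- pref
      n <- nrow(pos)
      if (n < 2) { chains[[ci]]$radius_area_mm <- ch$radius_mm; next }
      seglen <- sqrt(rowSums(diff(pos)^2))
      step <- c(seglen[1], (seglen[-1] + seglen[-length(seglen)]) / 2,
                seglen[length(seglen)])[seq_len(n)]
      cnt <- rep(NA_real_, n)
      okv <- !is.na(ch$skel_idx)
      cnt[okv] <- counts[ch$skel_idx[okv]]
      r <- sqrt(cnt * voxvol / (pi * pmax(step, 1e-6)))
      r[!is.finite(r)] <- ch$radius_mm[!is.finite(r)]
      chains[[ci]]$radius_area_mm <- r
    }
  }
  # re-estimate each junction on the refined (subvoxel) polylines
  for (ci in seq_along(chains)) {
    a <- chains[[ci]]$attach
    if (anyNA(a)) next
    pc <- a[1]
    pp <- chains[[pc]]$pos_mm
    dp <- chains[[ci]]$pos_mm[-1, , drop = FALSE]
    if (nrow(pp) < 6 || nrow(dp) < 5) next
    arc <- c(0, cumsum(sqrt(rowSums(diff(pp)^2))))
    s0 <- arc[a[2]]
    jvox <- chains[[ci]]$lin0[1]
    clear <- max(1.5, 1.1 * edt[jvox + 1L])
    darc <- c(0, cumsum(sqrt(rowSums(diff(dp)^2))))
    dwin <- which(darc >= clear & darc <= clear + 7)
    if (length(dwin) < 4) dwin <- which(darc <= clear + 7)
    fit_line <- function(W) {
      c0 <- colMeans(W)
      list(c = c0, d = svd(sweep(W, 2, c0, "-"))$v[, 1])
    }
    if (length(dwin) < 4) next
    l_d <- fit_line(dp[dwin, , drop = FALSE])
    newidx <- a[2]
    for (pass in 1:2) {
      win_up <- which(arc >= s0 - clear - 7 & arc <= s0 - clear)
      win_dn <- which(arc >= s0 + clear & arc <= s0 + clear + 7)
      lines <- list(l_d)
      if (length(win_up) >= 4)
        lines <- c(lines, list(fit_line(pp[win_up, , drop = FALSE])))
      if (length(win_dn) >= 4)
        lines <- c(lines, list(fit_line(pp[win_dn, , drop = FALSE])))
      if (length(lines) < 2) break
      A <- matrix(0, 3, 3); bb <- numeric(3)
      for (ln in lines) {
        P <- diag(3) - tcrossprod(ln$d)
        A <- A + P
        bb <- bb + P %*% ln$c
      }
      pj <- tryCatch(drop(solve(A, bb)), error = function(e) NULL)
      if (is.null(pj)) break
      dd2 <- rowSums(sweep(pp, 2, pj, "-")^2)
      j2 <- which.min(dd2)
      if (dd2[j2] >= 36) break
      newidx <- j2
      s0 <- arc[j2]
      pj_final <- pj
    }
    if (newidx != a[2]) {
      chains[[ci]]$attach <- c(pc, newidx)
      chains[[ci]]$lin0[1] <- chains[[pc]]$lin0[newidx]
      chains[[ci]]$ijk[1, ] <- chains[[pc]]$ijk[newidx, ]
      chains[[ci]]$radius_mm[1] <- chains[[pc]]$radius_mm[newidx]
    }
    # place the shared node at the fitted intersection itself (subvoxel),
    # on both the daughter head and the parent polyline point it splits at
    if (exists("pj_final", inherits = FALSE) &&
        sqrt(sum((pj_final -
                  chains[[pc]]$pos_mm[chains[[ci]]$attach[2], ])^2)) < 2) {
      chains[[pc]]$pos_mm[chains[[ci]]$attach[2], ] <- pj_final
      chains[[ci]]$pos_mm[1, ] <- pj_final
      # the first couple of millimetres of the daughter trace swing through
      # the junction bulge; regularize them onto the fitted branch axis
      strai <- which(darc < 2.5 * clear) + 1L
      strai <- strai[strai > 1 & strai <= nrow(chains[[ci]]$pos_mm)]
      for (q in strai) {
        rel <- chains[[ci]]$pos_mm[q, ] - l_d$c
        chains[[ci]]$pos_mm[q, ] <- l_d$c + sum(rel * l_d$d) * l_d$d
      }
      # likewise the parent trace bulges sideways while passing the
      # junction; project it onto its own up/downstream axes there
      win_up <- which(arc >= s0 - clear - 7 & arc <= s0 - clear)
      win_dn <- which(arc >= s0 + clear & arc <= s0 + clear + 7)
      if (length(win_up) >= 4) {
        l_up <- fit_line(pp[win_up, , drop = FALSE])
        for (q in which(arc > s0 - 2.5 * clear & arc < s0)) {
          rel <- chains[[pc]]$pos_mm[q, ] - l_up$c
          chains[[pc]]$pos_mm[q, ] <- l_up$c + sum(rel * l_up$d) * l_up$d
        }
      }
      if (length(win_dn) >= 4) {
        l_dn <- fit_line(pp[win_dn, , drop = FALSE])
        for (q in which(arc > s0 & arc < s0 + 2.5 * clear)) {
          rel <- chains[[pc]]$pos_mm[q, ] - l_dn$c
          chains[[pc]]$pos_mm[q, ] <- l_dn$c + sum(rel * l_dn$d) * l_dn$d
        }
      }
    } else {
      chains[[ci]]$pos_mm[1, ] <- chains[[pc]]$pos_mm[chains[[ci]]$attach[2], ]
    }
    rm(list = intersect("pj_final", ls()))
  }
  structure(list(chains = chains, spacing = spacing, origin = origin,
                 dims = d), class = "skeleton")
}

# Radius estimate at a centerline voxel: traced voxels sit up to half a
# voxel off the true axis, biasing the raw EDT low; the maximum over the
# 26-neighbourhood recovers the best-centred value.
.local_max_radius <- function(edt, lin0, d) {
  ijk <- arrayInd(lin0 + 1L, d)
  out <- numeric(length(lin0))
  for (q in seq_along(lin0)) {
    i0 <- pmax(ijk[q, ] - 1L, 1L)
    i1 <- pmin(ijk[q, ] + 1L, d)
    block <- edt[as.vector(outer(outer(i0[1]:i1[1],
      (i0[2]:i1[2] - 1L) * d[1], "+"),
      (i0[3]:i1[3] - 1L) * d[1] * d[2], "+"))]
    out[q] <- max(block)
  }
  out
}

#' @export
print.skeleton <- function(x, ...) {
  cat(sprintf("<skeleton> %d chain(s), %d voxels\n", length(x$chains),
              sum(vapply(x$chains, function(ch) nrow(ch$ijk), 1L))))
  invisible(x)
}

# --- graph construction ----------------------------------------------------

# Arc length of a noisy centerline polyline.  The traced points carry
# lattice noise that inflates the raw sum of segment lengths, so each
# coordinate is regressed on the chord-length parameter with a low-df
# smoothing spline before integrating; endpoints stay anchored.
.polyline_length <- function(pos, window = 7) {
  n <- nrow(pos)
  if (n < 2) return(0)
  if (n < 8) return(sum(sqrt(rowSums(diff(pos)^2))))
  s <- c(0, cumsum(sqrt(rowSums(diff(pos)^2))))
  df <- min(max(3, round(n / 8) + 2), n - 2)
  grid <- seq(0, s[n], length.out = 100)
  fit <- vapply(1:3, function(k) {
    sp <- stats::smooth.spline(s, pos[, k], df = df)
    stats::predict(sp, grid)$y
  }, numeric(100))
  fit[1, ] <- pos[1, ]
  fit[100, ] <- pos[n, ]
  sum(sqrt(rowSums(diff(fit)^2)))
}

#' Build a vessel graph from a skeleton
#'
#' One graph segment per skeleton branch between topological nodes (root,
#' junctions, tips).  Segment length is the arc length of the smoothed
#' centerline polyline; segment diameter is twice the median radius along
#' the branch (junction-adjacent voxels excluded).  Edges are oriented away
#' from the root; terminal branches thinner than `min_diameter_mm` are
#' pruned and any degree-2 joints left over are merged.
#'
#' @param skeleton a [skeletonize_and_measure()] result.
#' @param ostia optional matrix of ostium world positions; the first is used
#'   as the root node position (default: the first chain's first voxel).
#' @param min_diameter_mm prune terminal branches below this diameter.
#' @param c0 wall speed assigned to extracted segments, m/s.
#' @return a `vessel_graph` that passes [validate_graph()].
#' @export
build_artery_graph <- function(skeleton, ostia = NULL, min_diameter_mm = 2,
                               c0 = 10) {
  stopifnot(inherits(skeleton, "skeleton"))
  ch <- skeleton$chains
  if (!length(ch) || nrow(ch[[1]]$ijk) < 2)
    stop("no ostium-connected component: empty skeleton")
  for (i in seq_along(ch)) {
    a <- ch[[i]]$attach
    if (!anyNA(a) && a[1] >= i) stop("cycle detected in skeleton attachments")
  }
  sp <- skeleton$spacing; orig <- skeleton$origin
  world <- function(ijk) sweep(sweep(ijk - 1, 2, sp, "*"), 2, orig, "+")
  # collect cut indices per chain: ends + attach points of other chains
  cuts <- lapply(ch, function(x) c(1L, nrow(x$ijk)))
  for (i in seq_along(ch)) {
    a <- ch[[i]]$attach
    if (!anyNA(a)) cuts[[a[1]]] <- c(cuts[[a[1]]], a[2])
  }
  cuts <- lapply(cuts, function(x) sort(unique(x)))
  node_key <- function(chain, idx) paste0("v", ch[[chain]]$lin0[idx])
  branches <- list()
  for (i in seq_along(ch)) {
    cc <- cuts[[i]]
    for (b in seq_len(length(cc) - 1)) {
      i0 <- cc[b]; i1 <- cc[b + 1]
      if (i1 <= i0) next
      sel <- i0:i1
      pos <- if (!is.null(ch[[i]]$pos_mm))
        ch[[i]]$pos_mm[sel, , drop = FALSE]
      else world(ch[[i]]$ijk[sel, , drop = FALSE])
      rad <- ch[[i]]$radius_mm[sel]
      arad <- if (!is.null(ch[[i]]$radius_area_mm))
        ch[[i]]$radius_area_mm[sel] else rad
      arad[!is.finite(arad)] <- rad[!is.finite(arad)]
      core <- arad
      if (length(arad) > 7) core <- arad[4:(length(arad) - 3)]
      else if (length(arad) > 5) core <- arad[3:(length(arad) - 2)]
      branches[[length(branches) + 1]] <- list(
        from = node_key(i, i0), to = node_key(i, i1),
        p_from = pos[1, ], p_to = pos[nrow(pos), ], pos = pos,
        length_mm = max(.polyline_length(pos), min(sp)),
        diameter_mm = 2 * stats::median(core),
        tip_radius = rad[length(rad)],
        tip_dir = {
          n <- nrow(pos)
          v <- pos[n, ] - pos[max(1, n - 4), ]
          nv <- sqrt(sum(v^2))
          if (nv > 0) v / nv else c(0, 0, 0)
        })
    }
  }
  root_key <- node_key(1, 1L)
  # rounded vessel tips make the farthest traced voxel overshoot the true
  # branch end by about one radius; shorten leaf branches accordingly
  from0 <- vapply(branches, `[[`, "", "from")
  to0 <- vapply(branches, `[[`, "", "to")
  for (i in seq_along(branches)) {
    b <- branches[[i]]
    if (!(b$to %in% from0) && b$to != root_key) {
      rcap <- max(max(b$tip_radius, b$diameter_mm / 2) - 0.5 * min(sp), 0)
      branches[[i]]$length_mm <- max(b$length_mm - rcap, min(sp))
      tip <- b$p_to - b$tip_dir * rcap
      # project the tip onto the terminal axis fitted outside the cap
      n <- nrow(b$pos)
      if (n >= 6) {
        d_end <- rev(c(0, cumsum(sqrt(rowSums(diff(b$pos[n:1, ,
                                                          drop = FALSE])^2)))))
        sel2 <- which(d_end >= rcap & d_end <= rcap + 7)
        if (length(sel2) >= 4) {
          W <- b$pos[sel2, , drop = FALSE]
          ctr0 <- colMeans(W)
          dv <- svd(sweep(W, 2, ctr0, "-"))$v[, 1]
          tip <- ctr0 + sum((tip - ctr0) * dv) * dv
        }
      }
      branches[[i]]$p_to <- tip
    }
  }
  # iterative pruning of thin terminal branches, then merge degree-2 joints
  repeat {
    from <- vapply(branches, `[[`, "", "from")
    to <- vapply(branches, `[[`, "", "to")
    deg <- table(c(from, to))
    leaf <- vapply(seq_along(branches), function(i)
      deg[[branches[[i]]$to]] == 1 && branches[[i]]$to != root_key, TRUE)
    drop <- leaf & vapply(branches, function(b)
      b$diameter_mm < min_diameter_mm, TRUE)
    if (!any(drop)) break
    branches <- branches[!drop]
    if (!length(branches)) stop("all branches pruned below minimum diameter")
    # merge chains through degree-2 interior nodes
    repeat {
      from <- vapply(branches, `[[`, "", "from")
      to <- vapply(branches, `[[`, "", "to")
      mid <- names(which(table(c(from, to)) == 2))
      mid <- setdiff(mid, root_key)
      mid <- mid[mid %in% from & mid %in% to]
      if (!length(mid)) break
      key <- mid[1]
      iin <- which(to == key); iout <- which(from == key)
      a <- branches[[iin]]; b <- branches[[iout]]
      wa <- a$length_mm; wb <- b$length_mm
      merged <- list(from = a$from, to = b$to, p_from = a$p_from,
                     p_to = b$p_to, length_mm = wa + wb,
                     diameter_mm = (a$diameter_mm * wa + b$diameter_mm * wb) /
                       (wa + wb))
      branches <- c(branches[-c(iin, iout)], list(merged))
    }
  }
  from <- vapply(branches, `[[`, "", "from")
  to <- vapply(branches, `[[`, "", "to")
  ids <- unique(c(from, to))
  deg_out <- vapply(ids, function(k) sum(from == k), 1L)
  deg_in <- vapply(ids, function(k) sum(to == k), 1L)
  kind <- ifelse(ids == root_key, "ostium",
                 ifelse(deg_out == 0, "terminal", "junction"))
  pos <- matrix(0, length(ids), 3)
  for (i in seq_along(branches)) {
    pos[match(branches[[i]]$from, ids), ] <- branches[[i]]$p_from
    pos[match(branches[[i]]$to, ids), ] <- branches[[i]]$p_to
  }
  if (!is.null(ostia)) {
    # the traced root voxel sits a little inside the artery; anchor the root
    # node at the detected ostium and extend the root branch to it
    opos <- matrix(ostia, ncol = 3)[1, ]
    for (i in seq_along(branches))
      if (branches[[i]]$from == root_key) {
        # extend along the trunk axis, not along the oblique jog
        ext <- sqrt(sum((opos - branches[[i]]$p_from)^2))
        dirv <- branches[[i]]$p_to - branches[[i]]$p_from
        nv <- sqrt(sum(dirv^2))
        if (nv > 1e-9)
          ext <- abs(sum((branches[[i]]$p_from - opos) * dirv / nv))
        branches[[i]]$length_mm <- branches[[i]]$length_mm + ext
      }
    pos[match(root_key, ids), ] <- opos
  }
  nodes <- data.frame(id = ids, kind = kind, x = pos[, 1], y = pos[, 2],
                      z = pos[, 3], stringsAsFactors = FALSE)
  segs <- data.frame(
    id = sprintf("e%02d", seq_along(branches)),
    from = from, to = to,
    length_mm = vapply(branches, `[[`, 1, "length_mm"),
    reference_diameter_mm = vapply(branches, `[[`, 1, "diameter_mm"),
    effective_diameter_mm = vapply(branches, `[[`, 1, "diameter_mm"),
    wall_speed_m_s = c0, label = "artery", ffr_site = FALSE,
    stringsAsFactors = FALSE)
  g <- vessel_graph(nodes, segs, root_key)
  ok <- validate_graph(g)
  if (!ok$pass) stop("extracted graph invalid: ",
                     paste(ok$violations, collapse = "; "))
  g
}

#' Full image-to-graph extraction
#'
#' Convenience chain: [preprocess_volume()] (optional), [segment_vessels()],
#' [skeletonize_and_measure()] on the artery mask rooted at the detected
#' ostia, [build_artery_graph()].
#'
#' @param vol a [voxel_volume()].
#' @param seeds world positions for segmentation seeding (the aorta seed).
#' @param hu_threshold segmentation threshold.
#' @param min_diameter_mm terminal pruning threshold.
#' @param preprocess optional config list passed to [preprocess_volume()];
#'   `NULL` skips preprocessing.
#' @return a `vessel_graph`.
#' @export
extract_graph <- function(vol, seeds, hu_threshold = 200,
                          min_diameter_mm = 2, preprocess = NULL) {
  if (!is.null(preprocess)) vol <- preprocess_volume(vol, preprocess)
  seg <- segment_vessels(vol, hu_threshold, seeds)
  if (is.null(seg$ostia)) stop("no ostium found: aorta/artery contact missing")
  sk <- skeletonize_and_measure(seg$artery_mask, vol$spacing, vol$origin,
                                roots = seg$ostia[1, , drop = FALSE])
  build_artery_graph(sk, ostia = seg$ostia, min_diameter_mm = min_diameter_mm)
}
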