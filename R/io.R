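# NIfTI + JSON dataset I/O.
#
# A velocity dataset on disk is three NIfTI series (vx/vy/vz.nii.gz, one per
# encoding axis, each nx x ny x nz x n_phases) plus sidecar.json carrying
# what NIfTI cannot: VENC per axis, RR interval and phase count. A single
# 5-D NIfTI (nx, ny, nz, n_phases, 3) is accepted on read.

COMPONENT_FILES <- c("vx.nii.gz", "vy.nii.gz", "vz.nii.gz")

#' Write a velocity dataset to a directory
#'
#' Writes one NIfTI volume series per velocity component (`vx.nii.gz`,
#' `vy.nii.gz`, `vz.nii.gz`; values cm/s) plus a `sidecar.json` with the
#' acquisition metadata. [read_velocity_dataset()] inverts this exactly.
#'
#' @param field a [velocity_field()].
#' @param dir output directory (created if missing).
#' @param description free-text description stored in the sidecar.
#' @return Invisibly, the paths written (3 NIfTI + 1 JSON).
#' @export
write_velocity_dataset <- function(field, dir, description = "") {
  validate_velocity_field(field)
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", dir, call. = FALSE)
  }
  d <- dim(field$velocities)
  hdr <- RNifti::niftiHeader(list(
    dim = c(4L, d[1], d[2], d[3], d[4], 1L, 1L, 1L),
    pixdim = c(1, field$voxel_spacing, field$rr_interval / field$n_phases, 1, 1, 1),
    qform_code = 0L, sform_code = 2L,
    srow_x = c(field$voxel_spacing[1], 0, 0, field$origin[1]),
    srow_y = c(0, field$voxel_spacing[2], 0, field$origin[2]),
    srow_z = c(0, 0, field$voxel_spacing[3], field$origin[3]),
    xyzt_units = 18L  # mm + msec
  ))
  paths <- file.path(dir, COMPONENT_FILES)
  for (c_ in 1:3) {
    vol <- array(field$velocities[, , , , c_], dim = d[1:4])
    img <- RNifti::asNifti(vol, reference = hdr, datatype = "double")
    RNifti::writeNifti(img, paths[c_])
  }
  sidecar <- list(
    venc_cm_s = field$venc,
    rr_interval_ms = field$rr_interval,
    n_phases = field$n_phases,
    description = description
  )
  json_path <- file.path(dir, "sidecar.json")
  jsonlite::write_json(sidecar, json_path, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, json_path))
}

#' Read a velocity dataset
#'
#' Reads either a dataset directory written by [write_velocity_dataset()]
#' (three per-component NIfTI series + `sidecar.json`), explicit component
#' paths, or a single 5-D NIfTI `(nx, ny, nz, n_phases, 3)`.
#'
#' @param paths a dataset directory, a single 5-D NIfTI path, or a length-3
#'   character vector of per-component NIfTI paths.
#' @param sidecar path to the JSON sidecar; defaults to `sidecar.json` next
#'   to the data.
#' @return A [velocity_field()].
#' @export
read_velocity_dataset <- function(paths, sidecar = NULL) {
  if (length(paths) == 1L && dir.exists(paths)) {
    dir <- paths
    paths <- file.path(dir, COMPONENT_FILES)
    if (is.null(sidecar)) sidecar <- file.path(dir, "sidecar.json")
  }
  if (is.null(sidecar)) sidecar <- file.path(dirname(paths[1]), "sidecar.json")
  if (!file.exists(sidecar)) {
    stop("metadata error: sidecar JSON not found: ", sidecar, call. = FALSE)
  }
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (is.null(meta$venc_cm_s)) {
    stop("metadata error: sidecar lacks venc_cm_s", call. = FALSE)
  }
  if (is.null(meta$rr_interval_ms)) {
    stop("metadata error: sidecar lacks rr_interval_ms", call. = FALSE)
  }

  if (length(paths) == 1L) {
    img <- RNifti::readNifti(paths)
    d <- dim(img)
    if (length(d) != 5L || d[5] != 3L) {
      stop("format error: single-file dataset must be 5-D (nx,ny,nz,nt,3)",
           call. = FALSE)
    }
    geom <- nifti_grid_geometry(img, paths)
    vel <- array(as.numeric(img), dim = d)
  } else {
    if (length(paths) != 3L) {
      stop("format error: expected 3 component files or one 5-D file",
           call. = FALSE)
    }
    imgs <- lapply(paths, RNifti::readNifti)
    dims <- lapply(imgs, function(img) {
      d <- dim(img)
      if (length(d) == 3L) d <- c(d, 1L)  # trailing singleton phase dropped by NIfTI
      d
    })
    if (!all(vapply(dims, length, 1L) == 4L)) {
      stop("format error: component volumes must be 4-D", call. = FALSE)
    }
    if (!all(vapply(dims[-1], identical, TRUE, dims[[1]]))) {
      stop("format error: component volumes have mismatched shapes",
           call. = FALSE)
    }
    geoms <- lapply(seq_along(imgs),
                    function(i) nifti_grid_geometry(imgs[[i]], paths[i]))
    for (g in geoms[-1]) {
      if (max(abs(g$spacing - geoms[[1]]$spacing)) > 1e-6 ||
          max(abs(g$origin - geoms[[1]]$origin)) > 1e-6) {
        stop("format error: component volumes have mismatched affines",
             call. = FALSE)
      }
    }
    geom <- geoms[[1]]
    d <- c(dims[[1]], 3L)
    vel <- array(0, dim = d)
    for (c_ in 1:3) vel[, , , , c_] <- array(as.numeric(imgs[[c_]]), dim = d[1:4])
  }
  nt <- d[4]
  if (!is.null(meta$n_phases) && meta$n_phases != nt) {
    stop("metadata error: sidecar n_phases disagrees with data", call. = FALSE)
  }
  velocity_field(vel, voxel_spacing = geom$spacing, origin = geom$origin,
                 rr_interval = meta$rr_interval_ms,
                 venc = meta$venc_cm_s)
}

# Extract axis-aligned spacing/origin from a NIfTI xform; reject rotations.
nifti_grid_geometry <- function(img, path) {
  A <- RNifti::xform(img)
  M <- A[1:3, 1:3]
  offdiag <- M; diag(offdiag) <- 0
  if (max(abs(offdiag)) > 1e-6 * max(abs(diag(M))) || any(diag(M) <= 0)) {
    stop("format error: only axis-aligned, positive-diagonal affines are ",
         "supported (", path, ")", call. = FALSE)
  }
  list(spacing = diag(M), origin = A[1:3, 4])
}

#' Write / read a binary mask as NIfTI
#'
#' Masks live on the same grid as the velocity field: 3-D for time-invariant
#' masks (stationary tissue) or 4-D `(nx, ny, nz, n_phases)` for per-phase
#' segmentations. Values are stored as 0/1 and read back as logical
#' (any value > 0.5 is `TRUE`).
#'
#' @param mask logical 3-D or 4-D array.
#' @param path NIfTI file path (`.nii` / `.nii.gz`).
#' @param voxel_spacing 3-vector of voxel edge lengths, mm.
#' @param origin 3-vector world position of voxel (0, 0, 0), mm.
#' @return `write_mask_nifti()` returns the path invisibly;
#'   `read_mask_nifti()` returns a logical array.
#' @export
write_mask_nifti <- function(mask, path, voxel_spacing = c(1, 1, 1),
                             origin = c(0, 0, 0)) {
  d <- dim(mask)
  if (!length(d) %in% c(3L, 4L)) {
    stop("format error: mask must be a 3-D or 4-D array", call. = FALSE)
  }
  nd <- length(d)
  hdr <- RNifti::niftiHeader(list(
    dim = c(nd, d, rep(1L, 7L - nd)),
    pixdim = c(1, voxel_spacing, rep(1, 4)),
    qform_code = 0L, sform_code = 2L,
    srow_x = c(voxel_spacing[1], 0, 0, origin[1]),
    srow_y = c(0, voxel_spacing[2], 0, origin[2]),
    srow_z = c(0, 0, voxel_spacing[3], origin[3]),
    xyzt_units = 18L
  ))
  img <- RNifti::asNifti(array(as.integer(mask), dim = d), reference = hdr,
                         datatype = "uint8")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_mask_nifti
#' @export
read_mask_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  array(as.numeric(img) > 0.5, dim = dim(img))
}

#' Write / read an analysis plane as JSON
#'
#' @param plane an [analysis_plane()].
#' @param path JSON file path.
#' @return `write_analysis_plane()` returns the path invisibly;
#'   `read_analysis_plane()` returns an [analysis_plane()].
#' @export
write_analysis_plane <- function(plane, path) {
  jsonlite::write_json(
    list(origin_mm = plane$origin, normal = plane$normal,
         in_plane_u = plane$u, in_plane_v = plane$v,
         pixel_spacing_mm = plane$pixel_spacing, extent = plane$extent),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_analysis_plane
#' @export
read_analysis_plane <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  analysis_plane(origin = j$origin_mm, normal = j$normal,
                 u = j$in_plane_u, v = j$in_plane_v,
                 pixel_spacing = j$pixel_spacing_mm, extent = j$extent)
}

#' Write / read an ROI contour as JSON
#'
#' @param contour an [roi_contour()].
#' @param path JSON file path.
#' @return `write_roi_contour()` returns the path invisibly;
#'   `read_roi_contour()` returns an [roi_contour()].
#' @export
write_roi_contour <- function(contour, path) {
  jsonlite::write_json(
    list(vertices_mm = unname(apply(contour$vertices, 1, as.numeric,
                                    simplify = FALSE))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_roi_contour
#' @export
read_roi_contour <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  roi_contour(j$vertices_mm)
}

#' Write / read a background model as JSON (12 coefficients)
#'
#' @param model a [background_model()].
#' @param path JSON file path.
#' @return `write_background_model()` returns the path invisibly;
#'   `read_background_model()` returns a [background_model()].
#' @export
write_background_model <- function(model, path) {
  co <- model$coefficients
  jsonlite::write_json(
    list(components = rownames(co), terms = colnames(co),
         coefficients = unname(lapply(1:3, function(i) as.numeric(co[i, ])))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_background_model
#' @export
read_background_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  background_model(j$coefficients)
}

#' Write a flow or KE curve to CSV
#'
#' Scalar summaries (flow volume, density, RR) go into `#`-prefixed header
#' lines so the file still round-trips through
#' `read.csv(..., comment.char = "#")`.
#'
#' @param curve a [flow_curve()] or [ke_curve()].
#' @param path CSV file path.
#' @return The path, invisibly.
#' @export
write_curve_csv <- function(curve, path) {
  meta <- c(sprintf("# rr_interval_ms=%.10g", curve$rr_interval))
  if (inherits(curve, "flow_curve")) {
    meta <- c(meta, sprintf("# flow_volume_ml=%.10g", curve$flow_volume_ml))
  } else if (inherits(curve, "ke_curve")) {
    meta <- c(meta, sprintf("# density_g_ml=%.10g", curve$density))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta, con)
  utils::write.csv(as.data.frame(curve), con, row.names = FALSE)
  invisible(path)
}
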