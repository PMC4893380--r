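# High-level pipeline: configuration, quasi-dense reconstruction of a stereo
# pair, and deformation tracking over a sequence.

#' Default pipeline configuration
#'
#' Nested list with sections `matching` (see [match_config()]), `detector`,
#' `tracking`, `tps`, `force` and `io`.  [read_config()] loads a YAML file and
#' validates it against these defaults: unknown keys are rejected and
#' thresholds must lie within their documented ranges.
#'
#' @return Named list of sections.
#' @export
pipeline_config <- function() {
  list(
    detector = list(threshold = 5e-4, min_separation = 4, max_features = 1500),
    matching = list(thr_r = 0.60, thr_s = 0.90, epipolar_tolerance = 1.5,
                    normal_gate_deg = 1, propagation_threshold = 0.80,
                    seed_area_scale = 3),
    tracking = list(patch_radius = 7, pyramid_levels = 3,
                    confidence_threshold = 0.7, max_displacement = 20),
    tps = list(lambda = 0, snap_radius_px = 2),
    force = list(occlusion_radius_mm = 4, fit_baseline = TRUE),
    io = list(reference_frame = 1)
  )
}

#' @param path YAML configuration file.
#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  def <- pipeline_config()
  bad <- setdiff(names(user), names(def))
  if (length(bad)) {
    abort(paste("unknown config section(s):", paste(bad, collapse = ", ")),
          class = "tissuedeform_invalid_config")
  }
  for (sec in names(user)) {
    extra <- setdiff(names(user[[sec]]), names(def[[sec]]))
    if (length(extra)) {
      abort(paste0("unknown key(s) in [", sec, "]: ", paste(extra, collapse = ", ")),
            class = "tissuedeform_invalid_config")
    }
    def[[sec]] <- modifyList(def[[sec]], user[[sec]])
  }
  validate_config(def)
  def
}

validate_config <- function(cfg) {
  chk <- function(ok, msg) {
    if (!ok) abort(msg, class = "tissuedeform_invalid_config")
  }
  m <- cfg$matching
  chk(m$thr_r >= 0 && m$thr_r <= 1, "matching.thr_r must be in [0, 1]")
  chk(m$thr_s >= 0 && m$thr_s <= 1, "matching.thr_s must be in [0, 1]")
  chk(m$epipolar_tolerance > 0, "matching.epipolar_tolerance must be > 0")
  chk(m$normal_gate_deg > 0, "matching.normal_gate_deg must be > 0")
  chk(m$propagation_threshold >= -1 && m$propagation_threshold <= 1,
      "matching.propagation_threshold must be in [-1, 1]")
  chk(cfg$tracking$confidence_threshold >= -1 && cfg$tracking$confidence_threshold <= 1,
      "tracking.confidence_threshold must be in [-1, 1]")
  chk(cfg$tps$lambda >= 0, "tps.lambda must be >= 0")
  chk(cfg$force$occlusion_radius_mm >= 0, "force.occlusion_radius_mm must be >= 0")
  invisible(cfg)
}

config_match <- function(cfg) {
  m <- cfg$matching
  match_config(thr_r = m$thr_r, thr_s = m$thr_s,
               epipolar_tolerance = m$epipolar_tolerance,
               normal_gate_deg = m$normal_gate_deg,
               propagation_threshold = m$propagation_threshold,
               seed_area_scale = m$seed_area_scale)
}

#' Quasi-dense reconstruction of a rectified stereo pair
#'
#' Runs the full correspondence chain — detection, constrained global
#' matching, local densification, normal-gated affine propagation (with
#' sub-pixel refinement of propagated positions) — and triangulates the
#' matches.
#'
#' @param rect A `rectified_rig`.
#' @param img_L,img_R Rectified grayscale images.
#' @param config Pipeline configuration list (see [pipeline_config()]).
#' @return List: `cloud` (point tibble), `matches`, `features_L`,
#'   `features_R`, `normals`.
#' @export
reconstruct_pair <- function(rect, img_L, img_R, config = pipeline_config()) {
  dt <- config$detector
  mc <- config_match(config)
  fL <- detect_regions(img_L, threshold = dt$threshold,
                       min_separation = dt$min_separation,
                       max_features = dt$max_features)
  fR <- detect_regions(img_R, threshold = dt$threshold,
                       min_separation = dt$min_separation,
                       max_features = dt$max_features)
  log_stage("detect", n_left = nrow(fL), n_right = nrow(fR))
  matches <- match_global(fL, fR, mc)
  log_stage("match_global", n = nrow(matches))
  matches <- densify_local(matches, img_L, img_R, mc)
  log_stage("densify_local", n = nrow(matches))
  normals <- estimate_normals(img_L, focal_px = rect$K_rect[1, 1],
                              center_px = c(rect$K_rect[1, 3], rect$K_rect[2, 3]))
  lfL <- attr(matches, "local_features_L")
  cand <- dplyr::bind_rows(
    fL[!fL$id %in% matches$left_id, ],
    if (!is.null(lfL)) lfL[!lfL$id %in% matches$left_id, ]
  )
  prop <- propagate_matches(matches, cand, img_L, img_R, normals, mc)
  if (nrow(prop)) {
    prop <- refine_matches(prop, img_L, img_R,
                           min_ncc = config$matching$propagation_threshold)
  }
  log_stage("propagate", n = nrow(prop))
  matches <- dplyr::bind_rows(matches, prop)
  cloud <- reconstruct_cloud(matches, rect)
  log_stage("reconstruct", n = nrow(cloud))
  list(cloud = cloud, matches = matches, features_L = fL, features_R = fR,
       normals = normals)
}

#' Track deformation through a rectified stereo sequence
#'
#' Builds the reference structure by quasi-dense reconstruction of the
#' reference frame, tracks the distinctive (global-stage) features on the
#' left sequence, re-establishes their stereo correspondence per frame by
#' epipolar-constrained alignment, and measures per-point deformation
#' `D = ||S_t - S_ref||`.  Points with 3D data but no reliable track
#' (local/propagated stages, or lost tracks) are mapped with a 3D TPS warp
#' anchored on the stable features.
#'
#' @param rect A `rectified_rig`.
#' @param frames_L,frames_R Lists of rectified grayscale frames.
#' @param config Pipeline configuration.
#' @param reference Reference frame index (default from `config$io`).
#' @return List: `fields` (one deformation-field tibble per frame),
#'   `reference` (the reference reconstruction), `trajectories`.
#' @export
track_deformation <- function(rect, frames_L, frames_R,
                              config = pipeline_config(),
                              reference = config$io$reference_frame) {
  stopifnot(length(frames_L) == length(frames_R), length(frames_L) >= 1)
  nf <- length(frames_L)
  ref <- reconstruct_pair(rect, frames_L[[reference]], frames_R[[reference]], config)
  cloud_ref <- ref$cloud
  stable_ids <- cloud_ref$id[cloud_ref$stage == "global"]
  unstable_ref <- cloud_ref[!cloud_ref$id %in% stable_ids,
                            c("id", "x", "y", "z")]
  init <- tibble(id = cloud_ref$id[cloud_ref$stage == "global"],
                 col = cloud_ref$col_L[cloud_ref$stage == "global"],
                 row = cloud_ref$row_L[cloud_ref$stage == "global"])
  # track in schedule order starting at the reference frame
  order_idx <- c(reference, setdiff(seq_len(nf), reference))
  tk <- config$tracking
  traj <- track_features(frames_L[order_idx], init,
                         patch_radius = tk$patch_radius,
                         pyramid_levels = tk$pyramid_levels,
                         confidence_threshold = tk$confidence_threshold,
                         max_displacement = tk$max_displacement)
  traj$frame <- order_idx[traj$frame]
  ref_disp <- setNames(cloud_ref$col_L - cloud_ref$col_R, cloud_ref$id)
  # reference positions of the stable features measured with the same
  # epipolar LK estimator used per frame, so per-feature sub-pixel biases
  # cancel in the deformation difference
  ref_stable <- stereo_at_tracked(init, frames_L[[reference]],
                                  frames_R[[reference]], rect, ref_disp, tk)

  fields <- vector("list", nf)
  for (f in seq_len(nf)) {
    if (f == reference) {
      fields[[f]] <- as_deformation_field(deformation_at_stable(cloud_ref, cloud_ref))
      next
    }
    tr_f <- traj[traj$frame == f & traj$status == "tracked", ]
    # re-establish stereo per tracked feature: epipolar-constrained LK from
    # the reference disparity
    cl_t <- stereo_at_tracked(tr_f, frames_L[[f]], frames_R[[f]], rect,
                              ref_disp, tk)
    stable_field <- deformation_at_stable(cl_t, ref_stable)
    # quasi-dense structure of the current frame: supplies "3D information
    # already available" at the projections of TPS-mapped unstable points
    dense_t <- reconstruct_pair(rect, frames_L[[f]], frames_R[[f]], config)$cloud
    lost_ref <- cloud_ref[!cloud_ref$id %in% cl_t$id, c("id", "x", "y", "z")]
    unst <- lost_ref
    field <- stable_field
    if (nrow(unst) && nrow(stable_field) >= 4) {
      src <- stable_field[, c("x_ref", "y_ref", "z_ref")]
      names(src) <- c("x", "y", "z")
      warp <- tryCatch(
        fit_tps(src, stable_field[, c("x", "y", "z")], lambda = config$tps$lambda),
        error = function(e) NULL
      )
      if (!is.null(warp)) {
        warp <- with_snap_radius(warp, config$tps$snap_radius_px)
        unst_field <- map_unstable(warp, unst, dense_t, rect)
        # second pass: unstable points confirmed on the current surface become
        # additional TPS controls, anchoring the warp near the indentation
        # before extrapolating into the occluded area
        snapped <- unst_field[unst_field$confidence == "high", ]
        remaining <- unst_field[unst_field$confidence != "high", ]
        if (nrow(snapped) >= 1 && nrow(remaining) >= 1) {
          src2 <- rbind(as.matrix(src),
                        as.matrix(snapped[, c("x_ref", "y_ref", "z_ref")]))
          tgt2 <- rbind(as.matrix(stable_field[, c("x", "y", "z")]),
                        as.matrix(snapped[, c("x", "y", "z")]))
          dup <- duplicated(round(src2, 9))
          src2 <- src2[!dup, , drop = FALSE]; tgt2 <- tgt2[!dup, , drop = FALSE]
          warp2 <- tryCatch(fit_tps(src2, tgt2, lambda = config$tps$lambda),
                            error = function(e) NULL)
          if (!is.null(warp2)) {
            warp2 <- with_snap_radius(warp2, config$tps$snap_radius_px)
            # re-map every unstable point with the better-anchored warp: the
            # first-pass projections near the indentation were biased by the
            # sparsely anchored warp
            unst_field <- map_unstable(warp2, unst, dense_t, rect)
          }
        }
        field <- dplyr::bind_rows(stable_field, unst_field)
      }
    }
    log_stage("deformation", frame = f, n = nrow(field),
              n_stable = sum(field$stable))
    fields[[f]] <- as_deformation_field(field)
  }
  list(fields = fields, reference = ref, trajectories = traj)
}

# Stereo correspondence for temporally tracked features: LK alignment in the
# right frame, initialized from the reference disparity, then triangulation.
stereo_at_tracked <- function(tracks, img_L, img_R, rect, ref_disp, tk) {
  if (!nrow(tracks)) {
    return(tibble(id = integer(), col_L = numeric(), row_L = numeric(),
                  col_R = numeric(), row_R = numeric(),
                  x = numeric(), y = numeric(), z = numeric(), stage = character()))
  }
  rows <- lapply(seq_len(nrow(tracks)), function(i) {
    id <- tracks$id[i]
    d0 <- ref_disp[[as.character(id)]]
    if (is.null(d0) || !is.finite(d0)) return(NULL)
    tmpl <- sample_window(img_L, tracks$col[i], tracks$row[i], tk$patch_radius)
    res <- lk_align(img_R, tmpl, tracks$col[i] - d0, tracks$row[i],
                    tk$patch_radius, max_shift = 10)
    if (is.null(res) || res$ncc < tk$confidence_threshold) return(NULL)
    if (abs(res$row - tracks$row[i]) > 1.5) return(NULL)
    if (tracks$col[i] - res$col <= 0) return(NULL)
    tibble(id = id, col_L = tracks$col[i], row_L = tracks$row[i],
           col_R = res$col, row_R = res$row, stage = "global")
  })
  m <- dplyr::bind_rows(rows)
  if (!nrow(m)) {
    return(tibble(id = integer(), col_L = numeric(), row_L = numeric(),
                  col_R = numeric(), row_R = numeric(),
                  x = numeric(), y = numeric(), z = numeric(), stage = character()))
  }
  tr <- triangulate_points(m[, c("col_L", "row_L", "col_R", "row_R")], rect)
  tibble(id = m$id, col_L = m$col_L, row_L = m$row_L,
         col_R = m$col_R, row_R = m$row_R,
         x = tr$x, y = tr$y, z = tr$z, stage = m$stage)
}

# JSON-lines stage logging to stderr (machine-readable summaries).
log_stage <- function(stage, ...) {
  if (!isTRUE(getOption("tissuedeform.log", FALSE))) return(invisible())
  rec <- c(list(stage = stage), list(...))
  message(jsonlite::toJSON(rec, auto_unbox = TRUE))
}
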