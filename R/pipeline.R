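# End-to-end orchestration: inputs -> centerlines -> gating -> placement ->
# twist / carina / catheter-path corrections -> lofting -> refinement ->
# branch union -> model + mapping-back report, with a parameter audit trail.

#' Default reconstruction configuration
#'
#' @param mode `"bench"` (all frames treated as gated, no twist correction —
#'   the steady-flow silicone setting) or `"clinical"` (ECG gating enforced,
#'   twist correction on).
#' @param resample_step_mm Centerline resampling step.
#' @param n_theta Circumferential lofting resolution.
#' @param union_pitch_mm Signed-distance union grid pitch.
#' @param refine_tol_mm Mapping-back refinement target.
#' @param refine_max_iter Refinement sweep cap.
#' @param twist_grid_deg,twist_refine_deg,twist_span_deg Twist search grid.
#' @param outlier_k MAD multiplier for catheter path outliers.
#' @param s0_mm Arc length of the first gated frame on each centerline.
#' @param plaque_overlap_tau Plaque chaining overlap threshold.
#' @param seed Seed recorded in the manifest (the reconstruction itself is
#'   deterministic).
#' @return Named list of parameters.
#' @export
reconstruction_config <- function(mode = c("bench", "clinical"),
                                  resample_step_mm = 0.1,
                                  n_theta = 128L,
                                  union_pitch_mm = 0.1,
                                  refine_tol_mm = 0.05,
                                  refine_max_iter = 5L,
                                  twist_grid_deg = 1,
                                  twist_refine_deg = 0.1,
                                  twist_span_deg = 45,
                                  outlier_k = 3,
                                  s0_mm = 0,
                                  plaque_overlap_tau = 0.3,
                                  seed = 1L) {
  list(mode = match.arg(mode), resample_step_mm = resample_step_mm,
       n_theta = as.integer(n_theta), union_pitch_mm = union_pitch_mm,
       refine_tol_mm = refine_tol_mm, refine_max_iter = as.integer(refine_max_iter),
       twist_grid_deg = twist_grid_deg, twist_refine_deg = twist_refine_deg,
       twist_span_deg = twist_span_deg, outlier_k = outlier_k, s0_mm = s0_mm,
       plaque_overlap_tau = plaque_overlap_tau, seed = as.integer(seed))
}

load_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- reconstruction_config()
  for (nm in names(cfg)) base[[nm]] <- cfg[[nm]]
  base
}

#' Run the full bifurcation reconstruction
#'
#' @param mv_pullback,sb_pullback [pullback()] objects (or paths to contour
#'   stack JSONs). `sb_pullback` may be `NULL` for a degraded single-vessel
#'   run (no merge, no carina registration).
#' @param mv_centerline,sb_centerline [centerline3d()] objects, or lists
#'   `list(curveA, geomA, curveB, geomB)` to triangulate.
#' @param config A [reconstruction_config()].
#' @param output_dir Optional directory: meshes, manifest and log are written
#'   there.
#' @return List: `model` ([bifurcation_model()]), per-branch `mapback`
#'   reports, branch meshes, placements, stage `log`, and `manifest`.
#' @export
run_reconstruction <- function(mv_pullback, mv_centerline,
                               sb_pullback = NULL, sb_centerline = NULL,
                               config = reconstruction_config(),
                               output_dir = NULL) {
  log <- list()
  stage <- function(name, params = list()) {
    log[[length(log) + 1L]] <<- list(stage = name, params = params,
                                     time = format(Sys.time(), "%H:%M:%OS2"))
  }
  run_stage <- function(name, params, expr) {
    stage(name, params)
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)), call. = FALSE)
    })
  }

  as_cl <- function(x, branch) {
    if (inherits(x, "bifuse_centerline")) return(x)
    run_stage(paste0("triangulate_", branch),
              list(step = config$resample_step_mm),
              triangulate_centerlines(x$curveA, x$geomA, x$curveB, x$geomB))
  }
  as_pb <- function(x) if (is.character(x)) read_contour_stack(x) else x

  mv_pb <- as_pb(mv_pullback)
  sb_pb <- if (!is.null(sb_pullback)) as_pb(sb_pullback) else NULL
  have_sb <- !is.null(sb_pb) && !is.null(sb_centerline)
  if (!have_sb) warning("no SB inputs: reconstructing the main vessel only")

  mv_cl <- resample_by_arclength(as_cl(mv_centerline, "MV"), config$resample_step_mm)
  sb_cl <- if (have_sb) resample_by_arclength(as_cl(sb_centerline, "SB"),
                                              config$resample_step_mm) else NULL
  stage("resample", list(step_mm = config$resample_step_mm))

  prep_branch <- function(pb, cl, branch) {
    pb <- run_stage(paste0("gate_", branch), list(mode = config$mode), {
      gated <- vapply(pb$frames, function(f) f$gated, logical(1))
      if (config$mode == "bench" && !any(gated)) {
        # no ECG on the bench: use every frame
        for (i in seq_along(pb$frames)) pb$frames[[i]]$gated <- TRUE
      }
      select_gated_frames(pb)
    })
    rolls <- if (config$mode == "clinical") {
      run_stage(paste0("twist_", branch),
                list(grid = config$twist_grid_deg, refine = config$twist_refine_deg,
                     span = config$twist_span_deg),
                correct_relative_twist(pb, span_deg = config$twist_span_deg,
                                       grid_deg = config$twist_grid_deg,
                                       refine_deg = config$twist_refine_deg))
    } else {
      stage(paste0("twist_", branch), list(skipped = "bench mode"))
      rep(0, length(pb$frames))
    }
    pl <- run_stage(paste0("place_", branch), list(s0 = config$s0_mm),
                    place_frames(pb, cl, s0 = config$s0_mm, rolls = rolls))
    list(pb = pb, pl = pl)
  }

  mv <- prep_branch(mv_pb, mv_cl, "MV")
  sb <- if (have_sb) prep_branch(sb_pb, sb_cl, "SB") else NULL

  if (have_sb && !is.na(mv$pb$carina_frame) && !is.na(sb$pb$carina_frame)) {
    reg <- run_stage("register_carina", list(),
                     register_carina(mv$pl, sb$pl, mv$pb, sb$pb, mv_cl, sb_cl))
    mv$pl <- reg$mv
    sb$pl <- reg$sb
    stage("register_carina_residual", as.list(reg$residual_deg))
  }

  fix_path <- function(br, branch) {
    path <- catheter_path(br$pl)
    brk <- NULL
    corr <- run_stage(paste0("catheter_path_", branch), list(k = config$outlier_k),
                      correct_catheter_path(path, k = config$outlier_k, break_at = brk))
    br$pl <- apply_path_correction(br$pl, corr)
    br$path <- corr
    br
  }
  mv <- fix_path(mv, "MV")
  if (have_sb) sb <- fix_path(sb, "SB")

  build_branch <- function(br, branch) {
    placed <- function(label) {
      out <- list()
      for (i in seq_along(br$pb$frames)) {
        for (ct in br$pb$frames[[i]]$contours) {
          if (ct$label == label) out[[length(out) + 1L]] <- placed_contour(ct, br$pl[[i]])
        }
      }
      out
    }
    lum_pc <- placed("lumen")
    mesh <- run_stage(paste0("loft_", branch), list(n_theta = config$n_theta),
                      loft_surface(lum_pc, n_theta = config$n_theta))
    mesh <- run_stage(paste0("refine_", branch),
                      list(tol = config$refine_tol_mm, max_iter = config$refine_max_iter),
                      suppressWarnings(refine_to_contours(mesh, lum_pc,
                                                          tol = config$refine_tol_mm,
                                                          max_iter = config$refine_max_iter)))
    eem_pc <- placed("eem")
    eem <- if (length(eem_pc) >= 2L) {
      run_stage(paste0("loft_eem_", branch), list(), loft_surface(eem_pc, config$n_theta))
    } else NULL
    plaques <- list()
    for (lab in c("calcium", "fibrosis", "fibrolipid")) {
      pc <- placed(lab)
      if (length(pc)) {
        solids <- run_stage(paste0("plaque_", lab, "_", branch),
                            list(tau = config$plaque_overlap_tau),
                            loft_plaque_components(pc, tau = config$plaque_overlap_tau))
        if (length(solids)) plaques[[lab]] <- c(plaques[[lab]], solids)
      }
    }
    list(mesh = mesh, eem = eem, plaques = plaques, lum_pc = lum_pc)
  }

  mvb <- build_branch(mv, "MV")
  if (have_sb) {
    sbb <- build_branch(sb, "SB")
    lumen <- run_stage("merge", list(pitch = config$union_pitch_mm),
                       merge_branches(mvb$mesh, sbb$mesh, pitch = config$union_pitch_mm))
    eem <- if (!is.null(mvb$eem) && !is.null(sbb$eem)) {
      merge_branches(mvb$eem, sbb$eem, pitch = config$union_pitch_mm)
    } else mvb$eem
    carina <- run_stage("carina_point", list(),
                        find_carina_point(lumen, mv_cl, sb_cl))
  } else {
    sbb <- NULL
    lumen <- mvb$mesh
    eem <- mvb$eem
    carina <- c(NA_real_, NA_real_, NA_real_)
  }

  mapback <- list(MV = run_stage("mapback_MV", list(),
                                 map_back_check(mvb$mesh, mvb$lum_pc)))
  if (have_sb) mapback$SB <- run_stage("mapback_SB", list(),
                                       map_back_check(sbb$mesh, sbb$lum_pc))

  plaques <- mvb$plaques
  if (have_sb) for (lab in names(sbb$plaques)) {
    plaques[[lab]] <- c(plaques[[lab]], sbb$plaques[[lab]])
  }
  model <- bifurcation_model(lumen, mv_cl,
                             if (have_sb) sb_cl else mv_cl,
                             carina, eem = eem, plaques = plaques)

  manifest <- list(
    config = config,
    branches = if (have_sb) c("MV", "SB") else "MV",
    lumen = list(volume_mm3 = mesh_volume(lumen),
                 n_triangles = nrow(lumen$triangles),
                 sha = digest::digest(list(round(lumen$vertices, 9), lumen$triangles))),
    plaques = lapply(plaques, function(solids) {
      lapply(solids, function(msh) list(volume_mm3 = mesh_volume(msh),
                                        n_triangles = nrow(msh$triangles)))
    }),
    mapback_mean_mm = vapply(mapback, function(r) mean(r$mean_dev), numeric(1)))

  result <- list(model = model, mapback = mapback,
                 mv = mvb, sb = sbb, placements = list(MV = mv$pl, SB = if (have_sb) sb$pl),
                 log = log, manifest = manifest)

  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    write_model(model, output_dir)
    jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
    jsonlite::write_json(log, file.path(output_dir, "log.json"),
                         auto_unbox = TRUE, digits = NA)
    write_placements_csv(mv$pl, file.path(output_dir, "placements_MV.csv"))
    if (have_sb) write_placements_csv(sb$pl, file.path(output_dir, "placements_SB.csv"))
  }
  result
}

#' Write a bifurcation model to a directory
#'
#' Layout: `lumen.ply` (+ `eem.ply`, `<label>_<i>.ply`), `mv_centerline.csv`,
#' `sb_centerline.csv` (x,y,z mm) and `carina.json`.
#'
#' @param model A [bifurcation_model()].
#' @param dir Target directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_model <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_mesh(model$lumen, file.path(dir, "lumen.ply"))
  if (!is.null(model$eem)) write_mesh(model$eem, file.path(dir, "eem.ply"))
  for (lab in names(model$plaques)) {
    solids <- model$plaques[[lab]]
    for (i in seq_along(solids)) {
      write_mesh(solids[[i]], file.path(dir, sprintf("%s_%d.ply", lab, i)))
    }
  }
  wcl <- function(cl, f) {
    df <- as.data.frame(cl$points)
    names(df) <- c("x_mm", "y_mm", "z_mm")
    write.csv(df, file.path(dir, f), row.names = FALSE)
  }
  wcl(model$mv_centerline, "mv_centerline.csv")
  wcl(model$sb_centerline, "sb_centerline.csv")
  jsonlite::write_json(list(carina_point_mm = model$carina_point),
                       file.path(dir, "carina.json"), auto_unbox = FALSE, digits = NA)
  invisible(dir)
}

#' Read a bifurcation model from a directory written by [write_model()]
#' @param dir Model directory.
#' @return A [bifurcation_model()].
#' @export
read_model <- function(dir) {
  lumen <- read_mesh(file.path(dir, "lumen.ply"), "lumen")
  eem_path <- file.path(dir, "eem.ply")
  eem <- if (file.exists(eem_path)) read_mesh(eem_path, "eem") else NULL
  rcl <- function(f) {
    df <- read.csv(file.path(dir, f))
    centerline3d(as.matrix(df))
  }
  car <- jsonlite::fromJSON(file.path(dir, "carina.json"))$carina_point_mm
  plaques <- list()
  for (lab in c("calcium", "fibrosis", "fibrolipid")) {
    fs <- sort(list.files(dir, pattern = paste0("^", lab, "_\\d+\\.ply$"), full.names = TRUE))
    if (length(fs)) plaques[[lab]] <- lapply(fs, read_mesh, label = lab)
  }
  bifurcation_model(lumen, rcl("mv_centerline.csv"), rcl("sb_centerline.csv"),
                    car, eem = eem, plaques = plaques)
}

write_placements_csv <- function(placements, path) {
  rows <- lapply(placements, function(pl) {
    q <- triad_to_quaternion(cbind(pl$t, pl$u, pl$v))
    data.frame(frame_index = pl$frame_index, s_mm = pl$s,
               x_mm = pl$origin[1], y_mm = pl$origin[2], z_mm = pl$origin[3],
               qw = q[1], qx = q[2], qy = q[3], qz = q[4], roll_deg = pl$roll,
               shift_u_mm = pl$shift[1], shift_v_mm = pl$shift[2])
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

triad_to_quaternion <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    c(0.25 * s, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s, (R[2, 1] - R[1, 2]) / s)
  } else {
    i <- which.max(c(R[1, 1], R[2, 2], R[3, 3]))
    j <- i %% 3 + 1; k <- j %% 3 + 1
    s <- sqrt(R[i, i] - R[j, j] - R[k, k] + 1) * 2
    q <- numeric(4)
    q[1] <- (R[k, j] - R[j, k]) / s
    q[i + 1] <- 0.25 * s
    q[j + 1] <- (R[j, i] + R[i, j]) / s
    q[k + 1] <- (R[k, i] + R[i, k]) / s
    q
  }
}
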