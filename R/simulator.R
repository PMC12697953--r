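#' Parameters of the synthetic colony simulator
#'
#' The generator emulates a 2D monolayer colony of rod-shaped bacteria growing
#' from a single cell, recorded at a base interval of `dt_base` minutes:
#' exponential single-cell area growth around the colony rate with
#' multiplicative log-normal noise, diffusive centroid displacement, axial
#' orientation diffusion, and divisions into two equal daughters separated
#' along the mother axis whose orientations snap away from the mother axis by
#' a characteristic angle. The defaults are a desk-scale compression of a
#' multi-hour microfluidic experiment: a fast colony rate over few frames
#' keeps fixtures small while preserving the ratio of per-frame movement to
#' division frequency that makes tracking hard.
#'
#' @param n_frames number of base frames recorded.
#' @param dt_base minutes per base frame.
#' @param colony_rate area growth rate per minute.
#' @param growth_noise sd of the per-step growth-rate noise (added to
#'   `colony_rate` in the exponent).
#' @param motion_sd centroid random-walk scale in px per sqrt(min).
#' @param rotation_sd orientation diffusion scale in rad per sqrt(min).
#' @param division_area area threshold (px^2) at which a cell divides; each
#'   cell draws its personal threshold with log-normal jitter
#'   `division_area_sd`.
#' @param division_area_sd log-sd of the per-cell division threshold.
#' @param div_angle_mean,div_angle_sd each daughter's axis rotates away from
#'   the mother axis by `+/- Normal(div_angle_mean, div_angle_sd)` radians
#'   (so the inter-daughter snapping angle has mean `2 * div_angle_mean`).
#' @param div_distance_mean centre-to-centre separation of newborn daughters
#'   in px (along the mother axis).
#' @param detection_dropout probability, per detection, of being missed by the
#'   segmentation (must lie in `[0, 0.2]`).
#' @param initial_area area of the founder cell (px^2).
#' @param max_cells population cap; the simulation stops early (with a flag)
#'   if it is exceeded.
#' @return list of class `uat_sim_params`.
#' @export
sim_params <- function(n_frames = 60, dt_base = 1, colony_rate = 0.05,
                       growth_noise = 0.02, motion_sd = 1.5,
                       rotation_sd = 0.05, division_area = 200,
                       division_area_sd = 0.1, div_angle_mean = 0.15,
                       div_angle_sd = 0.15, div_distance_mean = 8,
                       detection_dropout = 0,
                       initial_area = if (is.finite(division_area))
                         division_area / 2 else 100,
                       max_cells = 1000) {
  if (detection_dropout < 0 || detection_dropout > 0.2) {
    uat_abort("detection_dropout must lie in [0, 0.2]", "uat_error_bad_params")
  }
  sds <- c(growth_noise, motion_sd, rotation_sd, division_area_sd,
           div_angle_sd)
  if (any(sds < 0)) {
    uat_abort("noise scales must be non-negative", "uat_error_bad_params")
  }
  structure(list(n_frames = n_frames, dt_base = dt_base,
                 colony_rate = colony_rate, growth_noise = growth_noise,
                 motion_sd = motion_sd, rotation_sd = rotation_sd,
                 division_area = division_area,
                 division_area_sd = division_area_sd,
                 div_angle_mean = div_angle_mean, div_angle_sd = div_angle_sd,
                 div_distance_mean = div_distance_mean,
                 detection_dropout = detection_dropout,
                 initial_area = initial_area, max_cells = max_cells),
            class = "uat_sim_params")
}

wrap_axial <- function(theta) theta %% pi

#' Simulate a colony time-lapse with ground-truth lineage
#'
#' Runs the stochastic single-cell model of [sim_params()] from one founder
#' cell and records per-frame detections plus the true lineage forest.
#' Detections dropped by the simulated segmentation truncate the ground-truth
#' tracks (the orphaned re-detection becomes an appearance), exactly as
#' segmentation artifacts do in real pipelines.
#'
#' @param params a `uat_sim_params`.
#' @param seed optional integer seed.
#' @return a `uat_dataset`: list with `detections`, `truth` (a
#'   `lineage_forest`), `dt` (minutes per processed frame), `params`, `capped`
#'   (TRUE if the population cap stopped the run early) and `unresolved`
#'   (count of gap divisions not representable after sub-sampling; 0 here).
#' @export
simulate_colony <- function(params = sim_params(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- params
  dt <- p$dt_base
  draw_threshold <- function(n) {
    if (p$division_area_sd == 0) rep(p$division_area, n)
    else rlnorm(n, log(p$division_area), p$division_area_sd)
  }
  # live-cell state
  cells <- data.frame(x = 0, y = 0, area = p$initial_area,
                      orientation = runif(1, 0, pi),
                      threshold = draw_threshold(1),
                      det = NA_integer_)   # detection id in previous frame (NA if dropped)
  next_id <- 0L
  det_rows <- list()
  edge_rows <- list()
  capped <- FALSE
  record <- function(frame) {
    n <- nrow(cells)
    drop <- if (p$detection_dropout > 0) runif(n) < p$detection_dropout
            else rep(FALSE, n)
    ids <- rep(NA_integer_, n)
    keep <- which(!drop)
    if (length(keep) > 0) {
      ids[keep] <- next_id + seq_along(keep) - 1L
      next_id <<- next_id + length(keep)
      det_rows[[length(det_rows) + 1]] <<-
        data.frame(id = ids[keep], frame = frame, x = cells$x[keep],
                   y = cells$y[keep], area = cells$area[keep],
                   orientation = cells$orientation[keep])
      parent <- cells$parent_det[keep]
      has <- !is.na(parent)
      if (any(has)) {
        edge_rows[[length(edge_rows) + 1]] <<-
          data.frame(parent = parent[has], child = ids[keep][has])
      }
    }
    cells$det <<- ids
  }
  cells$parent_det <- NA_integer_
  record(0L)
  for (t in seq_len(p$n_frames - 1)) {
    n <- nrow(cells)
    # grow, move, rotate
    eps <- if (p$growth_noise > 0) rnorm(n, 0, p$growth_noise) else 0
    cells$area <- cells$area * exp((p$colony_rate + eps) * dt)
    if (p$motion_sd > 0) {
      cells$x <- cells$x + rnorm(n, 0, p$motion_sd * sqrt(dt))
      cells$y <- cells$y + rnorm(n, 0, p$motion_sd * sqrt(dt))
    }
    if (p$rotation_sd > 0) {
      cells$orientation <- wrap_axial(cells$orientation +
                                        rnorm(n, 0, p$rotation_sd * sqrt(dt)))
    }
    cells$parent_det <- cells$det  # identity edge to previous detection
    # divisions
    div <- which(cells$area > cells$threshold)
    if (length(div) > 0) {
      daughters <- lapply(div, function(i) {
        m <- cells[i, ]
        ux <- cos(m$orientation)
        uy <- sin(m$orientation)
        off <- p$div_distance_mean / 2
        rot <- if (p$div_angle_sd > 0) rnorm(2, p$div_angle_mean, p$div_angle_sd)
               else rep(p$div_angle_mean, 2)
        data.frame(x = m$x + c(off, -off) * ux, y = m$y + c(off, -off) * uy,
                   area = rep(m$area / 2, 2),
                   orientation = wrap_axial(m$orientation + c(rot[1], -rot[2])),
                   threshold = draw_threshold(2),
                   det = NA_integer_, parent_det = rep(m$det, 2))
      })
      cells <- rbind(cells[-div, , drop = FALSE], do.call(rbind, daughters))
    }
    if (nrow(cells) > p$max_cells) {
      warning("population cap exceeded; simulation stopped early")
      capped <- TRUE
      break
    }
    record(as.integer(t))
  }
  detections <- do.call(rbind, det_rows)
  detections <- detections[order(detections$id), , drop = FALSE]
  edges <- if (length(edge_rows) > 0) do.call(rbind, edge_rows) else NULL
  truth <- build_forest(edges, detections)
  structure(list(detections = as_detections(detections), truth = truth,
                 dt = dt, params = p, capped = capped, unresolved = 0L),
            class = "uat_dataset")
}

#' @export
print.uat_dataset <- function(x, ...) {
  cat(sprintf("<uat_dataset> %d detections, %d frames, dt = %g min, %d true divisions\n",
              nrow(x$detections), length(unique(x$detections$frame)), x$dt,
              nrow(divisions_of(x$truth))))
  invisible(x)
}

#' Sub-sample a dataset in time
#'
#' Emulates longer imaging intervals by keeping every `factor`-th frame:
#' kept frames are renumbered consecutively, the physical interval becomes
#' `dt * factor`, and ground-truth edges are composed across the skipped
#' frames (ancestor at one kept frame to descendant at the next). A cell with
#' two surviving descendants maps to a composed division; with more than two
#' (several divisions inside one gap) the division closest to the later kept
#' frame defines the daughter pair and the remaining descendants are recorded
#' as unresolvable appearances (counted in `unresolved`).
#'
#' @param dataset a `uat_dataset`.
#' @param factor integer sub-sampling factor (>= 1).
#' @return a `uat_dataset` on the sub-sampled frame axis.
#' @export
subsample_dataset <- function(dataset, factor) {
  stopifnot(factor >= 1, factor == floor(factor))
  if (factor == 1) return(dataset)
  det <- dataset$detections
  keep_frames <- seq(0, max(det$frame), by = factor)
  det2 <- det[det$frame %in% keep_frames, , drop = FALSE]
  det2$frame <- as.integer(match(det2$frame, keep_frames) - 1L)
  parent_of <- setNames(dataset$truth$parent_id, dataset$truth$detections$id)
  frame_of <- setNames(det$frame, det$id)
  # walk each kept detection `factor` base steps up to its ancestor at the
  # previous kept frame (NA if the chain is broken by dropout or a root)
  ancestor_at_prev_kept <- function(id) {
    cur <- id
    for (s in seq_len(factor)) {
      cur <- parent_of[[as.character(cur)]]
      if (is.na(cur)) return(NA_integer_)
    }
    cur
  }
  unresolved <- 0L
  edges <- list()
  for (kf in keep_frames[-1]) {
    ids <- det$id[det$frame == kf]
    if (length(ids) == 0) next
    anc <- vapply(ids, ancestor_at_prev_kept, integer(1))
    ok <- !is.na(anc)
    groups <- split(ids[ok], anc[ok])
    for (a in names(groups)) {
      g <- groups[[a]]
      if (length(g) == 1) {
        edges[[length(edges) + 1]] <- data.frame(parent = as.integer(a),
                                                 child = g)
      } else if (length(g) == 2) {
        edges[[length(edges) + 1]] <- data.frame(parent = as.integer(a),
                                                 child = g)
      } else {
        # >2 descendants: the gap division closest to the later kept frame
        # defines the pair; everything earlier is unresolvable
        pair <- latest_gap_division_pair(g, parent_of, frame_of, factor)
        edges[[length(edges) + 1]] <- data.frame(parent = as.integer(a),
                                                 child = pair)
        unresolved <- unresolved + length(g) - 2L
      }
    }
  }
  edges <- if (length(edges) > 0) do.call(rbind, edges) else NULL
  truth <- build_forest(edges, det2)
  structure(list(detections = as_detections(det2), truth = truth,
                 dt = dataset$dt * factor, params = dataset$params,
                 capped = dataset$capped,
                 unresolved = dataset$unresolved + unresolved),
            class = "uat_dataset")
}

latest_gap_division_pair <- function(descendants, parent_of, frame_of, factor) {
  # paths from each descendant up through the gap (most recent first)
  paths <- lapply(descendants, function(id) {
    path <- id
    cur <- id
    for (s in seq_len(factor)) {
      cur <- parent_of[[as.character(cur)]]
      path <- c(path, cur)
    }
    path
  })
  # the branching node with the largest frame whose two child branches both
  # lead to surviving descendants
  best_frame <- -1L
  best_pair <- descendants[1:2]
  n <- length(descendants)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      common <- intersect(paths[[i]], paths[[j]])
      branch <- common[which.max(frame_of[as.character(common)])]
      bf <- frame_of[[as.character(branch)]]
      if (bf > best_frame) {
        best_frame <- bf
        best_pair <- c(descendants[i], descendants[j])
      }
    }
  }
  sort(best_pair)
}
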