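#' Frame-indexed forest for batched lineage walks
#'
#' Re-packs a lineage forest into per-frame arrays (ids, positions, areas,
#' orientations) plus a parent-pointer array aligned to the previous frame's id
#' array (sentinel -1 for roots). All history queries then run as one
#' vectorised index lookup per ancestor level instead of per-cell recursion,
#' which is what makes feature extraction cheap for thousands of cells.
#'
#' @param forest a `lineage_forest`.
#' @return an object of class `frame_indexed_forest`: a list with one entry per
#'   processed frame, each holding `ids`, `x`, `y`, `area`, `orientation` and
#'   `parent_idx` (1-based index into the previous frame's arrays, -1 for
#'   roots), plus the number of children of the previous-frame parent
#'   (`parent_nchild`).
#' @export
to_indexed <- function(forest) {
  det <- forest$detections
  if (nrow(det) == 0) {
    return(structure(list(), class = "frame_indexed_forest"))
  }
  frames <- sort(unique(det$frame))
  frames <- seq(min(frames), max(frames))
  out <- vector("list", length(frames))
  prev_ids <- integer(0)
  nchild <- children_counts(forest)
  for (k in seq_along(frames)) {
    sel <- det$frame == frames[k]
    ids <- det$id[sel]
    par <- forest$parent_id[sel]
    idx <- match(par, prev_ids)
    idx[is.na(idx)] <- -1L
    pn <- ifelse(idx > 0, unname(nchild[as.character(par)]), 0L)
    out[[k]] <- list(frame = frames[k], ids = ids,
                     x = det$x[sel], y = det$y[sel],
                     area = det$area[sel], orientation = det$orientation[sel],
                     parent_idx = idx, parent_nchild = as.integer(pn))
    prev_ids <- ids
  }
  structure(out, class = "frame_indexed_forest")
}

#' Rebuild a lineage forest from its frame-indexed form
#' @param fif a `frame_indexed_forest`.
#' @return a `lineage_forest`; the round trip [to_indexed()] / `from_indexed()`
#'   is lossless.
#' @export
from_indexed <- function(fif) {
  if (length(fif) == 0) {
    return(build_forest(NULL, empty_detections()))
  }
  dets <- do.call(rbind, lapply(fif, function(f) {
    data.frame(id = f$ids, frame = f$frame, x = f$x, y = f$y,
               area = f$area, orientation = f$orientation)
  }))
  edges <- do.call(rbind, lapply(seq_along(fif)[-1], function(k) {
    f <- fif[[k]]
    keep <- f$parent_idx > 0
    data.frame(parent = fif[[k - 1]]$ids[f$parent_idx[keep]],
               child = f$ids[keep])
  }))
  build_forest(edges, dets)
}

frame_entry <- function(fif, frame) {
  for (f in fif) if (f$frame == frame) return(f)
  uat_abort(sprintf("frame %d not present in indexed forest", frame),
            "uat_error_bad_frame")
}

#' Batched ancestor histories
#'
#' For every detection in frame `t`, collect its own `(x, y, area)` and those
#' of up to `depth` ancestors, walking one whole frame level at a time (one
#' vectorised parent lookup per level, no per-cell recursion). Histories are
#' shorter for cells born later.
#'
#' @param fif a `frame_indexed_forest`.
#' @param frame processed frame index.
#' @param depth maximum number of ancestors (>= 1).
#' @return named list (by detection id); each element a data.frame with columns
#'   `x`, `y`, `area`, first row the detection itself, subsequent rows its
#'   ancestors from parent upwards.
#' @export
ancestor_features <- function(fif, frame, depth) {
  stopifnot(depth >= 1)
  fr <- frame_entry(fif, frame)
  n <- length(fr$ids)
  hist <- vector("list", n)
  for (i in seq_len(n)) {
    hist[[i]] <- data.frame(x = fr$x[i], y = fr$y[i], area = fr$area[i])
  }
  # level-by-level batched walk: `cur_idx[i]` is the row of the current
  # ancestor of detection i within the level's frame arrays (-1 once the walk
  # fell off a root)
  cur_idx <- seq_len(n)
  level <- fr
  k_pos <- match(frame, vapply(fif, `[[`, numeric(1), "frame"))
  for (d in seq_len(depth)) {
    if (k_pos - 1 < 1) break
    nxt_idx <- rep(-1L, n)
    pos <- cur_idx > 0
    nxt_idx[pos] <- level$parent_idx[cur_idx[pos]]
    k_pos <- k_pos - 1
    level <- fif[[k_pos]]
    alive <- which(nxt_idx > 0)
    if (length(alive) == 0) break
    for (i in alive) {
      j <- nxt_idx[i]
      hist[[i]] <- rbind(hist[[i]],
                         data.frame(x = level$x[j], y = level$y[j],
                                    area = level$area[j]))
    }
    cur_idx <- nxt_idx
  }
  names(hist) <- fr$ids
  hist
}

#' Per-cell velocity estimate from the last lineage edge
#'
#' `v = (pos(cell) - pos(parent)) / dt` in px/min. Roots (cells without
#' history) get `(0, 0)`; daughters of a division use their own parent edge
#' like any other cell.
#'
#' @param fif a `frame_indexed_forest`.
#' @param frame processed frame index.
#' @param dt physical minutes per processed frame.
#' @return data.frame with columns `id`, `vx`, `vy`.
#' @export
estimate_velocity <- function(fif, frame, dt) {
  fr <- frame_entry(fif, frame)
  vx <- numeric(length(fr$ids))
  vy <- numeric(length(fr$ids))
  if (frame > fif[[1]]$frame) {
    prev <- frame_entry(fif, frame - 1)
    has <- fr$parent_idx > 0
    vx[has] <- (fr$x[has] - prev$x[fr$parent_idx[has]]) / dt
    vy[has] <- (fr$y[has] - prev$y[fr$parent_idx[has]]) / dt
  }
  data.frame(id = fr$ids, vx = vx, vy = vy)
}

#' Per-cell area growth factor from the last lineage edge
#'
#' `g = area(cell) / area(parent)` per processed frame, clipped to
#' `clip` to guard against segmentation artifacts. A division roughly halves
#' the area, so daughters are referenced against `parent_area / 2`; without
#' that, the self-learning growth feature would see a spurious 0.5x collapse
#' at every division. Roots default to the colony-level prior
#' `exp(colony_rate * dt)` (or an explicit `default`).
#'
#' @param fif a `frame_indexed_forest`.
#' @param frame processed frame index.
#' @param dt minutes per processed frame.
#' @param colony_rate colony area growth rate per minute (sets the root
#'   default).
#' @param default explicit root default growth factor (overrides
#'   `colony_rate`).
#' @param clip length-2 numeric clipping interval.
#' @return data.frame with columns `id`, `g`.
#' @export
estimate_growth_factor <- function(fif, frame, dt, colony_rate = 0,
                                   default = NULL, clip = c(0.5, 4)) {
  if (is.null(default)) default <- exp(colony_rate * dt)
  fr <- frame_entry(fif, frame)
  g <- rep(default, length(fr$ids))
  if (frame > fif[[1]]$frame) {
    prev <- frame_entry(fif, frame - 1)
    has <- fr$parent_idx > 0
    ref <- prev$area[fr$parent_idx[has]] /
      ifelse(fr$parent_nchild[has] == 2L, 2, 1)
    g[has] <- fr$area[has] / ref
  }
  g <- pmin(pmax(g, clip[1]), clip[2])
  data.frame(id = fr$ids, g = g)
}

#' Colony-level area growth rate from segmentation only
#'
#' Ordinary least squares of `log(total segmented area)` against physical time
#' recovers the mean single-cell exponential growth rate of the colony without
#' any tracking information.
#'
#' @param detections detection table spanning >= 2 frames.
#' @param dt minutes per processed frame.
#' @return growth rate per minute (slope of the log-area regression).
#' @export
estimate_colony_growth_rate <- function(detections, dt) {
  detections <- as_detections(detections)
  total <- tapply(detections$area, detections$frame, sum)
  if (length(total) < 2) {
    uat_abort("need at least two frames with positive total area",
              "uat_error_too_few_frames")
  }
  time_min <- as.numeric(names(total)) * dt
  unname(coef(lm(log(as.numeric(total)) ~ time_min))[2])
}
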