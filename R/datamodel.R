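#' @useDynLib uatrack, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif rlnorm lm coef aggregate setNames
#' @importFrom utils read.csv write.csv read.table write.table
NULL

uat_abort <- function(message, class) {
  stop(errorCondition(message, class = c(class, "uat_error", "error")))
}

#' Validate a detection table
#'
#' A detection is one segmented cell instance in one frame, reduced to point
#' features: centroid position, area and major-axis orientation. Orientation is
#' axial (a rod has no head or tail), so it lives in `[0, pi)`.
#'
#' @param df data.frame with columns `id`, `frame`, `x`, `y`, `area`,
#'   `orientation`.
#' @return the validated data.frame (row order preserved).
#' @export
as_detections <- function(df) {
  required <- c("id", "frame", "x", "y", "area", "orientation")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    uat_abort(paste("missing detection columns:", paste(missing, collapse = ", ")),
              "uat_error_missing_column")
  }
  df <- as.data.frame(df)[required]
  if (anyDuplicated(df$id)) {
    uat_abort("duplicate detection ids", "uat_error_duplicate_id")
  }
  if (any(df$id < 0) || any(df$id != floor(df$id))) {
    uat_abort("detection ids must be non-negative integers", "uat_error_bad_id")
  }
  if (any(df$frame < 0)) {
    uat_abort("frames must be non-negative", "uat_error_bad_frame")
  }
  if (any(df$area <= 0)) {
    uat_abort("areas must be positive", "uat_error_negative_area")
  }
  if (any(df$orientation < 0 | df$orientation >= pi)) {
    uat_abort("orientation must lie in [0, pi)", "uat_error_bad_orientation")
  }
  df$id <- as.integer(df$id)
  df$frame <- as.integer(df$frame)
  rownames(df) <- NULL
  df
}

empty_detections <- function() {
  data.frame(id = integer(0), frame = integer(0), x = numeric(0),
             y = numeric(0), area = numeric(0), orientation = numeric(0))
}

new_lineage_forest <- function(detections, parent_id) {
  structure(list(detections = detections, parent_id = parent_id),
            class = "lineage_forest")
}

#' Build a validated cell lineage forest
#'
#' A cell lineage tree (CLT) is a bifurcated forest over detections: edges link
#' a cell to its identity (migration) or to its two daughters (division) in the
#' *next processed frame*. A node therefore has at most one parent and at most
#' two children, and every edge spans exactly one frame.
#'
#' @param edges two-column data.frame/matrix of (parent id, child id); may have
#'   zero rows.
#' @param detections detection table (see [as_detections()]).
#' @return an object of class `lineage_forest`.
#' @export
build_forest <- function(edges, detections) {
  detections <- as_detections(detections)
  if (is.null(edges) || NROW(edges) == 0) {
    return(new_lineage_forest(detections, rep(NA_integer_, nrow(detections))))
  }
  edges <- as.data.frame(edges)
  names(edges)[1:2] <- c("parent", "child")
  pid <- as.integer(edges$parent)
  cid <- as.integer(edges$child)
  ids <- detections$id
  if (!all(pid %in% ids) || !all(cid %in% ids)) {
    uat_abort("edge refers to unknown detection id", "uat_error_unknown_id")
  }
  if (anyDuplicated(cid)) {
    uat_abort("a detection has more than one parent", "uat_error_multiple_parents")
  }
  if (any(table(pid) > 2)) {
    uat_abort("a detection has more than two children", "uat_error_too_many_children")
  }
  # cycle check before frame consistency so a->b->a reports as a cycle
  nxt <- setNames(pid, cid)   # child -> parent walk
  for (start in cid) {
    seen <- start
    cur <- start
    repeat {
      cur <- nxt[as.character(cur)]
      if (is.na(cur)) break
      if (cur %in% seen) {
        uat_abort("edges form a cycle", "uat_error_cycle")
      }
      seen <- c(seen, cur)
    }
  }
  frame_of <- setNames(detections$frame, detections$id)
  if (any(frame_of[as.character(cid)] != frame_of[as.character(pid)] + 1L)) {
    uat_abort("edge does not span consecutive processed frames",
              "uat_error_bad_frame_edge")
  }
  parent_id <- rep(NA_integer_, nrow(detections))
  parent_id[match(cid, ids)] <- pid
  new_lineage_forest(detections, parent_id)
}

#' Edge list of a lineage forest
#' @param forest a `lineage_forest`.
#' @return data.frame with columns `parent`, `child` (one row per edge).
#' @export
forest_edges <- function(forest) {
  keep <- !is.na(forest$parent_id)
  data.frame(parent = forest$parent_id[keep],
             child = forest$detections$id[keep])
}

children_counts <- function(forest) {
  # named count of children per detection id (0 for leaves)
  ids <- forest$detections$id
  n <- tabulate(match(forest$parent_id, ids), nbins = length(ids))
  setNames(n, ids)
}

#' Division events of a forest
#'
#' A division is a node with exactly two children (both in the following
#' processed frame).
#'
#' @param forest a `lineage_forest`.
#' @return data.frame with columns `parent` (dividing detection id) and
#'   `frame` (frame of the parent).
#' @export
divisions_of <- function(forest) {
  n <- children_counts(forest)
  ids <- forest$detections$id[n == 2L]
  data.frame(parent = ids,
             frame = forest$detections$frame[match(ids, forest$detections$id)])
}

#' @export
print.lineage_forest <- function(x, ...) {
  cat(sprintf("<lineage_forest> %d detections, %d edges, %d divisions\n",
              nrow(x$detections), sum(!is.na(x$parent_id)),
              nrow(divisions_of(x))))
  invisible(x)
}

new_particle <- function(forest, log_weight = 0, frame = NULL) {
  if (is.null(frame)) {
    frame <- if (nrow(forest$detections) > 0) max(forest$detections$frame) else 0L
  }
  structure(list(forest = forest, log_weight = log_weight,
                 frame = as.integer(frame)),
            class = "uat_particle")
}

#' Extend a lineage particle by one frame-pair cover
#'
#' Applies a valid exact cover of assignments between the particle's last frame
#' and the next: migration and division candidates add edges, appearance
#' targets become new roots, disappearance sources become leaves. The
#' particle's cumulative log-weight increases by the summed candidate
#' log-scores.
#'
#' @param particle a `uat_particle`.
#' @param cover a `uat_cover` (see [solve_optimal()]).
#' @param targets detection table of the next processed frame.
#' @return the extended particle.
#' @export
extend_particle <- function(particle, cover, targets) {
  targets <- as_detections(targets)
  cand <- cover$candidates
  forest <- particle$forest
  src_ids <- forest$detections$id[forest$detections$frame == particle$frame]
  covered_src <- cand$source[!is.na(cand$source)]
  covered_tgt <- c(cand$target1[!is.na(cand$target1)],
                   cand$target2[!is.na(cand$target2)])
  if (length(covered_src) != length(src_ids) ||
      !setequal(covered_src, src_ids) || anyDuplicated(covered_src) ||
      length(covered_tgt) != nrow(targets) ||
      !setequal(covered_tgt, targets$id) || anyDuplicated(covered_tgt)) {
    uat_abort("assignment set is not a valid cover of sources and targets",
              "uat_error_invalid_cover")
  }
  if (any(targets$frame != particle$frame + 1L)) {
    uat_abort("targets must sit in the particle's next frame",
              "uat_error_bad_frame_edge")
  }
  dets <- rbind(forest$detections, targets)
  parent_id <- c(forest$parent_id, rep(NA_integer_, nrow(targets)))
  add_edge <- function(p, c) {
    parent_id[match(c, dets$id)] <<- as.integer(p)
  }
  for (i in seq_len(nrow(cand))) {
    kind <- cand$kind[i]
    if (kind == "migrate") {
      add_edge(cand$source[i], cand$target1[i])
    } else if (kind == "divide") {
      add_edge(cand$source[i], cand$target1[i])
      add_edge(cand$source[i], cand$target2[i])
    }
  }
  new_particle(new_lineage_forest(dets, parent_id),
               particle$log_weight + cover$total_log_score,
               particle$frame + 1L)
}
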