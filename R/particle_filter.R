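split_frames <- function(detections) {
  detections <- as_detections(detections)
  if (nrow(detections) == 0) return(list(empty_detections()))
  frames <- 0:max(detections$frame)
  lapply(frames, function(f) detections[detections$frame == f, , drop = FALSE])
}

#' Initialise the lineage particle filter
#'
#' Every particle starts as the same trivial cell lineage tree hypothesis: a
#' forest of singleton roots, one per frame-0 detection, with log-weight 0.
#'
#' @param detections0 detection table of frame 0 (may be empty).
#' @param n_particles number of particles (>= 1).
#' @param seed optional integer seed (sets the R RNG).
#' @return a `uat_filter` state: list with `particles`, `frame`,
#'   `map_particle` (pre-resampling maximum-weight particle).
#' @export
init_filter <- function(detections0, n_particles = 1, seed = NULL) {
  stopifnot(n_particles >= 1)
  if (!is.null(seed)) set.seed(seed)
  detections0 <- as_detections(detections0)
  forest <- build_forest(NULL, detections0)
  particles <- replicate(n_particles, new_particle(forest, 0, 0L),
                         simplify = FALSE)
  structure(list(particles = particles, frame = 0L,
                 map_particle = particles[[1]]),
            class = "uat_filter")
}

systematic_resample <- function(weights, u) {
  # u ~ U(0,1); returns indices of the resampled particles
  n <- length(weights)
  cum <- cumsum(weights / sum(weights))
  findInterval((u + 0:(n - 1)) / n, cum) + 1L
}

particle_features <- function(particle, config) {
  det <- particle$forest$detections
  if (nrow(det) == 0 || !any(det$frame == particle$frame)) {
    return(default_features(config, integer(0)))
  }
  fif <- to_indexed(particle$forest)
  v <- estimate_velocity(fif, particle$frame, config$params$dt)
  g <- estimate_growth_factor(fif, particle$frame, config$params$dt,
                              colony_rate = config$params$colony_rate,
                              clip = config$params$growth_clip)
  cbind(v, g = g$g)
}

#' Advance the filter by one processed frame
#'
#' For each particle, assignment candidates between its last frame and the
#' next detections are generated and scored using history features harvested
#' from that particle's own forest (each hypothesis learns from its own past:
#' the self-learning capacity). The `k` best covers are computed and one is
#' sampled per offspring with probability proportional to
#' `exp(score - max score)` (softmax at temperature 1). The offspring
#' population is then reduced back to `n_particles` by systematic resampling
#' on the per-step score increments; the pre-resampling maximum cumulative
#' weight particle is kept aside as the MAP estimate.
#'
#' @param state a `uat_filter`.
#' @param next_detections detection table of the next processed frame.
#' @param config a `uat_config`.
#' @param k number of best covers sampled from per particle.
#' @return the advanced `uat_filter`.
#' @export
filter_step <- function(state, next_detections, config, k = 1) {
  next_detections <- as_detections(next_detections)
  n <- length(state$particles)
  offspring <- vector("list", n)
  step_scores <- numeric(n)
  for (i in seq_len(n)) {
    p <- state$particles[[i]]
    src <- p$forest$detections[p$forest$detections$frame == p$frame, ,
                               drop = FALSE]
    features <- particle_features(p, config)
    problem <- generate_candidates(src, next_detections, config, features)
    covers <- k_best_covers(problem, k)
    scores <- vapply(covers, `[[`, numeric(1), "total_log_score")
    if (length(covers) == 1) {
      j <- 1L
    } else {
      w <- exp(scores - max(scores))
      j <- sample.int(length(covers), 1, prob = w)
    }
    offspring[[i]] <- extend_particle(p, covers[[j]], next_detections)
    step_scores[i] <- scores[j]
  }
  cum <- vapply(offspring, `[[`, numeric(1), "log_weight")
  map_particle <- offspring[[which.max(cum)]]  # which.max: lowest index wins ties
  if (n == 1) {
    particles <- offspring
  } else {
    w <- exp(step_scores - max(step_scores))
    idx <- systematic_resample(w, runif(1))
    particles <- offspring[idx]
  }
  structure(list(particles = particles, frame = state$frame + 1L,
                 map_particle = map_particle),
            class = "uat_filter")
}

#' Run the tracker over a whole time-lapse
#'
#' Initialises the filter on frame 0 and repeats the candidate generation /
#' scoring / cover sampling / resampling cycle for every pair of consecutive
#' processed frames, yielding an approximation of the posterior distribution
#' over cell lineage trees. Deterministic given `seed`. With
#' `n_particles = 1, k = 1` the filter degenerates to greedy per-frame-pair
#' optimal assignment (no sampling randomness).
#'
#' @param detections detection table covering frames `0..T`.
#' @param config a `uat_config`.
#' @param n_particles number of particles.
#' @param k number of best covers sampled from per particle and step.
#' @param seed optional integer seed.
#' @return the final `uat_filter` state.
#' @export
run_tracking <- function(detections, config, n_particles = 1, k = 1,
                         seed = NULL) {
  by_frame <- split_frames(detections)
  state <- init_filter(by_frame[[1]], n_particles, seed)
  for (t in seq_along(by_frame)[-1]) {
    state <- filter_step(state, by_frame[[t]], config, k)
  }
  state
}

#' Maximum a-posteriori lineage forest
#'
#' The forest of the particle with maximal cumulative log-weight, tracked
#' before resampling so that resampling cannot discard the best hypothesis;
#' ties resolve to the lowest particle index.
#'
#' @param state a `uat_filter`.
#' @return a `lineage_forest`.
#' @export
map_forest <- function(state) {
  state$map_particle$forest
}

#' Posterior edge marginals
#'
#' For every lineage edge present in any particle, the fraction of particles
#' containing it: an edge-level summary of the tracking uncertainty captured
#' by the particle distribution.
#'
#' @param state a `uat_filter`.
#' @return data.frame with columns `parent`, `child`, `fraction` (in (0, 1]).
#' @export
edge_marginals <- function(state) {
  n <- length(state$particles)
  all_edges <- do.call(rbind, lapply(state$particles, function(p) {
    e <- forest_edges(p$forest)
    if (nrow(e) > 0) e$key <- paste(e$parent, e$child, sep = ">")
    e
  }))
  if (is.null(all_edges) || nrow(all_edges) == 0) {
    return(data.frame(parent = integer(0), child = integer(0),
                      fraction = numeric(0)))
  }
  counts <- table(all_edges$key)
  first <- all_edges[!duplicated(all_edges$key), , drop = FALSE]
  out <- data.frame(parent = first$parent, child = first$child,
                    fraction = as.numeric(counts[first$key]) / n)
  out[order(out$parent, out$child), , drop = FALSE]
}
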