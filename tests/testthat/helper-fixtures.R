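# shared fixture builders (all generated in code, no files)

make_dets <- function(ids, frames, x = 0, y = 0, area = 100,
                      orientation = 0) {
  data.frame(id = ids, frame = frames,
             x = rep_len(x, length(ids)), y = rep_len(y, length(ids)),
             area = rep_len(area, length(ids)),
             orientation = rep_len(orientation, length(ids)))
}

# small simulated colony used wherever "a random forest" is needed
small_colony <- function(seed, n_frames = 25, ...) {
  simulate_colony(sim_params(n_frames = n_frames, ...), seed = seed)
}

zero_noise_params <- function(n_frames = 40) {
  sim_params(n_frames = n_frames, colony_rate = 0.05, growth_noise = 0,
             motion_sd = 0, rotation_sd = 0, division_area_sd = 0,
             div_angle_sd = 0, detection_dropout = 0)
}

# config whose scales match the zero-noise generator (sigmas must stay > 0).
# sigma_move keeps its default: newborn daughters carry the division offset
# (div_distance/2 = 4 px) in their velocity feature, so first-order position
# residuals of ~4 px are part of this world even without diffusive motion.
zero_noise_config <- function(name = "FO+G+O+DD", dt = 1) {
  make_config(name, dt = dt, colony_rate = 0.05,
              sigma_area = 0.02, sigma_growth = 0.02, mu_div_angle = 0.3,
              sigma_div_angle = 0.05)
}

# random frame-pair problem with geometric structure but fully random scores
random_problem <- function(seed, ns, nt, lambda = -5) {
  set.seed(seed)
  sources <- make_dets(seq_len(ns), rep(0L, ns), x = runif(ns, 0, 50),
                       y = runif(ns, 0, 50), area = runif(ns, 50, 150))
  targets <- make_dets(ns + seq_len(nt), rep(1L, nt), x = runif(nt, 0, 50),
                       y = runif(nt, 0, 50), area = runif(nt, 50, 150))
  if (ns == 0) sources <- make_dets(integer(0), integer(0))
  if (nt == 0) targets <- make_dets(integer(0), integer(0))
  cfg <- make_config("NN", r_max = Inf,
                     lambda_appear = lambda, lambda_disappear = lambda)
  problem <- generate_candidates(sources, targets, cfg)
  problem$candidates$log_score <- round(runif(nrow(problem$candidates),
                                              -10, 0), 3)
  problem
}

# naive per-cell parent chasing, the oracle for the batched lineage walks
naive_ancestors <- function(forest, id, depth) {
  det <- forest$detections
  out <- det[det$id == id, c("x", "y", "area")]
  cur <- id
  for (d in seq_len(depth)) {
    p <- forest$parent_id[match(cur, det$id)]
    if (is.na(p)) break
    out <- rbind(out, det[det$id == p, c("x", "y", "area")])
    cur <- p
  }
  rownames(out) <- NULL
  out
}

edge_key_set <- function(forest) {
  e <- forest_edges(forest)
  sort(paste(e$parent, e$child, sep = ">"))
}
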