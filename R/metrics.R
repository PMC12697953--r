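check_same_universe <- function(pred, ref) {
  if (!setequal(pred$detections$id, ref$detections$id)) {
    uat_abort("predicted and reference forests must cover the same detections",
              "uat_error_universe")
  }
}

#' Division detection precision / recall / F1
#'
#' A predicted division (parent `p` at frame `t`) matches an as-yet-unmatched
#' reference division on the same lineage within `frame_tolerance` frames;
#' matching is greedy by increasing frame distance. With the identity
#' detection correspondence used here a tolerance-0 match is simply the same
#' dividing detection; larger tolerances also accept a division placed a few
#' frames early or late along the same reference track.
#'
#' @param pred,ref `lineage_forest`s over the same detection ids.
#' @param frame_tolerance allowed frame offset (default 0).
#' @return named numeric vector `precision`, `recall`, `f1` (F1 is 0 when
#'   both are 0).
#' @export
division_f1 <- function(pred, ref, frame_tolerance = 0) {
  check_same_universe(pred, ref)
  pd <- divisions_of(pred)
  rd <- divisions_of(ref)
  if (nrow(pd) == 0 || nrow(rd) == 0) {
    matches <- 0
    precision <- if (nrow(pd) == 0) 1 else 0  # no predictions: vacuously precise
  } else {
    # candidate pairs within tolerance on the same reference lineage
    ref_parent <- setNames(ref$parent_id, ref$detections$id)
    same_lineage <- function(a, b) {
      if (a == b) return(TRUE)
      for (pair in list(c(a, b), c(b, a))) {
        cur <- pair[1]
        for (s in seq_len(frame_tolerance)) {
          cur <- ref_parent[[as.character(cur)]]
          if (is.na(cur)) break
          if (cur == pair[2]) return(TRUE)
        }
      }
      FALSE
    }
    cand <- expand.grid(i = seq_len(nrow(pd)), j = seq_len(nrow(rd)))
    cand$dist <- abs(pd$frame[cand$i] - rd$frame[cand$j])
    cand <- cand[cand$dist <= frame_tolerance, , drop = FALSE]
    if (nrow(cand) > 0) {
      ok <- mapply(function(i, j) same_lineage(pd$parent[i], rd$parent[j]),
                   cand$i, cand$j)
      cand <- cand[ok, , drop = FALSE]
    }
    cand <- cand[order(cand$dist, cand$i, cand$j), , drop = FALSE]
    used_i <- used_j <- integer(0)
    matches <- 0
    for (r in seq_len(nrow(cand))) {
      if (cand$i[r] %in% used_i || cand$j[r] %in% used_j) next
      used_i <- c(used_i, cand$i[r])
      used_j <- c(used_j, cand$j[r])
      matches <- matches + 1
    }
    precision <- matches / nrow(pd)
  }
  recall <- if (nrow(rd) == 0) 1 else matches / nrow(rd)
  f1 <- if (precision + recall == 0) 0 else 2 * precision * recall /
    (precision + recall)
  c(precision = precision, recall = recall, f1 = f1)
}

edge_keys <- function(forest) {
  e <- forest_edges(forest)
  paste(e$parent, e$child, sep = ">")
}

#' AOGM-style linking score (LNK)
#'
#' Edge-level tracking quality in `[0, 1]` (1 perfect). With the identity
#' vertex correspondence the cost of a prediction is the weighted count of
#' edge operations needed to turn it into the reference:
#' `w_EA` per reference edge missing from the prediction (to add), `w_ED` per
#' predicted edge absent from the reference (redundant), `w_EC` per shared
#' edge whose semantics differ (migration in one forest, division branch in
#' the other). The score is `1 - min(cost, cost_empty) / cost_empty`, where
#' `cost_empty = w_EA * |reference edges|` is the cost of predicting no edges
#' at all. Weights default to the published AOGM edge-weight convention
#' (1.5, 1, 1).
#'
#' @param pred,ref `lineage_forest`s over the same detection ids.
#' @param w_ea,w_ed,w_ec edge-operation weights.
#' @return score in `[0, 1]`; defined as 1 when both forests have no edges and
#'   0 when only the prediction is empty.
#' @export
lnk_score <- function(pred, ref, w_ea = 1.5, w_ed = 1, w_ec = 1) {
  check_same_universe(pred, ref)
  pk <- edge_keys(pred)
  rk <- edge_keys(ref)
  if (length(rk) == 0) {
    return(if (length(pk) == 0) 1 else 0)
  }
  shared <- intersect(pk, rk)
  missing <- setdiff(rk, pk)
  spurious <- setdiff(pk, rk)
  # wrong semantics: shared edge whose parent divides in one forest only
  pn <- children_counts(pred)
  rn <- children_counts(ref)
  shared_parent <- as.character(sub(">.*", "", shared))
  wrong <- sum(pn[shared_parent] != rn[shared_parent])
  cost <- w_ea * length(missing) + w_ed * length(spurious) + w_ec * wrong
  cost_empty <- w_ea * length(rk)
  1 - min(cost, cost_empty) / cost_empty
}

#' Full evaluation report
#'
#' @param pred,ref `lineage_forest`s over the same detection ids.
#' @param frame_tolerance passed to [division_f1()].
#' @return list with division precision/recall/F1, `lnk` and edge counts
#'   (`edges_correct`, `edges_missing`, `edges_redundant`,
#'   `edges_wrong_semantics`).
#' @export
eval_report <- function(pred, ref, frame_tolerance = 0) {
  d <- division_f1(pred, ref, frame_tolerance)
  pk <- edge_keys(pred)
  rk <- edge_keys(ref)
  shared <- intersect(pk, rk)
  pn <- children_counts(pred)
  rn <- children_counts(ref)
  shared_parent <- as.character(sub(">.*", "", shared))
  list(division_precision = unname(d["precision"]),
       division_recall = unname(d["recall"]),
       division_f1 = unname(d["f1"]),
       lnk = lnk_score(pred, ref),
       edges_correct = length(shared),
       edges_missing = length(setdiff(rk, pk)),
       edges_redundant = length(setdiff(pk, rk)),
       edges_wrong_semantics = if (length(shared) == 0) 0L
         else sum(pn[shared_parent] != rn[shared_parent]))
}

#' Tracking degradation under time sub-sampling
#'
#' The central in-silico experiment: simulate a colony at the base interval,
#' sub-sample it by each factor, re-run the tracker with each configuration
#' (with its time-dependent parameters adjusted to the longer interval) and
#' evaluate against the composed ground truth. Results are averaged over
#' seeds.
#'
#' @param params a `uat_sim_params`.
#' @param factors integer sub-sampling factors.
#' @param configs character vector of configuration names.
#' @param seeds integer seeds (one simulation per seed).
#' @param n_particles,k tracker settings (defaults give the greedy
#'   per-frame-pair optimum).
#' @param ... extra overrides passed to [make_config()].
#' @return data.frame with one row per (config, factor): mean division F1 and
#'   mean LNK over seeds.
#' @export
degradation_experiment <- function(params, factors, configs, seeds,
                                   n_particles = 1, k = 1, ...) {
  rows <- list()
  for (seed in seeds) {
    base <- simulate_colony(params, seed = seed)
    for (f in factors) {
      ds <- subsample_dataset(base, f)
      for (cfg_name in configs) {
        cfg <- make_config(cfg_name, dt = ds$dt,
                           colony_rate = params$colony_rate, ...)
        state <- run_tracking(ds$detections, cfg, n_particles = n_particles,
                              k = k, seed = seed)
        rep <- eval_report(map_forest(state), ds$truth)
        rows[[length(rows) + 1]] <-
          data.frame(config = cfg_name, factor = f, seed = seed,
                     division_f1 = rep$division_f1, lnk = rep$lnk)
      }
    }
  }
  all <- do.call(rbind, rows)
  agg <- aggregate(cbind(division_f1, lnk) ~ config + factor, data = all,
                   FUN = mean)
  agg <- agg[order(match(agg$config, configs), agg$factor), , drop = FALSE]
  rownames(agg) <- NULL
  attr(agg, "per_seed") <- all
  agg
}
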