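new_cover <- function(problem, index) {
  # index and score are eager; the candidate subset is materialised on first
  # access only — the brute-force oracle creates tens of thousands of covers
  # of which almost all are never inspected further
  e <- new.env(parent = emptyenv())
  e$index <- as.integer(index)
  e$total_log_score <- sum(problem$candidates$log_score[index])
  delayedAssign("candidates", {
    structure(lapply(problem$candidates, `[`, index),
              names = names(problem$candidates),
              class = "data.frame",
              row.names = c(NA_integer_, -length(index)))
  }, assign.env = e)
  class(e) <- "uat_cover"
  e
}

#' Generate scored assignment candidates for one frame pair
#'
#' Enumerates all plausible assignments linking the sources (frame t) to the
#' targets (frame t+1), filtered for sensible proposals: migrations for every
#' source/target pair within radius `r_max` of the source, divisions for every
#' source and target pair with both daughters within `r_max` and daughter
#' separation at most `d_div_max`, plus one appearance per target and one
#' disappearance per source (which guarantee feasibility of the exact cover).
#' Every candidate carries its log-score under the configuration's models.
#'
#' @param sources detection table at frame t (may be empty).
#' @param targets detection table at frame t+1 (may be empty).
#' @param config a `uat_config`.
#' @param features per-source history features (`id`, `vx`, `vy`, `g`);
#'   `NULL` for root defaults.
#' @return a `uat_problem`: list with `sources`, `targets` and a `candidates`
#'   data.frame (`kind`, `source`, `target1`, `target2`, `log_score`).
#' @export
generate_candidates <- function(sources, targets, config, features = NULL) {
  sources <- as_detections(sources)
  targets <- as_detections(targets)
  p <- config$params
  ns <- nrow(sources)
  nt <- nrow(targets)

  mig <- div <- NULL
  if (ns > 0 && nt > 0) {
    si <- rep(seq_len(ns), each = nt)
    ti <- rep(seq_len(nt), times = ns)
    d <- sqrt((sources$x[si] - targets$x[ti])^2 +
              (sources$y[si] - targets$y[ti])^2)
    keep <- d <= p$r_max
    if (any(keep)) {
      mig <- data.frame(kind = "migrate",
                        source = sources$id[si[keep]],
                        target1 = targets$id[ti[keep]],
                        target2 = NA_integer_,
                        si = si[keep], t1i = ti[keep], t2i = NA_integer_)
    }
    # divisions: per source, all pairs of in-radius targets close to each other
    div_rows <- vector("list", ns)
    for (s in seq_len(ns)) {
      near <- which(sqrt((targets$x - sources$x[s])^2 +
                         (targets$y - sources$y[s])^2) <= p$r_max)
      if (length(near) < 2) next
      pairs <- utils::combn(near, 2)
      sep <- sqrt((targets$x[pairs[1, ]] - targets$x[pairs[2, ]])^2 +
                  (targets$y[pairs[1, ]] - targets$y[pairs[2, ]])^2)
      ok <- sep <= p$d_div_max
      if (!any(ok)) next
      div_rows[[s]] <- data.frame(kind = "divide",
                                  source = sources$id[s],
                                  target1 = targets$id[pairs[1, ok]],
                                  target2 = targets$id[pairs[2, ok]],
                                  si = s, t1i = pairs[1, ok], t2i = pairs[2, ok])
    }
    div <- do.call(rbind, div_rows)
  }
  unary <- rbind(
    if (ns > 0) data.frame(kind = "disappear", source = sources$id,
                           target1 = NA_integer_, target2 = NA_integer_,
                           si = seq_len(ns), t1i = NA_integer_,
                           t2i = NA_integer_),
    if (nt > 0) data.frame(kind = "appear", source = NA_integer_,
                           target1 = targets$id, target2 = NA_integer_,
                           si = NA_integer_, t1i = seq_len(nt),
                           t2i = NA_integer_))
  cand <- rbind(mig, div, unary)
  if (is.null(cand)) {
    cand <- data.frame(kind = character(0), source = integer(0),
                       target1 = integer(0), target2 = integer(0),
                       si = integer(0), t1i = integer(0), t2i = integer(0))
  }
  # vectorised scoring per kind
  score <- numeric(nrow(cand))
  is_mig <- cand$kind == "migrate"
  if (any(is_mig)) {
    score[is_mig] <- score_migration(config,
                                     sources[cand$si[is_mig], , drop = FALSE],
                                     targets[cand$t1i[is_mig], , drop = FALSE],
                                     features)
  }
  is_div <- cand$kind == "divide"
  if (any(is_div)) {
    score[is_div] <- score_division(config,
                                    sources[cand$si[is_div], , drop = FALSE],
                                    targets[cand$t1i[is_div], , drop = FALSE],
                                    targets[cand$t2i[is_div], , drop = FALSE],
                                    features)
  }
  score[cand$kind == "appear"] <- score_appear(config, sum(cand$kind == "appear"))
  score[cand$kind == "disappear"] <-
    score_disappear(config, sum(cand$kind == "disappear"))
  cand$log_score <- score
  rownames(cand) <- NULL
  structure(list(sources = sources, targets = targets, candidates = cand),
            class = "uat_problem")
}

solver_inputs <- function(problem) {
  cand <- problem$candidates
  list(ns = nrow(problem$sources), nt = nrow(problem$targets),
       src = as.integer(ifelse(is.na(cand$si), -1L, cand$si - 1L)),
       t1 = as.integer(ifelse(is.na(cand$t1i), -1L, cand$t1i - 1L)),
       t2 = as.integer(ifelse(is.na(cand$t2i), -1L, cand$t2i - 1L)),
       score = as.numeric(cand$log_score))
}

#' Optimal frame-to-frame assignment cover
#'
#' Selects the subset of candidates maximising the total log-score subject to
#' exact-cover constraints: every source and every target is covered by
#' exactly one selected assignment (the canonical integer-program encoding of
#' the linking problem with divisions; solved here by exact branch and bound).
#' Among equal-score optima, the solution with fewer appear+disappear events
#' and then the lexicographically smallest candidate set is returned, so
#' results are deterministic.
#'
#' @param problem a `uat_problem` from [generate_candidates()].
#' @return a `uat_cover`: list with `index` (rows into
#'   `problem$candidates`), `candidates` and `total_log_score`.
#' @export
solve_optimal <- function(problem) {
  covers <- k_best_covers(problem, 1)
  if (length(covers) == 0) {
    uat_abort("assignment problem is infeasible", "uat_error_infeasible")
  }
  covers[[1]]
}

#' k best assignment covers
#'
#' Iteratively re-solves the exact-cover problem with an exclusion constraint
#' forbidding each previously returned solution, yielding up to `k` distinct
#' covers in non-increasing score order; the first equals [solve_optimal()].
#'
#' @param problem a `uat_problem`.
#' @param k maximum number of covers.
#' @param max_nodes deterministic cap on branch-and-bound expansions per
#'   solve (0 = unlimited). The default is far above what realistic frame
#'   pairs need; if a degenerate flat-score instance ever hits it, the best
#'   cover found is returned and a warning is raised.
#' @return list of `uat_cover`, possibly shorter than `k` when the problem
#'   admits fewer covers (candidates strictly dominated by their
#'   disappear+appear replacement are never part of an optimal cover and are
#'   not enumerated).
#' @export
k_best_covers <- function(problem, k, max_nodes = 5e6) {
  inp <- solver_inputs(problem)
  if (inp$ns == 0 && inp$nt == 0) {
    # the empty cover is the unique solution
    return(if (k >= 1) list(new_cover(problem, integer(0))) else list())
  }
  out <- list()
  forbidden <- list()
  for (i in seq_len(k)) {
    sel <- .solve_cover_cpp(inp$ns, inp$nt, inp$src, inp$t1, inp$t2,
                            inp$score, forbidden, max_nodes)
    if (!isTRUE(attr(sel, "complete"))) {
      warning("branch-and-bound node cap reached; returned cover may be suboptimal")
    }
    if (length(sel) == 0) break  # all covers exhausted
    out[[length(out) + 1]] <- new_cover(problem, sel)
    forbidden[[length(forbidden) + 1]] <- sel
  }
  out
}

#' Exhaustive enumeration of assignment covers (test oracle)
#'
#' Enumerates every exact cover of a small frame-pair problem by recursion
#' over sources, then sorts by (score desc, fewer appear+disappear,
#' lexicographic candidate set). Guarded to at most 8 sources and 8 targets;
#' intended as an independent oracle for the branch-and-bound solver.
#'
#' @param problem a `uat_problem` with at most 8 sources and 8 targets.
#' @return list of `uat_cover`, best first.
#' @export
enumerate_bruteforce <- function(problem) {
  ns <- nrow(problem$sources)
  nt <- nrow(problem$targets)
  if (ns > 8 || nt > 8) {
    uat_abort("brute-force enumeration guarded to <= 8 sources and targets",
              "uat_error_guard")
  }
  cand <- problem$candidates
  appear_idx <- which(cand$kind == "appear")
  appear_of <- setNames(appear_idx, cand$t1i[appear_idx])
  by_source <- lapply(seq_len(ns), function(s)
    which(!is.na(cand$si) & cand$si == s))
  appear_by_tgt <- unname(appear_of[as.character(seq_len(nt))])
  results <- vector("list", 1024)
  n_results <- 0L
  push <- function(sol) {
    n_results <<- n_results + 1L
    if (n_results > length(results)) {
      length(results) <<- 2L * length(results)  # grow by doubling
    }
    results[[n_results]] <<- sol
  }
  cand_t1 <- cand$t1i
  cand_t2 <- cand$t2i
  recurse <- function(s, chosen, taken) {
    if (s > ns) {
      push(c(chosen, appear_by_tgt[!taken]))
      return()
    }
    for (ci in by_source[[s]]) {
      t1 <- cand_t1[ci]
      t2 <- cand_t2[ci]
      if (!is.na(t1) && taken[t1]) next
      if (!is.na(t2) && taken[t2]) next
      tk <- taken
      if (!is.na(t1)) tk[t1] <- TRUE
      if (!is.na(t2)) tk[t2] <- TRUE
      recurse(s + 1, c(chosen, ci), tk)
    }
  }
  recurse(1, integer(0), logical(nt))
  results <- results[seq_len(n_results)]
  if (n_results > 0) {
    # sort every cover's index set in one vectorised pass
    lens <- lengths(results)
    all_idx <- unlist(results, use.names = FALSE)
    grp <- rep.int(seq_len(n_results), lens)
    o <- order(grp, all_idx)
    results <- unname(split(all_idx[o],
                            factor(grp[o], levels = seq_len(n_results))))
  }
  score_vec <- cand$log_score
  is_unary <- cand$kind %in% c("appear", "disappear")
  scores <- vapply(results, function(idx) sum(score_vec[idx]), numeric(1))
  unary_n <- vapply(results, function(idx) sum(is_unary[idx]), numeric(1))
  ord <- order(-scores, unary_n)
  # lexicographic candidate-set comparison only within score/unary ties
  # (building string keys for every cover is wasteful)
  i <- 1
  while (i < length(ord)) {
    j <- i
    while (j < length(ord) &&
           abs(scores[ord[j + 1]] - scores[ord[i]]) < 1e-9 &&
           unary_n[ord[j + 1]] == unary_n[ord[i]]) j <- j + 1
    if (j > i) {
      tied <- ord[i:j]
      keys <- vapply(results[tied], function(idx)
        paste(sprintf("%06d", idx), collapse = ","), character(1))
      ord[i:j] <- tied[order(keys)]
    }
    i <- j + 1
  }
  lapply(results[ord], function(idx) new_cover(problem, idx))
}

#' Check the exact-cover conservation laws of a cover
#'
#' In any valid cover, migrations + divisions + disappearances equal the
#' number of sources and migrations + 2 divisions + appearances equal the
#' number of targets.
#'
#' @param cover a `uat_cover`.
#' @param problem the `uat_problem` it solves.
#' @return logical.
#' @export
is_valid_cover <- function(cover, problem) {
  kinds <- table(factor(cover$candidates$kind,
                        levels = c("appear", "disappear", "migrate", "divide")))
  kinds[["migrate"]] + kinds[["divide"]] + kinds[["disappear"]] ==
    nrow(problem$sources) &&
    kinds[["migrate"]] + 2 * kinds[["divide"]] + kinds[["appear"]] ==
      nrow(problem$targets)
}
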