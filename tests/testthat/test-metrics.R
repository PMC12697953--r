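# independent set-arithmetic oracles for the metrics
naive_lnk <- function(pred, ref, w_ea = 1.5, w_ed = 1, w_ec = 1) {
  pe <- forest_edges(pred)
  re <- forest_edges(ref)
  pk <- paste(pe$parent, pe$child)
  rk <- paste(re$parent, re$child)
  if (length(rk) == 0) return(if (length(pk) == 0) 1 else 0)
  wrong <- 0
  for (key in intersect(pk, rk)) {
    par <- as.integer(strsplit(key, " ")[[1]][1])
    wrong <- wrong +
      ((sum(pe$parent == par) == 2) != (sum(re$parent == par) == 2))
  }
  cost <- w_ea * length(setdiff(rk, pk)) + w_ed * length(setdiff(pk, rk)) +
    w_ec * wrong
  1 - min(cost, w_ea * length(rk)) / (w_ea * length(rk))
}

naive_division_counts <- function(pred, ref) {
  pd <- divisions_of(pred)$parent
  rd <- divisions_of(ref)$parent
  c(matches = length(intersect(pd, rd)), n_pred = length(pd),
    n_ref = length(rd))
}

test_that("division F1 matches hand-counted fixtures", {
  ds <- small_colony(1, n_frames = 30)
  perfect <- division_f1(ds$truth, ds$truth)
  expect_equal(unname(perfect), c(1, 1, 1))

  # prediction without divisions: recall and F1 collapse to 0
  chain_only <- build_forest(NULL, ds$truth$detections)
  d0 <- division_f1(chain_only, ds$truth)
  expect_equal(unname(d0[c("recall", "f1")]), c(0, 0))

  # 4 reference divisions; prediction finds 3 plus 1 spurious -> 0.75 across
  dets <- make_dets(1:13, c(0L, 1L, 1L, 2L, 2L, 2L, 2L,
                            3L, 3L, 3L, 3L, 3L, 4L))
  ref_edges <- data.frame(parent = c(1, 1, 2, 2, 3, 3, 4, 4, 5, 6, 7),
                          child = c(2, 3, 4, 5, 6, 7, 8, 12, 9, 10, 11))
  ref <- build_forest(ref_edges, dets)          # divisions at 1, 2, 3, 4
  expect_equal(nrow(divisions_of(ref)), 4)
  pred_edges <- data.frame(parent = c(1, 1, 2, 2, 3, 3, 5, 5, 4),
                           child = c(2, 3, 4, 5, 6, 7, 9, 12, 8))
  pred <- build_forest(pred_edges, dets)        # finds 1, 2, 3 + spurious at 5
  expect_equal(unname(division_f1(pred, ref)), c(0.75, 0.75, 0.75))

  expect_error(division_f1(chain_only, small_colony(2, n_frames = 10)$truth),
               class = "uat_error_universe")
})

test_that("LNK follows the weighted edge-operation formula", {
  ds <- small_colony(3, n_frames = 25)
  expect_equal(lnk_score(ds$truth, ds$truth), 1)
  empty <- build_forest(NULL, ds$truth$detections)
  expect_equal(lnk_score(empty, ds$truth), 0)

  # 10 reference edges; prediction misses 2, adds 1 spurious
  dets <- make_dets(1:12, rep(0:5, each = 2))
  left <- seq(1, 11, by = 2)
  right <- seq(2, 12, by = 2)
  ref <- build_forest(data.frame(parent = c(left[-6], right[-6]),
                                 child = c(left[-1], right[-1])), dets)
  expect_equal(nrow(forest_edges(ref)), 10)
  pred <- build_forest(data.frame(parent = c(left[-c(5, 6)], right[-c(5, 6)], 9),
                                  child = c(left[-c(1, 6)], right[-c(1, 6)], 12)),
                       dets)
  expect_equal(lnk_score(pred, ref), 1 - (1.5 * 2 + 1) / 15, tolerance = 1e-12)
})

test_that("metrics agree with naive set-arithmetic on random forest pairs", {
  cfg <- make_config("NN", colony_rate = 0.05)
  for (seed in c(2, 7, 11)) {
    ds <- small_colony(seed, n_frames = 30)
    sub <- subsample_dataset(ds, 3)
    st <- run_tracking(sub$detections,
                       make_config("FO", dt = 3, colony_rate = 0.05),
                       seed = seed)
    pred <- map_forest(st)
    expect_equal(lnk_score(pred, sub$truth), naive_lnk(pred, sub$truth),
                 tolerance = 1e-12)
    d <- division_f1(pred, sub$truth)
    n <- naive_division_counts(pred, sub$truth)
    expect_equal(unname(d["precision"]),
                 if (n[["n_pred"]] == 0) 1 else n[["matches"]] / n[["n_pred"]])
    expect_equal(unname(d["recall"]), n[["matches"]] / n[["n_ref"]])
  }
})

test_that("metrics depend only on edge sets, not detection row order", {
  ds <- small_colony(5, n_frames = 25)
  sub <- subsample_dataset(ds, 2)
  st <- run_tracking(sub$detections,
                     make_config("NN", dt = 2, colony_rate = 0.05), seed = 1)
  pred <- map_forest(st)
  # permute detection rows of both forests
  perm <- sample(nrow(pred$detections))
  shuffle <- function(f, perm) {
    build_forest(forest_edges(f), f$detections[perm, , drop = FALSE])
  }
  expect_equal(lnk_score(shuffle(pred, perm), shuffle(sub$truth, perm)),
               lnk_score(pred, sub$truth))
  expect_equal(division_f1(shuffle(pred, perm), shuffle(sub$truth, perm)),
               division_f1(pred, sub$truth))
})

test_that("first-order tracking beats nearest neighbour on drifting cells", {
  # constant-velocity drift: three cells moving at 6 px/min in a row
  frames <- 0:9
  rows <- list()
  id <- 1L
  for (f in frames) {
    for (c in 0:2) {
      rows[[length(rows) + 1]] <-
        make_dets(id, as.integer(f), x = 6 * f, y = 25 * c,
                  area = 100 * exp(0.01 * f))
      id <- id + 1L
    }
  }
  det <- do.call(rbind, rows)
  truth_edges <- do.call(rbind, lapply(1:(length(frames) - 1), function(f) {
    data.frame(parent = (f - 1) * 3 + 1:3, child = f * 3 + 1:3)
  }))
  truth <- build_forest(truth_edges, det)
  lnk_of <- function(name) {
    cfg <- make_config(name, dt = 1, colony_rate = 0.01, sigma_move = 2)
    lnk_score(map_forest(run_tracking(det, cfg, seed = 1)), truth)
  }
  expect_gte(lnk_of("FO"), lnk_of("NN"))
  expect_equal(lnk_of("FO"), 1)
})

test_that("the degradation experiment is reproducible and sane at factor 1", {
  p <- sim_params(n_frames = 25, growth_noise = 0.01, motion_sd = 0.5)
  tab <- degradation_experiment(p, factors = c(1, 4),
                                configs = c("NN", "FO+G+O+DD"), seeds = 1:2)
  expect_equal(nrow(tab), 4)
  f1 <- tab[tab$factor == 1, ]
  expect_true(all(f1$lnk > 0.95))
  expect_true(all(f1$division_f1 > 0.95))
  tab2 <- degradation_experiment(p, factors = c(1, 4),
                                 configs = c("NN", "FO+G+O+DD"), seeds = 1:2)
  expect_identical(tab, tab2)
})
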