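test_that("deterministic growth follows the closed form", {
  p <- sim_params(n_frames = 11, colony_rate = 0.02, growth_noise = 0,
                  motion_sd = 0, rotation_sd = 0, division_area = Inf,
                  initial_area = 100)
  ds <- simulate_colony(p, seed = 1)
  expect_equal(nrow(divisions_of(ds$truth)), 0)  # single lineage
  a10 <- ds$detections$area[ds$detections$frame == 10]
  expect_equal(a10, 100 * exp(0.2), tolerance = 1e-12)
})

test_that("ground truth satisfies the lineage conservation laws", {
  for (seed in c(1, 5, 12)) {
    ds <- small_colony(seed, n_frames = 40)
    f <- ds$truth
    # build_forest re-validation: <= 1 parent, <= 2 children, frames consecutive
    expect_s3_class(build_forest(forest_edges(f), f$detections),
                    "lineage_forest")
    nch <- uatrack:::children_counts(f)
    expect_true(all(nch <= 2))
    # without dropout every non-frame-0 detection has exactly one parent
    non_root <- f$detections$frame > 0
    expect_true(all(!is.na(f$parent_id[non_root])))
    expect_gt(nrow(divisions_of(f)), 0)
  }
})

test_that("total colony area grows exponentially at the colony rate", {
  rates <- vapply(1:4, function(seed) {
    ds <- small_colony(seed, n_frames = 60)
    estimate_colony_growth_rate(ds$detections, dt = 1)
  }, numeric(1))
  expect_lt(abs(mean(rates) - 0.05) / 0.05, 0.10)
})

test_that("sub-sampling renumbers frames and composes edges", {
  ds <- small_colony(2, n_frames = 41)
  expect_identical(subsample_dataset(ds, 1), ds)
  for (f in c(2, 5)) {
    sub <- subsample_dataset(ds, f)
    expect_equal(length(unique(sub$detections$frame)), ceiling(41 / f))
    expect_equal(sort(unique(sub$detections$frame)),
                 0:(ceiling(41 / f) - 1))
    expect_equal(sub$dt, f)
    # re-validates the composed forest
    expect_s3_class(build_forest(forest_edges(sub$truth),
                                 sub$detections), "lineage_forest")
  }

  # chain a(f0) -> b(f1) -> c(f2), factor 2: composed edge a -> c
  dets <- make_dets(1:3, 0:2)
  chain <- list(detections = as_detections(dets),
                truth = build_forest(data.frame(parent = 1:2, child = 2:3),
                                     dets),
                dt = 1, params = NULL, capped = FALSE, unresolved = 0L)
  class(chain) <- "uat_dataset"
  sub <- subsample_dataset(chain, 2)
  expect_equal(forest_edges(sub$truth), data.frame(parent = 1L, child = 3L))
  expect_equal(sub$detections$frame, c(0L, 1L))

  # a divides at f1 into b, c; both persist to f2 -> composed division
  dets2 <- make_dets(1:5, c(0L, 1L, 1L, 2L, 2L))
  divd <- list(detections = as_detections(dets2),
               truth = build_forest(data.frame(parent = c(1, 1, 2, 3),
                                               child = c(2, 3, 4, 5)), dets2),
               dt = 1, params = NULL, capped = FALSE, unresolved = 0L)
  class(divd) <- "uat_dataset"
  sub2 <- subsample_dataset(divd, 2)
  expect_equal(divisions_of(sub2$truth)$parent, 1L)
  expect_setequal(forest_edges(sub2$truth)$child, c(4L, 5L))

  # two divisions in one gap, three survivors: latest division defines the
  # pair, the earlier daughter becomes an unresolvable appearance
  dets3 <- make_dets(1:8, c(0L, 1L, 1L, 2L, 2L, 2L, 3L, 3L))
  # 1 -> (2,3); 2 -> 4; 3 -> (5,6); survivors at f2: 4,5,6 (subsample f=2)
  truth3 <- build_forest(data.frame(parent = c(1, 1, 2, 3, 3, 4, 5),
                                    child = c(2, 3, 4, 5, 6, 7, 8)), dets3)
  d3 <- list(detections = as_detections(dets3), truth = truth3, dt = 1,
             params = NULL, capped = FALSE, unresolved = 0L)
  class(d3) <- "uat_dataset"
  sub3 <- subsample_dataset(d3, 2)
  e3 <- forest_edges(sub3$truth)
  expect_setequal(e3$child[e3$parent == 1], c(5L, 6L))  # latest division (at 3)
  expect_equal(sub3$unresolved, 1L)
})

test_that("detection dropout truncates tracks into appearances", {
  ds <- simulate_colony(sim_params(n_frames = 40, detection_dropout = 0.1),
                        seed = 3)
  f <- ds$truth
  late_roots <- is.na(f$parent_id) & f$detections$frame > 0
  expect_gt(sum(late_roots), 0)
  expect_s3_class(build_forest(forest_edges(f), f$detections),
                  "lineage_forest")
})

test_that("the population cap stops runaway colonies with a warning", {
  p <- sim_params(n_frames = 200, colony_rate = 0.1, max_cells = 50)
  expect_warning(ds <- simulate_colony(p, seed = 1), "population cap")
  expect_true(ds$capped)
})

test_that("fixtures round trip and regenerate bitwise identically", {
  ds <- small_colony(7, n_frames = 30)
  dir1 <- file.path(tempdir(), "fx1")
  write_fixture(ds, dir1)
  back <- read_fixture(dir1)
  expect_setequal(edge_key_set(back$truth), edge_key_set(ds$truth))
  expect_equal(back$detections$x, ds$detections$x, tolerance = 1e-9)
  expect_equal(back$dt, ds$dt)

  # regeneration from (params, seed) is bitwise stable
  dir2 <- file.path(tempdir(), "fx2")
  write_fixture(small_colony(7, n_frames = 30), dir2)
  for (fn in c("detections.csv", "man_track.txt", "meta.json")) {
    expect_identical(readLines(file.path(dir1, fn)),
                     readLines(file.path(dir2, fn)))
  }
})
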