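test_that("half-normal log-density matches the closed form and normalises", {
  expect_equal(halfnormal_logpdf(0, 1), 0.5 * log(2 / pi), tolerance = 1e-12)
  for (s in c(0.5, 1, 10)) {
    expect_equal(halfnormal_logpdf(s, s), halfnormal_logpdf(0, s) - 0.5,
                 tolerance = 1e-12)
    mass <- integrate(function(x) exp(halfnormal_logpdf(x, s)), 0, Inf,
                      rel.tol = 1e-10)$value
    expect_equal(mass, 1, tolerance = 1e-6)
  }
  expect_error(halfnormal_logpdf(-1, 1), class = "uat_error_domain")
})

test_that("normal log-density matches the closed form and normalises", {
  expect_equal(normal_logpdf(2, 2, 3), -log(3 * sqrt(2 * pi)),
               tolerance = 1e-12)
  expect_equal(normal_logpdf(1.7, 1, 0.4), normal_logpdf(0.3, 1, 0.4),
               tolerance = 1e-12)
  # independent closed form
  expect_equal(normal_logpdf(c(-1, 0.3, 7), 0.5, 2),
               dnorm(c(-1, 0.3, 7), 0.5, 2, log = TRUE), tolerance = 1e-12)
  mass <- integrate(function(x) exp(normal_logpdf(x, 1, 0.25)), -Inf, Inf,
                    rel.tol = 1e-10)$value
  expect_equal(mass, 1, tolerance = 1e-6)
})

test_that("axial differences ignore head/tail flips", {
  expect_equal(axial_diff(0.1, pi - 0.1), 0.2, tolerance = 1e-12)
  expect_equal(axial_diff(0, pi / 2), pi / 2)
  expect_equal(axial_diff(1.2, 1.2), 0)
})

test_that("predictions: NN is the identity, FO extrapolates history", {
  det <- make_dets(1L, 0L, x = 0, y = 0, area = 100)
  nn <- make_config("NN", dt = 1, colony_rate = 0.05)
  p_nn <- predict_state(nn, det,
                        features = data.frame(id = 1L, vx = 3, vy = 4, g = 1.2))
  expect_equal(unlist(p_nn[c("px", "py", "parea")]),
               c(px = 0, py = 0, parea = 100))

  fo <- make_config("FO", dt = 1, colony_rate = 0.05)
  p_fo <- predict_state(fo, det,
                        features = data.frame(id = 1L, vx = 3, vy = 4, g = 1.2))
  expect_equal(unlist(p_fo[c("px", "py", "parea")]),
               c(px = 3, py = 4, parea = 120))

  # FO on a root: NN prediction apart from the colony-growth area scaling
  p_root <- predict_state(fo, det, features = NULL)
  expect_equal(c(p_root$px, p_root$py), c(p_nn$px, p_nn$py))
  expect_equal(p_root$parea, 100 * exp(0.05))
})

test_that("migration scores are sums of the stated closed forms", {
  cfg <- make_config("NN", dt = 1, sigma_move = 10, sigma_area = 0.1)
  src <- make_dets(1L, 0L, area = 100)
  # zero-residual: target exactly at prediction with identical area
  s0 <- score_migration(cfg, src, make_dets(2L, 1L, area = 100))
  expect_equal(s0, halfnormal_logpdf(0, 10) + normal_logpdf(1, 1, 0.1),
               tolerance = 1e-12)
  # hand-computed: residual 5 px, area ratio 1.1
  s1 <- score_migration(cfg, src, make_dets(2L, 1L, x = 5, area = 110))
  expect_equal(s1, halfnormal_logpdf(5, 10) + normal_logpdf(1.1, 1, 0.1),
               tolerance = 1e-12)
  # monotone: farther targets score strictly less
  d <- seq(0, 40, by = 5)
  s <- vapply(d, function(di)
    score_migration(cfg, src, make_dets(2L, 1L, x = di, area = 100)),
    numeric(1))
  expect_true(all(diff(s) < 0))
  # O and G terms switch in with their flags
  full <- make_config("FO+G+O+DD", dt = 2, colony_rate = 0.02, sigma_move = 10,
                      sigma_area = 0.1, sigma_angle = 0.3, sigma_growth = 0.1)
  tgt <- make_dets(2L, 1L, x = 5, area = 110, orientation = 0.2)
  s2 <- score_migration(full, src, tgt)
  expect_equal(s2,
               halfnormal_logpdf(5, 10 * sqrt(2)) +
                 normal_logpdf(110 / (100 * exp(0.02 * 2)), 1, 0.1) +
                 normal_logpdf(0.2, 0, 0.3) +
                 normal_logpdf(1.1, exp(0.02 * 2), 0.1),
               tolerance = 1e-12)
})

test_that("division scores are symmetric and penalise separation with DD", {
  cfg <- make_config("FO+G+O+DD", dt = 1, colony_rate = 0)
  src <- make_dets(1L, 0L, area = 200)
  a <- make_dets(2L, 1L, x = 4, area = 100, orientation = 0.3)
  b <- make_dets(3L, 1L, x = -4, area = 100, orientation = 0.1)
  expect_equal(score_division(cfg, src, a, b), score_division(cfg, src, b, a),
               tolerance = 1e-12)

  # coincident daughters at the predicted midpoint, summed area on target
  nn <- make_config("NN", dt = 1, sigma_move = 5, sigma_div_dist = 8)
  c1 <- make_dets(2L, 1L, x = 0, area = 100)
  c2 <- make_dets(3L, 1L, x = 0, area = 100)
  s <- score_division(nn, make_dets(1L, 0L, area = 200), c1, c2)
  expect_equal(s, halfnormal_logpdf(0, 5) + normal_logpdf(1, 1, 0.1),
               tolerance = 1e-12)

  # increasing separation strictly decreases the score when DD is on
  dd <- make_config("FO+DD", dt = 1, colony_rate = 0)
  seps <- seq(2, 30, by = 4)
  sc <- vapply(seps, function(d) {
    t1 <- make_dets(2L, 1L, x = d / 2, area = 100)
    t2 <- make_dets(3L, 1L, x = -d / 2, area = 100)
    score_division(dd, make_dets(1L, 0L, area = 200), t1, t2)
  }, numeric(1))
  expect_true(all(diff(sc) < 0))
})

test_that("appearance penalties lose against plausible migrations", {
  cfg <- make_config("NN", dt = 1)
  expect_equal(score_appear(cfg, 3), rep(-20, 3))
  expect_equal(score_disappear(cfg, 2), rep(-20, 2))
  # migration at residual <= 2 sigma beats appear+disappear
  src <- make_dets(1L, 0L, area = 100)
  tgt <- make_dets(2L, 1L, x = 2 * cfg$params$sigma_move,
                   area = 100 * (1 + 2 * cfg$params$sigma_area))
  expect_gt(score_migration(cfg, src, tgt),
            score_appear(cfg, 1) + score_disappear(cfg, 1))
  degen <- make_config("NN", lambda_appear = 0, lambda_disappear = 0)
  expect_equal(score_appear(degen, 1), 0)
})

test_that("configurations set the documented flags and dt scalings", {
  nn <- make_config("NN")
  expect_false(any(unlist(nn[c("use_first_order", "use_orientation",
                               "use_growth", "use_div_distance")])))
  full <- make_config("FO+O+G+DD")  # alias accepted
  expect_equal(full$name, "FO+G+O+DD")
  expect_true(all(unlist(full[c("use_first_order", "use_orientation",
                                "use_growth", "use_div_distance")])))
  expect_error(make_config("BOGUS"), class = "uat_error_unknown_config")

  # doubling dt doubles the displacement variance scale and the growth exponent
  c1 <- make_config("FO+G", dt = 2, colony_rate = 0.03)
  c2 <- make_config("FO+G", dt = 4, colony_rate = 0.03)
  expect_equal(c2$params$r_max / c1$params$r_max, sqrt(2))
  src <- make_dets(1L, 0L, area = 100)
  tgt <- make_dets(2L, 1L, area = 100)
  # extract the effective sigma from the displacement term at fixed residual
  resid_term <- function(cfg, d) {
    score_migration(cfg, src, make_dets(2L, 1L, x = d, area = 100)) -
      score_migration(cfg, src, tgt)
  }
  expect_equal(resid_term(c1, 3), -9 / (2 * c1$params$sigma_move^2 * 2))
  expect_equal(resid_term(c2, 3), -9 / (2 * c2$params$sigma_move^2 * 4))
})

test_that("scorers stay finite and NN == FO ranking in the degenerate limit", {
  cfg <- make_config("FO+G+O+DD", dt = 5, colony_rate = 0.05)
  src <- make_dets(1L, 0L, area = 1e-3)
  tgt <- make_dets(2L, 1L, x = 500, area = 1e5, orientation = 3)
  expect_true(is.finite(score_migration(cfg, src, tgt)))
  expect_true(is.finite(score_division(cfg, src, tgt,
                                       make_dets(3L, 1L, area = 1))))

  # zero motion/growth: FO history features equal the NN assumptions, so the
  # two configurations rank all candidates identically
  set.seed(1)
  srcs <- make_dets(1:4, rep(0L, 4), x = runif(4, 0, 30), y = runif(4, 0, 30))
  tgts <- srcs
  tgts$id <- 5:8
  tgts$frame <- 1L
  still <- data.frame(id = 1:4, vx = 0, vy = 0, g = 1)
  nn <- make_config("NN", colony_rate = 0)
  fo <- make_config("FO", colony_rate = 0)
  pn <- generate_candidates(srcs, tgts, nn)
  pf <- generate_candidates(srcs, tgts, fo, features = still)
  expect_equal(order(pn$candidates$log_score), order(pf$candidates$log_score))
  expect_equal(pn$candidates$log_score, pf$candidates$log_score,
               tolerance = 1e-12)
})
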