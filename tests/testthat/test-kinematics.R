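# Through-origin fits, velocities, vascular speeds, group comparisons.

test_that("fit_poly6_origin represents exact polynomials and passes the origin", {
  t <- seq(1, 20)
  f <- fit_poly6_origin(t, t)
  expect_equal(f$coefficients, c(1, 0, 0, 0, 0, 0), tolerance = 1e-8)
  expect_equal(predict_poly(f, 0), 0)
  # random through-origin sextic is reproduced
  set.seed(4)
  cf <- stats::rnorm(6) / 10^(0:5)
  y <- drop(outer(t, 1:6, "^") %*% cf)
  f2 <- fit_poly6_origin(t, y)
  expect_equal(f2$coefficients, cf, tolerance = 1e-6)
  expect_equal(predict_poly(f2, 0), 0)
  expect_error(fit_poly6_origin(t[1:5], t[1:5]), "at least 7")
  expect_error(fit_poly6_origin(rep(2, 8), rnorm(8)), "rank")
})

test_that("mean_curve equals pointwise averaging (shared basis)", {
  set.seed(7)
  t <- seq(0.5, 12, by = 0.5)
  fits <- lapply(1:5, function(i) {
    cf <- stats::rnorm(6) / 10^(0:5)
    fit_poly6_origin(t, drop(outer(t, 1:6, "^") %*% cf), replicate = i)
  })
  m <- mean_curve(fits)
  expect_equal(mean_curve(fits[1])$coefficients, fits[[1]]$coefficients)
  f13 <- list(fits[[1]], fits[[1]]); f13[[2]]$coefficients <- fits[[1]]$coefficients + c(2, 0, 0, 0, 0, 0)
  expect_equal(mean_curve(f13)$coefficients[1],
               fits[[1]]$coefficients[1] + 1)
  # pointwise oracle at arbitrary times
  tq <- c(0.3, 2.7, 9.1)
  brute <- rowMeans(vapply(fits, predict_poly, numeric(3), t = tq))
  expect_equal(predict_poly(m, tq), brute, tolerance = 1e-9)
})

test_that("velocity is the analytic derivative", {
  t <- seq(1, 20)
  f1 <- fit_poly6_origin(t, t)
  expect_equal(velocity(f1, c(0, 5, 10)), rep(1, 3), tolerance = 1e-7)
  f2 <- fit_poly6_origin(t, t^2)
  expect_equal(velocity(f2, 3), 6, tolerance = 1e-6)
  # finite-difference oracle on a random fit
  set.seed(12)
  f3 <- fit_poly6_origin(t, drop(outer(t, 1:6, "^") %*% (rnorm(6) / 10^(0:5))))
  h <- 1e-5
  tq <- c(1.5, 6.2, 15)
  fd <- (predict_poly(f3, tq + h) - predict_poly(f3, tq - h)) / (2 * h)
  expect_equal(velocity(f3, tq), fd, tolerance = 1e-5)
  # linearity: velocity of the mean is the mean of velocities
  fits <- lapply(1:4, function(i)
    fit_poly6_origin(t, drop(outer(t, 1:6, "^") %*% (rnorm(6) / 10^(0:5)))))
  vm <- velocity(mean_curve(fits), tq)
  mv <- rowMeans(vapply(fits, velocity, numeric(3), t = tq))
  expect_equal(vm, mv, tolerance = 1e-9)
})

test_that("fit_vascular_speed is the through-origin slope", {
  t <- seq(0.5, 15, by = 0.5)
  expect_equal(fit_vascular_speed(t, 300 * t)$slope, 300, tolerance = 1e-10)
  # scale equivariance
  set.seed(3)
  d <- 200 * t + stats::rnorm(length(t), sd = 30)
  expect_equal(fit_vascular_speed(t, 3 * d)$slope,
               3 * fit_vascular_speed(t, d)$slope, tolerance = 1e-10)
  # closed form sum(td)/sum(t^2)
  expect_equal(fit_vascular_speed(t, d)$slope, sum(t * d) / sum(t^2))
  # Monte-Carlo: slope 300 +- 10 for 95% of seeds (sd 50, 30 points)
  t30 <- seq(1, 30)
  hits <- vapply(1:100, function(s) {
    set.seed(s)
    abs(fit_vascular_speed(t30, 300 * t30 +
                             stats::rnorm(30, sd = 50))$slope - 300) < 10
  }, TRUE)
  expect_gte(mean(hits), 0.95)
  expect_error(fit_vascular_speed(1, 2), "at least 2")
})

test_that("pointwise t tests: identity, sensitivity, skip rule, shift invariance", {
  mk <- function(d) data.frame(t_s = seq_along(d), peak_um = d)
  gA <- list(mk(c(10, 20, 30)), mk(c(12, 22, 32)), mk(c(11, 21, 31)))
  # identical groups: t = 0, p = 1 everywhere
  res <- compare_tracks_pointwise(gA, gA)
  expect_equal(res$t_stat, rep(0, 3))
  expect_equal(res$p, rep(1, 3))
  # a time point with a single replicate in one group is skipped
  gB <- list(mk(c(10, 20, 30)), mk(c(14, 24, NA)))
  res2 <- compare_tracks_pointwise(gA, gB)
  expect_equal(res2$t_s, c(1, 2))
  # common shift leaves p unchanged
  gC <- lapply(gA, function(x) { x$peak_um <- x$peak_um + 5; x })
  gD <- list(mk(c(30, 40, 50)), mk(c(33, 44, 52)), mk(c(28, 39, 49)))
  gDs <- lapply(gD, function(x) { x$peak_um <- x$peak_um + 5; x })
  expect_equal(compare_tracks_pointwise(gA, gD)$p,
               compare_tracks_pointwise(gC, gDs)$p, tolerance = 1e-12)
  # pooled-Student equals stats::t.test(var.equal = TRUE)
  xa <- c(10, 12, 11, 14); xb <- c(15, 17, 16, 20)
  res3 <- compare_tracks_pointwise(list(mk(xa[1]), mk(xa[2]), mk(xa[3]),
                                        mk(xa[4])),
                                   list(mk(xb[1]), mk(xb[2]), mk(xb[3]),
                                        mk(xb[4])))
  ref <- stats::t.test(xa, xb, var.equal = TRUE)
  expect_equal(res3$p, ref$p.value, tolerance = 1e-12)
  expect_equal(res3$t_stat, unname(ref$statistic), tolerance = 1e-12)
})

test_that("groups generated with 4-fold different D separate at late times", {
  gen_group <- function(D, seeds) {
    lapply(seeds, function(s) {
      tt <- seq(2, 60, by = 2)
      set.seed(s)
      data.frame(t_s = tt,
                 peak_um = sqrt(6 * D * tt) + stats::rnorm(length(tt), sd = 8))
    })
  }
  res <- compare_tracks_pointwise(gen_group(100, 1:10), gen_group(25, 11:20))
  late <- res[res$t_s >= 40, ]
  expect_true(all(late$p < 0.01))
})

test_that("rank-sum speeds: exact p, Bonferroni bookkeeping", {
  # exact enumeration oracle for the extreme 3 vs 3 arrangement:
  # W statistic of {1,2,3} vs {10,11,12} is the most extreme of choose(6,3)=20
  # equally likely arrangements per tail -> two-sided p = 2/20
  res <- compare_speeds(list(a = c(1, 2, 3), b = c(10, 11, 12)),
                        correction = "none")
  expect_equal(res$p, 0.1)
  brute <- local({
    pooled <- c(1, 2, 3, 10, 11, 12)
    combos <- utils::combn(6, 3)
    w_obs <- sum(rank(pooled)[1:3]) - 6
    ws <- apply(combos, 2, function(i) sum(rank(pooled)[i]) - 6)
    mean(ws <= w_obs | ws >= (max(ws) + min(ws) - w_obs))
  })
  expect_equal(res$p, brute)
  # identical samples: p = 1
  expect_equal(compare_speeds(list(x = c(5, 6, 7), y = c(5, 6, 7)),
                              correction = "none")$p, 1)
  # three groups: 3 pairwise tests, Bonferroni factor 3 capped at 1
  res3 <- compare_speeds(list(a = c(1, 2, 3), b = c(10, 11, 12),
                              c = c(5, 6, 7)))
  expect_equal(nrow(res3), 3)
  expect_equal(res3$p_adj, pmin(res3$p * 3, 1))
  # speed_fit objects are accepted
  sf <- lapply(c(100, 120, 140), function(v)
    fit_vascular_speed(1:5, v * (1:5)))
  res4 <- compare_speeds(list(g1 = sf, g2 = c(400, 420, 440)),
                         correction = "none")
  expect_equal(res4$p, 0.1)
})
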