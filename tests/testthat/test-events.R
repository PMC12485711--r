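test_that("refractory filter matches the all-pairs oracle", {
  expect_equal(refractory_filter(c(0, 30, 80, 120)), c(0, 80))
  expect_equal(refractory_filter(42), 42)
  expect_equal(refractory_filter(numeric(0)), numeric(0))
  # the filter tests against all pokes, not only kept ones:
  # 80 is dropped by 50 even though 50 itself is dropped by 30
  expect_equal(refractory_filter(c(0, 30, 50, 80, 130)), c(0, 130))

  set.seed(13)
  for (rep in 1:200) {
    n <- sample(1:40, 1)
    tp <- round(sort(runif(n, 0, 500)), 1)
    r <- sample(c(0, 10, 45, 90), 1)
    expect_equal(refractory_filter(tp, refractory = r),
                 refractory_oracle(tp, r))
  }
})

test_that("alignment cuts a fixed window, renormalizes per event, and excludes partial windows", {
  t <- seq(0, 1000, by = 0.5)
  # small deterministic ripple for a non-degenerate baseline + unit step at
  # each event
  events <- c(300, 600, 900)
  y <- 0.01 * sin(t) + 5
  for (e in events) y <- y + (t >= e) * 1
  trace <- photo_trace(t, y, "corrected")
  al <- align_to_events(trace, events, pre = 45, post = 100)
  expect_equal(nrow(al$traces), 3)
  expect_equal(range(al$rel_t), c(-45, 100))
  expect_equal(al$n_input, 3)
  m <- aligned_mean(al)
  pre <- m$mean[m$rel_t < -1]
  post <- m$mean[m$rel_t > 5]
  expect_lt(abs(mean(pre)), 0.5)   # z units, baseline-centered
  expect_gt(mean(post), 10)        # step >> baseline ripple in z units
  # step occurs at rel_t = 0
  expect_gt(m$mean[which(al$rel_t == 0.5)], m$mean[which(al$rel_t == -1)])

  # events too close to the edges are excluded, accounting stays consistent
  al2 <- align_to_events(trace, c(10, 500, 995), pre = 45, post = 100)
  expect_equal(nrow(al2$traces) + al2$n_excluded + al2$n_degenerate, 3)
  expect_equal(al2$n_excluded, 2)

  # constant trace: degenerate per-event baseline excludes every event
  flat <- photo_trace(t, rep(2, length(t)), "corrected")
  expect_warning(al3 <- align_to_events(flat, events), "degenerate")
  expect_equal(nrow(al3$traces), 0)
  expect_error(aligned_mean(al3), "empty")
})

test_that("pooled averaging is two-stage per mouse with SEM over mice", {
  # mouse A trials [1, 3], mouse B [2] -> per-mouse [2, 2] -> group mean 2
  pa <- pool_and_average(c(1, 3, 2), c("A", "A", "B"))
  expect_equal(unname(pa$per_mouse), c(2, 2))
  expect_equal(pa$mean, 2)
  expect_equal(pa$n_mice, 2)

  # one mouse, one trial: mean passes through, SEM reported absent
  one <- pool_and_average(5, "A")
  expect_equal(one$mean, 5)
  expect_true(is.na(one$sem))

  # order invariance
  set.seed(2)
  v <- rnorm(9); m <- rep(c("a", "b", "c"), 3)
  o <- sample(9)
  expect_equal(pool_and_average(v, m)$mean, pool_and_average(v[o], m[o])$mean)
})

test_that("poke rate counts per minute over a sliding window and integrates back", {
  # one poke a minute for 2 h: interior rate 1 poke/min
  tp <- seq(60, 7200, by = 60)
  pr <- poke_rate(tp, window = 30, session = c(0, 7200))
  interior <- pr$rate[pr$t_s > 1800 & pr$t_s < 5400]
  expect_true(all(abs(interior - 1) <= 1 / 30 + 1e-9))

  expect_true(all(poke_rate(numeric(0), session = c(0, 3600))$rate == 0))

  # doubling every poke (both ports at once) doubles the rate
  pr2 <- poke_rate(rep(tp, each = 2), window = 30, session = c(0, 7200))
  expect_equal(pr2$rate, 2 * pr$rate)

  # integral of the rate over the session returns the total count
  set.seed(9)
  tp3 <- sort(runif(300, 0, 6 * 3600))
  pr3 <- poke_rate(tp3, window = 30, session = c(0, 6 * 3600), step = 60)
  total <- sum(pr3$rate) * 1  # rate in pokes/min on a 1-min grid
  expect_lt(abs(total - 300), 30)  # within one window of edge effects
})

test_that("decile split follows the ceiling rule and partitions all pokes", {
  mk_aligned <- function(n) {
    t <- seq(0, n * 200 + 400, by = 1)
    trace <- photo_trace(t, sin(t / 5) + 2, "corrected")
    align_to_events(trace, seq(150, by = 200, length.out = n),
                    pre = 45, post = 100)
  }
  ds10 <- decile_split(mk_aligned(10))
  expect_equal(ds10$sizes, rep(1L, 10))
  ds23 <- decile_split(mk_aligned(23))
  expect_equal(ds23$sizes, c(2L, 2L, 2L, 3L, 2L, 2L, 3L, 2L, 2L, 3L))
  expect_equal(ds23$presented_deciles, c(1L, 4L, 7L, 10L))
  # deciles are contiguous in time and cover every poke
  expect_true(all(diff(ds23$decile_index) >= 0))
  expect_equal(sum(ds23$sizes), 23L)

  for (n in c(1, 7, 37, 101)) {
    ds <- decile_split(mk_aligned(min(n, 101)))
    expect_equal(as.numeric(ds$decile_index), decile_oracle(sum(ds$sizes)))
  }
})

test_that("feeding-phase windows report piecewise means and reject bad ordering", {
  t <- seq(0, 60, by = 0.1)
  # 0 before contact at 10 s, -1 afterwards; drop at 0, bite at 20
  y <- ifelse(t >= 10, -1, 0)
  trace <- photo_trace(t, y, "dff")
  pm <- phase_means(trace, drop = 0, contact = 10, bite = 20)
  expect_equal(unname(pm["pre_contact"]), 0)
  expect_equal(unname(pm["pre_bite"]), -1)
  expect_equal(unname(pm["bite"]), -1)
  expect_true(is.na(pm["pre_drop"]))  # window precedes the recording: absent

  flat <- photo_trace(t, rep(4, length(t)), "dff")
  pm2 <- phase_means(flat, drop = 31, contact = 40, bite = 50)
  expect_true(all(pm2 == 4))

  expect_error(phase_means(trace, drop = 5, contact = 20, bite = 10),
               "ordered")
  # empty window (contact within 1 s of drop) is absent, not zero
  pm3 <- phase_means(flat, drop = 31, contact = 31.5, bite = 50)
  expect_true(is.na(pm3["pre_contact"]))
})
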