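test_that("UTCI classification follows the band edges, boundaries upward", {
  sc <- heat_stress_scale()
  expect_equal(classify_level(40, sc), 3)
  expect_equal(classify_level(20, sc), 0)
  expect_equal(classify_level(47, sc), 4)
  # boundary values are assigned the higher (conservative) level
  expect_equal(classify_level(c(26, 32, 38, 46), sc), 1:4)
  expect_equal(classify_level(c(25.999, 31.999), sc), c(0, 1))
  expect_error(classify_level(NaN, sc), "finite")
  expect_error(classify_level(Inf, sc), "finite")
})

test_that("classification is a nondecreasing step function of UTCI", {
  sc <- heat_stress_scale()
  u <- seq(-10, 55, by = 0.05)
  lv <- classify_level(u, sc)
  expect_true(all(diff(lv) >= 0))
  expect_setequal(unique(lv), 0:4)
  # degenerate segments agree with point classification
  expect_equal(segment_level(u, u, sc), lv)
})

test_that("segments spanning bands take the worst-case level", {
  expect_equal(segment_level(37, 40), 3)
  expect_equal(segment_level(34, 36), 2)
  expect_equal(segment_level(20, 20), 0)
  expect_error(segment_level(36, 34), "utci_min")
})

test_that("walking durations round up to the time quantum", {
  expect_equal(walk_duration(71.1), 1.2)
  expect_equal(walk_duration(44.8), 0.8)  # plain rounding would give 0.7
  expect_equal(walk_duration(60.0), 1.0)
  expect_equal(walk_duration(12.0), 0.2)  # exact quotient, no float creep
  expect_equal(walk_duration(0), 0)
  expect_error(walk_duration(-1), "non-negative")
  # doubling speed halves the pre-quantization time
  p2 <- tolerance_params(walking_speed = 2)
  expect_equal(walk_duration(120, p2), 1.0)
  # agrees with the long-hand rule on random lengths
  withr::with_seed(11, {
    len <- runif(500, 0, 2000)
    expect_equal(walk_duration(len), oracle_duration(len))
  })
})

test_that("cumulative stress reproduces the printed per-segment sums", {
  expect_equal(cumulative_stress(2, 1.2), 2.4)
  expect_equal(cumulative_stress(numeric(0), numeric(0)), numeric(0))
  tr <- oracle_trajectory(table4_segments())
  expect_equal(tail(tr$s_t, 1), 39.1)  # independent hand sum; 60 - 20.9
  got <- cumulative_stress(tr$level, tr$duration)
  expect_equal(got, tr$s_t)
})

test_that("recovery credits level-0 time and floors at zero", {
  p <- tolerance_params(recovery_rate = 1)
  s <- cumulative_stress(level = c(2, 0, 0), duration_min = c(3, 4, 10),
                         params = p)
  expect_equal(s, c(6, 2, 0))
  # default zero recovery: level-0 segments contribute nothing
  expect_equal(cumulative_stress(c(2, 0, 2), c(3, 4, 3)), c(6, 6, 12))
})

test_that("remaining tolerance is H - S_t with clamping and exhaustion", {
  r <- remaining_tolerance(2.4)
  expect_equal(r$r_t, 57.6)
  expect_false(r$exhausted)
  expect_equal(remaining_tolerance(0)$r_t, 60)
  r0 <- remaining_tolerance(60)
  expect_equal(r0$r_t, 0)
  expect_true(r0$exhausted)
  r1 <- remaining_tolerance(65)
  expect_equal(r1$r_t, -5)
  expect_equal(r1$clamped, 0)
})

test_that("evaluate_route reproduces the seven-segment published walk", {
  tr <- evaluate_route(table4_segments())
  expect_equal(tr$level, c(2, 3, 2, 3, 3, 2, 2))
  expect_equal(tr$duration_min, c(1.2, 2.9, 0.8, 0.9, 4.9, 0.2, 4.3))
  expect_equal(tr$r_t, c(57.6, 48.9, 47.3, 44.6, 29.9, 29.5, 20.9))
  expect_true(is.na(attr(tr, "exhausted_at")))
  s <- summary(tr)
  expect_equal(s$r_t, 20.9)
  expect_false(s$exhausted)
})

test_that("degenerate routes behave: zero length, empty, exhaustion flag", {
  tr <- evaluate_route(data.frame(utci_min = 40, utci_max = 42,
                                  length_m = 0))
  expect_equal(tr$r_t, 60)
  expect_error(evaluate_route(data.frame()), "at least one")
  # a long very-hot walk exhausts the budget but the trace is still returned
  long <- data.frame(utci_min = rep(47, 5), utci_max = rep(47, 5),
                     length_m = rep(300, 5))
  tr2 <- evaluate_route(long)
  expect_equal(nrow(tr2), 5)
  expect_lt(tr2$r_t[5], 0)
  expect_equal(attr(tr2, "exhausted_at"), 3)
})

test_that("trajectories match a straight-line oracle on random routes", {
  withr::with_seed(42, {
    for (i in 1:1000) {
      seg <- random_segments(sample(1:12, 1))
      tr <- evaluate_route(seg)
      or <- oracle_trajectory(seg)
      expect_equal(tr$level, or$level)
      expect_equal(tr$s_t, or$s_t)
      expect_equal(tr$r_t, or$r_t)
    }
  })
})

test_that("with zero recovery R_t is nonincreasing and S_t nondecreasing", {
  withr::with_seed(7, {
    for (i in 1:50) {
      tr <- evaluate_route(random_segments(20))
      expect_true(all(diff(tr$s_t) >= 0))
      expect_true(all(diff(tr$r_t) <= 0))
      expect_equal(tr$r_t, 60 - tr$s_t)
    }
  })
})

test_that("concatenating routes equals carrying over the terminal stress", {
  withr::with_seed(8, {
    a <- random_segments(6)
    b <- random_segments(5)
    whole <- evaluate_route(rbind(a, b))
    first <- evaluate_route(a)
    second <- evaluate_route(b, initial_stress = first$s_t[nrow(first)])
    expect_equal(second$r_t, whole$r_t[7:11])
  })
})

test_that("doubling speed halves stress when the quantum vanishes", {
  withr::with_seed(9, {
    seg <- random_segments(15)
    p1 <- tolerance_params(time_quantum = 1e-9)
    p2 <- tolerance_params(walking_speed = 2, time_quantum = 1e-9)
    s1 <- evaluate_route(seg, params = p1)$s_t
    s2 <- evaluate_route(seg, params = p2)$s_t
    expect_equal(s2, s1 / 2, tolerance = 1e-6)
  })
})

test_that("segment tables round-trip through CSV with computed columns", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  out <- withr::local_tempfile(fileext = ".csv")
  write.csv(table4_segments(), tmp, row.names = FALSE)
  tr <- evaluate_route(read_segments(tmp))
  write_trajectory(tr, out)
  back <- read.csv(out)
  expect_equal(back$r_t, tr$r_t)
  expect_true(all(c("level", "duration_min", "stress_contrib") %in%
                    names(back)))
})

test_that("parameter validation rejects non-physical settings", {
  expect_error(tolerance_params(H = 0), "positive")
  expect_error(tolerance_params(walking_speed = -1), "positive")
  expect_error(tolerance_params(recovery_rate = -0.1), "non-negative")
  expect_error(heat_stress_scale(breakpoints = c(26, 32, 32, 46)),
               "increasing")
  expect_error(heat_stress_scale(breakpoints = c(26, 32)), "four")
})
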