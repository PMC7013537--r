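test_that("the CM-I criterion is the midpoint of the class means", {
  ps <- pdf_params("section3")
  expect_equal(cm1_model(ps$fall, ps$bend)$r, 2.5)
  pt <- pdf_params("table3")
  expect_equal(cm1_model(pt$fall, pt$bend)$r, 1.7)
  m <- cm1_model(normal_time_model(1.3, 0.2), normal_time_model(2.1, 0.2))
  expect_equal(m$r, 1.7)
  expect_error(cm1_model(normal_time_model(3, 0.2),
                         normal_time_model(2, 0.2)),
               "below")
})

test_that("CM-I thresholds the total time with the boundary going to BEND", {
  ps <- pdf_params("section3")
  m <- cm1_model(ps$fall, ps$bend)
  expect_equal(classify_cm1(m, two_point_incident(2.0)), "FALL")
  expect_equal(classify_cm1(m, two_point_incident(3.0)), "BEND")
  expect_equal(classify_cm1(m, two_point_incident(2.5)), "BEND")
  # monotone in total time: shortening a descent never flips FALL -> BEND
  tt <- seq(1.2, 3.8, by = 0.2)
  preds <- vapply(tt, function(T) classify_cm1(m, two_point_incident(T)), "")
  expect_true(all(diff(preds == "FALL") <= 0))
})

test_that("CM-I fitting requires both classes and recovers fold statistics", {
  inc <- generate_dataset(simulation_config(n_fall = 10, n_bend = 10,
                                            seed = 5))
  m <- fit_cm1(inc)
  tt <- vapply(inc, total_time, 0)
  labels <- vapply(inc, function(x) x$label, "")
  expect_equal(m$fall$mu, mean(tt[labels == "FALL"]))
  expect_equal(m$bend$sigma, sd(tt[labels == "BEND"]))
  expect_equal(m$r, (m$fall$mu + m$bend$mu) / 2)
  only_falls <- inc[labels == "FALL"]
  expect_error(fit_cm1(only_falls), "class BEND")
})

test_that("CM-II references on identical trajectories are their crossing times", {
  f <- simulate_fall(1.72, 1.86, id = "f1")
  b <- simulate_bend(1.72, 3.14, id = "b1")
  train <- list(f, incident("f2", f$t, f$h, label = "FALL"),
                b, incident("b2", b$t, b$h, label = "BEND"))
  m <- fit_cm2(train, K = 10)
  expect_equal(m$t_fall_ref, checkpoint_times(f, m$checkpoints)$times)
  expect_equal(m$t_bend_ref, checkpoint_times(b, m$checkpoints)$times)
})

test_that("CM-II reference ordering follows the kinematics of the two profiles", {
  # The decelerating lean-over profile starts fast, so it crosses the HIGH
  # checkpoints earlier than the slow-starting free-fall profile despite its
  # longer total duration; the fall reference leads only below the
  # crossover height.  At the floor both references approach the class mean
  # durations.
  set.seed(31)
  inc <- generate_dataset(simulation_config(n_fall = 400, n_bend = 400,
                                            height_noise_sd = 0, seed = 31))
  m <- fit_cm2(inc, K = 20)
  K <- length(m$checkpoints)
  expect_gt(m$t_fall_ref[1], m$t_bend_ref[1])           # top checkpoint
  low <- m$checkpoints < 0.2 * 1.72
  expect_true(all(m$t_fall_ref[low] < m$t_bend_ref[low]))
  tt <- vapply(inc, total_time, 0)
  labels <- vapply(inc, function(x) x$label, "")
  n <- 400
  expect_lt(abs(m$t_fall_ref[K] - 1.86),
            3 * sd(tt[labels == "FALL"]) / sqrt(n))
  expect_lt(abs(m$t_bend_ref[K] - 3.14),
            3 * sd(tt[labels == "BEND"]) / sqrt(n))
})

test_that("CM-II voting matches hand-enumerated distance comparisons", {
  m <- cm2_model(checkpoints = c(0.9, 0.5, 0),
                 t_fall_ref = c(0.5, 1.0, 1.5),
                 t_bend_ref = c(1.0, 2.0, 3.0))
  # crossing times 0.6, 1.4, 2.9 -> votes FALL, FALL, BEND -> FALL
  inc <- incident("hand", c(0, 0.6, 1.4, 2.9), c(1.0, 0.9, 0.5, 0))
  res <- classify_cm2(m, inc)
  expect_equal(res$trace$records$vote, c("FALL", "FALL", "BEND"))
  expect_equal(res$label, "FALL")
  expect_equal(res$trace$fall_count, 2)
  expect_equal(res$trace$bend_count, 1)
})

test_that("CM-II ties resolve to BEND at both decision points", {
  m <- cm2_model(checkpoints = c(0.5, 0),
                 t_fall_ref = c(1, 2), t_bend_ref = c(3, 4))
  # crossing times exactly midway between the references at every checkpoint
  midway <- incident("mid", c(0, 2, 3), c(1.0, 0.5, 0))
  res <- classify_cm2(m, midway)
  expect_equal(res$trace$records$vote, c("BEND", "BEND"))
  expect_equal(res$label, "BEND")
  # crossing times identical to the fall reference -> unanimous FALL
  on_ref <- incident("onref", c(0, 1, 2), c(1.0, 0.5, 0))
  res2 <- classify_cm2(m, on_ref)
  expect_equal(res2$trace$fall_count, 2)
  expect_equal(res2$label, "FALL")
})

test_that("streaming CM-II equals batch CM-II on every fixture incident", {
  fx <- make_fixtures(seed = 408)
  m <- fit_cm2(fx$mini, K = 20)
  for (inc in c(fx$mini, fx$full[c(1:5, 42:46)])) {
    batch <- classify_cm2(m, inc)
    states <- cm2_stream_replay(m, inc$t, inc$h)
    fin <- states[[length(states)]]
    expect_true(fin$decided)
    expect_equal(fin$decision, batch$label)
    expect_equal(fin$fall_count, batch$trace$fall_count)
    expect_equal(fin$bend_count, batch$trace$bend_count)
    expect_equal(falltime:::.stream_trace(fin)$records$t_incident,
                 batch$trace$records$t_incident)
  }
})

test_that("a stream stopped before floor contact stays undecided", {
  fx <- make_fixtures(seed = 408)
  m <- fit_cm2(fx$mini, K = 20)
  inc <- fx$mini[[1]]
  cut <- which(inc$h <= 0.5)[1] - 1L
  state <- cm2_stream(m)
  for (i in seq_len(cut)) state <- cm2_stream_update(state, inc$t[i], inc$h[i])
  expect_false(state$decided)
  expect_true(is.na(state$decision))
  expect_gt(state$fall_count + state$bend_count, 0)
  expect_lt(state$fall_count + state$bend_count, length(m$checkpoints))
  # out-of-order samples and post-decision samples are rejected
  expect_error(cm2_stream_update(state, inc$t[cut] - 0.01, 0.4),
               "out-of-order")
  done <- classify_cm2(m, inc)
  full_state <- cm2_stream_replay(m, inc$t, inc$h)
  last <- full_state[[length(full_state)]]
  expect_error(cm2_stream_update(last, max(inc$t) + 1, 0), "complete")
  expect_equal(last$decision, done$label)
})

test_that("a noise-free fall holds a FALL majority by the half-height checkpoint", {
  set.seed(17)
  train <- generate_dataset(simulation_config(n_fall = 50, n_bend = 50,
                                              height_noise_sd = 0, seed = 17))
  m <- fit_cm2(train, K = 20)
  half_j <- which(abs(m$checkpoints - 1.72 / 2) < 1e-9)
  for (T in c(1.47, 1.86, 2.25)) {
    inc <- simulate_fall(1.72, T)
    states <- cm2_stream_replay(m, inc$t, inc$h)
    crossed <- Filter(function(s) s$next_j > half_j, states)
    s <- crossed[[1]]
    expect_gt(s$fall_count, s$bend_count)
  }
})

test_that("both models converge at the criterion r for a boundary incident", {
  set.seed(23)
  train <- generate_dataset(simulation_config(seed = 23))
  m1 <- fit_cm1(train)
  m2 <- fit_cm2(train, K = 20)
  boundary <- two_point_incident(m1$r)
  expect_equal(classify_cm1(m1, boundary), "BEND")
  K <- length(m2$checkpoints)
  res <- classify_cm2(m2, boundary)
  expected_final <- if (abs(m1$r - m2$t_fall_ref[K]) <
                          abs(m1$r - m2$t_bend_ref[K])) "FALL" else "BEND"
  expect_equal(res$trace$records$vote[K], expected_final)
})

test_that("classifier model files round-trip through JSON", {
  inc <- generate_dataset(simulation_config(n_fall = 8, n_bend = 8, seed = 2))
  m1 <- fit_cm1(inc)
  m2 <- fit_cm2(inc, K = 12)
  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".json")
  write_model(m1, p1)
  write_model(m2, p2)
  r1 <- read_model(p1)
  r2 <- read_model(p2)
  expect_equal(r1$r, m1$r)
  expect_equal(r1$fall$mu, m1$fall$mu)
  expect_equal(r2$checkpoints, m2$checkpoints)
  expect_equal(predict(r2, inc), predict(m2, inc))
})
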