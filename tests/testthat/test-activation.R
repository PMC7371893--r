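# Core declarative-memory equations: base level, mismatch, noise,
# activation, latency, retrieval.

test_that("base-level activation matches its closed form and direct sums", {
  # single retrieval at lag L: B = -d * log(L)
  expect_equal(base_level_activation(4, now = 5, d = 0.5), 0) # lag 1
  expect_equal(base_level_activation(1, now = 5, d = 0.5), -0.5 * log(4),
               tolerance = 1e-12)
  expect_equal(round(base_level_activation(1, now = 5, d = 0.5), 4), -0.6931)
  # retrievals at lags 1 and 2
  expect_equal(base_level_activation(c(3, 4), now = 5, d = 0.5),
               log(1 + 2^-0.5), tolerance = 1e-12)
  expect_equal(round(base_level_activation(c(3, 4), now = 5, d = 0.5), 4),
               0.5348)
  # closed form -d*log(L) over a sweep of lags and decays
  for (d in c(0, 0.5, 2, 10)) {
    for (L in c(1, 2, 7, 100)) {
      expect_equal(base_level_activation(10, now = 10 + L, d = d),
                   -d * log(L), tolerance = 1e-12)
    }
  }
})

test_that("base-level activation rejects empty or future histories", {
  expect_error(base_level_activation(integer(0), now = 5, d = 0.5),
               "no history")
  expect_error(base_level_activation(5, now = 5, d = 0.5), "before")
  expect_error(base_level_activation(c(3, 2), now = 5, d = 0.5), "increasing")
})

test_that("mismatch is 0 iff equal, -1 on full mismatch, graded with a table", {
  expect_identical(mismatch("red", "red"), 0)
  expect_identical(mismatch("red", "blue"), -1)
  expect_identical(mismatch("blue", "red"), mismatch("red", "blue")) # symmetric
  sim <- data.frame(a = "red", b = "pink", sim = 0.4)
  expect_equal(mismatch("red", "pink", similarity = sim), -0.6)
  expect_equal(mismatch("pink", "red", similarity = sim), -0.6)
  expect_identical(mismatch("red", "red", similarity = sim), 0)
  expect_error(mismatch("red", "mauve", vocabulary = c("red", "blue")),
               "vocabulary")
  # always within [-1, 0]
  vals <- mismatch(c("a", "a", "b"), c("a", "b", "b"))
  expect_true(all(vals >= -1 & vals <= 0))
})

test_that("noise transform hits its worked values", {
  expect_equal(noise_draw(1, s = 2, u = 0.5), 0)
  expect_equal(noise_draw(1, s = 2, u = 0.75), 2 * log(0.25 / 0.75),
               tolerance = 1e-12)
  expect_equal(round(noise_draw(1, s = 2, u = 0.75), 4), -2.1972)
  expect_identical(noise_draw(5, s = 0), rep(0, 5))
  expect_error(noise_draw(1, s = -1), "s")
})

test_that("noise draws have logistic moments at s = 2", {
  set.seed(42)
  x <- noise_draw(1e5, s = 2)
  expect_lt(abs(stats::median(x)), 0.05)
  expect_lt(abs(stats::var(x) - 4 * pi^2 / 3) / (4 * pi^2 / 3), 0.05)
  # symmetry about zero
  expect_lt(abs(mean(x > 0) - 0.5), 0.01)
})

test_that("activation composes base level, penalties and noise per the equation", {
  p <- model_params(f = 0.005, d = 0.5, s = 0, P = 1)
  inst <- list(color = "red", word = "none", events = 4L) # lag 1: B = 0
  # fully matching probe, noise off
  expect_equal(activation(inst, probe(color = "red"), p, now = 5, noise = FALSE), 0)
  # one fully mismatched slot, P = 1
  expect_equal(activation(inst, probe(color = "blue"), p, now = 5, noise = FALSE), -1)
  # lags {1, 2} and one mismatch
  inst2 <- list(color = "red", word = "none", events = c(3L, 4L))
  expect_equal(
    round(activation(inst2, probe(color = "red", word = "blue"), p,
                     now = 5, noise = FALSE), 4),
    0.5348 - 1
  )
  # adding a mismatched slot never increases activation
  a1 <- activation(inst2, probe(color = "red"), p, now = 5, noise = FALSE)
  a2 <- activation(inst2, probe(color = "red", word = "blue"), p, now = 5,
                   noise = FALSE)
  expect_lte(a2, a1)
})

test_that("activation equals a brute-force term-by-term oracle on small stores", {
  st <- small_store()
  p <- model_params(f = 0.005, d = 1.5, s = 0, P = 1)
  probes <- list(
    probe(color = "blue"),
    probe(word = "red"),
    probe(color = "green", word = "red"),
    probe(color = "red", word = "blue")
  )
  for (pr in probes) {
    acts <- vapply(st$instances,
                   function(i) activation(i, pr, p, st$now, noise = FALSE),
                   numeric(1))
    oracle <- vapply(st$instances,
                     function(i) brute_activation(i, pr$requested, p, st$now),
                     numeric(1))
    expect_equal(acts, oracle, tolerance = 1e-12)
  }
})

test_that("retrieval latency follows RT = F * exp(-f * A)", {
  expect_equal(retrieval_time(0, F = 1, f = 0.005), 1)
  expect_equal(round(retrieval_time(-1, F = 1, f = 0.005), 5), 1.00501)
  expect_equal(round(retrieval_time(2, F = 1, f = 0.003), 5), 0.99402)
  # strictly decreasing in A for f > 0
  A <- seq(-5, 5, by = 0.5)
  rt <- retrieval_time(A, F = 1, f = 0.01)
  expect_true(all(diff(rt) < 0))
  expect_error(retrieval_time(0, F = -1, f = 0.1), "F")
})

test_that("retrieve returns the arg-max instance and updates the store", {
  p <- model_params(f = 0.005, d = 0.5, s = 0, P = 1)
  st <- memory_store(c("red", "blue"))
  # matching beats mismatching under equal histories
  res <- retrieve(st, probe(word = "red"), p, noise = FALSE)
  expect_false(res$failed)
  expect_identical(res$word, "red")
  expect_equal(res$rt,
               retrieval_time(res$activation, p$F, p$f))
  # winner history gained the event and the clock advanced
  expect_equal(length(res$store$instances[[res$instance]]$events), 2L)
  expect_identical(res$store$now, st$now + 1L)
  # single-candidate store: RT = F * exp(-f * B)
  st1 <- memory_store(c("red", "blue"), init = "empty")
  st1 <- add_instance(st1, color = "red", word = "none")
  r1 <- retrieve(st1, probe(color = "red"), p, noise = FALSE)
  b <- base_level_activation(st1$instances[[1]]$events, st1$now, p$d)
  expect_equal(r1$rt, p$F * exp(-p$f * b))
  # unattainable threshold: failure
  ptau <- model_params(f = 0.005, d = 0.5, s = 0, tau = 10)
  expect_true(retrieve(st, probe(word = "red"), ptau, noise = FALSE)$failed)
  # empty store errors
  expect_error(
    retrieve(memory_store(c("red", "blue"), init = "empty"),
             probe(word = "red"), p),
    "empty"
  )
})

test_that("retrieval is deterministic under identical seeds", {
  p <- model_params(f = 0.005, d = 2, s = 2, P = 1)
  st <- small_store()
  pr <- probe(color = "blue", word = "red")
  r1 <- withr::with_seed(9, retrieve(st, pr, p))
  r2 <- withr::with_seed(9, retrieve(st, pr, p))
  expect_identical(r1$instance, r2$instance)
  expect_identical(r1$rt, r2$rt)
})

test_that("parameter validation enforces the declared ranges", {
  expect_error(model_params(F = 2), "F")
  expect_error(model_params(f = -0.1), "f")
  expect_error(model_params(d = 11), "d")
  expect_error(model_params(s = -1), "s")
  expect_error(model_params(t_nonretrieval = -1), "t_nonretrieval")
  expect_s3_class(model_params(d = 10, s = 10), "ibl_params")
  # published rows
  expect_equal(group_params("control")[c("F", "f", "d", "s")],
               list(F = 1, f = 0.003, d = 5, s = 2))
  expect_equal(group_params("dmd")[c("F", "f", "d", "s")],
               list(F = 1, f = 0.005, d = 4, s = 2))
})
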