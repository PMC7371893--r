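# Sheet construction, memory seeding, and the timed sheet simulation.

test_that("make_sheet builds the three sheet geometries", {
  cols <- c("red", "green", "blue")
  set.seed(1)
  cw <- make_sheet("color_word", n_items = 100, colors = cols)
  expect_equal(nrow(cw), 100)
  expect_equal(sum(cw$congruent), 0)            # all incongruent
  expect_true(all(cw$word != cw$ink))
  expect_true(all(cw$word %in% cols) && all(cw$ink %in% cols))

  w <- make_sheet("word", n_items = 10, colors = cols)
  expect_equal(nrow(w), 10)
  expect_true(all(w$ink == "none"))             # neutral ink throughout
  co <- make_sheet("color", n_items = 10, colors = cols)
  expect_true(all(co$word == "none"))           # neutral token throughout

  one <- make_sheet("color_word", n_items = 1, colors = c("red", "blue"))
  expect_true(one$word != one$ink)
  expect_error(make_sheet("color_word", n_items = 5, colors = "red"),
               "config error")
  # reproducible from seed
  s1 <- withr::with_seed(7, make_sheet("color_word", 50, cols))
  s2 <- withr::with_seed(7, make_sheet("color_word", 50, cols))
  expect_identical(s1, s2)
})

test_that("seed_instances registers one retrieval event per completion", {
  cols <- c("red", "green", "blue")
  st <- memory_store(cols, init = "empty")
  # empty prior results leave the store unchanged
  sh <- withr::with_seed(1, make_sheet("word", 30, cols))
  expect_identical(seed_instances(st, sh, 0), st)
  # 30 word completions over 3 distinct words: 3 instances, 30 events
  st2 <- seed_instances(st, sh, 30)
  expect_equal(length(st2$instances), length(unique(sh$word)))
  expect_equal(sum(vapply(st2$instances, function(i) length(i$events),
                          integer(1))), 30)
  # naming the same item twice: one instance, two events
  st3 <- memory_store(cols, init = "empty")
  rep2 <- sh[c(1, 1), ]
  attr(rep2, "kind") <- "word"
  st3 <- seed_instances(st3, rep2, 2)
  expect_equal(length(st3$instances), 1L)
  expect_equal(length(st3$instances[[1]]$events), 2L)
})

test_that("sheet simulation respects the time budget exactly", {
  cols <- c("red", "green", "blue", "yellow")
  # degenerate latency law: F = 0 so RT = 0, overhead 1 s per item -> 45 items
  p <- model_params(F = 0, f = 0, d = 0.5, s = 0, t_nonretrieval = 1)
  sh <- withr::with_seed(2, make_sheet("word", 100, cols))
  out <- simulate_sheet(sh, memory_store(cols), p)
  expect_equal(out$result$items_completed, 45L)
  # zero budget: no items
  sh0 <- withr::with_seed(2, make_sheet("word", 100, cols, time_budget = 0))
  expect_equal(simulate_sheet(sh0, memory_store(cols), p)$result$items_completed, 0L)
})

test_that("budget conservation holds in simulated sheets", {
  cols <- c("red", "green", "blue", "yellow")
  p <- group_params("control")
  for (seed in 1:5) {
    set.seed(seed)
    sh <- make_sheet("color_word", 100, cols)
    res <- simulate_sheet(sh, memory_store(cols), p)$result
    done <- res$items_completed
    lat <- res$latencies
    expect_lte(sum(lat[seq_len(done)]), res$time_budget)
    if (done < length(lat)) { # stopped early: next item would overflow
      expect_gt(sum(lat[seq_len(done + 1)]), res$time_budget)
    }
  }
})

test_that("the mismatch penalty produces Stroop interference in latency", {
  cols <- c("red", "green", "blue", "yellow")
  p <- model_params(F = 1, f = 0.005, d = 4, s = 0, P = 1)
  set.seed(3)
  st <- memory_store(cols)
  shw <- make_sheet("word", 100, cols)
  shc <- make_sheet("color", 100, cols)
  sw <- simulate_sheet(shw, st, p)
  sc <- simulate_sheet(shc, sw$store, p)
  warmed <- sc$store
  # from the *same* seeded store: a colour sheet and a colour-word sheet
  # with identical ink sequences, differing only in the word context
  shc2 <- withr::with_seed(5, make_sheet("color", 100, cols))
  shcw <- shc2
  shcw$word <- vapply(shcw$ink, function(i) setdiff(cols, i)[1], character(1))
  attr(shcw, "kind") <- "color_word"
  rc <- simulate_sheet(shc2, warmed, p)$result
  rcw <- simulate_sheet(shcw, warmed, p)$result
  # the penalty binds on every item: strictly slower, hence no more items
  expect_gt(mean(rcw$latencies), mean(rc$latencies))
  expect_lte(rcw$items_completed, rc$items_completed)
})

test_that("items completed is non-increasing in f when activations are negative", {
  cols <- c("red", "green", "blue", "yellow")
  # noise off and strong decay: every retrieval has negative activation
  counts <- vapply(c(0.001, 0.005, 0.01), function(f) {
    p <- model_params(F = 1, f = f, d = 8, s = 0, P = 1)
    out <- withr::with_seed(11, run_session_internal(p, task_config(), "r"))
    sum(out$counts)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("retrieval failures are skipped with a penalty and flagged", {
  cols <- c("red", "blue")
  p <- model_params(F = 1, f = 0.005, d = 0.5, s = 0, tau = 10) # unreachable
  sh <- withr::with_seed(4, make_sheet("word", 10, cols, time_budget = 5))
  res <- simulate_sheet(sh, memory_store(cols), p, skip_penalty = 1)$result
  expect_equal(res$items_completed, 0L)
  expect_true(all(res$failed))
  expect_true(all(res$latencies == 1))
})
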