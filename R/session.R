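# Whole-session driver: word -> color -> color_word sheets carried by one
# memory store, plus session scoring and cohort-level forward simulation.

# Internal: run one session from the current RNG state.  The compiled and
# pure-R engines consume identical random draws (item sequences first,
# then one uniform per instance per retrieval attempt), so they produce
# identical sessions for identical seeds.
run_session_internal <- function(params, config = task_config(),
                                 engine = c("compiled", "r")) {
  engine <- match.arg(engine)
  K <- length(config$colors)
  if (engine == "compiled") {
    specs <- lapply(SHEET_KINDS, function(k) sheet_items(k, config$n_items, K))
    out <- cpp_run_session(
      specs, params$F, params$f, params$d, params$s, params$P,
      tau = if (is.null(params$tau)) 0 else params$tau,
      has_tau = !is.null(params$tau),
      t0 = params$t_nonretrieval, budget = config$time_budget,
      skip_penalty = config$skip_penalty, n_colors = K
    )
    list(counts = as.numeric(out$completed), latencies = out$latencies,
         attempts = as.integer(out$attempts), failures = as.integer(out$failures))
  } else {
    sheets <- lapply(SHEET_KINDS, function(k) {
      make_sheet(k, n_items = config$n_items, colors = config$colors,
                 time_budget = config$time_budget)
    })
    store <- memory_store(config$colors)
    counts <- numeric(3)
    latencies <- vector("list", 3)
    attempts <- integer(3)
    failures <- integer(3)
    for (i in 1:3) {
      sim <- simulate_sheet(sheets[[i]], store, params,
                            skip_penalty = config$skip_penalty)
      store <- sim$store
      counts[i] <- sim$result$items_completed
      latencies[[i]] <- sim$result$latencies
      attempts[i] <- length(sim$result$latencies)
      failures[i] <- sum(sim$result$failed)
    }
    list(counts = counts, latencies = latencies, attempts = attempts,
         failures = failures)
  }
}

#' Score a Stroop session
#'
#' Derives the three Stroop-effect scores from the per-sheet word counts:
#' `effect1 = C - CW` (interference in items), `effect2 = CW / W` and
#' `effect3 = CW / C` (interference ratios).  Zero denominators yield
#' `NA`.
#'
#' @param W,C,CW Items completed on the word, colour and colour-word
#'   sheets (vectorised).
#' @return A tibble with columns `W`, `C`, `CW`, `effect1`, `effect2`,
#'   `effect3`.
#' @examples
#' score_session(W = 60.09, C = 46.79, CW = 28.34)
#' @export
score_session <- function(W, C, CW) {
  stopifnot(all(W >= 0, na.rm = TRUE), all(C >= 0, na.rm = TRUE),
            all(CW >= 0, na.rm = TRUE))
  tibble::tibble(
    W = W, C = C, CW = CW,
    effect1 = C - CW,
    effect2 = ifelse(W > 0, CW / W, NA_real_),
    effect3 = ifelse(C > 0, CW / C, NA_real_)
  )
}

#' Simulate a full Stroop session
#'
#' Runs the word, colour and colour-word sheets in order, carrying one
#' memory store: completions on the first two sheets lay down the
#' instances whose retrieval times the colour-word sheet inherits.
#'
#' @param params An [model_params()] object.
#' @param config A [task_config()].
#' @param seed Optional integer seed; when `NULL` the current RNG state is
#'   used.
#' @param engine `"compiled"` (default) or `"r"` (reference
#'   implementation; identical output for identical seeds).
#' @return A one-row tibble: per-sheet counts `W`, `C`, `CW`, the three
#'   Stroop-effect scores, mean per-item latencies `rt_w`, `rt_c`,
#'   `rt_cw` (seconds), and the number of failed retrievals.
#' @examples
#' simulate_session(group_params("control"), seed = 1)
#' @export
simulate_session <- function(params, config = task_config(), seed = NULL,
                             engine = c("compiled", "r")) {
  engine <- match.arg(engine)
  run <- function() run_session_internal(params, config, engine)
  out <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  mean_lat <- vapply(out$latencies, function(l) {
    if (length(l)) mean(l) else NA_real_
  }, numeric(1))
  dplyr::bind_cols(
    score_session(out$counts[1], out$counts[2], out$counts[3]),
    tibble::tibble(rt_w = mean_lat[1], rt_c = mean_lat[2], rt_cw = mean_lat[3],
                   n_failed = sum(out$failures))
  )
}

#' Forward-simulate a cohort of model subjects
#'
#' Runs `n` independent Stroop sessions and records each one's per-sheet
#' counts, effect scores and mean latencies.  Each session gets its own
#' seed drawn from `seed`, so a cohort is fully reproducible and session
#' `i` is identical regardless of `n` -- the property the grid-search
#' fitter exploits for common random numbers.
#'
#' @inheritParams simulate_session
#' @param n Number of sessions (subjects).
#' @return A tibble with one row per session (`subject` column first).
#' @examples
#' simulate_cohort(group_params("dmd"), n = 3, seed = 42)
#' @export
simulate_cohort <- function(params, n, config = task_config(), seed = NULL,
                            engine = c("compiled", "r")) {
  engine <- match.arg(engine)
  if (n == 0) {
    return(tibble::tibble(subject = integer(0)))
  }
  draw_seeds <- function() sample.int(.Machine$integer.max - 1L, n)
  seeds <- if (is.null(seed)) draw_seeds() else withr::with_seed(seed, draw_seeds())
  purrr::map_dfr(seq_len(n), function(i) {
    dplyr::bind_cols(
      tibble::tibble(subject = i),
      simulate_session(params, config, seed = seeds[i], engine = engine)
    )
  })
}
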