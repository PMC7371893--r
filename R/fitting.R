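# Grid-search ("hit and trial") parameter estimation: fitness and MSD
# between model and human per-sheet word counts, exhaustive search over a
# parameter lattice with common random numbers, and the group comparison.

#' Parameter lattice for the grid search
#'
#' Inclusive value grids for the four fitted scalars, constrained to the
#' model's normal ranges (`F`, `f` in \[0, 1\]; `d`, `s` in \[0, 10\]).
#' The default lattice steps `d` and `s` by 1 over \[0, 10\], `f` by 0.001
#' over \[0, 0.01\], and fixes the latency factor at its default `F = 1`.
#'
#' @param f,d,s,F Numeric vectors of candidate values.
#' @return An object of class `ibl_grid` (a tibble of all combinations,
#'   in lexicographic `(d, s, f, F)` order, which is also the tie-break
#'   order of [grid_fit()]).
#' @examples
#' nrow(fit_grid()) # 11 * 11 * 11 points
#' @export
fit_grid <- function(f = seq(0, 0.01, by = 0.001), d = 0:10, s = 0:10, F = 1) {
  chk <- function(x, nm, lo, hi) {
    if (length(x) < 1 || any(x < lo | x > hi)) {
      stop(sprintf("`%s` values must lie in [%g, %g]", nm, lo, hi),
           call. = FALSE)
    }
    sort(unique(as.numeric(x)))
  }
  g <- tidyr::expand_grid(
    d = chk(d, "d", 0, 10), s = chk(s, "s", 0, 10),
    f = chk(f, "f", 0, 1), F = chk(F, "F", 0, 1)
  )
  class(g) <- c("ibl_grid", class(g))
  g
}

# Internal: canonicalise human per-sheet counts to c(W=, C=, CW=).
as_sheet_counts <- function(x) {
  if (is.data.frame(x)) {
    if (all(c("sheet", "count") %in% names(x))) {
      x <- stats::setNames(x$count, toupper(x$sheet))
      names(x)[names(x) == "COLOR_WORD"] <- "CW"
      names(x)[names(x) == "WORD"] <- "W"
      names(x)[names(x) == "COLOR"] <- "C"
    } else if (all(c("W", "C", "CW") %in% names(x))) {
      x <- c(W = mean(x$W), C = mean(x$C), CW = mean(x$CW))
    } else {
      stop("alignment error: cannot find sheet counts in data frame",
           call. = FALSE)
    }
  }
  if (is.null(names(x))) {
    if (length(x) != 3) stop("alignment error: expected 3 sheet counts", call. = FALSE)
    names(x) <- c("W", "C", "CW")
  }
  if (!all(c("W", "C", "CW") %in% names(x))) {
    stop("alignment error: sheet counts must be named W, C, CW", call. = FALSE)
  }
  x[c("W", "C", "CW")]
}

#' Fitness of model counts against human counts
#'
#' Mean absolute deviation over sheets between the number of words
#' produced by the model and by the human group.  Lower is better; the
#' grid search minimises this quantity.
#'
#' @param model_counts,human_counts Per-sheet word counts: numeric
#'   vectors named `W`, `C`, `CW` (or unnamed length 3 in that order), or
#'   data frames with those columns.
#' @return A single non-negative number.
#' @examples
#' fitness(c(W = 50, C = 40, CW = 20), c(W = 52, C = 38, CW = 24)) # 8/3
#' @export
fitness <- function(model_counts, human_counts) {
  ct <- align_counts(model_counts, human_counts)
  mean(abs(ct$h - ct$m))
}

# Align two per-sheet count vectors: by sheet name when both are named
# (any sheet subset), positionally otherwise.
align_counts <- function(m, h) {
  if (is.data.frame(m)) m <- as_sheet_counts(m)
  if (is.data.frame(h)) h <- as_sheet_counts(h)
  if (!is.null(names(m)) && !is.null(names(h))) {
    if (!setequal(names(m), names(h))) {
      stop("alignment error: model and human sheets differ", call. = FALSE)
    }
    h <- h[names(m)]
  } else if (length(m) != length(h)) {
    stop("alignment error: model and human counts differ in length",
         call. = FALSE)
  }
  list(m = as.numeric(m), h = as.numeric(h))
}

#' Mean square deviation between model and human counts
#'
#' Mean over sheets (and over subjects, when matrices or multi-row data
#' frames are supplied) of the squared count differences.  The published
#' group comparison rests on the ordering of this quantity between the
#' fitted control and DMD models.
#'
#' @inheritParams fitness
#' @return A single non-negative number.
#' @examples
#' msd(c(50, 40, 20), c(52, 38, 24)) # (4 + 4 + 16) / 3
#' @export
msd <- function(model_counts, human_counts) {
  if (is.matrix(model_counts) || is.matrix(human_counts)) {
    if (!identical(dim(model_counts), dim(human_counts))) {
      stop("alignment error: count matrices must share dimensions", call. = FALSE)
    }
    return(mean((human_counts - model_counts)^2))
  }
  ct <- align_counts(model_counts, human_counts)
  mean((ct$h - ct$m)^2)
}

#' Fit model parameters by exhaustive grid search
#'
#' The estimation procedure is deliberate enumeration ("hit and trial"):
#' every lattice point is evaluated by forward-simulating
#' `sessions_per_point` Stroop sessions, averaging the per-sheet counts,
#' and scoring them against the human per-sheet means with [fitness()].
#' All points share the same per-session seeds (common random numbers),
#' so with noise off the fitness surface is deterministic and differences
#' between points reflect parameters, not simulation luck.  Ties are
#' broken lexicographically by `(d, s, f, F)`.
#'
#' @param human_counts Human per-sheet means (see [fitness()] for
#'   accepted shapes).
#' @param grid An [fit_grid()].
#' @param fixed An [model_params()] supplying the non-searched parameters
#'   (`P`, `tau`, `t_nonretrieval`).
#' @param sessions_per_point Sessions simulated at each lattice point.
#' @param config A [task_config()].
#' @param seed Integer seed for the common random numbers.
#' @param engine Simulation engine, as in [simulate_session()].
#' @return An `ibl_fit` object: best-fitting `params`, their `fitness`,
#'   `msd` (over sheet means) and `msd_sessions` (over individual
#'   sessions), the full grid `trace`, and the inputs.  Supports
#'   [generics::tidy()], [generics::glance()] and [ggplot2::autoplot()].
#' @examples
#' grid_fit(c(W = 45, C = 42, CW = 40),
#'          fit_grid(f = 0.005, d = c(2, 4), s = 0),
#'          sessions_per_point = 2, seed = 1)
#' @export
grid_fit <- function(human_counts, grid = fit_grid(), fixed = model_params(),
                     sessions_per_point = 20, config = task_config(),
                     seed = 1, engine = c("compiled", "r")) {
  engine <- match.arg(engine)
  if (!inherits(grid, "ibl_grid")) grid <- do.call(fit_grid, as.list(grid))
  if (nrow(grid) == 0) stop("config error: empty grid", call. = FALSE)
  human <- as_sheet_counts(human_counts)
  if (sessions_per_point < 1) stop("`sessions_per_point` must be >= 1", call. = FALSE)

  seeds <- withr::with_seed(
    seed, sample.int(.Machine$integer.max - 1L, sessions_per_point)
  )
  eval_point <- function(F, f, d, s) {
    p <- model_params(F = F, f = f, d = d, s = s, P = fixed$P,
                      tau = fixed$tau, t_nonretrieval = fixed$t_nonretrieval)
    counts <- matrix(0, nrow = sessions_per_point, ncol = 3)
    for (i in seq_len(sessions_per_point)) {
      counts[i, ] <- withr::with_seed(
        seeds[i], run_session_internal(p, config, engine)
      )$counts
    }
    mc <- colMeans(counts)
    names(mc) <- c("W", "C", "CW")
    c(mc,
      fitness = mean(abs(human - mc)),
      msd = mean((human - mc)^2),
      msd_sessions = mean((t(counts) - human)^2))
  }

  res <- purrr::pmap(grid, eval_point)
  trace <- dplyr::bind_cols(
    tibble::as_tibble(grid),
    dplyr::bind_rows(purrr::map(res, ~ tibble::as_tibble(as.list(.x))))
  )
  # grid rows are already in (d, s, f, F) lexicographic order; first min wins
  best_i <- which.min(trace$fitness)
  best <- trace[best_i, ]
  structure(
    list(
      params = model_params(F = best$F, f = best$f, d = best$d, s = best$s,
                            P = fixed$P, tau = fixed$tau,
                            t_nonretrieval = fixed$t_nonretrieval),
      fitness = best$fitness,
      msd = best$msd,
      msd_sessions = best$msd_sessions,
      model_counts = c(W = best$W, C = best$C, CW = best$CW),
      human_counts = human,
      trace = trace,
      sessions_per_point = sessions_per_point,
      seed = seed,
      config = config,
      engine = engine
    ),
    class = "ibl_fit"
  )
}

#' @export
print.ibl_fit <- function(x, ...) {
  cat("<ibl_fit> grid search over", nrow(x$trace), "points\n")
  cat(sprintf("  best: F = %g, f = %g, d = %g, s = %g\n",
              x$params$F, x$params$f, x$params$d, x$params$s))
  cat(sprintf("  fitness = %.3f, MSD = %.3f (sheet means), %.3f (sessions)\n",
              x$fitness, x$msd, x$msd_sessions))
  cat(sprintf("  model counts: W = %.1f, C = %.1f, CW = %.1f (human: %.1f, %.1f, %.1f)\n",
              x$model_counts["W"], x$model_counts["C"], x$model_counts["CW"],
              x$human_counts["W"], x$human_counts["C"], x$human_counts["CW"]))
  invisible(x)
}

#' Tidy the grid trace of a fit
#'
#' @param x An `ibl_fit`.
#' @param ... Unused.
#' @return The full grid trace: one row per lattice point with the
#'   simulated mean counts, fitness and MSD.
#' @method tidy ibl_fit
#' @export
tidy.ibl_fit <- function(x, ...) x$trace

#' One-row summary of a fit
#'
#' @param x An `ibl_fit`.
#' @param ... Unused.
#' @return A one-row tibble with the best parameters and scores.
#' @method glance ibl_fit
#' @export
glance.ibl_fit <- function(x, ...) {
  tibble::tibble(
    F = x$params$F, f = x$params$f, d = x$params$d, s = x$params$s,
    fitness = x$fitness, msd = x$msd, msd_sessions = x$msd_sessions,
    n_grid = nrow(x$trace), sessions_per_point = x$sessions_per_point
  )
}

#' Parameter-recovery experiment
#'
#' Forward-simulates a cohort of `n` sessions at known parameters, then
#' refits by grid search using the same seed stream, so the generating
#' lattice point reproduces the target counts exactly (fitness ~ 0) and
#' the experiment probes whether any *other* lattice point matches them
#' -- i.e. the identifiability of the parameters on the grid.
#'
#' @param true_params Generating [model_params()] (should lie on `grid`).
#' @param n Cohort size; also used as `sessions_per_point` in the refit.
#' @param grid An [fit_grid()].
#' @param config A [task_config()].
#' @param seed Integer seed shared by the target cohort and the grid
#'   evaluations.
#' @param engine Simulation engine.
#' @return An `ibl_recovery` object: `truth`, `fit` (the `ibl_fit`),
#'   `recovered` parameters and the target cohort.
#' @export
recover_params <- function(true_params, n, grid = fit_grid(),
                           config = task_config(), seed = 1,
                           engine = c("compiled", "r")) {
  engine <- match.arg(engine)
  cohort <- simulate_cohort(true_params, n, config, seed = seed,
                            engine = engine)
  target <- c(W = mean(cohort$W), C = mean(cohort$C), CW = mean(cohort$CW))
  fit <- grid_fit(target, grid = grid, fixed = true_params,
                  sessions_per_point = n, config = config, seed = seed,
                  engine = engine)
  structure(list(truth = true_params, fit = fit, recovered = fit$params,
                 cohort = cohort, target = target),
            class = "ibl_recovery")
}

#' @export
print.ibl_recovery <- function(x, ...) {
  cat("<ibl_recovery>\n")
  cat(sprintf("  truth:     f = %g, d = %g, s = %g (F = %g)\n",
              x$truth$f, x$truth$d, x$truth$s, x$truth$F))
  cat(sprintf("  recovered: f = %g, d = %g, s = %g (F = %g), fitness = %.4f\n",
              x$recovered$f, x$recovered$d, x$recovered$s, x$recovered$F,
              x$fit$fitness))
  invisible(x)
}

#' Compare fitted models between groups
#'
#' Lays the two fitted parameter sets side by side with their MSDs and
#' states the ordering: the group with the larger MSD is the one the
#' model reproduces less well.
#'
#' @param control_fit,dmd_fit `ibl_fit` objects for the control and DMD
#'   groups.
#' @return An `ibl_comparison`: a tibble with one row per group (`F`,
#'   `f`, `d`, `s`, `fitness`, `msd`, `msd_sessions`) and an `ordering`
#'   attribute (`"dmd > control"`, `"control > dmd"` or
#'   `"no difference"`).
#' @export
compare_groups <- function(control_fit, dmd_fit) {
  stopifnot(inherits(control_fit, "ibl_fit"), inherits(dmd_fit, "ibl_fit"))
  tab <- dplyr::bind_rows(
    dplyr::mutate(glance.ibl_fit(control_fit), group = "control", .before = 1),
    dplyr::mutate(glance.ibl_fit(dmd_fit), group = "dmd", .before = 1)
  )
  ordering <- if (dmd_fit$msd > control_fit$msd) {
    "dmd > control"
  } else if (dmd_fit$msd < control_fit$msd) {
    "control > dmd"
  } else {
    "no difference"
  }
  structure(tab, ordering = ordering, class = c("ibl_comparison", class(tab)))
}

#' @export
print.ibl_comparison <- function(x, ...) {
  cat("Model comparison (latency factor F, latency exponent f, decay d, noise s)\n")
  NextMethod()
  cat("MSD ordering:", attr(x, "ordering"), "\n")
  invisible(x)
}
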