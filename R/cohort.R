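# Synthetic cohort generator: subject-level score tables with the
# statistical structure the analysis assumes (truncated-normal marginals,
# independent across measures, bounded by the task maxima), plus
# per-word RAVLT recall grids with prescribed serial-position structure.

# Measure bounds: [0, task maximum].  Stroop counts are bounded by sheet
# length; RAVLT scores by the 15-word list.
measure_bounds <- function(measure, sheet_len = 100) {
  lo <- 0
  hi <- dplyr::case_when(
    grepl("^ravlt", measure) ~ 15,
    grepl("^stroop", measure) ~ as.numeric(sheet_len),
    TRUE ~ Inf
  )
  list(lo = rep(lo, length(measure)), hi = hi)
}

# Truncated-normal draws whose *truncated* mean equals `mean`: the
# location parameter is solved so that truncation at the task bounds does
# not bias the group mean (otherwise measures near ceiling, e.g. RAVLT
# trial 5, would undershoot their published means).
rtnorm_calibrated <- function(n, mean, sd, lo = 0, hi = Inf) {
  if (sd == 0) return(rep(mean, n))
  if (mean <= lo || mean >= hi) {
    stop(sprintf("mean %g must lie strictly inside [%g, %g]", mean, lo, hi),
         call. = FALSE)
  }
  tn_mean <- function(mu) {
    a <- (lo - mu) / sd
    b <- (hi - mu) / sd
    z <- stats::pnorm(b) - stats::pnorm(a)
    if (z < 1e-12) return(if (a > 0) lo else hi) # truncation region far in a tail
    mu + sd * (stats::dnorm(a) - stats::dnorm(b)) / z
  }
  # tn_mean is increasing in mu; bracket the root near `mean`, where the
  # computation is well conditioned, instead of at distant endpoints
  lo_mu <- up_mu <- mean
  for (i in 1:60) {
    if (tn_mean(lo_mu) <= mean) break
    lo_mu <- lo_mu - sd / 2
  }
  for (i in 1:60) {
    if (tn_mean(up_mu) >= mean) break
    up_mu <- up_mu + sd / 2
  }
  mu <- if (lo_mu == up_mu) lo_mu else
    stats::uniroot(function(m) tn_mean(m) - mean,
                   interval = c(lo_mu, up_mu), tol = 1e-10)$root
  pa <- stats::pnorm(lo, mu, sd)
  pb <- stats::pnorm(hi, mu, sd)
  stats::qnorm(pa + stats::runif(n) * (pb - pa), mu, sd)
}

#' Generate synthetic subject scores for a group
#'
#' Draws `n` subjects whose measures follow independent truncated normals
#' with the profile's means and SDs, truncated at 0 and at the task
#' maxima (15 words per RAVLT trial, sheet length for Stroop counts).
#' Sample means converge to the profile means.  With `grids = TRUE` the
#' five RAVLT learning-trial scores are rounded to integers and each
#' subject receives a 5 x 15 binary recall grid (see [gen_recall_grid()])
#' matching the group's serial-position targets.
#'
#' @param profile A group name (`"control"`, `"dp140_pos"`,
#'   `"dp140_neg"`) or a profile tibble as returned by [group_profiles()]
#'   (columns `group`, `measure`, `mean`, `sd`, optionally `n`).
#' @param n Number of subjects; defaults to the profile's group size.
#' @param seed Optional integer seed.
#' @param grids Attach per-subject recall grids?
#' @param sheet_len Stroop sheet length bounding the sheet counts.
#' @return A tibble with one row per subject: `subject`, `group`, one
#'   column per measure, and (optionally) a `recall_grid` list column.
#' @examples
#' gen_scores("control", n = 5, seed = 1)
#' @export
gen_scores <- function(profile, n = NULL, seed = NULL, grids = FALSE,
                       sheet_len = 100) {
  if (is.character(profile)) profile <- group_profiles(profile)
  stopifnot(all(c("group", "measure", "mean", "sd") %in% names(profile)))
  if (length(unique(profile$group)) != 1) {
    stop("`profile` must describe a single group", call. = FALSE)
  }
  if (any(profile$sd < 0)) stop("profile SDs must be >= 0", call. = FALSE)
  grp <- profile$group[1]
  if (is.null(n)) {
    n <- if ("n" %in% names(profile)) profile$n[1] else
      stop("`n` not given and profile carries no group size", call. = FALSE)
  }
  if (n < 1) stop("`n` must be >= 1", call. = FALSE)

  draw <- function() {
    b <- measure_bounds(profile$measure, sheet_len)
    cols <- purrr::pmap(
      list(profile$measure, profile$mean, profile$sd, b$lo, b$hi),
      function(m, mu, sd, lo, hi) rtnorm_calibrated(n, mu, sd, lo, hi)
    )
    names(cols) <- profile$measure
    out <- tibble::tibble(subject = seq_len(n), group = grp, !!!cols)
    if (grids) {
      trial_cols <- paste0("ravlt_t", 1:5)
      if (!all(trial_cols %in% names(out))) {
        stop("recall grids need measures ravlt_t1..ravlt_t5", call. = FALSE)
      }
      for (tc in trial_cols) {
        out[[tc]] <- pmin(pmax(round(out[[tc]]), 0), 15)
      }
      targets <- trial_bin_targets(grp, profile)
      out$recall_grid <- purrr::pmap(
        out[trial_cols],
        function(...) gen_recall_grid(c(...), targets)
      )
    }
    out
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# Per-trial serial-position bin targets (5 trials x 3 bins): trial 1 uses
# the published T1 targets; trials 2-5 split the remaining (total - T1)
# bin mass proportionally to the trial means.
trial_bin_targets <- function(group, profile) {
  sp <- serial_position_targets(group)
  if (nrow(sp) == 0) { # unknown group label: neutral targets
    sp <- tibble::tibble(bin = c("primacy", "middle", "recency"),
                         t1 = rep(1, 3), total = rep(5, 3))
  }
  tm <- vapply(paste0("ravlt_t", 1:5),
               function(m) profile$mean[profile$measure == m], numeric(1))
  share <- tm[2:5] / sum(tm[2:5])
  rest <- sp$total - sp$t1
  rbind(sp$t1, outer(share, rest)) # 5 trials x 3 bins
}

#' Generate one subject's RAVLT recall grid
#'
#' Builds a 5 x 15 binary matrix (trials x list positions) whose row sums
#' equal the given trial scores and whose expected primacy / middle /
#' recency masses (positions 1-5 / 6-10 / 11-15) match the target bin
#' masses.  Within each trial, recalled words are allocated to bins by
#' randomized rounding of the target-proportional allocation (unbiased),
#' then to uniformly chosen positions within each bin.
#'
#' @param trial_scores Integer vector of 5 trial scores in \[0, 15\].
#' @param targets A 5 x 3 matrix of per-trial bin targets (columns
#'   primacy, middle, recency), or a length-3 vector applied to every
#'   trial.  No target may exceed the bin capacity of 5.
#' @return A 5 x 15 binary integer matrix.
#' @examples
#' g <- gen_recall_grid(c(7, 9, 11, 12, 13), c(2.7, 2.2, 2.6))
#' rowSums(g)
#' @export
gen_recall_grid <- function(trial_scores, targets) {
  trial_scores <- as.integer(round(trial_scores))
  if (length(trial_scores) != 5 || any(trial_scores < 0 | trial_scores > 15)) {
    stop("`trial_scores` must be 5 scores in [0, 15]", call. = FALSE)
  }
  if (is.null(dim(targets))) targets <- matrix(targets, 5, 3, byrow = TRUE)
  targets <- as.matrix(targets)
  if (!all(dim(targets) == c(5, 3))) {
    stop("`targets` must be 5 x 3 (trials x bins)", call. = FALSE)
  }
  if (any(targets > 5)) {
    stop("config error: bin target exceeds the bin capacity of 5",
         call. = FALSE)
  }
  if (any(targets < 0) || any(rowSums(targets) <= 0)) {
    stop("config error: bin targets must be >= 0 with positive row sums",
         call. = FALSE)
  }
  grid <- matrix(0L, 5, 15)
  for (tr in 1:5) {
    k <- trial_scores[tr]
    if (k == 0) next
    p <- targets[tr, ] / sum(targets[tr, ])
    kb <- allocate_bins(k, p)
    for (b in 1:3) {
      if (kb[b] > 0) {
        pos <- (b - 1) * 5 + sample.int(5, kb[b])
        grid[tr, pos] <- 1L
      }
    }
  }
  grid
}

# Randomized-rounding allocation of k items over 3 bins (capacity 5) with
# expected counts k * p: floor the expectations, then place the remaining
# items so each bin gains one with probability equal to its fractional
# part (exact for the 1- and 2-remainder cases; expectations above the
# bin capacity are water-filled onto the other bins first, which only
# occurs for near-ceiling trial scores).
allocate_bins <- function(k, p) {
  m <- k * p
  for (iter in 1:3) { # water-fill expectations exceeding the capacity of 5
    over <- m > 5
    if (!any(over)) break
    excess <- sum(m[over] - 5)
    m[over] <- 5
    room <- m < 5
    if (!any(room)) break
    m[room] <- m[room] + excess * m[room] / sum(m[room])
  }
  m <- pmin(m, 5)
  kb <- floor(m + 1e-9)
  frac <- pmax(m - kb, 0)
  rem <- k - sum(kb)
  if (rem == 1) {
    i <- sample.int(3, 1, prob = frac + 1e-12)
    kb[i] <- kb[i] + 1
  } else if (rem == 2) {
    i <- sample.int(3, 1, prob = pmax(1 - frac, 0) + 1e-12) # exclude one bin
    kb[-i] <- kb[-i] + 1
  } else if (rem > 2) {
    for (j in seq_len(rem)) { # only reachable after capacity repair
      open <- which(kb < 5)
      i <- if (length(open) == 1) open else
        open[sample.int(length(open), 1, prob = frac[open] + 0.1)]
      kb[i] <- kb[i] + 1
    }
  }
  while (any(kb > 5)) { # defensive capacity repair
    i <- which.max(kb)
    j <- which.min(kb)
    kb[i] <- kb[i] - 1L
    kb[j] <- kb[j] + 1L
  }
  as.integer(kb)
}
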