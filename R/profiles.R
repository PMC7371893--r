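# Bundled group score profiles: published group means (SDs) for the
# control, Dp140-positive (proximal mutation) and Dp140-negative (distal
# mutation) groups, plus the serial-position bin targets used by the
# recall-grid generator.  RAVLT trials 2-4 and the list-B mean are not
# published; they are derived from the printed trial-1, trial-5,
# learning-capacity and proactive-interference values (linear trial
# spacing rescaled so the five trials sum to the learning capacity;
# list B = PI x trial 1, with trial-1 SD carried over).

GROUPS <- c("control", "dp140_pos", "dp140_neg")

profile_row <- function(group, measure, mean, sd) {
  tibble::tibble(group = group, measure = measure, mean = mean, sd = sd)
}

derive_trials <- function(t1, t1_sd, t5, t5_sd, lc) {
  mid <- (lc - t1 - t5) / 3          # trial-3 mean: middle trials carry LC
  step <- (t5 - t1) / 4              # linear spacing between t1 and t5
  sds <- t1_sd + (1:3) / 4 * (t5_sd - t1_sd)
  tibble::tibble(
    measure = c("ravlt_t2", "ravlt_t3", "ravlt_t4"),
    mean = c(mid - step, mid, mid + step),
    sd = sds
  )
}

#' Bundled group score profiles
#'
#' Group-wise means and SDs of the cognitive measures for the three study
#' groups (control n = 80, Dp140 positive n = 14, Dp140 negative n = 53):
#' Stroop per-sheet counts, RAVLT trials 1-7 and list B, digit spans and
#' full-scale IQ.  These are the generator inputs that the synthetic
#' cohort emulates.
#'
#' @param group Optional group name(s) to filter to.
#' @return A tibble with columns `group`, `measure`, `mean`, `sd`, `n`.
#' @examples
#' group_profiles("control")
#' @export
group_profiles <- function(group = NULL) {
  mk <- function(g, stroop, t1, t5, lc, ir, dr, pi, dsf, dsb, iq) {
    base <- dplyr::bind_rows(
      profile_row(g, c("stroop_w", "stroop_c", "stroop_cw"),
                  stroop[c(1, 3, 5)], stroop[c(2, 4, 6)]),
      profile_row(g, "ravlt_t1", t1[1], t1[2]),
      dplyr::mutate(derive_trials(t1[1], t1[2], t5[1], t5[2], lc), group = g),
      profile_row(g, "ravlt_t5", t5[1], t5[2]),
      profile_row(g, "ravlt_b", pi * t1[1], t1[2]),
      profile_row(g, "ravlt_ir", ir[1], ir[2]),
      profile_row(g, "ravlt_dr", dr[1], dr[2]),
      profile_row(g, "dsf", dsf[1], dsf[2]),
      profile_row(g, "dsb", dsb[1], dsb[2]),
      profile_row(g, "iq", iq[1], iq[2])
    )
    base[c("group", "measure", "mean", "sd")]
  }
  prof <- dplyr::bind_rows(
    mk("control",
       stroop = c(60.09, 13.4, 46.79, 13.9, 28.34, 9.8),
       t1 = c(7.48, 1.91), t5 = c(12.71, 2.22), lc = 52.89,
       ir = c(11.64, 2.74), dr = c(11.38, 2.89), pi = 0.88,
       dsf = c(5.52, 1.21), dsb = c(3.59, 1.26), iq = c(108, 11.16)),
    mk("dp140_pos",
       stroop = c(48.00, 20.52, 37.25, 15.33, 20.25, 7.35),
       t1 = c(6.00, 2.69), t5 = c(11.29, 3.17), lc = 47.29,
       ir = c(9.79, 3.02), dr = c(9.93, 2.92), pi = 0.92,
       dsf = c(4.73, 1.19), dsb = c(2.64, 1.29), iq = c(90, 10.75)),
    mk("dp140_neg",
       stroop = c(52.30, 20.07, 38.46, 13.71, 24.49, 9.44),
       t1 = c(6.73, 2.48), t5 = c(11.38, 3.18), lc = 47.82,
       ir = c(10.15, 3.74), dr = c(9.81, 3.48), pi = 0.84,
       dsf = c(4.94, 1.21), dsb = c(2.66, 1.84), iq = c(89, 19.94))
  )
  prof$n <- c(control = 80L, dp140_pos = 14L, dp140_neg = 53L)[prof$group]
  if (!is.null(group)) {
    bad <- setdiff(group, GROUPS)
    if (length(bad)) stop("unknown group(s): ", paste(bad, collapse = ", "),
                          call. = FALSE)
    prof <- prof[prof$group %in% group, ]
  }
  prof
}

#' Serial-position bin targets
#'
#' Published expected recall masses in the primacy (positions 1-5),
#' middle (6-10) and recency (11-15) bins, for trial 1 and for the five
#' learning trials combined, per group.  The recall-grid generator
#' distributes each trial's recalled words over positions so that these
#' bin masses are matched in expectation.
#'
#' @param group Optional group name(s) to filter to.
#' @return A tibble with columns `group`, `bin`, `t1`, `total`.
#' @export
serial_position_targets <- function(group = NULL) {
  tab <- tibble::tibble(
    group = rep(GROUPS, each = 3),
    bin = rep(c("primacy", "middle", "recency"), 3),
    t1 = c(2.70, 2.21, 2.58, 2.50, 1.71, 1.64, 2.37, 2.21, 2.06),
    total = c(19.09, 16.52, 17.44, 17.79, 13.36, 15.29, 17.17, 15.25, 15.46)
  )
  if (!is.null(group)) tab <- tab[tab$group %in% group, ]
  tab
}
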