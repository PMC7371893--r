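# Derived neuropsychological indices: RAVLT learning, interference and
# retention ratios, serial-position scores, digit-span attention
# fraction, and ICD-10 IQ banding.  All functions are vectorised and
# return NA (never an error) for undefined ratios, so batch scoring keeps
# one row per subject.

#' RAVLT learning capacity
#'
#' Total words acquired over the five learning trials:
#' `t1 + t2 + t3 + t4 + t5`.
#'
#' @param t1,t2,t3,t4,t5 Trial scores (words recalled, 0-15 each;
#'   vectorised).
#' @return Numeric vector; `NA` where any trial is missing.
#' @examples
#' learning_capacity(6, 9, 11, 12, 12) # 50
#' @export
learning_capacity <- function(t1, t2, t3, t4, t5) {
  t1 + t2 + t3 + t4 + t5
}

#' RAVLT interference and retention indices
#'
#' * proactive interference `PI = listB / t1` (susceptibility of new
#'   learning to prior memory),
#' * retroactive interference `RI = t6 / t5` (immediate recall after the
#'   interference list, relative to final learning),
#' * forgetting speed `FS = t7 / t6` (delayed relative to immediate
#'   recall),
#' * long-term percent retention `LTPR = 100 * t7 / t5`.
#'
#' @param t1,t5 Learning-trial scores.
#' @param listB Interference-list score.
#' @param t6 Immediate recall (after list B).
#' @param t7 Delayed recall.
#' @return A tibble with columns `pi`, `ri`, `forgetting_speed`, `ltpr`;
#'   zero denominators give `NA`.
#' @examples
#' interference_retention(t1 = 7.48, t5 = 12.71, listB = 6.58,
#'                        t6 = 11.64, t7 = 11.38)
#' @export
interference_retention <- function(t1, t5, listB, t6, t7) {
  ratio <- function(num, den) ifelse(!is.na(den) & den > 0, num / den, NA_real_)
  tibble::tibble(
    pi = ratio(listB, t1),
    ri = ratio(t6, t5),
    forgetting_speed = ratio(t7, t6),
    ltpr = 100 * ratio(t7, t5)
  )
}

#' Serial-position scores from a recall grid
#'
#' Bins the 15 list positions into primacy (1-5), middle (6-10) and
#' recency (11-15) and counts recalled words per bin, for trial 1 and for
#' all five trials combined.  The three totals always partition the
#' learning capacity.
#'
#' @param grid A 5 x 15 binary matrix (trials x positions), as from
#'   [gen_recall_grid()].
#' @return A one-row tibble: `primacy_t1`, `middle_t1`, `recency_t1`,
#'   `primacy_total`, `middle_total`, `recency_total`.
#' @examples
#' serial_position(matrix(1L, 5, 15))
#' @export
serial_position <- function(grid) {
  grid <- as.matrix(grid)
  if (!all(dim(grid) == c(5, 15)) || !all(grid %in% c(0, 1))) {
    stop("shape error: recall grid must be a 5 x 15 binary matrix",
         call. = FALSE)
  }
  bins <- rep(c("primacy", "middle", "recency"), each = 5)
  sum_bin <- function(rows, b) sum(grid[rows, bins == b, drop = FALSE])
  tibble::tibble(
    primacy_t1 = sum_bin(1, "primacy"),
    middle_t1 = sum_bin(1, "middle"),
    recency_t1 = sum_bin(1, "recency"),
    primacy_total = sum_bin(1:5, "primacy"),
    middle_total = sum_bin(1:5, "middle"),
    recency_total = sum_bin(1:5, "recency")
  )
}

#' Digit-span attention fraction
#'
#' The published index has no printed formula; two candidate variants are
#' provided and the one used is recorded in the result:
#' `"ratio_diff"` computes `(DSF - DSB) / DSF` and `"normalized"`
#' computes `(DSF - DSB) / (DSF + DSB)`.
#'
#' @param dsf,dsb Forward and backward digit spans (vectorised).
#' @param variant `"ratio_diff"` or `"normalized"`.
#' @return Numeric vector with attribute `variant`; `DSF = 0` (or a zero
#'   denominator) gives `NA`.
#' @examples
#' attention_fraction(5.52, 3.59, "normalized")
#' @export
attention_fraction <- function(dsf, dsb, variant = c("ratio_diff", "normalized")) {
  variant <- match.arg(variant)
  den <- if (variant == "ratio_diff") dsf else dsf + dsb
  out <- ifelse(!is.na(den) & den > 0 & dsf > 0, (dsf - dsb) / den, NA_real_)
  attr(out, "variant") <- variant
  out
}

#' ICD-10 intelligence band for a full-scale IQ
#'
#' `IQ > 84` adequate intelligence; 70-84 borderline; 50-69 mild,
#' 35-49 moderate and below 35 severe/profound intellectual disability.
#' The bands are exhaustive and mutually exclusive over positive IQs.
#'
#' @param iq Full-scale IQ (vectorised, `> 0`).
#' @return An ordered factor from `"severe/profound ID"` up to
#'   `"adequate"`.
#' @examples
#' iq_category(c(42, 55, 85))
#' @export
iq_category <- function(iq) {
  if (any(iq <= 0, na.rm = TRUE)) stop("IQ must be > 0", call. = FALSE)
  cut(iq,
      breaks = c(0, 34.5, 49.5, 69.5, 84.5, Inf),
      labels = c("severe/profound ID", "moderate ID", "mild ID",
                 "borderline", "adequate"),
      ordered_result = TRUE)
}

#' Memory efficiency index with interpretive cut-offs
#'
#' The memory efficiency index combines RAVLT encoding and retention
#' measures; its exact formula lives in an external reference and is not
#' fixed here.  Supply any callable computing it from a subject data
#' frame; the interpretive cut-offs 1.2 and 1.9 (dementia-spectrum versus
#' control discrimination) are attached to the result.
#'
#' @param data A subject-level data frame.
#' @param fn A function `data -> numeric` implementing the index.
#' @return The computed index with attribute `cutoffs = c(1.2, 1.9)`.
#' @export
mei_index <- function(data, fn) {
  stopifnot(is.function(fn))
  out <- fn(data)
  attr(out, "cutoffs") <- c(1.2, 1.9)
  out
}

#' Score a cohort table
#'
#' Batch computation of the derived indices for a subject-level cohort
#' tibble (as produced by [gen_scores()]): learning capacity,
#' interference/retention ratios, both attention-fraction variants, the
#' IQ band, and -- when a `recall_grid` list column is present -- the six
#' serial-position scores.  Undefined ratios are emitted as `NA`, never
#' dropped.
#'
#' @param cohort A tibble with (a subset of) the measure columns
#'   `ravlt_t1` ... `ravlt_t5`, `ravlt_b`, `ravlt_ir`, `ravlt_dr`, `dsf`,
#'   `dsb`, `iq`, `recall_grid`.
#' @return The cohort tibble with the derived index columns appended.
#' @examples
#' score_cohort(gen_scores("control", n = 3, seed = 1))
#' @export
score_cohort <- function(cohort) {
  out <- cohort
  has <- function(...) all(c(...) %in% names(cohort))
  if (has(paste0("ravlt_t", 1:5))) {
    out$learning_capacity <- learning_capacity(
      cohort$ravlt_t1, cohort$ravlt_t2, cohort$ravlt_t3,
      cohort$ravlt_t4, cohort$ravlt_t5
    )
  }
  if (has("ravlt_t1", "ravlt_t5", "ravlt_b", "ravlt_ir", "ravlt_dr")) {
    out <- dplyr::bind_cols(out, interference_retention(
      cohort$ravlt_t1, cohort$ravlt_t5, cohort$ravlt_b,
      cohort$ravlt_ir, cohort$ravlt_dr
    ))
  }
  if (has("dsf", "dsb")) {
    out$attention_ratio_diff <- as.numeric(
      attention_fraction(cohort$dsf, cohort$dsb, "ratio_diff")
    )
    out$attention_normalized <- as.numeric(
      attention_fraction(cohort$dsf, cohort$dsb, "normalized")
    )
  }
  if (has("iq")) out$iq_band <- iq_category(cohort$iq)
  if (has("recall_grid")) {
    sp <- purrr::map_dfr(cohort$recall_grid, serial_position)
    out <- dplyr::bind_cols(out, sp)
  }
  out
}
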