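# The activation machinery: base-level learning, partial matching,
# logistic noise, total activation, the latency law, and retrieval.

#' Base-level activation
#'
#' The base level of an instance reflects the recency and frequency of its
#' past use: `B = ln( sum over past retrievals of (now - t_i)^(-d) )`,
#' where the `t_i` are the instance's past retrieval event indices and
#' `now` the current event index (event-count time).
#'
#' For a single past retrieval at lag `L` this reduces to the closed form
#' `-d * log(L)`.
#'
#' @param events Integer vector of past retrieval event indices (strictly
#'   increasing, all `< now`).
#' @param now Current event index.
#' @param d Decay parameter in \[0, 10\].
#' @return The base-level activation (unitless, finite).
#' @examples
#' base_level_activation(1, now = 5, d = 0.5) # -0.5 * log(4)
#' @export
base_level_activation <- function(events, now, d) {
  if (length(events) == 0L) {
    stop("no history: instance has no past retrieval events", call. = FALSE)
  }
  if (any(events >= now)) {
    stop("all retrieval events must lie strictly before `now`", call. = FALSE)
  }
  if (is.unsorted(events, strictly = TRUE)) {
    stop("retrieval events must be strictly increasing", call. = FALSE)
  }
  log(sum((now - events)^(-d)))
}

#' Mismatch between a requested and a stored slot value
#'
#' Similarity-derived mismatch `M` in \[-1, 0\]: 0 when the values are
#' equal (no penalty) and -1 for a complete mismatch.  When a graded
#' similarity table is supplied, `M = sim - 1` for declared pairs and the
#' binary rule applies otherwise.
#'
#' @param requested,stored Slot values (vectorised; recycled).
#' @param vocabulary Optional character vector; values outside it raise an
#'   error.
#' @param similarity Optional similarity table: a data frame with columns
#'   `a`, `b`, `sim` (`sim` in \[0, 1\], symmetric pairs need only one row).
#' @return Numeric mismatch value(s) in \[-1, 0\].
#' @examples
#' mismatch("red", "red")  # 0
#' mismatch("red", "blue") # -1
#' @export
mismatch <- function(requested, stored, vocabulary = NULL, similarity = NULL) {
  if (!is.null(vocabulary)) {
    bad <- setdiff(unique(c(requested, stored)), vocabulary)
    if (length(bad)) {
      stop(sprintf("value(s) outside vocabulary: %s",
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
  }
  n <- max(length(requested), length(stored))
  requested <- rep_len(requested, n)
  stored <- rep_len(stored, n)
  m <- ifelse(requested == stored, 0, -1)
  if (!is.null(similarity)) {
    stopifnot(all(c("a", "b", "sim") %in% names(similarity)))
    if (any(similarity$sim < 0 | similarity$sim > 1)) {
      stop("similarities must lie in [0, 1]", call. = FALSE)
    }
    for (k in seq_len(nrow(similarity))) {
      hit <- (requested == similarity$a[k] & stored == similarity$b[k]) |
        (requested == similarity$b[k] & stored == similarity$a[k])
      m[hit & requested != stored] <- similarity$sim[k] - 1
    }
  }
  m
}

#' Draw logistic activation noise
#'
#' Noise added to an instance's activation at retrieval:
#' `eps = s * ln((1 - u) / u)` with `u ~ Uniform(0, 1)`, i.e. a logistic
#' draw with scale `s` (variance `s^2 * pi^2 / 3`), symmetric about 0.
#'
#' @param n Number of draws.
#' @param s Noise scale, `>= 0`.
#' @param u Optional uniform draws to transform (for reproducing a
#'   specific draw); length-`n` numeric in (0, 1).
#' @return Numeric vector of `n` noise values.
#' @examples
#' noise_draw(1, s = 2, u = 0.75) # 2 * log(1/3)
#' @export
noise_draw <- function(n, s, u = NULL) {
  if (s < 0) stop("noise scale `s` must be >= 0", call. = FALSE)
  if (s == 0 && is.null(u)) return(rep(0, n)) # consume no RNG at zero scale
  if (is.null(u)) u <- stats::runif(n)
  s * log((1 - u) / u)
}

#' Total activation of an instance against a probe
#'
#' `A = B + sum over probed slots of P_l * M_l + eps`, combining the
#' base level, the partial-matching penalty and (optionally) logistic
#' noise.  Mismatch penalties only ever lower activation.
#'
#' @param instance An instance (as stored in an [memory_store()]), i.e. a
#'   list with `color`, `word` and `events`.
#' @param probe An [probe()] object.
#' @param params An [model_params()] object.
#' @param now Current event index.
#' @param noise If `FALSE`, the noise term is 0.
#' @param similarity Optional graded similarity table (see [mismatch()]).
#' @return The activation value (unitless).
#' @export
activation <- function(instance, probe, params, now, noise = TRUE,
                       similarity = NULL) {
  stopifnot(inherits(probe, "ibl_probe"), inherits(params, "ibl_params"))
  b <- base_level_activation(instance$events, now, params$d)
  pen <- 0
  for (slot in names(probe$requested)) {
    w <- if (!is.null(probe$weights) && slot %in% names(probe$weights)) {
      probe$weights[[slot]]
    } else {
      params$P
    }
    pen <- pen + w * mismatch(probe$requested[[slot]], instance[[slot]],
                              similarity = similarity)
  }
  eps <- if (noise && params$s > 0) noise_draw(1, params$s) else 0
  b + pen + eps
}

#' Retrieval latency
#'
#' Maps activation to the time the declarative module needs to deliver an
#' instance: `RT = F * exp(-f * A)` seconds.  Strictly decreasing in `A`
#' for `f > 0`, with `RT = F` at `A = 0`: weakly activated (negative
#' activation) instances are retrieved more slowly.
#'
#' @param A Activation (vectorised).
#' @param F Latency factor, seconds, `>= 0`.
#' @param f Latency exponent.
#' @return Retrieval time(s) in seconds.
#' @examples
#' retrieval_time(0, F = 1, f = 0.005) # exactly F
#' @export
retrieval_time <- function(A, F, f) {
  if (F < 0) stop("`F` must be >= 0", call. = FALSE)
  F * exp(-f * A)
}

#' Retrieve the best-matching instance from memory
#'
#' Computes the (noisy) activation of every instance against the probe
#' and returns the arg-max together with its retrieval latency.  The
#' winning instance's history gains the current event index and the store
#' clock advances by one.  With noise off, ties go to the instance
#' created first.  If `params$tau` is set and no activation reaches it,
#' the retrieval fails.
#'
#' @inheritParams activation
#' @param store An [memory_store()] with at least one instance.
#' @return A list with `failed` (logical), and unless failed: `instance`
#'   (winner index), `color`, `word`, `activation`, `rt` (seconds), and
#'   the updated `store`.
#' @export
retrieve <- function(store, probe, params, noise = TRUE, similarity = NULL) {
  stopifnot(inherits(store, "ibl_store"))
  if (length(store$instances) == 0L) {
    stop("retrieval from an empty store", call. = FALSE)
  }
  acts <- vapply(
    store$instances,
    function(inst) activation(inst, probe, params, store$now,
                              noise = noise, similarity = similarity),
    numeric(1)
  )
  win <- which.max(acts) # first max: earliest-created instance wins ties
  if (!is.null(params$tau) && acts[win] < params$tau) {
    return(list(failed = TRUE, activations = acts, store = store))
  }
  store$instances[[win]]$events <- c(store$instances[[win]]$events, store$now)
  store$now <- store$now + 1L
  list(
    failed = FALSE,
    instance = win,
    color = store$instances[[win]]$color,
    word = store$instances[[win]]$word,
    activation = acts[win],
    rt = retrieval_time(acts[win], params$F, params$f),
    activations = acts,
    store = store
  )
}
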