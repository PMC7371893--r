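# Declarative memory store: a flat list of instances plus an event clock.
# Time is event-count time -- each retrieval attempt advances `now` by one;
# seconds appear only in retrieval latencies.

NEUTRAL <- "none"

#' Create a declarative memory store
#'
#' An instance is a Situation--Decision--Utility record whose situation
#' slots are a `color` and a `word` attribute; its utility is a numeric
#' outcome and its history an ordered vector of past retrieval event
#' indices.  `memory_store()` builds a store over a colour vocabulary,
#' optionally pre-seeded with one word-reading instance (word = colour
#' name, colour slot neutral) and one colour-naming instance (colour =
#' ink, word slot neutral) per colour, each with a single baseline
#' retrieval event.  The baseline represents pre-experimental familiarity
#' with reading colour words and naming inks; without it the first sheet
#' of a session would have nothing to retrieve.
#'
#' @param colors Character vector (length `>= 2`) of colour labels.
#' @param init `"baseline"` (default) seeds the reading/naming instances;
#'   `"empty"` creates a bare store.
#' @return An object of class `ibl_store`: a list with elements
#'   `instances` (list of instances), `now` (current event index) and
#'   `vocab` (colour vocabulary including the neutral token).
#' @examples
#' st <- memory_store(c("red", "green", "blue", "yellow"))
#' st
#' @export
memory_store <- function(colors, init = c("baseline", "empty")) {
  init <- match.arg(init)
  colors <- as.character(colors)
  if (length(colors) < 2L || anyDuplicated(colors) || NEUTRAL %in% colors) {
    stop("`colors` must be >= 2 distinct labels not containing the neutral token",
         call. = FALSE)
  }
  store <- structure(
    list(instances = list(), now = 1L, vocab = c(NEUTRAL, colors)),
    class = "ibl_store"
  )
  if (init == "baseline") {
    for (cl in colors) { # word-reading knowledge
      store <- add_instance(store, color = NEUTRAL, word = cl)
    }
    for (cl in colors) { # colour-naming knowledge
      store <- add_instance(store, color = cl, word = NEUTRAL)
    }
  }
  store
}

#' Add an instance to a memory store
#'
#' Creates a new instance with a single retrieval event at the store's
#' current event index and advances the clock.  If an instance with the
#' same `(color, word)` situation already exists, a new event is appended
#' to it instead (instances are identified by their situation slots).
#'
#' @param store An `ibl_store`.
#' @param color,word Situation slot values (from the store vocabulary).
#' @param outcome Numeric utility attached to the instance.
#' @return The updated store.
#' @export
add_instance <- function(store, color, word, outcome = 1) {
  stopifnot(inherits(store, "ibl_store"))
  chk_vocab(store, color)
  chk_vocab(store, word)
  idx <- instance_index(store, color, word)
  if (is.na(idx)) {
    store$instances[[length(store$instances) + 1L]] <- list(
      color = color, word = word, outcome = outcome,
      events = store$now
    )
  } else {
    store$instances[[idx]]$events <- c(store$instances[[idx]]$events, store$now)
  }
  store$now <- store$now + 1L
  store
}

instance_index <- function(store, color, word) {
  for (i in seq_along(store$instances)) {
    inst <- store$instances[[i]]
    if (identical(inst$color, color) && identical(inst$word, word)) return(i)
  }
  NA_integer_
}

chk_vocab <- function(store, value) {
  if (!value %in% store$vocab) {
    stop(sprintf("value '%s' is outside the declared vocabulary", value),
         call. = FALSE)
  }
  invisible(value)
}

#' @export
print.ibl_store <- function(x, ...) {
  cat(sprintf("<ibl_store> %d instance(s), now = %d\n",
              length(x$instances), x$now))
  for (inst in x$instances) {
    cat(sprintf("  (color=%s, word=%s): %d event(s)\n",
                inst$color, inst$word, length(inst$events)))
  }
  invisible(x)
}

#' Tidy view of a memory store
#'
#' @param x An `ibl_store`.
#' @param ... Unused.
#' @return A tibble with one row per instance: situation slots, outcome,
#'   number of retrieval events and the most recent event index.
#' @method tidy ibl_store
#' @export
tidy.ibl_store <- function(x, ...) {
  tibble::tibble(
    instance = seq_along(x$instances),
    color = purrr::map_chr(x$instances, "color"),
    word = purrr::map_chr(x$instances, "word"),
    outcome = purrr::map_dbl(x$instances, "outcome"),
    n_events = purrr::map_int(x$instances, ~ length(.x$events)),
    last_event = purrr::map_int(x$instances, ~ as.integer(max(.x$events)))
  )
}

#' Build a retrieval probe
#'
#' A probe names the requested situation slots and the penalty weight
#' attached to each; slots omitted from the probe do not enter the
#' partial-matching sum.
#'
#' @param color,word Requested slot values, or `NULL` to leave the slot
#'   out of the probe.
#' @param weights Named numeric vector of per-slot penalty weights; slots
#'   not named fall back to the model's `P`.
#' @return An object of class `ibl_probe`.
#' @examples
#' probe(color = "red", word = "blue")
#' @export
probe <- function(color = NULL, word = NULL, weights = NULL) {
  requested <- list()
  if (!is.null(color)) requested$color <- color
  if (!is.null(word)) requested$word <- word
  if (length(requested) == 0L) stop("probe must request at least one slot", call. = FALSE)
  if (!is.null(weights)) {
    if (is.null(names(weights)) || !all(names(weights) %in% names(requested))) {
      stop("`weights` must be named after requested slots", call. = FALSE)
    }
    if (any(weights < 0)) stop("probe weights must be >= 0", call. = FALSE)
  }
  structure(list(requested = requested, weights = weights), class = "ibl_probe")
}
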