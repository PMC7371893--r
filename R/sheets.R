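# The three-sheet Stroop Color and Word Task: sheet construction, memory
# seeding, and the timed per-sheet simulation (reference R engine; the
# compiled engine in src/ runs the identical algorithm).

SHEET_KINDS <- c("word", "color", "color_word")

#' Task configuration for a simulated Stroop session
#'
#' Geometry and bookkeeping for the three naming sheets: a fixed colour
#' vocabulary, items per sheet, the 45-second time budget per sheet, and
#' the penalty time logged when a retrieval fails (only possible when a
#' retrieval threshold `tau` is set).
#'
#' @param colors Colour vocabulary (default the standard four-colour set).
#' @param n_items Items printed on each sheet.
#' @param time_budget Seconds allowed per sheet.
#' @param skip_penalty Seconds charged for an item skipped after a
#'   retrieval failure.
#' @return A list of class `stroop_config`.
#' @export
task_config <- function(colors = c("red", "green", "blue", "yellow"),
                        n_items = 100, time_budget = 45, skip_penalty = 1) {
  stopifnot(length(colors) >= 2, n_items >= 1, time_budget >= 0,
            skip_penalty >= 0)
  structure(list(colors = as.character(colors), n_items = as.integer(n_items),
                 time_budget = time_budget, skip_penalty = skip_penalty),
            class = "stroop_config")
}

# Internal: integer item codes for one sheet (0 = neutral), drawn from the
# current RNG state.  `make_sheet()` and the session engines share this so
# a seed fixes the item sequence identically everywhere.
sheet_items <- function(kind, n_items, n_colors) {
  switch(kind,
    word = list(kind = 0L,
                word = sample.int(n_colors, n_items, replace = TRUE),
                ink = integer(n_items)),
    color = list(kind = 1L,
                 word = integer(n_items),
                 ink = sample.int(n_colors, n_items, replace = TRUE)),
    color_word = {
      ink <- sample.int(n_colors, n_items, replace = TRUE)
      # word drawn uniformly from the other colours: always incongruent
      shift <- sample.int(n_colors - 1L, n_items, replace = TRUE)
      word <- 1L + (ink - 1L + shift) %% n_colors
      list(kind = 2L, word = word, ink = ink)
    },
    stop("unknown sheet kind: ", kind, call. = FALSE)
  )
}

#' Construct a Stroop sheet
#'
#' Builds one of the three task sheets as a tibble of items.  A word sheet
#' prints colour words in neutral ink; a colour sheet prints neutral
#' tokens in coloured ink; a colour-word sheet prints colour words in a
#' different ink (every item incongruent).  The item sequence is drawn
#' from the current RNG state, so `set.seed()` makes it reproducible.
#'
#' @param kind One of `"word"`, `"color"`, `"color_word"`.
#' @param n_items Number of items, `>= 1`.
#' @param colors Colour vocabulary (`>= 2` colours).
#' @param time_budget Seconds allowed for the sheet.
#' @return A tibble with columns `item`, `word`, `ink`, `congruent`, and
#'   attributes `kind` and `time_budget`.
#' @examples
#' set.seed(1)
#' make_sheet("color_word", n_items = 5, colors = c("red", "green", "blue"))
#' @export
make_sheet <- function(kind = SHEET_KINDS, n_items = 100,
                       colors = c("red", "green", "blue", "yellow"),
                       time_budget = 45) {
  kind <- match.arg(kind)
  if (n_items < 1) stop("`n_items` must be >= 1", call. = FALSE)
  if (length(colors) < 2) {
    stop("config error: at least 2 colours are required", call. = FALSE)
  }
  ids <- sheet_items(kind, n_items, length(colors))
  lab <- function(v) ifelse(v == 0L, NEUTRAL, colors[pmax(v, 1L)])
  out <- tibble::tibble(
    item = seq_len(n_items),
    word = lab(ids$word),
    ink = lab(ids$ink),
    congruent = ids$word == ids$ink & ids$word != 0L
  )
  attr(out, "kind") <- kind
  attr(out, "time_budget") <- time_budget
  attr(out, "colors") <- as.character(colors)
  out
}

#' Seed a memory store from completed sheet results
#'
#' Registers the completions of an already-simulated sheet as retrieval
#' events: every named item becomes (or strengthens) an instance carrying
#' the named attribute, with one retrieval event per completion.  Used to
#' rebuild the memory state that the colour-word sheet inherits from the
#' word and colour sheets.
#'
#' @param store An [memory_store()].
#' @param sheet A sheet tibble from [make_sheet()].
#' @param items_completed Number of items completed on that sheet (the
#'   first `items_completed` items are registered, in order).
#' @return The updated store.
#' @examples
#' st <- memory_store(c("red", "green", "blue"), init = "empty")
#' sh <- make_sheet("word", n_items = 10, colors = c("red", "green", "blue"))
#' st <- seed_instances(st, sh, items_completed = 10)
#' @export
seed_instances <- function(store, sheet, items_completed) {
  stopifnot(inherits(store, "ibl_store"))
  items_completed <- min(items_completed, nrow(sheet))
  if (items_completed < 1) return(store)
  kind <- attr(sheet, "kind")
  for (i in seq_len(items_completed)) {
    if (kind == "word") {
      store <- add_instance(store, color = NEUTRAL, word = sheet$word[i])
    } else {
      store <- add_instance(store, color = sheet$ink[i], word = NEUTRAL)
    }
  }
  store
}

#' Simulate one timed naming sheet
#'
#' Iterates the sheet's items in order.  Each item is named by retrieving
#' the instance matching the to-be-named attribute: word sheets probe the
#' word slot, colour sheets the ink slot, and colour-word sheets probe the
#' ink slot with the printed word supplied as a context slot, so partial
#' matching penalises the colour-naming instance (the Stroop
#' interference).  Item time is the retrieval latency plus the model's
#' fixed non-retrieval overhead; the sheet stops once the budget is
#' exhausted.  Every retrieval attempt leaves its event in memory.
#'
#' @param sheet A sheet tibble from [make_sheet()].
#' @param store An [memory_store()] over the sheet's colours.
#' @param params An [model_params()] object.
#' @param noise If `FALSE` the activation noise term is suppressed.
#' @param skip_penalty Seconds charged for an item skipped after a
#'   retrieval failure (see [task_config()]).
#' @return A list with `result` (a `sheet_result`: kind, items_completed,
#'   latencies of all attempted items, failure flags, time budget) and
#'   `store` (the updated memory).
#' @export
simulate_sheet <- function(sheet, store, params, noise = TRUE,
                           skip_penalty = 1) {
  stopifnot(inherits(store, "ibl_store"), inherits(params, "ibl_params"))
  kind <- attr(sheet, "kind")
  budget <- attr(sheet, "time_budget")
  lat <- numeric(0)
  failed <- logical(0)
  cum <- 0
  done <- 0L
  for (i in seq_len(nrow(sheet))) {
    pr <- switch(kind,
      word = probe(word = sheet$word[i]),
      color = probe(color = sheet$ink[i]),
      color_word = probe(color = sheet$ink[i], word = sheet$word[i])
    )
    res <- retrieve(store, pr, params, noise = noise)
    if (res$failed) {
      lat <- c(lat, skip_penalty)
      failed <- c(failed, TRUE)
      cum <- cum + skip_penalty
      if (cum > budget) break
      next
    }
    store <- res$store
    t_item <- res$rt + params$t_nonretrieval
    lat <- c(lat, t_item)
    failed <- c(failed, FALSE)
    if (cum + t_item <= budget) {
      cum <- cum + t_item
      done <- done + 1L
    } else {
      break
    }
  }
  result <- structure(
    list(kind = kind, items_completed = done, latencies = lat,
         failed = failed, time_budget = budget),
    class = "sheet_result"
  )
  list(result = result, store = store)
}

#' @export
print.sheet_result <- function(x, ...) {
  cat(sprintf("<sheet_result> %s sheet: %d items in %g s (%d attempted, %d failed)\n",
              x$kind, x$items_completed, x$time_budget,
              length(x$latencies), sum(x$failed)))
  invisible(x)
}
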