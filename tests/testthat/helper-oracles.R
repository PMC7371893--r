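# Brute-force re-evaluation of the activation equation, term by term,
# independent of the package's activation() code path.
brute_activation <- function(instance, requested, params, now) {
  b <- log(sum((now - instance$events)^(-params$d)))
  pen <- 0
  for (slot in names(requested)) {
    m <- if (identical(requested[[slot]], instance[[slot]])) 0 else -1
    pen <- pen + params$P * m
  }
  b + pen
}

# A small deterministic store: 3 colours, baseline knowledge, plus a few
# extra retrieval events so base levels differ between instances.
small_store <- function(colors = c("red", "green", "blue")) {
  st <- memory_store(colors)
  st <- add_instance(st, color = "none", word = "red")   # strengthen red word
  st <- add_instance(st, color = "blue", word = "none")  # strengthen blue ink
  st
}
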