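#' @name automata
#' @title Finite-state machines over the serialized amplitude alphabet
#'
#' @description
#' The detector's pattern layer is a set of four finite-state machines over
#' the alphabet `{0..9, -, .}`: a positive-peak machine, a negative-peak
#' machine (used for both Q and S), a rest-phase machine, and a composite
#' machine for a whole QRS complex
#' `QRS = {Q}? {rest}? {R} {rest}? {S}`.
#' The published transition tables contain epsilon-moves and duplicate
#' entries, so the engine executes them as epsilon-NFAs by closure/subset
#' simulation; each machine's language equals its defining regular
#' expression, and [matches_pattern()] provides that regex as an independent
#' oracle.
NULL

EPS <- "eps"
SIGMA_ALPHABET <- c(as.character(0:9), "-", ".")

expand_symbol <- function(sym) {
  switch(sym,
    "0-9" = as.character(0:9),
    "1-9" = as.character(1:9),
    sym
  )
}

# assemble a machine from a transition list of c(from, symbol, to) triples;
# digit-range shorthands ("0-9", "1-9") expand to per-digit transitions
make_machine <- function(name, states, transitions, start, finals) {
  from <- integer(0); sym <- character(0); to <- integer(0)
  for (tr in transitions) {
    syms <- expand_symbol(tr[[2]])
    from <- c(from, rep(as.integer(tr[[1]]), length(syms)))
    sym <- c(sym, syms)
    to <- c(to, rep(as.integer(tr[[3]]), length(syms)))
  }
  tab <- tibble::tibble(from = from, symbol = sym, to = to)
  tab <- dplyr::distinct(tab)  # the printed tables repeat some entries
  stopifnot(all(tab$from %in% states), all(tab$to %in% states),
            all(tab$symbol %in% c(SIGMA_ALPHABET, EPS)),
            start %in% states, all(finals %in% states))
  lookup <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(tab))) {
    key <- paste0(tab$from[i], "|", tab$symbol[i])
    lookup[[key]] <- c(lookup[[key]], tab$to[i])
  }
  structure(list(name = name, states = as.integer(states),
                 alphabet = SIGMA_ALPHABET, transitions = tab,
                 start = as.integer(start), finals = as.integer(finals),
                 lookup = lookup),
            class = "qrs_machine")
}

#' @export
print.qrs_machine <- function(x, ...) {
  cat(sprintf("<qrs_machine: %s> %d states, %d transitions, start %d, finals {%s}\n",
              x$name, length(x$states), nrow(x$transitions), x$start,
              paste(x$finals, collapse = ",")))
  invisible(x)
}

eps_closure <- function(machine, states) {
  out <- states
  frontier <- states
  while (length(frontier)) {
    nxt <- unlist(lapply(frontier, \(s) machine$lookup[[paste0(s, "|", EPS)]]))
    nxt <- setdiff(unique(nxt), out)
    out <- c(out, nxt)
    frontier <- nxt
  }
  out
}

#' Run a machine on a symbol string
#'
#' Epsilon-closure subset simulation: the machine accepts when some path
#' consumes the whole input and ends in a final state. The result is
#' deterministic for a fixed machine and input even though the transition
#' tables contain epsilon-moves.
#'
#' @param machine A machine built by [build_positive_peak_machine()],
#'   [build_negative_peak_machine()], [build_rest_machine()] or
#'   [build_qrs_machine()].
#' @param input A single string over the alphabet `{0..9, -, .}` (typically a
#'   concatenation of [serialize_sample()] outputs).
#' @return A list with `accepted` (logical) and `consumed` (number of symbols
#'   consumed before the live state set died out; equals `nchar(input)` when
#'   the whole input was consumed). `consumed` exists for diagnostics only.
#' @examples
#' m <- build_positive_peak_machine()
#' run_automaton(m, "0.5")$accepted
#' @export
run_automaton <- function(machine, input) {
  stopifnot(inherits(machine, "qrs_machine"), is.character(input),
            length(input) == 1L)
  syms <- if (nzchar(input)) strsplit(input, "", fixed = TRUE)[[1]] else character(0)
  bad <- setdiff(syms, machine$alphabet)
  if (length(bad)) {
    stop("input symbol(s) outside the alphabet: ",
         paste(unique(bad), collapse = " "), call. = FALSE)
  }
  cur <- eps_closure(machine, machine$start)
  consumed <- 0L
  for (s in syms) {
    nxt <- unlist(lapply(cur, \(q) machine$lookup[[paste0(q, "|", s)]]))
    if (is.null(nxt) || !length(nxt)) {
      return(list(accepted = FALSE, consumed = consumed))
    }
    cur <- eps_closure(machine, unique(nxt))
    consumed <- consumed + 1L
  }
  list(accepted = any(cur %in% machine$finals), consumed = consumed)
}

#' @rdname automata
#' @details
#' `build_positive_peak_machine()` accepts one or more positive-peak samples,
#' `(0.[1-9][0-9]*|1)+`: states 0..4, finals \{3, 4\}, with epsilon-loops back
#' to the start realizing the repetition.
#' @return Each `build_*` function returns a `qrs_machine`.
#' @export
build_positive_peak_machine <- function() {
  make_machine("positive_peak", 0:4, list(
    list(0, "0", 1), list(1, ".", 2), list(2, "1-9", 3), list(3, "0-9", 3),
    list(3, EPS, 0), list(0, "1", 4), list(4, EPS, 0)
  ), start = 0, finals = c(3, 4))
}

#' @rdname automata
#' @details
#' `build_negative_peak_machine()` accepts `(-0.[1-9][0-9]*|-1)+`; it serves
#' both the Q and the S peak (same shape, different sigma threshold applied
#' later by the detector).
#' @export
build_negative_peak_machine <- function() {
  make_machine("negative_peak", 0:5, list(
    list(0, "-", 1), list(1, "0", 2), list(2, ".", 3), list(3, "1-9", 4),
    list(4, "0-9", 4), list(4, EPS, 0), list(1, "1", 5), list(5, EPS, 0)
  ), start = 0, finals = c(4, 5))
}

#' @rdname automata
#' @details
#' `build_rest_machine()` accepts `(-?0.0[0-9]*)+` -- runs of near-isoelectric
#' samples (magnitude below 0.1).
#' @export
build_rest_machine <- function() {
  make_machine("rest", 0:5, list(
    list(0, "0", 1), list(1, ".", 2), list(2, "0", 3), list(3, "0-9", 3),
    list(3, EPS, 0), list(0, "-", 4), list(4, "0", 5), list(5, ".", 2)
  ), start = 0, finals = 3)
}

#' @rdname automata
#' @details
#' `build_qrs_machine()` accepts a serialized whole complex,
#' `{Q}? {rest}? {R} {rest}? {S}` with Q and the rests optional. States 0..28,
#' finals \{27, 28\}. The published table is kept verbatim (including its
#' duplicated epsilon entries); two moves it omits are added so the language
#' equals the defining expression: an epsilon-move from the start into the
#' leading rest block (rest present, Q absent) and the fractional-digit loop
#' on the R section (state 15).
#' @export
build_qrs_machine <- function() {
  make_machine("qrs", 0:28, list(
    # Q block (optional, repeatable): -0.[1-9][0-9]* | -1
    list(0, "-", 1), list(1, "0", 2), list(2, ".", 3), list(3, "1-9", 4),
    list(4, "0-9", 4), list(4, EPS, 6), list(1, "1", 5), list(4, EPS, 0),
    list(5, EPS, 6), list(5, EPS, 0),
    # first rest block: -?0.0[0-9]*
    list(6, "0", 7), list(7, ".", 8), list(8, "0", 9), list(6, "-", 10),
    list(10, "0", 11), list(11, ".", 8), list(9, "0-9", 9), list(9, EPS, 6),
    list(6, EPS, 12), list(0, EPS, 12), list(9, EPS, 12),
    list(0, EPS, 6),       # leading rest with Q absent
    # R block (mandatory): 0.[1-9][0-9]* | 1
    list(12, "0", 13), list(13, ".", 14), list(14, "1-9", 15),
    list(15, "0-9", 15),   # fractional-digit loop
    list(15, EPS, 17), list(15, EPS, 12), list(12, "1", 16),
    list(16, EPS, 12), list(16, EPS, 17),
    # second rest block
    list(17, "0", 18), list(18, ".", 19), list(19, "0", 20),
    list(20, "0-9", 20), list(17, "-", 21), list(21, "0", 22),
    list(22, ".", 19), list(20, EPS, 17), list(17, EPS, 23), list(20, EPS, 23),
    # S block (mandatory): -0.[1-9][0-9]* | -1
    list(23, "-", 24), list(24, "0", 25), list(25, ".", 26), list(26, "1-9", 27),
    list(27, EPS, 23), list(27, "0-9", 27), list(24, "1", 28), list(28, EPS, 23)
  ), start = 0, finals = c(27, 28))
}

pattern_regexes <- function() {
  r <- "(0\\.[1-9][0-9]*|1)+"
  neg <- "(-0\\.[1-9][0-9]*|-1)+"
  rest <- "(-?0\\.0[0-9]*)+"
  list(
    R = r, Qneg = neg, Sneg = neg, rest = rest,
    QRS = paste0("(", neg, ")?", "(", rest, ")?", "(", r, ")",
                 "(", rest, ")?", "(", neg, ")")
  )
}

#' Match a symbol string against the defining regular expressions
#'
#' The regex forms of the positive-peak, negative-peak, rest and composite
#' QRS patterns, anchored to the full string. This is the independent oracle
#' the machines are tested against.
#'
#' @param pattern_id One of `"R"`, `"Qneg"`, `"Sneg"`, `"rest"`, `"QRS"`.
#' @param input Character vector of symbol strings.
#' @return Logical vector: whole-string match per input.
#' @examples
#' matches_pattern("R", c("0.5", "0.05"))
#' matches_pattern("QRS", "0.9-0.4")
#' @export
matches_pattern <- function(pattern_id, input) {
  pats <- pattern_regexes()
  pattern_id <- match.arg(pattern_id, names(pats))
  grepl(paste0("^", pats[[pattern_id]], "$"), input, perl = TRUE)
}

#' Serialize a machine to / from a JSON description
#'
#' @param machine A `qrs_machine`.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return `machine_to_json()`: the JSON string (invisibly when written to a
#'   file); `machine_from_json()`: a `qrs_machine`.
#' @export
machine_to_json <- function(machine, path = NULL) {
  obj <- list(name = machine$name, states = machine$states,
              alphabet = machine$alphabet,
              transitions = machine$transitions,
              start = machine$start, finals = machine$finals)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  write_atomic(path, \(tmp) writeLines(js, tmp))
  invisible(js)
}

#' @rdname machine_to_json
#' @param json A JSON string or file path produced by [machine_to_json()].
#' @export
machine_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json)
  trs <- purrr::pmap(obj$transitions, \(from, symbol, to) list(from, symbol, to))
  make_machine(obj$name, obj$states, trs, obj$start, obj$finals)
}
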