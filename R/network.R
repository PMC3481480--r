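#' Construct a synchronous Boolean network
#'
#' A network has exogenous input nodes (per-step external signals, not part
#' of the state vector), ordered state nodes (the bit order of the encoded
#' state, first node = most significant bit), constant nodes fixed at 0 or
#' 1, a set of observable state nodes, and one Boolean update expression
#' per state node.  All state nodes are updated synchronously: each update
#' expression is evaluated on the previous state together with the current
#' inputs and the constants.
#'
#' @param state_nodes character vector of state node names, in bit order.
#' @param updates named list of [bn_expr] objects (or strings, parsed with
#'   [parse_bool_expr()]), one per state node.
#' @param inputs character vector of input node names.
#' @param constants named 0/1 vector of constant nodes.
#' @param observables character vector, subset of `state_nodes`.
#' @param name optional network name.
#' @return An object of class `bn`.
#' @examples
#' net <- boolean_network(
#'   state_nodes = c("A", "B"),
#'   updates = list(A = "B", B = "!A"),
#'   observables = "B"
#' )
#' net
#' @export
boolean_network <- function(state_nodes, updates, inputs = character(0),
                            constants = integer(0),
                            observables = character(0), name = "network") {
  stopifnot(is.character(state_nodes), is.list(updates))
  updates <- lapply(updates, function(u) {
    if (is.character(u)) parse_bool_expr(u) else u
  })
  cnames <- names(constants)
  constants <- as.integer(constants)
  if (length(constants) && is.null(cnames))
    stop("constants must be a named 0/1 vector", call. = FALSE)
  names(constants) <- cnames
  net <- structure(
    list(name = name,
         inputs = as.character(inputs),
         state_nodes = as.character(state_nodes),
         constants = constants,
         observables = as.character(observables),
         updates = updates),
    class = "bn")
  validate_bn(net)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

validate_bn <- function(net, where = NULL) {
  loc <- function(msg) {
    if (is.null(where)) stop(msg, call. = FALSE)
    stop(msg, " (", where, ")", call. = FALSE)
  }
  all_names <- c(net$inputs, net$state_nodes, names(net$constants))
  if (anyDuplicated(all_names))
    loc(paste0("duplicate node declaration: '",
               all_names[duplicated(all_names)][1L], "'"))
  if (length(net$state_nodes) == 0L)
    loc("network has no state nodes")
  if (length(net$constants) && !all(net$constants %in% c(0L, 1L)))
    loc("constants must be 0 or 1")
  missing_upd <- setdiff(net$state_nodes, names(net$updates))
  if (length(missing_upd))
    loc(paste0("missing update expression for node '", missing_upd[1L], "'"))
  extra_upd <- setdiff(names(net$updates), net$state_nodes)
  if (length(extra_upd))
    loc(paste0("update given for undeclared state node '", extra_upd[1L], "'"))
  net$updates <- net$updates[net$state_nodes]
  bad_obs <- setdiff(net$observables, net$state_nodes)
  if (length(bad_obs))
    loc(paste0("observable '", bad_obs[1L], "' is not a state node"))
  for (nd in net$state_nodes) {
    refs <- expr_vars(net$updates[[nd]])
    undecl <- setdiff(refs, all_names)
    if (length(undecl))
      loc(paste0("update of '", nd, "' references undeclared variable '",
                 undecl[1L], "'"))
  }
  net
}

#' @export
print.bn <- function(x, ...) {
  cat("Boolean network '", x$name, "': ", length(x$state_nodes),
      " state nodes\n", sep = "")
  if (length(x$inputs))
    cat("  inputs:     ", paste(x$inputs, collapse = ", "), "\n", sep = "")
  if (length(x$constants))
    cat("  constants:  ", paste0(names(x$constants), "=", x$constants,
                                 collapse = ", "), "\n", sep = "")
  cat("  state order:", paste(x$state_nodes, collapse = " "),
      " (first = most significant bit)\n")
  if (length(x$observables))
    cat("  observables:", paste(x$observables, collapse = ", "), "\n")
  for (nd in x$state_nodes)
    cat("  ", nd, "' = ", format(x$updates[[nd]]), "\n", sep = "")
  invisible(x)
}

#' Parse a network definition document
#'
#' One declaration per line: `input <name>`, `const <name> = 0|1`,
#' `node <name> = <expr>`, `output <name>` (marks an observable) and an
#' optional `order <name> ...` line fixing the state bit order (default:
#' node declaration order).  `#` starts a comment.  Expressions follow the
#' grammar of [parse_bool_expr()].  Errors are reported with the line
#' number at fault.
#'
#' @param text character vector of lines, or a single string with newlines.
#' @param name network name (defaults to "network").
#' @return A validated [boolean_network()] object.
#' @seealso [read_network()] to parse from a file, [write_network()]
#' @export
parse_network <- function(text, name = "network") {
  if (length(text) == 1L && grepl("\n", text))
    text <- strsplit(text, "\n", fixed = TRUE)[[1L]]
  inputs <- character(0); consts <- integer(0); outputs <- character(0)
  nodes <- character(0); updates <- list(); order <- NULL
  fail <- function(i, msg) stop("line ", i, ": ", msg, call. = FALSE)
  for (i in seq_along(text)) {
    line <- sub("#.*$", "", text[[i]])
    line <- trimws(line)
    if (!nzchar(line)) next
    if (grepl("^input\\s+", line)) {
      nm <- trimws(sub("^input\\s+", "", line))
      if (!grepl("^[A-Za-z_][A-Za-z0-9_.]*$", nm)) fail(i, "bad input name")
      inputs <- c(inputs, nm)
    } else if (grepl("^const\\s+", line)) {
      m <- regmatches(line, regexec(
        "^const\\s+([A-Za-z_][A-Za-z0-9_.]*)\\s*=\\s*([01])\\s*$", line))[[1L]]
      if (length(m) != 3L) fail(i, "bad const declaration (expected 'const NAME = 0|1')")
      consts[[m[[2L]]]] <- as.integer(m[[3L]])
    } else if (grepl("^node\\s+", line)) {
      m <- regmatches(line, regexec(
        "^node\\s+([A-Za-z_][A-Za-z0-9_.]*)\\s*=\\s*(.+)$", line))[[1L]]
      if (length(m) != 3L) fail(i, "bad node declaration (expected 'node NAME = expr')")
      nm <- m[[2L]]
      if (nm %in% nodes) fail(i, paste0("duplicate node '", nm, "'"))
      e <- tryCatch(parse_bool_expr(m[[3L]]),
                    error = function(c) fail(i, conditionMessage(c)))
      nodes <- c(nodes, nm)
      updates[[nm]] <- e
    } else if (grepl("^output\\s+", line)) {
      outputs <- c(outputs, trimws(sub("^output\\s+", "", line)))
    } else if (grepl("^order\\s+", line)) {
      order <- strsplit(trimws(sub("^order\\s+", "", line)), "\\s+")[[1L]]
    } else fail(i, paste0("unrecognized declaration: '", line, "'"))
  }
  if (!is.null(order)) {
    if (!setequal(order, nodes) || length(order) != length(nodes))
      stop("'order' line must list every node exactly once", call. = FALSE)
    nodes <- order
  }
  net <- structure(
    list(name = name, inputs = inputs, state_nodes = nodes,
         constants = consts, observables = outputs,
         updates = updates[nodes[nodes %in% names(updates)]]),
    class = "bn")
  validate_bn(net)
}

#' @rdname parse_network
#' @param path path to a network definition file.
#' @export
read_network <- function(path, name = sub("\\.[^.]*$", "", basename(path))) {
  parse_network(readLines(path, warn = FALSE), name = name)
}

#' Write a network definition document
#'
#' Inverse of [parse_network()]: the written document re-parses to a
#' network with the same node order and logically equivalent updates.
#'
#' @param net a `bn` object.
#' @param path file path, or `NULL` to return the lines invisibly printed.
#' @return The character vector of lines, invisibly when written to a file.
#' @export
write_network <- function(net, path = NULL) {
  stopifnot(inherits(net, "bn"))
  lines <- c(
    paste0("# Boolean network: ", net$name),
    paste("input", net$inputs),
    if (length(net$constants))
      paste("const", names(net$constants), "=", net$constants),
    paste("order", paste(net$state_nodes, collapse = " ")),
    vapply(net$state_nodes, function(nd)
      paste0("node ", nd, " = ", format(net$updates[[nd]])), ""),
    paste("output", net$observables)
  )
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}

#' Encode / decode network states
#'
#' States are interchangeably a named 0/1 assignment over the state nodes
#' and its decimal code, with the first declared state node as the most
#' significant bit (so `c(1,1,1,1,0,0)` on six nodes encodes to 60).
#'
#' @param net a `bn` object.
#' @param bits named (or positional, in state order) 0/1 vector.
#' @param decimal integer in `[0, 2^n - 1]`.
#' @return `encode_state()` an integer; `decode_state()` a named 0/1 vector.
#' @export
encode_state <- function(net, bits) {
  stopifnot(inherits(net, "bn"))
  n <- length(net$state_nodes)
  if (!is.null(names(bits))) {
    missing <- setdiff(net$state_nodes, names(bits))
    if (length(missing))
      stop("incomplete state assignment; missing '", missing[1L], "'",
           call. = FALSE)
    bits <- bits[net$state_nodes]
  } else if (length(bits) != n) {
    stop("positional state must have length ", n, call. = FALSE)
  }
  bits <- as.integer(bits)
  if (!all(bits %in% c(0L, 1L)))
    stop("state bits must be 0 or 1", call. = FALSE)
  as.integer(sum(bits * 2^((n - 1L):0)))
}

#' @rdname encode_state
#' @export
decode_state <- function(net, decimal) {
  stopifnot(inherits(net, "bn"), length(decimal) == 1L)
  n <- length(net$state_nodes)
  decimal <- as.integer(decimal)
  if (is.na(decimal) || decimal < 0L || decimal > 2^n - 1L)
    stop("state decimal out of range [0, ", 2^n - 1L, "]: ", decimal,
         call. = FALSE)
  bits <- as.integer(bitwAnd(bitwShiftR(decimal, (n - 1L):0), 1L))
  names(bits) <- net$state_nodes
  bits
}

# Decode many decimals at once into a (length(decimals) x n) 0/1 matrix.
decode_states <- function(net, decimals) {
  n <- length(net$state_nodes)
  m <- outer(as.integer(decimals), (n - 1L):0,
             function(d, k) bitwAnd(bitwShiftR(d, k), 1L))
  colnames(m) <- net$state_nodes
  m
}

check_inputs <- function(net, inputs) {
  inputs <- unlist(inputs)
  missing <- setdiff(net$inputs, names(inputs))
  if (length(missing))
    stop("incomplete input assignment; missing '", missing[1L], "'",
         call. = FALSE)
  storage.mode(inputs) <- "integer"
  inputs[net$inputs]
}

#' Advance a network one synchronous step
#'
#' Every state node is simultaneously set to its update expression
#' evaluated on the previous state, the supplied inputs, and the constants.
#'
#' @param net a `bn` object.
#' @param state a decimal state code or a named 0/1 assignment.
#' @param inputs named 0/1 vector covering every input node (may be empty
#'   for input-free networks).
#' @return The successor state, in the same representation as `state`
#'   (decimal in, decimal out).
#' @examples
#' net <- fixture_oxidative_stress()
#' step_network(net, 44, c(Stress = 1))  # 45
#' @export
step_network <- function(net, state, inputs = integer(0)) {
  stopifnot(inherits(net, "bn"))
  as_decimal <- length(state) == 1L && is.null(names(state))
  bits <- if (as_decimal) decode_state(net, state) else {
    # normalize through encode/decode so validation applies
    decode_state(net, encode_state(net, state))
  }
  inputs <- check_inputs(net, inputs)
  env <- c(as.list(bits), as.list(inputs), as.list(net$constants))
  nxt <- vapply(net$state_nodes, function(nd)
    eval_bool_expr(net$updates[[nd]], env), integer(1))
  if (as_decimal) encode_state(net, nxt) else nxt
}

#' Simulate a network over an input sequence
#'
#' Deterministic synchronous simulation: the trace has one more state than
#' there are input vectors, `trace[k+1] = step(trace[k], inputs[k])`.
#'
#' @param net a `bn` object.
#' @param initial initial state (decimal or named assignment).
#' @param input_sequence one of: a list of named input assignments; a
#'   numeric vector (single-input networks, one value per step); or a
#'   matrix with one column per input node and one row per step.  Length 0
#'   gives the trivial trace containing only `initial`.
#' @return A data frame of class `bn_trace` with columns `time`, one 0/1
#'   column per state node, and `decimal`.
#' @examples
#' net <- fixture_oxidative_stress()
#' tr <- simulate_network(net, 18, rep(1, 7))  # traverses the stress cycle
#' tr$decimal
#' @export
simulate_network <- function(net, initial, input_sequence = list()) {
  stopifnot(inherits(net, "bn"))
  seq_list <- normalize_input_sequence(net, input_sequence)
  d <- if (length(initial) == 1L && is.null(names(initial)))
    as.integer(initial) else encode_state(net, initial)
  decode_state(net, d)  # range check
  decs <- integer(length(seq_list) + 1L)
  decs[[1L]] <- d
  for (k in seq_along(seq_list))
    decs[[k + 1L]] <- step_network(net, decs[[k]], seq_list[[k]])
  bits <- decode_states(net, decs)
  out <- data.frame(time = seq_along(decs) - 1L, bits, decimal = decs,
                    check.names = FALSE)
  class(out) <- c("bn_trace", "data.frame")
  attr(out, "network") <- net$name
  out
}

normalize_input_sequence <- function(net, input_sequence) {
  p <- length(net$inputs)
  if (is.matrix(input_sequence)) {
    stopifnot(ncol(input_sequence) == p)
    if (is.null(colnames(input_sequence))) colnames(input_sequence) <- net$inputs
    return(lapply(seq_len(nrow(input_sequence)),
                  function(i) input_sequence[i, , drop = TRUE]))
  }
  if (is.numeric(input_sequence)) {
    if (p != 1L && length(input_sequence) > 0L)
      stop("a bare numeric input sequence needs a single-input network",
           call. = FALSE)
    return(lapply(input_sequence, function(v) stats::setNames(v, net$inputs)))
  }
  stopifnot(is.list(input_sequence))
  input_sequence
}

#' @export
print.bn_trace <- function(x, ...) {
  cat("Synchronous trace (", nrow(x), " states) of '",
      attr(x, "network") %||% "?", "'\n", sep = "")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Write a trace as tab-separated values
#' @param trace a `bn_trace`.
#' @param path output path or `""` for stdout.
#' @export
write_trace_tsv <- function(trace, path = "") {
  utils::write.table(trace, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(trace)
}
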