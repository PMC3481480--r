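#' Build the complete state transition graph under fixed inputs
#'
#' For a constant input assignment the synchronous dynamics form a
#' functional graph on the `2^n` states (out-degree exactly one).  The
#' successor of every state is computed in one vectorized pass over the
#' update expressions.
#'
#' @param net a `bn` object.
#' @param fixed_inputs named 0/1 vector covering every input node.
#' @param max_nodes refuse networks with more state nodes than this
#'   (default 20, i.e. about a million states).
#' @return An object of class `bn_stg` with fields `net`, `fixed_inputs`
#'   and `successor`: an integer vector where `successor[s + 1]` is the
#'   decimal successor of state `s`.
#' @examples
#' g <- build_stg(fixture_oxidative_stress(), c(Stress = 0))
#' g$successor[18 + 1]  # 18: the resting state is fixed
#' @export
build_stg <- function(net, fixed_inputs = integer(0), max_nodes = 20L) {
  stopifnot(inherits(net, "bn"))
  n <- length(net$state_nodes)
  if (n > max_nodes)
    stop("network has ", n, " state nodes; exhaustive transition graphs are ",
         "capped at ", max_nodes, call. = FALSE)
  fixed_inputs <- check_inputs(net, fixed_inputs)
  N <- 2^n
  bits <- decode_states(net, 0:(N - 1L))
  env <- c(lapply(seq_len(n), function(j) bits[, j]),
           lapply(as.list(fixed_inputs), rep, N),
           lapply(as.list(net$constants), rep, N))
  names(env) <- c(net$state_nodes, names(fixed_inputs), names(net$constants))
  nxt <- vapply(net$state_nodes, function(nd) {
    v <- eval_bool_expr(net$updates[[nd]], env)
    if (length(v) == 1L) rep(v, N) else v
  }, integer(N))
  if (N == 1L) nxt <- matrix(nxt, nrow = 1L)
  succ <- as.integer(nxt %*% 2^((n - 1L):0))
  structure(list(net = net, fixed_inputs = fixed_inputs, successor = succ),
            class = "bn_stg")
}

#' @export
print.bn_stg <- function(x, ...) {
  cat("State transition graph of '", x$net$name, "': ",
      length(x$successor), " states", sep = "")
  if (length(x$fixed_inputs))
    cat(" under ", paste0(names(x$fixed_inputs), "=", x$fixed_inputs,
                          collapse = ", "), sep = "")
  cat("\n")
  invisible(x)
}

#' Enumerate attractors, basins and transients of a transition graph
#'
#' Follows successor pointers with visited-marking (linear in the number
#' of states).  Every state of a functional graph eventually enters
#' exactly one cycle; cycles are the attractors (length-1 cycles are
#' singleton attractors / fixed points).  Each cycle is reported in
#' traversal order starting from its smallest decimal.
#'
#' @param graph a `bn_stg`.
#' @return An object of class `bn_attractors`: `cycles` (list of integer
#'   vectors in canonical rotation), `basin_sizes` (integer vector summing
#'   to `2^n`), `transient_depth` (max steps from any state to its
#'   attractor), plus per-state vectors `attractor_of` and
#'   `steps_to_attractor` (indexed by decimal + 1).
#' @examples
#' g <- build_stg(fixture_oxidative_stress(), c(Stress = 1))
#' a <- find_attractors(g)
#' a$cycles[[1]]  # the 7-state stress cycle
#' @export
find_attractors <- function(graph) {
  stopifnot(inherits(graph, "bn_stg"))
  succ <- graph$successor
  N <- length(succ)
  attractor_of <- rep(NA_integer_, N)
  steps <- rep(NA_integer_, N)
  on_cycle <- rep(FALSE, N)
  cycles <- list()
  color <- integer(N)  # 0 new, 1 on current path, 2 finished
  for (s0 in 0:(N - 1L)) {
    if (color[s0 + 1L] != 0L) next
    path <- integer(0)
    s <- s0
    while (color[s + 1L] == 0L) {
      color[s + 1L] <- 1L
      path[length(path) + 1L] <- s
      s <- succ[s + 1L]
    }
    if (color[s + 1L] == 1L) {
      # new cycle discovered: it starts where the path first met s
      start <- match(s, path)
      cyc <- path[start:length(path)]
      id <- length(cycles) + 1L
      rot <- which.min(cyc)
      cycles[[id]] <- c(cyc[rot:length(cyc)], cyc[seq_len(rot - 1L)])
      attractor_of[cyc + 1L] <- id
      steps[cyc + 1L] <- 0L
      on_cycle[cyc + 1L] <- TRUE
    }
    # propagate attractor id and distances back along the tail
    for (i in rev(seq_along(path))) {
      p <- path[[i]]
      color[p + 1L] <- 2L
      if (is.na(attractor_of[p + 1L])) {
        nx <- succ[p + 1L]
        attractor_of[p + 1L] <- attractor_of[nx + 1L]
        steps[p + 1L] <- if (on_cycle[p + 1L]) 0L else steps[nx + 1L] + 1L
      }
    }
  }
  basin <- as.integer(tabulate(attractor_of, nbins = length(cycles)))
  structure(list(cycles = cycles, basin_sizes = basin,
                 transient_depth = max(steps),
                 attractor_of = attractor_of,
                 steps_to_attractor = steps,
                 n_states = N, net = graph$net,
                 fixed_inputs = graph$fixed_inputs),
            class = "bn_attractors")
}

#' @export
print.bn_attractors <- function(x, ...) {
  cat(length(x$cycles), " attractor(s) over ", x$n_states, " states",
      sep = "")
  if (length(x$fixed_inputs))
    cat(" (", paste0(names(x$fixed_inputs), "=", x$fixed_inputs,
                     collapse = ", "), ")", sep = "")
  cat("; max transient ", x$transient_depth, " step(s)\n", sep = "")
  for (i in seq_along(x$cycles)) {
    cyc <- x$cycles[[i]]
    lab <- vapply(cyc, function(d)
      state_label(x$net, d), "")
    kind <- if (length(cyc) == 1L) "fixed point" else
      paste0("cycle of length ", length(cyc))
    cat("  [", i, "] ", kind, ", basin ", x$basin_sizes[[i]], ": ",
        paste(lab, collapse = " -> "), "\n", sep = "")
  }
  invisible(x)
}

#' Label a state as `decimal(binary)`
#' @param net a `bn` object.
#' @param decimal state decimal code.
#' @return A string such as `"18(010010)"`.
#' @export
state_label <- function(net, decimal) {
  paste0(decimal, "(", paste(decode_state(net, decimal), collapse = ""), ")")
}

#' Maximum transient length of a transition graph
#'
#' The largest number of steps any state needs before first entering an
#' attractor state.
#'
#' @param graph a `bn_stg`.
#' @return A non-negative integer.
#' @export
transient_depth <- function(graph) {
  find_attractors(graph)$transient_depth
}

#' Rotate a cycle to start at a given state
#'
#' Attractor cycles are stored starting at their smallest decimal; display
#' sometimes wants a different anchor (e.g. the resting state).
#'
#' @param cycle integer vector of states forming a cycle.
#' @param start state to rotate to the front (must be on the cycle).
#' @return The rotated cycle.
#' @export
rotate_cycle <- function(cycle, start) {
  i <- match(start, cycle)
  if (is.na(i)) stop("state ", start, " is not on the cycle", call. = FALSE)
  c(cycle[i:length(cycle)], cycle[seq_len(i - 1L)])
}

#' Export a transition graph as a DOT (Graphviz) document
#'
#' One node per state labeled `decimal(binary)`, one edge per transition;
#' attractor states are drawn filled.
#'
#' @param graph a `bn_stg`.
#' @param highlight integer vector of states to style distinctly; default:
#'   all attractor states of the graph.
#' @param path optional output file.
#' @return Character vector of DOT lines (invisibly when written to file).
#' @export
export_dot <- function(graph, highlight = NULL, path = NULL) {
  stopifnot(inherits(graph, "bn_stg"))
  if (is.null(highlight)) {
    att <- find_attractors(graph)
    highlight <- unlist(att$cycles)
  }
  N <- length(graph$successor)
  labs <- vapply(0:(N - 1L), function(d) state_label(graph$net, d), "")
  nodes <- vapply(0:(N - 1L), function(d) {
    style <- if (d %in% highlight)
      " [style=filled, fillcolor=lightblue, penwidth=2]" else ""
    paste0("  \"", labs[d + 1L], "\"", style, ";")
  }, "")
  edges <- vapply(0:(N - 1L), function(d)
    paste0("  \"", labs[d + 1L], "\" -> \"",
           labs[graph$successor[d + 1L] + 1L], "\";"), "")
  out <- c(paste0("digraph \"", graph$net$name, "\" {"),
           "  rankdir=LR;", nodes, edges, "}")
  if (!is.null(path)) { writeLines(out, path); return(invisible(out)) }
  out
}

#' Export a transition graph as tab-separated values
#'
#' Columns: `state`, `successor`, `attractor_id`, `transient_length`.
#'
#' @param graph a `bn_stg`.
#' @param path output path or `""` for stdout.
#' @return The exported data frame, invisibly.
#' @export
export_stg_tsv <- function(graph, path = "") {
  att <- find_attractors(graph)
  df <- data.frame(state = 0:(length(graph$successor) - 1L),
                   successor = graph$successor,
                   attractor_id = att$attractor_of,
                   transient_length = att$steps_to_attractor)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
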