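#' Sequential machine view of a Boolean network
#'
#' For fault diagnosis a network is read as a synchronous sequential
#' circuit: the state nodes are the memory elements (secondary
#' inputs/outputs), the network inputs are the primary inputs, and the
#' observable nodes are the primary outputs.  The response `R(q, T)` of
#' the machine started in state `q` to an input sequence `T` is the
#' sequence of observable projections of the states reached after each
#' applied vector.
#'
#' @param net a `bn` object.
#' @param observables primary outputs; default the network's own
#'   observables (must be non-empty).
#' @return An object of class `bn_machine`.
#' @export
sequential_machine <- function(net, observables = net$observables) {
  stopifnot(inherits(net, "bn"))
  observables <- as.character(observables)
  bad <- setdiff(observables, net$state_nodes)
  if (length(bad))
    stop("observable '", bad[1L], "' is not a state node", call. = FALSE)
  if (length(observables) == 0L)
    stop("a sequential machine needs at least one observable output",
         call. = FALSE)
  structure(list(net = net, observables = observables,
                 primary_inputs = net$inputs),
            class = "bn_machine")
}

#' @export
print.bn_machine <- function(x, ...) {
  cat("Sequential machine on '", x$net$name, "': ",
      length(x$net$state_nodes), " memory elements, primary inputs (",
      paste(x$primary_inputs, collapse = ", "), "), primary outputs (",
      paste(x$observables, collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Enumerate the single stuck-at fault universe of a network
#'
#' Each gene (state) node can be permanently locked OFF (stuck-at-0) or ON
#' (stuck-at-1), modeling a mutation that fixes the gene's activity; with
#' `g` gene nodes there are `2g` single faults.  Inputs and constants are
#' not fault sites.
#'
#' @param net a `bn` object.
#' @return A data frame of class `bn_faults` with columns `node` and
#'   `stuck_value`, in declaration order, stuck-at-0 before stuck-at-1.
#' @examples
#' enumerate_faults(fixture_oxidative_stress())  # 12 faults
#' @export
enumerate_faults <- function(net) {
  stopifnot(inherits(net, "bn"))
  nodes <- net$state_nodes
  df <- data.frame(node = rep(nodes, each = 2L),
                   stuck_value = rep(c(0L, 1L), length(nodes)),
                   stringsAsFactors = FALSE)
  class(df) <- c("bn_faults", "data.frame")
  df
}

#' Inject stuck-at faults into a network
#'
#' Returns a copy of the network in which each faulty node's update
#' expression is replaced by the constant stuck value: from the first
#' update step onward the node holds that value and every reader sees it.
#' The initial state remains arbitrary (the fault acts on updates, not on
#' the starting state).  The original network is not modified.
#'
#' @param net a `bn` object.
#' @param node character vector of state node names (several nodes inject
#'   a multiple fault).
#' @param stuck_value 0/1 vector, recycled along `node`.
#' @return The faulty `bn`.
#' @examples
#' bad <- inject_fault(fixture_oxidative_stress(), "ARE", 1)
#' format(bad$updates$ARE)
#' @export
inject_fault <- function(net, node, stuck_value) {
  stopifnot(inherits(net, "bn"))
  node <- as.character(node)
  stuck_value <- as.integer(rep(stuck_value, length.out = length(node)))
  for (i in seq_along(node)) {
    nd <- node[[i]]
    if (!(nd %in% net$state_nodes))
      stop("fault site '", nd, "' is not a gene (state) node; inputs and ",
           "constants cannot be fault sites", call. = FALSE)
    if (!(stuck_value[[i]] %in% c(0L, 1L)))
      stop("stuck value must be 0 or 1", call. = FALSE)
    net$updates[[nd]] <- bx_const(stuck_value[[i]])
  }
  net$name <- paste0(net$name, " + ",
                     paste0(node, " s-a-", stuck_value, collapse = ", "))
  net
}

# Successor lookup tables, one integer vector per distinct primary-input
# assignment: maps[[key]][s + 1] = successor decimal of s.
input_key <- function(inputs) paste(inputs, collapse = "")

successor_maps <- function(machine, input_vectors) {
  keys <- vapply(input_vectors, input_key, "")
  maps <- list()
  for (i in seq_along(input_vectors)) {
    k <- keys[[i]]
    if (is.null(maps[[k]]))
      maps[[k]] <- build_stg(machine$net, input_vectors[[i]])$successor
  }
  list(maps = maps, keys = keys)
}

obs_signature_matrix <- function(machine, input_vectors, maps = NULL) {
  # rows = initial states, one column per step: observable bits packed
  # into a small integer
  net <- machine$net
  n <- length(net$state_nodes)
  N <- 2^n
  if (is.null(maps)) maps <- successor_maps(machine, input_vectors)
  obs_pos <- match(machine$observables, net$state_nodes)
  obs_weight <- 2^(n - obs_pos)  # bit weights of the observables
  out <- matrix(0L, nrow = N, ncol = length(input_vectors))
  cur <- 0:(N - 1L)
  for (t in seq_along(input_vectors)) {
    cur <- maps$maps[[maps$keys[[t]]]][cur + 1L]
    # pack observable bits of every state
    packed <- integer(N)
    for (j in seq_along(obs_pos))
      packed <- packed * 2L + bitwAnd(cur %/% obs_weight[[j]], 1L)
    out[, t] <- packed
  }
  out
}

normalize_test_inputs <- function(machine, T) {
  normalize_input_sequence(machine$net, T)
}

#' Does a test sequence detect a fault?
#'
#' Implements the strict all-pairs criterion: a test sequence `T` detects
#' a fault iff for *every* pair of initial states `(q, q_f)` of the normal
#' and faulty machines, the observable output sequences `R(q, T)` and
#' `R_f(q_f, T)` differ at some position.  Nothing is assumed about either
#' machine's starting state.
#'
#' @param normal,faulty `bn_machine` objects sharing primary inputs and
#'   outputs.
#' @param T input sequence (list of named assignments, numeric vector for
#'   single-input machines, or matrix); may be empty, in which case no
#'   fault is detected.
#' @return `TRUE` or `FALSE`; when `FALSE` and `T` is non-empty, the
#'   attribute `"witness"` holds an undistinguished pair `c(q, q_f)` of
#'   state decimals.
#' @examples
#' net <- fixture_oxidative_stress()
#' m <- sequential_machine(net)
#' mf <- sequential_machine(inject_fault(net, "ARE", 0), net$observables)
#' is_detected(m, mf, rep(c(0, 1), c(4, 8)))
#' @export
is_detected <- function(normal, faulty, T) {
  stopifnot(inherits(normal, "bn_machine"), inherits(faulty, "bn_machine"))
  if (!identical(normal$primary_inputs, faulty$primary_inputs) ||
      !identical(normal$observables, faulty$observables))
    stop("machines must share primary inputs and outputs", call. = FALSE)
  T <- normalize_test_inputs(normal, T)
  if (length(T) == 0L) return(FALSE)
  Rn <- obs_signature_matrix(normal, T)
  Rf <- obs_signature_matrix(faulty, T)
  rows_n <- apply(Rn, 1L, paste, collapse = ",")
  rows_f <- apply(Rf, 1L, paste, collapse = ",")
  common <- intersect(rows_n, rows_f)
  if (length(common) == 0L) return(TRUE)
  q <- which(rows_n == common[[1L]])[1L] - 1L
  qf <- which(rows_f == common[[1L]])[1L] - 1L
  structure(FALSE, witness = c(q = q, q_f = qf))
}

# all primary-input assignments, in increasing binary order (MSB = first
# declared input)
input_alphabet <- function(machine) {
  p <- length(machine$primary_inputs)
  if (p == 0L) return(list(stats::setNames(integer(0), character(0))))
  lapply(0:(2^p - 1L), function(d) {
    stats::setNames(bitwAnd(bitwShiftR(d, (p - 1L):0), 1L),
                    machine$primary_inputs)
  })
}

#' Find a shortest homing (synchronizing) sequence
#'
#' A homing sequence drives the fault-free machine into one single known
#' state regardless of its initial state, so later test responses can be
#' interpreted.  Breadth-first search over images of the initial
#' uncertainty set under the input alphabet returns a shortest such
#' sequence, or `NULL` when none exists within `max_len` steps.
#'
#' @param machine a `bn_machine`.
#' @param max_len search cap on sequence length.
#' @param initial_set integer vector of possible start states (default:
#'   all of them).
#' @return `NULL` on failure, otherwise a list with `sequence` (list of
#'   input assignments, possibly empty), `final_state` (decimal), and
#'   `length`.
#' @examples
#' h <- find_homing_sequence(sequential_machine(fixture_oxidative_stress()))
#' h$final_state  # 18: the resting state
#' @export
find_homing_sequence <- function(machine, max_len = 64L,
                                 initial_set = NULL) {
  stopifnot(inherits(machine, "bn_machine"), max_len >= 1L)
  n <- length(machine$net$state_nodes)
  if (is.null(initial_set)) initial_set <- 0:(2^n - 1L)
  initial_set <- sort(unique(as.integer(initial_set)))
  if (length(initial_set) == 1L)
    return(list(sequence = list(), final_state = initial_set, length = 0L))
  alphabet <- input_alphabet(machine)
  maps <- lapply(alphabet, function(a) build_stg(machine$net, a)$successor)
  key <- function(set) paste(set, collapse = ",")
  frontier <- list(list(set = initial_set, seq = integer(0)))
  visited <- key(initial_set)
  for (depth in seq_len(max_len)) {
    nxt <- list()
    for (node in frontier) {
      for (ai in seq_along(alphabet)) {
        img <- sort(unique(maps[[ai]][node$set + 1L]))
        if (length(img) == 1L) {
          idx <- c(node$seq, ai)
          return(list(sequence = alphabet[idx],
                      final_state = img, length = length(idx)))
        }
        k <- key(img)
        if (!(k %in% visited)) {
          visited <- c(visited, k)
          nxt[[length(nxt) + 1L]] <- list(set = img, seq = c(node$seq, ai))
        }
      }
    }
    if (length(nxt) == 0L) return(NULL)  # search space exhausted
    frontier <- nxt
  }
  NULL
}

#' Image of a state set under an input sequence
#'
#' Applies the inputs to every state in `states` and returns the set of
#' final states; a sequence is homing exactly when the image of the full
#' state set is a singleton.
#'
#' @param machine a `bn_machine`.
#' @param T input sequence (as in [is_detected()]).
#' @param states integer vector of start states (default all).
#' @return Sorted integer vector of reachable final states.
#' @export
homing_image <- function(machine, T, states = NULL) {
  stopifnot(inherits(machine, "bn_machine"))
  n <- length(machine$net$state_nodes)
  if (is.null(states)) states <- 0:(2^n - 1L)
  T <- normalize_test_inputs(machine, T)
  maps <- successor_maps(machine, T)
  cur <- sort(unique(as.integer(states)))
  for (t in seq_along(T)) cur <- sort(unique(maps$maps[[maps$keys[[t]]]][cur + 1L]))
  cur
}

#' Generate a shortest detecting test sequence for a fault
#'
#' Searches primary-input sequences in order of increasing length, exactly
#' realizing, at this scale, the time-frame expansion idea of unrolling
#' the circuit until the fault effect reaches a primary output.  The
#' search state is the set of still-unresolved initial-state pairs
#' `(q, q_f)` whose outputs have agreed so far; applying an input vector
#' maps each pair forward and discards pairs whose outputs now differ.
#' A sequence detects the fault exactly when the set empties, so
#' breadth-first search for the empty set returns a shortest detecting
#' sequence under the all-pairs criterion of [is_detected()].
#'
#' @param normal,faulty `bn_machine` objects sharing primary inputs and
#'   outputs.
#' @param max_frames cap on the number of unrolled time frames (sequence
#'   length), default 16.
#' @return A list of class `bn_test` with `vectors` (list of input
#'   assignments) and `length`; or, when no sequence within the cap
#'   detects the fault, a `bn_undetectable` object (see
#'   [is_undetectable()]) whose `proven` field is `TRUE` when the
#'   reachable search space was exhausted, i.e. the fault is undetectable
#'   at any length.
#' @export
generate_test <- function(normal, faulty, max_frames = 16L) {
  stopifnot(inherits(normal, "bn_machine"), inherits(faulty, "bn_machine"),
            max_frames >= 1L)
  if (!identical(normal$primary_inputs, faulty$primary_inputs) ||
      !identical(normal$observables, faulty$observables))
    stop("machines must share primary inputs and outputs", call. = FALSE)
  net <- normal$net
  n <- length(net$state_nodes)
  if (n > 10L)
    stop("exhaustive pair-set test search is capped at 10 state nodes",
         call. = FALSE)
  N <- 2^n
  alphabet <- input_alphabet(normal)
  maps_n <- lapply(alphabet, function(a) build_stg(net, a)$successor)
  maps_f <- lapply(alphabet, function(a) build_stg(faulty$net, a)$successor)
  obs_pos <- match(normal$observables, net$state_nodes)
  obs_weight <- 2^(n - obs_pos)
  pack_obs <- function(states) {
    packed <- integer(length(states))
    for (j in seq_along(obs_pos))
      packed <- packed * 2L + bitwAnd(states %/% obs_weight[[j]], 1L)
    packed
  }
  # pairs packed as q * N + qf
  pairs0 <- as.integer(outer(0:(N - 1L) * N, 0:(N - 1L), `+`))
  advance <- function(pairs, ai) {
    q <- pairs %/% N
    qf <- pairs %% N
    q2 <- maps_n[[ai]][q + 1L]
    qf2 <- maps_f[[ai]][qf + 1L]
    alive <- pack_obs(q2) == pack_obs(qf2)
    sort(unique(q2[alive] * N + qf2[alive]))
  }
  key <- function(pairs) paste(pairs, collapse = ",")
  frontier <- list(list(pairs = pairs0, seq = integer(0)))
  visited <- key(pairs0)
  for (depth in seq_len(max_frames)) {
    nxt <- list()
    for (node in frontier) {
      for (ai in seq_along(alphabet)) {
        p2 <- advance(node$pairs, ai)
        if (length(p2) == 0L) {
          idx <- c(node$seq, ai)
          return(structure(list(vectors = alphabet[idx],
                                length = length(idx),
                                primary_inputs = normal$primary_inputs),
                           class = "bn_test"))
        }
        k <- key(p2)
        if (!(k %in% visited)) {
          visited <- c(visited, k)
          nxt[[length(nxt) + 1L]] <- list(pairs = p2, seq = c(node$seq, ai))
        }
      }
    }
    if (length(nxt) == 0L)  # search space closed: undetectable outright
      return(structure(list(proven = TRUE), class = "bn_undetectable"))
    frontier <- nxt
  }
  structure(list(proven = FALSE), class = "bn_undetectable")
}

#' Is a test-generation result "undetectable"?
#'
#' @param x a result of [generate_test()].
#' @return `TRUE` for a `bn_undetectable` sentinel, `FALSE` for a test
#'   sequence.
#' @export
is_undetectable <- function(x) inherits(x, "bn_undetectable")

#' @export
print.bn_undetectable <- function(x, ...) {
  cat("undetectable",
      if (x$proven) "(search space exhausted: no sequence of any length works)"
      else "(within the frame cap)", "\n")
  invisible(x)
}

#' @export
print.bn_test <- function(x, ...) {
  cat("Test sequence of length ", x$length, ": ",
      test_bit_string(x), "\n", sep = "")
  invisible(x)
}

test_bit_string <- function(test) {
  if (is.null(test)) return(NA_character_)
  vapply(test$vectors, function(v) paste(v, collapse = ""), "") |>
    paste(collapse = if (length(test$primary_inputs) > 1L) ";" else "")
}

#' Build a single-fault diagnosis table
#'
#' For every fault in the universe of [enumerate_faults()], generates a
#' shortest detecting sequence ([generate_test()]), records its output
#' signature, and groups faults whose signatures under their sequences are
#' identical into ambiguity classes.  The `truncations` attribute notes,
#' per distinct generated sequence, the shortest prefix that still detects
#' each fault it covers (`NA` when the full sequence does not detect that
#' fault) -- truncated versions of one sequence can serve several faults.
#'
#' The signature of a detected fault is the sorted set of positions at
#' which, over all initial-state pairs, the first output difference
#' between the normal and faulty machine can appear.
#'
#' @param net a `bn` object.
#' @param observables primary outputs (default the network's).
#' @param max_frames search cap per fault.
#' @param homing when `TRUE`, a homing sequence for the normal machine is
#'   searched once and recorded in the `homing` attribute (it is not part
#'   of the detection criterion, which quantifies over all state pairs).
#' @return A data frame of class `bn_diagnosis` with columns `fault_node`,
#'   `stuck_value`, `detected`, `undetectable_proven`,
#'   `detecting_sequence` (bit string over the primary inputs),
#'   `detect_length`, `signature`, `ambiguity_class_id`.
#' @examples
#' \donttest{
#' tab <- build_diagnosis_table(fixture_oxidative_stress())
#' tab[, c("fault_node", "stuck_value", "detecting_sequence")]
#' }
#' @export
build_diagnosis_table <- function(net, observables = net$observables,
                                  max_frames = 16L, homing = TRUE) {
  stopifnot(inherits(net, "bn"))
  normal <- sequential_machine(net, observables)
  faults <- enumerate_faults(net)
  rows <- vector("list", nrow(faults))
  tests <- vector("list", nrow(faults))
  for (i in seq_len(nrow(faults))) {
    fnet <- inject_fault(net, faults$node[[i]], faults$stuck_value[[i]])
    faulty <- sequential_machine(fnet, observables)
    test <- generate_test(normal, faulty, max_frames = max_frames)
    tests[[i]] <- test
    if (is_undetectable(test)) {
      rows[[i]] <- data.frame(
        fault_node = faults$node[[i]], stuck_value = faults$stuck_value[[i]],
        detected = FALSE,
        undetectable_proven = test$proven,
        detecting_sequence = NA_character_, detect_length = NA_integer_,
        signature = NA_character_, stringsAsFactors = FALSE)
    } else {
      sig <- fault_signature(normal, faulty, test$vectors)
      rows[[i]] <- data.frame(
        fault_node = faults$node[[i]], stuck_value = faults$stuck_value[[i]],
        detected = TRUE, undetectable_proven = FALSE,
        detecting_sequence = test_bit_string(test),
        detect_length = test$length,
        signature = sig, stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  sig_key <- ifelse(tab$detected,
                    paste(tab$detecting_sequence, tab$signature, sep = "@"),
                    paste0("undetected#", seq_len(nrow(tab))))
  tab$ambiguity_class_id <- as.integer(factor(sig_key, levels = unique(sig_key)))
  attr(tab, "truncations") <- truncation_table(net, observables, tab, max_frames)
  if (homing) attr(tab, "homing") <- find_homing_sequence(normal)
  class(tab) <- c("bn_diagnosis", "data.frame")
  tab
}

# first-difference positions over all state pairs, as "p1,p2,..."
fault_signature <- function(normal, faulty, T) {
  T <- normalize_test_inputs(normal, T)
  Rn <- obs_signature_matrix(normal, T)
  Rf <- obs_signature_matrix(faulty, T)
  m <- length(T)
  firsts <- integer(0)
  for (q in seq_len(nrow(Rn))) {
    diffs <- which(matrix(Rn[q, ], nrow = nrow(Rf), ncol = m,
                          byrow = TRUE) != Rf, arr.ind = TRUE)
    # earliest differing position per faulty start state
    if (nrow(diffs)) {
      fp <- tapply(diffs[, 2L], diffs[, 1L], min)
      firsts <- union(firsts, as.integer(fp))
    }
  }
  paste(sort(firsts), collapse = ",")
}

truncation_table <- function(net, observables, tab, max_frames) {
  normal <- sequential_machine(net, observables)
  seqs <- unique(tab$detecting_sequence[tab$detected])
  if (length(seqs) == 0L) return(NULL)
  out <- matrix(NA_integer_, nrow = length(seqs), ncol = nrow(tab),
                dimnames = list(seqs,
                                paste0(tab$fault_node, ".sa", tab$stuck_value)))
  p <- length(normal$primary_inputs)
  for (s in seqs) {
    vecs <- bit_string_to_inputs(s, normal$primary_inputs)
    for (i in seq_len(nrow(tab))) {
      faulty <- sequential_machine(
        inject_fault(net, tab$fault_node[[i]], tab$stuck_value[[i]]),
        observables)
      for (len in seq_along(vecs)) {
        if (isTRUE(is_detected(normal, faulty, vecs[seq_len(len)]))) {
          out[s, i] <- len
          break
        }
      }
    }
  }
  out
}

bit_string_to_inputs <- function(s, primary_inputs) {
  parts <- if (length(primary_inputs) > 1L)
    strsplit(s, ";", fixed = TRUE)[[1L]]
  else strsplit(s, "", fixed = TRUE)[[1L]]
  lapply(parts, function(p)
    stats::setNames(as.integer(strsplit(p, "")[[1L]]), primary_inputs))
}

#' @export
print.bn_diagnosis <- function(x, ...) {
  cat("Single stuck-at fault diagnosis table (", nrow(x), " faults, ",
      sum(x$detected), " detected)\n", sep = "")
  print.data.frame(x, row.names = FALSE)
  h <- attr(x, "homing")
  if (!is.null(h))
    cat("Homing sequence of length ", h$length, " -> state ",
        h$final_state, "\n", sep = "")
  invisible(x)
}

#' Write a diagnosis table as tab-separated values
#' @param tab a `bn_diagnosis` table.
#' @param path output path or `""` for stdout.
#' @export
write_diagnosis_tsv <- function(tab, path = "") {
  utils::write.table(as.data.frame(tab), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(tab)
}
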