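#' Timed pathway segments
#'
#' A pathway segment records one literature-derived regulation constraint:
#' if the predictor nodes hold the stated values, the target node takes the
#' stated value within `t` time steps.  A *negating* segment states that
#' the target follows the complement of a single predictor (covering both
#' predictor values at once).  Segments with `t = 1` are the raw material
#' the compiler turns into synchronous update functions.
#'
#' @param predictors character vector of predictor node names (1-3).
#' @param values 0/1 vector, positionally matched to `predictors`.
#' @param target target node name.
#' @param target_value 0 or 1.
#' @param time_bound positive integer number of steps.
#' @param negating logical; a negating segment has exactly one predictor
#'   and ignores `values`/`target_value`.
#' @return An object of class `bn_segment`.
#' @export
pathway_segment <- function(predictors, values = integer(0), target,
                            target_value = NA_integer_, time_bound = 1L,
                            negating = FALSE) {
  predictors <- as.character(predictors)
  if (negating) {
    if (length(predictors) != 1L)
      stop("a negating segment has exactly one predictor", call. = FALSE)
    values <- NA_integer_
    target_value <- NA_integer_
  } else {
    values <- as.integer(values)
    if (length(values) != length(predictors))
      stop("arity mismatch: ", length(predictors), " predictor(s) but ",
           length(values), " value(s)", call. = FALSE)
    if (!all(values %in% c(0L, 1L)) || !(as.integer(target_value) %in% c(0L, 1L)))
      stop("segment values must be 0 or 1", call. = FALSE)
  }
  if (length(predictors) < 1L || length(predictors) > 3L)
    stop("a segment has between 1 and 3 predictors", call. = FALSE)
  if (anyDuplicated(predictors))
    stop("duplicate predictor in segment: '",
         predictors[duplicated(predictors)][1L], "'", call. = FALSE)
  time_bound <- as.integer(time_bound)
  if (is.na(time_bound) || time_bound < 1L)
    stop("time bound must be a positive integer", call. = FALSE)
  structure(list(predictors = predictors, values = values,
                 target = as.character(target),
                 target_value = as.integer(target_value),
                 time_bound = time_bound, negating = isTRUE(negating)),
            class = "bn_segment")
}

#' @export
format.bn_segment <- function(x, ...) {
  if (x$negating)
    paste0(x$predictors, " ~> ", x$target, " @", x$time_bound)
  else
    paste0(paste(x$predictors, collapse = ","), " | ",
           paste(x$values, collapse = ","), " => ", x$target, "=",
           x$target_value, " @", x$time_bound)
}

#' @export
print.bn_segment <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

#' Parse a pathway-segment document
#'
#' One segment per line.  Plain form:
#' `P1[,P2[,P3]] | v1[,v2[,v3]] => T=v @t` (if predictors P hold values v,
#' target T takes value v within t steps).  Negating form: `P ~> T @t`
#' (T follows the complement of P).  `#` starts a comment.
#'
#' @param text character vector of lines or a single string with newlines.
#' @return List of [pathway_segment()] objects, class `bn_segments`.
#' @examples
#' parse_pathways("Nrf2,ROS | 1,0 => Keap1=1 @1")
#' @export
parse_pathways <- function(text) {
  if (length(text) == 1L && grepl("\n", text))
    text <- strsplit(text, "\n", fixed = TRUE)[[1L]]
  segs <- list()
  id <- "[A-Za-z_][A-Za-z0-9_.]*"
  for (i in seq_along(text)) {
    line <- trimws(sub("#.*$", "", text[[i]]))
    if (!nzchar(line)) next
    seg <- tryCatch({
      if (grepl("~>", line, fixed = TRUE)) {
        m <- regmatches(line, regexec(paste0(
          "^(", id, ")\\s*~>\\s*(", id, ")\\s*@\\s*([0-9]+)\\s*$"), line))[[1L]]
        if (length(m) != 4L) stop("bad negating segment syntax", call. = FALSE)
        pathway_segment(m[[2L]], target = m[[3L]], time_bound = as.integer(m[[4L]]),
                        negating = TRUE)
      } else {
        m <- regmatches(line, regexec(paste0(
          "^(", id, "(\\s*,\\s*", id, ")*)\\s*\\|\\s*([01](\\s*,\\s*[01])*)\\s*",
          "=>\\s*(", id, ")\\s*=\\s*([01])\\s*@\\s*([0-9]+)\\s*$"), line))[[1L]]
        if (length(m) != 8L) stop("bad segment syntax", call. = FALSE)
        preds <- trimws(strsplit(m[[2L]], ",")[[1L]])
        vals <- as.integer(trimws(strsplit(m[[4L]], ",")[[1L]]))
        pathway_segment(preds, vals, target = m[[6L]],
                        target_value = as.integer(m[[7L]]),
                        time_bound = as.integer(m[[8L]]))
      }
    }, error = function(c) stop("line ", i, ": ", conditionMessage(c),
                                call. = FALSE))
    segs[[length(segs) + 1L]] <- seg
  }
  structure(segs, class = "bn_segments")
}

#' @rdname parse_pathways
#' @param path path to a pathway file.
#' @export
read_pathways <- function(path) parse_pathways(readLines(path, warn = FALSE))

#' @export
print.bn_segments <- function(x, ...) {
  cat(length(x), "pathway segment(s)\n")
  for (s in x) cat("  ", format(s), "\n", sep = "")
  invisible(x)
}

#' @export
`[.bn_segments` <- function(x, i) structure(unclass(x)[i], class = "bn_segments")

# Expand a negating segment into its two literal constituents.
expand_segment <- function(seg) {
  if (!seg$negating) return(list(seg))
  list(pathway_segment(seg$predictors, 1L, seg$target, 0L, seg$time_bound),
       pathway_segment(seg$predictors, 0L, seg$target, 1L, seg$time_bound))
}

#' Build a per-target constraint table
#'
#' The table is the programmatic Karnaugh map for one target: every
#' segment writes its target value into each cell (predictor assignment)
#' consistent with its predictor requirements.  A cell that receives both
#' a 0 and a 1 is marked `conflict`; a cell no segment touches is
#' `dont_care`.  Negating segments are expanded first.  Predictors that
#' are declared constants are reduced away: a requirement matching the
#' constant's value is dropped, a contradicting requirement makes the
#' segment vacuous.
#'
#' @param segments a `bn_segments` list (or plain list of segments), all
#'   sharing one target and all with `time_bound = 1` (segments with a
#'   larger bound under-determine a one-step update and are rejected).
#' @param predictors character vector (length <= 3) fixing the table's
#'   variables and their order; default: first-appearance order over the
#'   segments.
#' @param constants named 0/1 vector of constant nodes to reduce.
#' @return An object of class `bn_table` with fields `target`,
#'   `predictors`, `values` (0/1/NA per cell, all-zero assignment first,
#'   first predictor = most significant bit) and logical `conflict`.
#' @export
build_constraint_table <- function(segments, predictors = NULL,
                                   constants = integer(0)) {
  segments <- unlist(lapply(segments, expand_segment), recursive = FALSE)
  if (length(segments) == 0L && is.null(predictors))
    stop("no segments and no predictor set given", call. = FALSE)
  target <- unique(vapply(segments, `[[`, "", "target"))
  if (length(target) > 1L)
    stop("segments target different nodes: ", paste(target, collapse = ", "),
         call. = FALSE)
  if (length(target) == 0L) target <- NA_character_
  bad_t <- vapply(segments, function(s) s$time_bound != 1L, TRUE)
  if (any(bad_t))
    stop("only segments with time bound 1 compile to a one-step update; ",
         "got t=", segments[[which(bad_t)[1L]]]$time_bound, call. = FALSE)

  # constant reduction
  segments <- Filter(Negate(is.null), lapply(segments, function(s) {
    keep <- !(s$predictors %in% names(constants))
    drop_vals <- constants[s$predictors[!keep]]
    if (length(drop_vals) && any(drop_vals != s$values[!keep]))
      return(NULL)  # requirement contradicts a constant: vacuous
    if (all(keep)) return(s)
    s$predictors <- s$predictors[keep]
    s$values <- s$values[keep]
    s
  }))

  seen <- unique(unlist(lapply(segments, `[[`, "predictors")))
  if (is.null(predictors)) predictors <- seen
  extra <- setdiff(seen, predictors)
  if (length(extra))
    stop("segment predictor '", extra[1L], "' not in the table's predictor set",
         call. = FALSE)
  if (length(predictors) > 3L)
    stop("more than 3 distinct predictors for target '", target, "': ",
         paste(predictors, collapse = ", "), call. = FALSE)

  k <- length(predictors)
  values <- rep(NA_integer_, 2^k)
  conflict <- rep(FALSE, 2^k)
  # row i = bits of cell i-1, first predictor as most significant bit
  cells <- outer(seq_len(2^k) - 1L, seq_len(k),
                 function(d, j) bitwAnd(bitwShiftR(d, k - j), 1L))
  for (s in segments) {
    pos <- match(s$predictors, predictors)
    hit <- if (length(pos) == 0L) rep(TRUE, nrow(cells))
    else apply(cells, 1L, function(row) all(row[pos] == s$values))
    for (i in which(hit)) {
      if (is.na(values[[i]]) && !conflict[[i]]) values[[i]] <- s$target_value
      else if (!conflict[[i]] && values[[i]] != s$target_value) {
        conflict[[i]] <- TRUE
        values[[i]] <- NA_integer_
      }
    }
  }
  structure(list(target = target, predictors = predictors,
                 values = values, conflict = conflict),
            class = "bn_table")
}

#' @export
print.bn_table <- function(x, ...) {
  k <- length(x$predictors)
  cat("Constraint table for '", x$target, "' over (",
      paste(x$predictors, collapse = ", "), ")\n", sep = "")
  lab <- vapply(seq_len(2^k) - 1L, function(d)
    paste(bitwAnd(bitwShiftR(d, (k - 1L):0), 1L), collapse = ""), "")
  cell <- ifelse(x$conflict, "conflict",
                 ifelse(is.na(x$values), "dont_care", x$values))
  cat(paste0("  ", lab, " : ", cell, "\n"), sep = "")
  invisible(x)
}

#' Resolve a constraint table into a complete or minimization-ready table
#'
#' Conflict cells must be assigned by `overrides` (the place where
#' biological judgement enters the compilation, shipped as data).
#' Remaining don't-care cells are handled per `dont_care_policy`:
#' `"free"` leaves them for the minimizer to exploit, `"to_zero"` /
#' `"to_one"` pins them, `"hold_previous"` sets each to the target's own
#' value in that cell (requires the target among the predictors).
#' Overrides may also pin non-conflict don't-care cells.
#'
#' @param table a `bn_table`.
#' @param overrides named 0/1 vector; names are cell bit strings in
#'   predictor order (e.g. `c("110" = 1)`).
#' @param dont_care_policy one of `"free"`, `"to_zero"`, `"to_one"`,
#'   `"hold_previous"`.
#' @return The table with `values` completed (`NA` kept only under the
#'   `"free"` policy) and no conflicts.
#' @export
resolve_table <- function(table, overrides = integer(0),
                          dont_care_policy = c("free", "to_zero", "to_one",
                                               "hold_previous")) {
  stopifnot(inherits(table, "bn_table"))
  dont_care_policy <- match.arg(dont_care_policy)
  k <- length(table$predictors)
  lab <- vapply(seq_len(2^k) - 1L, function(d)
    paste(bitwAnd(bitwShiftR(d, (k - 1L):0), 1L), collapse = ""), "")
  if (length(overrides)) {
    bad <- setdiff(names(overrides), lab)
    if (length(bad))
      stop("override cell '", bad[1L], "' does not match the ", k,
           "-predictor table of '", table$target, "'", call. = FALSE)
    idx <- match(names(overrides), lab)
    table$values[idx] <- as.integer(overrides)
    table$conflict[idx] <- FALSE
  }
  if (any(table$conflict))
    stop("unresolved conflict cell ", lab[which(table$conflict)[1L]],
         " for target '", table$target, "' (supply an override)",
         call. = FALSE)
  dc <- is.na(table$values)
  if (any(dc) && dont_care_policy != "free") {
    table$values[dc] <- switch(dont_care_policy,
      to_zero = 0L,
      to_one = 1L,
      hold_previous = {
        j <- match(table$target, table$predictors)
        if (is.na(j))
          stop("'hold_previous' needs the target among the predictors",
               call. = FALSE)
        vapply(which(dc), function(i)
          bitwAnd(bitwShiftR(i - 1L, k - j), 1L), 0L)
      })
  }
  table
}

#' Parse a compile configuration (overrides) document
#'
#' Declares everything the compiler needs beyond the segments themselves:
#' `input`/`const`/`order`/`output` lines as in [parse_network()], optional
#' `predictors T : P1 P2 ...` lines fixing a target's table variables and
#' their bit order, optional `policy T : free|to_zero|to_one|hold_previous`
#' lines, and cell overrides `T : <bits> = 0|1` with bits in declared
#' predictor order.  `#` starts a comment.
#'
#' @param text character vector of lines or single string.
#' @return A list with components `inputs`, `constants`, `order`,
#'   `outputs`, `predictors` (named list), `policies` (named character),
#'   `overrides` (named list of named 0/1 vectors).
#' @export
parse_overrides <- function(text) {
  if (length(text) == 1L && grepl("\n", text))
    text <- strsplit(text, "\n", fixed = TRUE)[[1L]]
  cfg <- list(inputs = character(0), constants = integer(0), order = NULL,
              outputs = character(0), predictors = list(),
              policies = character(0), overrides = list())
  id <- "[A-Za-z_][A-Za-z0-9_.]*"
  for (i in seq_along(text)) {
    line <- trimws(sub("#.*$", "", text[[i]]))
    if (!nzchar(line)) next
    if (grepl("^input\\s+", line)) {
      cfg$inputs <- c(cfg$inputs, trimws(sub("^input\\s+", "", line)))
    } else if (grepl("^const\\s+", line)) {
      m <- regmatches(line, regexec(paste0(
        "^const\\s+(", id, ")\\s*=\\s*([01])\\s*$"), line))[[1L]]
      if (length(m) != 3L) stop("line ", i, ": bad const declaration",
                                call. = FALSE)
      cfg$constants[[m[[2L]]]] <- as.integer(m[[3L]])
    } else if (grepl("^order\\s+", line)) {
      cfg$order <- strsplit(trimws(sub("^order\\s+", "", line)), "\\s+")[[1L]]
    } else if (grepl("^output\\s+", line)) {
      cfg$outputs <- c(cfg$outputs, trimws(sub("^output\\s+", "", line)))
    } else if (grepl("^predictors\\s+", line)) {
      m <- regmatches(line, regexec(paste0(
        "^predictors\\s+(", id, ")\\s*:\\s*(.+)$"), line))[[1L]]
      if (length(m) != 3L) stop("line ", i, ": bad predictors declaration",
                                call. = FALSE)
      cfg$predictors[[m[[2L]]]] <- strsplit(trimws(m[[3L]]), "\\s+")[[1L]]
    } else if (grepl("^policy\\s+", line)) {
      m <- regmatches(line, regexec(paste0(
        "^policy\\s+(", id, ")\\s*:\\s*(free|to_zero|to_one|hold_previous)\\s*$"),
        line))[[1L]]
      if (length(m) != 3L) stop("line ", i, ": bad policy declaration",
                                call. = FALSE)
      cfg$policies[[m[[2L]]]] <- m[[3L]]
    } else {
      m <- regmatches(line, regexec(paste0(
        "^(", id, ")\\s*:\\s*([01]+)\\s*=\\s*([01])\\s*$"), line))[[1L]]
      if (length(m) != 4L)
        stop("line ", i, ": unrecognized override line: '", line, "'",
             call. = FALSE)
      cfg$overrides[[m[[2L]]]] <- c(cfg$overrides[[m[[2L]]]],
                                    stats::setNames(as.integer(m[[4L]]), m[[3L]]))
    }
  }
  cfg
}

#' @rdname parse_overrides
#' @param path path to a compile configuration file.
#' @export
read_overrides <- function(path) parse_overrides(readLines(path, warn = FALSE))

#' Compile pathway segments into a Boolean network
#'
#' End-to-end compilation: segments are grouped by target, each group is
#' turned into a constraint table ([build_constraint_table()]), conflicts
#' and don't-cares are resolved per the configuration
#' ([resolve_table()]), and each completed table is minimized to a
#' sum-of-products update expression ([minimize_sop()]).  Segments whose
#' target is a declared constant are ignored (the constant already fixes
#' that node).
#'
#' @param segments a `bn_segments` list.
#' @param config a compile configuration from [parse_overrides()] /
#'   [read_overrides()], or a list with the same components.
#' @param name network name.
#' @return A [boolean_network()] object.
#' @examples
#' segs <- fixture_pathways()
#' cfg <- read_overrides(fixture_overrides_path())
#' net <- compile_network(segs, cfg)
#' format(net$updates$ARE)
#' @export
compile_network <- function(segments, config = list(), name = "compiled") {
  defaults <- list(inputs = character(0), constants = integer(0), order = NULL,
                   outputs = character(0), predictors = list(),
                   policies = character(0), overrides = list())
  config <- utils::modifyList(defaults, config)
  targets <- unique(vapply(segments, `[[`, "", "target"))
  targets <- setdiff(targets, names(config$constants))
  if (length(targets) == 0L)
    stop("no compilable segments: network would have no state nodes",
         call. = FALSE)
  if (!is.null(config$order)) {
    missing <- setdiff(targets, config$order)
    if (length(missing))
      stop("order line omits compiled target '", missing[1L], "'",
           call. = FALSE)
    targets <- setdiff(config$order, names(config$constants))
  }
  updates <- list()
  tables <- list()
  for (tg in targets) {
    segs_t <- Filter(function(s) s$target == tg, segments)
    preds <- config$predictors[[tg]]
    if (length(segs_t) == 0L && is.null(preds))
      stop("no segments and no predictor declaration for target '", tg, "'",
           call. = FALSE)
    tab <- build_constraint_table(segs_t, predictors = preds,
                                  constants = config$constants)
    tab$target <- tg
    policy <- if (tg %in% names(config$policies)) config$policies[[tg]] else "free"
    tab <- resolve_table(tab, overrides = config$overrides[[tg]] %||% integer(0),
                         dont_care_policy = policy)
    updates[[tg]] <- minimize_sop(tab$values, tab$predictors)
    tables[[tg]] <- tab
  }
  net <- boolean_network(state_nodes = targets, updates = updates,
                         inputs = config$inputs, constants = config$constants,
                         observables = intersect(config$outputs, targets),
                         name = name)
  attr(net, "tables") <- tables
  net
}
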