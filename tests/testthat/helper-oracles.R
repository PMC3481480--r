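# Independent oracles used to cross-check the package's algorithms.
# Each deliberately takes the dumbest correct route (hand-coded rules,
# explicit enumeration) rather than the package's own code path.

# Hand-coded update rules of the oxidative stress network, written out
# arithmetically; bit order [ROS Keap1 PKC Nrf2 Bach1 ARE], MSB first.
hand_step_oxidative <- function(decimal, stress) {
  b <- as.integer(bitwAnd(bitwShiftR(decimal, 5:0), 1L))
  ROS <- b[1]; Keap1 <- b[2]; PKC <- b[3]; Nrf2 <- b[4]; Bach1 <- b[5]; ARE <- b[6]
  nxt <- c(
    stress * (1 - ARE),
    (1 - ROS) * max(Nrf2, Keap1),
    ROS * (1 - ARE),
    max(PKC, 1 - Keap1),
    1 - ROS,
    Nrf2 * max(1 - ARE, 1 - Bach1)
  )
  sum(nxt * 2^(5:0))
}

# Attractors by brute force: from every state iterate 2^n steps to land on
# the periodic tail, then walk the cycle.  Uses step_network() one state at
# a time, never the successor-array machinery under test.
oracle_attractors <- function(net, fixed_inputs) {
  n <- length(net$state_nodes)
  N <- 2^n
  canon <- function(cyc) {
    i <- which.min(cyc)
    c(cyc[i:length(cyc)], cyc[seq_len(i - 1L)])
  }
  cycles <- list()
  for (s0 in 0:(N - 1L)) {
    s <- s0
    for (k in seq_len(N)) s <- step_network(net, s, fixed_inputs)
    cyc <- s
    repeat {
      s <- step_network(net, s, fixed_inputs)
      if (s == cyc[[1L]]) break
      cyc <- c(cyc, s)
    }
    cyc <- canon(cyc)
    key <- paste(cyc, collapse = ",")
    cycles[[key]] <- cyc
  }
  unname(cycles[order(vapply(cycles, `[[`, 0L, 1L))])
}

# All-pairs fault detection by explicit simulation of every initial state
# of both machines and pairwise comparison of observable trajectories.
oracle_is_detected <- function(normal, faulty, input_bits) {
  net_n <- normal$net
  net_f <- faulty$net
  obs <- normal$observables
  n <- length(net_n$state_nodes)
  N <- 2^n
  resp <- function(net, q) {
    tr <- simulate_network(net, q, input_bits)
    as.matrix(tr[-1L, obs, drop = FALSE])
  }
  Rn <- lapply(0:(N - 1L), function(q) resp(net_n, q))
  Rf <- lapply(0:(N - 1L), function(q) resp(net_f, q))
  for (q in seq_len(N)) for (qf in seq_len(N))
    if (identical(Rn[[q]], Rf[[qf]])) return(FALSE)
  TRUE
}

# Minimum number of product terms covering a truth table, by exhaustive
# search over ALL valid product terms (3^k candidates), increasing cover
# size.  Independent of the prime-implicant machinery.
oracle_min_terms <- function(values, k) {
  on <- which(values == 1L) - 1L
  off <- which(values == 0L) - 1L
  if (length(on) == 0L) return(0L)
  if (length(off) == 0L) return(1L)
  cell_bits <- function(d) bitwAnd(bitwShiftR(d, (k - 1L):0), 1L)
  # a term is a k-vector over c(0,1,NA); NA = variable absent
  specs <- expand.grid(rep(list(c(0L, 1L, NA)), k))
  covers <- list()
  for (i in seq_len(nrow(specs))) {
    tm <- unlist(specs[i, ])
    cov <- Filter(function(d) {
      b <- cell_bits(d)
      all(is.na(tm) | b == tm)
    }, 0:(2^k - 1L))
    if (any(cov %in% off)) next           # not a valid implicant
    if (!any(cov %in% on)) next           # useless
    covers[[length(covers) + 1L]] <- intersect(cov, on)
  }
  for (size in seq_along(covers)) {
    sets <- utils::combn(length(covers), size, simplify = FALSE)
    for (sel in sets)
      if (setequal(intersect(unlist(covers[sel]), on), on)) return(size)
  }
  stop("no cover found (impossible)")
}

# Sum-of-products term set of an expression, as sorted "Var=bit" strings,
# for comparing minimizer output against expected term sets.
expr_term_set <- function(expr) {
  terms <- attr(expr, "terms")
  apply(terms, 1L, function(row) {
    keep <- row != "-"
    paste(paste0(colnames(terms)[keep], "=", row[keep]), collapse = "&")
  })
}

# truth table (over vars, MSB-first cell order) of an expression
expr_truth_table <- function(expr, vars) {
  k <- length(vars)
  vapply(0:(2^k - 1L), function(d) {
    env <- as.list(bitwAnd(bitwShiftR(d, (k - 1L):0), 1L))
    names(env) <- vars
    eval_bool_expr(expr, env)
  }, integer(1))
}
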