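#' The oxidative stress response network
#'
#' The six-gene synchronous Boolean model of the Nrf2-Keap1-ARE oxidative
#' stress response, with reactive oxygen species (ROS) as the biological
#' manifestation of an exogenous Stress input, PKC as the kinase
#' transducer, Bach1 as the competing repressor of the antioxidant
#' response element (ARE), and small Maf proteins (SMP) ubiquitously
#' expressed (a constant-1 node outside the state vector).  State bit
#' order is `[ROS Keap1 PKC Nrf2 Bach1 ARE]`, most significant bit first;
#' ARE is the observable.  Update rules:
#'
#' \preformatted{
#'   ROS'   = Stress & !ARE
#'   Keap1' = !ROS & (Nrf2 | Keap1)
#'   PKC'   = ROS & !ARE
#'   Nrf2'  = PKC | !Keap1
#'   Bach1' = !ROS
#'   ARE'   = Nrf2 & (!ARE | !Bach1)
#' }
#'
#' Under constant Stress=0 the network has the single fixed point
#' 18(010010) (Keap1 and Bach1 on, everything else off); under constant
#' Stress=1 it has a single 7-state attractor cycle.
#'
#' @return A [boolean_network()] object.
#' @seealso [fixture_pathways()] for the pathway segments it was compiled
#'   from, [fixture_network_path()] for the shipped definition file.
#' @export
fixture_oxidative_stress <- function() {
  read_network(fixture_network_path(), name = "oxidative_stress")
}

#' Paths to the shipped fixture files
#'
#' Plain-text fixtures installed with the package: the oxidative stress
#' network definition, the twelve pathway segments it derives from, and
#' the compile configuration (predictor choices plus conflict/don't-care
#' resolutions, reconstructed so that compilation reproduces the published
#' update rules).
#'
#' @return A file path.
#' @export
fixture_network_path <- function() {
  system.file("extdata", "oxidative_stress.bnet", package = "boolfault",
              mustWork = TRUE)
}

#' @rdname fixture_network_path
#' @export
fixture_pathways_path <- function() {
  system.file("extdata", "oxidative_stress_pathways.txt",
              package = "boolfault", mustWork = TRUE)
}

#' @rdname fixture_network_path
#' @export
fixture_overrides_path <- function() {
  system.file("extdata", "oxidative_stress_overrides.txt",
              package = "boolfault", mustWork = TRUE)
}

#' The oxidative stress pathway segments
#'
#' The twelve timed regulation constraints of the oxidative stress
#' response (all with time bound 1), including the negating segments for
#' Bach1 (which follows the complement of ROS) and Nrf2 (complement of
#' Keap1).  Compiling them with the shipped configuration
#' ([fixture_overrides_path()]) reproduces [fixture_oxidative_stress()].
#'
#' @return A `bn_segments` list of [pathway_segment()] objects.
#' @export
fixture_pathways <- function() {
  read_pathways(fixture_pathways_path())
}

#' Seeded random Boolean networks
#'
#' Generates reproducible random networks for property testing: every node
#' draws up to `max_in_degree` predictors (uniformly among 0..max, from
#' state nodes and inputs) and a uniform random truth table over them.
#' Generation is a pure function of the configuration: the same seed gives
#' the identical network, and the caller's RNG state is untouched.
#'
#' @param n_nodes number of state nodes (<= 12 so exhaustive analyses stay
#'   cheap).
#' @param max_in_degree maximum predictors per node (default 3).
#' @param n_inputs number of exogenous input nodes.
#' @param seed integer seed.
#' @return A [boolean_network()] object named after the configuration.
#' @examples
#' net <- generate_random_network(4, seed = 1)
#' identical(write_network(net),
#'           write_network(generate_random_network(4, seed = 1)))
#' @export
generate_random_network <- function(n_nodes, max_in_degree = 3L,
                                    n_inputs = 0L, seed = 1L) {
  stopifnot(n_nodes >= 1L, n_nodes <= 12L, max_in_degree >= 0L,
            n_inputs >= 0L)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  state_nodes <- paste0("x", seq_len(n_nodes))
  inputs <- if (n_inputs > 0L) paste0("u", seq_len(n_inputs)) else character(0)
  pool <- c(state_nodes, inputs)
  updates <- list()
  for (nd in state_nodes) {
    k <- sample(0:min(max_in_degree, length(pool)), 1L)
    preds <- if (k > 0L) sample(pool, k) else character(0)
    tt <- sample(0:1, 2^k, replace = TRUE)
    updates[[nd]] <- truth_table_expr(tt, preds)
  }
  boolean_network(state_nodes, updates, inputs = inputs,
                  observables = state_nodes[[1L]],
                  name = sprintf("random(n=%d,k=%d,p=%d,seed=%d)",
                                 n_nodes, max_in_degree, n_inputs, seed))
}

# canonical sum-of-minterms expression for a truth table (not minimized;
# the minimizer is exercised elsewhere and must not be load-bearing here)
truth_table_expr <- function(tt, vars) {
  k <- length(vars)
  on <- which(tt == 1L) - 1L
  if (length(on) == 0L) return(bx_const(0L))
  if (length(on) == 2^k) return(bx_const(1L))
  term <- function(d) {
    lits <- lapply(seq_len(k), function(j) {
      if (bitwAnd(bitwShiftR(d, k - j), 1L) == 1L) bx_var(vars[[j]])
      else bx_not(bx_var(vars[[j]]))
    })
    if (length(lits) == 1L) lits[[1L]] else bx_and(lits)
  }
  terms <- lapply(on, term)
  if (length(terms) == 1L) terms[[1L]] else bx_or(terms)
}
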