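ox_machine <- function() {
  net <- fixture_oxidative_stress()
  sequential_machine(net)
}

faulty_machine <- function(node, value) {
  net <- fixture_oxidative_stress()
  sequential_machine(inject_fault(net, node, value), net$observables)
}

test_that("the single stuck-at fault universe is two faults per gene", {
  net <- fixture_oxidative_stress()
  f <- enumerate_faults(net)
  expect_equal(nrow(f), 12L)
  expect_equal(f$node[1:2], c("ROS", "ROS"))
  expect_equal(f$stuck_value[1:2], c(0L, 1L))
  expect_equal(f$node, rep(net$state_nodes, each = 2L))

  # fifteen gene nodes -> thirty faults
  nodes15 <- paste0("g", 1:15)
  net15 <- boolean_network(nodes15,
                           stats::setNames(as.list(nodes15), nodes15),
                           observables = "g1")
  expect_equal(nrow(enumerate_faults(net15)), 30L)
})

test_that("fault injection fixes the node from the first update onward", {
  net <- fixture_oxidative_stress()
  bad <- inject_fault(net, "ARE", 1L)
  # original untouched
  expect_equal(format(net$updates$ARE), "Nrf2 & (!ARE | !Bach1)")
  expect_equal(bad$updates$ARE$type, "const")
  for (s in 0:63) {
    nxt <- decode_state(bad, step_network(bad, s, c(Stress = 0)))
    expect_equal(unname(nxt[["ARE"]]), 1L)
  }
  # a stuck ROS derails the stress cycle
  ros0 <- inject_fault(net, "ROS", 0L)
  norm <- simulate_network(net, 18, rep(1, 10))$decimal
  flt <- simulate_network(ros0, 18, rep(1, 10))$decimal
  expect_false(setequal(unique(norm), unique(flt)))
  # a state already agreeing with the stuck value steps identically elsewhere
  s <- 18L  # ARE bit is 0
  n1 <- decode_state(net, step_network(net, s, c(Stress = 0)))
  f1 <- decode_state(inject_fault(net, "ARE", 0L),
                     step_network(inject_fault(net, "ARE", 0L), s, c(Stress = 0)))
  expect_equal(n1[names(n1) != "ARE"], f1[names(f1) != "ARE"])
  expect_error(inject_fault(net, "Stress", 1L), "not a gene")
  expect_error(inject_fault(net, "SMP", 1L), "not a gene")
})

test_that("detection follows the strict all-pairs criterion", {
  m <- ox_machine()
  mf <- faulty_machine("ARE", 0L)
  # quiesce, then hold stress long enough to traverse the cycle: the normal
  # machine raises ARE, the stuck one never does
  T <- c(rep(0, 4), rep(1, 8))
  expect_true(is_detected(m, mf, T))
  # the empty sequence detects nothing
  expect_false(is_detected(m, mf, numeric(0)))
  # too short to force a visible difference for every pair: witness returned
  short <- is_detected(m, mf, c(0))
  expect_false(short)
  expect_length(attr(short, "witness"), 2L)
})

test_that("faults with no path to an observable are never detected", {
  net <- parse_network(c(
    "input u",
    "node A = u",
    "node B = !B",   # disconnected from the output
    "node C = A",
    "output C"
  ))
  m <- sequential_machine(net)
  mf <- sequential_machine(inject_fault(net, "B", 1L), net$observables)
  for (T in list(c(0, 1), c(1, 1, 1, 0), rep(0, 6)))
    expect_false(is_detected(m, mf, T))
})

test_that("detection agrees with the explicit all-pairs simulation oracle", {
  set.seed(99)
  for (seed in 1:12) {
    net <- generate_random_network(sample(3:5, 1), n_inputs = 1, seed = seed)
    m <- sequential_machine(net, net$state_nodes[1L])
    fnode <- sample(net$state_nodes, 1)
    fval <- sample(0:1, 1)
    mf <- sequential_machine(inject_fault(net, fnode, fval), net$state_nodes[1L])
    T <- sample(0:1, sample(1:6, 1), replace = TRUE)
    expect_equal(isTRUE(is_detected(m, mf, T)),
                 oracle_is_detected(m, mf, T),
                 info = paste("seed", seed, fnode, fval,
                              paste(T, collapse = "")))
  }
})

test_that("monotonicity: any extension of a detecting sequence still detects", {
  m <- ox_machine()
  set.seed(5)
  for (fault in list(c("ARE", 0), c("ROS", 1), c("Nrf2", 0))) {
    mf <- faulty_machine(fault[[1]], as.integer(fault[[2]]))
    T <- c(rep(0, 4), rep(1, 8))
    expect_true(is_detected(m, mf, T))
    ext <- c(T, sample(0:1, 3, replace = TRUE))
    expect_true(is_detected(m, mf, ext))
  }
})

test_that("the quiescent input homes the stress network in four steps", {
  m <- ox_machine()
  h <- find_homing_sequence(m)
  expect_equal(h$length, 4L)
  expect_equal(h$final_state, 18L)
  expect_true(all(vapply(h$sequence, `[[`, 0L, "Stress") == 0L))
  # the homing property itself: the image of the full state set is {18}
  expect_equal(homing_image(m, rep(0, 4)), 18L)
  # three steps are not enough
  expect_gt(length(homing_image(m, rep(0, 3))), 1L)
})

test_that("homing search handles trivial and impossible machines", {
  m <- ox_machine()
  # a machine already known to be in one state needs no input
  h0 <- find_homing_sequence(m, initial_set = 44L)
  expect_equal(h0$length, 0L)
  expect_equal(h0$final_state, 44L)
  # identity networks never merge states
  idn <- parse_network(c("node A = A", "node B = B"))
  expect_null(find_homing_sequence(sequential_machine(idn, "A"), max_len = 50))
})

test_that("generated tests are self-consistent and shortest-first", {
  m <- ox_machine()
  for (fault in list(c("Nrf2", 0), c("ARE", 1), c("Keap1", 0))) {
    mf <- faulty_machine(fault[[1]], as.integer(fault[[2]]))
    test <- generate_test(m, mf)
    expect_false(is_undetectable(test))
    expect_true(is_detected(m, mf, test$vectors))
    # shortest: every proper prefix fails
    if (test$length > 1L)
      expect_false(isTRUE(is_detected(m, mf, test$vectors[seq_len(test$length - 1L)])))
  }
})

test_that("behaviorally equivalent faults are proven undetectable", {
  # the node is constant 1 in the fault-free machine, so sticking it at 1
  # changes nothing: the pair search must close without finding a test
  net <- parse_network(c("input u", "node A = 1", "node B = A & u", "output B"))
  m <- sequential_machine(net)
  mf <- sequential_machine(inject_fault(net, "A", 1L), "B")
  r <- generate_test(m, mf, max_frames = 10)
  expect_true(is_undetectable(r))
  expect_true(r$proven)
})

test_that("the fixture diagnosis table covers all twelve faults", {
  net <- fixture_oxidative_stress()
  tab <- build_diagnosis_table(net)
  expect_equal(nrow(tab), 12L)
  expect_true(all(tab$detected | !is.na(tab$undetectable_proven)))
  m <- ox_machine()
  for (i in which(tab$detected)) {
    mf <- faulty_machine(tab$fault_node[[i]], tab$stuck_value[[i]])
    vecs <- boolfault:::bit_string_to_inputs(tab$detecting_sequence[[i]],
                                             m$primary_inputs)
    expect_true(is_detected(m, mf, vecs),
                info = paste(tab$fault_node[[i]], tab$stuck_value[[i]]))
    expect_equal(length(vecs), tab$detect_length[[i]])
  }
  # complementary detected faults never collapse into one ambiguity class
  for (nd in unique(tab$fault_node)) {
    rows <- tab[tab$fault_node == nd, ]
    if (all(rows$detected))
      expect_false(rows$ambiguity_class_id[1] == rows$ambiguity_class_id[2],
                   info = nd)
  }
  # the homing prefix is recorded alongside
  h <- attr(tab, "homing")
  expect_equal(h$final_state, 18L)
  # truncation notes: shortest detecting prefixes never exceed full length
  tr <- attr(tab, "truncations")
  expect_true(all(is.na(tr) | tr <= nchar(rownames(tr)[row(tr)])))
})

test_that("a one-gene machine is diagnosed by a length-one sequence", {
  net <- parse_network(c("input u", "node A = !u", "output A"))
  tab <- build_diagnosis_table(net)
  expect_equal(nrow(tab), 2L)
  expect_true(all(tab$detected))
  expect_true(any(tab$detect_length == 1L))
  # driving u=1 forces the normal gene to 0, exposing stuck-at-1
  sa1 <- tab[tab$stuck_value == 1L, ]
  expect_equal(sa1$detect_length, 1L)
  expect_equal(sa1$detecting_sequence, "1")
})

test_that("diagnosis tables export as TSV", {
  net <- parse_network(c("input u", "node A = !u", "output A"))
  tab <- build_diagnosis_table(net, homing = FALSE)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_diagnosis_tsv(tab, path)
  back <- utils::read.delim(path)
  expect_equal(nrow(back), 2L)
  expect_true(all(c("fault_node", "stuck_value", "detecting_sequence",
                    "detect_length", "signature", "ambiguity_class_id")
                  %in% names(back)))
})
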