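test_that("pathway segment documents parse, including the negating form", {
  segs <- parse_pathways(c(
    "Nrf2,ROS | 1,0 => Keap1=1 @1",
    "ROS ~> Bach1 @1"
  ))
  expect_length(segs, 2L)
  s <- segs[[1L]]
  expect_equal(s$predictors, c("Nrf2", "ROS"))
  expect_equal(s$values, c(1L, 0L))
  expect_equal(s$target, "Keap1")
  expect_equal(s$target_value, 1L)
  expect_equal(s$time_bound, 1L)
  expect_false(s$negating)
  expect_true(segs[[2L]]$negating)
  expect_equal(segs[[2L]]$predictors, "ROS")

  expect_error(parse_pathways("A | 1,0 => B=1 @1"), "arity mismatch")
  expect_error(parse_pathways("A => B @1"), "line 1.*syntax")
  expect_error(parse_pathways("A,B,C,D | 1,1,1,1 => E=1 @1"),
               "between 1 and 3 predictors")
})

test_that("the shipped pathway fixture has the twelve published segments", {
  segs <- fixture_pathways()
  expect_length(segs, 12L)
  expect_true(all(vapply(segs, `[[`, 0L, "time_bound") == 1L))
  s5 <- segs[[5L]]
  expect_equal(s5$predictors, c("Nrf2", "ROS"))
  expect_equal(s5$values, c(1L, 0L))
  expect_equal(s5$target, "Keap1")
  expect_equal(s5$target_value, 1L)
  expect_equal(sum(vapply(segs, `[[`, TRUE, "negating")), 2L)
})

test_that("constraint tables record conflicts and don't-cares correctly", {
  # the ARE example: activator and repressor segments collide when both
  # Bach1 and Nrf2 are up (the SMP predictor reduces away as a constant 1)
  segs <- parse_pathways(c(
    "Bach1,SMP | 1,1 => ARE=0 @1",
    "Nrf2,SMP | 1,1 => ARE=1 @1"
  ))
  tab <- build_constraint_table(segs, predictors = c("Bach1", "Nrf2"),
                                constants = c(SMP = 1L))
  # cells in order (Bach1,Nrf2): 00, 01, 10, 11
  expect_equal(tab$conflict, c(FALSE, FALSE, FALSE, TRUE))
  expect_equal(tab$values, c(NA_integer_, 1L, 0L, NA_integer_))

  # single segment: one forced cell, rest don't-care
  tab2 <- build_constraint_table(parse_pathways("A | 1 => B=1 @1"))
  expect_equal(tab2$predictors, "A")
  expect_equal(tab2$values, c(NA_integer_, 1L))
  expect_false(any(tab2$conflict))

  # no segments at all: every cell is a don't-care
  tab3 <- build_constraint_table(list(), predictors = c("A", "B"))
  expect_true(all(is.na(tab3$values)))

  # a segment whose requirement contradicts a constant is vacuous
  tab4 <- build_constraint_table(parse_pathways("SMP | 0 => B=1 @1"),
                                 predictors = "A", constants = c(SMP = 1L))
  expect_true(all(is.na(tab4$values)))

  expect_error(build_constraint_table(parse_pathways(c(
    "A | 1 => Z=1 @1", "B | 1 => Z=1 @1", "C | 1 => Z=1 @1", "D | 1 => Z=1 @1"
  ))), "more than 3 distinct predictors")
  expect_error(build_constraint_table(parse_pathways("A | 1 => B=1 @2")),
               "time bound 1")
})

test_that("conflict resolution demands overrides and applies policies", {
  segs <- parse_pathways(c("A | 1 => T=1 @1", "B | 1 => T=0 @1"))
  tab <- build_constraint_table(segs, predictors = c("A", "B"))
  expect_error(resolve_table(tab), "unresolved conflict cell 11")
  r <- resolve_table(tab, overrides = c("11" = 1L), dont_care_policy = "to_zero")
  expect_equal(r$values, c(0L, 0L, 1L, 1L))
  r1 <- resolve_table(tab, overrides = c("11" = 0L), dont_care_policy = "to_one")
  expect_equal(r1$values, c(1L, 0L, 1L, 0L))
  # hold_previous keeps the target's own bit in untouched cells
  segs2 <- parse_pathways("A | 1 => T=1 @1")
  tab2 <- build_constraint_table(segs2, predictors = c("A", "T"))
  r2 <- resolve_table(tab2, dont_care_policy = "hold_previous")
  expect_equal(r2$values, c(0L, 1L, 1L, 1L))  # cells 00,01 hold T; 10,11 forced 1
  expect_error(resolve_table(tab, overrides = c("2" = 1L)), "override cell")
})

test_that("minimization reproduces the antioxidant response worked example", {
  # full truth table of ARE' = Nrf2 & (!ARE | !Bach1) over (Nrf2,Bach1,ARE)
  tt <- c(0L, 0L, 0L, 0L, 1L, 1L, 1L, 0L)
  e <- minimize_sop(tt, c("Nrf2", "Bach1", "ARE"))
  terms <- expr_term_set(e)
  expect_length(terms, 2L)
  expect_setequal(terms, c("Nrf2=1&ARE=0", "Nrf2=1&Bach1=0"))
  expect_equal(expr_truth_table(e, c("Nrf2", "Bach1", "ARE")), tt)
})

test_that("minimization handles constants and non-mergeable tables", {
  one <- minimize_sop(rep(1L, 4), c("a", "b"))
  expect_equal(one$type, "const")
  expect_equal(one$value, 1L)
  zero <- minimize_sop(rep(0L, 8), c("a", "b", "c"))
  expect_equal(zero$value, 0L)
  # XOR: two terms of two literals each, nothing merges
  xor <- minimize_sop(c(0L, 1L, 1L, 0L), c("a", "b"))
  expect_setequal(expr_term_set(xor), c("a=0&b=1", "a=1&b=0"))
  # don't-cares are exploited: 1 at 11, dc elsewhere except 00=0
  e <- minimize_sop(c(0L, NA, NA, 1L), c("a", "b"))
  expect_length(expr_term_set(e), 1L)
})

test_that("minimizer output is equivalent, prime, and minimal (oracle check)", {
  set.seed(11)
  for (rep in 1:60) {
    k <- sample(2:4, 1L)
    vars <- letters[seq_len(k)]
    vals <- sample(c(0L, 1L, NA), 2^k, replace = TRUE,
                   prob = c(0.35, 0.45, 0.2))
    e <- minimize_sop(vals, vars)
    tt <- expr_truth_table(e, vars)
    # equivalent on every specified cell
    spec_cells <- which(!is.na(vals))
    expect_equal(tt[spec_cells], vals[spec_cells], info = paste(vals, collapse = ""))
    terms <- attr(e, "terms")
    # every term is prime: dropping any literal lets it cover a 0-cell
    if (nrow(terms) > 0 && e$type != "const") {
      off <- which(vals == 0L) - 1L
      for (i in seq_len(nrow(terms))) for (j in seq_len(k)) {
        if (terms[i, j] == "-") next
        t2 <- terms[i, ]; t2[j] <- "-"
        fixed <- t2 != "-"
        covered <- Filter(function(d) {
          b <- bitwAnd(bitwShiftR(d, (k - 1L):0), 1L)
          all(b[fixed] == as.integer(t2[fixed]))
        }, 0:(2^k - 1L))
        expect_true(any(covered %in% off),
                    info = paste("non-prime term", paste(terms[i, ], collapse = "")))
      }
    }
    # term count matches the brute-force optimum
    n_terms <- if (e$type == "const") as.integer(e$value == 1L) else nrow(terms)
    expect_equal(n_terms, oracle_min_terms(vals, k),
                 info = paste(vals, collapse = ","))
  }
})

test_that("compiling the shipped pathways reproduces the fixture network", {
  segs <- fixture_pathways()
  cfg <- read_overrides(fixture_overrides_path())
  net <- compile_network(segs, cfg)
  fix <- fixture_oxidative_stress()
  expect_equal(net$state_nodes, fix$state_nodes)
  for (s in 0:63) for (stress in 0:1)
    expect_equal(step_network(net, s, c(Stress = stress)),
                 step_network(fix, s, c(Stress = stress)),
                 info = paste("state", s, "stress", stress))
})

test_that("compilation failure modes are reported", {
  expect_error(compile_network(list(), list()), "no state nodes")
  segs <- fixture_pathways()
  cfg <- read_overrides(fixture_overrides_path())
  cfg$overrides$ARE <- cfg$overrides$ARE[-1L]  # drop one conflict resolution
  expect_error(compile_network(segs, cfg), "unresolved conflict")
})

test_that("a different biological override yields a different but valid model", {
  segs <- fixture_pathways()
  cfg <- read_overrides(fixture_overrides_path())
  cfg$overrides$ARE[["110"]] <- 0L  # let the repressor win the contested cell
  net <- compile_network(segs, cfg)
  fix <- fixture_oxidative_stress()
  same <- TRUE
  for (s in 0:63)
    if (step_network(net, s, c(Stress = 1)) != step_network(fix, s, c(Stress = 1)))
      same <- FALSE
  expect_false(same)
  # still a single attractor containing the resting state under no stress
  att <- find_attractors(build_stg(net, c(Stress = 0)))
  expect_true(18 %in% unlist(att$cycles))
})
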