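test_that("sequences validate, normalize T/lowercase, and reject junk", {
  s <- rna_sequence("gatUac", id = "x")
  expect_equal(s$seq, "GAUUAC")
  expect_equal(s$n, 6L)
  expect_error(rna_sequence("GANC"), "position 3")
  expect_error(rna_sequence(""), "at least one")
})

test_that("dot-bracket parsing matches hand examples and round-trips", {
  expect_equal(nrow(parse_dot_bracket(".....")$pairs), 0L)
  expect_equal(parse_dot_bracket(".....")$n, 5L)
  expect_equal(parse_dot_bracket("(...)")$pairs, rbind(c(1L, 5L)))
  expect_error(parse_dot_bracket("((..))."), "theta")
  expect_error(parse_dot_bracket("(.."), "unmatched '\\(' at position 1")
  expect_error(parse_dot_bracket("...)"), "unmatched '\\)' at position 4")
  expect_error(parse_dot_bracket("..x.."), "position 3")
  # render inverse on random nested structures
  for (seed in 1:10) {
    S <- rand_structure(seed, n = 18L)
    expect_equal(parse_dot_bracket(format_dot_bracket(S))$pairs, S$pairs)
  }
})

test_that("structure construction rejects clashes, crossings, bad theta", {
  expect_error(secondary_structure(rbind(c(1, 4)), n = 8), "theta")
  expect_error(secondary_structure(rbind(c(1, 6), c(1, 8)), n = 8), "more than one pair")
  expect_error(secondary_structure(rbind(c(1, 6), c(2, 8)), n = 9), "cross")
  # nested pairs in arbitrary input order are fine
  expect_no_error(secondary_structure(rbind(c(2, 6), c(1, 8)), n = 9))
})

test_that("base-pair distance is the symmetric difference of the pair sets", {
  S <- secondary_structure(rbind(c(1, 5)), n = 8)
  expect_equal(bp_distance(S, secondary_structure(rbind(c(1, 5)), n = 8)), 0L)
  expect_equal(bp_distance(S, secondary_structure(NULL, n = 8)), 1L)
  # hand count on raw pair sets: {(1,8),(2,7)} vs {(2,7),(3,8)} share one pair
  expect_equal(bf_bp_distance(rbind(c(1, 8), c(2, 7)), rbind(c(2, 7), c(3, 8))), 2L)
  A <- secondary_structure(rbind(c(1, 8), c(2, 7)), n = 8)
  B <- secondary_structure(rbind(c(2, 7)), n = 8)
  expect_equal(bp_distance(A, B), 1L)
  expect_error(bp_distance(A, secondary_structure(NULL, n = 9)), "length")
})

test_that("distance symmetry and triangle inequality hold on random structures", {
  for (seed in 1:12) {
    n <- 16L
    A <- rand_structure(seed, n); B <- rand_structure(seed + 100L, n)
    C <- rand_structure(seed + 200L, n)
    expect_identical(bp_distance(A, B), bp_distance(B, A))
    expect_identical(bp_distance(A, B), bf_bp_distance(A$pairs, B$pairs))
    expect_lte(bp_distance(A, C), bp_distance(A, B) + bp_distance(B, C))
    expect_identical(bp_distance(A, A), 0L)
  }
})

test_that("restriction keeps boundary-inclusive pairs and composes", {
  S <- secondary_structure(rbind(c(1, 10), c(3, 8)), n = 10)
  expect_equal(restrict_structure(S, 3, 8)$pairs, rbind(c(3L, 8L)))
  expect_equal(nrow(restrict_structure(secondary_structure(rbind(c(1, 10)), n = 10), 2, 9)$pairs), 0L)
  expect_equal(nrow(restrict_structure(secondary_structure(NULL, n = 10), 4, 7)$pairs), 0L)
  expect_error(restrict_structure(S, 0, 5), "out of range")
  for (seed in 1:8) {
    S <- rand_structure(seed, 20L)
    r1 <- restrict_structure(restrict_structure(S, 3, 18), 5, 15)
    r2 <- restrict_structure(S, 5, 15)
    expect_equal(r1$pairs, r2$pairs)
    expect_equal(r2$pairs, bf_restrict_pairs(S$pairs, 5, 15))
  }
})

test_that("the distance bound matches its closed form and dominates the ensemble", {
  expect_equal(max_distance_bound(secondary_structure(NULL, n = 5)), 1L)
  expect_equal(max_distance_bound(secondary_structure(rbind(c(1, 5)), n = 5)), 2L)
  expect_equal(max_distance_bound(secondary_structure(NULL, n = 3)), 0L)
  # oracle verification: no enumerated structure exceeds the bound
  for (seed in c(3, 9)) {
    inst <- rand_instance(seed, nmin = 12L, nmax = 14L)
    K <- max_distance_bound(inst$Sstar)
    dmax <- max(vapply(inst$structures, function(p) bf_bp_distance(p, inst$Sstar$pairs), integer(1)))
    expect_lte(dmax, K)
    expect_lt(K, inst$n)
  }
})

test_that("compatibility reports admissible Watson-Crick and wobble pairs", {
  S <- secondary_structure(rbind(c(1, 5)), n = 5)
  expect_equal(nrow(validate_compatibility("GAAAC", S)), 0L)
  expect_equal(nrow(validate_compatibility("GAAAU", S)), 0L)  # G-U wobble
  bad <- validate_compatibility("AAAAA", S)
  expect_equal(bad$i, 1L)
  expect_equal(bad$j, 5L)
  expect_error(validate_compatibility("AAAA", S), "length")
})
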