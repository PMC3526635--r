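test_that("profile statistics match closed forms", {
  mk <- function(p) rnaprof:::new_structural_profile(p, p_full = p, digits = NA_integer_,
    meta = list(seq_id = "toy", n = length(p), reference = "", model = "nussinov",
                theta = 3L, RT = 1, Z = 1, bound = length(p) - 1L,
                method = "test", imag_residual = 0, pre_truncation_mass = 1))
  st <- profile_stats(mk(c(0.25, 0.5, 0.25)))
  expect_equal(st$mean, 1)
  expect_equal(st$sd, sqrt(0.5))
  expect_equal(st$cv, sqrt(0.5))
  st0 <- profile_stats(mk(1))
  expect_equal(st0$mean, 0)
  expect_equal(st0$sd, 0)
  expect_true(is.na(st0$cv))
  e <- exp(1)
  stg <- profile_stats(structure_profile("GAAAC", ".....", model = nussinov_model(RT = 1)))
  expect_equal(stg$mean, e / (1 + e), tolerance = 1e-10)
})

test_that("expected distance agrees between the FFT pipeline and enumeration", {
  mod <- nussinov_model(RT = 1)
  expect_equal(expected_distance_to("AAAAA", ".....", mod), 0)
  expect_equal(expected_distance_to("GAAAC", ".....", mod), exp(1) / (1 + exp(1)),
               tolerance = 1e-10)
  for (seed in c(4, 14)) {
    inst <- rand_instance(seed + 3100L, nmin = 10L, nmax = 20L)
    mu_fft <- expected_distance_to(inst$seq, inst$Sstar, nussinov_model())
    mu_ex <- profile_stats(exact_profile(inst$seq, inst$Sstar, nussinov_model()))$mean
    expect_equal(mu_fft, mu_ex, tolerance = 1e-8)
  }
})

test_that("window scans have the right geometry and flat/zero baselines", {
  mod <- nussinov_model()
  tr <- window_scan(strrep("A", 10), ".....", model = mod)
  expect_equal(tr$offset, 1:6)  # floor((10-5)/1)+1 windows
  # a target with pairs over an unpairable sequence: flat track = |pairs|
  tr2 <- window_scan(strrep("A", 12), "((...))", model = mod)
  expect_true(all(abs(tr2$expected_distance - 2) < 1e-9))
  # a sequence equal to its own unpaired target: distance 0 at offset 1
  tr3 <- window_scan("AAAAA", ".....", model = mod)
  expect_equal(tr3$expected_distance[1], 0)
  expect_error(window_scan("AAAA", ".....", model = mod), "exceeds")
  tr4 <- window_scan(strrep("A", 12), "((...))", step = 2L, model = mod)
  expect_equal(tr4$offset, seq(1, 6, by = 2))
})

test_that("an embedded hairpin is localized by the scan minimum", {
  hp <- embed_hairpin(60, seed = 91L, stem = 5L, loop = 4L, offset = 23L)
  tr <- window_scan(hp$seq, hp$target, model = nussinov_model())
  expect_equal(tr$offset[which.min(tr$expected_distance)], 23L)
})

test_that("prefix scans return one normalized profile per length", {
  mod <- nussinov_model()
  ps1 <- prefix_scan("CCCCAAAAGGGGAAAACCCC", from = 20, to = 20, model = mod)
  expect_equal(length(attr(ps1, "profiles")), 1L)
  ps <- prefix_scan("CCCCAAAAGGGGAAAACCCC", from = 10, to = 20, model = mod, ref = "mfe")
  profs <- attr(ps, "profiles")
  expect_equal(length(profs), 11L)
  for (pr in profs) {
    expect_lt(abs(sum(profile_probabilities(pr)) - 1), 1e-9)
  }
  # the two-state toy shows a multimodal profile at some prefix length
  locmax <- function(p) {
    sum(vapply(seq_along(p), function(k) {
      v <- p[k]
      v > 1e-6 && v > (if (k > 1) p[k - 1] else -1) && v > (if (k < length(p)) p[k + 1] else -1)
    }, logical(1)))
  }
  modes <- vapply(profs, function(pr) locmax(profile_probabilities(pr)), numeric(1))
  expect_gte(max(modes), 2)
  expect_error(prefix_scan("GAAAC", 3, 9, model = mod), "from <= to <= n")
})

test_that("MFE structures minimize energy over the enumerated ensemble", {
  for (seed in c(6, 16)) {
    sq <- random_rna(withr::with_seed(seed, sample(10:16, 1)), seed = 3500L + seed)
    en <- enumerate_structures(sq)
    for (mod in list(nussinov_model(), turner_model())) {
      best <- min(vapply(en$structures, function(p) {
        structure_energy(sq, secondary_structure(p, n = sq$n), mod)
      }, numeric(1)))
      mfe <- mfe_structure(sq, mod)
      expect_equal(structure_energy(sq, mfe, mod), best, tolerance = 1e-9)
    }
  }
  expect_equal(format_dot_bracket(mfe_structure("GGGGAAAACCCC", turner_model())),
               "((((....))))")
})
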