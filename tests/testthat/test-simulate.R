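test_that("alignment simulator is deterministic and hits the JC69 scale", {
  spec <- data.frame(label = c("A", "B"), n = 1L, d = 0.025)
  s1 <- simulate_alignment(spec, length = 1300L, seed = 5)
  s2 <- simulate_alignment(spec, length = 1300L, seed = 5)
  expect_identical(s1$alignment$matrix, s2$alignment$matrix)
  z <- simulate_alignment(data.frame(label = c("A", "B"), n = 2L, d = 0),
                          length = 200L, seed = 5)
  pd <- pairwise_p_distance(z$alignment)
  expect_true(all(pd$d == 0))
  # outputs satisfy the consuming types' invariants
  expect_s3_class(s1$alignment, "seq_alignment")
  expect_equal(sort(names(s1$groups)), sort(s1$alignment$ids))
  m <- simulate_alignment(spec, length = 500L, seed = 6, missing_frac = 0.2)
  expect_gt(mean(m$alignment$matrix == "N"), 0.1)
})

test_that("morphometric simulator respects its allometric contract", {
  spec <- data.frame(label = "a", n_male = 10L, n_female = 0L,
                     svl_mean = 25, svl_sd = 2,
                     HL_slope = 0.35, HL_offset = 1, HL_noise = 0)
  tab <- simulate_morphometrics(spec, variables = "HL", seed = 3)
  expect_equal(tab$HL, 0.35 * tab$SVL + 1, tolerance = 1e-12)
  expect_identical(tab, simulate_morphometrics(spec, variables = "HL",
                                               seed = 3))
  expect_true(all(tab$SVL > 0))
})

test_that("offset differences of 5 noise SDs are detected with high power", {
  spec <- data.frame(label = c("a", "b"), n_male = 20L, n_female = 0L,
                     svl_mean = 25, svl_sd = 2,
                     HL_slope = 0.35, HL_offset = c(1, 1 + 5 * 0.2),
                     HL_noise = 0.2)
  hits <- vapply(1:200, function(s) {
    tab <- simulate_morphometrics(spec, variables = "HL", seed = 1000 + s)
    sc <- size_correct(tab, variables = "HL")
    res <- pairwise_tests(sc, variables = "HL", sexes = "male",
                          adjust = "none")
    res$p < 0.05
  }, logical(1L))
  expect_gte(mean(hits), 0.95)
})

test_that("call synthesis is reproducible and robust to noise", {
  a <- synthesize_call(n_notes = 2L, note_s = 0.1, gap_s = 0.2,
                       f_start = 2000, snr_db = 20, seed = 4)
  b <- synthesize_call(n_notes = 2L, note_s = 0.1, gap_s = 0.2,
                       f_start = 2000, snr_db = 20, seed = 4)
  expect_identical(a$samples, b$samples)
  clean <- synthesize_call(n_notes = 3L, note_s = 0.12, gap_s = 0.25,
                           f_start = 2400)
  noisy <- synthesize_call(n_notes = 3L, note_s = 0.12, gap_s = 0.25,
                           f_start = 2400, snr_db = 20, seed = 4)
  expect_equal(nrow(segment_notes(noisy)), nrow(segment_notes(clean)))
  expect_error(synthesize_call(f_start = 15000, harmonics_db = c(-10, -10)),
               "Nyquist")
})

test_that("locality and environment simulators honour their contracts", {
  cl <- data.frame(species = "a", lon = -78.5, lat = -3.2, spread_km = 0,
                   n = 5L)
  pts <- simulate_localities(cl, seed = 2)
  expect_equal(aoo(pts), 4)
  expect_equal(eoo(pts), 0)
  expect_identical(pts, simulate_localities(cl, seed = 2))

  sh <- rbind(a = rep(0, 11), b = rep(1, 11))
  env <- simulate_env(sh, n = 6, seed = 2)
  expect_identical(env, simulate_env(sh, n = 6, seed = 2))
  expect_equal(nrow(env), 12L)
  expect_no_error(validate_env_matrix(env))
  badcor <- matrix(-1, 11, 11); diag(badcor) <- 1
  expect_error(simulate_env(sh, n = 4, correlation = badcor, seed = 1),
               "positive semi-definite")
})

test_that("strong temperature shifts separate species on PC1", {
  # at the default block correlation the long-run no-overlap rate is ~0.90;
  # assert a bound 2.7 binomial SEs below it so the check is stable
  hits <- vapply(1:200, function(s) {
    shifts <- rbind(a = rep(0, 11), b = c(rep(4, 5), rep(0, 6)))
    env <- simulate_env(shifts, n = 10, seed = 2000 + s)
    pca <- run_pca(env)
    sa <- range(pca$scores[env$species == "a", 1L])
    sb <- range(pca$scores[env$species == "b", 1L])
    sa[2] < sb[1] || sb[2] < sa[1]
  }, logical(1L))
  expect_gte(mean(hits), 0.85)
})
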