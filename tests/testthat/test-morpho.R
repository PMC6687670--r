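test_that("descriptive statistics match independent recomputation", {
  tab <- data.frame(specimen_id = paste0("s", 1:5), species = "alpha",
                    sex = "female", stage = "adult",
                    SVL = c(29.4, 29.5, 35.3, 30.0, 32.3))
  ds <- descriptive_stats(tab, variables = "SVL")
  x <- tab$SVL
  m <- sum(x) / length(x)
  s <- sqrt(sum((x - m)^2) / (length(x) - 1))
  expect_equal(round(ds$mean, 2), round(m, 2))
  expect_equal(round(ds$sd, 2), round(s, 2))
  expect_equal(ds$n, 5L)

  const <- data.frame(specimen_id = paste0("c", 1:3), species = "beta",
                      sex = "male", stage = "adult", SVL = c(3, 3, 3))
  expect_equal(descriptive_stats(const, variables = "SVL")$formatted,
               "3.0 ± 0.0; 3.0–3.0")

  single <- data.frame(specimen_id = "u1", species = "gamma", sex = "female",
                       stage = "adult", SVL = 38.6)
  ds1 <- descriptive_stats(single, variables = "SVL")
  expect_equal(ds1$formatted, "38.6")   # bare value when n = 1
  expect_true(is.na(ds1$sd))
  expect_equal(c(ds1$min, ds1$max), c(38.6, 38.6))
  expect_error(descriptive_stats(tab[0, ]), "empty")
})

test_that("size correction recovers exact and noisy allometries", {
  set.seed(11)
  svl <- runif(40, 20, 35)
  tab <- data.frame(specimen_id = paste0("s", 1:40), species = "alpha",
                    sex = rep(c("male", "female"), 20), stage = "adult",
                    SVL = svl,
                    HL = 0.3 * svl + 1,   # exact line
                    HW = svl)             # identity
  sc <- size_correct(tab, variables = c("HL", "HW"))
  expect_true(all(abs(sc$data$HL_resid) < 1e-9))
  hw <- sc$fits[sc$fits$variable == "HW", ]
  expect_equal(hw$slope, c(1, 1), tolerance = 1e-9)
  expect_equal(hw$intercept, c(0, 0), tolerance = 1e-9)

  # parameter recovery under noise
  set.seed(12)
  svl2 <- rnorm(200, 28, 3)
  tab2 <- data.frame(specimen_id = paste0("n", 1:200), species = "alpha",
                     sex = "male", stage = "adult", SVL = svl2,
                     HL = 0.35 * svl2 + 0.5 + rnorm(200, 0, 0.1))
  sc2 <- size_correct(tab2, variables = "HL")
  se <- 0.1 / sqrt(sum((svl2 - mean(svl2))^2))
  expect_lt(abs(sc2$fits$slope - 0.35), 3 * se)
  # residuals orthogonal to SVL and centered
  expect_lt(abs(cor(sc2$data$HL_resid, sc2$data$SVL)), 1e-8)
  expect_lt(abs(sum(sc2$data$HL_resid)), 1e-9 * nrow(tab2))

  bad <- tab2; bad$SVL <- 25
  expect_error(size_correct(bad, variables = "HL"), "zero variance")
})

test_that("rank test: exact extremes, symmetry, degenerate ties", {
  rt <- rank_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(rt$p, 0.1)       # 2 of the 20 label arrangements are as extreme
  expect_equal(rt$method, "exact enumeration")
  same <- rank_test(c(2, 5, 7, 7), c(5, 7, 2, 7))
  expect_equal(same$Z, 0)
  expect_equal(same$p, 1)
  const <- rank_test(rep(4, 5), rep(4, 6))
  expect_equal(const$Z, 0)
  expect_equal(const$p, 1)
  # Z antisymmetric under swapping samples
  a <- rnorm(15); b <- rnorm(15) + 1
  expect_equal(rank_test(a, b)$Z, -rank_test(b, a)$Z, tolerance = 1e-12)
})

test_that("normal-approximation p tracks exact/permutation references", {
  # exhaustive small-sample grid: the returned p IS the exact enumeration
  # value, matching the base distribution function for untied data
  set.seed(21)
  for (nx in 2:6) for (ny in 2:6) {
    x <- rnorm(nx); y <- rnorm(ny)
    rt <- rank_test(x, y)             # exact branch (nx+ny <= 12)
    p_ref <- min(1, 2 * min(pwilcox(rt$U, nx, ny),
                            1 - pwilcox(rt$U - 1, nx, ny)))
    expect_equal(rt$p, p_ref, tolerance = 1e-12)
  }
  # where the normal branch is used, it stays within 0.02 of exact across
  # the whole support
  for (n in c(7L, 10L, 15L)) {
    mu <- n * n / 2
    sig <- sqrt(n * n * (2 * n + 1) / 12)
    for (u in 0:(n * n)) {
      exact <- min(1, 2 * min(pwilcox(u, n, n), 1 - pwilcox(u - 1, n, n)))
      normp <- 2 * pnorm(-max(abs(u - mu) - 0.5, 0) / sig)
      expect_lt(abs(exact - normp), 0.02)
    }
  }
  # larger samples: permutation oracle on one drawn data set
  set.seed(22)
  x <- rnorm(15); y <- rnorm(15, 0.8)
  rt <- rank_test(x, y)
  pooled <- c(x, y)
  r <- rank(pooled)
  mu <- 15 * 31 / 2
  obs <- abs(sum(r[1:15]) - mu)
  perm <- replicate(1e5, {
    idx <- sample.int(30, 15)
    abs(sum(r[idx]) - mu)
  })
  p_perm <- mean(perm >= obs - 1e-9)
  expect_lt(abs(rt$p - p_perm), 0.01)
})

test_that("batch pairwise tests count results and adjust p-values", {
  tab <- toy_morpho()
  sc <- size_correct(tab)
  res <- pairwise_tests(sc, variables = "HL", adjust = "none")
  expect_equal(nrow(res), 2L)          # 1 pair x 1 variable x 2 sexes
  expect_equal(res$p_adjusted, res$p)
  res_h <- pairwise_tests(sc, variables = "HL", adjust = "holm")
  expect_true(all(res_h$p_adjusted >= res_h$p))
  # Holm on {0.01, 0.04} -> {0.02, 0.04}
  expect_equal(p.adjust(c(0.01, 0.04), "holm"), c(0.02, 0.04))
  expect_error(pairwise_tests(sc, species = c("alpha", "nope")), "unknown")
})

test_that("discriminant classification separates and reports correctly", {
  # two groups 10 within-group SDs apart on every variable
  set.seed(31)
  n <- 30L
  mk <- function(label, shift) data.frame(
    specimen_id = paste0(label, 1:n), species = label, sex = "female",
    stage = "adult",
    SVL = rnorm(n, 25 + shift), HL = rnorm(n, 9 + shift),
    HW = rnorm(n, 9 + shift), TD = rnorm(n, 5 + shift),
    ED = rnorm(n, 3 + shift))
  dfa <- discriminant_classify(rbind(mk("a", 0), mk("b", 10)), sex = "female")
  expect_equal(dfa$rate, 100)
  expect_equal(dfa$correct, sum(diag(dfa$confusion)))
  expect_equal(sum(dfa$confusion), dfa$total)
  expect_equal(rowSums(dfa$confusion), c(a = n, b = n))

  # identical distributions: resubstitution rate near chance
  rates <- vapply(1:100, function(s) {
    set.seed(s)
    d <- rbind(mk("a", 0), mk("b", 0))
    d$species <- rep(c("a", "b"), each = n)
    discriminant_classify(d, sex = "female")$rate
  }, numeric(1L))
  expect_gt(mean(rates), 40)
  expect_lt(mean(rates), 70)
})

test_that("reported classification rate identity holds", {
  expect_equal(round(classification_rate(64, 83), 1), 77.1)
  expect_error(classification_rate(5, 0), "positive")
})
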