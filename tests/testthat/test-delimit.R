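test_that("single-lineage decisions follow the integrative rules", {
  expect_equal(evaluate_lineage("x", TRUE)$status, "UCS")
  expect_equal(evaluate_lineage("x", TRUE, morphology = "divergent")$status,
               "CCS")
  expect_equal(evaluate_lineage("x", TRUE, morphology = "not_divergent",
                                acoustics = "not_divergent")$status, "DCL")
  expect_equal(evaluate_lineage("x", FALSE, morphology = "divergent")$status,
               "conspecific")
  expect_error(evaluate_lineage("x", TRUE, morphology = "odd"))
})

test_that("every evidence state maps to exactly one status", {
  states <- c("divergent", "not_divergent", "unavailable")
  grid <- expand.grid(g = c(TRUE, FALSE), m = states, a = states, e = states,
                      stringsAsFactors = FALSE)
  st <- vapply(seq_len(nrow(grid)), function(i)
    evaluate_lineage("x", grid$g[i], grid$m[i], grid$a[i], grid$e[i])$status,
    character(1L))
  expect_equal(length(st), 54L)
  expect_true(all(st %in% c("CCS", "UCS", "DCL", "conspecific")))
  expect_true(all(st[!grid$g] == "conspecific"))
  any_div <- grid$m == "divergent" | grid$a == "divergent" |
    grid$e == "divergent"
  all_unavail <- grid$m == "unavailable" & grid$a == "unavailable" &
    grid$e == "unavailable"
  expect_true(all(st[grid$g & any_div] == "CCS"))
  expect_true(all(st[grid$g & all_unavail] == "UCS"))
  expect_true(all(st[grid$g & !any_div & !all_unavail] == "DCL"))
})

test_that("reports aggregate counts and demand complete evidence", {
  ev <- data.frame(
    lineage = paste0("L", 1:20),
    genetic_exceeds_threshold = TRUE,
    morphology = c(rep("divergent", 17), rep("unavailable", 3)),
    acoustics = "unavailable", environment = "unavailable",
    stringsAsFactors = FALSE)
  rep <- delimit_all(evidence = ev)
  expect_equal(unname(rep$counts[c("n_CCS", "n_UCS", "n_DCL")]),
               c(17L, 3L, 0L))
  empty <- delimit_all(evidence = ev[0, ])
  expect_equal(nrow(empty$decisions), 0L)
  all_nd <- ev
  all_nd$morphology <- "not_divergent"
  expect_true(all(delimit_all(evidence = all_nd)$decisions$status == "DCL"))

  # partition join requires one evidence row per cluster
  b <- matrix(c(0, 5, 5, 0), 2, 2, dimnames = list(c("p", "q"), c("p", "q")))
  part <- identify_candidates(group_dist_summary(b), 0.02)
  expect_error(delimit_all(part, ev), "no evidence")
})

test_that("rule-based morphology flag follows the all-neighbours convention", {
  tests <- data.frame(
    species_a = c("a", "a", "a", "b"), species_b = c("b", "b", "c", "c"),
    sex = "female", variable = c("HL", "HW", "HL", "HL"),
    Z = 1, p = c(0.001, 0.2, 0.01, 0.5),
    p_adjusted = c(0.004, 0.4, 0.04, 0.9), n_a = 5, n_b = 5,
    stringsAsFactors = FALSE)
  expect_equal(morphology_flag(tests, "a"), "divergent")
  expect_equal(morphology_flag(tests, "b"), "not_divergent")
  expect_equal(morphology_flag(tests, "zz"), "unavailable")
})

test_that("end-to-end synthetic study returns the designed decision vector", {
  # four lineages: two well separated with characters, one distinct but
  # character-less, one within threshold of the first
  sim <- simulate_alignment(
    data.frame(label = c("sp1", "sp1b", "sp2", "sp3"),
               n = c(3L, 2L, 3L, 2L),
               d = c(0.000, 0.002, 0.035, 0.080)),
    length = 1300L, seed = 71)
  gs <- group_distance_summary(sim$alignment, sim$groups, n_boot = 0L,
                               seed = 71)
  part <- identify_candidates(gs, 0.02)
  labs <- lineage_labels(part)
  expect_equal(length(labs), 3L)               # sp1+sp1b merged
  expect_true("sp1+sp1b" %in% labs)
  ev <- data.frame(
    lineage = labs, genetic_exceeds_threshold = TRUE,
    morphology = ifelse(labs == "sp3", "unavailable", "divergent"),
    acoustics = "unavailable", environment = "unavailable",
    stringsAsFactors = FALSE)
  rep <- delimit_all(part, ev)
  st <- setNames(rep$decisions$status, rep$decisions$lineage)
  expect_equal(unname(st["sp1+sp1b"]), "CCS")
  expect_equal(unname(st["sp2"]), "CCS")
  expect_equal(unname(st["sp3"]), "UCS")
  # the merged pair records the within-threshold member as conspecific
  ev2 <- rbind(ev, data.frame(lineage = "sp1b-alone",
                              genetic_exceeds_threshold = FALSE,
                              morphology = "divergent",
                              acoustics = "unavailable",
                              environment = "unavailable"))
  rep2 <- delimit_all(evidence = ev2)
  expect_equal(rep2$decisions$status[rep2$decisions$lineage == "sp1b-alone"],
               "conspecific")
})
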