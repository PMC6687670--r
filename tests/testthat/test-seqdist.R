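test_that("FASTA round trip preserves records and normalizes symbols", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">s1", "ACGTACGTAC",
               ">s2", "acgt-nACGT",
               ">s3", "ACGUACGUAC"), path)
  aln <- read_alignment(path)
  expect_s3_class(aln, "seq_alignment")
  expect_equal(aln$length, 10L)
  expect_equal(aln$ids, c("s1", "s2", "s3"))
  expect_equal(paste(aln$matrix["s2", ], collapse = ""), "ACGT-NACGT")
  # U mapped to T
  expect_equal(paste(aln$matrix["s3", ], collapse = ""), "ACGTACGTAC")
  out <- withr::local_tempfile(fileext = ".fasta")
  write_alignment(aln, out)
  expect_equal(read_alignment(out)$matrix, aln$matrix)
})

test_that("malformed alignments are rejected with the offending record", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACGTACGTAC", ">b", "ACGTACGTA"), path)
  expect_error(read_alignment(path), "record 2")
  expect_error(seq_alignment(c(x = "ACGX")), "illegal symbol 'X'.*position 4")
  expect_error(seq_alignment(c(a = "ACGT", a = "ACGT")), "duplicated")
})

test_that("p-distance handles identity, mismatch, gaps and empty overlap", {
  aln <- seq_alignment(c(a = "ACGT", b = "ACGA", c = "AC-T", d = "A---",
                         e = "ACGT"))
  pd <- pairwise_p_distance(aln)
  expect_equal(pd$d["a", "e"], 0)
  expect_equal(pd$n_sites["a", "e"], 4L)
  expect_equal(pd$d["a", "b"], 0.25)
  expect_equal(pd$d["a", "c"], 0)           # gap excluded pairwise
  expect_equal(pd$n_sites["a", "c"], 3L)
  f <- seq_alignment(c(x = "A---", y = "-CGT"))
  pf <- pairwise_p_distance(f)
  expect_true(is.na(pf$d["x", "y"]))
  expect_equal(pf$n_sites["x", "y"], 0L)
})

test_that("p-distance matches the nested-loop oracle and stays symmetric", {
  set.seed(101)
  for (rep in 1:25) {
    aln <- random_alignment(sample(2:6, 1L), sample(10:50, 1L))
    pd <- pairwise_p_distance(aln)
    expect_equal(pd$d, t(pd$d))
    expect_true(all(diag(pd$d) == 0))
    n <- length(aln$ids)
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      o <- oracle_p_distance(paste(aln$matrix[i, ], collapse = ""),
                             paste(aln$matrix[j, ], collapse = ""))
      expect_equal(pd$d[i, j], o$d)
      expect_equal(pd$n_sites[i, j], o$n)
    }
  }
})

test_that("p-distance agrees with an independent phylogenetics library", {
  skip_if_not_installed("ape")
  set.seed(77)
  aln <- random_alignment(6, 200, missing_frac = 0)
  pd <- pairwise_p_distance(aln)
  tmp <- withr::local_tempfile(fileext = ".fasta")
  write_alignment(aln, tmp)
  ref <- as.matrix(ape::dist.dna(ape::read.FASTA(tmp), model = "raw",
                                 pairwise.deletion = TRUE))
  expect_equal(unname(pd$d), unname(ref[aln$ids, aln$ids]), tolerance = 1e-12)
})

test_that("group summary reproduces hand-enumerated pair means", {
  # 4 sequences, 2 groups; brute-force mean over all pairs
  aln <- seq_alignment(c(a1 = "ACGTACGTAC", a2 = "ACGTACGTAA",
                         b1 = "TCGTACGGAC", b2 = "TCGAACGGAC"))
  groups <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B")
  gs <- group_distance_summary(aln, groups, n_boot = 0L, seed = 1)
  cross <- c(oracle_p_distance("ACGTACGTAC", "TCGTACGGAC")$d,
             oracle_p_distance("ACGTACGTAC", "TCGAACGGAC")$d,
             oracle_p_distance("ACGTACGTAA", "TCGTACGGAC")$d,
             oracle_p_distance("ACGTACGTAA", "TCGAACGGAC")$d)
  expect_equal(gs$between_mean["A", "B"], 100 * mean(cross), tolerance = 1e-12)
  expect_equal(gs$within_mean[["A"]],
               100 * oracle_p_distance("ACGTACGTAC", "ACGTACGTAA")$d,
               tolerance = 1e-12)
  # n_boot = 0: SEs missing, means unchanged
  expect_true(all(is.na(gs$se_within)))
})

test_that("identical-within groups give zero within mean and zero SE", {
  s1 <- strrep("ACGTACGTAC", 2)
  s2 <- sub("^AC", "GT", s1)  # differs at 2 of 20 sites
  aln <- seq_alignment(c(a1 = s1, a2 = s1, b1 = s2, b2 = s2))
  gs <- group_distance_summary(aln, c(a1 = "A", a2 = "A", b1 = "B", b2 = "B"),
                               n_boot = 50L, seed = 3)
  expect_equal(gs$between_mean["A", "B"], 10)
  expect_equal(gs$within_mean[["A"]], 0)
  expect_equal(gs$se_within[["A"]], 0)
  # singleton group flagged NA
  gs1 <- group_distance_summary(aln, c(a1 = "A", a2 = "A", b1 = "B", b2 = "C"),
                                n_boot = 0L, seed = 1)
  expect_true(is.na(gs1$within_mean[["B"]]))
})

test_that("bootstrap SE shrinks as alignment length grows", {
  se_at <- function(len, seed) {
    sim <- simulate_alignment(data.frame(label = c("A", "B"), n = 2L,
                                         d = 0.03),
                              length = len, seed = seed, d_within = 0.002)
    gs <- group_distance_summary(sim$alignment, sim$groups, n_boot = 120L,
                                 seed = seed)
    gs$se_between["A", "B"]
  }
  short <- mean(vapply(1:4, function(s) se_at(300L, s), numeric(1L)))
  long <- mean(vapply(1:4, function(s) se_at(1200L, s + 10L), numeric(1L)))
  expect_lt(long, short)
})

test_that("the published-table CSV layout round-trips", {
  gs <- read_group_summary_csv(table2_path())
  expect_equal(length(gs$groups), 20L)
  expect_equal(gs$between_mean["gloria", "CCS2"], 2.0)
  expect_true(is.na(gs$within_mean[["hampatusami"]]))
  out <- withr::local_tempfile(fileext = ".csv")
  write_group_summary_csv(gs, out)
  back <- read_group_summary_csv(out)
  expect_equal(back$between_mean, gs$between_mean, tolerance = 1e-9)
  expect_equal(is.na(back$within_mean), is.na(gs$within_mean))
})

test_that("threshold clustering is strict and monotone in the threshold", {
  gs <- read_group_summary_csv(table2_path())
  eps_part <- identify_candidates(gs, 1e-6)
  expect_equal(length(eps_part$clusters), 20L)
  counts <- vapply(c(0.015, 0.02, 0.025, 0.03, 0.05, 0.08),
                   function(th) length(identify_candidates(gs, th)$clusters),
                   integer(1L))
  expect_true(all(diff(counts) <= 0))
  # strict <: the 2.0% pair does not merge at threshold 0.02
  p <- identify_candidates(gs, 0.02)
  labs <- lineage_labels(p)
  expect_true("gloria" %in% labs && "CCS2" %in% labs)
  # missing between entry is reported with the pair
  b <- gs$between_mean[1:3, 1:3]
  b["atillo", "chomskyi"] <- NA; b["chomskyi", "atillo"] <- NA
  expect_error(identify_candidates(group_dist_summary(b), 0.02),
               "atillo-chomskyi")
})
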