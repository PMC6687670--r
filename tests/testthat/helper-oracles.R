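# Independent site-counting oracle for uncorrected p-distance under pairwise
# deletion: plain nested loops over string characters, no shared code with
# pairwise_p_distance().
oracle_p_distance <- function(s1, s2) {
  c1 <- strsplit(toupper(s1), "")[[1L]]
  c2 <- strsplit(toupper(s2), "")[[1L]]
  bases <- c("A", "C", "G", "T")
  ncomp <- 0L
  ndiff <- 0L
  for (k in seq_along(c1)) {
    if (c1[k] %in% bases && c2[k] %in% bases) {
      ncomp <- ncomp + 1L
      if (c1[k] != c2[k]) ndiff <- ndiff + 1L
    }
  }
  list(d = if (ncomp > 0L) ndiff / ncomp else NA_real_, n = ncomp)
}

random_alignment <- function(n_seq, n_sites, missing_frac = 0.1) {
  symbols <- c("A", "C", "G", "T", "-", "N")
  probs <- c(rep((1 - missing_frac) / 4, 4), missing_frac / 2, missing_frac / 2)
  seqs <- vapply(seq_len(n_seq), function(i)
    paste(sample(symbols, n_sites, replace = TRUE, prob = probs),
          collapse = ""), character(1L))
  seq_alignment(seqs, ids = paste0("s", seq_len(n_seq)))
}

table2_path <- function() {
  system.file("extdata", "divergence_16s_phoxocephalus_group.csv",
              package = "specdelim")
}

call_params_path <- function() {
  system.file("extdata", "call_parameters.csv", package = "specdelim")
}

# small morphometric frame built in code
toy_morpho <- function() {
  set.seed(42)
  simulate_morphometrics(
    data.frame(label = c("alpha", "beta"), n_male = 12L, n_female = 10L,
               svl_mean = c(25, 31), svl_sd = 2,
               HL_slope = 0.35, HL_offset = c(0.5, 2.0), HL_noise = 0.2,
               HW_slope = 0.37, HW_offset = c(0.4, 1.8), HW_noise = 0.2,
               TD_slope = 0.05, TD_offset = c(0.1, 0.5), TD_noise = 0.05,
               ED_slope = 0.11, ED_offset = c(0.2, 0.6), ED_noise = 0.1),
    seed = 42)
}
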