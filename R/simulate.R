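# Evolve each site of `seqs` (character matrix) along a branch of `d`
# substitutions/site under JC69: a site changes with probability
# 3/4 (1 - exp(-4 d / 3)), uniformly to one of the other three bases.
.jc_evolve <- function(seqs, d) {
  if (d <= 0) return(seqs)
  p_change <- 0.75 * (1 - exp(-4 * d / 3))
  hit <- matrix(stats::runif(length(seqs)) < p_change, nrow = nrow(seqs))
  if (any(hit)) {
    cur <- seqs[hit]
    pick <- function(b) sample(setdiff(.sd_bases, b), 1L)
    seqs[hit] <- vapply(cur, pick, character(1L), USE.NAMES = FALSE)
  }
  seqs
}

#' Simulate a star-topology alignment under JC69
#'
#' Draws a random root sequence and evolves each group's ancestor from the
#' root along a group-specific branch length, then each member from its
#' group ancestor along \code{d_within}. The expected p-distance between
#' groups g and h is the JC69 closed form
#' \code{3/4 (1 - exp(-4 (d_g + d_h) / 3))} (ignoring the small within-group
#' component). Optionally masks a fraction of sites as \code{N}.
#'
#' @param groups Data frame with columns \code{label}, \code{n} (sequences)
#'   and \code{d} (branch length from the root, substitutions/site).
#' @param length Number of alignment sites.
#' @param seed Integer seed (mandatory).
#' @param d_within Tip branch length within groups (default 0: identical
#'   group members up to missing data).
#' @param missing_frac Fraction of cells masked as \code{N}.
#' @return List with \code{alignment} (a \code{\link{seq_alignment}}) and
#'   \code{groups} (named vector id -> group label).
#' @export
simulate_alignment <- function(groups, length = 1300L, seed,
                               d_within = 0, missing_frac = 0) {
  if (missing(seed)) stop("a seed is required")
  if (length < 1L) stop("alignment length must be >= 1")
  stopifnot(all(c("label", "n", "d") %in% names(groups)), all(groups$d >= 0))
  set.seed(seed)
  root <- sample(.sd_bases, length, replace = TRUE)
  ids <- character(0); seqs <- character(0); assign <- character(0)
  for (g in seq_len(nrow(groups))) {
    anc <- .jc_evolve(matrix(root, nrow = 1L), groups$d[g])
    for (i in seq_len(groups$n[g])) {
      tip <- .jc_evolve(anc, d_within)[1L, ]
      if (missing_frac > 0) {
        mask <- stats::runif(length) < missing_frac
        tip[mask] <- "N"
      }
      id <- sprintf("%s_%02d", groups$label[g], i)
      ids <- c(ids, id)
      seqs <- c(seqs, paste(tip, collapse = ""))
      assign <- c(assign, groups$label[g])
    }
  }
  list(alignment = seq_alignment(seqs, ids),
       groups = stats::setNames(assign, ids))
}

#' Simulate a morphometric table with allometric scaling
#'
#' SVL is drawn from a truncated-positive normal per species and sex; each
#' other measurement is \code{slope * SVL + offset + Normal(0, noise_sd)}.
#' Species-level offsets create the between-species shape differences the
#' rank tests and discriminant analysis are meant to detect.
#'
#' @param species Data frame with columns \code{label}, \code{n_male},
#'   \code{n_female}, \code{svl_mean}, \code{svl_sd}, and per-variable
#'   columns \code{<var>_slope}, \code{<var>_offset}, \code{<var>_noise}
#'   for each variable in \code{variables}.
#' @param variables Measurement names (default HL, HW, TD, ED).
#' @param seed Integer seed (mandatory).
#' @return A morphometric data frame (all adults).
#' @export
simulate_morphometrics <- function(species,
                                   variables = c("HL", "HW", "TD", "ED"),
                                   seed) {
  if (missing(seed)) stop("a seed is required")
  set.seed(seed)
  rows <- list()
  for (s in seq_len(nrow(species))) {
    for (sx in c("male", "female")) {
      n <- species[[paste0("n_", sx)]][s]
      if (is.null(n) || is.na(n) || n < 1L) next
      svl <- stats::rnorm(n, species$svl_mean[s], species$svl_sd[s])
      while (any(svl <= 0)) svl[svl <= 0] <- stats::rnorm(sum(svl <= 0),
                                                          species$svl_mean[s],
                                                          species$svl_sd[s])
      df <- data.frame(
        specimen_id = sprintf("%s_%s_%02d", species$label[s], sx, seq_len(n)),
        species = species$label[s], sex = sx, stage = "adult", SVL = svl,
        stringsAsFactors = FALSE)
      for (v in variables) {
        sl <- species[[paste0(v, "_slope")]][s]
        off <- species[[paste0(v, "_offset")]][s]
        ns <- species[[paste0(v, "_noise")]][s]
        df[[v]] <- pmax(sl * svl + off + stats::rnorm(n, 0, ns), 1e-3)
      }
      rows[[length(rows) + 1L]] <- df
    }
  }
  validate_morphometrics(do.call(rbind, rows))
}

#' Synthesize a multi-note advertisement call
#'
#' Each note is a linear frequency sweep from \code{f_start} to \code{f_end}
#' with optional harmonics and a raised-cosine amplitude envelope (peak at
#' the note midpoint, mirroring the stereotyped whistle shape of the study
#' group); notes are separated by silent gaps and the whole call is padded
#' with leading/trailing silence. Gaussian noise is added at the requested
#' signal-to-noise ratio.
#'
#' Durations and sweep endpoints refer to the \emph{audible} note: the
#' region where the envelope exceeds \code{det_threshold} times its peak,
#' which is what an oscillogram measurement (and
#' \code{\link{segment_notes}} at the same relative threshold) delimits.
#' The raised-cosine support is scaled accordingly, so a synthesized note of
#' \code{note_s} seconds is detected with that duration and its sweep spans
#' \code{f_start} to \code{f_end} between the detected boundaries.
#'
#' @param n_notes Number of notes.
#' @param note_s Audible note duration in seconds.
#' @param gap_s Silent gap between consecutive audible notes in seconds.
#' @param f_start,f_end Fundamental frequency at the audible note start/end
#'   (Hz); equal values give a constant-frequency whistle.
#' @param det_threshold Relative amplitude defining the audible note edges
#'   (default 0.1, matching \code{segment_notes}).
#' @param harmonics_db Amplitudes of harmonics 2, 3, ... in dB relative to
#'   the fundamental (e.g. \code{c(-10, -10, -10)} adds harmonics 2-4);
#'   empty for a pure tone.
#' @param snr_db Signal-to-noise ratio in dB (\code{Inf} = noiseless).
#' @param rate Sampling rate in Hz.
#' @param pad_s Leading/trailing silence in seconds.
#' @param seed Integer seed for the noise (mandatory when \code{snr_db} is
#'   finite).
#' @return A \code{\link{call_recording}}; attribute \code{"truth"} holds
#'   the ground-truth parameters (note boundaries, dominant frequency at the
#'   envelope peak, sweep endpoints).
#' @export
synthesize_call <- function(n_notes = 1L, note_s = 0.4, gap_s = 0.3,
                            f_start = 2000, f_end = f_start,
                            harmonics_db = numeric(0), snr_db = Inf,
                            det_threshold = 0.1, rate = 44100, pad_s = 0.05,
                            seed = NULL) {
  if (note_s <= 0 || gap_s < 0) stop("durations must be positive")
  if (!(det_threshold > 0 && det_threshold < 0.5))
    stop("det_threshold must be in (0, 0.5)")
  n_h <- length(harmonics_db) + 1L
  # fraction of the raised-cosine support below the audibility threshold at
  # each edge; support is stretched so the above-threshold part lasts note_s
  frac <- acos(1 - 2 * det_threshold) / (2 * pi)
  support_s <- note_s / (1 - 2 * frac)
  nn <- round(support_s * rate)
  t <- (seq_len(nn) - 0.5) / rate
  sweep_rate <- (f_end - f_start) / note_s
  f0_support <- f_start - sweep_rate * frac * support_s
  f_top <- max(f0_support, f0_support + sweep_rate * support_s)
  if (f0_support <= 0) stop("sweep extends to non-positive frequencies")
  if (n_h * f_top >= rate / 2)
    stop("highest harmonic exceeds the Nyquist frequency")
  phase <- 2 * pi * (f0_support * t + 0.5 * sweep_rate * t^2)
  amps <- c(1, 10^(harmonics_db / 20))
  note <- rowSums(vapply(seq_len(n_h),
                         function(k) amps[k] * sin(k * phase),
                         numeric(nn)))
  env <- 0.5 * (1 - cos(2 * pi * seq_len(nn) / (nn + 1)))
  note <- note * env
  edge_s <- frac * support_s
  gap <- numeric(round((gap_s - 2 * edge_s) * rate))
  pad <- numeric(round(max(pad_s - edge_s, 0) * rate))
  if (gap_s - 2 * edge_s < 0)
    stop("gap_s too short for the sub-threshold note tails")
  pieces <- list(pad)
  starts <- numeric(n_notes); ends <- numeric(n_notes)
  pos <- length(pad)
  for (i in seq_len(n_notes)) {
    starts[i] <- pos / rate + edge_s
    pieces[[length(pieces) + 1L]] <- note
    pos <- pos + nn
    ends[i] <- pos / rate - edge_s
    if (i < n_notes) {
      pieces[[length(pieces) + 1L]] <- gap
      pos <- pos + length(gap)
    }
  }
  pieces[[length(pieces) + 1L]] <- pad
  x <- unlist(pieces)
  if (is.finite(snr_db)) {
    if (is.null(seed)) stop("a seed is required when adding noise")
    set.seed(seed)
    p_sig <- mean(note^2)
    sd_noise <- sqrt(p_sig * 10^(-snr_db / 10))
    x <- x + stats::rnorm(length(x), 0, sd_noise)
  }
  x <- x / max(abs(x))
  rec <- call_recording(x, rate)
  attr(rec, "truth") <- list(n_notes = n_notes, note_s = note_s,
                             gap_s = gap_s, f_start = f_start, f_end = f_end,
                             dominant_hz = (f_start + f_end) / 2,
                             n_harmonics = n_h, starts = starts, ends = ends)
  rec
}

#' Simulate clustered occurrence localities
#'
#' Points are placed around each cluster center by isotropic Gaussian
#' offsets on the local tangent plane (km converted to degrees at the
#' center's latitude).
#'
#' @param clusters Data frame with columns \code{species}, \code{lon},
#'   \code{lat} (cluster center), \code{spread_km} (SD of the offsets) and
#'   \code{n}.
#' @param seed Integer seed (mandatory).
#' @return Locality data frame (\code{locality_id}, \code{species},
#'   \code{lon}, \code{lat}).
#' @export
simulate_localities <- function(clusters, seed) {
  if (missing(seed)) stop("a seed is required")
  stopifnot(all(c("species", "lon", "lat", "spread_km", "n") %in%
                  names(clusters)), all(clusters$spread_km >= 0))
  set.seed(seed)
  rows <- list()
  for (i in seq_len(nrow(clusters))) {
    n <- clusters$n[i]
    dx <- stats::rnorm(n, 0, clusters$spread_km[i])
    dy <- stats::rnorm(n, 0, clusters$spread_km[i])
    km_per_deg_lat <- 111.195  # 6371 km sphere
    lat <- clusters$lat[i] + dy / km_per_deg_lat
    lon <- clusters$lon[i] + dx / (km_per_deg_lat * cos(clusters$lat[i] * pi / 180))
    rows[[length(rows) + 1L]] <- data.frame(
      locality_id = sprintf("%s_c%d_%02d", clusters$species[i], i, seq_len(n)),
      species = clusters$species[i], lon = lon, lat = lat,
      stringsAsFactors = FALSE)
  }
  validate_localities(do.call(rbind, rows))
}

#' Simulate an environmental matrix with group shifts
#'
#' Rows are drawn from a multivariate normal with a common within-group
#' correlation structure and species-specific mean shifts on the 11
#' standard environmental variables (units are z-scores of the underlying
#' layers).
#'
#' @param shifts Matrix or data frame of species mean shifts: one row per
#'   species (row names are the labels), 11 columns in the order of the
#'   standard variables; or a named list of length-11 vectors.
#' @param n Rows (localities) per species.
#' @param correlation Common 11 x 11 within-group correlation matrix. The
#'   default correlates variables within the three thematic blocks
#'   (temperature 1-5, precipitation 6-8, vegetation 9-11) at 0.6 and
#'   leaves the blocks independent, mirroring the block structure that
#'   correlation-PCA loadings of such variables typically show.
#' @param seed Integer seed (mandatory).
#' @return Environmental data frame (\code{locality_id}, \code{species} and
#'   the 11 variables).
#' @export
simulate_env <- function(shifts, n = 10L, correlation = NULL, seed) {
  if (missing(seed)) stop("a seed is required")
  if (is.list(shifts) && !is.data.frame(shifts))
    shifts <- do.call(rbind, shifts)
  shifts <- as.matrix(shifts)
  if (ncol(shifts) != length(.sd_env_vars))
    stop("shift vectors must have ", length(.sd_env_vars), " entries")
  if (is.null(correlation)) {
    correlation <- matrix(0, length(.sd_env_vars), length(.sd_env_vars))
    for (block in list(1:5, 6:8, 9:11))
      correlation[block, block] <- 0.6
    diag(correlation) <- 1
  }
  ev <- eigen(correlation, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < -1e-8)) stop("correlation matrix is not positive semi-definite")
  set.seed(seed)
  labels <- rownames(shifts)
  if (is.null(labels)) labels <- paste0("sp", seq_len(nrow(shifts)))
  rows <- list()
  for (s in seq_len(nrow(shifts))) {
    X <- MASS::mvrnorm(n, mu = shifts[s, ], Sigma = correlation)
    if (n == 1L) X <- matrix(X, nrow = 1L)
    df <- as.data.frame(X)
    names(df) <- .sd_env_vars
    rows[[length(rows) + 1L]] <- cbind(
      data.frame(locality_id = sprintf("%s_%02d", labels[s], seq_len(n)),
                 species = labels[s], stringsAsFactors = FALSE),
      df)
  }
  validate_env_matrix(do.call(rbind, rows))
}
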