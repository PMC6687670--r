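#' Uncorrected pairwise p-distances with pairwise deletion
#'
#' For every pair of sequences, alignment sites where either record carries a
#' symbol outside \{A, C, G, T\} (gaps, N, ?, IUPAC ambiguity) are excluded,
#' and the distance is the proportion of differing sites among those compared.
#' Pairs sharing no comparable site get a missing distance, not an error.
#'
#' @param aln A \code{\link{seq_alignment}}.
#' @return An object of class \code{pdist_matrix}: list with \code{ids},
#'   \code{d} (square matrix of proportions, \code{NA} where no site is
#'   shared) and \code{n_sites} (square integer matrix of compared sites).
#' @export
pairwise_p_distance <- function(aln) {
  stopifnot(inherits(aln, "seq_alignment"))
  m <- aln$matrix
  n <- nrow(m)
  valid <- matrix(m %in% .sd_bases, nrow = n)
  d <- matrix(0, n, n, dimnames = list(aln$ids, aln$ids))
  ns <- matrix(0L, n, n, dimnames = list(aln$ids, aln$ids))
  diag(ns) <- as.integer(rowSums(valid))
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        ok <- valid[i, ] & valid[j, ]
        k <- sum(ok)
        ns[i, j] <- ns[j, i] <- k
        d[i, j] <- d[j, i] <- if (k > 0L) sum(m[i, ok] != m[j, ok]) / k else NA_real_
      }
    }
  }
  structure(list(ids = aln$ids, d = d, n_sites = ns), class = "pdist_matrix")
}

#' @export
print.pdist_matrix <- function(x, digits = 4, ...) {
  cat(sprintf("Uncorrected p-distance matrix (%d sequences, pairwise deletion)\n",
              length(x$ids)))
  print(round(x$d, digits))
  invisible(x)
}

#' Write a p-distance matrix as CSV
#' @param pd A \code{pdist_matrix}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_pdist_csv <- function(pd, path) {
  stopifnot(inherits(pd, "pdist_matrix"))
  utils::write.csv(as.data.frame(pd$d), path, row.names = TRUE)
  invisible(path)
}

# Per-pair difference/validity site indicators; rows = unordered pairs.
# Shared by the point estimate and the site bootstrap so both resample the
# same site-level statistics.
.pair_site_stats <- function(aln) {
  m <- aln$matrix
  n <- nrow(m)
  valid <- matrix(m %in% .sd_bases, nrow = n)
  pairs <- if (n > 1L) utils::combn(n, 2L) else matrix(integer(0), 2L, 0L)
  np <- ncol(pairs)
  diff <- matrix(0, np, aln$length)
  ok <- matrix(0, np, aln$length)
  for (p in seq_len(np)) {
    i <- pairs[1L, p]; j <- pairs[2L, p]
    o <- valid[i, ] & valid[j, ]
    ok[p, ] <- o
    diff[p, ] <- o & (m[i, ] != m[j, ])
  }
  list(pairs = pairs, diff = diff, ok = ok)
}

#' Within/between-group mean p-distances with site-bootstrap SEs
#'
#' Group means of pairwise uncorrected p-distances, reported in percent, in
#' the layout used for published 16S divergence tables: between-group means
#' for every unordered pair of groups and within-group means (missing for
#' single-sequence groups). Standard errors are obtained by resampling
#' alignment sites with replacement and recomputing the group means.
#'
#' @param aln A \code{\link{seq_alignment}}.
#' @param groups Named character vector mapping every aligned id to a group
#'   label (see \code{\link{read_groups}}).
#' @param n_boot Number of site-bootstrap replicates (default 1000); with
#'   \code{n_boot = 0} the SEs are reported missing.
#' @param seed Integer seed for the bootstrap (mandatory).
#' @return An object of class \code{group_dist_summary}: \code{groups}
#'   (ordered labels), \code{n} (sequences per group), \code{between_mean},
#'   \code{se_between} (square matrices, percent), \code{within_mean},
#'   \code{se_within} (vectors, percent; \code{NA} for singleton groups).
#' @export
group_distance_summary <- function(aln, groups, n_boot = 1000L, seed) {
  stopifnot(inherits(aln, "seq_alignment"))
  if (missing(seed)) stop("a bootstrap seed is required")
  if (n_boot < 0L) stop("n_boot must be >= 0")
  missing_ids <- setdiff(aln$ids, names(groups))
  if (length(missing_ids) > 0L)
    stop("ids missing from group assignment: ",
         paste(missing_ids, collapse = ", "))
  g <- as.character(groups[aln$ids])
  labels <- unique(g)
  st <- .pair_site_stats(aln)
  pg1 <- g[st$pairs[1L, ]]
  pg2 <- g[st$pairs[2L, ]]

  # mean pair distance per group pair given site weights w (counts per site)
  group_means <- function(w) {
    dsum <- as.vector(st$diff %*% w)
    osum <- as.vector(st$ok %*% w)
    d <- ifelse(osum > 0, dsum / osum, NA_real_)
    k <- length(labels)
    between <- matrix(NA_real_, k, k, dimnames = list(labels, labels))
    within <- stats::setNames(rep(NA_real_, k), labels)
    for (a in seq_len(k)) {
      wa <- (pg1 == labels[a] & pg2 == labels[a])
      if (any(wa)) within[a] <- mean(d[wa], na.rm = TRUE)
      if (a < k) for (b in seq(a + 1L, k)) {
        ab <- (pg1 == labels[a] & pg2 == labels[b]) |
              (pg1 == labels[b] & pg2 == labels[a])
        if (any(ab))
          between[a, b] <- between[b, a] <- mean(d[ab], na.rm = TRUE)
      }
    }
    diag(between) <- 0
    list(between = between, within = within)
  }

  L <- aln$length
  est <- group_means(rep(1, L))
  if (n_boot > 0L) {
    set.seed(seed)
    bet_rep <- array(NA_real_, c(length(labels), length(labels), n_boot))
    wit_rep <- matrix(NA_real_, length(labels), n_boot)
    for (b in seq_len(n_boot)) {
      w <- tabulate(sample.int(L, L, replace = TRUE), nbins = L)
      gm <- group_means(w)
      bet_rep[, , b] <- gm$between
      wit_rep[, b] <- gm$within
    }
    se_between <- apply(bet_rep, c(1L, 2L), stats::sd)
    se_within <- apply(wit_rep, 1L, stats::sd)
    dimnames(se_between) <- list(labels, labels)
    names(se_within) <- labels
    diag(se_between) <- 0
  } else {
    se_between <- matrix(NA_real_, length(labels), length(labels),
                         dimnames = list(labels, labels))
    se_within <- stats::setNames(rep(NA_real_, length(labels)), labels)
  }
  structure(list(groups = labels,
                 n = as.integer(table(factor(g, levels = labels))),
                 between_mean = 100 * est$between,
                 within_mean = 100 * est$within,
                 se_between = 100 * se_between,
                 se_within = 100 * se_within),
            class = "group_dist_summary")
}

#' Assemble a group-distance summary from precomputed matrices
#'
#' Used when the means/SEs come from a transcribed published table rather
#' than from an alignment.
#'
#' @param between_mean Square matrix of between-group mean distances (percent).
#' @param within_mean Vector of within-group means (percent, \code{NA} for
#'   singleton groups).
#' @param se_between,se_within Matching bootstrap SEs (percent), optional.
#' @param n Sequences per group, optional.
#' @return A \code{group_dist_summary}.
#' @export
group_dist_summary <- function(between_mean, within_mean = NULL,
                               se_between = NULL, se_within = NULL, n = NULL) {
  labels <- rownames(between_mean)
  if (is.null(labels)) stop("between_mean must have row names (group labels)")
  k <- length(labels)
  if (!isTRUE(all.equal(between_mean, t(between_mean), tolerance = 1e-8,
                        check.attributes = FALSE)))
    stop("between_mean must be symmetric")
  empty_m <- matrix(NA_real_, k, k, dimnames = list(labels, labels))
  empty_v <- stats::setNames(rep(NA_real_, k), labels)
  structure(list(groups = labels,
                 n = if (is.null(n)) rep(NA_integer_, k) else as.integer(n),
                 between_mean = between_mean,
                 within_mean = if (is.null(within_mean)) empty_v else within_mean,
                 se_between = if (is.null(se_between)) empty_m else se_between,
                 se_within = if (is.null(se_within)) empty_v else se_within),
            class = "group_dist_summary")
}

#' @export
print.group_dist_summary <- function(x, digits = 1, ...) {
  k <- length(x$groups)
  cat(sprintf("Group p-distance summary: %d groups (%%; means lower triangle, SEs upper)\n", k))
  m <- matrix("", k, k, dimnames = list(x$groups, x$groups))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    m[i, j] <- if (i > j) formatC(x$between_mean[i, j], digits = digits, format = "f")
      else if (i < j) formatC(x$se_between[i, j], digits = digits, format = "f")
      else if (is.na(x$within_mean[i])) "NA"
      else paste0(formatC(x$within_mean[i], digits = digits, format = "f"),
                  if (!is.na(x$se_within[i]))
                    paste0("±", formatC(x$se_within[i], digits = digits, format = "f"))
                  else "")
  }
  print(m, quote = FALSE)
  invisible(x)
}

#' Write a group-distance summary CSV in the published-table layout
#'
#' Between-group means are placed in the lower triangle, bootstrap SEs in the
#' upper triangle, and \code{within mean +/- SE} (or \code{NA} for singleton
#' groups) on the diagonal.
#'
#' @param x A \code{group_dist_summary}.
#' @param path Output path.
#' @param digits Digits kept at report time (internal values are full
#'   precision).
#' @return \code{path}, invisibly.
#' @export
write_group_summary_csv <- function(x, path, digits = 1) {
  stopifnot(inherits(x, "group_dist_summary"))
  k <- length(x$groups)
  m <- matrix("", k, k, dimnames = list(x$groups, x$groups))
  fmt <- function(v) formatC(v, digits = digits, format = "f")
  for (i in seq_len(k)) for (j in seq_len(k)) {
    m[i, j] <- if (i > j) fmt(x$between_mean[i, j])
      else if (i < j) fmt(x$se_between[i, j])
      else if (is.na(x$within_mean[i])) "NA"
      else if (is.na(x$se_within[i])) fmt(x$within_mean[i])
      else paste0(fmt(x$within_mean[i]), "±", fmt(x$se_within[i]))
  }
  df <- data.frame(group = x$groups, n = x$n, m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a group-distance summary CSV written by
#' \code{\link{write_group_summary_csv}}
#'
#' @param path Path to the CSV (lower triangle = between means, upper
#'   triangle = SEs, diagonal = within mean \code{+/-} SE or \code{NA}).
#' @return A \code{group_dist_summary}.
#' @export
read_group_summary_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        comment.char = "#")
  labels <- as.character(df$group)
  n <- if ("n" %in% names(df)) as.integer(df$n) else rep(NA_integer_, length(labels))
  cells <- as.matrix(df[, labels, drop = FALSE])
  k <- length(labels)
  between <- matrix(NA_real_, k, k, dimnames = list(labels, labels))
  se_between <- matrix(NA_real_, k, k, dimnames = list(labels, labels))
  within <- stats::setNames(rep(NA_real_, k), labels)
  se_within <- stats::setNames(rep(NA_real_, k), labels)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    cell <- trimws(cells[i, j])
    if (i > j) {
      between[i, j] <- between[j, i] <- as.numeric(cell)
    } else if (i < j) {
      se_between[i, j] <- se_between[j, i] <- as.numeric(cell)
    } else if (!is.na(cell) && cell != "NA" && cell != "") {
      parts <- strsplit(cell, "±|\\+/-")[[1L]]
      within[i] <- as.numeric(parts[1L])
      if (length(parts) > 1L) se_within[i] <- as.numeric(parts[2L])
    }
  }
  diag(between) <- 0
  group_dist_summary(between, within, se_between, se_within, n)
}

#' Identify candidate lineages by threshold clustering
#'
#' Single-linkage merging of groups whose between-group mean p-distance is
#' strictly below the threshold: two groups end up in the same cluster
#' whenever a chain of below-threshold pairs connects them. Groups at exactly
#' the threshold remain distinct, so a pair at the 2.0\% reference distance
#' is kept separate at \code{threshold = 0.02}. Each resulting cluster is a
#' candidate lineage.
#'
#' @param summary A \code{group_dist_summary}.
#' @param threshold Merge threshold as a proportion in (0, 1); the summary's
#'   percent distances are compared against \code{100 * threshold}.
#' @return An object of class \code{candidate_partition}: list with
#'   \code{threshold}, \code{linkage} (\code{"single"}) and \code{clusters}
#'   (list of character vectors of group labels).
#' @export
identify_candidates <- function(summary, threshold = 0.02) {
  stopifnot(inherits(summary, "group_dist_summary"))
  if (!(threshold > 0 && threshold < 1)) stop("threshold must be in (0, 1)")
  b <- summary$between_mean
  k <- length(summary$groups)
  if (k > 1L) {
    miss <- which(is.na(b) & upper.tri(b), arr.ind = TRUE)
    if (nrow(miss) > 0L)
      stop("missing between-group distances for pairs: ",
           paste(sprintf("%s-%s", summary$groups[miss[, 1L]],
                         summary$groups[miss[, 2L]]), collapse = ", "))
  }
  adj <- (b < 100 * threshold)
  diag(adj) <- TRUE
  comp <- rep(0L, k)
  cur <- 0L
  for (s in seq_len(k)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue) > 0L) {
      v <- queue[1L]; queue <- queue[-1L]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  clusters <- lapply(seq_len(cur), function(cc) summary$groups[comp == cc])
  structure(list(threshold = threshold, linkage = "single",
                 clusters = clusters),
            class = "candidate_partition")
}

#' @export
print.candidate_partition <- function(x, ...) {
  cat(sprintf("Candidate partition: %d clusters at threshold %.3f (single linkage, strict <)\n",
              length(x$clusters), x$threshold))
  for (i in seq_along(x$clusters))
    cat(sprintf("  %2d: %s\n", i, paste(x$clusters[[i]], collapse = " + ")))
  invisible(x)
}

#' Write a candidate partition as JSON
#' @param partition A \code{candidate_partition}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_partition_json <- function(partition, path) {
  stopifnot(inherits(partition, "candidate_partition"))
  jsonlite::write_json(list(threshold = partition$threshold,
                            linkage = partition$linkage,
                            clusters = partition$clusters),
                       path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Cluster labels of a candidate partition
#'
#' A lineage label per cluster: the group label for singleton clusters,
#' otherwise the member labels joined with \code{"+"}.
#' @param partition A \code{candidate_partition}.
#' @return Character vector of lineage labels.
#' @export
lineage_labels <- function(partition) {
  vapply(partition$clusters,
         function(cl) paste(sort(cl), collapse = "+"), character(1L))
}
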