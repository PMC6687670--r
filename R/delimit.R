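.sd_char_states <- c("divergent", "not_divergent", "unavailable")

#' Classify one lineage from its character evidence
#'
#' Applies the integrative-taxonomy decision rules: a lineage whose genetic
#' distance to its nearest neighbour does not exceed the threshold is
#' \code{conspecific}; above threshold it is a candidate species, classified
#' as \code{UCS} (unconfirmed) when no non-genetic character set is
#' available, \code{CCS} (confirmed) when at least one character set
#' (morphology, acoustics or environment) covaries — i.e. is divergent —
#' with the genetic split, and \code{DCL} (deep conspecific lineage) when
#' character sets are available but none is divergent.
#'
#' @param lineage Lineage (cluster) label.
#' @param genetic_exceeds_threshold Logical: nearest-neighbour distance above
#'   the threshold.
#' @param morphology,acoustics,environment Character-state tags, each one of
#'   \code{"divergent"}, \code{"not_divergent"}, \code{"unavailable"}.
#' @return An object of class \code{delimitation_decision}: \code{lineage},
#'   \code{status} in \{CCS, UCS, DCL, conspecific\},
#'   \code{evidence_summary}.
#' @export
evaluate_lineage <- function(lineage, genetic_exceeds_threshold,
                             morphology = "unavailable",
                             acoustics = "unavailable",
                             environment = "unavailable") {
  morphology <- match.arg(morphology, .sd_char_states)
  acoustics <- match.arg(acoustics, .sd_char_states)
  environment <- match.arg(environment, .sd_char_states)
  chars <- c(morphology = morphology, acoustics = acoustics,
             environment = environment)
  status <- if (!isTRUE(genetic_exceeds_threshold)) "conspecific"
    else if (any(chars == "divergent")) "CCS"
    else if (all(chars == "unavailable")) "UCS"
    else "DCL"
  summary <- sprintf("genetic %s threshold; morphology %s, acoustics %s, environment %s",
                     if (isTRUE(genetic_exceeds_threshold)) "exceeds" else "within",
                     morphology, acoustics, environment)
  structure(list(lineage = lineage, status = status,
                 evidence_summary = summary, evidence = chars,
                 genetic_exceeds_threshold = isTRUE(genetic_exceeds_threshold)),
            class = "delimitation_decision")
}

#' @export
print.delimitation_decision <- function(x, ...) {
  cat(sprintf("%s: %s (%s)\n", x$lineage, x$status, x$evidence_summary))
  invisible(x)
}

#' Read a character-evidence table
#'
#' CSV with header
#' \code{lineage,genetic_exceeds_threshold,morphology,acoustics,environment};
#' the three character columns hold the tags \code{divergent},
#' \code{not_divergent} or \code{unavailable}.
#'
#' @param path Path to the CSV file.
#' @return Validated evidence data frame.
#' @export
read_evidence <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("lineage", "genetic_exceeds_threshold")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stop("evidence table lacks columns: ", paste(miss, collapse = ", "))
  for (col in c("morphology", "acoustics", "environment")) {
    if (!col %in% names(df)) df[[col]] <- "unavailable"
    bad <- setdiff(unique(df[[col]]), .sd_char_states)
    if (length(bad) > 0L)
      stop(sprintf("invalid %s state(s): %s", col, paste(bad, collapse = ", ")))
  }
  df$genetic_exceeds_threshold <- as.logical(df$genetic_exceeds_threshold)
  df
}

#' Delimit every candidate lineage of a partition
#'
#' Joins a candidate partition with per-lineage character evidence and
#' returns the decisions plus CCS/UCS/DCL counts. Every cluster of the
#' partition must have an evidence row keyed by its lineage label
#' (\code{\link{lineage_labels}}).
#'
#' @param partition A \code{\link{identify_candidates}} result, or NULL to
#'   delimit the evidence rows as-is.
#' @param evidence Evidence data frame (see \code{\link{read_evidence}}).
#' @return An object of class \code{delimitation_report}: \code{decisions}
#'   (data frame lineage/status/evidence_summary), \code{counts}
#'   (n_CCS, n_UCS, n_DCL, n_conspecific), \code{threshold}.
#' @export
delimit_all <- function(partition = NULL, evidence) {
  if (!is.null(partition)) {
    stopifnot(inherits(partition, "candidate_partition"))
    labels <- lineage_labels(partition)
    missing <- setdiff(labels, evidence$lineage)
    if (length(missing) > 0L)
      stop("no evidence for lineages: ", paste(missing, collapse = ", "))
    evidence <- evidence[match(labels, evidence$lineage), , drop = FALSE]
  }
  decisions <- lapply(seq_len(nrow(evidence)), function(i)
    evaluate_lineage(evidence$lineage[i],
                     evidence$genetic_exceeds_threshold[i],
                     evidence$morphology[i],
                     evidence$acoustics[i],
                     evidence$environment[i]))
  df <- data.frame(
    lineage = vapply(decisions, `[[`, character(1L), "lineage"),
    status = vapply(decisions, `[[`, character(1L), "status"),
    evidence_summary = vapply(decisions, `[[`, character(1L),
                              "evidence_summary"),
    stringsAsFactors = FALSE)
  counts <- c(n_CCS = sum(df$status == "CCS"),
              n_UCS = sum(df$status == "UCS"),
              n_DCL = sum(df$status == "DCL"),
              n_conspecific = sum(df$status == "conspecific"))
  structure(list(decisions = df, counts = counts,
                 threshold = if (is.null(partition)) NA_real_
                             else partition$threshold),
            class = "delimitation_report")
}

#' @export
print.delimitation_report <- function(x, ...) {
  cat(sprintf("Delimitation report: %d lineages (CCS %d, UCS %d, DCL %d, conspecific %d)\n",
              nrow(x$decisions), x$counts[["n_CCS"]], x$counts[["n_UCS"]],
              x$counts[["n_DCL"]], x$counts[["n_conspecific"]]))
  print(x$decisions[, c("lineage", "status")], row.names = FALSE)
  invisible(x)
}

#' @export
summary.delimitation_report <- function(object, ...) {
  cat(sprintf("Candidate species: %d (%d confirmed, %d unconfirmed, %d deep conspecific lineages)\n",
              sum(object$counts[c("n_CCS", "n_UCS", "n_DCL")]),
              object$counts[["n_CCS"]], object$counts[["n_UCS"]],
              object$counts[["n_DCL"]]))
  invisible(object)
}

#' Rule-based morphology divergence flag
#'
#' Optional convention for deriving the morphology character state from
#' pairwise rank tests: a lineage is flagged \code{divergent} when at least
#' one variable differs (adjusted p below \code{alpha}) from every
#' neighbouring lineage it is compared against, \code{not_divergent} when
#' comparisons exist but that fails, \code{unavailable} without comparisons.
#' The manual evidence path remains primary; this helper encodes one
#' explicit reading of character covariation.
#'
#' @param tests Result of \code{\link{pairwise_tests}}.
#' @param lineage Species/lineage label to flag.
#' @param neighbours Labels the lineage must differ from (default: all
#'   others appearing in \code{tests}).
#' @param alpha Significance level on \code{p_adjusted} (default 0.05).
#' @return One of \code{"divergent"}, \code{"not_divergent"},
#'   \code{"unavailable"}.
#' @export
morphology_flag <- function(tests, lineage, neighbours = NULL, alpha = 0.05) {
  rel <- tests[tests$species_a == lineage | tests$species_b == lineage, ,
               drop = FALSE]
  if (nrow(rel) == 0L) return("unavailable")
  other <- ifelse(rel$species_a == lineage, rel$species_b, rel$species_a)
  if (is.null(neighbours)) neighbours <- unique(other)
  ok <- vapply(neighbours, function(nb) {
    sub <- rel[other == nb, , drop = FALSE]
    nrow(sub) > 0L && any(sub$p_adjusted < alpha, na.rm = TRUE)
  }, logical(1L))
  if (length(ok) > 0L && all(ok)) "divergent" else "not_divergent"
}

#' Write a delimitation report as JSON and Markdown
#' @param report A \code{delimitation_report}.
#' @param json_path,md_path Output paths (either may be NULL).
#' @return Invisibly, the paths written.
#' @export
write_delimitation <- function(report, json_path = NULL, md_path = NULL) {
  stopifnot(inherits(report, "delimitation_report"))
  if (!is.null(json_path)) {
    jsonlite::write_json(list(threshold = report$threshold,
                              counts = as.list(report$counts),
                              decisions = report$decisions),
                         json_path, auto_unbox = TRUE, pretty = TRUE)
  }
  if (!is.null(md_path)) {
    lines <- c("# Delimitation summary", "",
               sprintf("Threshold: %s", format(report$threshold)),
               sprintf("CCS: %d, UCS: %d, DCL: %d, conspecific: %d",
                       report$counts[["n_CCS"]], report$counts[["n_UCS"]],
                       report$counts[["n_DCL"]],
                       report$counts[["n_conspecific"]]), "",
               "| Lineage | Status |", "|---|---|",
               sprintf("| %s | %s |", report$decisions$lineage,
                       report$decisions$status))
    writeLines(lines, md_path)
  }
  invisible(c(json_path, md_path))
}
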