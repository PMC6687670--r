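# IUPAC nucleotide alphabet accepted in alignments; only A/C/G/T count as
# comparable sites, everything else is missing under pairwise deletion.
.sd_alphabet <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                  "B", "D", "H", "V", "N", "-", "?")
.sd_bases <- c("A", "C", "G", "T")

#' Construct a multiple sequence alignment
#'
#' Stores equal-length nucleotide records as a character matrix. Symbols are
#' normalized to upper case and \code{U} is mapped to \code{T}; anything
#' outside the IUPAC alphabet (plus \code{-}, \code{N}, \code{?}) is rejected.
#'
#' @param sequences Named character vector of aligned sequences (names are the
#'   record ids), or an unnamed vector together with \code{ids}.
#' @param ids Optional character vector of record ids.
#' @return An object of class \code{seq_alignment} with elements \code{ids},
#'   \code{matrix} (records x sites character matrix) and \code{length}.
#' @export
seq_alignment <- function(sequences, ids = names(sequences)) {
  if (length(sequences) == 0L) stop("alignment must contain at least one record")
  if (is.null(ids)) ids <- paste0("seq", seq_along(sequences))
  if (anyDuplicated(ids)) stop("duplicated sequence ids: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  sequences <- toupper(as.character(sequences))
  sequences <- gsub("U", "T", sequences, fixed = TRUE)
  lens <- nchar(sequences)
  if (lens[1L] < 1L) stop("alignment length must be >= 1")
  bad <- which(lens != lens[1L])
  if (length(bad) > 0L)
    stop(sprintf("alignment is not rectangular: record %d ('%s') has length %d, expected %d",
                 bad[1L], ids[bad[1L]], lens[bad[1L]], lens[1L]))
  mat <- matrix("", nrow = length(sequences), ncol = lens[1L],
                dimnames = list(ids, NULL))
  for (i in seq_along(sequences)) {
    chars <- strsplit(sequences[i], "", fixed = TRUE)[[1L]]
    ill <- which(!(chars %in% .sd_alphabet))
    if (length(ill) > 0L)
      stop(sprintf("illegal symbol '%s' in record '%s' at position %d",
                   chars[ill[1L]], ids[i], ill[1L]))
    mat[i, ] <- chars
  }
  structure(list(ids = ids, matrix = mat, length = lens[1L]),
            class = "seq_alignment")
}

#' Read a FASTA alignment
#'
#' Relaxed FASTA reader (multi-line records, mixed case). Records are returned
#' in file order, normalized to upper case with \code{U} mapped to \code{T}.
#'
#' @param path Path to a FASTA file.
#' @param format Input format; only \code{"fasta"} is supported.
#' @return A \code{\link{seq_alignment}}.
#' @export
read_alignment <- function(path, format = "fasta") {
  format <- match.arg(tolower(format), "fasta")
  if (!file.exists(path)) stop("file not found: ", path)
  recs <- seqinr::read.fasta(path, seqtype = "DNA", as.string = TRUE,
                             forceDNAtolower = FALSE)
  if (length(recs) == 0L) stop("no FASTA records found in ", path)
  seq_alignment(vapply(recs, as.character, character(1L)),
                ids = names(recs))
}

#' Write an alignment to FASTA
#' @param aln A \code{seq_alignment}.
#' @param path Output path.
#' @param width Line width for wrapped sequences.
#' @return \code{path}, invisibly.
#' @export
write_alignment <- function(aln, path, width = 70L) {
  stopifnot(inherits(aln, "seq_alignment"))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(aln$ids)) {
    writeLines(paste0(">", aln$ids[i]), con)
    s <- paste(aln$matrix[i, ], collapse = "")
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' @export
print.seq_alignment <- function(x, ...) {
  cat(sprintf("Sequence alignment: %d records, %d sites\n",
              length(x$ids), x$length))
  show <- utils::head(x$ids, 6L)
  cat("  ids:", paste(show, collapse = ", "),
      if (length(x$ids) > 6L) "..." else "", "\n")
  invisible(x)
}

#' Read a group-assignment table
#'
#' Reads a CSV with header \code{id,group} mapping sequence ids to group
#' (clade) labels.
#'
#' @param path Path to the CSV file.
#' @return Named character vector: group label per id.
#' @export
read_groups <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("id", "group") %in% names(df)))
    stop("group table must have columns 'id' and 'group'")
  if (anyDuplicated(df$id))
    stop("duplicated ids in group table: ",
         paste(unique(df$id[duplicated(df$id)]), collapse = ", "))
  stats::setNames(as.character(df$group), as.character(df$id))
}
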