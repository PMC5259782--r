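#' Read protein sequences from FASTA
#'
#' Thin wrapper around [Biostrings::readAAStringSet()] that enforces the
#' package's alignment conventions: ids must be unique, `.` gaps are
#' normalised to `-`, residues are uppercased, and with
#' `expect_aligned = TRUE` ragged lengths are an error.
#'
#' The id of each record is the first whitespace-delimited token of its
#' header; the remainder is kept as the description.
#'
#' @param path path to a FASTA file (aligned or unaligned).
#' @param expect_aligned if `TRUE`, require all sequences to have equal
#'   length and return a [clade_aln()]; otherwise return a tibble.
#' @param clades optional clade map passed on to [clade_aln()] when
#'   `expect_aligned = TRUE`.
#' @param unknown_chars see [clade_aln()].
#' @return with `expect_aligned = TRUE` a [clade_aln()]; otherwise a tibble
#'   with columns `id`, `description`, `sequence`.
#' @export
read_fasta <- function(path, expect_aligned = FALSE, clades = NULL,
                       unknown_chars = c("error", "to_X")) {
  unknown_chars <- match.arg(unknown_chars)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  ss <- Biostrings::readAAStringSet(path)
  if (length(ss) == 0L) abort(paste0("empty FASTA file: ", path))
  headers <- names(ss)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers),
                 sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate ids in ", path, ": ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  seqs <- setNames(toupper(chartr(".", GAP_CHAR, as.character(ss))), ids)
  if (expect_aligned) {
    if (length(unique(nchar(seqs))) != 1L) {
      abort(paste0("ragged alignment in ", path,
                   ": sequences differ in length"))
    }
    clade_aln(seqs, clades = clades,
              descriptions = setNames(desc, ids),
              unknown_chars = unknown_chars)
  } else {
    tibble::tibble(id = ids, description = desc, sequence = unname(seqs))
  }
}

#' Write sequences to FASTA
#'
#' Accepts a [clade_aln()] or a tibble/data frame with `id` and `sequence`
#' columns (optionally `description`). Gaps are written as `-`.
#'
#' @param x sequences to write.
#' @param path output file path.
#' @param width line width for wrapping (default 70).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 70L) {
  if (inherits(x, "clade_aln")) {
    seqs <- x$seq
    desc <- x$descriptions
  } else {
    seqs <- setNames(x$sequence, x$id)
    desc <- if ("description" %in% names(x))
      setNames(x$description, x$id) else NULL
  }
  headers <- names(seqs)
  if (!is.null(desc)) {
    d <- desc[headers]
    has <- !is.na(d) & nzchar(d)
    headers[has] <- paste(headers[has], d[has])
  }
  ss <- Biostrings::AAStringSet(seqs)
  names(ss) <- headers
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}
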