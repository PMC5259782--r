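#' Protein alignment container
#'
#' A `clade_aln` bundles equal-length gapped protein sequences with an
#' optional clade (taxonomic order) label per sequence. It is the substrate
#' of the residue scan ([candidate_screen()]) and of tree building
#' ([pairwise_distances()]).
#'
#' Sequences are stored uppercase over the 20 amino acids plus `X`
#' (unknown) and `-` (gap); `.` gaps are normalised to `-` on construction.
#' `X` never counts as conserved. Columns consisting entirely of gaps are
#' rejected.
#'
#' @param sequences named character vector of gapped sequences (names are
#'   sequence ids), or a list coercible to one.
#' @param clades named character vector mapping sequence id to clade label
#'   (e.g. `"Nostocales"`), or a two-column data frame `(id, clade)`.
#'   Optional; required only by clade-aware operations.
#' @param descriptions optional named character vector of free-text
#'   descriptions.
#' @param unknown_chars how to handle residue characters outside the
#'   alphabet: `"error"` (default) rejects the input, `"to_X"` maps them
#'   to `X`.
#'
#' @return an object of class `clade_aln` with elements `seq` (named
#'   character vector), `clades` (named character vector or `NULL`),
#'   `descriptions`, and `n_columns`.
#' @examples
#' aln <- clade_aln(c(a = "MK-E", b = "MKLE"))
#' n_columns(aln)
#' @export
clade_aln <- function(sequences, clades = NULL, descriptions = NULL,
                      unknown_chars = c("error", "to_X")) {
  unknown_chars <- match.arg(unknown_chars)
  seqs <- toupper(unlist(sequences, use.names = TRUE))
  ids <- names(seqs)
  if (is.null(ids) || any(!nzchar(ids))) {
    abort("every sequence must have a non-empty id (name)")
  }
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate sequence ids: ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  if (any(!nzchar(seqs))) abort("sequences must be non-empty")
  seqs <- chartr(".", GAP_CHAR, seqs)
  allowed <- c(AA_ORDER, "X", GAP_CHAR)
  bad <- vapply(strsplit(seqs, ""), function(ch) any(!ch %in% allowed),
                logical(1))
  if (any(bad)) {
    if (unknown_chars == "error") {
      abort(paste0("unknown residue characters in: ",
                   paste(ids[bad], collapse = ", "),
                   " (use unknown_chars = \"to_X\" to map them to X)"))
    }
    seqs <- vapply(strsplit(seqs, ""), function(ch) {
      ch[!ch %in% allowed] <- "X"
      paste(ch, collapse = "")
    }, character(1))
    names(seqs) <- ids
  }
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    abort("ragged alignment: sequences differ in length")
  }
  ncol <- lens[[1]]
  m <- alignment_matrix_chr(seqs)
  if (any(colSums(m != GAP_CHAR) == 0L)) {
    abort("alignment has a column consisting entirely of gaps")
  }
  if (!is.null(clades)) {
    if (is.data.frame(clades)) {
      clades <- setNames(as.character(clades[[2]]), as.character(clades[[1]]))
    }
    missing_ids <- setdiff(names(clades), ids)
    if (length(missing_ids)) {
      abort(paste0("clade map refers to unknown sequence ids: ",
                   paste(missing_ids, collapse = ", ")))
    }
  }
  structure(
    list(seq = seqs, clades = clades, descriptions = descriptions,
         n_columns = ncol),
    class = "clade_aln"
  )
}

alignment_matrix_chr <- function(seqs) {
  matrix(unlist(strsplit(seqs, ""), use.names = FALSE),
         nrow = length(seqs), byrow = TRUE,
         dimnames = list(names(seqs), NULL))
}

#' @export
print.clade_aln <- function(x, ...) {
  cat("<clade_aln> ", length(x$seq), " sequences x ", x$n_columns,
      " columns\n", sep = "")
  if (!is.null(x$clades)) {
    tab <- table(x$clades)
    cat("clades: ", paste(names(tab), tab, sep = "=", collapse = ", "), "\n",
        sep = "")
  }
  invisible(x)
}

#' Number of alignment columns
#' @param aln a [clade_aln()].
#' @return integer.
#' @export
n_columns <- function(aln) {
  stopifnot(inherits(aln, "clade_aln"))
  aln$n_columns
}

#' Sequence ids of an alignment
#' @param aln a [clade_aln()].
#' @return character vector.
#' @export
aln_ids <- function(aln) names(aln$seq)

#' Tidy an alignment into a tibble
#'
#' @param x a [clade_aln()].
#' @param ... unused.
#' @return a tibble with columns `id`, `clade`, `sequence`, `length`
#'   (ungapped residue count).
#' @export
tidy.clade_aln <- function(x, ...) {
  tibble::tibble(
    id = names(x$seq),
    clade = if (is.null(x$clades)) NA_character_ else
      unname(x$clades[names(x$seq)]),
    sequence = unname(x$seq),
    length = nchar(gsub(GAP_CHAR, "", x$seq, fixed = TRUE))
  )
}

#' Attach clade labels to an alignment
#'
#' @param aln a [clade_aln()].
#' @param clades named character vector or two-column data frame
#'   `(id, clade)`; also accepts the tibble returned by [read_clade_table()].
#' @return the alignment with its clade map replaced.
#' @export
set_clades <- function(aln, clades) {
  clade_aln(aln$seq, clades = clades, descriptions = aln$descriptions)
}

#' Read a sequence-id/clade table
#'
#' Reads the two-column tab-separated format `sequence_id<TAB>clade` (no
#' header, `#` comments allowed).
#'
#' @param path file path.
#' @return tibble with columns `id`, `clade`.
#' @export
read_clade_table <- function(path) {
  df <- read.delim(path, header = FALSE, comment.char = "#",
                   col.names = c("id", "clade"),
                   colClasses = "character", strip.white = TRUE)
  tibble::as_tibble(df)
}

seq_chars <- function(aln, seq_id) {
  if (!seq_id %in% names(aln$seq)) {
    abort(paste0("unknown sequence id: ", seq_id))
  }
  strsplit(aln$seq[[seq_id]], "")[[1]]
}

clade_members <- function(aln, clade) {
  if (is.null(aln$clades)) abort("alignment has no clade map")
  ids <- names(aln$clades)[aln$clades == clade]
  if (!length(ids)) abort(paste0("clade has no members: ", clade))
  ids
}
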