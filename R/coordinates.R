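#' Map an alignment column to an ungapped residue position
#'
#' Positions are 1-based on the ungapped sequence counting from the
#' initiator methionine, the convention in which a residue such as "E954"
#' is named. If the sequence has a gap at the requested column, the [GAP]
#' marker is returned.
#'
#' @param aln a [clade_aln()].
#' @param seq_id sequence id.
#' @param column 1-based alignment column.
#' @return 1-based residue position, or [GAP].
#' @seealso [position_to_column()], [equivalent_position()]
#' @export
column_to_position <- function(aln, seq_id, column) {
  ch <- seq_chars(aln, seq_id)
  if (any(column < 1L | column > length(ch))) {
    abort(paste0("column out of range for ", seq_id))
  }
  pos <- cumsum(ch != GAP_CHAR)
  out <- pos[column]
  out[ch[column] == GAP_CHAR] <- GAP
  out
}

#' Map an ungapped residue position to its alignment column
#'
#' Inverse of [column_to_position()] on non-gap columns.
#'
#' @inheritParams column_to_position
#' @param position 1-based ungapped residue position.
#' @return 1-based alignment column.
#' @export
position_to_column <- function(aln, seq_id, position) {
  ch <- seq_chars(aln, seq_id)
  cols <- which(ch != GAP_CHAR)
  if (any(position < 1L | position > length(cols))) {
    abort(paste0("position out of range for ", seq_id,
                 " (ungapped length ", length(cols), ")"))
  }
  cols[position]
}

#' Find the equivalent residue position in a homolog
#'
#' Maps a residue position in one sequence through its alignment column to
#' the aligned position in another sequence; this is how, e.g., position
#' 954 of one PEPC corresponds to position 946 of another. Returns [GAP]
#' when the second sequence is gapped at that column.
#'
#' @param aln a [clade_aln()].
#' @param seq_id_a,seq_id_b sequence ids.
#' @param pos_a 1-based ungapped position in `seq_id_a`.
#' @return 1-based position in `seq_id_b`, or [GAP].
#' @examples
#' aln <- clade_aln(c(a = "MK-E", b = "MKLE"))
#' equivalent_position(aln, "a", 3, "b")  # 4
#' @export
equivalent_position <- function(aln, seq_id_a, pos_a, seq_id_b) {
  col <- position_to_column(aln, seq_id_a, pos_a)
  column_to_position(aln, seq_id_b, col)
}

#' Full column/position coordinate map for one sequence
#'
#' @inheritParams column_to_position
#' @return tibble with columns `column`, `residue`, `position` (position is
#'   [GAP] at gap columns).
#' @export
coordinate_map <- function(aln, seq_id) {
  ch <- seq_chars(aln, seq_id)
  pos <- cumsum(ch != GAP_CHAR)
  pos[ch == GAP_CHAR] <- GAP
  tibble::tibble(column = seq_along(ch), residue = ch, position = pos)
}

#' Select conserved (low-gap) alignment columns
#'
#' Column-selection step used before distance/tree computation. The
#' `"gap-free"` policy keeps columns with no gaps in any sequence; the
#' `max_gap_fraction` policy keeps columns whose gap fraction does not
#' exceed `f`.
#'
#' @param aln a [clade_aln()].
#' @param policy `"gap-free"` (default) or `"max-gap-fraction"`.
#' @param f maximum tolerated gap fraction when
#'   `policy = "max-gap-fraction"`.
#' @return ascending integer vector of 1-based column indices (possibly
#'   empty).
#' @export
conserved_columns <- function(aln, policy = c("gap-free", "max-gap-fraction"),
                              f = 0) {
  policy <- match.arg(policy)
  m <- alignment_matrix_chr(aln$seq)
  gap_frac <- colMeans(m == GAP_CHAR)
  thr <- if (policy == "gap-free") 0 else f
  which(gap_frac <= thr)
}
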