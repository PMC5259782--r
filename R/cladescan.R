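#' Parameters for the clade-discriminating residue scan
#'
#' @param target_clade clade whose conservation is required (e.g. the order
#'   carrying the divergent regulatory residue).
#' @param contrast_clades clades whose consensus must differ from the
#'   target consensus.
#' @param conservation_threshold minimum target-clade consensus frequency
#'   in `(0, 1]` for a column to count as "highly conserved". Default 0.9.
#' @param other_gap_policy how gapped rows are treated when assessing the
#'   other sequences at a column: `"treat-as-mismatch"` (default; a gap is
#'   counted in the denominator and always differs from any residue) or
#'   `"ignore-gapped-rows"` (gapped rows are dropped from the denominator).
#' @param strict_contrast if `TRUE`, the target consensus residue must be
#'   absent from every member of each contrast clade, not merely differ
#'   from the contrast consensus.
#' @return a list of class `scan_params`.
#' @export
scan_params <- function(target_clade, contrast_clades,
                        conservation_threshold = 0.9,
                        other_gap_policy = c("treat-as-mismatch",
                                             "ignore-gapped-rows"),
                        strict_contrast = FALSE) {
  other_gap_policy <- match.arg(other_gap_policy)
  if (!(conservation_threshold > 0 && conservation_threshold <= 1)) {
    abort("conservation_threshold must be in (0, 1]")
  }
  if (target_clade %in% contrast_clades) {
    abort("target_clade must not appear among contrast_clades")
  }
  structure(list(target_clade = target_clade,
                 contrast_clades = contrast_clades,
                 conservation_threshold = conservation_threshold,
                 other_gap_policy = other_gap_policy,
                 strict_contrast = strict_contrast),
            class = "scan_params")
}

#' Residues unique to a reference sequence
#'
#' Finds every alignment column where the reference carries a non-gap
#' residue that differs from the residue of each other sequence at that
#' column. This is the first filter of the scan that, applied to a
#' cyanobacterial PEPC alignment, isolates the reference-specific residue
#' set from which regulatory candidates are drawn. `X` in the reference is
#' never reported; under `"treat-as-mismatch"` a gap (or `X`) in another
#' sequence counts as different from the reference residue, under
#' `"ignore-gapped-rows"` gapped rows are ignored (a column where all
#' others are gapped is then not unique).
#'
#' @param aln a [clade_aln()] with at least two sequences.
#' @param ref_id reference sequence id.
#' @param other_gap_policy see [scan_params()].
#' @return tibble with one row per unique site: `column`,
#'   `reference_position`, `reference_residue`.
#' @export
reference_unique_positions <- function(aln, ref_id,
                                       other_gap_policy =
                                         c("treat-as-mismatch",
                                           "ignore-gapped-rows")) {
  other_gap_policy <- match.arg(other_gap_policy)
  if (length(aln$seq) < 2L) abort("alignment must have >= 2 sequences")
  m <- alignment_matrix_chr(aln$seq)
  if (!ref_id %in% rownames(m)) abort(paste0("unknown sequence id: ", ref_id))
  ref <- m[ref_id, ]
  others <- m[setdiff(rownames(m), ref_id), , drop = FALSE]
  uniq <- logical(ncol(m))
  for (j in seq_len(ncol(m))) {
    r <- ref[[j]]
    if (r == GAP_CHAR || r == "X") next
    oth <- others[, j]
    if (other_gap_policy == "ignore-gapped-rows") {
      oth <- oth[oth != GAP_CHAR]
      if (!length(oth)) next
    }
    uniq[[j]] <- all(oth != r)
  }
  cols <- which(uniq)
  tibble::tibble(
    column = cols,
    reference_position = if (length(cols))
      column_to_position(aln, ref_id, cols) else integer(),
    reference_residue = ref[cols]
  )
}

#' Modal residue of a clade at one column
#'
#' Returns the most frequent non-gap, non-`X` residue among the clade's
#' members and its frequency. Ties are broken by a fixed alphabetical
#' amino-acid ordering so results are deterministic. Under the
#' `"treat-as-mismatch"` gap policy the frequency denominator is the full
#' clade size; under `"ignore-gapped-rows"` it is the number of members
#' with a residue at the column.
#'
#' @param aln a [clade_aln()] with a clade map.
#' @param clade clade label.
#' @param column 1-based column index.
#' @param other_gap_policy see [scan_params()].
#' @return tibble with columns `clade`, `column`, `residue`, `frequency`,
#'   `n` (denominator). `residue` is `NA` if the clade has no residue at
#'   the column.
#' @export
clade_consensus <- function(aln, clade, column,
                            other_gap_policy = c("treat-as-mismatch",
                                                 "ignore-gapped-rows")) {
  other_gap_policy <- match.arg(other_gap_policy)
  ids <- clade_members(aln, clade)
  if (column < 1L || column > aln$n_columns) abort("column out of range")
  res <- substr(aln$seq[ids], column, column)
  informative <- res[res != GAP_CHAR & res != "X"]
  denom <- if (other_gap_policy == "treat-as-mismatch") length(res)
           else sum(res != GAP_CHAR)
  if (!length(informative) || denom == 0L) {
    return(tibble::tibble(clade = clade, column = column,
                          residue = NA_character_, frequency = 0,
                          n = denom))
  }
  counts <- table(factor(informative, levels = AA_ORDER))
  best <- AA_ORDER[which.max(counts)]  # which.max takes first => AA order
  tibble::tibble(clade = clade, column = column, residue = best,
                 frequency = as.numeric(counts[[best]]) / denom, n = denom)
}

#' Columns conserved in one clade but divergent in others
#'
#' The second filter of the scan: keep columns where the target clade's
#' consensus frequency reaches `conservation_threshold` and the target
#' consensus residue differs from the consensus residue of each contrast
#' clade (or, with `strict_contrast`, is absent from every contrast-clade
#' member).
#'
#' @param aln a [clade_aln()] with a clade map covering all clades named in
#'   `params`.
#' @param params a [scan_params()].
#' @return tibble with one row per discriminating column: `column`,
#'   `target_residue`, `target_frequency`, plus one
#'   `consensus_<clade>`/`frequency_<clade>` pair per contrast clade.
#' @export
discriminating_positions <- function(aln, params) {
  stopifnot(inherits(params, "scan_params"))
  clades <- c(params$target_clade, params$contrast_clades)
  for (cl in clades) clade_members(aln, cl)  # errors on missing clade
  gp <- params$other_gap_policy
  cons <- lapply(clades, function(cl) {
    dplyr::bind_rows(lapply(seq_len(aln$n_columns), function(j)
      clade_consensus(aln, cl, j, other_gap_policy = gp)))
  })
  names(cons) <- clades
  tgt <- cons[[params$target_clade]]
  keep <- !is.na(tgt$residue) &
    tgt$frequency >= params$conservation_threshold
  for (cl in params$contrast_clades) {
    if (params$strict_contrast) {
      ids <- clade_members(aln, cl)
      present <- vapply(seq_len(aln$n_columns), function(j) {
        res <- substr(aln$seq[ids], j, j)
        !is.na(tgt$residue[[j]]) && tgt$residue[[j]] %in% res
      }, logical(1))
      keep <- keep & !present
    } else {
      cc <- cons[[cl]]
      keep <- keep & (is.na(cc$residue) | cc$residue != tgt$residue)
    }
  }
  out <- tibble::tibble(column = which(keep),
                        target_residue = tgt$residue[keep],
                        target_frequency = tgt$frequency[keep])
  for (cl in params$contrast_clades) {
    cc <- cons[[cl]][keep, ]
    out[[paste0("consensus_", cl)]] <- cc$residue
    out[[paste0("frequency_", cl)]] <- cc$frequency
  }
  out
}

#' Candidate allosteric-determinant sites
#'
#' Intersection of the two scan filters: columns both unique to the
#' reference sequence ([reference_unique_positions()]) and
#' clade-discriminating ([discriminating_positions()]). Applied to a full
#' cyanobacterial PEPC alignment with the Nostocales as target clade this
#' is the screen that narrows 28 reference-unique residues to the two
#' regulatory candidates.
#'
#' @param aln a [clade_aln()] with clade map.
#' @param ref_id reference sequence id.
#' @param params a [scan_params()].
#' @return tibble sorted by ascending column: `column`,
#'   `reference_position`, `reference_residue`, target/contrast consensus
#'   columns as in [discriminating_positions()], and `passes` (string
#'   naming the filters passed).
#' @export
candidate_screen <- function(aln, ref_id, params) {
  uniq <- reference_unique_positions(aln, ref_id,
                                     other_gap_policy = params$other_gap_policy)
  disc <- discriminating_positions(aln, params)
  out <- dplyr::inner_join(uniq, disc, by = "column")
  out$passes <- "reference-unique,clade-discriminating"
  dplyr::arrange(out, .data$column)
}

#' Conservation report for known functional positions
#'
#' For user-supplied reference positions (e.g. residues known to form an
#' inhibitor-binding site), reports the reference residue, each clade's
#' consensus and frequency, and whether the residue is identical across
#' every sequence in the alignment.
#'
#' @param aln a [clade_aln()] with clade map.
#' @param ref_id reference sequence id.
#' @param positions 1-based reference positions, reported in input order.
#' @param other_gap_policy see [scan_params()].
#' @return tibble with one row per (position, clade):
#'   `reference_position`, `column`, `reference_residue`, `clade`,
#'   `consensus`, `frequency`, `conserved_in_all`.
#' @export
known_site_conservation <- function(aln, ref_id, positions,
                                    other_gap_policy =
                                      c("treat-as-mismatch",
                                        "ignore-gapped-rows")) {
  other_gap_policy <- match.arg(other_gap_policy)
  if (is.null(aln$clades)) abort("alignment has no clade map")
  clades <- unique(unname(aln$clades))
  m <- alignment_matrix_chr(aln$seq)
  rows <- lapply(positions, function(p) {
    col <- position_to_column(aln, ref_id, p)
    ref_res <- m[ref_id, col]
    all_same <- all(m[, col] == ref_res)
    dplyr::bind_rows(lapply(clades, function(cl) {
      cc <- clade_consensus(aln, cl, col, other_gap_policy = other_gap_policy)
      tibble::tibble(reference_position = p, column = col,
                     reference_residue = ref_res, clade = cl,
                     consensus = cc$residue, frequency = cc$frequency,
                     conserved_in_all = all_same)
    }))
  })
  dplyr::bind_rows(rows)
}

#' Aliphatic index of a protein sequence
#'
#' A weighted fraction of the aliphatic side chains (Ala, Val, Ile, Leu),
#' used as a proxy for thermostability. The default is the classical
#' Ikai-weighted index
#' \deqn{Ai = 100\,(X_{Ala} + 2.9\,X_{Val} + 3.9\,(X_{Ile} + X_{Leu}))}
#' with `X` the mole fractions over all (ungapped) residues;
#' `method = "fraction"` instead returns the plain percentage of residues
#' that are A/V/I/L.
#'
#' @param sequence a character string (gaps are removed) or a single-row
#'   entry of [tidy.clade_aln()].
#' @param method `"ikai"` (default) or `"fraction"`.
#' @return numeric scalar.
#' @examples
#' aliphatic_index("AVIL")  # 292.5
#' @export
aliphatic_index <- function(sequence, method = c("ikai", "fraction")) {
  method <- match.arg(method)
  s <- gsub(GAP_CHAR, "", toupper(sequence), fixed = TRUE)
  if (!nzchar(s)) abort("empty sequence")
  ch <- strsplit(s, "")[[1]]
  n <- length(ch)
  x <- function(a) sum(ch == a) / n
  if (method == "ikai") {
    100 * (x("A") + 2.9 * x("V") + 3.9 * (x("I") + x("L")))
  } else {
    100 * (x("A") + x("V") + x("I") + x("L"))
  }
}
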