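#' Configuration for the clade-structured MSA simulator
#'
#' Describes a synthetic protein family shaped like an order-level
#' alignment panel: several clades diverged from a common root, one
#' designated reference sequence, and planted signal columns whose
#' identity is recorded as ground truth.
#'
#' Two kinds of signal are planted:
#' * *reference-unique* columns — the reference carries a residue that
#'   differs from every other sequence (but all other sequences agree, so
#'   the column is not clade-discriminating);
#' * *candidate* columns — the reference is unique **and** the target
#'   clade is perfectly conserved for a residue that differs from every
#'   other clade's residue, i.e. the column passes both scan filters.
#'
#' Planted columns are kept gap-free and noise-free so that, at any noise
#' level, the planted truth is exactly recoverable; substitution noise and
#' indels act on the remaining columns only.
#'
#' @param clades named integer vector: clade label -> number of
#'   sequences. The first clade hosts the reference (its first sequence);
#'   the second clade is the default target of [scan_params()].
#' @param length number of alignment columns.
#' @param clade_divergence per-column probability that a clade's
#'   consensus differs from the root residue.
#' @param within_noise per-residue substitution probability within a
#'   clade (0 = every member equals its clade consensus).
#' @param indel_prob per-residue gap probability at non-planted columns.
#' @param planted_unique columns to plant as reference-unique only.
#' @param planted_candidate columns to plant as scan candidates.
#' @param seed RNG seed (required; the generator is a pure function of
#'   the config).
#' @return a list of class `msa_sim_config`.
#' @export
msa_sim_config <- function(clades = c(Chroococcales = 3L, Nostocales = 3L,
                                      Oscillatoriales = 3L),
                           length = 120L,
                           clade_divergence = 0.1,
                           within_noise = 0,
                           indel_prob = 0,
                           planted_unique = integer(),
                           planted_candidate = integer(),
                           seed) {
  if (missing(seed)) abort("seed is required")
  if (length(clades) < 2L || is.null(names(clades))) {
    abort("clades must be a named vector with >= 2 clades")
  }
  if (any(clades < 1L)) abort("every clade needs >= 1 sequence")
  probs <- c(clade_divergence, within_noise, indel_prob)
  if (any(probs < 0 | probs > 1)) abort("probabilities must be in [0, 1]")
  planted_unique <- as.integer(planted_unique)
  planted_candidate <- as.integer(planted_candidate)
  if (length(intersect(planted_unique, planted_candidate))) {
    abort("planted column lists must be disjoint")
  }
  planted <- c(planted_unique, planted_candidate)
  if (length(planted) && (any(planted < 1L) || any(planted > length))) {
    abort("planted columns outside the alignment")
  }
  structure(list(clades = clades, length = as.integer(length),
                 clade_divergence = clade_divergence,
                 within_noise = within_noise, indel_prob = indel_prob,
                 planted_unique = planted_unique,
                 planted_candidate = planted_candidate,
                 seed = as.integer(seed)),
            class = "msa_sim_config")
}

#' Simulate a clade-structured alignment with planted sites
#'
#' @param config an [msa_sim_config()].
#' @return a list with elements
#'   * `alignment` — a [clade_aln()] with clade map; sequence ids are
#'     `<clade>_<i>`, the reference is the first sequence of the first
#'     clade;
#'   * `ref_id` — the reference id;
#'   * `truth` — tibble of planted sites: `column`, `type`
#'     (`"unique"`/`"candidate"`), `reference_position` (after indels),
#'     `reference_residue`, `target_residue`, `background_residue`.
#' @examples
#' sim <- generate_clade_msa(msa_sim_config(length = 60, seed = 1,
#'                                          planted_candidate = 10))
#' sim$truth
#' @export
generate_clade_msa <- function(config) {
  stopifnot(inherits(config, "msa_sim_config"))
  set.seed(config$seed)
  L <- config$length
  clade_labels <- names(config$clades)
  target_clade <- clade_labels[[2L]]
  root <- sample(AA_ORDER, L, replace = TRUE)

  clade_cons <- lapply(clade_labels, function(cl) {
    cons <- root
    flip <- stats::runif(L) < config$clade_divergence
    cons[flip] <- vapply(cons[flip], mutate_residue, character(1))
    cons
  })
  names(clade_cons) <- clade_labels

  ids <- unlist(lapply(clade_labels, function(cl)
    paste0(cl, "_", seq_len(config$clades[[cl]]))))
  clade_of <- setNames(rep(clade_labels, config$clades), ids)
  ref_id <- ids[[1L]]

  m <- matrix("", nrow = length(ids), ncol = L,
              dimnames = list(ids, NULL))
  for (id in ids) {
    s <- clade_cons[[clade_of[[id]]]]
    if (config$within_noise > 0) {
      flip <- stats::runif(L) < config$within_noise
      s[flip] <- vapply(s[flip], mutate_residue, character(1))
    }
    m[id, ] <- s
  }

  # plant signals (overwrites noise; planted columns stay gap-free)
  truth_rows <- list()
  for (col in config$planted_unique) {
    bg <- sample(AA_ORDER, 1L)
    a <- mutate_residue(bg)
    m[, col] <- bg
    m[ref_id, col] <- a
    truth_rows[[length(truth_rows) + 1L]] <-
      tibble::tibble(column = col, type = "unique",
                     reference_residue = a, target_residue = bg,
                     background_residue = bg)
  }
  for (col in config$planted_candidate) {
    res3 <- sample(AA_ORDER, 3L)  # a = ref, c = target clade, b = rest
    a <- res3[[1L]]; c_ <- res3[[2L]]; b <- res3[[3L]]
    m[, col] <- b
    m[ids[clade_of == target_clade], col] <- c_
    m[ref_id, col] <- a
    truth_rows[[length(truth_rows) + 1L]] <-
      tibble::tibble(column = col, type = "candidate",
                     reference_residue = a, target_residue = c_,
                     background_residue = b)
  }

  if (config$indel_prob > 0) {
    planted <- c(config$planted_unique, config$planted_candidate)
    ref_mates <- which(clade_of == clade_of[[ref_id]] & ids != ref_id)
    for (j in setdiff(seq_len(L), planted)) {
      gap <- stats::runif(length(ids)) < config$indel_prob
      if (all(gap)) gap[sample(length(ids), 1L)] <- FALSE
      # keep one ungapped clade-mate of the reference so that, at zero
      # substitution noise, reference-unique columns exist only where planted
      if (length(ref_mates) && all(gap[ref_mates])) {
        gap[ref_mates[sample(length(ref_mates), 1L)]] <- FALSE
      }
      m[gap, j] <- GAP_CHAR
    }
  }

  aln <- clade_aln(setNames(apply(m, 1L, paste, collapse = ""), ids),
                   clades = clade_of)
  truth <- if (length(truth_rows)) dplyr::bind_rows(truth_rows)
           else tibble::tibble(column = integer(), type = character(),
                               reference_residue = character(),
                               target_residue = character(),
                               background_residue = character())
  if (nrow(truth)) {
    truth$reference_position <-
      column_to_position(aln, ref_id, truth$column)
    truth <- dplyr::arrange(truth, .data$column)
  } else {
    truth$reference_position <- integer()
  }
  list(alignment = aln, ref_id = ref_id, truth = truth)
}

# uniform substitution to one of the 19 other residues
mutate_residue <- function(res) {
  sample(setdiff(AA_ORDER, res), 1L)
}
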