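# Shared fixture builders; everything is generated in code.

# noiseless (or multiplicative-noise) Michaelis-Menten velocities
mm_data <- function(vmax, km, s = c(0.125, 0.25, 0.5, 1, 2, 4),
                    cv = 0, reps = 1L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  d <- expand.grid(substrate_mM = s, replicate = seq_len(reps))
  mu <- vmax * d$substrate_mM / (km + d$substrate_mM)
  noise <- if (cv > 0) 1 + cv * rnorm(nrow(d)) else 1
  d$velocity <- pmax(1e-12, mu * noise)
  d
}

# random gapped alignment for fuzz tests (no all-gap columns)
random_gapped_alignment <- function(n_seq, n_col, gap_prob = 0.2) {
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
          "P", "Q", "R", "S", "T", "V", "W", "Y")
  repeat {
    m <- matrix(sample(aa, n_seq * n_col, replace = TRUE), n_seq, n_col)
    gap <- matrix(runif(n_seq * n_col) < gap_prob, n_seq, n_col)
    # keep at least one residue per sequence and per column
    for (j in which(colSums(!gap) == 0)) gap[sample(n_seq, 1), j] <- FALSE
    if (any(rowSums(!gap) == 0)) next
    m[gap] <- "-"
    seqs <- apply(m, 1, paste, collapse = "")
    names(seqs) <- paste0("s", seq_len(n_seq))
    return(clade_aln(seqs))
  }
}

# toy three-clade alignment used across scan tests:
# column 2 is clade-discriminating (A: K, B: E, C: E is NOT discriminating;
# built explicitly per test), so tests construct what they need from this.
toy_clades <- function(seqs) {
  ids <- names(seqs)
  clade <- sub("_.*$", "", ids)
  clade_aln(seqs, clades = setNames(clade, ids))
}

# independent naive residue scan: straight double loop over columns,
# re-deriving both filters from their definitions
naive_candidate_columns <- function(aln, ref_id, target, contrasts,
                                    threshold = 0.9) {
  tid <- tidy(aln)
  chars <- strsplit(setNames(tid$sequence, tid$id), "")
  clade_of <- setNames(tid$clade, tid$id)
  ncol <- nchar(tid$sequence[[1]])
  aa_order <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
                "P", "Q", "R", "S", "T", "V", "W", "Y")
  consensus <- function(ids, j) {
    res <- vapply(ids, function(i) chars[[i]][j], character(1))
    keep <- res[!res %in% c("-", "X")]
    if (!length(keep)) return(list(res = NA_character_, f = 0))
    counts <- table(factor(keep, levels = aa_order))
    best <- aa_order[which.max(counts)]
    list(res = best, f = counts[[best]] / length(res))
  }
  out <- integer()
  for (j in seq_len(ncol)) {
    r <- chars[[ref_id]][j]
    if (r %in% c("-", "X")) next
    others <- setdiff(names(chars), ref_id)
    uniq <- all(vapply(others, function(i) chars[[i]][j] != r, logical(1)))
    if (!uniq) next
    tc <- consensus(names(clade_of)[clade_of == target], j)
    if (is.na(tc$res) || tc$f < threshold) next
    ok <- all(vapply(contrasts, function(cl) {
      cc <- consensus(names(clade_of)[clade_of == cl], j)
      is.na(cc$res) || cc$res != tc$res
    }, logical(1)))
    if (ok) out <- c(out, j)
  }
  out
}
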