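#' Pairwise protein distances over selected columns
#'
#' Computes the proportion of mismatching residues (p-distance) between
#' every pair of sequences over the chosen columns, with pairwise deletion
#' of sites where either sequence has a gap or `X`. The Poisson correction
#' `d = -ln(1 - p)` accounts for multiple substitutions and is the default
#' input to [neighbor_joining()].
#'
#' @param aln a [clade_aln()].
#' @param columns columns to use; defaults to [conserved_columns()] under
#'   the gap-free policy.
#' @param model `"poisson"` (default) or `"p-distance"`.
#' @return a symmetric numeric matrix with zero diagonal, sequence ids as
#'   dimnames.
#' @section Errors: a pair with no mutually ungapped column, or a pair with
#'   `p = 1` under the Poisson model (infinite distance), is an error; use
#'   `model = "p-distance"` or restrict `columns` in that case.
#' @export
pairwise_distances <- function(aln, columns = conserved_columns(aln),
                               model = c("poisson", "p-distance")) {
  model <- match.arg(model)
  if (!length(columns)) abort("no columns selected")
  if (any(columns < 1L | columns > aln$n_columns)) {
    abort("column index out of range")
  }
  m <- alignment_matrix_chr(aln$seq)[, columns, drop = FALSE]
  ok <- m != GAP_CHAR & m != "X"
  n <- nrow(m)
  ids <- rownames(m)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      comp <- ok[i, ] & ok[j, ]
      nc <- sum(comp)
      if (nc == 0L) {
        abort(paste0("no comparable (mutually ungapped) columns between ",
                     ids[[i]], " and ", ids[[j]]))
      }
      p <- sum(m[i, comp] != m[j, comp]) / nc
      if (model == "poisson") {
        if (p >= 1) {
          abort(paste0("saturated pair ", ids[[i]], "/", ids[[j]],
                       " (p = 1): Poisson distance is infinite; ",
                       "use model = \"p-distance\""))
        }
        p <- -log(1 - p)
      }
      d[i, j] <- d[j, i] <- p
    }
  }
  d
}

#' Neighbor-joining tree
#'
#' Standard NJ agglomeration (via [ape::nj()]) on a distance matrix; exact
#' on additive matrices. Negative branch lengths, which NJ can produce on
#' noisy matrices, are clamped to zero with the deficit moved to the
#' adjacent (sibling) edge, and a message is emitted.
#'
#' @param d symmetric distance matrix (ids as dimnames) or `dist`.
#' @return an unrooted `phylo` tree (ape).
#' @export
neighbor_joining <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (nrow(d) < 3L) abort("neighbor joining requires >= 3 taxa")
  if (max(abs(d - t(d))) > 1e-8) abort("distance matrix is not symmetric")
  tree <- ape::nj(stats::as.dist(d))
  clamp_negative_branches(tree)
}

clamp_negative_branches <- function(tree) {
  neg <- which(tree$edge.length < 0)
  if (!length(neg)) return(tree)
  for (e in neg) {
    deficit <- -tree$edge.length[[e]]
    tree$edge.length[[e]] <- 0
    parent <- tree$edge[e, 1L]
    sibs <- which(tree$edge[, 1L] == parent)
    sibs <- setdiff(sibs, e)
    if (length(sibs)) {
      s <- sibs[[1L]]
      tree$edge.length[[s]] <- max(0, tree$edge.length[[s]] + deficit)
    }
  }
  message(length(neg), " negative NJ branch length(s) clamped to zero")
  tree
}

#' NJ tree with column-bootstrap support
#'
#' Builds the point-estimate NJ tree from the selected columns, then
#' resamples columns with replacement (same count) `n_reps` times,
#' rebuilds the tree per replicate, and annotates each internal edge of the
#' point tree with the percentage of replicates containing the same
#' bipartition. Replicates whose distance computation fails (e.g. a
#' saturated pair in the resample) are skipped with a warning and the
#' denominator adjusted.
#'
#' @inheritParams pairwise_distances
#' @param n_reps number of bootstrap replicates (>= 1).
#' @param seed RNG seed; required so runs are reproducible.
#' @return a `phylo` tree whose `node.label` holds bootstrap percentages
#'   (in `[0, 100]`, root label empty).
#' @export
bootstrap_support <- function(aln, columns = conserved_columns(aln),
                              n_reps = 500L, seed,
                              model = c("poisson", "p-distance")) {
  model <- match.arg(model)
  if (missing(seed)) abort("seed is required for bootstrap_support")
  if (n_reps < 1L) abort("n_reps must be >= 1")
  point <- neighbor_joining(pairwise_distances(aln, columns, model))
  set.seed(as.integer(seed))
  reps <- vector("list", n_reps)
  failed <- 0L
  for (b in seq_len(n_reps)) {
    cols_b <- sample(columns, length(columns), replace = TRUE)
    reps[[b]] <- tryCatch(
      suppressMessages(neighbor_joining(pairwise_distances(aln, cols_b,
                                                           model))),
      error = function(e) NULL
    )
    if (is.null(reps[[b]])) failed <- failed + 1L
  }
  reps <- reps[!vapply(reps, is.null, logical(1))]
  if (failed > 0L) {
    warn(paste0(failed, " bootstrap replicate(s) skipped after distance ",
                "errors; supports use ", length(reps), " replicates"))
  }
  if (!length(reps)) abort("all bootstrap replicates failed")
  counts <- ape::prop.clades(point, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0
  support <- round(100 * counts / length(reps), 1)
  point$node.label <- as.character(support)
  point$node.label[[1L]] <- ""  # root of the unrooted representation
  point
}

#' Test whether a taxon set is monophyletic in an unrooted tree
#'
#' `TRUE` iff some edge of the unrooted tree bipartitions the leaves into
#' exactly (`taxa`, rest). Singleton sets, the complement of a singleton,
#' and the full leaf set are trivially monophyletic.
#'
#' @param tree a `phylo` object.
#' @param taxa non-empty character vector of tip labels.
#' @return logical scalar.
#' @export
is_monophyletic <- function(tree, taxa) {
  tips <- tree$tip.label
  if (!length(taxa)) abort("taxa must be non-empty")
  unknown <- setdiff(taxa, tips)
  if (length(unknown)) {
    abort(paste0("unknown taxa: ", paste(unknown, collapse = ", ")))
  }
  taxa <- unique(taxa)
  k <- length(taxa)
  n <- length(tips)
  if (k %in% c(1L, n - 1L, n)) return(TRUE)
  parts <- ape::prop.part(tree)
  target <- sort(match(taxa, tips))
  comp <- sort(setdiff(seq_len(n), target))
  any(vapply(parts, function(p) {
    p <- sort(p)
    identical(p, target) || identical(p, comp)
  }, logical(1)))
}

#' Read and write Newick trees
#'
#' Thin wrappers over [ape::read.tree()] and [ape::write.tree()]; bootstrap
#' supports travel as internal node labels. Branch lengths are written with
#' 6 significant digits.
#'
#' @param tree a `phylo` object.
#' @param path file path.
#' @return `write_newick()` returns `path` invisibly; `read_newick()`
#'   returns a `phylo`.
#' @export
write_newick <- function(tree, path) {
  if (!is.null(tree$edge.length)) {
    tree$edge.length <- signif(tree$edge.length, 6)
  }
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  tree <- tryCatch(suppressWarnings(ape::read.tree(path)),
                   error = function(e) abort(paste0("malformed Newick: ",
                                                    conditionMessage(e))))
  if (is.null(tree)) abort("malformed Newick file")
  tree
}

#' Export a distance matrix as TSV (PHYLIP-like square format)
#'
#' @param d symmetric distance matrix with ids as dimnames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_distances <- function(d, path) {
  df <- data.frame(id = rownames(d), d, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
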