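#' Run the residue scan on files
#'
#' File-level wrapper over [candidate_screen()] and (optionally)
#' [known_site_conservation()]: reads an aligned FASTA and a clade TSV,
#' writes a TSV site report plus a short text summary, and returns the
#' candidate table.
#'
#' @param msa_path aligned FASTA path.
#' @param clade_path two-column TSV `sequence_id<TAB>clade`.
#' @param ref_id reference sequence id.
#' @param target_clade,contrast_clades scan clades (defaults: all
#'   non-target clades contrast).
#' @param threshold conservation threshold (see [scan_params()]).
#' @param known_positions optional reference positions for the known-site
#'   conservation report.
#' @param out_dir output directory (created if needed); `NULL` disables
#'   file output.
#' @return list with `candidates`, `unique_sites`, `known_sites`
#'   (tibbles; `known_sites` `NULL` unless requested).
#' @export
run_scan <- function(msa_path, clade_path, ref_id, target_clade,
                     contrast_clades = NULL, threshold = 0.9,
                     known_positions = NULL, out_dir = NULL) {
  clades <- read_clade_table(clade_path)
  aln <- read_fasta(msa_path, expect_aligned = TRUE, clades = clades)
  if (is.null(contrast_clades)) {
    contrast_clades <- setdiff(unique(clades$clade), target_clade)
  }
  params <- scan_params(target_clade, contrast_clades,
                        conservation_threshold = threshold)
  uniq <- reference_unique_positions(aln, ref_id)
  cand <- candidate_screen(aln, ref_id, params)
  known <- if (!is.null(known_positions)) {
    known_site_conservation(aln, ref_id, known_positions)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_report_tsv(cand, file.path(out_dir, "candidate_sites.tsv"),
                     header = c(paste0("reference: ", ref_id),
                                paste0("target clade: ", target_clade),
                                paste0("threshold: ", threshold)))
    write_report_tsv(uniq, file.path(out_dir, "reference_unique_sites.tsv"))
    if (!is.null(known)) {
      write_report_tsv(known, file.path(out_dir, "known_site_conservation.tsv"))
    }
    summary_lines <- c(
      paste0("reference-unique residues: ", nrow(uniq)),
      paste0("candidate sites (unique + clade-discriminating): ",
             nrow(cand)),
      if (nrow(cand)) paste0("  reference positions: ",
                             paste(cand$reference_position, collapse = ", ")))
    writeLines(summary_lines, file.path(out_dir, "scan_summary.txt"))
  }
  list(candidates = cand, unique_sites = uniq, known_sites = known)
}

#' Build a bootstrap NJ tree from files
#'
#' Reads an aligned FASTA, computes Poisson-corrected distances over
#' gap-free columns, builds the NJ tree with column-bootstrap supports and
#' writes it as Newick.
#'
#' @inheritParams run_scan
#' @param n_reps bootstrap replicates (default 500).
#' @param seed RNG seed (required).
#' @param model distance model (see [pairwise_distances()]).
#' @param out_path Newick output path; `NULL` disables file output.
#' @return the annotated `phylo` tree.
#' @export
run_tree <- function(msa_path, n_reps = 500L, seed,
                     model = "poisson", out_path = NULL) {
  aln <- read_fasta(msa_path, expect_aligned = TRUE)
  tree <- bootstrap_support(aln, n_reps = n_reps, seed = seed,
                            model = model)
  if (!is.null(out_path)) write_newick(tree, out_path)
  tree
}

#' Run the kinetics analysis on an assay table
#'
#' Accepts a long-format CSV/TSV of either pre-reduced velocities or raw
#' A340 traces. Traces are reduced with [initial_rate()] first. Then, per
#' variant/effector with a substrate titration, Michaelis-Menten
#' parameters are fitted by both the double-reciprocal and nonlinear
#' routes; conditions measured at a single substrate concentration are
#' analysed as an effector relative-activity panel instead.
#'
#' Required columns: `variant`, `effector` (`MOCK` for no effector),
#' `substrate_mM`, `replicate`, and either `velocity` or
#' (`time_s`, `A340`).
#'
#' @param assay_path CSV/TSV file path.
#' @param out_dir output directory for TSV reports; `NULL` disables file
#'   output.
#' @return list with `fits` (tibble of per-condition LB and NLS
#'   parameters), `effects` (relative-activity tibble per variant, or
#'   `NULL`), `rates` (the reduced velocity table).
#' @export
run_kinetics <- function(assay_path, out_dir = NULL) {
  sep <- if (grepl("\\.csv$", assay_path, ignore.case = TRUE)) "," else "\t"
  df <- tibble::as_tibble(read.delim(assay_path, sep = sep,
                                     comment.char = "#"))
  need <- c("variant", "effector", "substrate_mM", "replicate")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    abort(paste0("assay table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!"velocity" %in% names(df)) {
    if (!all(c("time_s", "A340") %in% names(df))) {
      abort("assay table needs either a velocity column or time_s + A340")
    }
    df <- dplyr::group_modify(
      dplyr::group_by(df, .data$variant, .data$effector,
                      .data$substrate_mM, .data$replicate),
      function(tr, key) {
        r <- initial_rate(tr)
        tibble::tibble(velocity = r$velocity_units)
      })
    df <- dplyr::ungroup(df)
  }
  rates <- df

  fits <- dplyr::bind_rows(lapply(
    split(rates, interaction(rates$variant, rates$effector, drop = TRUE)),
    function(d) {
      if (length(unique(d$substrate_mM)) < 3L) return(NULL)
      row <- function(method) {
        f <- fit_michaelis_menten(d, method = method)
        tibble::tibble(variant = d$variant[[1]],
                       effector = d$effector[[1]], method = method,
                       vmax = f$vmax, km_mM = f$km,
                       r_squared = f$r_squared, n_points = f$n_points)
      }
      dplyr::bind_rows(row("LB"), row("NLS"))
    }))

  single <- dplyr::ungroup(dplyr::mutate(
    dplyr::group_by(rates, .data$variant, .data$effector),
    n_conc = dplyr::n_distinct(.data$substrate_mM)))
  single <- dplyr::filter(single, .data$n_conc < 3L)
  effects <- NULL
  if (nrow(single) && "MOCK" %in% single$effector) {
    effects <- dplyr::bind_rows(lapply(split(single, single$variant),
      function(d) {
        if (!"MOCK" %in% d$effector) return(NULL)
        tab <- effector_table(d)
        tab$variant <- d$variant[[1]]
        tab
      }))
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    if (nrow(fits)) write_report_tsv(fits, file.path(out_dir, "kinetic_fits.tsv"))
    if (!is.null(effects)) {
      write_report_tsv(effects, file.path(out_dir, "effector_effects.tsv"))
    }
  }
  list(fits = fits, effects = effects, rates = rates)
}

#' Emit a synthetic dataset with its ground truth
#'
#' Convenience wrapper used by the command-line interface: simulates an
#' alignment panel ([generate_clade_msa()]) and an assay dataset
#' ([generate_assay_dataset()]) and writes them in the same formats the
#' analysis consumes (FASTA + clade TSV + assay CSV), each paired with a
#' JSON truth record.
#'
#' @param out_dir output directory.
#' @param seed RNG seed (required).
#' @param msa_config,assay_config optional configs; sensible defaults
#'   (one planted candidate, wild-type-like kinetics) are used when
#'   omitted.
#' @return list with the simulated objects, invisibly.
#' @export
run_simulate <- function(out_dir, seed, msa_config = NULL,
                         assay_config = NULL) {
  if (missing(seed)) abort("seed is required")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(msa_config)) {
    msa_config <- msa_sim_config(length = 200L, indel_prob = 0.02,
                                 planted_unique = c(30L, 90L),
                                 planted_candidate = 150L, seed = seed)
  }
  if (is.null(assay_config)) {
    assay_config <- assay_sim_config(
      variants = tibble::tibble(variant = "WT",
                                vmax = 1.74 * 0.6e-3, km_mM = 0.34),
      effectors = tibble::tibble(effector = "malate",
                                 vmax_factor = 1.26, km_factor = 2.4),
      cv = 0.05, seed = seed)
  }
  sim_msa <- generate_clade_msa(msa_config)
  sim_assay <- generate_assay_dataset(assay_config)

  write_fasta(sim_msa$alignment, file.path(out_dir, "alignment.fasta"))
  aln_tbl <- tidy(sim_msa$alignment)
  write.table(aln_tbl[, c("id", "clade")],
              file.path(out_dir, "clades.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  utils::write.csv(sim_assay$rates, file.path(out_dir, "assay.csv"),
                   row.names = FALSE)
  truth <- list(seed = seed, ref_id = sim_msa$ref_id,
                planted_sites = sim_msa$truth,
                kinetic_truth = sim_assay$truth)
  writeLines(to_truth_json(truth), file.path(out_dir, "truth.json"))
  invisible(list(msa = sim_msa, assay = sim_assay))
}

# minimal JSON emitter for truth records (data frames of scalars only)
to_truth_json <- function(x) {
  enc <- function(v) {
    if (is.data.frame(v)) {
      rows <- vapply(seq_len(nrow(v)), function(i) {
        fields <- vapply(names(v), function(nm)
          paste0("\"", nm, "\": ", enc(v[[nm]][[i]])), character(1))
        paste0("{", paste(fields, collapse = ", "), "}")
      }, character(1))
      paste0("[", paste(rows, collapse = ", "), "]")
    } else if (is.list(v)) {
      fields <- vapply(names(v), function(nm)
        paste0("\"", nm, "\": ", enc(v[[nm]])), character(1))
      paste0("{", paste(fields, collapse = ", "), "}")
    } else if (is.character(v)) {
      paste0("\"", v, "\"")
    } else if (is.na(v)) {
      "null"
    } else {
      format(v, digits = 15)
    }
  }
  enc(x)
}

write_report_tsv <- function(df, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
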