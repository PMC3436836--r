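# pipeline: wire surfaces -> structural features -> sequence features ->
# training / cross-validation

#' Pipeline run configuration
#'
#' Collects every input and tunable of an end-to-end run. Structures and
#' alignment rows are joined by instance name (whitespace-stripped,
#' case-sensitive).
#'
#' @param structures Named list of \code{ProteinStructure} objects or named
#'   character vector of PDB paths.
#' @param alignment A \code{\link{labeled_alignment}} whose names match the
#'   structure names, or a path to an aligned FASTA/Stockholm file (then
#'   \code{labels} is required).
#' @param labels Optional named 0/1 vector (or label TSV path) when
#'   \code{alignment} is a file path.
#' @param grids Optional named list of \code{ScalarGrid}s or DX paths for the
#'   electrostatic channel; structures without one fall back to
#'   \code{\link{coulomb_grid}}.
#' @param probe_radius,grid_spacing Surface construction (Angstrom).
#' @param offset Grid-to-surface probe offset (Angstrom).
#' @param hyd_C,hyd_min Hydrophobic patch tolerance and eligibility cutoff.
#' @param rule_lengths,n_bootstrap,n_rules Rule-mining parameters.
#' @param n_iterations ADtree boosting rounds.
#' @param n_folds,algo Cross-validation folds and algorithm
#'   ("adtree" or "svm").
#' @param seed Single seed behind all stochastic steps.
#' @return A \code{RunConfig}.
#' @export
run_config <- function(structures, alignment, labels = NULL, grids = NULL,
                       probe_radius = 1.4, grid_spacing = 0.6, offset = 1.0,
                       hyd_C = 1.5, hyd_min = 0, rule_lengths = 3:6,
                       n_bootstrap = 50, n_rules = 25, n_iterations = 15,
                       n_folds = 20, algo = c("adtree", "svm"), seed = 1) {
  algo <- match.arg(algo)
  stopifnot(probe_radius > 0, grid_spacing > 0, n_rules >= 1,
            n_bootstrap >= 1, n_iterations >= 1, n_folds >= 2)
  structure(list(structures = structures, alignment = alignment,
                 labels = labels, grids = grids, probe_radius = probe_radius,
                 grid_spacing = grid_spacing, offset = offset, hyd_C = hyd_C,
                 hyd_min = hyd_min, rule_lengths = rule_lengths,
                 n_bootstrap = n_bootstrap, n_rules = n_rules,
                 n_iterations = n_iterations, n_folds = n_folds, algo = algo,
                 seed = seed),
            class = "RunConfig")
}

load_structures <- function(structures) {
  if (is.character(structures)) structures <- lapply(structures, read_pdb)
  if (is.null(names(structures)) || any(!nzchar(names(structures))))
    stop("structures must be named by instance")
  names(structures) <- trimws(names(structures))
  structures
}

load_alignment <- function(alignment, labels) {
  if (inherits(alignment, "LabeledAlignment")) return(alignment)
  raw <- if (grepl("\\.(sto|stk|stockholm)$", alignment))
    read_stockholm(alignment) else read_fasta_alignment(alignment)
  if (is.character(labels) && length(labels) == 1) labels <- read_labels_tsv(labels)
  if (is.null(labels)) stop("labels are required with an alignment file")
  miss <- setdiff(raw$names, names(labels))
  if (length(miss))
    stop("no label for alignment row(s): ", paste(miss, collapse = ", "))
  labeled_alignment(raw$names, raw$rows, labels[raw$names])
}

#' Structural feature row for one structure
#'
#' Builds the surface, maps the three channels (DX grid if supplied,
#' screened-Coulomb fallback otherwise) and computes the 35 structural
#' features.
#'
#' @param struct A \code{ProteinStructure}.
#' @param grid Optional \code{ScalarGrid} (or DX path) for electrostatics.
#' @param config A \code{\link{run_config}} (surface/patch parameters).
#' @return Named numeric vector of length 35.
#' @export
structure_features <- function(struct, grid = NULL, config = NULL) {
  probe <- if (is.null(config)) 1.4 else config$probe_radius
  spacing <- if (is.null(config)) 0.6 else config$grid_spacing
  offset <- if (is.null(config)) 1.0 else config$offset
  hyd_C <- if (is.null(config)) 1.5 else config$hyd_C
  hyd_min <- if (is.null(config)) 0 else config$hyd_min
  if (is.character(grid)) grid <- read_dx(grid)
  if (is.null(grid)) grid <- coulomb_grid(struct)
  mesh <- build_surface(struct, probe_radius = probe, grid_spacing = spacing)
  mesh <- map_grid_to_surface(mesh, grid, offset = offset, channel_name = "elec")
  mesh <- map_hydrophobicity(mesh, struct, channel_name = "hyd")
  mesh <- map_hbond(mesh, struct, channel_name = "hbond")
  structural_features(mesh, hyd_C = hyd_C, hyd_min = hyd_min)
}

#' Run the full pipeline
#'
#' Computes 35 structural features per structure and 25 subsequence-rule
#' features per aligned sequence, joins them by instance name into a
#' 60-column table, trains the configured classifier on the joined table and
#' (when enough instances exist) cross-validates it.
#'
#' @param config A \code{\link{run_config}}.
#' @return List with \code{features} (data.frame, 60 columns + label),
#'   \code{rules}, \code{rfc}, \code{model} (trained on all instances),
#'   \code{report} (an \code{EvalReport}, or NULL when n < n_folds).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  structures <- load_structures(config$structures)
  aln <- load_alignment(config$alignment, config$labels)
  aln$names <- trimws(aln$names)

  s_names <- names(structures)
  only_s <- setdiff(s_names, aln$names)
  only_a <- setdiff(aln$names, s_names)
  if (length(only_s) || length(only_a))
    stop("instance name mismatch between structures and alignment; ",
         "structure-only: [", paste(only_s, collapse = ", "),
         "] alignment-only: [", paste(only_a, collapse = ", "), "]")

  grids <- config$grids
  struct_feats <- t(vapply(s_names, function(nm)
    structure_features(structures[[nm]],
                       grid = if (!is.null(grids)) grids[[nm]] else NULL,
                       config = config),
    numeric(35)))

  rfc <- compute_rfc(aln)
  rules <- mine_subseq_rules(aln, lengths = config$rule_lengths,
                             n_bootstrap = config$n_bootstrap,
                             n_rules = config$n_rules, seed = config$seed)
  seq_feats <- t(vapply(seq_along(aln$rows), function(i)
    subseq_features(rules, rfc, aln$rows[i]), numeric(config$n_rules)))
  rownames(seq_feats) <- aln$names

  X <- cbind(struct_feats, seq_feats[s_names, , drop = FALSE])
  y <- stats::setNames(aln$labels, aln$names)[s_names]

  model <- train_adtree(X, y, n_iterations = config$n_iterations)
  learner <- if (config$algo == "svm") svm_learner() else
    adtree_learner(config$n_iterations)
  report <- if (nrow(X) >= config$n_folds &&
                any(y == 1) && any(y == 0)) {
    cross_validate(X, y, learner, n_folds = config$n_folds,
                   seed = config$seed)
  } else NULL

  features <- data.frame(name = s_names, X, check.names = FALSE,
                         stringsAsFactors = FALSE)
  features$label <- unname(y)
  list(features = features, rules = rules, rfc = rfc, model = model,
       report = report)
}

#' Write a named feature table as TSV
#' @param features data.frame with a \code{name} column.
#' @param path Output path.
#' @export
write_feature_tsv <- function(features, path) {
  write.table(features, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a feature table written by \code{\link{write_feature_tsv}}
#' @param path TSV path.
#' @return data.frame.
#' @export
read_feature_tsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
             stringsAsFactors = FALSE)
}
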