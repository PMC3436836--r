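# seqfeat: RFC matrix, subsequence-rule mining, identity baseline

GAP_CHARS <- c("-", ".")

#' Construct a labeled family alignment
#'
#' @param names Sequence names.
#' @param rows Equal-length gapped sequences (20 amino acids + gap).
#' @param labels Binary labels, 1 = binding (+), 0 = non-binding (-).
#' @return A \code{LabeledAlignment}.
#' @export
labeled_alignment <- function(names, rows, labels) {
  labels <- as.integer(labels)
  stopifnot(length(names) == length(rows), length(rows) == length(labels),
            all(labels %in% c(0L, 1L)))
  L <- unique(nchar(rows))
  if (length(L) != 1) stop("alignment rows have unequal lengths")
  structure(list(names = as.character(names), rows = toupper(rows),
                 labels = labels, L = L),
            class = "LabeledAlignment")
}

#' @export
print.LabeledAlignment <- function(x, ...) {
  cat("LabeledAlignment:", length(x$rows), "sequences x", x$L, "columns;",
      sum(x$labels == 1), "binding /", sum(x$labels == 0), "non-binding\n")
  invisible(x)
}

alignment_char_matrix <- function(aln) {
  do.call(rbind, strsplit(aln$rows, ""))
}

# per-class column distributions over 20 residues + gap, with pseudocount
class_column_probs <- function(cm, pseudocount) {
  n <- nrow(cm)
  L <- ncol(cm)
  syms <- c(unname(AA1[AA3]), "-")
  cm[!(cm %in% AA1)] <- "-"          # non-standard and gap fold to gap symbol
  counts <- vapply(seq_len(L), function(j) {
    tab <- table(factor(cm[, j], levels = syms))
    as.numeric(tab)
  }, numeric(21))
  (counts + pseudocount) / (n + 21 * pseudocount)
}

#' Compute the RFC (residue functional classification) log-odds matrix
#'
#' For each residue a and alignment column i, estimates the probability of
#' observing a at i separately in the binding (+) and non-binding (-) class
#' with an additive pseudocount (gap counts as a 21st symbol for
#' normalization), and stores M[a,i] = ln(P+ / P-). Positive entries are
#' evidence for membrane binding.
#'
#' @param aln A \code{\link{labeled_alignment}}.
#' @param pseudocount Additive pseudocount (default 1).
#' @return An \code{RFCMatrix}: list with \code{M} (20 x L, rownames
#'   one-letter codes), \code{P_plus}, \code{P_minus} (21 x L including the
#'   gap row), \code{pseudocount}, \code{L}.
#' @export
compute_rfc <- function(aln, pseudocount = 1.0) {
  stopifnot(inherits(aln, "LabeledAlignment"))
  if (!any(aln$labels == 1) || !any(aln$labels == 0))
    stop("both classes must be non-empty")
  cm <- alignment_char_matrix(aln)
  syms <- c(unname(AA1[AA3]), "-")
  Pp <- class_column_probs(cm[aln$labels == 1, , drop = FALSE], pseudocount)
  Pm <- class_column_probs(cm[aln$labels == 0, , drop = FALSE], pseudocount)
  rownames(Pp) <- rownames(Pm) <- syms
  M <- log(Pp[seq_len(20), , drop = FALSE] / Pm[seq_len(20), , drop = FALSE])
  structure(list(M = M, P_plus = Pp, P_minus = Pm,
                 pseudocount = pseudocount, L = aln$L),
            class = "RFCMatrix")
}

#' @export
print.RFCMatrix <- function(x, ...) {
  cat("RFCMatrix: 20 x", x$L, "log-odds entries, pseudocount",
      x$pseudocount, "\n")
  invisible(x)
}

# per-position M contribution of one aligned sequence (0 at gaps)
position_scores <- function(rfc, aligned_sequence) {
  s <- strsplit(toupper(aligned_sequence), "")[[1]]
  if (length(s) != rfc$L)
    stop("sequence length ", length(s), " does not match matrix columns ", rfc$L)
  out <- numeric(rfc$L)
  ri <- match(s, rownames(rfc$M))
  hit <- !is.na(ri)
  out[hit] <- rfc$M[cbind(ri[hit], which(hit))]
  out
}

#' Summed RFC evidence score of an aligned sequence
#'
#' S = sum over non-gap positions i of M[s_i, i]; positive S is evidence the
#' domain is membrane binding.
#'
#' @param rfc An \code{RFCMatrix}.
#' @param aligned_sequence A gapped sequence over the matrix's L columns.
#' @return A single real score.
#' @export
rfc_score <- function(rfc, aligned_sequence) {
  stopifnot(inherits(rfc, "RFCMatrix"))
  sum(position_scores(rfc, aligned_sequence))
}

subseq_candidates <- function(L, lengths) {
  cand <- do.call(rbind, lapply(lengths, function(len) {
    if (L - len + 1 < 1) return(NULL)
    cbind(start = seq_len(L - len + 1), length = len)
  }))
  if (is.null(cand)) stop("alignment shorter than the smallest rule length")
  cand
}

# n x n_candidates matrix of window scores for all rows of a char matrix
window_score_matrix <- function(rfc, cm, cand) {
  n <- nrow(cm)
  ps <- matrix(0, n, ncol(cm))
  for (r in seq_len(n)) {
    ri <- match(cm[r, ], rownames(rfc$M))
    hit <- !is.na(ri)
    ps[r, hit] <- rfc$M[cbind(ri[hit], which(hit))]
  }
  cs <- cbind(0, t(apply(ps, 1, cumsum)))
  cs[, cand[, "start"] + cand[, "length"], drop = FALSE] -
    cs[, cand[, "start"], drop = FALSE]
}

#' Mine discriminative subsequence rules by bootstrap ranking
#'
#' Candidate rules are all alignment windows of the given lengths. For each
#' stratified bootstrap resample (rows drawn with replacement within class),
#' the RFC matrix is recomputed and each window's potential score is the mean
#' window score of the resampled binding rows minus that of the non-binding
#' rows. Rules are ranked by mean potential score across bootstraps, ties
#' broken by smaller start then shorter length.
#'
#' @param aln A \code{\link{labeled_alignment}} (L >= max rule length).
#' @param lengths Window lengths (default 3:6).
#' @param n_bootstrap Number of bootstrap resamples (default 50).
#' @param n_rules Number of rules to return (default 25).
#' @param seed Integer RNG seed for the bootstrap.
#' @param pseudocount Passed to \code{\link{compute_rfc}}.
#' @return List of \code{SubseqRule}s: \code{start} (1-based column),
#'   \code{length}, \code{rank_score} (mean potential score), ordered by
#'   decreasing rank_score.
#' @export
mine_subseq_rules <- function(aln, lengths = 3:6, n_bootstrap = 50,
                              n_rules = 25, seed = 1, pseudocount = 1.0) {
  stopifnot(inherits(aln, "LabeledAlignment"))
  if (aln$L < max(lengths))
    stop("degenerate alignment: L < maximum rule length")
  cand <- subseq_candidates(aln$L, lengths)
  if (n_rules > nrow(cand))
    stop("n_rules exceeds the number of candidate windows")
  cm <- alignment_char_matrix(aln)
  pos <- which(aln$labels == 1)
  neg <- which(aln$labels == 0)
  if (!length(pos) || !length(neg)) stop("both classes must be non-empty")

  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  total <- matrix(0, n_bootstrap, nrow(cand))
  for (b in seq_len(n_bootstrap)) {
    bp <- sample(pos, length(pos), replace = TRUE)
    bn <- sample(neg, length(neg), replace = TRUE)
    idx <- c(bp, bn)
    baln <- labeled_alignment(aln$names[idx], aln$rows[idx], aln$labels[idx])
    rfc <- compute_rfc(baln, pseudocount)
    ws <- window_score_matrix(rfc, cm[idx, , drop = FALSE], cand)
    is_pos <- baln$labels == 1
    total[b, ] <- colMeans(ws[is_pos, , drop = FALSE]) -
      colMeans(ws[!is_pos, , drop = FALSE])
  }
  mean_score <- colMeans(total)
  ord <- order(-mean_score, cand[, "start"], cand[, "length"])
  lapply(ord[seq_len(n_rules)], function(i)
    structure(list(start = unname(cand[i, "start"]),
                   length = unname(cand[i, "length"]),
                   rank_score = unname(mean_score[i])),
              class = "SubseqRule"))
}

#' Sequence feature vector from mined rules
#'
#' Feature j is the summed RFC score of the sequence over rule j's window
#' (gap positions contribute 0) - i.e. \code{rfc_score} restricted to that
#' window.
#'
#' @param rules List of rules from \code{\link{mine_subseq_rules}}.
#' @param rfc The \code{RFCMatrix} in the same alignment coordinates.
#' @param aligned_sequence Gapped sequence over the matrix's L columns.
#' @return Named numeric vector \code{rule_score_1..n}.
#' @export
subseq_features <- function(rules, rfc, aligned_sequence) {
  for (r in rules)
    if (r$start + r$length - 1 > rfc$L)
      stop("rule window outside matrix coordinates")
  ps <- position_scores(rfc, aligned_sequence)
  out <- vapply(rules, function(r)
    sum(ps[r$start:(r$start + r$length - 1)]), numeric(1))
  names(out) <- paste0("rule_score_", seq_along(out))
  out
}

#' Global pairwise sequence identity
#'
#' Needleman-Wunsch global alignment (match 1, mismatch 0, gap open 10,
#' gap extend 0.5 on the unit score scale, via Biostrings), identity =
#' identical positions / alignment length.
#'
#' @param seq1,seq2 Ungapped sequences.
#' @return Identity fraction in [0, 1].
#' @export
pairwise_identity <- function(seq1, seq2) {
  if (!nzchar(seq1) || !nzchar(seq2)) stop("empty sequence")
  chars <- unique(c(strsplit(toupper(seq1), "")[[1]],
                    strsplit(toupper(seq2), "")[[1]]))
  sm <- matrix(0, length(chars), length(chars),
               dimnames = list(chars, chars))
  diag(sm) <- 1
  aln <- Biostrings::pairwiseAlignment(
    toupper(seq1), toupper(seq2), type = "global",
    substitutionMatrix = sm, gapOpening = 10, gapExtension = 0.5)
  Biostrings::nmatch(aln) /
    nchar(as.character(Biostrings::alignedPattern(aln)))
}

#' Greedy redundancy reduction at an identity cutoff
#'
#' Iterates sequences in input order and keeps a sequence iff its identity to
#' every previously kept sequence is below the cutoff.
#'
#' @param sequences Character vector of ungapped sequences.
#' @param cutoff Identity cutoff (default 0.70).
#' @return Integer indices of the kept sequences.
#' @export
redundancy_reduce <- function(sequences, cutoff = 0.70) {
  stopifnot(length(sequences) >= 1)
  kept <- integer(0)
  for (i in seq_along(sequences)) {
    ok <- TRUE
    for (j in kept) {
      if (pairwise_identity(sequences[i], sequences[j]) >= cutoff) {
        ok <- FALSE
        break
      }
    }
    if (ok) kept <- c(kept, i)
  }
  kept
}

#' k-nearest-neighbor sequence-similarity baseline
#'
#' Predicts each query's label as the majority vote of its k most identical
#' training sequences (ties in identity broken by training index; an even
#' vote split predicts positive).
#'
#' @param train_seqs,train_labels Training sequences and 0/1 labels.
#' @param query_seqs Query sequences.
#' @param k Number of neighbors (default 3).
#' @return Integer vector of predicted 0/1 labels.
#' @export
nn_baseline <- function(train_seqs, train_labels, query_seqs, k = 3) {
  train_labels <- as.integer(train_labels)
  stopifnot(length(train_seqs) >= k, all(train_labels %in% c(0L, 1L)))
  vapply(query_seqs, function(q) {
    ids <- vapply(train_seqs, function(t) pairwise_identity(q, t), numeric(1))
    top <- order(-ids, seq_along(ids))[seq_len(k)]
    votes <- sum(train_labels[top] == 1L)
    as.integer(votes >= k / 2)
  }, integer(1), USE.NAMES = FALSE)
}

# --- alignment / label I/O --------------------------------------------------

#' Read an aligned FASTA file
#' @param path Path to a FASTA file of equal-length gapped sequences.
#' @return List with \code{names} and \code{rows}.
#' @export
read_fasta_alignment <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  list(names = sub("\\s.*", "", names(ss)), rows = as.character(ss))
}

#' Read a Stockholm alignment
#' @param path Path to a Stockholm (.sto) file.
#' @return List with \code{names} and \code{rows}.
#' @export
read_stockholm <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines, which = "right")
  body <- lines[nzchar(lines) & !startsWith(lines, "#") & lines != "//"]
  if (!length(body)) stop("no sequence lines in Stockholm file: ", path)
  parts <- strsplit(body, "\\s+")
  nm <- vapply(parts, `[[`, character(1), 1)
  sq <- vapply(parts, function(p) paste(p[-1], collapse = ""), character(1))
  agg <- tapply(sq, factor(nm, levels = unique(nm)), paste, collapse = "")
  list(names = names(agg), rows = as.vector(unname(agg)))
}

#' Read a two-column name/label TSV
#' @param path TSV with columns name and label (0/1); no header required.
#' @return Named integer vector of labels.
#' @export
read_labels_tsv <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE)
  if (is.character(df[[2]])) { # tolerate a header row
    df <- df[-1, ]
    df[[2]] <- as.integer(df[[2]])
  }
  stats::setNames(as.integer(df[[2]]), df[[1]])
}
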