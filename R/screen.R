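#' Filter alignments by mean pairwise identity
#'
#' Alignments with mean percentage identity strictly below the threshold are
#' removed; the boundary value is retained.
#'
#' @param alignments Named list of [alignment()] objects.
#' @param threshold Percentage threshold (default 60).
#' @return List with `retained`, `filtered` (names) and `report` data frame.
#' @export
filter_alignments <- function(alignments, threshold = 60) {
  ident <- vapply(alignments, mean_pairwise_identity, numeric(1))
  keep <- ident >= threshold
  nm <- names(alignments) %||% as.character(seq_along(alignments))
  list(retained = alignments[keep],
       filtered = nm[!keep],
       report = data.frame(gene = nm, mean_identity = ident, retained = keep))
}

#' Is a taxon set monophyletic (unrooted bipartition sense)?
#'
#' TRUE iff some edge of the unrooted tree splits the leaves into exactly
#' the focal set versus the rest. This is how a monophyletic grouping is
#' read off an unrooted gene tree without committing to a root.
#'
#' @param tree `ape::phylo`.
#' @param focal Character vector of leaf labels.
#' @return Logical.
#' @export
is_focal_monophyletic <- function(tree, focal) {
  if (!all(focal %in% tree$tip.label)) {
    stop("focal taxa missing from tree: ",
         paste(setdiff(focal, tree$tip.label), collapse = ", "))
  }
  n <- length(tree$tip.label)
  if (length(focal) <= 1 || length(focal) >= n - 1) return(TRUE)
  splits <- bipartitions(tree)
  target <- paste(sort(focal), collapse = "|")
  complement <- paste(sort(setdiff(tree$tip.label, focal)), collapse = "|")
  (target %in% splits) || (complement %in% splits)
}

#' Build a gene tree from an alignment
#'
#' Neighbor joining on corrected distances, optionally refined by an NNI
#' hill climb under a likelihood model. The screen default is plain NJ,
#' which recovers bipartitions reliably at screening scale; NNI refinement
#' is available for final analyses.
#'
#' @param aln An [alignment()].
#' @param method `"nj"` or `"nj+nni"`.
#' @param family Model family for the NNI refinement.
#' @param model Optional [substitution_model()]: when supplied, NJ runs on
#'   [ml_distances()] under that model (recommended; robust to rate
#'   heterogeneity), otherwise on JC/Poisson-corrected distances.
#' @return Unrooted `ape::phylo`.
#' @export
build_gene_tree <- function(aln, method = c("nj", "nj+nni"), family = "JC",
                            model = NULL) {
  method <- match.arg(method)
  d <- if (is.null(model)) {
    alignment_distances(aln, if (aln$alphabet == "nt") "jc" else "poisson")
  } else {
    ml_distances(aln, model)
  }
  tr <- neighbor_joining(d)
  if (method == "nj+nni") {
    tr <- ape::unroot(nni_search(aln, tr, family)$tree)
  }
  tr
}

#' Monophyly screen over gene trees
#'
#' Applies [is_focal_monophyletic()] to a batch of gene trees; unreadable
#' entries produce per-gene error records and the batch continues. The
#' summary counts flagged genes; the result is independent of input order.
#'
#' @param trees Named list of `ape::phylo` objects, or paths to Newick files.
#' @param focal Character vector of focal (long-lived) taxa.
#' @return List of class `"screen_report"`: `report` data frame (gene,
#'   status, monophyletic), `n_flagged`, `flagged`.
#' @export
screen_gene_trees <- function(trees, focal) {
  nm <- names(trees) %||% as.character(seq_along(trees))
  status <- character(length(trees))
  mono <- rep(NA, length(trees))
  for (i in seq_along(trees)) {
    tr <- trees[[i]]
    if (is.character(tr)) {
      tr <- tryCatch(read_tree(tr), error = function(e) e)
    }
    if (inherits(tr, "error") || inherits(tr, "condition")) {
      status[i] <- paste("error:", conditionMessage(tr)); next
    }
    if (!all(focal %in% tr$tip.label)) {
      status[i] <- "skipped: focal taxa missing"
      warning("gene ", nm[i], " skipped: focal taxa missing")
      next
    }
    mono[i] <- is_focal_monophyletic(tr, focal)
    status[i] <- "ok"
  }
  rep_df <- data.frame(gene = nm, status = status, monophyletic = mono)
  structure(list(report = rep_df,
                 n_flagged = sum(mono, na.rm = TRUE),
                 flagged = nm[which(mono)]), class = "screen_report")
}

#' @export
print.screen_report <- function(x, ...) {
  cat(sprintf("<monophyly screen> %d/%d genes flagged\n",
              x$n_flagged, nrow(x$report)))
  invisible(x)
}

#' Reciprocal best hits from precomputed score tables
#'
#' Keeps pairs (a, b) where b is a's unique top-scoring hit in the forward
#' table and a is b's unique top-scoring hit in the reverse table. Tied top
#' scores discard the query (no unique best).
#'
#' @param hits_ab,hits_ba Data frames with columns `query`, `subject`,
#'   `score`.
#' @return Data frame with columns `a`, `b` of 1:1 ortholog pairs.
#' @export
reciprocal_best_hits <- function(hits_ab, hits_ba) {
  need <- c("query", "subject", "score")
  if (!all(need %in% names(hits_ab)) || !all(need %in% names(hits_ba))) {
    stop("hit tables need columns query, subject, score")
  }
  best <- function(h) {
    out <- list()
    for (q in unique(h$query)) {
      rows <- h[h$query == q, ]
      top <- max(rows$score)
      winners <- rows$subject[rows$score == top]
      if (length(unique(winners)) == 1) out[[q]] <- winners[1]
    }
    out
  }
  fwd <- best(hits_ab)
  rev <- best(hits_ba)
  pairs <- list()
  for (a in names(fwd)) {
    b <- fwd[[a]]
    if (!is.null(rev[[b]]) && rev[[b]] == a) {
      pairs[[length(pairs) + 1]] <- data.frame(a = a, b = b)
    }
  }
  if (length(pairs)) do.call(rbind, pairs) else
    data.frame(a = character(0), b = character(0))
}
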