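#' Neighbor joining
#'
#' Saitou-Nei neighbor joining from a symmetric distance matrix. Ties in the
#' Q criterion are broken by joining the pair with the lowest (row, column)
#' index order, so the result is fully deterministic. On additive distances
#' the generating tree (topology and branch lengths) is recovered exactly.
#'
#' @param d Symmetric numeric matrix with zero diagonal and taxon names as
#'   dimnames, or a `dist` object.
#' @return Unrooted binary `ape::phylo` tree.
#' @export
neighbor_joining <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-8)) stop("distance matrix must be symmetric")
  if (any(!is.finite(d)) || any(d < 0)) stop("distances must be finite and non-negative")
  n <- nrow(d)
  labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  if (n < 3) stop("need at least 3 taxa")

  # node bookkeeping: active entries carry a subtree (Newick fragment)
  frag <- labels
  D <- d
  while (nrow(D) > 3) {
    n <- nrow(D)
    tot <- rowSums(D)
    Q <- (n - 2) * D - outer(tot, tot, "+")
    diag(Q) <- Inf
    # lowest-index tie-break: scan column-major over i < j
    best <- c(NA, NA); bestq <- Inf
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        if (Q[i, j] < bestq - 1e-12) {
          bestq <- Q[i, j]; best <- c(i, j)
        }
      }
    }
    i <- best[1]; j <- best[2]
    vi <- 0.5 * D[i, j] + (tot[i] - tot[j]) / (2 * (n - 2))
    vj <- D[i, j] - vi
    vi <- max(vi, 0); vj <- max(vj, 0)
    newfrag <- sprintf("(%s:%.10g,%s:%.10g)", frag[i], vi, frag[j], vj)
    dnew <- 0.5 * (D[i, ] + D[j, ] - D[i, j])
    dnew <- dnew[-c(i, j)]
    D <- D[-c(i, j), -c(i, j), drop = FALSE]
    D <- rbind(cbind(D, dnew), c(dnew, 0))
    frag <- c(frag[-c(i, j)], newfrag)
  }
  # final three-taxon star: three-point formulas
  v1 <- max(0, (D[1, 2] + D[1, 3] - D[2, 3]) / 2)
  v2 <- max(0, (D[1, 2] + D[2, 3] - D[1, 3]) / 2)
  v3 <- max(0, (D[1, 3] + D[2, 3] - D[1, 2]) / 2)
  nwk <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
                 frag[1], v1, frag[2], v2, frag[3], v3)
  read_tree_text(nwk)
}

#' Pairwise evolutionary distances from an alignment
#'
#' Distances are computed over columns where both sequences are non-missing.
#' `"raw"` is the p-distance; `"jc"` applies the Jukes-Cantor correction
#' (nucleotides), `"poisson"` the Poisson correction (amino acids).
#' Saturated pairs are capped at `max_dist`.
#'
#' @param aln An [alignment()].
#' @param correction `"jc"`, `"poisson"`, or `"raw"`.
#' @param max_dist Cap for saturated distances.
#' @return Symmetric distance matrix.
#' @export
alignment_distances <- function(aln, correction = c("jc", "poisson", "raw"),
                                max_dist = 10) {
  correction <- match.arg(correction)
  enc <- encode_alignment(aln)
  n <- nrow(enc)
  S <- length(alphabet_states(aln$alphabet))
  D <- matrix(0, n, n, dimnames = list(rownames(enc), rownames(enc)))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      ok <- !is.na(enc[i, ]) & !is.na(enc[j, ])
      p <- if (any(ok)) mean(enc[i, ok] != enc[j, ok]) else 0
      d <- switch(correction,
        raw = p,
        jc = {
          a <- (S - 1) / S
          if (p >= a) max_dist else -a * log(1 - p / a)
        },
        poisson = if (p >= 1) max_dist else -log(1 - p)
      )
      D[i, j] <- D[j, i] <- min(d, max_dist)
    }
  }
  D
}

#' Maximum-likelihood pairwise distances
#'
#' For each sequence pair, the branch length `t` maximising the two-sequence
#' likelihood `sum_ij N_ij log(pi_i P_ij(t))` under the given model
#' (including gamma mixtures) is found by 1-D optimisation. Corrects for
#' multiple hits and rate heterogeneity, which plain JC/Poisson distances
#' underestimate at depth.
#'
#' @param aln An [alignment()].
#' @param model A [substitution_model()].
#' @param max_dist Upper bound for the search.
#' @return Symmetric distance matrix.
#' @export
ml_distances <- function(aln, model, max_dist = 10) {
  enc <- encode_alignment(aln)
  n <- nrow(enc)
  S <- length(model$states)
  D <- matrix(0, n, n, dimnames = list(rownames(enc), rownames(enc)))
  nll <- function(t, N) {
    P <- matrix(0, S, S)
    for (cc in seq_len(model$k)) {
      P <- P + model$weights[cc] * transition_matrix(model, t, model$rates[cc])
    }
    -sum(N * log(pmax(model$freq * P, 1e-300)))
  }
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      ok <- !is.na(enc[i, ]) & !is.na(enc[j, ])
      N <- matrix(0, S, S)
      tab <- table(factor(enc[i, ok], levels = 1:S),
                   factor(enc[j, ok], levels = 1:S))
      N[] <- tab
      opt <- stats::optimize(nll, c(1e-8, max_dist), N = N)
      D[i, j] <- D[j, i] <- opt$minimum
    }
  }
  D
}
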