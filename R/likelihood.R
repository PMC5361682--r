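# ---------------------------------------------------------------------------
# Pruning-likelihood engine.
#
# All per-site quantities are computed with Felsenstein's pruning algorithm
# under a reversible model, with per-node rescaling of partial likelihoods to
# avoid underflow (log-space scale accumulators). Gamma rate heterogeneity is
# handled as a discrete mixture: conditional likelihoods are computed per
# category and combined with the (equal prior) category weights; posterior
# quantities are averaged over categories with per-site posterior category
# weights.
# ---------------------------------------------------------------------------

# leaf partial likelihoods: S x m indicator matrices, all-ones for missing
leaf_partials <- function(enc, S) {
  m <- ncol(enc)
  lapply(seq_len(nrow(enc)), function(i) {
    X <- matrix(0, S, m)
    obs <- enc[i, ]
    ok <- !is.na(obs)
    X[cbind(obs[ok], which(ok))] <- 1
    X[, !ok] <- 1
    X
  })
}

# build the engine: per-category downward partials, scale logs, site
# likelihoods, and lazily computed upward messages
build_engine <- function(aln, tree, model) {
  if (!setequal(rownames(aln$mat), tree$tip.label)) {
    stop("alignment taxa and tree leaves do not match")
  }
  idx <- tree_index(tree)
  enc <- encode_alignment(aln)[idx$tree$tip.label, , drop = FALSE]
  S <- length(model$states)
  m <- ncol(enc)
  k <- model$k
  lp <- leaf_partials(enc, S)

  down <- vector("list", k)   # down[[c]][[node]]: S x m
  dscale <- vector("list", k) # dscale[[c]][[node]]: length-m log scale
  Pmats <- vector("list", k)  # Pmats[[c]][[node]]: P along branch above node
  for (cc in seq_len(k)) {
    D <- vector("list", idx$nnode)
    Sc <- vector("list", idx$nnode)
    Pm <- vector("list", idx$nnode)
    for (v in seq_len(idx$ntip)) {
      D[[v]] <- lp[[v]]
      Sc[[v]] <- numeric(m)
    }
    for (v in seq_len(idx$nnode)) {
      if (v != idx$root) {
        Pm[[v]] <- transition_matrix(model, idx$elen[v], model$rates[cc])
      }
    }
    for (v in idx$int_postorder) {
      X <- matrix(1, S, m)
      sc <- numeric(m)
      for (ch in idx$children[[v]]) {
        X <- X * (Pm[[ch]] %*% D[[ch]])
        sc <- sc + Sc[[ch]]
      }
      mx <- apply(X, 2, max)
      mx[mx == 0] <- 1
      X <- X / rep(mx, each = S)
      D[[v]] <- X
      Sc[[v]] <- sc + log(mx)
    }
    down[[cc]] <- D
    dscale[[cc]] <- Sc
    Pmats[[cc]] <- Pm
  }

  # per-category site log-likelihoods
  cat_loglik <- matrix(NA_real_, k, m)
  for (cc in seq_len(k)) {
    L <- colSums(model$freq * down[[cc]][[idx$root]])
    cat_loglik[cc, ] <- log(L) + dscale[[cc]][[idx$root]]
  }
  mx <- apply(cat_loglik, 2, max)
  site_loglik <- mx + log(colSums(model$weights * exp(sweep(cat_loglik, 2, mx))))
  # posterior category weights per site
  cat_post <- model$weights * exp(sweep(cat_loglik, 2, site_loglik))

  env <- new.env(parent = emptyenv())
  env$idx <- idx; env$model <- model; env$S <- S; env$m <- m; env$k <- k
  env$enc <- enc
  env$down <- down; env$dscale <- dscale; env$P <- Pmats
  env$cat_loglik <- cat_loglik
  env$site_loglik <- site_loglik
  env$cat_post <- cat_post
  env$up <- NULL
  env
}

# upward ("above") messages A[[c]][[node]]: S x m, A includes the stationary
# prior at the root, so posterior(node) ~ A * down (per category, per site)
compute_up <- function(env) {
  if (!is.null(env$up)) return(invisible(env))
  idx <- env$idx; S <- env$S; m <- env$m
  up <- vector("list", env$k)
  for (cc in seq_len(env$k)) {
    A <- vector("list", idx$nnode)
    A[[idx$root]] <- matrix(env$model$freq, S, m)
    for (p in env$idx$int_preorder) {
      kids <- idx$children[[p]]
      msgs <- lapply(kids, function(ch) env$P[[cc]][[ch]] %*% env$down[[cc]][[ch]])
      for (j in seq_along(kids)) {
        B <- A[[p]]
        for (l in seq_along(kids)) if (l != j) B <- B * msgs[[l]]
        v <- kids[[j]]
        Av <- crossprod(env$P[[cc]][[v]], B)  # t(P) %*% B
        mx <- apply(Av, 2, max)
        mx[mx == 0] <- 1
        A[[v]] <- Av / rep(mx, each = S)
      }
    }
    up[[cc]] <- A
  }
  env$up <- up
  invisible(env)
}

# "outside" message at the parent endpoint of the branch above node v:
# B(i) = A_parent(i) * prod over siblings of (P %*% down), normalised per site
branch_outside <- function(env, v, cc) {
  idx <- env$idx
  p <- idx$parent[v]
  B <- env$up[[cc]][[p]]
  for (s in idx$children[[p]]) {
    if (s != v) B <- B * (env$P[[cc]][[s]] %*% env$down[[cc]][[s]])
  }
  B
}

#' Per-site log-likelihoods by the pruning algorithm
#'
#' Gaps and unknown residues are treated as missing data (all-ones partial
#' likelihoods). Underflow is handled by per-node rescaling, so arbitrarily
#' long trees and alignments are safe.
#'
#' @param aln An [alignment()].
#' @param tree Rooted `ape::phylo` with branch lengths (leaf set must match
#'   the alignment's taxa).
#' @param model A [substitution_model()] on the same alphabet.
#' @return List with `site_loglik` (per-site vector) and `total` (their sum).
#' @export
compute_log_likelihood <- function(aln, tree, model) {
  env <- build_engine(aln, tree, model)
  list(site_loglik = as.numeric(env$site_loglik),
       total = sum(env$site_loglik))
}

# marginal posterior state distributions, gamma-averaged: returns a list of
# S x m matrices for the requested nodes
node_posteriors <- function(env, nodes) {
  compute_up(env)
  out <- vector("list", length(nodes))
  names(out) <- as.character(nodes)
  for (iN in seq_along(nodes)) {
    v <- nodes[[iN]]
    acc <- matrix(0, env$S, env$m)
    for (cc in seq_len(env$k)) {
      post <- env$up[[cc]][[v]] * env$down[[cc]][[v]]
      Z <- colSums(post)
      Z[Z == 0] <- 1
      acc <- acc + rep(env$cat_post[cc, ], each = env$S) * post / rep(Z, each = env$S)
    }
    out[[iN]] <- acc
  }
  out
}

# per-branch substitution probability matrix q (S x m): q[j, s] is the
# posterior probability that the branch above node v underwent a
# substitution ending in state j at site s (parent state != j), averaged
# over gamma categories with posterior category weights
branch_subst_probs <- function(env, v) {
  compute_up(env)
  acc <- matrix(0, env$S, env$m)
  for (cc in seq_len(env$k)) {
    B <- branch_outside(env, v, cc)
    P <- env$P[[cc]][[v]]
    L <- env$down[[cc]][[v]]
    M <- crossprod(P, B) * L            # sum_i B_i P_ij L_j
    Z <- colSums(M)
    Z[Z == 0] <- 1
    same <- (B * diag(P)) * L           # i == j term
    q <- (M - same) / rep(Z, each = env$S)
    q[q < 0] <- 0
    acc <- acc + rep(env$cat_post[cc, ], each = env$S) * q
  }
  acc
}

# full joint posterior over (parent, child) endpoint states of the branch
# above node v at one site s: S x S matrix (gamma-averaged)
branch_joint_posterior <- function(env, v, s) {
  compute_up(env)
  acc <- matrix(0, env$S, env$S)
  for (cc in seq_len(env$k)) {
    B <- branch_outside(env, v, cc)[, s]
    P <- env$P[[cc]][[v]]
    L <- env$down[[cc]][[v]][, s]
    J <- (B * P) * rep(L, each = env$S)
    acc <- acc + env$cat_post[cc, s] * J / sum(J)
  }
  acc
}

# closure for repeated likelihood evaluation with varying branch lengths
# under a fixed model: tree indexing, state encoding and leaf partials are
# computed once; `el` is in the postorder edge order of `tree`
lean_loglik_fn <- function(aln, tree, model) {
  tree <- stats::reorder(tree, "postorder")
  if (is.null(tree$edge.length)) tree$edge.length <- rep(0.1, nrow(tree$edge))
  idx <- tree_index(tree)
  enc <- encode_alignment(aln)[idx$tree$tip.label, , drop = FALSE]
  S <- length(model$states)
  m <- ncol(enc)
  lp <- leaf_partials(enc, S)
  edge <- idx$tree$edge
  function(el) {
    elen <- rep(NA_real_, idx$nnode)
    elen[edge[, 2]] <- el
    sitelik <- matrix(0, model$k, m)
    for (cc in seq_len(model$k)) {
      D <- vector("list", idx$nnode)
      Sc <- vector("list", idx$nnode)
      for (v in seq_len(idx$ntip)) { D[[v]] <- lp[[v]]; Sc[[v]] <- numeric(m) }
      for (v in idx$int_postorder) {
        X <- matrix(1, S, m)
        sc <- numeric(m)
        for (ch in idx$children[[v]]) {
          P <- transition_matrix(model, elen[ch], model$rates[cc])
          X <- X * (P %*% D[[ch]])
          sc <- sc + Sc[[ch]]
        }
        mx <- apply(X, 2, max)
        mx[mx == 0] <- 1
        D[[v]] <- X / rep(mx, each = S)
        Sc[[v]] <- sc + log(mx)
      }
      sitelik[cc, ] <- log(colSums(model$freq * D[[idx$root]])) + Sc[[idx$root]]
    }
    mx <- apply(sitelik, 2, max)
    sum(mx + log(colSums(model$weights * exp(sweep(sitelik, 2, mx)))))
  }
}
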