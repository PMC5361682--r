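# Independent brute-force oracles: likelihoods, posteriors and branch joints
# by exhaustive enumeration over all node state assignments. Deliberately
# written without the package's pruning machinery (direct products of
# transition probabilities over an explicit assignment grid).

enum_quantities <- function(aln, tree, model) {
  idx <- adaptconv:::tree_index(tree)
  enc <- adaptconv:::encode_alignment(aln)[idx$tree$tip.label, , drop = FALSE]
  S <- length(model$states)
  m <- ncol(enc)
  nn <- idx$nnode
  edges <- idx$tree$edge
  Pcat <- lapply(seq_len(model$k), function(cc) {
    lapply(seq_len(nrow(edges)), function(e) {
      transition_matrix(model, idx$tree$edge.length[e], model$rates[cc])
    })
  })
  site_loglik <- numeric(m)
  post <- lapply(seq_len(nn), function(v) matrix(0, S, m))
  joints <- lapply(seq_len(nn), function(v) array(0, c(S, S, m)))
  for (s in seq_len(m)) {
    choices <- lapply(seq_len(nn), function(v) {
      if (v <= idx$ntip && !is.na(enc[v, s])) enc[v, s] else seq_len(S)
    })
    A <- as.matrix(expand.grid(choices))
    catlik <- numeric(model$k)
    prob_by_cat <- vector("list", model$k)
    for (cc in seq_len(model$k)) {
      pr <- model$freq[A[, idx$root]]
      for (e in seq_len(nrow(edges))) {
        pr <- pr * Pcat[[cc]][[e]][cbind(A[, edges[e, 1]], A[, edges[e, 2]])]
      }
      prob_by_cat[[cc]] <- pr
      catlik[cc] <- sum(pr)
    }
    lik <- sum(model$weights * catlik)
    site_loglik[s] <- log(lik)
    w <- model$weights / lik
    for (v in seq_len(nn)) {
      for (cc in seq_len(model$k)) {
        tot <- tapply(prob_by_cat[[cc]], factor(A[, v], levels = seq_len(S)), sum)
        tot[is.na(tot)] <- 0
        post[[v]][, s] <- post[[v]][, s] + w[cc] * as.numeric(tot)
      }
      p <- idx$parent[v]
      if (!is.na(p)) {
        for (cc in seq_len(model$k)) {
          jt <- tapply(prob_by_cat[[cc]],
                       list(factor(A[, p], levels = seq_len(S)),
                            factor(A[, v], levels = seq_len(S))), sum)
          jt[is.na(jt)] <- 0
          joints[[v]][, , s] <- joints[[v]][, , s] + w[cc] * jt
        }
      }
    }
  }
  list(idx = idx, site_loglik = site_loglik, posterior = post, joints = joints)
}

# expected convergent/divergent counts for a branch pair from enumerated
# per-branch endpoint joints, combined with the factorised definition
enum_expected_convergence <- function(enum, node_a, node_b) {
  S <- nrow(enum$posterior[[1]])
  m <- length(enum$site_loglik)
  qvec <- function(v) {
    sapply(seq_len(m), function(s) {
      J <- enum$joints[[v]][, , s]
      colSums(J) - diag(J)
    })
  }
  qa <- qvec(node_a); qb <- qvec(node_b)
  mu <- colSums(qa * qb)
  list(E_C = sum(mu), E_D = sum(colSums(qa) * colSums(qb) - mu),
       mu_sites = as.numeric(mu))
}

# random rooted binary tree with exponential branch lengths
random_tree <- function(ntaxa, mean_bl = 0.3) {
  tr <- ape::rtree(ntaxa, rooted = TRUE,
                   tip.label = paste0("t", seq_len(ntaxa)))
  tr$edge.length <- stats::rexp(nrow(tr$edge), rate = 1 / mean_bl)
  tr
}

random_alignment <- function(taxa, sites, states, gap_prob = 0) {
  mat <- matrix(sample(states, length(taxa) * sites, replace = TRUE),
                length(taxa), sites, dimnames = list(taxa, NULL))
  if (gap_prob > 0) {
    mask <- matrix(stats::runif(length(mat)) < gap_prob, nrow(mat))
    mat[mask] <- "-"
  }
  alignment(mat, alphabet = if (all(states %in% c("A", "C", "G", "T"))) "nt" else "aa")
}

random_nt_model <- function(gamma = FALSE) {
  rates <- stats::rexp(6) + 0.2
  freq <- stats::runif(4, 0.5, 2); freq <- freq / sum(freq)
  gtr_model(rates = rates, freq = freq,
            alpha = if (gamma) stats::runif(1, 0.3, 2) else NULL, k = 3)
}
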