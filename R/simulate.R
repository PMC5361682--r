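#' Simulate an alignment on a tree
#'
#' Root states are drawn from the model's stationary frequencies and evolved
#' down every branch with the model's transition matrices; per-site rates
#' are drawn from the discrete-gamma categories. The full set of true states
#' at every node, per-site rate categories, and per-branch realised
#' substitution counts are returned as ground truth. Deterministic under
#' `seed`.
#'
#' @param tree Rooted `ape::phylo` with branch lengths.
#' @param model A [substitution_model()].
#' @param sites Number of sites (> 0).
#' @param seed Mandatory integer seed.
#' @return List with `aln` (an [alignment()]) and `truth` (class
#'   `"sim_truth"`): `states` (nodes x sites character matrix), `rates`
#'   (per-site category rates), `branch_subs` (named per-branch realised
#'   substitution counts), `planted` (empty registry).
#' @export
simulate_alignment <- function(tree, model, sites, seed) {
  if (sites <= 0) stop("need a positive number of sites")
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  idx <- tree_index(tree)
  S <- length(model$states)
  withr::with_seed(as.integer(seed), {
    rate_cat <- sample.int(model$k, sites, replace = TRUE)
    states <- matrix(NA_integer_, idx$nnode, sites)
    states[idx$root, ] <- sample.int(S, sites, replace = TRUE, prob = model$freq)
    nsub <- setNames(integer(idx$nnode), branch_ids(idx$tree))
    for (v in idx$int_preorder) {
      for (ch in idx$children[[v]]) {
        for (cc in seq_len(model$k)) {
          cols <- which(rate_cat == cc)
          if (!length(cols)) next
          P <- transition_matrix(model, idx$elen[ch], model$rates[cc])
          par_states <- states[v, cols]
          for (si in seq_len(S)) {
            here <- cols[par_states == si]
            if (!length(here)) next
            states[ch, here] <- sample.int(S, length(here), replace = TRUE,
                                           prob = P[si, ])
          }
        }
        nsub[ch] <- sum(states[ch, ] != states[v, ])
      }
    }
    mat <- matrix(model$states[states[seq_len(idx$ntip), ]], idx$ntip, sites)
    rownames(mat) <- idx$tree$tip.label
    truth <- structure(list(
      tree = idx$tree,
      states = matrix(model$states[states], idx$nnode, sites),
      rates = model$rates[rate_cat],
      branch_subs = nsub[setdiff(seq_len(idx$nnode), idx$root)],
      planted = data.frame(site = integer(0), derived = character(0),
                           parent_a = character(0), parent_b = character(0))),
      class = "sim_truth")
    list(aln = alignment(mat, alphabet = model$alphabet), truth = truth)
  })
}

#' Plant convergent substitutions on two focal branches
#'
#' At each chosen site, the child clade of each focal branch (the child node
#' and all its descendants) is rewritten to a common derived state that
#' differs from both focal parents' true states, creating a pure convergent
#' event with known ground truth. Policies: `"uniform"` draws the derived
#' state uniformly among states differing from both parents; `"parallel"`
#' restricts the planted sites to those where the two parents' states are
#' already equal; `"radical"` (amino acids) picks the state maximising the
#' smaller hydropathy change from the two parents, guaranteeing
#' radical-category replacements.
#'
#' @param sim A [simulate_alignment()] result.
#' @param branch_a,branch_b Focal branch specifications (independent pair).
#' @param n_sites Number of sites to plant.
#' @param policy `"uniform"`, `"parallel"`, or `"radical"`.
#' @param seed Mandatory integer seed.
#' @return Updated list with `aln` and `truth` (planted registry filled in).
#' @export
plant_convergence <- function(sim, branch_a, branch_b, n_sites,
                              policy = c("uniform", "parallel", "radical"),
                              seed) {
  policy <- match.arg(policy)
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  if (n_sites == 0) return(sim)
  truth <- sim$truth
  idx <- tree_index(truth$tree)
  a <- match_branch(idx$tree, branch_a)
  b <- match_branch(idx$tree, branch_b)
  check_independent(idx, a, b)
  model_states <- alphabet_states(sim$aln$alphabet)
  if (policy == "radical" && sim$aln$alphabet != "aa") {
    stop("the radical planting policy needs an amino-acid alignment")
  }
  desc <- node_descendant_tips(idx)
  clade_nodes <- function(v) {
    keep <- c(v)
    repeat {
      nxt <- unlist(idx$children[keep])
      new <- setdiff(nxt, keep)
      if (!length(new)) break
      keep <- c(keep, new)
    }
    keep
  }
  ca <- clade_nodes(a); cb <- clade_nodes(b)
  m <- ncol(truth$states)
  pa_all <- truth$states[idx$parent[a], ]
  pb_all <- truth$states[idx$parent[b], ]
  avail <- setdiff(seq_len(m), truth$planted$site)
  if (policy == "parallel") avail <- avail[pa_all[avail] == pb_all[avail]]
  if (length(avail) < n_sites) stop("not enough available sites to plant")
  withr::with_seed(as.integer(seed), {
    chosen <- sort(sample(avail, n_sites))
    derived <- character(n_sites)
    for (i in seq_along(chosen)) {
      s <- chosen[i]
      cand <- setdiff(model_states, c(pa_all[s], pb_all[s]))
      derived[i] <- if (policy == "radical") {
        hyd <- AA_PROPERTY_SCALES$hydropathy
        score <- pmin(abs(hyd[cand] - hyd[pa_all[s]]),
                      abs(hyd[cand] - hyd[pb_all[s]]))
        cand[which.max(score)]
      } else {
        if (length(cand) == 1) cand else sample(cand, 1)
      }
      truth$states[ca, s] <- derived[i]
      truth$states[cb, s] <- derived[i]
    }
  })
  tips <- seq_len(idx$ntip)
  mat <- truth$states[tips, , drop = FALSE]
  rownames(mat) <- idx$tree$tip.label
  truth$planted <- rbind(truth$planted, data.frame(
    site = chosen, derived = derived,
    parent_a = pa_all[chosen], parent_b = pb_all[chosen]))
  # refresh realised substitution counts after the rewrite
  for (v in setdiff(seq_len(idx$nnode), idx$root)) {
    truth$branch_subs[branch_ids(idx$tree)[v]] <-
      sum(truth$states[v, ] != truth$states[idx$parent[v], ])
  }
  list(aln = alignment(mat, alphabet = sim$aln$alphabet,
                       positions = sim$aln$positions),
       truth = truth)
}
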