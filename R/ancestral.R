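#' Marginal maximum-likelihood ancestral state reconstruction
#'
#' Computes, for every internal node and site, the marginal posterior
#' distribution over states by combining below-node (pruning) and above-node
#' partial likelihoods; under a gamma model the posteriors are averaged over
#' rate categories weighted by each category's per-site posterior. MAP
#' states are reported with their posterior probability; ties (within 1e-9)
#' are broken toward the parent node's MAP state, which is conservative for
#' substitution mapping, and otherwise toward the lowest state index.
#'
#' @param aln An [alignment()].
#' @param tree Rooted `ape::phylo` with branch lengths.
#' @param model A [substitution_model()].
#' @return Object of class `"anc_recon"`: list with `posterior` (list of
#'   S x sites matrices per internal node, indexed by node number), `map`
#'   (internal-nodes x sites character matrix), `map_prob` (same shape,
#'   numeric), `tree` (the reordered tree used), `engine` (internal).
#' @export
marginal_ancestral_states <- function(aln, tree, model) {
  if (!ape::is.rooted(tree)) {
    stop("tree must be rooted; root it first (e.g. with root_at())")
  }
  env <- build_engine(aln, tree, model)
  idx <- env$idx
  internal <- idx$int_postorder
  post <- node_posteriors(env, internal)
  S <- env$S; m <- env$m
  states <- model$states
  map <- matrix(NA_character_, idx$nnode, m)
  map_prob <- matrix(NA_real_, idx$nnode, m)
  # preorder so the parent's MAP is known when a child is processed
  for (v in idx$int_preorder) {
    pp <- post[[as.character(v)]]
    best <- max.col(t(pp), ties.method = "first")
    mx <- pp[cbind(best, seq_len(m))]
    p <- idx$parent[v]
    if (!is.na(p)) {
      pstate <- match(map[p, ], states)
      near <- which(!is.na(pstate) & pp[cbind(pstate, seq_len(m))] >= mx - 1e-9)
      best[near] <- pstate[near]
      mx[near] <- pp[cbind(best[near], near)]
    }
    map[v, ] <- states[best]
    map_prob[v, ] <- mx
  }
  structure(list(posterior = post, map = map, map_prob = map_prob,
                 tree = idx$tree, model = model, aln = aln, engine = env),
            class = "anc_recon")
}

#' @export
print.anc_recon <- function(x, ...) {
  cat(sprintf("<ancestral reconstruction> %d internal nodes x %d sites\n",
              length(x$posterior), ncol(x$map)))
  invisible(x)
}

# state of a node (observed for leaves, MAP for internal nodes)
node_states <- function(recon, v) {
  idx <- recon$engine$idx
  if (v <= idx$ntip) {
    recon$aln$mat[idx$tree$tip.label[v], ]
  } else {
    recon$map[v, ]
  }
}

#' Map substitutions onto branches
#'
#' For every branch and site, a substitution is recorded when the MAP state
#' of the parent differs from the child's state (observed for leaves, MAP
#' for internal nodes) and neither endpoint is a gap or unknown. Skipped
#' gap/unknown endpoints are tallied in the `skipped` attribute.
#'
#' @param recon An [marginal_ancestral_states()] result.
#' @return Data frame (class `"branch_subst"`): branch id, child node, site
#'   (1-based original position), parent and child states and MAP
#'   probabilities.
#' @export
map_substitutions <- function(recon) {
  idx <- recon$engine$idx
  states <- recon$model$states
  ids <- branch_ids(idx$tree)
  out <- list()
  skipped <- 0L
  for (v in seq_len(idx$nnode)) {
    if (v == idx$root) next
    p <- idx$parent[v]
    ps <- recon$map[p, ]
    cs <- node_states(recon, v)
    valid <- ps %in% states & cs %in% states
    skipped <- skipped + sum(!valid)
    hit <- which(valid & ps != cs)
    if (length(hit) == 0) next
    pprob <- recon$map_prob[p, hit]
    cprob <- if (v <= idx$ntip) rep(1, length(hit)) else recon$map_prob[v, hit]
    out[[length(out) + 1]] <- data.frame(
      branch = ids[v], node = v, site = recon$aln$positions[hit],
      parent_state = ps[hit], child_state = cs[hit],
      parent_prob = pprob, child_prob = cprob,
      stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(branch = character(0), node = integer(0), site = integer(0),
               parent_state = character(0), child_state = character(0),
               parent_prob = numeric(0), child_prob = numeric(0))
  attr(res, "skipped") <- skipped
  class(res) <- c("branch_subst", class(res))
  res
}

#' Ancestral state table for export
#'
#' Flattens a reconstruction into a long table (node, site, MAP state,
#' posterior probability), suitable for [write_tsv_report()].
#'
#' @param recon A [marginal_ancestral_states()] result.
#' @return Data frame with one row per internal node and site.
#' @export
ancestral_states_table <- function(recon) {
  idx <- recon$engine$idx
  ids <- branch_ids(idx$tree)
  internal <- idx$int_postorder
  out <- do.call(rbind, lapply(internal, function(v) {
    data.frame(node = v,
               clade = if (v == idx$root) "root" else ids[v],
               site = recon$aln$positions,
               state = recon$map[v, ],
               posterior = recon$map_prob[v, ])
  }))
  rownames(out) <- NULL
  out
}
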