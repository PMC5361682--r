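branch_is_ancestor <- function(idx, a, b) {
  # is the branch above node a on the root path of node b?
  v <- b
  while (!is.na(idx$parent[v])) {
    if (v == a) return(TRUE)
    v <- idx$parent[v]
  }
  v == a
}

check_independent <- function(idx, a, b) {
  if (a == b) stop("branch pair must consist of two distinct branches")
  if (branch_is_ancestor(idx, a, b) || branch_is_ancestor(idx, b, a)) {
    stop("branches are nested (ancestor-descendant); convergence is only ",
         "defined for independent branch pairs whose substitutions lie on ",
         "disjoint root-to-tip paths")
  }
}

#' All independent branch pairs of a rooted tree
#'
#' Independent means non-nested: neither branch lies on the other's
#' root-to-tip path, so their substitutions occur on disjoint paths. Sister
#' branches are retained.
#'
#' @param tree Rooted `ape::phylo`.
#' @return Data frame with child node numbers (`node_a`, `node_b`) and
#'   branch ids (`branch_a`, `branch_b`).
#' @export
independent_branch_pairs <- function(tree) {
  idx <- tree_index(tree)
  ids <- branch_ids(idx$tree)
  desc <- node_descendant_tips(idx)
  branches <- setdiff(seq_len(idx$nnode), idx$root)
  out <- list()
  for (i in seq_along(branches)) {
    for (j in seq_along(branches)) {
      if (j <= i) next
      a <- branches[i]; b <- branches[j]
      # nested iff one descendant-tip set contains the other
      da <- desc[[a]]; db <- desc[[b]]
      if (all(da %in% db) || all(db %in% da)) next
      out[[length(out) + 1]] <- c(a, b)
    }
  }
  mat <- do.call(rbind, out)
  data.frame(node_a = mat[, 1], node_b = mat[, 2],
             branch_a = ids[mat[, 1]], branch_b = ids[mat[, 2]],
             stringsAsFactors = FALSE)
}

#' Observed convergent and divergent substitutions for a branch pair
#'
#' A site is convergent when both branches carry a substitution (from
#' [map_substitutions()]) and the derived states are identical; divergent
#' when both carry substitutions with different derived states. Parallel
#' substitutions (identical ancestral states) are counted within the
#' convergent total and also reported separately.
#'
#' @param recon A [marginal_ancestral_states()] result.
#' @param branch_a,branch_b Branch specifications (see [match_branch()]);
#'   must be an independent (non-nested) pair.
#' @param subs Optional precomputed [map_substitutions()] table.
#' @return List of class `"branch_pair_conv"`: observed counts `C_obs`,
#'   `D_obs`, `parallel_obs`, and `sites` (per-site detail for convergent
#'   sites).
#' @export
count_convergent_divergent <- function(recon, branch_a, branch_b, subs = NULL) {
  idx <- recon$engine$idx
  a <- match_branch(idx$tree, branch_a)
  b <- match_branch(idx$tree, branch_b)
  check_independent(idx, a, b)
  if (is.null(subs)) subs <- map_substitutions(recon)
  sa <- subs[subs$node == a, ]
  sb <- subs[subs$node == b, ]
  common <- intersect(sa$site, sb$site)
  ia <- sa[match(common, sa$site), ]
  ib <- sb[match(common, sb$site), ]
  conv <- ia$child_state == ib$child_state
  sites <- data.frame(
    site = common,
    anc_a = ia$parent_state, derived_a = ia$child_state,
    anc_b = ib$parent_state, derived_b = ib$child_state,
    type = ifelse(conv,
                  ifelse(ia$parent_state == ib$parent_state, "parallel",
                         "convergent"),
                  "divergent"),
    stringsAsFactors = FALSE)
  structure(list(
    branch_a = branch_ids(idx$tree)[a], branch_b = branch_ids(idx$tree)[b],
    C_obs = sum(conv), D_obs = sum(!conv),
    parallel_obs = sum(sites$type == "parallel"),
    sites = sites[conv, , drop = FALSE],
    all_sites = sites), class = "branch_pair_conv")
}

#' Posterior-expected convergent and divergent counts for a branch pair
#'
#' For each site, the probability that branch `a` substitutes to state `j`
#' and branch `b` substitutes to state `l` is combined across the two
#' branches (factorised conditional on the data, exact for the per-branch
#' endpoint posteriors and an approximation for the cross-branch joint;
#' see the methods vignette). Events with `j == l` contribute to the
#' expected convergent count, `j != l` to the expected divergent count;
#' expectations are summed over sites.
#'
#' @param aln,tree,model As in [compute_log_likelihood()]; `tree` rooted.
#' @param branch_a,branch_b Branch specifications; independent pair.
#' @param engine Optional prebuilt engine (internal reuse).
#' @return List with `E_C`, `E_D`, and `mu_sites` (per-site convergent-event
#'   probabilities, the Zhang-Kumar inputs).
#' @export
posterior_expected_convergence <- function(aln = NULL, tree = NULL, model = NULL,
                                           branch_a, branch_b, engine = NULL) {
  env <- engine %||% build_engine(aln, tree, model)
  idx <- env$idx
  a <- match_branch(idx$tree, branch_a)
  b <- match_branch(idx$tree, branch_b)
  check_independent(idx, a, b)
  qa <- branch_subst_probs(env, a)
  qb <- branch_subst_probs(env, b)
  mu <- colSums(qa * qb)
  div <- colSums(qa) * colSums(qb) - mu
  list(E_C = sum(mu), E_D = sum(div), mu_sites = as.numeric(mu))
}

#' Pairwise convergence scan over all independent branch pairs
#'
#' Computes posterior-expected convergent/divergent counts for every
#' independent branch pair (and observed MAP-based counts when a
#' reconstruction is supplied).
#'
#' @param aln,tree,model As in [compute_log_likelihood()].
#' @param recon Optional [marginal_ancestral_states()] result for observed
#'   counts.
#' @return Data frame: branch ids, `E_C`, `E_D` (and `C_obs`, `D_obs`).
#' @export
convergence_scan <- function(aln, tree, model, recon = NULL) {
  env <- build_engine(aln, tree, model)
  idx <- env$idx
  pairs <- independent_branch_pairs(idx$tree)
  branches <- sort(unique(c(pairs$node_a, pairs$node_b)))
  qs <- qtot <- vector("list", idx$nnode)
  for (v in branches) {
    qs[[v]] <- branch_subst_probs(env, v)
    qtot[[v]] <- colSums(qs[[v]])
  }
  pairs$E_C <- pairs$E_D <- NA_real_
  for (r in seq_len(nrow(pairs))) {
    a <- pairs$node_a[r]; b <- pairs$node_b[r]
    mu <- colSums(qs[[a]] * qs[[b]])
    pairs$E_C[r] <- sum(mu)
    pairs$E_D[r] <- sum(qtot[[a]] * qtot[[b]]) - pairs$E_C[r]
  }
  if (!is.null(recon)) {
    subs <- map_substitutions(recon)
    pairs$C_obs <- pairs$D_obs <- NA_real_
    for (r in seq_len(nrow(pairs))) {
      sa <- subs[subs$node == pairs$node_a[r], ]
      sb <- subs[subs$node == pairs$node_b[r], ]
      common <- intersect(sa$site, sb$site)
      conv <- sa$child_state[match(common, sa$site)] ==
        sb$child_state[match(common, sb$site)]
      pairs$C_obs[r] <- sum(conv)
      pairs$D_obs[r] <- sum(!conv)
    }
  }
  pairs
}

#' Divergence-versus-convergence empirical null
#'
#' Ordinary least squares regression (with intercept) of convergent on
#' divergent counts across branch pairs; pairs are ranked by their vertical
#' residual and the top-ranked pair is flagged as the outlier. Degenerate
#' inputs (no variation) are flagged without a ranking.
#'
#' @param pairs Data frame with columns for convergent and divergent counts.
#' @param conv_col,div_col Column names to regress (defaults `E_C` on `E_D`).
#' @return List of class `"conv_null"`: `slope`, `intercept`, `residuals`,
#'   `ranking` (row indices, largest residual first), `top`, `degenerate`.
#' @export
fit_convergence_null <- function(pairs, conv_col = "E_C", div_col = "E_D") {
  if (nrow(pairs) < 3) stop("need at least 3 branch pairs")
  x <- pairs[[div_col]]; y <- pairs[[conv_col]]
  if (var(x) < 1e-12 && var(y) < 1e-12) {
    return(structure(list(degenerate = TRUE, slope = NA, intercept = NA,
                          residuals = rep(0, length(x)), ranking = NULL,
                          top = NA), class = "conv_null"))
  }
  fit <- lm(y ~ x)
  res <- resid(fit)
  ranking <- order(res, decreasing = TRUE)
  structure(list(degenerate = FALSE, slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]), residuals = as.numeric(res),
                 ranking = ranking, top = ranking[1],
                 pairs = pairs), class = "conv_null")
}

#' Zhang-Kumar convergence significance test
#'
#' Tests whether an observed number of convergent events exceeds the random
#' expectation, treating sites as independent Bernoulli events with
#' posterior convergence probabilities `mu_sites`. The p-value is the exact
#' Poisson-binomial tail `P(X >= c_obs)` (computed by convolution for up to
#' 5000 sites; Poisson approximation with the same mean beyond that).
#'
#' @param c_obs Observed convergent count.
#' @param mu_sites Per-site convergence probabilities in `[0, 1]`.
#' @param method `"auto"`, `"exact"` or `"poisson"`.
#' @return List of class `"zk_test"`: `c_obs`, `mu` (expected total),
#'   `p_value`, `method`.
#' @export
zhang_kumar_test <- function(c_obs, mu_sites, method = c("auto", "exact", "poisson")) {
  method <- match.arg(method)
  if (any(mu_sites < 0 | mu_sites > 1)) stop("mu_sites must be probabilities")
  if (c_obs < 0) stop("c_obs must be non-negative")
  n <- length(mu_sites)
  if (c_obs > n) stop("observed count exceeds the number of sites")
  mu <- sum(mu_sites)
  if (method == "auto") method <- if (n <= 5000) "exact" else "poisson"
  if (method == "exact") {
    pv <- 1  # P(X = 0)
    for (p in mu_sites) pv <- c(pv * (1 - p), 0) + c(0, pv * p)
    p_value <- if (c_obs == 0) 1 else sum(pv[(c_obs + 1):length(pv)])
    p_value <- min(max(p_value, 0), 1)
  } else {
    p_value <- if (c_obs == 0) 1 else ppois(c_obs - 1, mu, lower.tail = FALSE)
  }
  structure(list(c_obs = c_obs, mu = mu, mu_sites = mu_sites,
                 p_value = p_value, method = method), class = "zk_test")
}

#' @export
print.zk_test <- function(x, ...) {
  cat(sprintf("Zhang-Kumar convergence test: c_obs = %d, E = %.3f, p = %.4g (%s)\n",
              x$c_obs, x$mu, x$p_value, x$method))
  invisible(x)
}

#' Null per-site convergence probabilities for the Zhang-Kumar test
#'
#' The Zhang-Kumar null keeps each site's reconstructed ancestral states,
#' the branch lengths and the per-site posterior rate-category weights, and
#' randomises substitutions on the two focal branches under the model. The
#' observed derived states never enter, so real or planted convergence at a
#' site does not inflate its own null expectation.
#'
#' Two conditioning modes:
#' * `"destination"` (default): condition on the set of sites where both
#'   branches carry an inferred substitution; only the substitution
#'   destinations are random. The per-site probability is the model chance
#'   that two substitutions away from the (MAP) parent states land on a
#'   common state. Because observed count and null expectation then refer to
#'   the same inferred double-substitution events, reconstruction-detection
#'   biases cancel and the test is well calibrated.
#' * `"occurrence"`: substitution occurrence and destination are both
#'   random given the parent states (the classical unconditional form);
#'   more conservative because inferred and model substitution rates need
#'   not match exactly.
#'
#' @param recon A [marginal_ancestral_states()] result.
#' @param branch_a,branch_b Branch specifications (independent pair).
#' @param conditional `"destination"` or `"occurrence"`.
#' @param subs Optional precomputed [map_substitutions()] table.
#' @return Numeric vector of per-site convergence probabilities (one entry
#'   per alignment site; zero where the destination-conditional null has no
#'   double substitution).
#' @export
zk_site_probs <- function(recon, branch_a, branch_b,
                          conditional = c("destination", "occurrence"),
                          subs = NULL) {
  conditional <- match.arg(conditional)
  env <- recon$engine
  idx <- env$idx
  a <- match_branch(idx$tree, branch_a)
  b <- match_branch(idx$tree, branch_b)
  check_independent(idx, a, b)
  S <- env$S; m <- env$m
  states <- recon$model$states
  mu <- numeric(m)
  if (conditional == "occurrence") {
    ia <- match(recon$map[idx$parent[a], ], states)
    ib <- match(recon$map[idx$parent[b], ], states)
    for (cc in seq_len(env$k)) {
      Pa <- env$P[[cc]][[a]]
      Pb <- env$P[[cc]][[b]]
      for (s in seq_len(m)) {
        pa <- Pa[ia[s], ]; pa[ia[s]] <- 0
        pb <- Pb[ib[s], ]; pb[ib[s]] <- 0
        mu[s] <- mu[s] + env$cat_post[cc, s] * sum(pa * pb)
      }
    }
    return(mu)
  }
  if (is.null(subs)) subs <- map_substitutions(recon)
  sa <- subs[subs$node == a, ]
  sb <- subs[subs$node == b, ]
  common <- intersect(sa$site, sb$site)
  if (!length(common)) return(mu)
  ra <- sa[match(common, sa$site), ]
  rb <- sb[match(common, sb$site), ]
  ia <- match(ra$parent_state, states)
  ib <- match(rb$parent_state, states)
  scol <- match(common, recon$aln$positions)
  for (cc in seq_len(env$k)) {
    Pa <- env$P[[cc]][[a]]
    Pb <- env$P[[cc]][[b]]
    for (t in seq_along(common)) {
      i <- ia[t]; k <- ib[t]; s <- scol[t]
      pa <- Pa[i, ]; pa[i] <- 0; pa <- pa / sum(pa)
      pb <- Pb[k, ]; pb[k] <- 0; pb <- pb / sum(pb)
      mu[s] <- mu[s] + env$cat_post[cc, s] * sum(pa * pb)
    }
  }
  # a coincidence is only scored as convergent if both derived MAP states
  # are right; weight by the derived-endpoint MAP posteriors (1 at leaves)
  mu[scol] <- mu[scol] * ra$child_prob * rb$child_prob
  mu
}
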