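family_model <- function(family, par) {
  gamma <- grepl("\\+G$", family)
  alpha <- if (gamma) exp(par[["logalpha"]]) else NULL
  base <- sub("\\+G$", "", family)
  if (base == "JC") return(jc_model(alpha = alpha))
  if (base == "WAG") return(wag_model(alpha = alpha))
  if (base == "GTR") {
    rates <- c(exp(par[paste0("logr", 1:5)]), 1)
    f <- exp(c(par[paste0("logf", 1:3)], 0))
    return(gtr_model(rates = rates, freq = f / sum(f), alpha = alpha))
  }
  stop("unknown family")
}

family_init <- function(family) {
  par <- numeric(0)
  if (grepl("^GTR", family)) {
    par <- c(par, setNames(rep(0, 5), paste0("logr", 1:5)),
             setNames(rep(0, 3), paste0("logf", 1:3)))
  }
  if (grepl("\\+G$", family)) par <- c(par, logalpha = 0)
  par
}

#' Fit branch lengths and model parameters on a fixed topology
#'
#' Maximum-likelihood optimisation (L-BFGS-B on log-transformed parameters)
#' of all branch lengths plus the free parameters of the requested model
#' family (`"JC"`, `"GTR"`, `"WAG"`, each optionally `"+G"`). When `family`
#' is an existing [substitution_model()], only branch lengths are optimised.
#'
#' @param aln An [alignment()].
#' @param tree Rooted `ape::phylo` giving the fixed topology (branch lengths,
#'   if present, are used as starting values).
#' @param family Model family name or a fixed [substitution_model()].
#' @param maxit Iteration cap; non-convergence is flagged, not silent.
#' @param factr L-BFGS-B convergence tolerance (relative, in units of
#'   machine epsilon).
#' @return List with `tree` (optimised lengths), `model`, `loglik`,
#'   `converged`.
#' @export
fit_branch_lengths_and_params <- function(aln, tree, family = "JC",
                                          maxit = 200, factr = 1e6) {
  if (!ape::is.rooted(tree)) tree <- root_at_node(tree)
  tree <- stats::reorder(tree, "postorder")
  ne <- nrow(tree$edge)
  el0 <- tree$edge.length
  if (is.null(el0)) el0 <- rep(0.1, ne)
  el0 <- pmax(el0, 1e-6)
  fixed_model <- inherits(family, "subst_model")
  mpar0 <- if (fixed_model) numeric(0) else family_init(family)
  np <- length(mpar0)
  mk_model <- function(par) {
    if (fixed_model) family else family_model(family, par[seq_len(np)])
  }
  fn <- if (fixed_model) {
    # lean path: tree indexing, encoding and leaf partials are computed once
    lean <- lean_loglik_fn(aln, tree, family)
    function(par) -lean(exp(par[np + seq_len(ne)]))
  } else {
    function(par) {
      model <- mk_model(par)
      tr <- tree
      tr$edge.length <- exp(par[np + seq_len(ne)])
      -compute_log_likelihood(aln, tr, model)$total
    }
  }
  par0 <- c(mpar0, log(el0))
  opt <- optim(par0, fn, method = "L-BFGS-B",
               lower = c(rep(-10, np), rep(log(1e-7), ne)),
               upper = c(rep(10, np), rep(log(50), ne)),
               control = list(maxit = maxit, factr = factr))
  if (opt$convergence != 0) {
    warning("branch length/parameter optimisation did not converge (flag set)")
  }
  model <- mk_model(opt$par)
  tree$edge.length <- exp(opt$par[np + seq_len(ne)])
  list(tree = tree, model = model, loglik = -opt$value,
       converged = opt$convergence == 0, n_free = np + ne)
}

#' Model selection by AIC
#'
#' Fits each candidate family on the fixed topology and returns the full AIC
#' table plus the best (minimum AIC) fit. AIC = 2k - 2 lnL where k counts
#' branch lengths and free model parameters.
#'
#' @inheritParams fit_branch_lengths_and_params
#' @param candidates Character vector of family names.
#' @return List with `table` (data frame: family, k, loglik, AIC) and `best`
#'   (fit of the winning family).
#' @export
select_model <- function(aln, tree, candidates = c("JC", "JC+G", "GTR", "GTR+G"),
                         maxit = 200) {
  if (length(candidates) == 0) stop("empty candidate set")
  fits <- lapply(candidates, function(fam) {
    fit_branch_lengths_and_params(aln, tree, fam, maxit = maxit)
  })
  tab <- data.frame(
    family = candidates,
    k = vapply(fits, function(f) f$n_free, numeric(1)),
    loglik = vapply(fits, function(f) f$loglik, numeric(1))
  )
  tab$AIC <- 2 * tab$k - 2 * tab$loglik
  best <- which.min(tab$AIC)  # which.min takes the first (lowest index) on ties
  list(table = tab, best_family = candidates[best], best = fits[[best]])
}

#' NNI hill-climbing tree search
#'
#' Starting from a binary tree, repeatedly evaluates all nearest-neighbour
#' interchange rearrangements (branch lengths re-optimised for each
#' candidate), accepts the best strictly improving move, and stops at a
#' local optimum. The returned log-likelihood is never below the start
#' tree's.
#'
#' @inheritParams fit_branch_lengths_and_params
#' @param start_tree Binary starting tree.
#' @param max_rounds Cap on accepted moves.
#' @return List with `tree`, `model`, `loglik`, `rounds`.
#' @export
nni_search <- function(aln, start_tree, family = "JC", maxit = 100,
                       max_rounds = 20) {
  cur <- fit_branch_lengths_and_params(aln, start_tree, family, maxit = maxit)
  rounds <- 0
  repeat {
    nbrs <- phangorn::nni(ape::unroot(cur$tree))
    fits <- lapply(nbrs, function(tr) {
      tr$edge.length <- NULL
      fit_branch_lengths_and_params(aln, root_at_node(tr), family, maxit = maxit)
    })
    lls <- vapply(fits, function(f) f$loglik, numeric(1))
    if (max(lls) > cur$loglik + 1e-6 && rounds < max_rounds) {
      cur <- fits[[which.max(lls)]]
      rounds <- rounds + 1
    } else {
      break
    }
  }
  c(cur, list(rounds = rounds))
}
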