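# WAG amino-acid exchangeabilities (Whelan & Goldman 2001), lower triangle of
# the symmetric 20x20 matrix in PAML residue order (column-wise), together
# with the WAG equilibrium frequencies. These are the published constants.
WAG_EXCH <- c(
  0.551571, 0.509848, 0.738998, 1.02704, 0.908598, 1.58285, 1.41672,
  0.316954, 0.193335, 0.397915, 0.906265, 0.893496, 0.210494, 1.43855,
  3.37079, 2.12111, 0.113133, 0.240735, 2.00601, 0.635346, 0.147304,
  0.528191, 3.0355, 0.439157, 0.584665, 2.13715, 0.186979, 0.497671,
  5.35142, 0.683162, 0.102711, 0.679489, 1.22419, 0.554413, 1.16392,
  0.381533, 0.251849, 5.42942, 0.265256, 1.54364, 0.947198, 1.12556,
  3.95629, 0.554236, 0.131528, 3.01201, 0.198221, 0.0961621, 0.195081,
  3.97423, 2.03006, 0.0719167, 1.086, 0.196246, 0.0302949, 0.616783,
  6.17416, 0.865584, 0.930676, 0.039437, 0.0848047, 0.479855, 0.103754,
  0.0467304, 0.423984, 1.07176, 0.374866, 0.129767, 0.325711, 0.152335,
  0.0988179, 0.021352, 0.306674, 0.248972, 0.170135, 0.384287, 0.0740339,
  0.390482, 0.39802, 0.109404, 1.40766, 0.512984, 0.71707, 0.543833,
  1.00214, 5.46947, 0.330052, 4.29411, 0.113917, 0.869489, 3.8949,
  1.54526, 0.0999208, 0.933372, 1.02887, 0.857928, 0.215737, 0.22771,
  0.301281, 0.567717, 0.570025, 0.127395, 0.154263, 2.58443, 0.315124,
  0.0811339, 0.682355, 0.704939, 0.822765, 0.156557, 0.196303, 0.588731,
  0.24941, 0.0304501, 0.0613037, 0.373558, 0.1741, 0.049931, 0.24357,
  1.34182, 0.225833, 0.336983, 0.103604, 0.187247, 0.13819, 0.499462,
  0.890432, 0.404141, 0.679371, 0.696198, 0.740169, 0.473307, 0.262569,
  3.87344, 0.118358, 3.17097, 0.323832, 4.25746, 1.05947, 0.0999288,
  0.31944, 1.45816, 0.212483, 0.42017, 7.8213, 0.257555, 4.85402,
  2.11517, 0.415844, 0.344739, 0.326622, 0.665309, 0.398618, 1.80034,
  0.934276, 0.088836, 0.556896, 0.96713, 1.38698, 0.137505, 0.133264,
  0.305434, 1.19063, 0.171329, 0.493905, 1.51612, 0.515706, 0.428437,
  2.05845, 0.161444, 0.545931, 0.171903, 1.52964, 6.45428, 0.649892,
  1.61328, 0.795384, 0.139405, 0.216046, 0.314887, 4.37802, 0.523742,
  0.786993, 0.232739, 0.110864, 0.291148, 1.38823, 2.48539, 0.365369,
  0.31473)

WAG_FREQ <- c(0.0866279, 0.043972, 0.0390894, 0.0570451, 0.0193078,
              0.0367281, 0.0580589, 0.0832518, 0.0244313, 0.048466,
              0.086209, 0.0620286, 0.0195027, 0.0384319, 0.0457631,
              0.0695179, 0.0610127, 0.0143859, 0.0352742, 0.0708956)

lower_tri_to_sym <- function(x, S) {
  m <- matrix(0, S, S)
  m[lower.tri(m)] <- x
  m + t(m)
}

# discrete gamma category rates (mean 1): k categories with equal weight,
# category mean computed from the incomplete-gamma identity
discrete_gamma_rates <- function(alpha, k) {
  if (k == 1) return(1)
  qb <- qgamma(seq(0, 1, length.out = k + 1), shape = alpha, rate = alpha)
  p <- pgamma(qb, shape = alpha + 1, rate = alpha)
  r <- k * diff(p)
  r / mean(r) * 1  # numerically exact mean 1
}

#' Construct a reversible substitution model
#'
#' Builds a time-reversible rate matrix `Q = R diag(pi)` (off-diagonal), with
#' `R` a symmetric exchangeability matrix, normalised so the mean
#' substitution rate at stationarity is 1 substitution per site per unit
#' branch length. Rate heterogeneity across sites uses the discrete-gamma
#' approximation with `k` mean-one categories of equal weight.
#'
#' @param alphabet `"aa"` or `"nt"`.
#' @param exch Symmetric exchangeability matrix (or lower-triangle vector).
#'   Defaults: all-equal for `"nt"` (Jukes-Cantor when frequencies are equal).
#' @param freq Stationary frequencies (simplex).
#' @param alpha Gamma shape; `NULL` or `Inf` for uniform rates.
#' @param k Number of discrete gamma categories (field default 4).
#' @param name Model label.
#' @return Object of class `"subst_model"` with the scaled `Q`, an eigen
#'   decomposition cache, category rates and weights.
#' @export
substitution_model <- function(alphabet = c("nt", "aa"), exch = NULL,
                               freq = NULL, alpha = NULL, k = 4,
                               name = NULL) {
  alphabet <- match.arg(alphabet)
  states <- alphabet_states(alphabet)
  S <- length(states)
  if (is.null(freq)) freq <- rep(1 / S, S)
  stopifnot(length(freq) == S, all(freq > 0))
  freq <- freq / sum(freq)
  if (is.null(exch)) exch <- matrix(1, S, S)
  if (is.null(dim(exch))) exch <- lower_tri_to_sym(exch, S)
  stopifnot(isTRUE(all.equal(exch, t(exch))))
  Q <- exch * rep(freq, each = S)  # Q[i,j] = exch[i,j] * freq[j]
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  mu <- -sum(freq * diag(Q))
  Q <- Q / mu
  # reversible eigen decomposition via pi-symmetrisation
  d <- sqrt(freq)
  Sym <- Q * (d %o% (1 / d))
  Sym <- (Sym + t(Sym)) / 2
  eig <- eigen(Sym, symmetric = TRUE)
  if (is.null(alpha) || !is.finite(alpha)) {
    rates <- 1; weights <- 1; alpha <- NULL
  } else {
    rates <- discrete_gamma_rates(alpha, k)
    weights <- rep(1 / k, k)
  }
  structure(list(alphabet = alphabet, states = states, freq = freq, Q = Q,
                 exch = exch, alpha = alpha, k = length(rates),
                 rates = rates, weights = weights,
                 eig = list(values = eig$values,
                            right = eig$vectors / d,
                            left = t(eig$vectors * d)),
                 name = name %||% if (alphabet == "nt") "NT" else "AA"),
            class = "subst_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.subst_model <- function(x, ...) {
  cat(sprintf("<subst_model> %s (%s, %d states)%s\n", x$name, x$alphabet,
              length(x$states),
              if (is.null(x$alpha)) "" else
                sprintf(", +G(alpha=%.3g, k=%d)", x$alpha, x$k)))
  invisible(x)
}

#' Jukes-Cantor-type equal-rates model
#'
#' @param alphabet `"aa"` or `"nt"`.
#' @inheritParams substitution_model
#' @export
jc_model <- function(alphabet = "nt", alpha = NULL, k = 4) {
  substitution_model(alphabet, alpha = alpha, k = k,
                     name = if (is.null(alpha)) "JC" else "JC+G")
}

#' General time-reversible nucleotide model
#'
#' @param rates Six exchangeabilities in order AC, AG, AT, CG, CT, GT.
#' @param freq Base frequencies (A, C, G, T).
#' @inheritParams substitution_model
#' @export
gtr_model <- function(rates = c(1, 2, 1, 1, 2, 1), freq = rep(0.25, 4),
                      alpha = NULL, k = 4) {
  stopifnot(length(rates) == 6)
  ex <- matrix(0, 4, 4)
  ex[lower.tri(ex)] <- rates[c(1, 2, 3, 4, 5, 6)]
  # order in lower.tri (column-wise): (C,A),(G,A),(T,A),(G,C),(T,C),(T,G)
  ex <- ex + t(ex)
  substitution_model("nt", exch = ex, freq = freq, alpha = alpha, k = k,
                     name = if (is.null(alpha)) "GTR" else "GTR+G")
}

#' WAG empirical amino-acid model
#'
#' The package's built-in empirical amino-acid replacement model (WAG
#' exchangeabilities and frequencies); any other exchangeability matrix can
#' be supplied to [substitution_model()].
#'
#' @param freq Amino-acid frequencies; defaults to the WAG equilibrium set.
#' @inheritParams substitution_model
#' @export
wag_model <- function(freq = WAG_FREQ, alpha = NULL, k = 4) {
  substitution_model("aa", exch = WAG_EXCH, freq = freq, alpha = alpha, k = k,
                     name = if (is.null(alpha)) "WAG" else "WAG+G")
}

#' Transition probability matrix
#'
#' `P(t) = exp(Q t r)` for branch length `t` (expected substitutions per site
#' at rate 1) and rate multiplier `r`, computed from the cached reversible
#' eigen decomposition. Rows sum to 1 and `P(0)` is the identity.
#'
#' @param model A [substitution_model()].
#' @param t Non-negative branch length.
#' @param rate Rate multiplier (e.g. a gamma category rate).
#' @return Row-stochastic matrix.
#' @export
transition_matrix <- function(model, t, rate = 1) {
  if (t < 0) stop("negative branch length")
  e <- model$eig
  P <- e$right %*% (exp(e$values * t * rate) * e$left)
  P[P < 0] <- 0
  P / rowSums(P)
}
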