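# Published amino-acid property scales used by the physicochemical
# positive-selection scan: Kyte-Doolittle hydropathy, Grantham polarity,
# Zamyatnin residue volume (A^3) and Zimmerman isoelectric point. Any named
# list of 20-value vectors can be supplied instead.
AA_PROPERTY_SCALES <- local({
  nm <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  mk <- function(x) setNames(x, nm)
  list(
    hydropathy = mk(c(1.8, -4.5, -3.5, -3.5, 2.5, -3.5, -3.5, -0.4, -3.2,
                      4.5, 3.8, -3.9, 1.9, 2.8, -1.6, -0.8, -0.7, -0.9,
                      -1.3, 4.2)),
    polarity = mk(c(8.1, 10.5, 11.6, 13.0, 5.5, 10.5, 12.3, 9.0, 10.4, 5.2,
                    4.9, 11.3, 5.7, 5.2, 8.0, 9.2, 8.6, 5.4, 6.2, 5.9)),
    volume = mk(c(88.6, 173.4, 114.1, 111.1, 108.5, 143.8, 138.4, 60.1,
                  153.2, 166.7, 166.7, 168.6, 162.9, 189.9, 112.7, 89.0,
                  116.1, 227.8, 193.6, 140.0)),
    isoelectric = mk(c(6.00, 10.76, 5.41, 2.77, 5.07, 5.65, 3.22, 5.97,
                       7.59, 6.02, 5.98, 9.74, 5.74, 5.48, 6.30, 5.68,
                       5.60, 5.89, 5.66, 5.96))
  )
})

#' Amino-acid property scales shipped with the package
#'
#' @return Named list of four published 20-residue property scales.
#' @export
aa_property_scales <- function() AA_PROPERTY_SCALES

# all amino-acid replacements reachable by a single nucleotide change,
# weighted by the number of codon paths (uniform codon usage)
single_step_replacements <- function() {
  code <- Biostrings::GENETIC_CODE
  codons <- names(code)[code != "*"]
  nts <- c("A", "C", "G", "T")
  out <- list()
  for (cod in codons) {
    sp <- strsplit(cod, "")[[1]]
    for (pos in 1:3) {
      for (nt in setdiff(nts, sp[pos])) {
        alt <- sp; alt[pos] <- nt
        alt <- paste(alt, collapse = "")
        if (code[[alt]] == "*" || code[[alt]] == code[[cod]]) next
        out[[length(out) + 1]] <- c(code[[cod]], code[[alt]])
      }
    }
  }
  m <- do.call(rbind, out)
  pair <- paste(pmin(m[, 1], m[, 2]), pmax(m[, 1], m[, 2]), sep = "")
  tab <- table(pair)
  data.frame(aa1 = substr(names(tab), 1, 1), aa2 = substr(names(tab), 2, 2),
             weight = as.numeric(tab), stringsAsFactors = FALSE)
}

# null magnitude distribution and 8 equal-width categories for one scale
property_categories <- function(scale) {
  reps <- single_step_replacements()
  mag <- abs(scale[reps$aa1] - scale[reps$aa2])
  breaks <- seq(min(mag), max(mag), length.out = 9)
  cat_of <- function(x) pmin(pmax(findInterval(x, breaks, rightmost.closed = TRUE), 1), 8)
  p <- vapply(1:8, function(k) sum(reps$weight[cat_of(mag) == k]), numeric(1))
  list(breaks = breaks, p = p / sum(p), cat_of = cat_of)
}

#' Physicochemical-property positive-selection scan on a focal branch
#'
#' Infers amino-acid substitutions on the focal branch by marginal ancestral
#' reconstruction, measures the magnitude of change under each property
#' scale, bins magnitudes into 8 equal-width categories spanning the range
#' of all single-nucleotide amino-acid replacements (weighted by codon
#' structure), and z-scores the observed category counts per scan window
#' against that uniform nonsynonymous null. Sites whose substitution falls
#' in a radical category (6-8) with `z > z_threshold` are reported as
#' positively selected. The default window is a single codon.
#'
#' @param aln Codon-oriented nucleotide [alignment()] (translated in frame)
#'   or an amino-acid alignment.
#' @param tree Rooted species tree with branch lengths.
#' @param focal_branch Branch specification (see [match_branch()]).
#' @param model Amino-acid [substitution_model()] for the reconstruction
#'   (default [wag_model()]).
#' @param property_scales Named list of residue scales (default the four
#'   shipped scales).
#' @param z_threshold Strict z-score threshold (default 3.09, one-tailed
#'   p of about 0.001).
#' @param window Scan window size in codons (default 1).
#' @return List of class `"selscan"`: `selected_sites` (1-based amino-acid
#'   positions), `table` (site, property, magnitude, category, z),
#'   `focal_branch`.
#' @export
property_selection_scan <- function(aln, tree, focal_branch,
                                    model = wag_model(),
                                    property_scales = aa_property_scales(),
                                    z_threshold = 3.09, window = 1) {
  if (aln$alphabet == "nt") aln <- translate_alignment(aln)
  recon <- marginal_ancestral_states(aln, tree, model)
  subs <- map_substitutions(recon)
  v <- match_branch(recon$engine$idx$tree, focal_branch)
  subs <- subs[subs$node == v, , drop = FALSE]
  if (nrow(subs) == 0) {
    return(structure(list(selected_sites = integer(0),
                          table = data.frame(), focal_branch = focal_branch,
                          z_threshold = z_threshold), class = "selscan"))
  }
  rows <- list()
  for (pn in names(property_scales)) {
    sc <- property_scales[[pn]]
    pc <- property_categories(sc)
    mag <- abs(sc[subs$parent_state] - sc[subs$child_state])
    cat <- pc$cat_of(mag)
    # window z-scores: windows of `window` codons along the alignment
    win <- (subs$site - 1) %/% window
    for (w in unique(win)) {
      in_w <- which(win == w)
      N <- length(in_w)
      for (k in unique(cat[in_w])) {
        O <- sum(cat[in_w] == k)
        E <- N * pc$p[k]
        z <- (O - E) / sqrt(N * pc$p[k] * (1 - pc$p[k]))
        rows[[length(rows) + 1]] <- data.frame(
          site = subs$site[in_w][cat[in_w] == k], property = pn,
          magnitude = mag[in_w][cat[in_w] == k], category = k, z = z)
      }
    }
  }
  tab <- do.call(rbind, rows)
  sel <- sort(unique(tab$site[tab$category >= 6 & tab$z > z_threshold]))
  structure(list(selected_sites = sel, table = tab,
                 focal_branch = focal_branch, z_threshold = z_threshold),
            class = "selscan")
}

#' @export
print.selscan <- function(x, ...) {
  cat(sprintf("<property selection scan> %d selected sites (z > %.2f, categories 6-8)\n",
              length(x$selected_sites), x$z_threshold))
  invisible(x)
}
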