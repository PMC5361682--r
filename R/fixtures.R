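fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "adaptconv")
  if (p == "") stop("fixture file not found: ", file)
  p
}

#' Load a built-in fixture
#'
#' Available fixtures:
#' * `table1_matrix` — the 15-taxon x 21-column ADAMTS9 convergent-site
#'   amino-acid character matrix, with gaps (`-`) and unknowns (`X`)
#'   preserved and the original alignment positions in `positions`.
#' * `fig1_topology` — the accepted species topology for the 15 taxa
#'   (unit branch lengths; none are published).
#' * `fig2_gene_topology` — the convergent gene-tree topology in which the
#'   long-lived taxa form a clade (unit branch lengths).
#' * `sim_tree` — the species topology with the package's default synthetic
#'   branch lengths used by the simulation studies.
#' * `sim_gene_tree` — the convergent gene-tree topology with matching
#'   synthetic branch lengths (the screen's positive-control gene evolves
#'   on this tree).
#' * `taxon_attributes` — per-taxon longevity/body-mass table (masses are
#'   representative placeholders, not study data).
#'
#' @param name Fixture name.
#' @return An [alignment()], `ape::phylo`, or data frame.
#' @export
load_fixture <- function(name = c("table1_matrix", "fig1_topology",
                                  "fig2_gene_topology", "sim_tree",
                                  "sim_gene_tree", "taxon_attributes")) {
  name <- match.arg(name)
  switch(name,
    table1_matrix = read_alignment(
      fixture_path("table1_adamts9_convergent_sites.tsv"),
      format = "tsv-matrix", alphabet = "aa"),
    fig1_topology = set_branch_lengths(
      read_tree(fixture_path("species_tree_fig1a.nwk")), 1),
    fig2_gene_topology = set_branch_lengths(
      read_tree(fixture_path("gene_tree_fig2a.nwk")), 1),
    sim_tree = read_tree(fixture_path("species_tree_synthetic_lengths.nwk")),
    sim_gene_tree = read_tree(fixture_path("gene_tree_synthetic_lengths.nwk")),
    taxon_attributes = read.delim(fixture_path("taxon_attributes_synthetic.tsv"),
                                  comment.char = "#")
  )
}

#' Focal long-lived taxa and focal branches
#'
#' The long-lived, small-bodied focal taxa (naked mole-rat and the three
#' microbats) and the two focal branches of the convergence analysis: the
#' naked-mole-rat terminal branch and the ancestral-microbat branch.
#'
#' @return `focal_taxa()`: character vector of four leaf labels.
#'   `focal_branches()`: list with `nmr` (leaf label) and `microbat_stem`
#'   (clade spec usable with [match_branch()]).
#' @export
focal_taxa <- function() {
  c("Naked_mole_rat", "Eptesicus_fuscus", "Myotis_brandtii",
    "Myotis_lucifugus")
}

#' @rdname focal_taxa
#' @export
focal_branches <- function() {
  list(nmr = "Naked_mole_rat",
       microbat_stem = c("Eptesicus_fuscus", "Myotis_brandtii",
                         "Myotis_lucifugus"))
}

#' Default simulation model for the package's synthetic studies
#'
#' A transition-rich GTR+G nucleotide model (exchangeabilities AC 1.5, AG 4,
#' AT 1, CG 1.2, CT 6, GT 1; base frequencies 0.28/0.22/0.24/0.26; gamma
#' shape 0.8 with 4 categories) representative of a conserved mammalian
#' nuclear gene. Used, together with the `sim_tree` fixture, as the fixed
#' study condition for the null-calibration and planted-convergence
#' simulation studies.
#'
#' @return A [substitution_model()].
#' @export
default_sim_model <- function() {
  gtr_model(rates = c(1.5, 4, 1, 1.2, 6, 1),
            freq = c(0.28, 0.22, 0.24, 0.26), alpha = 0.8, k = 4)
}

#' Default amino-acid model for the convergence simulation studies
#'
#' WAG with gamma rate heterogeneity (shape 0.8, 4 categories). Together
#' with the `sim_tree` fixture this defines the fixed study condition for
#' the Zhang-Kumar calibration and planted-convergence power studies, which
#' are run at the amino-acid level as in the original convergence analyses.
#'
#' @return A [substitution_model()].
#' @export
default_aa_model <- function() wag_model(alpha = 0.8, k = 4)
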