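test_that("single-step replacement set has codon-weighted magnitudes", {
  reps <- adaptconv:::single_step_replacements()
  # L<->P is reachable (CUA->CCA etc); W<->G needs two changes? (UGG->GGG) is
  # one change, so it IS reachable; R<->D (CGU->GAU) is not
  key <- paste0(reps$aa1, reps$aa2)
  expect_true("LP" %in% key || "PL" %in% key)
  expect_false(any(key %in% c("DR", "RD")))
  expect_true(all(reps$weight >= 1))
  pc <- adaptconv:::property_categories(aa_property_scales()$hydropathy)
  expect_equal(sum(pc$p), 1, tolerance = 1e-12)
  expect_length(pc$p, 8)
})

test_that("empty focal branch yields an empty result, not an error", {
  m <- matrix("A", 4, 9, dimnames = list(letters[1:4], NULL))
  aln <- alignment(m, alphabet = "aa")
  tr <- read_tree_text("((a:0.1,b:0.1):0.1,(c:0.1,d:0.1):0.1);")
  res <- property_selection_scan(aln, tr, "a", model = wag_model())
  expect_s3_class(res, "selscan")
  expect_length(res$selected_sites, 0)
})

test_that("z threshold is strict and radical categories are required", {
  # category-probability table makes selection deterministic per category:
  # with one substitution per window, z = sqrt((1-p)/p); z > 3.09 iff
  # p < 1/(1 + 3.09^2)
  pc <- adaptconv:::property_categories(aa_property_scales()$hydropathy)
  z1 <- sqrt((1 - pc$p) / pc$p)
  selectable <- which(z1 > 3.09)
  boundary_p <- 1 / (1 + 3.09^2)
  expect_true(all(pc$p[selectable] < boundary_p))
  # a z of exactly the threshold must not select: construct via the formula
  expect_false(sqrt((1 - boundary_p) / boundary_p) > 3.09 + 1e-12)
})

test_that("planted radical replacements on the focal branch are selected", {
  tr <- load_fixture("sim_tree")
  model <- default_aa_model()
  fb <- focal_branches()
  sim <- simulate_alignment(tr, model, 300, seed = 21)
  sim <- plant_convergence(sim, fb$nmr, fb$microbat_stem, 10, "radical", seed = 22)
  scan <- property_selection_scan(sim$aln, tr, fb$microbat_stem, model = model)
  planted <- sim$truth$planted$site
  expect_gte(sum(planted %in% scan$selected_sites), 7)
  # selected sites all carry a substitution on the focal branch
  rec <- marginal_ancestral_states(sim$aln, tr, model)
  subs <- map_substitutions(rec)
  v <- match_branch(rec$engine$idx$tree, fb$microbat_stem)
  expect_true(all(scan$selected_sites %in% subs$site[subs$node == v]))
})

test_that("codon alignments are translated before scanning", {
  # build codons for an amino-acid pattern with a radical change on branch d
  codon_of <- c(I = "ATT", K = "AAA", E = "GAA")
  mk <- function(aas) unlist(strsplit(codon_of[aas], ""))
  m <- rbind(a = mk(c("K", "I")), b = mk(c("K", "I")),
             c = mk(c("K", "I")), d = mk(c("I", "I")))
  aln <- alignment(m, alphabet = "nt")
  tr <- read_tree_text("((a:0.05,b:0.05):0.05,(c:0.05,d:0.05):0.05);")
  scan <- property_selection_scan(aln, tr, "d", model = wag_model())
  expect_true(1 %in% scan$table$site)  # K->I change on codon 1 measured
})

test_that("site-wise lnL columns sum to the tree totals; identical trees tie", {
  tr <- load_fixture("sim_tree")
  sim <- simulate_alignment(tr, default_aa_model(), 40, seed = 23)
  sw <- sitewise_lnl(sim$aln, list(t1 = tr, t2 = tr), model = wag_model(),
                     reoptimize = FALSE)
  expect_equal(sw[, 1], sw[, 2], tolerance = 1e-10)
  tot <- compute_log_likelihood(sim$aln, tr, wag_model())$total
  expect_equal(sum(sw[, 1]), tot, tolerance = 1e-8)
  bad <- ape::rtree(5)
  expect_error(sitewise_lnl(sim$aln, list(tr, bad)), "leaf")
})

test_that("sites simulated under one topology favour it site-wise", {
  spec <- load_fixture("sim_tree")
  gene <- load_fixture("sim_gene_tree")
  sim <- simulate_alignment(gene, default_aa_model(), 200, seed = 24)
  sw <- sitewise_lnl(sim$aln, list(species = spec, convergent = gene),
                     model = wag_model())
  delta <- sw[, "species"] - sw[, "convergent"]
  # sign test: informative sites favour the generating (convergent) topology
  informative <- delta[abs(delta) > 1e-6]
  expect_gt(sum(informative < 0), 0.5 * length(informative))
  expect_lt(sum(delta), 0)
})

test_that("AU test: ties, determinism, and signal monotonicity", {
  withr::with_seed(31, {
    base <- matrix(rnorm(60, -3, 0.2), 30, 2)
  })
  tie <- base; tie[, 2] <- tie[, 1]
  expect_warning(au_tie <- au_test(tie, seed = 5), "identical")
  expect_equal(au_tie$au_p, c(0.5, 0.5))
  # injected signal: tree 1 progressively better
  ps <- sapply(c(0.02, 0.08, 0.2), function(s) {
    m <- base; m[, 1] <- m[, 1] + s
    au_test(m, seed = 6)$au_p[1]
  })
  expect_true(all(diff(ps) > 0))
  expect_gt(ps[3], 0.9)
  # reproducibility under the seed
  m <- base; m[, 1] <- m[, 1] + 0.05
  expect_identical(au_test(m, seed = 7)$au_p, au_test(m, seed = 7)$au_p)
  expect_error(au_test(base[1, , drop = FALSE], seed = 1), "2 sites")
})
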