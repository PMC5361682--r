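test_that("identity filter removes strictly-below-threshold alignments", {
  mk <- function(p_match) {
    n <- 200
    a <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
    b <- ifelse(runif(n) < p_match, a, "T")
    alignment(rbind(s1 = a, s2 = b), alphabet = "nt")
  }
  # exact-identity constructions at the boundary
  exact <- function(pct) {
    a <- rep("A", 1000)
    b <- c(rep("A", pct * 10), rep("C", 1000 - pct * 10))
    alignment(rbind(s1 = a, s2 = b), alphabet = "nt")
  }
  alns <- list(low = exact(59.9), edge = exact(60), high = exact(90))
  res <- filter_alignments(alns, threshold = 60)
  expect_setequal(names(res$retained), c("edge", "high"))
  expect_equal(res$filtered, "low")
  expect_equal(nrow(res$report), 3)
  expect_equal(sum(res$report$retained) + length(res$filtered), 3)
})

test_that("monophyly agrees with a brute-force split enumeration", {
  brute <- function(tree, focal) {
    # independent oracle: check every edge's split via ape::prop.part
    pp <- ape::prop.part(ape::unroot(tree))
    labs <- attr(pp, "labels")
    want <- sort(focal)
    comp <- sort(setdiff(labs, focal))
    for (side in pp) {
      s <- sort(labs[side])
      if (identical(s, want) || identical(s, comp)) return(TRUE)
    }
    FALSE
  }
  withr::with_seed(401, {
    for (rep in 1:50) {
      tr <- ape::rtree(10)
      k <- sample(2:5, 1)
      focal <- sample(tr$tip.label, k)
      expect_equal(is_focal_monophyletic(tr, focal), brute(tr, focal))
    }
  })
  expect_error(is_focal_monophyletic(ape::rtree(5), c("t1", "zzz")), "missing")
})

test_that("screen report handles errors, skips and order permutations", {
  fig1 <- load_fixture("fig1_topology")
  fig2 <- load_fixture("fig2_gene_topology")
  bad <- withr::local_tempfile(lines = "((a,b,;")
  small <- ape::rtree(4)  # lacks the focal taxa
  trees <- list(g1 = fig1, g2 = fig2, g3 = bad, g4 = small)
  rep1 <- suppressWarnings(screen_gene_trees(trees, focal_taxa()))
  expect_equal(rep1$n_flagged, 1)
  expect_equal(rep1$flagged, "g2")
  expect_match(rep1$report$status[3], "error")
  expect_match(rep1$report$status[4], "skipped")
  rep2 <- suppressWarnings(screen_gene_trees(rev(trees), focal_taxa()))
  expect_equal(rep2$n_flagged, rep1$n_flagged)
  empty <- screen_gene_trees(list(), focal_taxa())
  expect_equal(empty$n_flagged, 0)
  expect_equal(nrow(empty$report), 0)
})

test_that("reciprocal best hits keep mutual unique bests only", {
  ab <- data.frame(query = c("a1", "a1", "a2", "a3", "a3"),
                   subject = c("b1", "b2", "b2", "b3", "b4"),
                   score = c(100, 50, 80, 60, 60))
  ba <- data.frame(query = c("b1", "b2", "b3", "b4"),
                   subject = c("a1", "a2", "a9", "a3"),
                   score = c(90, 70, 55, 44))
  rbh <- reciprocal_best_hits(ab, ba)
  # a1<->b1 mutual best kept; a2->b2 and b2->a2 mutual; a3 ties -> dropped;
  # b3's best is a9 so a3-b3 would fail anyway
  expect_setequal(paste(rbh$a, rbh$b), c("a1 b1", "a2 b2"))
  expect_error(reciprocal_best_hits(ab[, 1:2], ba), "columns")
})

test_that("randomised ortholog truth with paralog decoys is fully recovered", {
  withr::with_seed(402, {
    n <- 60
    genes_a <- sprintf("a%02d", 1:n)
    genes_b <- sprintf("b%02d", 1:n)
    ab <- data.frame(query = genes_a, subject = genes_b,
                     score = runif(n, 90, 100))
    ba <- data.frame(query = genes_b, subject = genes_a,
                     score = runif(n, 90, 100))
    # 8 decoy paralogs: a's best hit points to the wrong b
    decoys <- sample(n, 8)
    ab$subject[decoys] <- genes_b[c(decoys[-1], decoys[1])]
    rbh <- reciprocal_best_hits(ab, ba)
    expect_setequal(rbh$a, genes_a[-decoys])
    expect_true(all(sub("a", "", rbh$a) == sub("b", "", rbh$b)))
  })
})

test_that("desk-scale screen flags exactly the convergent-topology gene", {
  tr <- load_fixture("sim_tree")
  gt <- load_fixture("sim_gene_tree")
  model <- default_sim_model()
  trees <- lapply(1:12, function(i) {
    src <- if (i == 7) gt else tr
    sim <- simulate_alignment(src, model, 1000, seed = 500 + i)
    build_gene_tree(sim$aln, model = model)
  })
  names(trees) <- sprintf("gene%02d", 1:12)
  rep <- screen_gene_trees(trees, focal_taxa())
  expect_equal(rep$flagged, "gene07")
})
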