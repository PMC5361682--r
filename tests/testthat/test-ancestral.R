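test_that("unanimous leaves give a near-certain root state", {
  m <- matrix("R", 4, 3, dimnames = list(letters[1:4], NULL))
  aln <- alignment(m, alphabet = "aa")
  tr <- read_tree_text("((a:0.02,b:0.02):0.02,(c:0.02,d:0.02):0.02);")
  rec <- marginal_ancestral_states(aln, tr, wag_model())
  root <- adaptconv:::tree_index(tr)$root
  expect_equal(unname(rec$map[root, ]), rep("R", 3))
  expect_true(all(rec$map_prob[root, ] > 0.99))
})

test_that("star-tree posterior matches the direct Bayes computation", {
  # 3-leaf star: posterior(center = x) ~ pi_x * prod_leaves P(t)[x, leaf];
  # encode the star as a rooted tree with a zero-length root edge (the
  # center node posterior is unchanged under reversibility)
  tr <- read_tree_text("(c:0.2,(a:0.3,b:0.7):0);")
  m <- rbind(a = "A", b = "C", c = "A")
  aln <- alignment(m, alphabet = "nt")
  model <- jc_model()
  # direct computation
  post_direct <- model$freq *
    transition_matrix(model, 0.3)[, 1] *
    transition_matrix(model, 0.7)[, 2] *
    transition_matrix(model, 0.2)[, 1]
  post_direct <- post_direct / sum(post_direct)
  rec <- marginal_ancestral_states(aln, tr, model)
  center <- match_branch(tr, c("a", "b"))
  got <- rec$posterior[[as.character(center)]][, 1]
  expect_equal(got, post_direct, tolerance = 1e-10)
})

test_that("posteriors are proper distributions and match enumeration", {
  withr::with_seed(201, {
    for (rep in 1:6) {
      tr <- random_tree(4)
      model <- random_nt_model(gamma = rep %% 2 == 0)
      aln <- random_alignment(tr$tip.label, 3, c("A", "C", "G", "T"),
                              gap_prob = 0.1)
      rec <- marginal_ancestral_states(aln, tr, model)
      en <- enum_quantities(aln, tr, model)
      for (v in names(rec$posterior)) {
        expect_equal(colSums(rec$posterior[[v]]), rep(1, 3), tolerance = 1e-8)
        expect_equal(rec$posterior[[v]], en$posterior[[as.integer(v)]],
                     tolerance = 1e-8)
      }
    }
  })
})

test_that("reconstruction requires a rooted tree and is deterministic", {
  tr <- ape::unroot(read_tree_text("((a:1,b:1):1,(c:1,d:1):1);"))
  aln <- alignment(matrix("A", 4, 2, dimnames = list(letters[1:4], NULL)),
                   alphabet = "nt")
  expect_error(marginal_ancestral_states(aln, tr, jc_model()), "root")
  rtr <- adaptconv:::root_at_node(tr)
  r1 <- marginal_ancestral_states(aln, rtr, jc_model())
  r2 <- marginal_ancestral_states(aln, rtr, jc_model())
  expect_identical(r1$map, r2$map)
})

test_that("substitution mapping finds the parsimony-obvious change", {
  m <- rbind(a = c("I", "M"), b = c("I", "M"), c = c("I", "M"), d = c("V", "M"))
  aln <- alignment(m, alphabet = "aa")
  tr <- read_tree_text("((a:0.05,b:0.05):0.05,(c:0.05,d:0.05):0.05);")
  rec <- marginal_ancestral_states(aln, tr, wag_model())
  subs <- map_substitutions(rec)
  expect_equal(nrow(subs), 1)
  expect_equal(subs$branch, "d")
  expect_equal(subs$site, 1)
  expect_equal(subs$parent_state, "I")
  expect_equal(subs$child_state, "V")
})

test_that("zero-length tree on identical sequences maps no substitutions", {
  m <- matrix("K", 4, 5, dimnames = list(letters[1:4], NULL))
  aln <- alignment(m, alphabet = "aa")
  tr <- read_tree_text("((a:0,b:0):0,(c:0,d:0):0);")
  rec <- marginal_ancestral_states(aln, tr, wag_model())
  expect_equal(nrow(map_substitutions(rec)), 0)
})

test_that("gap/unknown endpoints are skipped and tallied", {
  m <- rbind(a = c("I", "-"), b = c("I", "X"), c = c("I", "K"), d = c("V", "K"))
  aln <- alignment(m, alphabet = "aa")
  tr <- read_tree_text("((a:0.05,b:0.05):0.05,(c:0.05,d:0.05):0.05);")
  subs <- map_substitutions(marginal_ancestral_states(aln, tr, wag_model()))
  expect_false(any(subs$site == 2 & subs$branch %in% c("a", "b")))
  expect_gte(attr(subs, "skipped"), 2)
})

test_that("root MAP accuracy exceeds 90% on short-branch simulations", {
  tr <- load_fixture("sim_tree")
  tr$edge.length <- tr$edge.length / sum(tr$edge.length)  # total length 1
  model <- jc_model()
  sim <- simulate_alignment(tr, model, 1000, seed = 55)
  rec <- marginal_ancestral_states(sim$aln, tr, model)
  root <- adaptconv:::tree_index(tr)$root
  truth_root <- sim$truth$states[root, ]
  expect_gt(mean(rec$map[root, ] == truth_root), 0.9)
})

test_that("focal-branch substitutions at the first fixture column go to V", {
  aln <- load_fixture("table1_matrix")
  tr <- root_at(load_fixture("fig1_topology"), "Opossum")
  fit <- fit_branch_lengths_and_params(aln, tr, wag_model(), maxit = 300)
  rec <- marginal_ancestral_states(aln, fit$tree, fit$model)
  subs <- map_substitutions(rec)
  fb <- focal_branches()
  nmr <- subs[subs$branch == "Naked_mole_rat" & subs$site == 54, ]
  bat <- subs[subs$branch == paste(sort(fb$microbat_stem), collapse = "|") &
                subs$site == 54, ]
  expect_equal(nmr$child_state, "V")
  expect_equal(bat$child_state, "V")
})
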