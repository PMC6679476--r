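test_that("prior estimation applies add-one smoothing over the alphabet", {
  cd <- character_data(paste0("t", 1:4), c("red", "red", "blue", "blue"))
  expect_equal(unname(estimate_priors(cd)), c(0.5, 0.5))
  cd2 <- character_data(paste0("t", 1:4), c("red", "red", "red", "blue"))
  expect_equal(estimate_priors(cd2), c(blue = 2 / 6, red = 4 / 6))
  cd3 <- character_data(paste0("t", 1:4), rep("red", 4),
                        alphabet = c("blue", "red"))
  expect_equal(estimate_priors(cd3), c(blue = 1 / 6, red = 5 / 6))
  expect_true(all(estimate_priors(cd3) > 0))
})

test_that("transition probabilities are identity at t = 0 and reach the priors", {
  m <- f81_model(c(a = 0.2, b = 0.3, c = 0.5), sigma = 1.7)
  expect_equal(unname(f81_transition_probability(m, 0)), diag(3))
  Pinf <- f81_transition_probability(m, 1e9)
  for (i in 1:3) expect_equal(unname(Pinf[i, ]), m$pi, tolerance = 1e-12)
  expect_error(f81_transition_probability(m, -1), ">= 0")
})

test_that("equal priors over four states reduce to the Jukes-Cantor closed form", {
  m <- f81_model(setNames(rep(0.25, 4), letters[1:4]), sigma = 2)
  expect_equal(m$mu, 4 / 3)
  for (t in c(0.05, 0.3, 1, 4)) {
    P <- f81_transition_probability(m, t)
    expect_equal(unname(diag(P)),
                 rep(0.25 + 0.75 * exp(-(4 / 3) * 2 * t), 4), tolerance = 1e-12)
    expect_equal(unname(P[1, 2]), 0.25 - 0.25 * exp(-(4 / 3) * 2 * t),
                 tolerance = 1e-12)
  }
})

test_that("rows are stochastic and priors are stationary for random models", {
  for (seed in 1:20) {
    set.seed(seed)
    K <- sample(2:5, 1)
    pi <- stats::rgamma(K, 1) + 0.05
    pi <- setNames(pi / sum(pi), paste0("s", seq_len(K)))
    m <- f81_model(pi, sigma = stats::runif(1, 0.1, 5))
    t <- stats::rexp(1)
    P <- f81_transition_probability(m, t)
    expect_equal(unname(rowSums(P)), rep(1, K), tolerance = 1e-12)
    expect_equal(unname(as.numeric(m$pi %*% P)), m$pi, tolerance = 1e-12)
    # time reversibility: pi_i P_ij = pi_j P_ji
    expect_equal(unname(m$pi * P), unname(t(m$pi * P)), tolerance = 1e-12)
  }
})

test_that("a lone observed state contributes its log prior", {
  tr <- parse_newick("(A:0,B:0);")
  m <- f81_model(c(x = 0.3, y = 0.7))
  cd <- character_data(c("A", "B"), c("x", NA), alphabet = c("x", "y"))
  expect_equal(tree_log_likelihood(tr, cd, m), log(0.3))
})

test_that("the two-leaf likelihood equals the direct summation", {
  tr <- parse_newick("(A:0.4,B:1.3);")
  m <- f81_model(c(x = 0.3, y = 0.7), sigma = 1.9)
  cd <- character_data(c("A", "B"), c("x", "y"))
  P1 <- f81_transition_probability(m, 0.4)
  P2 <- f81_transition_probability(m, 1.3)
  direct <- sum(m$pi * P1[, "x"] * P2[, "y"])
  expect_equal(tree_log_likelihood(tr, cd, m), log(direct), tolerance = 1e-12)
})

test_that("conflicting states across zero-length branches give -Inf, not an error", {
  tr <- parse_newick("(A:0,B:0);")
  m <- f81_model(c(x = 0.5, y = 0.5))
  cd <- character_data(c("A", "B"), c("x", "y"))
  expect_identical(tree_log_likelihood(tr, cd, m), -Inf)
})

test_that("pruning, posteriors and joint match exhaustive enumeration on a seeded grid", {
  grid_seed <- 0
  for (n in 3:5) {
    for (K in 2:4) {
      grid_seed <- grid_seed + 1
      fx <- random_annotated_tips(n, K, seed = 3000 + grid_seed)
      # include an occasional missing tip
      tips <- fx$tips
      if (grid_seed %% 3 == 0) {
        tips <- character_data(tips$taxon,
                               replace(tips$state, 1, NA),
                               alphabet = state_alphabet(tips))
      }
      pi <- estimate_priors(tips)
      m <- f81_model(pi, sigma = 0.8 + 0.1 * K)
      br <- brute_likelihood(fx$tree, tips, m)
      expect_equal(tree_log_likelihood(fx$tree, tips, m), log(br$lik),
                   tolerance = 1e-10)
      post <- marginal_posteriors(fx$tree, tips, m)
      wide <- tidyr::pivot_wider(post, names_from = "state", values_from = "prob")
      got <- as.matrix(wide[, m$alphabet])
      expect_equal(unname(got), unname(br$post[wide$node, , drop = FALSE]),
                   tolerance = 1e-9)
      expect_equal(rowSums(got), rep(1, nrow(got)), tolerance = 1e-9)
      j <- joint_reconstruction(fx$tree, tips, m)
      bj <- brute_joint(fx$tree, tips, m)
      expect_equal(j$log_prob, log(bj$prob), tolerance = 1e-10)
      # the returned assignment itself attains the exhaustive maximum
      # (ties between equally likely assignments are legitimate)
      expect_equal(log(assignment_prob(fx$tree, j$states$state, m)),
                   log(bj$prob), tolerance = 1e-10)
      expect_lte(j$log_prob, tree_log_likelihood(fx$tree, tips, m) + 1e-12)
    }
  }
})

test_that("annotated leaves have point-mass posteriors; symmetric cherries split the root", {
  tr <- parse_newick("(A:1,B:1);")
  m <- f81_model(c(x = 0.5, y = 0.5), sigma = 1)
  cd <- character_data(c("A", "B"), c("x", "y"))
  post <- marginal_posteriors(tr, cd, m)
  root <- post[post$node == 3, ]
  expect_equal(root$prob, c(0.5, 0.5), tolerance = 1e-12)
  leafA <- post[post$node == 1, ]
  expect_equal(leafA$prob[leafA$state == "x"], 1)
})

test_that("MAP states take the argmax with flagged lexicographic ties", {
  tr <- parse_newick("(A:1,B:1);")
  m <- f81_model(c(x = 0.5, y = 0.5))
  cd <- character_data(c("A", "B"), c("x", "y"))
  ms <- map_states(marginal_posteriors(tr, cd, m))
  expect_identical(unname(ms$state[ms$node == 3]), "x") # exact tie -> lexicographic
  expect_true(ms$tie[ms$node == 3])
  expect_false(any(ms$tie[ms$node %in% 1:2]))
})

test_that("the MAP-of-marginals labeling can differ from the joint assignment", {
  found <- FALSE
  for (seed in 1:200) {
    fx <- random_annotated_tips(4, 3, seed = 5000 + seed)
    m <- f81_model(estimate_priors(fx$tips), sigma = 2.5)
    ms <- map_states(marginal_posteriors(fx$tree, fx$tips, m))
    j <- joint_reconstruction(fx$tree, fx$tips, m)
    if (!identical(ms$state, j$states$state)) { found <- TRUE; break }
  }
  expect_true(found)
})

test_that("likelihood is invariant to child order and to rerooting at fixed parameters", {
  fx <- random_annotated_tips(9, 3, seed = 6100, p_multi = 0)
  m <- f81_model(estimate_priors(fx$tips), sigma = 1.4)
  base <- tree_log_likelihood(fx$tree, fx$tips, m)
  sw <- swap_children(fx$tree, ape::Ntip(fx$tree) + 1L)
  expect_equal(tree_log_likelihood(sw, fx$tips, m), base, tolerance = 1e-9)
  lad <- ladderize_tree(fx$tree)
  expect_equal(tree_log_likelihood(lad, fx$tips, m), base, tolerance = 1e-9)
  internal <- setdiff((ape::Ntip(fx$tree) + 2L):(ape::Ntip(fx$tree) + fx$tree$Nnode),
                      integer(0))
  rr <- reroot_tree(fx$tree, internal[1])
  expect_equal(tree_log_likelihood(rr, fx$tips, m), base, tolerance = 1e-6)
})

test_that("rescaling every branch by c rescales the fitted sigma by 1/c", {
  fx <- random_annotated_tips(40, 3, seed = 6200, p_multi = 0)
  sim <- simulate_character(fx$tree, f81_model(estimate_priors(fx$tips), sigma = 1.5),
                            seed = 6201)
  f1 <- fit_scaling_factor(fx$tree, sim$tips)
  scaled <- fx$tree
  scaled$edge.length <- scaled$edge.length * 4
  f2 <- fit_scaling_factor(scaled, sim$tips)
  expect_equal(f2$sigma, f1$sigma / 4, tolerance = 1e-3)
  expect_equal(f2$loglik, f1$loglik, tolerance = 1e-6)
})

test_that("uninformative data pin sigma to 1 with a warning", {
  tr <- random_tree(6, seed = 6300)
  cd <- character_data(tr$tip.label, rep("only", 6), alphabet = c("alt", "only"))
  expect_warning(m <- fit_scaling_factor(tr, cd),
                 class = "traitmaps_sigma_unidentifiable")
  expect_equal(m$sigma, 1)
})

test_that("trees without branch lengths fall back to unit lengths with a warning", {
  tr <- parse_newick("((A,B),(C,D));")
  cd <- character_data(LETTERS[1:4], c("x", "x", "y", "y"))
  expect_warning(m <- fit_scaling_factor(tr, cd),
                 class = "traitmaps_unit_lengths")
  expect_true(m$sigma > 0)
})

test_that("MAP accuracy at internal nodes beats chance on simulated data", {
  pi <- setNames(rep(1 / 3, 3), paste0("s", 1:3))
  correct <- 0; total <- 0
  for (rep in 1:10) {
    tr <- sim_yule_tree(30, seed = 6400 + rep)
    sim <- simulate_character(tr, f81_model(pi, sigma = 0.5), seed = 6500 + rep)
    m <- f81_model(pi, sigma = 0.5)
    ms <- map_states(marginal_posteriors(tr, sim$tips, m))
    internal <- (ape::Ntip(tr) + 1L):(ape::Ntip(tr) + tr$Nnode)
    truth <- sim$truth$state[match(internal, sim$truth$node)]
    got <- ms$state[match(internal, ms$node)]
    correct <- correct + sum(got == truth)
    total <- total + length(internal)
  }
  expect_gt(correct / total, 1 / 3 + 0.1)
})
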