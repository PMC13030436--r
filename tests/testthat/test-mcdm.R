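test_that("min-max normalisation respects directions and flags constants", {
  dm <- decision_matrix(cbind(a = c(1, 2, 3), b = c(1, 2, 3)),
                        directions = c("benefit", "cost"))
  Z <- normalize_decision(dm)
  expect_equal(unname(Z[, "a"]), c(0, 0.5, 1))
  expect_equal(unname(Z[, "b"]), c(1, 0.5, 0))

  toy <- decision_matrix(cbind(x = c(2, 6), y = c(10, 4)),
                         directions = c("benefit", "cost"))
  expect_equal(unname(normalize_decision(toy)), cbind(c(0, 1), c(0, 1)),
               ignore_attr = TRUE)

  cst <- decision_matrix(cbind(u = c(1, 5, 3), v = c(7, 7, 7)))
  expect_warning(Zc <- normalize_decision(cst), "constant")
  expect_true(all(Zc[, "v"] == 0))
  expect_identical(unname(attr(Zc, "degenerate")), c(FALSE, TRUE))

  # min-max shift invariance of a raw benefit column
  shifted <- decision_matrix(cbind(u = c(1, 5, 3) + 100, v = c(1, 2, 3)))
  plain <- decision_matrix(cbind(u = c(1, 5, 3), v = c(1, 2, 3)))
  expect_equal(unname(normalize_decision(shifted)),
               unname(normalize_decision(plain)))

  expect_error(decision_matrix(cbind(1:3)), "2 alternatives")
  expect_error(decision_matrix(cbind(a = c(1, NA), b = c(1, 2))),
               "missing")
})

test_that("entropy weights match the hand-worked information-utility oracle", {
  Z <- cbind(flat = c(1, 1, 1, 1), bin = c(0, 1, 0, 1),
             grad = c(0.2, 0.4, 0.6, 0.8))
  w <- entropy_weights(Z)
  expect_equal(w$entropy, c(1, 0.5, 0.9232196723), tolerance = 1e-9)
  expect_equal(w$utility, 1 - w$entropy)
  expect_equal(w$weight, c(0, 0.8668811608, 0.1331188392), tolerance = 1e-9)
  expect_equal(sum(w$weight), 1)

  # all weight flows to the only informative column
  w2 <- entropy_weights(cbind(a = c(2, 2), b = c(0, 1)))
  expect_equal(w2$weight, c(0, 1))

  expect_error(entropy_weights(cbind(a = c(1, 1), b = c(3, 3))),
               "degenerate")
})

test_that("TOPSIS reproduces the hand-worked distances and limit cases", {
  Z <- rbind(worst = c(0, 0), mid = c(0.5, 1), alt = c(1, 0.5))
  res <- topsis(Z, c(0.5, 0.5))
  res <- res[match(rownames(Z), res$alternative), ]
  expect_equal(res$d_plus, c(sqrt(0.5), 0.25, 0.25), tolerance = 1e-12)
  expect_equal(res$d_minus, c(0, 0.5590169944, 0.5590169944),
               tolerance = 1e-9)
  expect_equal(res$ci, c(0, 0.6909830056, 0.6909830056), tolerance = 1e-9)
  # tie on Ci broken by alternative ID
  expect_identical(res$rank[match(c("alt", "mid"), res$alternative)],
                   c(1L, 2L))

  # ideal and worst alternatives hit the Ci limits
  Z2 <- rbind(best = c(1, 1), mid = c(0.3, 0.6), low = c(0, 0))
  r2 <- topsis(Z2, c(0.4, 0.6))
  expect_equal(r2$ci[r2$alternative == "best"], 1)
  expect_equal(r2$ci[r2$alternative == "low"], 0)
  expect_true(all(r2$ci >= 0 & r2$ci <= 1))

  # identical alternatives: Ci defined as 0.5 with a warning
  expect_warning(same <- topsis(rbind(a = c(1, 1), b = c(1, 1)),
                                c(0.5, 0.5)),
                 "0.5")
  expect_equal(same$ci, c(0.5, 0.5))

  expect_error(topsis(Z, c(0.7, 0.7)), "sum to 1")
})

test_that("TOPSIS ranking is invariant to row order", {
  withr::with_seed(14, {
    Z <- matrix(runif(40), 8, 5,
                dimnames = list(paste0("g", 1:8), paste0("i", 1:5)))
  })
  w <- rep(0.2, 5)
  r1 <- topsis(Z, w)
  perm <- sample(8)
  r2 <- topsis(Z[perm, ], w)
  expect_identical(r1$alternative, r2$alternative)
  expect_equal(r1$ci, r2$ci)
})

test_that("CRITIC weights follow sigma times conflict", {
  # orthogonal columns with sds 1 and 2 -> weights (1/3, 2/3)
  Z <- cbind(a = c(-1, 0, 1), b = c(1, -2, 1) * 2 / sqrt(3))
  w <- critic_weights(Z)
  expect_equal(w$weight, c(1 / 3, 2 / 3), tolerance = 1e-12)

  # perfectly correlated equal-SD columns share the weight equally
  w2 <- critic_weights(cbind(a = c(1, 2, 3), b = c(2, 4, 6) / 2))
  expect_equal(w2$weight, c(0.5, 0.5))

  # 4x3 toy against the direct formula
  withr::with_seed(3, {
    Z3 <- matrix(runif(12), 4, 3, dimnames = list(NULL, c("x", "y", "z")))
  })
  w3 <- critic_weights(Z3)
  sds <- apply(Z3, 2, function(v) sqrt(sum((v - mean(v))^2) / 3))
  r <- cor(Z3)
  C <- sds * (rowSums(1 - r))
  expect_equal(w3$weight, unname(C / sum(C)))
  expect_equal(sum(w3$weight), 1)

  expect_error(critic_weights(cbind(a = 1:3)), "single indicator")
})

test_that("integrated evaluation agrees across weightings on dominance gradients", {
  # one alternative dominates every indicator
  dm <- decision_matrix(rbind(top = c(9, 9, 9), low = c(1, 2, 3)))
  ev <- evaluate_genotypes(dm)
  expect_identical(ev$rankings$entropy$alternative[1], "top")
  expect_identical(ev$rankings$critic$alternative[1], "top")
  expect_equal(ev$agreement$spearman_rho, 1)

  # planted dominance gradient: entropy and CRITIC rankings correlate
  withr::with_seed(77, {
    quality <- sort(runif(17), decreasing = TRUE)
    X <- sapply(1:10, function(j) quality + rnorm(17, 0, 0.15))
    dimnames(X) <- list(sprintf("G%02d", 1:17), sprintf("I%02d", 1:10))
  })
  ev2 <- evaluate_genotypes(decision_matrix(X))
  expect_gt(ev2$agreement$spearman_rho, 0)

  # duplicating an indicator: removing the duplicate and renormalising
  # recovers the original entropy weights, hence the original ranking
  dup <- cbind(X, I11 = X[, 1])
  w_dup <- entropy_weights(normalize_decision(decision_matrix(dup)))
  w_orig <- ev2$weights$entropy
  expect_equal(w_dup$weight[11], w_dup$weight[1])
  expect_equal(w_dup$weight[1:10] / sum(w_dup$weight[1:10]),
               w_orig$weight)
  r_back <- topsis(normalize_decision(decision_matrix(X)),
                   w_dup$weight[1:10] / sum(w_dup$weight[1:10]))
  expect_identical(r_back$alternative,
                   ev2$rankings$entropy$alternative)
})

test_that("adding a constant to a raw benefit column leaves weights and Ci unchanged", {
  withr::with_seed(21, {
    X <- matrix(runif(24, 1, 5), 6, 4,
                dimnames = list(paste0("g", 1:6), paste0("i", 1:4)))
  })
  ev1 <- evaluate_genotypes(decision_matrix(X))
  X2 <- X; X2[, 2] <- X2[, 2] + 50
  ev2 <- evaluate_genotypes(decision_matrix(X2))
  expect_equal(ev1$weights$entropy$weight, ev2$weights$entropy$weight)
  expect_equal(ev1$rankings$entropy$ci, ev2$rankings$entropy$ci)
})

test_that("decision matrices built from trait tables use genotype means", {
  tt <- generate_trait_tables(trait_gen_config(replicates = 2, seed = 19))
  dm <- decision_matrix_from_traits(tt, c("H", "LA", "Fv/Fm"))
  expect_identical(dim(dm), c(17L, 3L))
  gm <- genotype_means(tt, "H", "October")
  expect_equal(unname(dm[gm$genotype, "H"]), gm$mean)
  gl <- genotype_means(tt, "LA")  # single-campaign trait keeps its month
  expect_equal(unname(dm[gl$genotype, "LA"]), gl$mean)
})
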