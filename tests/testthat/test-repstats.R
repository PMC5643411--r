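test_that("size spectrum reports clonotype proportions", {
  sp <- size_spectrum(c(1, 1, 1, 2))
  expect_equal(sp$abundance, c(1L, 2L))
  expect_equal(sp$proportion, c(0.75, 0.25))
  expect_equal(size_spectrum(rep(1, 10))$proportion, 1)
  sp2 <- size_spectrum(c(rep(1, 95), rep(2, 4), 10))
  expect_equal(sp2[abundance == 1, proportion], 0.95)
  expect_equal(sum(sp2$proportion), 1)
  expect_error(size_spectrum(integer()), "empty")
})

test_that("diversity indices match closed forms, hand values and oracles", {
  expect_equal(gini_index(c(5, 5, 5, 5)), 0)
  expect_equal(gini_index(c(1, 1, 1, 97)), 0.72)
  expect_equal(shannon_entropy(rep(7, 4)), log(4))
  expect_equal(shannon_entropy(42), 0)
  expect_equal(shannon_entropy(c(1, 1, 2)), 1.0397, tolerance = 1e-4)
  expect_equal(shannon_entropy(c(1, 1, 2), base = "bits"),
               1.0397 / log(2), tolerance = 1e-4)
  expect_equal(inverse_simpson(rep(3, 6)), 6)
  expect_equal(inverse_simpson(10), 1)
  expect_equal(inverse_simpson(c(1, 1, 2)), 8 / 3)
  set.seed(1)
  for (i in 1:5) {
    x <- sample(1:50, 8, replace = TRUE)
    expect_equal(gini_index(x), oracle_gini(x))
    # permutation invariance
    expect_equal(gini_index(sample(x)), gini_index(x))
  }
  expect_error(gini_index(numeric()), "empty")
})

test_that("diversity indices agree with vegan and respect the uniform
           extremum", {
  skip_if_not_installed("vegan")
  set.seed(2)
  for (i in 1:5) {
    x <- sample(1:100, 12, replace = TRUE)
    expect_equal(shannon_entropy(x),
                 unname(vegan::diversity(x, index = "shannon")))
    expect_equal(inverse_simpson(x),
                 unname(vegan::diversity(x, index = "invsimpson")))
  }
  # for fixed clone count the uniform repertoire minimises Gini and
  # maximises Shannon / inverse Simpson
  uni <- rep(10, 20)
  for (i in 1:10) {
    pert <- uni + sample(c(-3, 0, 3), 20, replace = TRUE)
    pert <- pmax(pert, 1)
    if (all(pert == pert[1])) next
    expect_gt(gini_index(pert), gini_index(uni))
    expect_lt(shannon_entropy(pert), shannon_entropy(uni))
    expect_lt(inverse_simpson(pert), inverse_simpson(uni))
  }
})

test_that("power-law fits match the hand-evaluated closed form and flag
           degenerate tails", {
  # shifted-Hill closed form, evaluated by hand on {1,1,1,1,2}
  fit <- fit_power_law(c(1, 1, 1, 1, 2), x_min = 1, method = "hill")
  expect_equal(fit$exponent, 1 + 5 / (4 * log(2) + log(4)),
               tolerance = 1e-12)
  expect_equal(fit$n_tail, 5L)
  expect_true(fit$ks_distance >= 0 && fit$ks_distance <= 1)
  # exact MLE solves the zeta score equation: E[log X] at the optimum
  # equals the observed mean log
  ml <- fit_power_law(c(1, 1, 1, 1, 2), x_min = 1)
  b <- ml$exponent
  eps <- 1e-5
  dlogz <- (log(umitcr:::hurwitz_zeta(b + eps, 1)) -
              log(umitcr:::hurwitz_zeta(b - eps, 1))) / (2 * eps)
  expect_equal(-dlogz, log(2) / 5, tolerance = 1e-4)
  expect_error(fit_power_law(c(5), x_min = 5), "degenerate")
  expect_error(fit_power_law(numeric()), "empty")
  expect_error(fit_power_law(c(0, 1)), ">= 1")
})

test_that("the exact MLE recovers sampler exponents where the closed form
           is biased (seeded, reduced n)", {
  set.seed(97)
  for (b in c(2, 3)) {
    x <- rpowerlaw(2e4, b, 1L, 1e6L)
    fit <- fit_power_law(x, x_min = 1)
    expect_lt(abs(fit$exponent - b), 0.1)
    # the closed form is only reliable away from x_min = 1
    hill6 <- fit_power_law(x[x >= 2], x_min = 6, method = "hill")
    expect_lt(abs(hill6$exponent - b), 0.35)
  }
  # automatic x_min selection lands near the true cutoff when the body is
  # contaminated below it
  x <- c(rpowerlaw(2e4, 2.5, 3L, 1e6L), rep(1L, 500), rep(2L, 300))
  fit_auto <- fit_power_law(x)
  expect_lte(abs(fit_auto$x_min - 3), 1)
  expect_lt(abs(fit_auto$exponent - 2.5), 0.15)
})

test_that("subsampling preserves molecule counts and expected shares", {
  sizes <- c(60, 40)
  sub <- subsample_repertoire(sizes, 50, seed = 1)
  expect_equal(sum(sub), 50)
  expect_error(subsample_repertoire(sizes, 101), "cannot subsample")
  expect_equal(sum(subsample_repertoire(sizes, 100, seed = 2)), 100)
  expect_equal(length(subsample_repertoire(c(5, 5), 1, seed = 3)), 1L)
  # mean share of clone 1 across repeated draws ~ hypergeometric mean
  set.seed(4)
  shares <- replicate(300, {
    s <- subsample_repertoire(c(50, 50), 100 / 2)
    s[1] / sum(s)
  })
  expect_equal(mean(shares), 0.5, tolerance = 0.02)
})

test_that("overlap removal and annotated-CDR3 search behave set-wise", {
  naive <- data.table(v_index = c(0L, 1L), j_index = 0L, v_deletions = 0L,
                      j_deletions = 0L, insert = c("A", "C"),
                      abundance = c(5L, 1L))
  mem1 <- naive[1L]
  expect_equal(nrow(remove_shared(naive, list(mem1))), 1L)
  expect_equal(remove_shared(naive, list(mem1))$abundance, 1L)
  expect_equal(nrow(remove_shared(naive, list(naive))), 0L)
  disjoint <- copy(naive)[, insert := c("G", "T")]
  expect_equal(nrow(remove_shared(naive, list(disjoint))), 2L)

  reps <- list(
    s1 = data.table(cdr3_aa = c("CASSF", "CATTF", "CASSF"),
                    frequency = c(1L, 4L, 1L)),
    s2 = data.table(cdr3_aa = "CAGGF", frequency = 7L)
  )
  m <- search_annotated_cdr3(reps, c("CASSF", "CAGGF", "CXXXF"))
  expect_equal(m["CASSF", "s1"], 2)
  expect_equal(m["CAGGF", "s2"], 7)
  expect_equal(unname(m["CXXXF", ]), c(0, 0))
  # brute-force scan oracle on the full matrix
  for (q in rownames(m)) for (s in colnames(m)) {
    tab <- reps[[s]]
    expect_equal(m[q, s], sum(tab$frequency[tab$cdr3_aa == q]))
  }
  top <- search_annotated_cdr3(reps, c("CASSF", "CAGGF", "CXXXF"),
                               top_k = 1)
  expect_equal(rownames(top), "CAGGF")
})
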