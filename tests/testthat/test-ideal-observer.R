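test_that("posterior predictive has the conjugate closed form", {
  expect_equal(
    unname(posterior_predictive(mdm_state(c("present", "absent")))),
    c(0.5, 0.5)
  )
  expect_equal(
    unname(posterior_predictive(mdm_state(c("A", "B", "C")))),
    rep(1 / 3, 3)
  )
  s <- mdm_state(c("A", "B"), counts = c(A = 4, B = 0))
  expect_equal(unname(posterior_predictive(s)), c(5 / 6, 1 / 6))
  expect_equal(sum(posterior_predictive(s)), 1)
})

test_that("surprisal is the negative log predictive probability", {
  s <- mdm_state(c("A", "B"), counts = c(A = 4, B = 0))
  expect_equal(surprisal(s, "A"), -log2(5 / 6))
  expect_equal(surprisal(s, "B"), log2(6))
  expect_equal(surprisal(mdm_state(c("A", "B")), "A"), 1)
  expect_equal(surprisal(s, "B", log_base = exp(1)), log(6))
  expect_error(surprisal(s, "Z"), "alphabet")
})

test_that("updates count events and commute with batch counting", {
  s <- mdm_state(c("A", "B"))
  s <- mdm_update(s, "A")
  expect_equal(s$counts, c(A = 1, B = 0))
  for (i in 1:3) s <- mdm_update(s, "A")
  expect_equal(s$counts, c(A = 4, B = 0))
  expect_gt(posterior_predictive(s)[["A"]], 0.8)
  # exchangeability: sequential updates equal direct count construction
  expect_equal(
    posterior_predictive(s),
    posterior_predictive(mdm_state(c("A", "B"), counts = c(A = 4, B = 0)))
  )
  expect_error(mdm_update(s, "Z"), "alphabet")
})

test_that("posterior entropy matches the Dirichlet closed form and an MC oracle", {
  expect_equal(posterior_entropy(mdm_state(c("A", "B"))), 0)
  s21 <- mdm_state(c("A", "B"), counts = c(A = 1, B = 0))
  expect_equal(posterior_entropy(s21), log(1 / 2) + digamma(3) - digamma(2))
  expect_lt(abs(posterior_entropy(s21) - (-0.1931)), 1e-4)

  # Monte-Carlo differential entropy of Beta(2,1): -E[log f(theta)]
  withr::with_seed(99, {
    th <- stats::rbeta(2e5, 2, 1)
    mc <- -mean(log(stats::dbeta(th, 2, 1)))
  })
  expect_lt(abs(posterior_entropy(s21) - mc), 0.005)

  # uncertainty shrinks monotonically along an all-A stream
  s <- mdm_state(c("A", "B"))
  ent <- numeric(30)
  for (i in 1:30) {
    s <- mdm_update(s, "A")
    ent[i] <- posterior_entropy(s)
  }
  expect_true(all(diff(c(0, ent)) < 0))
})

test_that("sequence traces follow predict-then-update scoring", {
  tr <- sequence_complexity(rep("A", 5), alphabet = c("A", "B"))
  expect_equal(tr$surprisal_bits,
               -log2(c(1 / 2, 2 / 3, 3 / 4, 4 / 5, 5 / 6)))
  expect_true(all(diff(tr$surprisal_bits) < 0))
  expect_equal(tr$surprisal_bits, -log2(tr$predictive_prob))

  tr2 <- sequence_complexity(c("1", "1", "0"), alphabet = c("0", "1"))
  expect_equal(tr2$surprisal_bits[3], 2)

  tr3 <- sequence_complexity("A", alphabet = c("A", "B"))
  expect_equal(tr3$surprisal_bits, 1)

  expect_error(sequence_complexity(character(0), alphabet = c("A", "B")),
               "at least one")
  expect_error(sequence_complexity(c("A", "Z"), alphabet = c("A", "B")),
               "alphabet")
})

test_that("transitional scoring conditions on the preceding event", {
  ev <- c("A", "B", "A", "B", "A")
  tr <- sequence_complexity(ev, alphabet = c("A", "B"), mode = "transitional")
  # first event scored by the prior-only marginal model
  expect_equal(tr$surprisal_bits[1], 1)
  # after A->B observed once, the A row predicts B with (1+1)/(1+2)
  expect_equal(tr$predictive_prob[4], 2 / 3)
  # alternation becomes increasingly predictable; repetition would not
  expect_lt(tr$surprisal_bits[5], 1)

  # a conditioning-blind transitional model reduces exactly to the marginal
  ev2 <- c("A", "B", "B", "A", "C", "B", "A", "A")
  m <- sequence_complexity(ev2, alphabet = c("A", "B", "C"))
  t_shared <- sequence_complexity(ev2, alphabet = c("A", "B", "C"),
                                  mode = "transitional",
                                  .collapse_transitions = TRUE)
  expect_equal(t_shared$surprisal_bits, m$surprisal_bits)
})

test_that("surprisal is equivariant under symbol relabeling", {
  withr::with_seed(11, {
    for (rep in 1:5) {
      ev <- sample(c("A", "B", "C"), 20, replace = TRUE)
      perm <- setNames(sample(c("X", "Y", "Z")), c("A", "B", "C"))
      for (mode in c("marginal", "transitional")) {
        a <- sequence_complexity(ev, alphabet = c("A", "B", "C"), mode = mode)
        b <- sequence_complexity(unname(perm[ev]), alphabet = sort(unname(perm)),
                                 mode = mode)
        expect_equal(a$surprisal_bits, b$surprisal_bits)
        expect_equal(a$posterior_entropy, b$posterior_entropy)
      }
    }
  })
})

test_that("predictive probabilities are a proper distribution on random states", {
  withr::with_seed(13, {
    for (rep in 1:20) {
      k <- sample(2:5, 1)
      st <- mdm_state(letters[1:k], alpha = runif(1, 0.2, 3),
                      counts = setNames(rpois(k, 4), letters[1:k]))
      p <- posterior_predictive(st)
      expect_equal(sum(p), 1, tolerance = 1e-12)
      expect_true(all(p > 0 & p < 1))
    }
  })
})

test_that("session traces cover every trial at full length", {
  design <- toy_exp2_design()
  tr <- session_complexity(design)
  expect_identical(nrow(tr), 18L)
  expect_identical(unique(tr$trial_id), 1:3)
  # all-A trial: monotone decreasing surprisal under K = 3
  aa <- tr[tr$trial_id == 1, ]
  expect_equal(aa$surprisal_bits[1], log2(3))
  expect_true(all(diff(aa$surprisal_bits) < 0))
})
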