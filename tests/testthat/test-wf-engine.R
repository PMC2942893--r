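test_that("population construction enforces the two-sex invariants", {
  pop <- pop_state(c(10, 10, 5), c(8, 12, 5))
  expect_s3_class(pop, "pop_state")
  expect_identical(pop$size, 50L)
  expect_equal(allele_freq(pop), (2 * 18 + 22) / 100)

  expect_error(pop_state(c(10, 0, 0), c(5, 0, 0)), "equally many")
  expect_error(pop_state(c(-1, 11, 0), c(5, 5, 0)), "non-negative")
  expect_error(init_population(51, 0.5), "even")
  expect_error(init_population(0, 0.5), "even")
  expect_error(init_population(50, 1.2), "\\[0, 1\\]")
})

test_that("initialisation gives half males, half females, and respects degenerate frequencies", {
  set.seed(11)
  pop <- init_population(50, 0.37)
  expect_identical(sum(pop$male), 25L)
  expect_identical(sum(pop$female), 25L)

  fixed <- init_population(50, 1.0)
  expect_identical(unname(fixed$male), c(25L, 0L, 0L))
  expect_equal(allele_freq(fixed), 1.0)
  lost <- init_population(50, 0.0)
  expect_equal(allele_freq(lost), 0.0)
})

test_that("initial genotypes follow Hardy-Weinberg sampling at the given frequency", {
  # binomial oracle: 2*size allele copies i.i.d. Bernoulli(p), genotype
  # classes multinomial (p^2, 2pq, q^2)
  for (seed in 1:3) {
    set.seed(seed)
    pop <- init_population(10000, 0.3)
    se_p <- sqrt(0.3 * 0.7 / 20000)
    expect_lt(abs(allele_freq(pop) - 0.3), 4 * se_p)
    props <- (pop$male + pop$female) / 10000
    hw <- c(0.09, 0.42, 0.49)
    se_g <- sqrt(hw * (1 - hw) / 10000)
    expect_true(all(abs(props - hw) < 5 * se_g))
  }
})

test_that("initial frequency draws are uniform on the open interval and reproducible", {
  set.seed(99)
  u1 <- draw_initial_frequency()
  set.seed(99)
  u2 <- draw_initial_frequency()
  expect_identical(u1, u2)
  expect_gt(u1, 0)
  expect_lt(u1, 1)

  set.seed(5)
  u <- replicate(10000, draw_initial_frequency())
  expect_lt(abs(mean(u) - 0.5), 4 * sqrt(1 / 12 / 10000))
  expect_gt(stats::ks.test(u, "punif")$p.value, 0.01)
})

test_that("selection scheme follows the additive no-dominance convention", {
  expect_equal(unname(selection_scheme(0.5)$fitness), c(1.5, 1.25, 1))
  expect_equal(unname(selection_scheme(0)$fitness), c(1, 1, 1))
  expect_error(selection_scheme(-0.1), "non-negative")
})

test_that("neutral reproduction is a martingale with Wright-Fisher variance", {
  for (n in c(50, 500)) {
    parent <- exact_freq_population(n, 6 * n / 50, 13 * n / 50)  # p = 0.5
    p0 <- allele_freq(parent)
    set.seed(101)
    p1 <- replicate(10000, allele_freq(next_generation(parent)))
    expect_lt(abs(mean(p1) - p0), 4 * sqrt(p0 * (1 - p0) / (2 * n) / 10000))
    expect_lt(abs(var(p1) / (p0 * (1 - p0) / (2 * n)) - 1), 0.10)
  }
})

test_that("selection matches the deterministic viability recursion in one generation", {
  # parents at exact Hardy-Weinberg proportions for p = 0.4, n = 10000
  parent <- pop_state(c(800, 2400, 1800), c(800, 2400, 1800))
  expect_equal(allele_freq(parent), 0.4)
  p_exp <- deterministic_selection_recursion(0.4, s = 0.5)
  set.seed(42)
  p1 <- replicate(200, allele_freq(next_generation(parent, 10000,
                                                   selection_scheme(0.5))))
  se <- sqrt(p_exp * (1 - p_exp) / 20000) / sqrt(200)
  expect_lt(abs(mean(p1) - p_exp), 4 * se)
})

test_that("mean frequency change under selection is positive at interior frequencies", {
  set.seed(7)
  for (counts in list(c(0, 5), c(6, 13), c(21, 3))) {  # p = 0.1, 0.5, 0.9
    parent <- exact_freq_population(50, counts[1], counts[2])
    p0 <- allele_freq(parent)
    dp <- replicate(10000, allele_freq(next_generation(parent, scheme = selection_scheme(0.25)))) - p0
    expect_gt(mean(dp), 0)
  }
})

test_that("fixation is absorbing and a zero-generation evolve is the identity", {
  fixed <- pop_state(c(25, 0, 0), c(25, 0, 0))
  set.seed(3)
  out <- evolve(fixed, 5, selection_scheme(2))
  expect_identical(out$male, fixed$male)
  expect_identical(out$female, fixed$female)

  pop <- init_population(50, 0.5)
  expect_identical(evolve(pop, 0), pop)
  expect_error(evolve(pop, -1), "non-negative")

  lost <- pop_state(c(0, 0, 25), c(0, 0, 25))
  expect_equal(allele_freq(evolve(lost, 3)), 0)
})

test_that("expected heterozygosity decays by (1 - 1/(2Ne)) per generation", {
  parent <- exact_freq_population(50, 6, 13)  # p = 0.5 exactly
  expected <- 0.5 * (1 - 1 / 100)^10
  set.seed(202)
  h10 <- replicate(2000, {
    p <- allele_freq(evolve(parent, 10))
    2 * p * (1 - p)
  })
  se <- sd(h10) / sqrt(2000)
  expect_lt(abs(mean(h10) - expected), 4 * se)
})

test_that("very strong selection drives the favored allele to fixation", {
  # near-deterministic limit: the unfavored allele is sheltered in
  # heterozygotes, so its gamete frequency falls by at most the factor
  # (1 + s/2)/(1 + s) -> 1/2 per generation; from p = 0.5 at Ne = 50 about
  # 20 generations are needed before the residual expected copy number
  # (100 * 0.5 * 0.545^t at s = 10) makes fixation a >= 99% event
  parent <- exact_freq_population(50, 6, 13)
  set.seed(77)
  fixed <- replicate(300, allele_freq(evolve(parent, 20, selection_scheme(10))) == 1)
  expect_gte(mean(fixed), 0.99)
})

test_that("a large population under selection tracks the deterministic trajectory", {
  n <- 10000
  pop <- pop_state(c(1250, 2500, 1250), c(1250, 2500, 1250))  # HW at p = 0.5
  p_det <- 0.5
  drift_var <- 0
  set.seed(55)
  for (g in 1:10) {
    pop <- next_generation(pop, scheme = selection_scheme(0.3))
    p_det <- deterministic_selection_recursion(p_det, 0.3)
    drift_var <- drift_var + p_det * (1 - p_det) / (2 * n)
    expect_lt(abs(allele_freq(pop) - p_det), 4 * sqrt(drift_var))
  }
})

test_that("expansion is one neutral generation that cannot shrink the census", {
  pop <- exact_freq_population(50, 6, 13)
  expect_error(expand_population(pop, 48), "at least")
  expect_error(expand_population(pop, 501), "even")

  set.seed(8)
  big <- expand_population(pop, 500)
  expect_identical(big$size, 500L)

  fixed <- pop_state(c(25, 0, 0), c(25, 0, 0))
  expect_equal(allele_freq(expand_population(fixed, 500)), 1)

  set.seed(9)
  p_exp <- replicate(5000, allele_freq(expand_population(pop, 500)))
  expect_lt(abs(mean(p_exp) - 0.5), 4 * sqrt(0.5 * 0.5 / 1000 / 5000))
})

test_that("identical seeds give bit-identical trajectories", {
  run <- function() {
    set.seed(123)
    pop <- init_population(50, draw_initial_frequency())
    lapply(1:5, function(g) pop <<- next_generation(pop, scheme = selection_scheme(0.2)))
    pop
  }
  expect_identical(run(), run())
})
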