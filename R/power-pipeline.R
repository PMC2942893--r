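# Orchestration of the two power-analysis designs: neutral burn-in to the
# target initial F_ST, generation of null and alternative theta
# distributions over independent iterations, and empirical-percentile power.

#' Simulation scenario
#'
#' Bundles the parameters of one power analysis. The defaults describe the
#' base case of a set of parallel aquaculture breeding programs: 10 closed
#' farmed populations of effective size 50, 10 generations of selection,
#' initial differentiation F_ST = 0.05 among founder populations, and (for
#' the high-F(ST) design) wild reference populations expanded to census 500
#' so that drift is concentrated in the small farmed strains.
#'
#' @param ne Per-population effective size, simulated literally as the census
#'   size with an equal sex ratio; positive even integer.
#' @param n_pop Number of farmed populations (the high-F(ST) design simulates
#'   `2 * n_pop` populations, half of them wild).
#' @param n_gen Generations of selection after the burn-in.
#' @param fst0 Target initial F(ST) among populations, in `[0, 1)`.
#' @param s Selection coefficient applied in the farmed populations under the
#'   alternative hypothesis (see [selection_scheme()]).
#' @param wild_size Census size wild populations are expanded to at the
#'   farmed/wild split; positive even integer, at least `ne`.
#' @param approach `"low_fst"` (scan among farmed strains for deficient
#'   differentiation) or `"high_fst"` (scan between pooled farmed and pooled
#'   wild metapopulations for excess differentiation).
#' @param n_iter Number of Monte Carlo iterations per hypothesis arm.
#' @param burnin_cap Maximum number of burn-in generations before the
#'   iteration is restarted with a fresh initial frequency.
#' @return An object of class `sim_scenario`.
#' @examples
#' sim_scenario(s = 0.25, approach = "high_fst", n_iter = 100)
#' @export
sim_scenario <- function(ne = 50, n_pop = 10, n_gen = 10, fst0 = 0.05,
                         s = 0, wild_size = 500,
                         approach = c("low_fst", "high_fst"),
                         n_iter = 1000, burnin_cap = 500) {
  approach <- match.arg(approach)
  check_even_size(ne, "`ne`")
  check_even_size(wild_size, "`wild_size`")
  stopifnot(
    "`n_pop` must be a positive integer" =
      is.numeric(n_pop) && n_pop >= 1 && n_pop == round(n_pop),
    "`n_gen` must be a non-negative integer" =
      is.numeric(n_gen) && n_gen >= 0 && n_gen == round(n_gen),
    "`fst0` must lie in [0, 1)" = is.numeric(fst0) && fst0 >= 0 && fst0 < 1,
    "`s` must be non-negative" = is.numeric(s) && s >= 0,
    "`n_iter` must be at least 2" =
      is.numeric(n_iter) && n_iter >= 2 && n_iter == round(n_iter),
    "`burnin_cap` must be a positive integer" =
      is.numeric(burnin_cap) && burnin_cap >= 1,
    "`wild_size` must be at least `ne`" = wild_size >= ne
  )
  if (approach == "low_fst" && n_pop < 2) {
    stop("the low-F(ST) design needs at least two farmed populations",
         call. = FALSE)
  }
  structure(
    list(ne = as.integer(ne), n_pop = as.integer(n_pop),
         n_gen = as.integer(n_gen), fst0 = fst0, s = s,
         wild_size = as.integer(wild_size), approach = approach,
         n_iter = as.integer(n_iter), burnin_cap = as.integer(burnin_cap)),
    class = "sim_scenario"
  )
}

#' @export
print.sim_scenario <- function(x, ...) {
  cat("<sim_scenario> approach =", x$approach, "\n")
  cat(sprintf("  ne = %d, n_pop = %d, n_gen = %d, fst0 = %g, s = %g\n",
              x$ne, x$n_pop, x$n_gen, x$fst0, x$s))
  cat(sprintf("  wild_size = %d, n_iter = %d, burnin_cap = %d\n",
              x$wild_size, x$n_iter, x$burnin_cap))
  invisible(x)
}

# Deterministic per-iteration seed derived from the master seed, keyed by
# (hypothesis, iteration index) so that iterations are reproducible
# individually and adding iterations never perturbs earlier ones. All
# arithmetic stays well below 2^53, the result below 2^31.
iteration_seed <- function(master_seed, selected, index) {
  m <- as.double(master_seed) %% 65521
  as.integer((m * 32452843 + as.double(index) * 104729 +
                as.double(selected) * 15485863) %% 2147483629) + 1L
}

#' Neutral burn-in: drift a set of populations to a target F(ST)
#'
#' All populations are founded from the same overall allele frequency `p0`
#' (independent Hardy-Weinberg draws) and then evolve neutrally and
#' synchronously, one generation at a time, until the multi-population
#' Weir-Cockerham theta first reaches `fst0`. This emulates the divergence
#' accumulated among founder river populations before breeding programs (or
#' the farmed/wild contrast) begin. `fst0 = 0` stops immediately at
#' generation 0.
#'
#' @param n_populations Number of populations to drift jointly (at least 2).
#' @param ne Size of each population; positive even integer.
#' @param fst0 Target F(ST) in `[0, 1)`.
#' @param p0 Founding allele frequency shared by all populations.
#' @param burnin_cap Maximum generations before giving up.
#' @return On success, a list with `pops` (list of [pop_state()]),
#'   `generations` (stopping time) and `theta` (the achieved value, `>=
#'   fst0`). On failure — cap exceeded, or the locus monomorphic for the same
#'   allele in every population so that theta can never reach the target —
#'   returns `NULL`, signalling the caller to redraw `p0`.
#' @export
drift_to_initial_fst <- function(n_populations, ne, fst0, p0,
                                 burnin_cap = 500) {
  if (n_populations < 2) {
    stop("burn-in needs at least two populations", call. = FALSE)
  }
  pops <- replicate(n_populations, init_population(ne, p0), simplify = FALSE)
  gen <- 0L
  repeat {
    th <- weir_cockerham_theta(lapply(pops, summarize_population))
    if (fst0 <= 0 || (th$defined && th$theta >= fst0)) {
      return(list(pops = pops, generations = gen,
                  theta = if (th$defined) th$theta else 0))
    }
    if (!th$defined || gen >= burnin_cap) {
      # all populations fixed for the same allele (theta frozen undefined),
      # or the cap was hit: this founding frequency cannot deliver fst0
      return(NULL)
    }
    pops <- lapply(pops, next_generation)
    gen <- gen + 1L
  }
}

# Shared restart loop: `body(p0)` returns a theta value or NULL to request a
# fresh founding frequency (burn-in failure or a monomorphic final sample).
with_restarts <- function(body, max_restarts = 100L) {
  restarts <- 0L
  repeat {
    theta <- body(draw_initial_frequency())
    if (!is.null(theta)) {
      return(list(theta = theta, restarts = restarts))
    }
    restarts <- restarts + 1L
    if (restarts > max_restarts) {
      stop("more than ", max_restarts, " restarts in one iteration; ",
           "the scenario is pathological (burn-in target unreachable)",
           call. = FALSE)
    }
  }
}

#' One iteration of the low-F(ST) design
#'
#' Draws a founding frequency, burns `n_pop` farmed populations in to
#' `fst0`, evolves each for `n_gen` generations with selection coefficient
#' `s` (`selected = TRUE`) or neutrally (`FALSE`), and returns the final
#' multi-population Weir-Cockerham theta. Iterations whose final locus is
#' monomorphic across all populations (theta undefined — such a locus is
#' unobservable as a marker) are discarded and rerun with a fresh founding
#' frequency; the restart count is reported.
#'
#' @param scn A [sim_scenario()] with `approach = "low_fst"`.
#' @param selected Logical: apply selection in the farmed populations?
#' @return A list with `theta` and `restarts`.
#' @export
run_iteration_low <- function(scn, selected) {
  scheme <- selection_scheme(if (selected) scn$s else 0)
  with_restarts(function(p0) {
    burn <- drift_to_initial_fst(scn$n_pop, scn$ne, scn$fst0, p0,
                                 scn$burnin_cap)
    if (is.null(burn)) return(NULL)
    pops <- lapply(burn$pops, evolve, n_gen = scn$n_gen, scheme = scheme)
    th <- weir_cockerham_theta(lapply(pops, summarize_population))
    if (th$defined) th$theta else NULL
  })
}

#' One iteration of the high-F(ST) design
#'
#' Burns `2 * n_pop` populations in jointly to `fst0`, designates the first
#' half as farmed and the second half as wild (the populations are
#' exchangeable at the split, so the rule is immaterial). Farmed populations
#' evolve `n_gen` generations with selection coefficient `s`
#' (`selected = TRUE`) or neutrally; wild populations are first expanded to
#' `wild_size` by one neutral generation and then evolve neutrally for
#' `n_gen` generations. Both sets are pooled into one farmed and one wild
#' metapopulation sample and the two-group theta is returned. Monomorphic
#' outcomes restart as in [run_iteration_low()].
#'
#' @param scn A [sim_scenario()] with `approach = "high_fst"`.
#' @param selected Logical: apply selection in the farmed populations?
#' @return A list with `theta` and `restarts`.
#' @export
run_iteration_high <- function(scn, selected) {
  scheme <- selection_scheme(if (selected) scn$s else 0)
  with_restarts(function(p0) {
    burn <- drift_to_initial_fst(2L * scn$n_pop, scn$ne, scn$fst0, p0,
                                 scn$burnin_cap)
    if (is.null(burn)) return(NULL)
    farmed <- lapply(burn$pops[seq_len(scn$n_pop)],
                     evolve, n_gen = scn$n_gen, scheme = scheme)
    wild <- lapply(burn$pops[scn$n_pop + seq_len(scn$n_pop)], function(pop) {
      evolve(expand_population(pop, scn$wild_size), n_gen = scn$n_gen)
    })
    th <- weir_cockerham_theta(merge_samples(farmed, wild))
    if (th$defined) th$theta else NULL
  })
}

#' Simulate the null and alternative F(ST) distributions
#'
#' Runs `n_iter` independent iterations without selection (null hypothesis)
#' and `n_iter` with selection (alternative), each iteration on its own
#' deterministic RNG substream derived from `seed` and keyed by
#' (hypothesis, iteration index), so runs are exactly reproducible and the
#' two arms are independent (no common-random-number pairing).
#'
#' @param scn A [sim_scenario()].
#' @param seed Master integer seed for the whole computation.
#' @return A list with numeric vectors `null_dist` and `alt_dist` (length
#'   `n_iter` each), integer vectors `restarts_null` and `restarts_alt`
#'   (per-iteration discarded restarts), and totals `n_discarded_null`,
#'   `n_discarded_alt`.
#' @export
build_distributions <- function(scn, seed) {
  run_one <- switch(scn$approach,
                    low_fst = run_iteration_low,
                    high_fst = run_iteration_high)
  arm <- function(selected) {
    theta <- numeric(scn$n_iter)
    restarts <- integer(scn$n_iter)
    for (i in seq_len(scn$n_iter)) {
      set.seed(iteration_seed(seed, selected, i))
      res <- run_one(scn, selected)
      theta[i] <- res$theta
      restarts[i] <- res$restarts
    }
    list(theta = theta, restarts = restarts)
  }
  null <- arm(FALSE)
  alt <- arm(TRUE)
  list(null_dist = null$theta, alt_dist = alt$theta,
       restarts_null = null$restarts, restarts_alt = alt$restarts,
       n_discarded_null = sum(null$restarts),
       n_discarded_alt = sum(alt$restarts))
}

#' Empirical-percentile power from null and alternative distributions
#'
#' The detection threshold is an order statistic of the simulated null
#' distribution: with `n` null values sorted ascending, the low-F(ST) design
#' uses the `ceiling(0.05 n)`-th value (empirical 5th percentile) and counts
#' alternative values strictly below it; the high-F(ST) design uses the
#' `floor(0.95 n)`-th value (empirical 95th percentile) and counts
#' alternative values strictly above it. Power is the counted fraction.
#' Under the null the strict count gives power just below 0.05 by
#' construction (e.g. 49/1000 when all values are distinct).
#'
#' @param null_dist,alt_dist Non-empty numeric vectors of theta values.
#' @param approach `"low_fst"` or `"high_fst"`.
#' @param scenario Optional [sim_scenario()] carried along in the result.
#' @param extra Optional named list (e.g. discard counters) merged into the
#'   result.
#' @return An object of class `power_result`: list with `power`,
#'   `threshold`, `null_dist`, `alt_dist`, `approach`, plus any `extra`
#'   fields and the `scenario`.
#' @examples
#' compute_power(null_dist = seq(0.1, 1, by = 0.1),
#'               alt_dist = rep(0, 5), approach = "low_fst")$power
#' @export
compute_power <- function(null_dist, alt_dist,
                          approach = c("low_fst", "high_fst"),
                          scenario = NULL, extra = list()) {
  approach <- match.arg(approach)
  if (length(null_dist) < 1L || length(alt_dist) < 1L) {
    stop("both distributions must be non-empty", call. = FALSE)
  }
  n <- length(null_dist)
  sorted <- sort(null_dist)
  if (approach == "low_fst") {
    threshold <- sorted[max(1L, ceiling(0.05 * n))]
    power <- mean(alt_dist < threshold)
  } else {
    threshold <- sorted[max(1L, floor(0.95 * n))]
    power <- mean(alt_dist > threshold)
  }
  structure(
    c(list(power = power, threshold = threshold, approach = approach,
           null_dist = null_dist, alt_dist = alt_dist),
      extra, list(scenario = scenario)),
    class = "power_result"
  )
}

#' @export
print.power_result <- function(x, ...) {
  side <- if (x$approach == "low_fst") "below 5th" else "above 95th"
  cat(sprintf(
    "<power_result> %s: power = %.3f (%d of %d alternative theta values %s null percentile %.4f)\n",
    x$approach, x$power, round(x$power * length(x$alt_dist)),
    length(x$alt_dist), side, x$threshold))
  if (!is.null(x$n_discarded_null)) {
    cat(sprintf("  discarded restarts: %d (null), %d (alt)\n",
                x$n_discarded_null, x$n_discarded_alt))
  }
  invisible(x)
}

#' Estimate outlier-scan power for one scenario
#'
#' Convenience wrapper: simulates both hypothesis arms with
#' [build_distributions()] and evaluates [compute_power()].
#'
#' @param scn A [sim_scenario()].
#' @param seed Master integer seed.
#' @return A [compute_power()] result.
#' @examples
#' \donttest{
#' scn <- sim_scenario(s = 0.5, approach = "high_fst", n_iter = 100)
#' estimate_power(scn, seed = 1)
#' }
#' @export
estimate_power <- function(scn, seed) {
  dists <- build_distributions(scn, seed)
  compute_power(dists$null_dist, dists$alt_dist, scn$approach,
                scenario = scn,
                extra = list(restarts_null = dists$restarts_null,
                             restarts_alt = dists$restarts_alt,
                             n_discarded_null = dists$n_discarded_null,
                             n_discarded_alt = dists$n_discarded_alt,
                             seed = seed))
}
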