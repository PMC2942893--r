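# Forward-time Wright-Fisher engine for one bi-allelic diploid locus in a
# two-sex finite population. Genotypes are tracked as counts per sex in the
# fixed order (AA, Aa, aa); allele "A" is the allele favored by selection.

GENOTYPES <- c("AA", "Aa", "aa")

#' Construct a population state
#'
#' A population is a set of diploid individuals typed at one bi-allelic locus,
#' split into equally many males and females. Only genotype counts are kept;
#' individuals of the same sex and genotype are exchangeable.
#'
#' @param male_counts Integer vector of length 3: counts of (AA, Aa, aa) males.
#' @param female_counts Integer vector of length 3: counts of (AA, Aa, aa)
#'   females. Must sum to the same total as `male_counts`.
#' @return An object of class `pop_state` with elements `male`, `female`
#'   (named integer count vectors) and `size` (total number of individuals).
#' @examples
#' pop_state(c(10, 10, 5), c(8, 12, 5))
#' @export
pop_state <- function(male_counts, female_counts) {
  male <- as.integer(male_counts)
  female <- as.integer(female_counts)
  if (length(male) != 3L || length(female) != 3L) {
    stop("genotype counts must have length 3 (AA, Aa, aa)", call. = FALSE)
  }
  if (any(is.na(male)) || any(is.na(female)) || any(male < 0L) || any(female < 0L)) {
    stop("genotype counts must be non-negative integers", call. = FALSE)
  }
  if (sum(male) != sum(female)) {
    stop("males and females must be equally many (equal sex ratio)", call. = FALSE)
  }
  names(male) <- names(female) <- GENOTYPES
  structure(
    list(male = male, female = female, size = sum(male) + sum(female)),
    class = "pop_state"
  )
}

#' @export
print.pop_state <- function(x, ...) {
  cat("<pop_state> ", x$size, " individuals, p(A) = ",
      format(allele_freq(x), digits = 4), "\n", sep = "")
  print(rbind(male = x$male, female = x$female))
  invisible(x)
}

#' Allele-A frequency of a population
#'
#' @param pop A [pop_state()].
#' @return Frequency of allele A in `[0, 1]`.
#' @export
allele_freq <- function(pop) {
  counts <- pop$male + pop$female
  (2 * counts[[1]] + counts[[2]]) / (2 * pop$size)
}

#' Additive (no-dominance) selection scheme
#'
#' Maps a selection coefficient `s` to genotype fitness values under the
#' standard no-dominance convention (heterozygote exactly intermediate,
#' h = 1/2): w(AA) = 1 + s, w(Aa) = 1 + s/2, w(aa) = 1. Allele A is favored
#' in every selected population, modelling parallel breeding programs that
#' share the same breeding goal. `s = 0` gives neutrality.
#'
#' @param s Selection coefficient, a non-negative real: the fitness advantage
#'   of the favored homozygote over the unfavored homozygote.
#' @return An object of class `selection_scheme` with elements `s` and
#'   `fitness` (named numeric vector over AA, Aa, aa).
#' @examples
#' selection_scheme(0.25)$fitness
#' @export
selection_scheme <- function(s) {
  if (!is.numeric(s) || length(s) != 1L || is.na(s) || s < 0) {
    stop("selection coefficient `s` must be a single non-negative number",
         call. = FALSE)
  }
  fitness <- c(AA = 1 + s, Aa = 1 + s / 2, aa = 1)
  structure(list(s = s, fitness = fitness), class = "selection_scheme")
}

#' Initialise a population at Hardy-Weinberg proportions
#'
#' Each individual's two allele copies are independent Bernoulli(p) draws,
#' i.e. genotypes are multinomial with Hardy-Weinberg class probabilities
#' (p^2, 2p(1-p), (1-p)^2), sampled independently within each sex. Half the
#' individuals are males, half females.
#'
#' @param size Total population size; a positive even integer.
#' @param p Allele-A frequency in `[0, 1]` from which genotypes are drawn.
#' @return A [pop_state()] of `size` individuals.
#' @examples
#' set.seed(1)
#' init_population(50, 0.3)
#' @export
init_population <- function(size, p) {
  check_even_size(size, "population size")
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1) {
    stop("allele frequency `p` must lie in [0, 1]", call. = FALSE)
  }
  half <- size / 2
  probs <- c(p^2, 2 * p * (1 - p), (1 - p)^2)
  pop_state(
    stats::rmultinom(1L, half, probs)[, 1L],
    stats::rmultinom(1L, half, probs)[, 1L]
  )
}

#' Draw a random initial allele frequency
#'
#' Uniform on (0, 1); exact 0 or 1 (probability-zero events that would make
#' the locus monomorphic, hence not a marker) are redrawn.
#'
#' @return A single frequency strictly between 0 and 1.
#' @export
draw_initial_frequency <- function() {
  repeat {
    u <- stats::runif(1L)
    if (u > 0 && u < 1) return(u)
  }
}

# Frequency of allele A among gametes contributed by one sex class when each
# parent is drawn with probability proportional to its genotype fitness and
# transmits one uniformly chosen allele: AA parents always pass A, Aa parents
# pass A with probability 1/2.
gamete_freq <- function(counts, fitness) {
  w <- counts * fitness
  (w[[1]] + w[[2]] / 2) / sum(w)
}

#' Produce the next generation by random mating with optional selection
#'
#' Each offspring independently receives one father drawn from the males and
#' one mother drawn from the females, each parent chosen with probability
#' proportional to its genotype fitness (uniformly when `s = 0`), with
#' replacement, and inherits one uniformly chosen allele from each parent.
#' There is no mutation and no migration. Because parents are sampled
#' independently with replacement, each offspring's paternal allele is an
#' independent Bernoulli draw with the fitness-weighted male gamete frequency
#' (and likewise maternal), so the per-sex offspring genotype counts are
#' exactly multinomial; that equivalent form is what is sampled.
#'
#' @param pop Parent [pop_state()]; must contain at least one individual of
#'   each sex.
#' @param offspring_size Number of offspring; a positive even integer (half of
#'   each sex). Defaults to the parent population size.
#' @param scheme A [selection_scheme()]; defaults to neutrality.
#' @return The offspring [pop_state()] of `offspring_size` individuals.
#' @examples
#' set.seed(1)
#' pop <- init_population(50, 0.5)
#' next_generation(pop, scheme = selection_scheme(0.25))
#' @export
next_generation <- function(pop, offspring_size = pop$size,
                            scheme = selection_scheme(0)) {
  check_even_size(offspring_size, "offspring size")
  if (sum(pop$male) < 1L || sum(pop$female) < 1L) {
    stop("cannot breed from an empty sex class", call. = FALSE)
  }
  pf <- gamete_freq(pop$male, scheme$fitness)
  pm <- gamete_freq(pop$female, scheme$fitness)
  probs <- c(pf * pm, pf * (1 - pm) + (1 - pf) * pm, (1 - pf) * (1 - pm))
  half <- offspring_size / 2
  pop_state(
    stats::rmultinom(1L, half, probs)[, 1L],
    stats::rmultinom(1L, half, probs)[, 1L]
  )
}

#' Evolve a population for a number of generations
#'
#' Applies [next_generation()] `n_gen` times with a constant offspring size
#' and selection scheme; `n_gen = 0` returns the input unchanged.
#'
#' @inheritParams next_generation
#' @param n_gen Non-negative integer number of generations.
#' @return The [pop_state()] after `n_gen` generations.
#' @export
evolve <- function(pop, n_gen, scheme = selection_scheme(0),
                   offspring_size = pop$size) {
  if (!is.numeric(n_gen) || length(n_gen) != 1L || is.na(n_gen) ||
      n_gen < 0 || n_gen != round(n_gen)) {
    stop("`n_gen` must be a non-negative integer", call. = FALSE)
  }
  for (i in seq_len(n_gen)) {
    pop <- next_generation(pop, offspring_size, scheme)
  }
  pop
}

#' Expand a population by one neutral generation
#'
#' A single round of neutral random mating producing `new_size` offspring
#' from the current parents, modelling an instantaneous census expansion
#' (e.g. wild populations enlarged to damp drift relative to the small
#' farmed strains). Shrinking is not permitted.
#'
#' @param pop Parent [pop_state()].
#' @param new_size Target size; a positive even integer `>= pop$size`.
#' @return A [pop_state()] of `new_size` individuals.
#' @export
expand_population <- function(pop, new_size) {
  check_even_size(new_size, "expanded size")
  if (new_size < pop$size) {
    stop("`new_size` must be at least the current population size",
         call. = FALSE)
  }
  next_generation(pop, offspring_size = new_size)
}

check_even_size <- function(size, what) {
  if (!is.numeric(size) || length(size) != 1L || is.na(size) ||
      size < 2 || size != round(size) || size %% 2 != 0) {
    stop(sprintf("%s must be a positive even integer (half males, half females)",
                 what), call. = FALSE)
  }
  invisible(size)
}
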