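# Weir & Cockerham (1984) theta estimator of F_ST for a single bi-allelic
# locus over r >= 2 population samples, from per-sample summaries
# (n_i, p_i, h_i). Sexes carry no genetic role at the locus and are pooled.

#' Per-population sample summary for F(ST) estimation
#'
#' @param n Diploid sample size (positive integer).
#' @param p Allele-A sample frequency; `p * 2n` must be an integer allele
#'   count.
#' @param h Observed heterozygote proportion; `h * n` must be an integer
#'   count, and the implied counts must be non-negative.
#' @return An object of class `pop_sample`.
#' @export
pop_sample <- function(n, p, h) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1 || n != round(n)) {
    stop("sample size `n` must be a positive integer", call. = FALSE)
  }
  if (p < 0 || p > 1 || h < 0 || h > 1) {
    stop("`p` and `h` must lie in [0, 1]", call. = FALSE)
  }
  if (abs(p * 2 * n - round(p * 2 * n)) > 1e-8 || abs(h * n - round(h * n)) > 1e-8) {
    stop("`p` and `h` must correspond to integer allele/heterozygote counts",
         call. = FALSE)
  }
  structure(list(n = as.integer(n), p = p, h = h), class = "pop_sample")
}

#' Summarise a population as an F(ST) input sample
#'
#' Pools both sexes and reports the diploid size, allele-A frequency and
#' observed heterozygote proportion — the per-population sufficient
#' statistics for the Weir-Cockerham estimator.
#'
#' @param pop A [pop_state()].
#' @return A [pop_sample()].
#' @examples
#' summarize_population(pop_state(c(20, 5, 0), c(10, 10, 5)))
#' @export
summarize_population <- function(pop) {
  counts <- pop$male + pop$female
  n <- pop$size
  pop_sample(n = n, p = (2 * counts[[1]] + counts[[2]]) / (2 * n),
             h = counts[[2]] / n)
}

#' Weir-Cockerham theta for a bi-allelic locus
#'
#' Computes the variance components of Weir & Cockerham (1984) — `a` among
#' populations, `b` among individuals within populations, `c` within
#' individuals — and the estimator theta = a / (a + b + c), from r >= 2
#' sample summaries with (possibly unequal) sizes. The estimator may be
#' negative; negative values are retained because the low-F(ST) outlier scan
#' depends on the null distribution's lower tail. When the locus is
#' monomorphic for the same allele in every sample all three components are
#' zero and theta is undefined (`defined = FALSE`).
#'
#' @param samples A list of [pop_sample()] objects (at least two).
#' @return An object of class `fst_components`: a list with numeric `a`,
#'   `b`, `c`, `theta` and logical `defined`.
#' @examples
#' s1 <- pop_sample(50, 0.75, 0.30)
#' s2 <- pop_sample(50, 0.25, 0.30)
#' weir_cockerham_theta(list(s1, s2))
#' @export
weir_cockerham_theta <- function(samples) {
  if (!is.list(samples) || length(samples) < 2L) {
    stop("theta requires at least two population samples", call. = FALSE)
  }
  r <- length(samples)
  n <- vapply(samples, function(x) as.numeric(x$n), numeric(1))
  p <- vapply(samples, function(x) x$p, numeric(1))
  h <- vapply(samples, function(x) x$h, numeric(1))

  n_tot <- sum(n)
  n_bar <- n_tot / r
  n_c <- (n_tot - sum(n^2) / n_tot) / (r - 1)
  p_bar <- sum(n * p) / n_tot
  s2 <- sum(n * (p - p_bar)^2) / ((r - 1) * n_bar)
  h_bar <- sum(n * h) / n_tot

  a <- (n_bar / n_c) *
    (s2 - (p_bar * (1 - p_bar) - ((r - 1) / r) * s2 - h_bar / 4) / (n_bar - 1))
  b <- (n_bar / (n_bar - 1)) *
    (p_bar * (1 - p_bar) - ((r - 1) / r) * s2 - ((2 * n_bar - 1) / (4 * n_bar)) * h_bar)
  c_ <- h_bar / 2

  denom <- a + b + c_
  defined <- denom != 0
  structure(
    list(a = a, b = b, c = c_,
         theta = if (defined) a / denom else NA_real_,
         defined = defined),
    class = "fst_components"
  )
}

#' @export
print.fst_components <- function(x, ...) {
  if (x$defined) {
    cat("<fst_components> theta =", format(x$theta, digits = 6), "\n")
  } else {
    cat("<fst_components> theta undefined (no variance in any sample)\n")
  }
  cat(sprintf("  a = %.6g, b = %.6g, c = %.6g\n", x$a, x$b, x$c))
  invisible(x)
}

#' Pool two groups of populations into metapopulation samples
#'
#' Sums genotype counts across all populations within each group (e.g. all
#' farmed strains, and all wild populations), producing one pooled sample per
#' group for a two-group theta computation.
#'
#' @param farmed,wild Non-empty lists of [pop_state()] objects.
#' @return A list of two [pop_sample()] objects, in the order given.
#' @export
merge_samples <- function(farmed, wild) {
  pool <- function(group, label) {
    if (!is.list(group) || length(group) < 1L) {
      stop(sprintf("the %s group must contain at least one population", label),
           call. = FALSE)
    }
    counts <- Reduce(`+`, lapply(group, function(pop) pop$male + pop$female))
    n <- sum(counts)
    pop_sample(n = n, p = (2 * counts[[1]] + counts[[2]]) / (2 * n),
               h = counts[[2]] / n)
  }
  list(pool(farmed, "first"), pool(wild, "second"))
}
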