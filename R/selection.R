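#' Genetic-algorithm stimulus-subset selection
#'
#' Searches for a size-`k` subset of conditions that minimizes the absolute
#' Spearman correlation between the two reference RDMs restricted to that
#' subset — the strategy for picking stimuli that elicit decorrelated
#' responses at the entry and endpoint of the ventral visual hierarchy.
#'
#' Individuals are index subsets; selection is by binary tournament on the
#' objective, crossover is uniform on the membership vector with repair back
#' to size `k`, mutation swaps members for non-members, and the single best
#' individual is carried over unchanged each generation (elitism), so the
#' best objective in `history` is non-increasing.
#'
#' @param rdm_a,rdm_b Square dissimilarity matrices over the same K items.
#' @param k Subset size (4 <= k < K).
#' @param population Population size.
#' @param generations Number of generations.
#' @param mutation_rate Per-gene swap probability.
#' @param seed Integer seed.
#' @return Object of class `subset_result`: `indices` (sorted item ids),
#'   `objective` (|Spearman| of the sub-RDMs), `history` (best objective per
#'   generation).
#' @examples
#' set.seed(1)
#' a <- as_rdm(1 - cor(matrix(rnorm(80), 10, 8)))
#' b <- as_rdm(1 - cor(matrix(rnorm(80), 10, 8)))
#' genetic_subset(a, b, k = 4, population = 30, generations = 40, seed = 1)
#' @export
genetic_subset <- function(rdm_a, rdm_b, k, population = 200,
                           generations = 500, mutation_rate = 0.02,
                           seed = 1) {
  rdm_a <- as.matrix(rdm_a); rdm_b <- as.matrix(rdm_b)
  K <- nrow(rdm_a)
  stopifnot(all(dim(rdm_a) == c(K, K)), all(dim(rdm_b) == c(K, K)))
  if (k >= K) stop("k must be smaller than the number of items")
  if (k < 4) stop("k must be >= 4 (need enough pairs to correlate)")
  set.seed(seed)
  objective <- function(idx) {
    sa <- rdm_a[idx, idx]; sb <- rdm_b[idx, idx]
    abs(stats::cor(sa[lower.tri(sa)], sb[lower.tri(sb)], method = "spearman"))
  }
  pop <- replicate(population, sort(sample.int(K, k)), simplify = FALSE)
  fit <- vapply(pop, objective, numeric(1))
  history <- numeric(generations)
  for (gen in seq_len(generations)) {
    best <- which.min(fit)
    newpop <- list(pop[[best]])               # elitism
    while (length(newpop) < population) {
      pick <- function() {
        cand <- sample.int(population, 2, replace = TRUE)
        pop[[cand[which.min(fit[cand])]]]
      }
      p1 <- pick(); p2 <- pick()
      # uniform crossover on membership, repaired to size k
      memb <- logical(K)
      both <- intersect(p1, p2)
      one <- setdiff(union(p1, p2), both)
      memb[both] <- TRUE
      memb[one] <- stats::runif(length(one)) < 0.5
      child <- which(memb)
      if (length(child) > k) child <- sort(sample(child, k))
      while (length(child) < k) {
        child <- sort(c(child, sample(setdiff(seq_len(K), child), 1)))
      }
      # mutation: swap members for non-members
      n_mut <- stats::rbinom(1, k, mutation_rate)
      if (n_mut > 0) {
        out_pool <- setdiff(seq_len(K), child)
        n_mut <- min(n_mut, length(out_pool))
        drop_i <- sample(seq_len(k), n_mut)
        child <- sort(c(child[-drop_i], sample(out_pool, n_mut)))
      }
      newpop[[length(newpop) + 1]] <- child
    }
    pop <- newpop
    fit <- vapply(pop, objective, numeric(1))
    history[gen] <- min(fit)
  }
  best <- which.min(fit)
  structure(list(indices = pop[[best]], objective = fit[best],
                 history = cummin(history)),
            class = "subset_result")
}

#' @export
print.subset_result <- function(x, ...) {
  cat("SubsetResult:", length(x$indices), "items {",
      paste(x$indices, collapse = ", "), "}\n")
  cat("  |Spearman| objective:", signif(x$objective, 4), "after",
      length(x$history), "generations\n")
  invisible(x)
}

#' Best objective among random subsets (baseline for the GA)
#' @inheritParams genetic_subset
#' @param n_draws Number of random subsets to evaluate.
#' @return The minimum |Spearman| objective over the draws.
#' @export
random_subset_baseline <- function(rdm_a, rdm_b, k, n_draws = 200, seed = 1) {
  rdm_a <- as.matrix(rdm_a); rdm_b <- as.matrix(rdm_b)
  K <- nrow(rdm_a)
  set.seed(seed)
  min(replicate(n_draws, {
    idx <- sample.int(K, k)
    sa <- rdm_a[idx, idx]; sb <- rdm_b[idx, idx]
    abs(stats::cor(sa[lower.tri(sa)], sb[lower.tri(sb)], method = "spearman"))
  }))
}
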