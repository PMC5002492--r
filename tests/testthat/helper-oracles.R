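# Independent oracles used across the suite.

# centered log-ratio of one composition
clr <- function(x) log(x) - mean(log(x))

# Aitchison distance computed from clr coordinates (independent of any SBP)
clr_dist <- function(p, q) sqrt(sum((clr(p) - clr(q))^2))

# closed per-part geometric mean of a composition matrix
geomean_comp <- function(m, kappa = 1000) {
  g <- exp(colMeans(log(m)))
  g * kappa / sum(g)
}

# brute-force count of ordered sequences of binary splits resolving D parts
enumerate_sbps <- function(D) {
  split_group <- function(g) {
    # unordered bipartitions into two nonempty subsets: fix the first element
    rest <- g[-1]
    out <- list()
    for (mask in 0:(2^length(rest) - 1)) {
      a <- c(g[1], rest[bitwAnd(mask, 2^(seq_along(rest) - 1)) > 0])
      b <- setdiff(g, a)
      if (length(b) > 0) out[[length(out) + 1]] <- list(a, b)
    }
    out
  }
  count <- function(groups) {
    splittable <- which(lengths(groups) >= 2)
    if (length(splittable) == 0) return(1)
    total <- 0
    for (gi in splittable) {
      for (bp in split_group(groups[[gi]])) {
        total <- total + count(c(groups[-gi], bp))
      }
    }
    total
  }
  count(list(seq_len(D)))
}

# random strictly positive compositions, rows closed to kappa
random_comps <- function(n, D, kappa = 1000, sd = 1) {
  m <- exp(matrix(rnorm(n * D, sd = sd), n, D))
  colnames(m) <- paste0("x", seq_len(D))
  m * kappa / rowSums(m)
}

# a second, different complete SBP over the 8 guava parts (pure left-branching)
sbp_guava_alt <- function() {
  parts <- c("N", "P", "K", "Ca", "Mg", "S", "B", "Fv")
  rows <- t(vapply(1:7, function(j) {
    r <- numeric(8)
    r[seq_len(j)] <- 1
    r[j + 1] <- -1
    r
  }, numeric(8)))
  sbp_table(rows, parts = parts)
}
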