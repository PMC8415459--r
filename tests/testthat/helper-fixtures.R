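# Shared fixtures built in code.

toy_table <- function(seed = 1, n = 6, S = 8, depth = 100) {
  set.seed(seed)
  m <- matrix(rpois(n * S, depth / S), n, S,
              dimnames = list(paste0("s", seq_len(n)),
                              paste0("t", seq_len(S))))
  otu_table(m)
}

# random symmetric distance-like matrix from points in the plane
random_distmat <- function(n, seed, dim = 2) {
  set.seed(seed)
  m <- as.matrix(dist(matrix(rnorm(n * dim), n)))
  dimnames(m) <- list(paste0("s", seq_len(n)), paste0("s", seq_len(n)))
  m
}

# all permutations of 1..n (Heap's algorithm), as a list
all_perms <- function(n) {
  out <- list()
  a <- seq_len(n)
  rec <- function(k) {
    if (k == 1) {
      out[[length(out) + 1]] <<- a
      return(invisible())
    }
    for (i in seq_len(k)) {
      rec(k - 1)
      if (k %% 2 == 0) { tmp <- a[i]; a[i] <<- a[k]; a[k] <<- tmp }
      else { tmp <- a[1]; a[1] <<- a[k]; a[k] <<- tmp }
    }
  }
  rec(n)
  out
}

# all set partitions of 1..n as membership vectors (restricted growth strings)
all_partitions <- function(n) {
  out <- list()
  rec <- function(memb, k, maxg) {
    if (k > n) {
      out[[length(out) + 1]] <<- memb
      return(invisible())
    }
    for (g in seq_len(maxg + 1)) {
      memb[k] <- g
      rec(memb, k + 1, max(maxg, g))
    }
  }
  rec(integer(n), 1, 0)
  out
}

adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  s <- function(x) sum(choose(x, 2))
  sij <- s(tab)
  si <- s(rowSums(tab))
  sj <- s(colSums(tab))
  exp_ <- si * sj / choose(length(a), 2)
  (sij - exp_) / ((si + sj) / 2 - exp_)
}

# brute-force group-equalized IndVal maximum over candidate splits,
# independent of the package's vectorized implementation
oracle_max_indval <- function(a, g, cands) {
  best <- 0
  for (cp in cands) {
    L <- a[g <= cp]
    R <- a[g > cp]
    ml <- mean(L)
    mr <- mean(R)
    if (ml + mr > 0) {
      ivl <- 100 * (ml / (ml + mr)) * mean(L > 0)
      ivr <- 100 * (mr / (ml + mr)) * mean(R > 0)
      best <- max(best, ivl, ivr)
    }
  }
  best
}
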