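# Shared fixtures: everything is generated in code; nothing binary on disk.

options(sidefx.quiet = TRUE)

DRUGS <- sidefx_drugs()
CLASSES10 <- drug_class_map()$class

# one small study reused across tests that only need plausible structure
small_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n_participants = 600L, n_variants = 60L,
                        n_blocks = 6L, seed = 424L,
                        emit_indication_flag = TRUE)
      cache <<- simulate_study(cfg)
    }
    cache
  }
})

# draw a 2x2 table from a latent bivariate normal with given rho/thresholds
sample_2x2 <- function(n, rho, tau_x, tau_y) {
  p11 <- pbvnorm(-tau_x, -tau_y, rho)
  p1x <- 1 - pnorm(tau_x)
  px1 <- 1 - pnorm(tau_y)
  probs <- c(p11, p1x - p11, px1 - p11, 1 - p1x - px1 + p11)
  counts <- as.vector(rmultinom(1, n, probs))
  list(a = counts[1], b = counts[2], c = counts[3], d = counts[4])
}

# independent brute-force greedy clumping used as the oracle
clump_oracle <- function(pval, chrom, pos, dosages, r2_max, window_kb) {
  ord <- order(pval, chrom, pos)
  remaining <- ord
  index <- integer(0)
  while (length(remaining) > 0) {
    i <- remaining[1]
    index <- c(index, i)
    remaining <- remaining[-1]
    drop <- c()
    for (j in remaining) {
      if (chrom[j] == chrom[i] &&
          abs(pos[j] - pos[i]) <= window_kb * 1000) {
        r <- suppressWarnings(cor(dosages[, i], dosages[, j]))
        if (!is.na(r) && r^2 > r2_max) drop <- c(drop, j)
      }
    }
    remaining <- setdiff(remaining, drop)
  }
  sort(index)
}

# brute-force minimum-variance agglomerator over actual coordinates:
# at every step merge the pair of clusters whose union minimizes the
# increase in total within-cluster sum of squares
ward_bruteforce <- function(X) {
  clusters <- lapply(seq_len(nrow(X)), identity)
  wss <- function(idx) {
    if (length(idx) == 1L) return(0)
    sum(scale(X[idx, , drop = FALSE], scale = FALSE)^2)
  }
  merges <- list()
  while (length(clusters) > 1L) {
    best <- NULL; best_inc <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        inc <- wss(c(clusters[[i]], clusters[[j]])) -
          wss(clusters[[i]]) - wss(clusters[[j]])
        if (inc < best_inc - 1e-12) { best_inc <- inc; best <- c(i, j) }
      }
    }
    merges[[length(merges) + 1L]] <-
      sort(c(min(clusters[[best[1]]]), min(clusters[[best[2]]])))
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- c(clusters[-best], list(merged))
  }
  merges
}

# the leaf pair (by smallest member) merged at each step of a linkage tree
merge_pairs <- function(tree) {
  members <- as.list(-seq_along(tree$labels))
  out <- list()
  for (s in seq_along(tree$height)) {
    get <- function(node) if (node < 0) -node else members[[length(tree$labels) + node]]
    m1 <- get(tree$merge[s, 1]); m2 <- get(tree$merge[s, 2])
    out[[s]] <- sort(c(min(m1), min(m2)))
    members[[length(tree$labels) + s]] <- c(m1, m2)
  }
  out
}

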