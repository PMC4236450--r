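# Independent brute-force oracles. These deliberately share no code with
# the package implementations they check.

# mean pairwise difference over all C(n,2) chromosome pairs
pairwise_pi_oracle <- function(alt, total) {
  chroms <- c(rep(1L, alt), rep(0L, total - alt))
  pairs <- utils::combn(total, 2)
  mean(chroms[pairs[1, ]] != chroms[pairs[2, ]])
}

# dense O(n^2) reciprocal-overlap matrix
ro_matrix_oracle <- function(calls) {
  n <- nrow(calls)
  o <- pmax(0, outer(calls$end, calls$end, pmin) -
              outer(calls$start, calls$start, pmax))
  len <- calls$end - calls$start
  ro <- pmin(o / matrix(len, n, n), o / matrix(len, n, n, byrow = TRUE))
  ro * outer(calls$chrom, calls$chrom, "==")
}

# single-linkage clusters on the dense matrix (BFS transitive closure),
# followed by the same seed-split policy, re-derived independently
merge_oracle <- function(calls, threshold = 0.8) {
  ord <- order(calls$chrom, calls$start, calls$end, calls$sample)
  calls <- calls[ord, , drop = FALSE]
  rownames(calls) <- NULL
  ro <- ro_matrix_oracle(calls)
  adj <- ro >= threshold
  n <- nrow(calls)
  cluster <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    if (!is.na(cluster[i])) next
    frontier <- i
    comp <- i
    while (length(frontier) > 0L) {
      nxt <- setdiff(which(rowSums(adj[, frontier, drop = FALSE]) > 0), comp)
      comp <- c(comp, nxt)
      frontier <- nxt
    }
    cluster[comp] <- i
  }
  repeat {
    changed <- FALSE
    for (cl in unique(cluster)) {
      m <- which(cluster == cl)
      seed <- min(m)
      bad <- m[ro[seed, m] < threshold]
      if (length(bad) > 0L) {
        cluster[bad] <- min(bad)
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  split(seq_len(n), cluster) # members (in canonical order) per cluster seed
}

# dense site-by-reference reciprocal-overlap matrix (independent loop)
ro_matrix_reference <- function(sites, reference) {
  ro <- matrix(0, nrow(sites), nrow(reference))
  for (i in seq_len(nrow(sites))) {
    for (j in seq_len(nrow(reference))) {
      if (sites$chrom[i] != reference$chrom[j]) next
      o <- max(0, min(sites$end[i], reference$end[j]) -
                 max(sites$start[i], reference$start[j]))
      ro[i, j] <- min(o / (sites$end[i] - sites$start[i]),
                      o / (reference$end[j] - reference$start[j]))
    }
  }
  ro
}

sort_canonical <- function(calls) {
  out <- calls[order(calls$chrom, calls$start, calls$end, calls$sample), ,
               drop = FALSE]
  rownames(out) <- NULL
  out
}

random_callset <- function(n = 1000, n_chrom = 3, span = 3e5,
                           sizes = 51:3000) {
  data.frame(
    chrom = paste0("chr", sample.int(n_chrom, n, replace = TRUE)),
    start = st <- round(runif(n, 0, span)),
    end = st + sample(sizes, n, replace = TRUE),
    sample = paste0("S", sample.int(8, n, replace = TRUE)),
    stringsAsFactors = FALSE)
}

# textbook Saitou-Nei neighbor joining returning the tree's cophenetic
# (leaf-to-leaf path length) matrix; every leaf pair's distance is fixed
# at the join that first unites their clusters
nj_cophenetic_oracle <- function(d) {
  labels <- rownames(d)
  n_leaf <- length(labels)
  coph <- matrix(0, n_leaf, n_leaf, dimnames = list(labels, labels))
  # per active cluster: root-to-leaf path lengths, named by leaf
  leafdist <- lapply(labels, function(l) stats::setNames(0, l))
  D <- d
  join <- function(li, lj, extra) {
    for (a in names(li)) {
      for (b in names(lj)) {
        coph[a, b] <<- coph[b, a] <<- li[a] + lj[b] + extra
      }
    }
  }
  while (length(leafdist) > 2L) {
    m <- nrow(D)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    ij <- which(Q == min(Q), arr.ind = TRUE)[1, ]
    i <- min(ij); j <- max(ij)
    bi <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    bj <- D[i, j] - bi
    join(leafdist[[i]] + bi, leafdist[[j]] + bj, 0)
    newleaf <- c(leafdist[[i]] + bi, leafdist[[j]] + bj)
    newD <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], newD[keep]),
               c(newD[keep], 0))
    leafdist <- c(leafdist[keep], list(newleaf))
  }
  join(leafdist[[1]], leafdist[[2]], D[1, 2])
  coph
}

# additive (tree-metric) test fixtures: random topology + positive branch
# lengths, with the exact leaf-to-leaf path lengths
random_additive_matrix <- function(n_taxa) {
  tr <- ape::rtree(n_taxa, br = function(k) runif(k, 0.1, 2))
  tr <- ape::unroot(tr)
  list(tree = tr, d = as.matrix(stats::cophenetic(tr)))
}
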