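# Independent oracles used across tests. These deliberately avoid the code
# paths they check.

# Exact frequency-weighted 1-D k-means: optimal clusters of sorted points are
# contiguous, so enumerate all contiguous partitions of the bins into k
# clusters and minimise the weighted within-cluster sum of squares.
exact_weighted_kmeans <- function(v, w, k) {
  ord <- order(v)
  v <- v[ord]; w <- w[ord]
  n <- length(v)
  stopifnot(k <= n)
  if (k == n) return(v)
  cuts <- utils::combn(n - 1L, k - 1L)
  best <- NULL; best_ss <- Inf
  for (j in seq_len(ncol(cuts))) {
    bounds <- c(0L, cuts[, j], n)
    ss <- 0; cen <- numeric(k)
    for (c_ in seq_len(k)) {
      idx <- (bounds[c_] + 1L):bounds[c_ + 1L]
      mu <- sum(v[idx] * w[idx]) / sum(w[idx])
      cen[c_] <- mu
      ss <- ss + sum(w[idx] * (v[idx] - mu)^2)
    }
    if (ss < best_ss) { best_ss <- ss; best <- cen }
  }
  best
}

# 8-connected components via igraph on the pixel adjacency graph.
label_oracle <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  n <- nrow(idx)
  lab <- matrix(0L, nrow(mask), ncol(mask))
  if (n == 0L) return(lab)
  key <- paste(idx[, 1], idx[, 2])
  lookup <- seq_len(n); names(lookup) <- key
  edges <- NULL
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    nb <- paste(idx[, 1] + dr, idx[, 2] + dc)
    hit <- !is.na(lookup[nb])
    if (any(hit))
      edges <- rbind(edges, cbind(which(hit), unname(lookup[nb[hit]])))
  }
  g <- igraph::graph_from_edgelist(rbind(edges, cbind(seq_len(n), seq_len(n))),
                                   directed = FALSE)
  comp <- igraph::components(g)$membership[seq_len(n)]
  lab[idx] <- as.integer(comp)   # labelling differs from the implementation;
  lab                            # compare as partitions, not label values
}

# Brute-force hypergeometric tail via direct binomial-coefficient ratios
# (double precision; adequate for N <= 60).
brute_hyper_tail <- function(N, K, n, k, tail) {
  pmf <- function(x) choose(K, x) * choose(N - K, n - x) / choose(N, n)
  xs <- if (tail == "upper") k:min(K, n) else max(0, n + K - N):k
  sum(vapply(xs, pmf, numeric(1)))
}

# Rasterised disk mask (pixel centres within radius of the given centre).
raster_disk <- function(nr, nc, cy, cx, r_px) {
  ri <- matrix(seq_len(nr), nr, nc)
  ci <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  (ri - cy)^2 + (ci - cx)^2 <= r_px^2
}

# Greedy one-to-one matching of truth centres to found centroids within a
# pixel tolerance; returns recall, precision and the matched index pairs.
match_regions <- function(truth_rc, found_rc, tol_px = 2) {
  if (nrow(found_rc) == 0L)
    return(list(recall = 0, precision = NA_real_, pairs = NULL))
  d <- outer(seq_len(nrow(truth_rc)), seq_len(nrow(found_rc)),
             Vectorize(function(i, j)
               sqrt(sum((truth_rc[i, ] - found_rc[j, ])^2))))
  pairs <- NULL
  dd <- d
  repeat {
    mn <- min(dd)
    if (!is.finite(mn) || mn > tol_px) break
    ij <- arrayInd(which.min(dd), dim(dd))
    pairs <- rbind(pairs, ij)
    dd[ij[1], ] <- Inf
    dd[, ij[2]] <- Inf
  }
  nm <- if (is.null(pairs)) 0L else nrow(pairs)
  list(recall = nm / nrow(truth_rc), precision = nm / nrow(found_rc),
       pairs = pairs)
}
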