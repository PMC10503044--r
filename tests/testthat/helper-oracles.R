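# Independent brute-force oracles. These deliberately use naive loops and
# first-principles formulas, never the package's own code paths.

# Mode-m unfolding by explicit index walk: row = index on `mode`, column
# determined by the remaining modes with the lower-numbered one fastest.
oracle_unfold <- function(x, mode) {
  d <- dim(x)
  rest <- setdiff(1:3, mode)
  out <- matrix(0, d[mode], prod(d[rest]))
  for (i in seq_len(d[1])) {
    for (j in seq_len(d[2])) {
      for (k in seq_len(d[3])) {
        idx <- c(i, j, k)
        col <- (idx[rest[2]] - 1L) * d[rest[1]] + idx[rest[1]]
        out[idx[mode], col] <- x[i, j, k]
      }
    }
  }
  out
}

# Tucker sum evaluated as an explicit quadruple loop.
oracle_reconstruct <- function(core, factors) {
  rk <- dim(core)
  d <- vapply(factors, nrow, integer(1))
  out <- array(0, d)
  for (i in seq_len(d[1])) {
    for (j in seq_len(d[2])) {
      for (k in seq_len(d[3])) {
        s <- 0
        for (l1 in seq_len(rk[1])) {
          for (l2 in seq_len(rk[2])) {
            for (l3 in seq_len(rk[3])) {
              s <- s + core[l1, l2, l3] * factors[[1]][i, l1] *
                factors[[2]][j, l2] * factors[[3]][k, l3]
            }
          }
        }
        out[i, j, k] <- s
      }
    }
  }
  out
}

# Benjamini-Hochberg step-up from the definition:
# adjusted_(i) = min_{j >= i} p_(j) * m / j, capped at 1.
oracle_bh <- function(p) {
  m <- length(p)
  if (m == 0L) return(numeric(0))
  ord <- order(p)
  sorted <- p[ord]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    vals <- vapply(i:m, function(j) (m / j) * sorted[j], numeric(1))
    adj[i] <- min(1, min(vals))
  }
  out <- numeric(m)
  out[ord] <- adj
  out
}

# Sample-space Gram tensor by triple loop over features and sample pairs.
oracle_gram <- function(layers, center = TRUE) {
  M <- ncol(layers[[1]])
  K <- length(layers)
  out <- array(0, c(M, M, K))
  for (k in seq_len(K)) {
    X <- layers[[k]]
    if (center) X <- X - rowMeans(X)
    for (j1 in seq_len(M)) {
      for (j2 in seq_len(M)) {
        s <- 0
        for (i in seq_len(nrow(X))) s <- s + X[i, j1] * X[i, j2]
        out[j1, j2, k] <- s
      }
    }
  }
  out
}

# Back-projection by double loop.
oracle_project <- function(X, u) {
  out <- numeric(nrow(X))
  for (i in seq_len(nrow(X))) {
    s <- 0
    for (j in seq_len(ncol(X))) s <- s + X[i, j] * u[j]
    out[i] <- s
  }
  out
}

f1_score <- function(selected_ids, truth_ids) {
  tp <- length(intersect(selected_ids, truth_ids))
  2 * tp / (length(selected_ids) + length(truth_ids))
}

selected_ids <- function(selection) {
  tab <- if (inherits(selection, "feature_selection")) selection$table
         else selection$selection$table
  tab$feature_id[tab$selected]
}

rel_frob <- function(a, b) sqrt(sum((a - b)^2)) / sqrt(sum(b^2))
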