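# independent LMG oracle: average sequential R^2 gains over explicit
# permutations, each R^2 from lm()
lmg_brute <- function(y, X) {
  X <- as.matrix(X)
  p <- ncol(X)
  perms <- as.matrix(expand.grid(rep(list(seq_len(p)), p)))
  perms <- perms[apply(perms, 1, function(r) length(unique(r)) == p), ,
                 drop = FALSE]
  r2 <- function(cols) {
    if (!length(cols)) return(0)
    summary(lm(y ~ X[, cols, drop = FALSE]))$r.squared
  }
  shares <- numeric(p)
  for (i in seq_len(nrow(perms))) {
    entered <- integer(0)
    for (k in perms[i, ]) {
      shares[k] <- shares[k] + r2(c(entered, k)) - r2(entered)
      entered <- c(entered, k)
    }
  }
  shares / nrow(perms)
}


# exhaustive 3-node DAG oracle: score every one of the 25 DAGs on 3 labelled
# nodes with an independently coded Gaussian BIC and return the maximum
exhaustive_best_score <- function(X) {
  n <- nrow(X)
  score_node <- function(y, parents) {
    res <- if (length(parents)) {
      resid(lm(y ~ X[, parents, drop = FALSE]))
    } else {
      y - mean(y)
    }
    s2 <- sum(res^2) / n
    -n / 2 * (log(2 * pi * s2) + 1) - (length(parents) + 2) / 2 * log(n)
  }
  edges <- expand.grid(e12 = 0:2, e13 = 0:2, e23 = 0:2)  # 0 none, 1 ->, 2 <-
  best <- -Inf
  for (i in seq_len(nrow(edges))) {
    adj <- matrix(FALSE, 3, 3)
    e <- edges[i, ]
    if (e$e12 == 1) adj[1, 2] <- TRUE else if (e$e12 == 2) adj[2, 1] <- TRUE
    if (e$e13 == 1) adj[1, 3] <- TRUE else if (e$e13 == 2) adj[3, 1] <- TRUE
    if (e$e23 == 1) adj[2, 3] <- TRUE else if (e$e23 == 2) adj[3, 2] <- TRUE
    # cycle check for 3 nodes: a cycle needs all three edges forming a loop
    g <- adj
    reach <- g | (g %*% g > 0) | (g %*% g %*% g > 0)
    if (any(diag(reach))) next
    sc <- sum(sapply(1:3, function(v) score_node(X[, v], which(adj[, v]))))
    if (sc > best) best <- sc
  }
  best
}

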