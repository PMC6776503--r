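# Tier-constrained Bayesian-network structure learning over {PRS,
# endophenotypes, motor outcome}: greedy hill-climbing on the linear-Gaussian
# BIC score with random restarts, bootstrap edge confidence, and per-edge
# annotation (sign, incremental variance explained, Wald p).

#' Tier constraints for network learning
#'
#' Variables are assigned to tiers: \code{source} (exogenous; no incoming
#' edges — the PRS), \code{intermediate} (endophenotypes; edges among them
#' are free), and \code{sink} (terminal; no outgoing edges — the motor
#' outcome).
#'
#' @param tiers named character vector mapping each variable to
#'   \code{"source"}, \code{"intermediate"} or \code{"sink"}; exactly one
#'   source and at least one sink are required.
#' @return object of class \code{tier_constraint}.
#' @export
tier_constraint <- function(tiers) {
  stopifnot(is.character(tiers), !is.null(names(tiers)))
  bad <- setdiff(unique(tiers), c("source", "intermediate", "sink"))
  if (length(bad)) stop("unknown tier(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  if (sum(tiers == "source") != 1) {
    stop("exactly one source variable is required", call. = FALSE)
  }
  if (!any(tiers == "sink")) stop("at least one sink is required", call. = FALSE)
  structure(tiers, class = "tier_constraint")
}

# allowed directed edges under the tiers: never into a source, never out of
# a sink; self-edges never
allowed_edge_matrix <- function(vars, constraints) {
  p <- length(vars)
  A <- matrix(TRUE, p, p, dimnames = list(vars, vars))
  diag(A) <- FALSE
  if (!is.null(constraints)) {
    tiers <- constraints[vars]
    if (anyNA(tiers)) {
      stop("constraints missing for variable(s): ",
           paste(vars[is.na(tiers)], collapse = ", "), call. = FALSE)
    }
    A[, tiers == "source"] <- FALSE
    A[tiers == "sink", ] <- FALSE
  }
  A
}

has_path <- function(adj, from, to) {
  # DFS: is `to` reachable from `from`?
  seen <- logical(nrow(adj))
  stack <- from
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (v == to) return(TRUE)
    if (seen[v]) next
    seen[v] <- TRUE
    stack <- c(stack, which(adj[v, ]))
  }
  FALSE
}

is_acyclic <- function(adj) {
  # repeatedly strip nodes with no incoming edges
  p <- nrow(adj)
  alive <- rep(TRUE, p)
  repeat {
    indeg <- colSums(adj[alive, alive, drop = FALSE])
    leaf <- which(indeg == 0)
    if (!length(leaf)) break
    alive[which(alive)[leaf]] <- FALSE
    if (!any(alive)) break
  }
  !any(alive)
}

# linear-Gaussian BIC local score of a node given its parents, from the MLE
# covariance matrix S (n divisor); parameters = coefficients + intercept +
# residual variance
node_score <- function(S, n, v, parents) {
  s2 <- if (length(parents)) {
    S[v, v] - as.numeric(crossprod(S[parents, v],
                                   solve(S[parents, parents, drop = FALSE],
                                         S[parents, v])))
  } else {
    S[v, v]
  }
  s2 <- max(s2, 1e-12)
  loglik <- -n / 2 * (log(2 * pi * s2) + 1)
  loglik - (length(parents) + 2) / 2 * log(n)
}

network_score <- function(S, n, adj) {
  sum(vapply(seq_len(nrow(adj)),
             function(v) node_score(S, n, v, which(adj[, v])), numeric(1)))
}

hill_climb <- function(S, n, allowed, adj0) {
  p <- nrow(allowed)
  adj <- adj0
  scores <- vapply(seq_len(p), function(v) node_score(S, n, v, which(adj[, v])),
                   numeric(1))
  repeat {
    best <- list(delta = 1e-9, move = NULL)
    for (u in seq_len(p)) {
      for (v in seq_len(p)) {
        if (u == v) next
        if (adj[u, v]) {
          # delete u -> v
          d <- node_score(S, n, v, setdiff(which(adj[, v]), u)) - scores[v]
          if (d > best$delta) best <- list(delta = d, move = c(1L, u, v))
          # reverse u -> v (becomes v -> u)
          if (allowed[v, u]) {
            adj[u, v] <- FALSE
            ok <- !has_path(adj, u, v)
            adj[u, v] <- TRUE
            if (ok) {
              d2 <- (node_score(S, n, v, setdiff(which(adj[, v]), u)) - scores[v]) +
                (node_score(S, n, u, c(which(adj[, u]), v)) - scores[u])
              if (d2 > best$delta) best <- list(delta = d2, move = c(3L, u, v))
            }
          }
        } else if (allowed[u, v] && !has_path(adj, v, u)) {
          # add u -> v
          d <- node_score(S, n, v, c(which(adj[, v]), u)) - scores[v]
          if (d > best$delta) best <- list(delta = d, move = c(2L, u, v))
        }
      }
    }
    if (is.null(best$move)) break
    mv <- best$move
    u <- mv[2]; v <- mv[3]
    if (mv[1] == 1L) {
      adj[u, v] <- FALSE
    } else if (mv[1] == 2L) {
      adj[u, v] <- TRUE
    } else {
      adj[u, v] <- FALSE
      adj[v, u] <- TRUE
      scores[u] <- node_score(S, n, u, which(adj[, u]))
    }
    scores[v] <- node_score(S, n, v, which(adj[, v]))
  }
  adj
}

random_start_dag <- function(allowed, edge_prob = 0.25) {
  p <- nrow(allowed)
  ord <- sample.int(p)
  adj <- matrix(FALSE, p, p, dimnames = dimnames(allowed))
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      u <- ord[i]; v <- ord[j]
      if (allowed[u, v] && runif(1) < edge_prob) adj[u, v] <- TRUE
    }
  }
  adj
}

#' Learn a tier-constrained DAG by score-based search
#'
#' Greedy hill-climbing over add / delete / reverse moves maximizing the
#' linear-Gaussian log-likelihood with a BIC penalty, rejecting moves that
#' violate the tier constraints or create a cycle. The best structure over
#' \code{restarts} random initial DAGs (the first restart starts empty) is
#' returned. Deterministic given \code{seed}.
#'
#' @param data data.frame/matrix of continuous variables; complete cases
#'   required.
#' @param constraints a \code{tier_constraint} or NULL for unconstrained
#'   search.
#' @param seed integer seed for the restart initializations.
#' @param restarts number of random restarts (default 10).
#' @return logical adjacency matrix (entry [u, v] = edge u -> v) with the
#'   achieved score as attribute \code{"score"}.
#' @export
learn_structure <- function(data, constraints = NULL, seed = 1L,
                            restarts = 10L) {
  X <- as.matrix(data)
  if (anyNA(X)) {
    stop("missing values present; filter to complete cases first",
         call. = FALSE)
  }
  n <- nrow(X)
  p <- ncol(X)
  if (n <= 5 * p) {
    stop(sprintf("need n > 5 x node count (n=%d, nodes=%d)", n, p),
         call. = FALSE)
  }
  S <- cov(X) * (n - 1) / n
  allowed <- allowed_edge_matrix(colnames(X), constraints)
  best <- NULL
  best_score <- -Inf
  for (r in seq_len(restarts)) {
    adj0 <- if (r == 1L) {
      matrix(FALSE, p, p, dimnames = dimnames(allowed))
    } else {
      with_stream(seed, sprintf("bn-restart-%d", r), random_start_dag(allowed))
    }
    adj <- hill_climb(S, n, allowed, adj0)
    sc <- network_score(S, n, adj)
    if (sc > best_score) {
      best_score <- sc
      best <- adj
    }
  }
  stopifnot(is_acyclic(best))
  attr(best, "score") <- best_score
  best
}

find_cycle <- function(adj) {
  # returns a matrix of edges (from, to) forming one directed cycle, or NULL
  p <- nrow(adj)
  color <- integer(p)  # 0 white, 1 grey, 2 black
  parent <- integer(p)
  cyc <- NULL
  dfs <- function(v) {
    color[v] <<- 1L
    for (w in which(adj[v, ])) {
      if (!is.null(cyc)) return()
      if (color[w] == 0L) {
        parent[w] <<- v
        dfs(w)
      } else if (color[w] == 1L) {
        path <- v
        while (path[1] != w) path <- c(parent[path[1]], path)
        cyc <<- cbind(path, c(path[-1], w))
        return()
      }
    }
    color[v] <<- 2L
  }
  for (v in seq_len(p)) {
    if (color[v] == 0L && is.null(cyc)) dfs(v)
  }
  cyc
}

#' Bootstrap consensus network with edge annotation
#'
#' Relearns the structure on bootstrap resamples of the rows, keeps edges
#' whose selection frequency reaches \code{threshold}, breaks any cycle in
#' the consensus by dropping the lowest-frequency edge on it, and annotates
#' each consensus edge by regressing the child on its consensus parents:
#' sign of the coefficient, incremental R^2 of the edge given the other
#' parents, and the Wald p-value.
#'
#' @param data data.frame/matrix of continuous variables (complete cases).
#' @param constraints a \code{tier_constraint} or NULL.
#' @param n_boot number of bootstrap resamples (>= 10; default 100).
#' @param seed integer seed.
#' @param threshold consensus frequency threshold (default 0.5).
#' @param restarts hill-climb restarts per resample (default 2; the empty
#'   start plus one random).
#' @return object of class \code{bnetwork}: node set, annotated edge table
#'   (parent, child, frequency, sign, variance_explained, p), and the full
#'   frequency matrix.
#' @export
bootstrap_network <- function(data, constraints = NULL, n_boot = 100L,
                              seed = 1L, threshold = 0.5, restarts = 2L) {
  if (n_boot < 10) stop("n_boot must be >= 10", call. = FALSE)
  X <- as.matrix(data)
  if (anyNA(X)) stop("missing values present; filter to complete cases first",
                     call. = FALSE)
  n <- nrow(X)
  p <- ncol(X)
  freq <- matrix(0, p, p, dimnames = list(colnames(X), colnames(X)))
  for (b in seq_len(n_boot)) {
    idx <- with_stream(seed, sprintf("bn-boot-%d", b),
                       sample.int(n, n, replace = TRUE))
    adj <- learn_structure(X[idx, , drop = FALSE], constraints,
                           seed = stream_seed(seed, sprintf("boot%d", b)),
                           restarts = restarts)
    freq <- freq + adj
  }
  freq <- freq / n_boot
  cons <- freq >= threshold
  while (!is_acyclic(cons)) {
    cyc <- find_cycle(cons)
    f <- freq[cyc]
    drop <- cyc[which.min(f), , drop = FALSE]
    cons[drop] <- FALSE
    log_msg("bayesnet", "consensus cycle broken: dropped %s -> %s (freq %.2f)",
            colnames(cons)[drop[1]], colnames(cons)[drop[2]], min(f))
  }
  edges <- annotate_edges(X, cons, freq)
  structure(list(nodes = colnames(X), edges = edges, freq = freq,
                 threshold = threshold, n_boot = n_boot,
                 constraints = constraints),
            class = "bnetwork")
}

annotate_edges <- function(X, cons, freq) {
  rows <- list()
  vars <- colnames(X)
  for (v in seq_along(vars)) {
    parents <- which(cons[, v])
    if (!length(parents)) next
    df <- data.frame(X[, c(v, parents), drop = FALSE])
    names(df)[1] <- ".child"
    fit <- lm(.child ~ ., data = df)
    sm <- summary(fit)
    r2_full <- sm$r.squared
    co <- sm$coefficients
    for (u in parents) {
      others <- setdiff(parents, u)
      r2_red <- if (length(others)) {
        summary(lm(X[, v] ~ X[, others, drop = FALSE]))$r.squared
      } else 0
      nm <- make.names(vars[u])
      rows[[length(rows) + 1L]] <- data.frame(
        parent = vars[u], child = vars[v],
        frequency = freq[u, v],
        sign = ifelse(co[nm, "Estimate"] < 0, -1, 1),
        variance_explained = r2_full - r2_red,
        p = co[nm, "Pr(>|t|)"],
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(rows)) {
    return(data.frame(parent = character(), child = character(),
                      frequency = numeric(), sign = numeric(),
                      variance_explained = numeric(), p = numeric()))
  }
  out <- do.call(rbind, rows)
  out[order(-out$frequency, out$parent, out$child), , drop = FALSE]
}

#' @export
print.bnetwork <- function(x, ...) {
  cat(sprintf("bnetwork: %d nodes, %d consensus edges (freq >= %.2f over %d resamples)\n",
              length(x$nodes), nrow(x$edges), x$threshold, x$n_boot))
  if (nrow(x$edges)) {
    df <- x$edges
    df$frequency <- round(df$frequency, 2)
    df$variance_explained <- signif(df$variance_explained, 3)
    df$p <- signif(df$p, 3)
    print(df, row.names = FALSE)
  }
  invisible(x)
}

#' Direct upstream regulators of an outcome node
#'
#' Parents of the outcome in the consensus network, sorted by bootstrap
#' frequency (descending; ties by node label).
#'
#' @param net a \code{bnetwork}.
#' @param outcome node name.
#' @return character vector of parent node names.
#' @export
direct_regulators <- function(net, outcome) {
  stopifnot(inherits(net, "bnetwork"))
  if (!outcome %in% net$nodes) {
    stop("outcome '", outcome, "' not in network", call. = FALSE)
  }
  e <- net$edges[net$edges$child == outcome, , drop = FALSE]
  e$parent[order(-e$frequency, e$parent)]
}
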