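# Gaussian BIC network score machinery. All scores are computed from the
# MLE covariance matrix S (n divisor) so resampled datasets reduce to one
# O(n p^2) covariance pass; a node's score given parents P is
#   loglik(v | P) - (|P| + 2)/2 * log n
# with loglik from the residual variance S_vv - S_vP S_PP^-1 S_Pv.

ridge_solve <- function(A, b) {
  # tiny ridge keeps near-collinear parent sets (bootstrap duplicates,
  # correlated taxa) numerically well-posed without changing the optimum
  solve(A + diag(1e-8 * mean(diag(A)), nrow(A)), b)
}

node_score <- function(S, n, v, parents) {
  s2 <- if (length(parents) == 0) S[v, v] else {
    S[v, v] - drop(S[v, parents, drop = FALSE] %*%
                     ridge_solve(S[parents, parents, drop = FALSE],
                                 S[parents, v, drop = FALSE]))
  }
  s2 <- max(s2, 1e-12)
  -n / 2 * (log(2 * pi * s2) + 1) - (length(parents) + 2) / 2 * log(n)
}

# Vector of deltas for adding each candidate parent x to node y: based on
# the partial correlation of x and y given y's current parents.
add_deltas <- function(S, n, y, parents) {
  p <- ncol(S)
  Sp <- if (length(parents) == 0) S else {
    S - S[, parents, drop = FALSE] %*%
      ridge_solve(S[parents, parents, drop = FALSE], S[parents, , drop = FALSE])
  }
  denom <- Sp[y, y] * diag(Sp)
  rho2 <- ifelse(denom > 1e-12, Sp[, y]^2 / denom, 0)
  rho2 <- pmin(rho2, 1 - 1e-8)
  out <- -n / 2 * log(1 - rho2) - 0.5 * log(n)
  out[y] <- -Inf
  out[parents] <- -Inf
  out
}

# Is there a directed path from `from` to `to` in adjacency matrix adj?
has_path <- function(adj, from, to) {
  if (from == to) return(TRUE)
  visited <- logical(ncol(adj))
  stack <- from
  while (length(stack) > 0) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (visited[v]) next
    visited[v] <- TRUE
    nxt <- which(adj[v, ])
    if (to %in% nxt) return(TRUE)
    stack <- c(stack, nxt[!visited[nxt]])
  }
  FALSE
}

#' Learn a Gaussian Bayesian-network structure by greedy hill climbing
#'
#' Starts from the empty graph and repeatedly applies the single edge
#' addition, deletion or reversal that most improves the total Gaussian BIC
#' score while preserving acyclicity, stopping at a local optimum. The
#' search is deterministic given the data: equal-score moves are broken
#' lexicographically by (operation, source, target).
#'
#' @param data Numeric data frame or matrix (samples x variables);
#'   standardized internally. Constant columns are an error.
#' @param restarts Number of random restarts (default 0; the default search
#'   is fully deterministic).
#' @param seed Seed used only when `restarts > 0`.
#' @param max_iter Safety cap on hill-climbing moves.
#' @param max_parents Cap on the number of parents per node (default
#'   `max(3, floor(n / 10))`, so small bootstrap samples cannot overfit
#'   near-collinear variables).
#' @param engine `"cpp"` (default, compiled search) or `"r"` (pure-R
#'   reference implementation of the identical search; useful for
#'   cross-checking).
#' @return An object of class `bn_structure`: adjacency matrix `adj`
#'   (`adj[x, y]` is the edge x -> y), `nodes`, `score`, `n`.
#' @export
#' @examples
#' set.seed(1)
#' a <- rnorm(200); b <- a + rnorm(200, 0, 0.3); c <- b + rnorm(200, 0, 0.3)
#' learn_structure(data.frame(a, b, c))
learn_structure <- function(data, restarts = 0, seed = 1, max_iter = 500L,
                            max_parents = NULL, engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  X <- as.matrix(data)
  storage.mode(X) <- "double"
  n <- nrow(X)
  p <- ncol(X)
  if (n < 5) abort("need at least 5 samples", class = "scfamap_domain_error")
  sds <- apply(X, 2, sd)
  if (any(sds <= 1e-12 | !is.finite(sds))) {
    abort(sprintf("constant column(s): %s",
                  paste(colnames(X)[sds <= 1e-12 | !is.finite(sds)],
                        collapse = ", ")),
          class = "scfamap_domain_error")
  }
  max_parents <- max_parents %||% max(3L, floor(n / 10))
  X <- scale(X)
  S <- crossprod(X) / n
  nodes <- colnames(X) %||% paste0("V", seq_len(p))
  dimnames(S) <- list(nodes, nodes)

  climb <- function(adj) {
    parents <- lapply(seq_len(p), function(y) which(adj[, y]))
    sc <- vapply(seq_len(p), function(y) node_score(S, n, y, parents[[y]]),
                 numeric(1))
    Dadd <- sapply(seq_len(p), function(y) add_deltas(S, n, y, parents[[y]]))
    del_cache <- vector("list", p)
    del_delta <- function(x, y) {
      if (is.null(del_cache[[y]])) {
        del_cache[[y]] <<- vapply(parents[[y]], function(xx) {
          node_score(S, n, y, setdiff(parents[[y]], xx)) - sc[y]
        }, numeric(1))
        names(del_cache[[y]]) <<- as.character(parents[[y]])
      }
      del_cache[[y]][[as.character(x)]]
    }
    it <- 0L
    repeat {
      it <- it + 1L
      if (it > max_iter) break
      best <- list(delta = 1e-10, op = NULL)
      consider <- function(delta, op, x, y, cur) {
        if (delta > cur$delta + 1e-9) list(delta = delta, op = op, x = x, y = y)
        else cur
      }
      # additions (op order: add < delete < reverse; then source, target)
      cand <- which(Dadd > best$delta & !adj & !t(adj), arr.ind = TRUE)
      cand <- cand[cand[, 1] != cand[, 2], , drop = FALSE]
      if (nrow(cand) > 0) {
        ord <- order(-Dadd[cand], cand[, 1], cand[, 2])
        for (i in ord) {
          x <- cand[i, 1]; y <- cand[i, 2]
          if (Dadd[x, y] <= best$delta + 1e-9) break
          if (length(parents[[y]]) >= max_parents) next
          if (!has_path(adj, y, x)) {
            best <- list(delta = Dadd[x, y], op = "add", x = x, y = y)
            break
          }
        }
      }
      edges <- which(adj, arr.ind = TRUE)
      if (nrow(edges) > 0) {
        ord <- order(edges[, 1], edges[, 2])
        for (i in ord) {
          x <- edges[i, 1]; y <- edges[i, 2]
          dd <- del_delta(x, y)
          best <- consider(dd, "delete", x, y, best)
          # reversal = delete x->y then add y->x given x's parents; the
          # add part is exactly the cached Dadd[y, x]
          rd <- dd + Dadd[y, x]
          if (rd > best$delta + 1e-9 && length(parents[[x]]) < max_parents) {
            adj2 <- adj; adj2[x, y] <- FALSE
            if (!has_path(adj2, x, y)) {
              best <- list(delta = rd, op = "reverse", x = x, y = y)
            }
          }
        }
      }
      if (is.null(best$op)) break
      x <- best$x; y <- best$y
      if (best$op == "add") {
        adj[x, y] <- TRUE
      } else if (best$op == "delete") {
        adj[x, y] <- FALSE
      } else {
        adj[x, y] <- FALSE; adj[y, x] <- TRUE
      }
      touched <- if (best$op == "reverse") c(x, y) else y
      for (v in touched) {
        parents[[v]] <- which(adj[, v])
        sc[v] <- node_score(S, n, v, parents[[v]])
        Dadd[, v] <- add_deltas(S, n, v, parents[[v]])
        del_cache[v] <- list(NULL)
      }
    }
    list(adj = adj, score = sum(sc))
  }

  run_climb <- function(adj0) {
    if (engine == "cpp") {
      res <- .hc_climb_cpp(S, n, max_parents, max_iter, adj0)
      dimnames(res$adj) <- list(nodes, nodes)
      res
    } else {
      climb(adj0)
    }
  }
  empty <- matrix(FALSE, p, p, dimnames = list(nodes, nodes))
  best <- run_climb(empty)
  if (restarts > 0) {
    old <- .Random.seed_guard(seed)
    on.exit(old(), add = TRUE)
    for (r in seq_len(restarts)) {
      adj0 <- empty
      k <- sample.int(p, 2)
      adj0[k[1], k[2]] <- TRUE
      cand <- run_climb(adj0)
      if (cand$score > best$score + 1e-9) best <- cand
    }
  }
  structure(list(adj = best$adj, nodes = nodes, score = best$score, n = n),
            class = "bn_structure")
}

#' @export
print.bn_structure <- function(x, ...) {
  e <- which(x$adj, arr.ind = TRUE)
  cat(sprintf("Gaussian BN structure: %d nodes, %d edges (BIC score %.2f)\n",
              length(x$nodes), nrow(e), x$score))
  if (nrow(e) > 0) {
    cat(paste0("  ", x$nodes[e[, 1]], " -> ", x$nodes[e[, 2]], "\n"), sep = "")
  }
  invisible(x)
}

#' @export
tidy.bn_structure <- function(x, ...) {
  e <- which(x$adj, arr.ind = TRUE)
  tibble(from = x$nodes[e[, 1]], to = x$nodes[e[, 2]]) |>
    arrange(.data$from, .data$to)
}

#' Bootstrap-consensus Bayesian network
#'
#' Learns a structure on each of `n_boot` row resamples and retains the
#' undirected edges appearing in at least a `retention` fraction of
#' bootstraps (defaults 500 and 0.5). Edge direction is the majority
#' direction among bootstraps containing the edge (ties flagged
#' undirected); any cycle among retained edges is broken by dropping its
#' lowest-frequency edge. Each retained edge is annotated with the sign of
#' the associated partial regression coefficient.
#'
#' @inheritParams learn_structure
#' @param n_boot Number of bootstrap resamples.
#' @param retention Minimum edge frequency to retain.
#' @param seed Integer seed driving the resamples.
#' @param ... Passed to [learn_structure()] (e.g. `max_parents`, `engine`).
#' @return An object of class `consensus_network`: `nodes`, `edge_freq`
#'   tibble (`from`, `to`, `frequency`, `n_forward`, `n_backward`) and
#'   `retained` tibble (`from`, `to`, `frequency`, `direction`, `sign`).
#' @export
bootstrap_consensus <- function(data, n_boot = 500, retention = 0.5, seed = 1,
                                ...) {
  if (n_boot < 1) abort("n_boot must be >= 1", class = "scfamap_config_error")
  X <- as.matrix(data)
  n <- nrow(X)
  p <- ncol(X)
  nodes <- colnames(X) %||% paste0("V", seq_len(p))
  colnames(X) <- nodes
  fwd <- matrix(0L, p, p, dimnames = list(nodes, nodes))
  old <- .Random.seed_guard(seed)
  on.exit(old(), add = TRUE)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    g <- learn_structure(X[idx, , drop = FALSE], ...)
    fwd <- fwd + g$adj
  }
  undirected <- fwd + t(fwd)
  pairs <- which(upper.tri(undirected) & undirected > 0, arr.ind = TRUE)
  edge_freq <- tibble(
    from = nodes[pairs[, 1]], to = nodes[pairs[, 2]],
    frequency = undirected[pairs] / n_boot,
    n_forward = fwd[pairs], n_backward = t(fwd)[pairs]
  ) |> arrange(desc(.data$frequency), .data$from, .data$to)

  ret <- filter(edge_freq, .data$frequency >= retention) |>
    mutate(direction = dplyr::case_when(
      n_forward > n_backward ~ "forward",
      n_backward > n_forward ~ "backward",
      TRUE ~ "undirected"
    ))
  # orient: forward keeps from->to, backward swaps
  if (nrow(ret) > 0) {
    swap <- ret$direction == "backward"
    tmp <- ret$from[swap]; ret$from[swap] <- ret$to[swap]; ret$to[swap] <- tmp
    ret$direction[swap] <- "forward"
    ret <- break_cycles(ret)
    ret$sign <- edge_signs(X, ret)
    ret <- select(ret, "from", "to", "frequency", "direction", "sign")
  } else {
    ret <- tibble(from = character(), to = character(), frequency = numeric(),
                  direction = character(), sign = numeric())
  }
  structure(list(nodes = nodes, edge_freq = edge_freq, retained = ret,
                 n_boot = n_boot, retention = retention, seed = seed),
            class = "consensus_network")
}

# Drop the lowest-frequency edge of each directed cycle until acyclic.
# Undirected ties never form part of a directed cycle check (treated as
# absent for orientation purposes).
break_cycles <- function(ret) {
  repeat {
    dir_edges <- ret[ret$direction == "forward", , drop = FALSE]
    if (nrow(dir_edges) == 0) return(ret)
    nodes <- unique(c(dir_edges$from, dir_edges$to))
    p <- length(nodes)
    adj <- matrix(FALSE, p, p, dimnames = list(nodes, nodes))
    adj[cbind(match(dir_edges$from, nodes), match(dir_edges$to, nodes))] <- TRUE
    cyc <- find_cycle(adj)
    if (is.null(cyc)) return(ret)
    cyc_edges <- paste(nodes[cyc$from], nodes[cyc$to])
    in_cycle <- paste(ret$from, ret$to) %in% cyc_edges
    drop_idx <- which(in_cycle)[which.min(ret$frequency[in_cycle])]
    ret <- ret[-drop_idx, , drop = FALSE]
  }
}

# Return one directed cycle (as from/to index vectors) or NULL if acyclic.
find_cycle <- function(adj) {
  p <- ncol(adj)
  color <- integer(p)  # 0 white, 1 grey, 2 black
  parent <- integer(p)
  cycle <- NULL
  dfs <- function(v) {
    color[v] <<- 1L
    for (w in which(adj[v, ])) {
      if (!is.null(cycle)) return()
      if (color[w] == 0L) {
        parent[w] <<- v
        dfs(w)
      } else if (color[w] == 1L) {
        path_v <- v
        chain <- c(v)
        while (path_v != w) {
          path_v <- parent[path_v]
          chain <- c(path_v, chain)
        }
        cycle <<- list(from = chain, to = c(chain[-1], w))
      }
    }
    color[v] <<- 2L
  }
  for (v in seq_len(p)) {
    if (color[v] == 0L) dfs(v)
    if (!is.null(cycle)) break
  }
  cycle
}

# Sign annotation: for edge u -> v, regress v on its retained parents and
# take the sign of u's partial coefficient (plain correlation sign for
# undirected ties).
edge_signs <- function(X, ret) {
  vapply(seq_len(nrow(ret)), function(i) {
    v <- ret$to[i]; u <- ret$from[i]
    if (ret$direction[i] != "forward") {
      return(sign(cor(X[, u], X[, v])))
    }
    pars <- ret$from[ret$to == v & ret$direction == "forward"]
    fit <- stats::lm.fit(cbind(1, X[, pars, drop = FALSE]), X[, v])
    sign(fit$coefficients[[match(u, pars) + 1]])
  }, numeric(1))
}

#' Classify taxa as direct or indirect SCFA neighbours
#'
#' On the retained consensus edges (taken as an undirected skeleton), a
#' node is `direct` if it shares an edge with any SCFA node, `indirect` if
#' it reaches an SCFA node through a path of length >= 2 but has no direct
#' edge, and `none` otherwise. Paths through transit (or any other node)
#' count.
#'
#' @param net A `consensus_network`.
#' @param scfa_ids Character vector of SCFA node names.
#' @return A tibble `node`, `status` for every non-SCFA node.
#' @export
scfa_neighborhood <- function(net, scfa_ids) {
  unknown <- setdiff(scfa_ids, net$nodes)
  if (length(unknown) > 0) {
    abort(sprintf("unknown node(s): %s", paste(unknown, collapse = ", ")),
          class = "scfamap_key_error")
  }
  others <- setdiff(net$nodes, scfa_ids)
  edges <- net$retained
  nbr <- function(v) {
    c(edges$to[edges$from == v], edges$from[edges$to == v])
  }
  direct <- others[vapply(others, function(v) any(nbr(v) %in% scfa_ids),
                          logical(1))]
  # undirected reachability from the SCFA set
  reach <- unique(scfa_ids)
  frontier <- reach
  while (length(frontier) > 0) {
    nxt <- unique(unlist(lapply(frontier, nbr)))
    frontier <- setdiff(nxt, reach)
    reach <- c(reach, frontier)
  }
  tibble(node = others,
         status = dplyr::case_when(
           others %in% direct ~ "direct",
           others %in% reach ~ "indirect",
           TRUE ~ "none"
         ))
}

#' @export
print.consensus_network <- function(x, ...) {
  cat(sprintf("Consensus Bayesian network: %d nodes, %d retained edge(s) (>= %.0f%% of %d bootstraps)\n",
              length(x$nodes), nrow(x$retained), 100 * x$retention, x$n_boot))
  if (nrow(x$retained) > 0) print(as.data.frame(x$retained), row.names = FALSE)
  invisible(x)
}

#' @export
tidy.consensus_network <- function(x, ...) x$retained

#' @export
glance.consensus_network <- function(x, ...) {
  tibble(n_nodes = length(x$nodes), n_retained = nrow(x$retained),
         n_boot = x$n_boot, retention = x$retention)
}

#' Plot a consensus network
#'
#' Circular-layout graph of retained consensus edges; edge width maps to
#' bootstrap frequency, colour to association sign.
#'
#' @param object A `consensus_network`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.consensus_network <- function(object, ...) {
  nodes <- object$nodes
  theta <- seq(0, 2 * pi, length.out = length(nodes) + 1)[seq_along(nodes)]
  layout <- tibble(node = nodes, x = cos(theta), y = sin(theta))
  e <- object$retained |>
    left_join(layout, by = c(from = "node")) |>
    left_join(layout, by = c(to = "node"), suffix = c("", "_to")) |>
    mutate(sign_lab = ifelse(.data$sign >= 0, "positive", "negative"))
  p <- ggplot2::ggplot(layout, ggplot2::aes(.data$x, .data$y))
  if (nrow(e) > 0) {
    p <- p + ggplot2::geom_segment(
      data = e,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$x_to,
                   yend = .data$y_to, linewidth = .data$frequency,
                   colour = .data$sign_lab)) +
      ggplot2::scale_colour_manual(values = c(positive = "firebrick",
                                              negative = "purple4")) +
      ggplot2::scale_linewidth(range = c(0.3, 1.5))
  }
  p + ggplot2::geom_point(size = 2) +
    ggplot2::geom_text(ggplot2::aes(label = .data$node), vjust = -1, size = 3) +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::labs(colour = NULL, linewidth = "frequency")
}
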