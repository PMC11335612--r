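# Overlapping community detection by cluster-affiliation likelihood ascent
# (BigClam-style nonnegative factorization of the adjacency structure).
#
# Model: edge probability p(u,v) = 1 - exp(-F_u . F_v) with nonnegative
# affiliation vectors F_u. The log-likelihood
#   l(F) = sum_{(u,v) in E} log(1 - exp(-F_u.F_v)) - sum_{(u,v) notin E} F_u.F_v
# is maximized by projected gradient ascent one node at a time with
# backtracking line search, so accepted steps never decrease l(F).

BIGCLAM_MAX_F <- 10      # cap on affiliation weights, for numerical safety
BIGCLAM_MIN_P <- 1e-10   # floor on edge scores inside log(1 - exp(-s))

bigclam_node_ll <- function(f_u, f_nbrs, s_total_with_u) {
  # terms of l(F) that involve node u; changing F_u changes exactly these.
  # s_total_with_u = column sums of F with f_u as node u's row.
  s <- pmax(as.numeric(f_nbrs %*% f_u), BIGCLAM_MIN_P)
  edge_term <- sum(log1p(-exp(-s)))
  # nonedge dot products = F_u . (S - F_u - sum of neighbor rows)
  nonedge_term <- sum(f_u * (s_total_with_u - f_u - colSums(f_nbrs)))
  edge_term - nonedge_term
}

bigclam_log_likelihood <- function(f, edges_i, edges_j) {
  s_e <- rowSums(f[edges_i, , drop = FALSE] * f[edges_j, , drop = FALSE])
  s_e_floor <- pmax(s_e, BIGCLAM_MIN_P)
  s_col <- colSums(f)
  total_pairs <- (sum(s_col^2) - sum(rowSums(f^2))) / 2  # sum over u<v F_u.F_v
  sum(log1p(-exp(-s_e_floor))) - (total_pairs - sum(s_e))
}

#' Overlapping communities by cluster-affiliation likelihood
#'
#' Fits a nonnegative node-by-community affiliation matrix `F` by
#' coordinate (per-node) projected gradient ascent with backtracking on the
#' cluster-affiliation log-likelihood, then thresholds memberships at
#' `epsilon = sqrt(-log(1 - 1/N))`, the affiliation strength at which the
#' modeled edge probability equals the background probability `1/N`. Edge
#' weights are ignored (the affiliation model is over the unweighted
#' topology). A node may belong to zero, one or several communities.
#'
#' @param network A non-empty `psn_network`.
#' @param n_communities Number of communities `k` (1 <= k <= node count).
#' @param seed Integer seed (random initialization and sweep order).
#' @param max_iter Maximum number of full sweeps over the nodes.
#' @param tol Stop when a full sweep improves the log-likelihood by less
#'   than this.
#' @return A `psn_cover`: list with `F` (node x community matrix, rownames
#'   = node ids), `memberships` (named list of integer community ids,
#'   0-based), `log_likelihood`, `epsilon`, `trace` (per-sweep
#'   log-likelihood, non-decreasing).
#' @export
bigclam <- function(network, n_communities, seed = 1L, max_iter = 100L,
                    tol = 1e-6) {
  stopifnot(inherits(network, "psn_network"))
  nodes <- network$nodes
  n <- length(nodes)
  if (n == 0) stop_psn("psn_empty_network", "empty network")
  if (n_communities < 1 || n_communities > n) {
    stop_psn("psn_parameter_error",
             "n_communities must be between 1 and the node count (%d)", n)
  }
  k <- as.integer(n_communities)
  e <- network$edges
  ui <- match(e$u, nodes)
  vi <- match(e$v, nodes)
  nbrs <- lapply(seq_len(n), function(i) integer(0))
  for (t in seq_along(ui)) {
    nbrs[[ui[t]]] <- c(nbrs[[ui[t]]], vi[t])
    nbrs[[vi[t]]] <- c(nbrs[[vi[t]]], ui[t])
  }
  trace <- numeric(0)
  f <- with_seed(seed, {
    f <- matrix(stats::runif(n * k, 0, 1), n, k)
    s_col <- colSums(f)
    ll <- bigclam_log_likelihood(f, ui, vi)
    for (sweep in seq_len(max_iter)) {
      order_nodes <- sample.int(n)
      for (u in order_nodes) {
        f_u <- f[u, ]
        f_nbrs <- f[nbrs[[u]], , drop = FALSE]
        ll_old <- bigclam_node_ll(f_u, f_nbrs, s_col)
        # gradient: sum_{v in N(u)} F_v * exp(-s)/(1-exp(-s)) - (nonedge sum)
        s <- pmax(as.numeric(f_nbrs %*% f_u), BIGCLAM_MIN_P)
        coef <- exp(-s) / (1 - exp(-s))
        grad_pos <- as.numeric(crossprod(f_nbrs, coef))
        grad_neg <- s_col - f_u - colSums(f_nbrs)
        grad <- grad_pos - grad_neg
        step <- 0.1
        for (bt in 1:12) {
          f_new <- pmin(pmax(f_u + step * grad, 0), BIGCLAM_MAX_F)
          ll_new <- bigclam_node_ll(f_new, f_nbrs, s_col - f_u + f_new)
          if (ll_new > ll_old + 1e-12) break
          step <- step / 2
          f_new <- NULL
        }
        if (!is.null(f_new)) {
          s_col <- s_col - f_u + f_new
          f[u, ] <- f_new
        }
      }
      ll_new_total <- bigclam_log_likelihood(f, ui, vi)
      trace <- c(trace, ll_new_total)
      if (ll_new_total - ll < tol) break
      ll <- ll_new_total
    }
    f
  })
  rownames(f) <- nodes
  epsilon <- sqrt(-log(1 - 1 / n))
  memberships <- apply(f, 1, function(row) which(row >= epsilon) - 1L,
                       simplify = FALSE)
  structure(class = "psn_cover", list(
    F = f,
    memberships = memberships,
    log_likelihood = bigclam_log_likelihood(f, ui, vi),
    epsilon = epsilon,
    trace = trace,
    seed = as.integer(seed)
  ))
}

#' @export
print.psn_cover <- function(x, ...) {
  n_mem <- lengths(x$memberships)
  cat(sprintf(
    "Overlapping cover: %d nodes, %d communities, log-likelihood %.3f\n",
    nrow(x$F), ncol(x$F), x$log_likelihood))
  cat(sprintf("  memberships per node: min %d / median %s / max %d\n",
              min(n_mem), format(stats::median(n_mem)), max(n_mem)))
  invisible(x)
}

#' Write an overlapping cover
#'
#' JSON mapping node id to its list of community ids at `path`; optionally
#' the dense affiliation matrix `F` as CSV.
#'
#' @param cover A `psn_cover`.
#' @param path JSON output path.
#' @param f_matrix_path Optional CSV path for the affiliation matrix.
#' @return `path`, invisibly.
#' @export
write_cover <- function(cover, path, f_matrix_path = NULL) {
  jsonlite::write_json(
    list(epsilon = cover$epsilon,
         log_likelihood = cover$log_likelihood,
         seed = cover$seed,
         memberships = cover$memberships),
    path, auto_unbox = TRUE, digits = NA)
  if (!is.null(f_matrix_path)) {
    utils::write.csv(data.frame(node_id = rownames(cover$F), cover$F,
                                check.names = FALSE),
                     f_matrix_path, row.names = FALSE)
  }
  invisible(path)
}
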