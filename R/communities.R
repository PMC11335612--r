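# Community detection: weighted modularity, Louvain (two-phase greedy
# modularity maximization, implemented here rather than delegated), and
# partition bookkeeping.

new_psn_partition <- function(membership, network, resolution = 1,
                              seed = NA_integer_, parameters = list()) {
  membership <- membership[order(names(membership))]
  # module ids contiguous from 0, numbered by decreasing module size
  # (ties: smallest original id), so module 0 is the largest subgroup
  sizes <- sort(table(membership), decreasing = TRUE)
  relabel <- stats::setNames(seq_along(sizes) - 1L, names(sizes))
  membership <- stats::setNames(as.integer(relabel[as.character(membership)]),
                                names(membership))
  part <- structure(class = "psn_partition", list(
    membership = membership,
    modularity = NA_real_,
    n_modules = length(sizes),
    seed = seed,
    parameters = parameters
  ))
  part$modularity <- modularity_score(network, part, resolution = resolution)
  part
}

#' Build a partition from an explicit membership vector
#'
#' Wraps a named node-to-module assignment (e.g. labels from an external
#' clustering) as a `psn_partition`, renumbering module ids to be
#' contiguous from 0 in decreasing-size order. Modularity is `NA` unless a
#' network is supplied.
#'
#' @param membership Named vector: names are node ids, values module
#'   labels (any atomic type).
#' @param network Optional `psn_network` on which to score modularity.
#' @return A `psn_partition`.
#' @export
as_psn_partition <- function(membership, network = NULL) {
  stopifnot(!is.null(names(membership)), !anyNA(membership))
  membership <- membership[order(names(membership))]
  sizes <- sort(table(membership), decreasing = TRUE)
  relabel <- stats::setNames(seq_along(sizes) - 1L, names(sizes))
  membership <- stats::setNames(as.integer(relabel[as.character(membership)]),
                                names(membership))
  part <- structure(class = "psn_partition", list(
    membership = membership,
    modularity = NA_real_,
    n_modules = length(sizes),
    seed = NA_integer_,
    parameters = list()
  ))
  if (!is.null(network)) {
    part$modularity <- modularity_score(network, part)
  }
  part
}

#' @export
print.psn_partition <- function(x, ...) {
  cat(sprintf("Partition: %d nodes, %d modules, Q = %.4f\n",
              length(x$membership), x$n_modules, x$modularity))
  invisible(x)
}

#' Weighted Newman–Girvan modularity of a partition
#'
#' `Q = sum_c [ W_in_c / m - resolution * (S_c / 2m)^2 ]` where `W_in_c` is
#' the total weight of edges inside module `c`, `S_c` the total strength of
#' its nodes and `m` the total edge weight. The all-in-one-module partition
#' scores exactly 0.
#'
#' @param network A `psn_network` with at least one edge.
#' @param partition A `psn_partition`, or a named vector mapping every
#'   network node to a module id.
#' @param resolution Resolution parameter (1 = classic modularity).
#' @return Q in \[-1, 1\].
#' @export
modularity_score <- function(network, partition, resolution = 1) {
  membership <- if (inherits(partition, "psn_partition")) {
    partition$membership
  } else {
    partition
  }
  if (!all(network$nodes %in% names(membership))) {
    stop_psn("psn_coverage_error",
             "partition does not cover all network nodes")
  }
  e <- network$edges
  if (nrow(e) == 0) {
    stop_psn("psn_empty_network", "modularity requires at least one edge")
  }
  m <- sum(e$weight)
  cu <- membership[e$u]
  cv <- membership[e$v]
  w_in <- tapply(e$weight[cu == cv], cu[cu == cv], sum)
  strength <- tapply(c(e$weight, e$weight), membership[c(e$u, e$v)], sum)
  q <- sum(w_in / m) - resolution * sum((strength / (2 * m))^2)
  as.numeric(q)
}

# --- Louvain internals -----------------------------------------------------
# Graph state during aggregation: n nodes, adjacency lists adj[[i]] =
# list(nb = integer neighbors, w = weights), self[i] = internal (self-loop)
# weight. Strength k_i = sum(w) + 2 * self_i.

louvain_local_phase <- function(adj, self, m, resolution, n_pass_max = 100L) {
  n <- length(adj)
  comm <- seq_len(n)
  k <- vapply(seq_len(n), function(i) sum(adj[[i]]$w), numeric(1)) + 2 * self
  sigma_tot <- k  # per community (indexed by community id)
  improved_any <- FALSE
  for (pass in seq_len(n_pass_max)) {
    moved <- FALSE
    order_nodes <- sample.int(n)
    for (u in order_nodes) {
      cu <- comm[u]
      nb <- adj[[u]]$nb
      wv <- adj[[u]]$w
      keep <- nb != u
      nb <- nb[keep]; wv <- wv[keep]
      # weight from u to each neighboring community (and to its own)
      w_uc <- tapply(wv, comm[nb], sum)
      cand <- as.integer(names(w_uc))
      if (!(cu %in% cand)) {
        cand <- c(cand, cu)
        w_uc <- c(w_uc, 0)
      }
      sigma_tot[cu] <- sigma_tot[cu] - k[u]
      gain <- as.numeric(w_uc) - resolution * k[u] * sigma_tot[cand] / (2 * m)
      best <- which(gain == max(gain))
      target <- min(cand[best])  # tie-break: lowest module id
      if (target != cu && max(gain) > gain[match(cu, cand)]) {
        comm[u] <- target
        moved <- TRUE
        improved_any <- TRUE
        sigma_tot[target] <- sigma_tot[target] + k[u]
      } else {
        sigma_tot[cu] <- sigma_tot[cu] + k[u]
      }
    }
    if (!moved) break
  }
  list(comm = comm, improved = improved_any)
}

louvain_aggregate <- function(adj, self, comm) {
  ids <- sort(unique(comm))
  remap <- integer(max(comm))
  remap[ids] <- seq_along(ids)
  comm2 <- remap[comm]
  n2 <- length(ids)
  self2 <- numeric(n2)
  # self-loop weight of a supernode = old self-loops + internal edge weight
  acc <- new.env(parent = emptyenv())
  for (u in seq_along(adj)) {
    cu <- comm2[u]
    self2[cu] <- self2[cu] + self[u]
    nb <- adj[[u]]$nb
    wv <- adj[[u]]$w
    for (t in seq_along(nb)) {
      v <- nb[t]
      if (v <= u) next  # each undirected edge once
      cv <- comm2[v]
      if (cu == cv) {
        self2[cu] <- self2[cu] + wv[t]
      } else {
        key <- if (cu < cv) paste(cu, cv) else paste(cv, cu)
        assign(key, (get0(key, envir = acc) %||% 0) + wv[t], envir = acc)
      }
    }
  }
  keys <- ls(acc)
  adj2 <- replicate(n2, list(nb = integer(0), w = numeric(0)),
                    simplify = FALSE)
  if (length(keys) > 0) {
    parts <- do.call(rbind, strsplit(keys, " ", fixed = TRUE))
    a <- as.integer(parts[, 1]); b <- as.integer(parts[, 2])
    w <- vapply(keys, get, numeric(1), envir = acc)
    for (t in seq_along(a)) {
      adj2[[a[t]]]$nb <- c(adj2[[a[t]]]$nb, b[t])
      adj2[[a[t]]]$w <- c(adj2[[a[t]]]$w, w[t])
      adj2[[b[t]]]$nb <- c(adj2[[b[t]]]$nb, a[t])
      adj2[[b[t]]]$w <- c(adj2[[b[t]]]$w, w[t])
    }
  }
  list(adj = adj2, self = self2, comm2 = comm2)
}

louvain_q <- function(adj, self, comm, m, resolution) {
  n <- length(adj)
  k <- vapply(seq_len(n), function(i) sum(adj[[i]]$w), numeric(1)) + 2 * self
  w_in <- numeric(max(comm))
  s_tot <- numeric(max(comm))
  for (u in seq_len(n)) {
    w_in[comm[u]] <- w_in[comm[u]] + self[u]
    s_tot[comm[u]] <- s_tot[comm[u]] + k[u]
    nb <- adj[[u]]$nb; wv <- adj[[u]]$w
    sel <- nb > u & comm[nb] == comm[u]
    w_in[comm[u]] <- w_in[comm[u]] + sum(wv[sel])
  }
  sum(w_in / m) - resolution * sum((s_tot / (2 * m))^2)
}

#' Louvain community detection (weighted, two-phase)
#'
#' Greedy modularity maximization: repeated passes of local node moves (each
#' node joins the neighboring module with the largest modularity gain, ties
#' broken by lowest module id), followed by aggregation of modules into
#' supernodes, iterated until the modularity gain between levels falls
#' below `tolerance`. Node visit order is a seeded random permutation per
#' pass, so results are deterministic given `seed`.
#'
#' @param network A non-empty `psn_network`.
#' @param seed Integer seed controlling visit order.
#' @param tolerance Minimum between-level modularity gain to continue.
#' @param resolution Resolution parameter (1 = classic modularity).
#' @param n_restarts Independent seeded restarts; the best-Q partition is
#'   returned (greedy local moves can lock into a suboptimum on small
#'   graphs; a handful of restarts removes this in practice).
#' @return A `psn_partition`; its `modularity` field is recomputed from the
#'   final assignment with [modularity_score()].
#' @export
louvain <- function(network, seed = 1L, tolerance = 1e-7, resolution = 1.0,
                    n_restarts = 10L) {
  best <- NULL
  for (r in seq_len(max(1L, n_restarts))) {
    part <- louvain_once(network, seed = as.integer(seed) + (r - 1L) * 7919L,
                         tolerance = tolerance, resolution = resolution)
    if (is.null(best) ||
        (!is.na(part$modularity) && part$modularity > best$modularity)) {
      best <- part
    }
  }
  best$seed <- as.integer(seed)
  best$parameters$n_restarts <- as.integer(n_restarts)
  best
}

louvain_once <- function(network, seed, tolerance, resolution) {
  stopifnot(inherits(network, "psn_network"))
  nodes <- network$nodes
  if (length(nodes) == 0) {
    stop_psn("psn_empty_network", "cannot partition an empty network")
  }
  e <- network$edges
  if (nrow(e) == 0) {
    membership <- stats::setNames(seq_along(nodes) - 1L, nodes)
    part <- structure(class = "psn_partition", list(
      membership = membership, modularity = NA_real_,
      n_modules = length(nodes), seed = as.integer(seed),
      parameters = list(tolerance = tolerance, resolution = resolution)
    ))
    return(part)
  }
  n <- length(nodes)
  ui <- match(e$u, nodes)
  vi <- match(e$v, nodes)
  adj <- replicate(n, list(nb = integer(0), w = numeric(0)), simplify = FALSE)
  for (t in seq_len(nrow(e))) {
    adj[[ui[t]]]$nb <- c(adj[[ui[t]]]$nb, vi[t])
    adj[[ui[t]]]$w <- c(adj[[ui[t]]]$w, e$weight[t])
    adj[[vi[t]]]$nb <- c(adj[[vi[t]]]$nb, ui[t])
    adj[[vi[t]]]$w <- c(adj[[vi[t]]]$w, e$weight[t])
  }
  self <- numeric(n)
  m <- sum(e$weight)
  assignment <- seq_len(n)  # original node -> current supernode
  with_seed(seed, {
    q_prev <- louvain_q(adj, self, seq_along(adj), m, resolution)
    repeat {
      res <- louvain_local_phase(adj, self, m, resolution)
      if (!res$improved) break
      agg <- louvain_aggregate(adj, self, res$comm)
      assignment <- agg$comm2[res$comm[assignment]]
      adj <- agg$adj
      self <- agg$self
      q_now <- louvain_q(adj, self, seq_along(adj), m, resolution)
      if (q_now - q_prev < tolerance) break
      q_prev <- q_now
    }
  })
  membership <- stats::setNames(assignment, nodes)
  new_psn_partition(membership, network, resolution = resolution,
                    seed = as.integer(seed),
                    parameters = list(tolerance = tolerance,
                                      resolution = resolution))
}

#' Module size table
#'
#' Sizes and share-of-network percentages per module, sorted by decreasing
#' size. Shares are computed against the network node count and rounded to
#' one decimal (e.g. a module of 860 nodes in a 4,418-node network is
#' 19.5%).
#'
#' @param partition A `psn_partition`.
#' @return Data frame with columns `module`, `size`, `share` (percent).
#' @export
module_size_table <- function(partition) {
  stopifnot(inherits(partition, "psn_partition"))
  tab <- table(partition$membership)
  n <- length(partition$membership)
  out <- data.frame(
    module = as.integer(names(tab)),
    size = as.integer(tab),
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$size, out$module), , drop = FALSE]
  out$share <- round(100 * out$size / n, 1)
  rownames(out) <- NULL
  out
}

#' Write / read a partition
#'
#' Two files: a 2-column TSV `node_id<TAB>module_id` at `path`, and JSON
#' metadata (modularity, module count, seed, parameters) at `paste0(path,
#' ".meta.json")`.
#'
#' @param partition A `psn_partition`.
#' @param path TSV path.
#' @param network Network the partition was computed on (used on read to
#'   restore modularity; optional).
#' @return `path` (write) or a `psn_partition` (read).
#' @export
write_partition <- function(partition, path) {
  d <- data.frame(node_id = names(partition$membership),
                  module_id = unname(partition$membership))
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, fileEncoding = "UTF-8")
  meta <- list(modularity = partition$modularity,
               n_modules = partition$n_modules,
               seed = partition$seed,
               parameters = partition$parameters)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_partition
#' @export
read_partition <- function(path, network = NULL) {
  d <- utils::read.delim(path, colClasses = c("character", "integer"))
  membership <- stats::setNames(d$module_id, d$node_id)
  meta_path <- paste0(path, ".meta.json")
  meta <- if (file.exists(meta_path)) jsonlite::fromJSON(meta_path) else list()
  part <- structure(class = "psn_partition", list(
    membership = membership[order(names(membership))],
    modularity = meta$modularity %||% NA_real_,
    n_modules = length(unique(membership)),
    seed = meta$seed %||% NA_integer_,
    parameters = meta$parameters %||% list()
  ))
  if (!is.null(network)) {
    part$modularity <- modularity_score(network, part)
  }
  part
}
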