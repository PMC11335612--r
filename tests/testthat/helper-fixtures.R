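# Fixture builders and independent oracles shared across the suite.
# Oracles are deliberately naive (loops, enumeration, closed forms) and
# share no code with the implementation paths they check.

# one-row cohort data frame; list fields passed as character vectors,
# NULL = missing
rec <- function(pid, aid = paste0(pid, "-a1"), date = "2020-01-01",
                age = 60L, sex = "male",
                main = character(0), general = character(0),
                tongue = character(0), pulse = character(0),
                dx = "chronic gastritis", icd = character(0),
                herbs = character(0), discharge = character(0),
                outcome = "improvement") {
  d <- data.frame(patient_id = pid, admission_id = aid,
                  admission_date = as.Date(date), age = age, sex = sex,
                  stringsAsFactors = FALSE)
  d$main_symptoms <- list(main)
  d$general_symptoms <- list(general)
  d$tongue_features <- list(tongue)
  d$pulse_features <- list(pulse)
  d$tcm_diagnoses <- list(dx)
  d$icd_codes <- list(icd)
  d$herbs <- list(herbs)
  d$discharge_symptoms <- list(discharge)
  d$outcome <- outcome
  d[psnstrat:::COHORT_COLUMNS]
}

cohort_of <- function(...) do.call(rbind, list(...))

# identity dictionary over a set of symptom terms (plus other classes)
identity_dict <- function(symptoms = character(0), tongue = character(0),
                          pulse = character(0), dx = "chronic gastritis",
                          herbs = character(0)) {
  data.frame(
    raw_term = c(symptoms, tongue, pulse, dx, herbs),
    canonical_term = c(symptoms, tongue, pulse, dx, herbs),
    feature_class = c(rep("symptom", length(symptoms)),
                      rep("tongue", length(tongue)),
                      rep("pulse", length(pulse)),
                      rep("diagnosis", length(dx)),
                      rep("herb", length(herbs))),
    stringsAsFactors = FALSE
  )
}

# --- PSN oracle: brute-force all-pairs three-step construction ------------
brute_force_psn <- function(records, main_threshold = 0.8) {
  n <- nrow(records)
  edges <- list()
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i >= j) next
      mi <- unique(unlist(records$main_symptoms[i]))
      mj <- unique(unlist(records$main_symptoms[j]))
      gi <- unique(unlist(records$general_symptoms[i]))
      gj <- unique(unlist(records$general_symptoms[j]))
      if (length(mi) == 0 || length(mj) == 0) next
      if (length(gi) == 0 || length(gj) == 0) next
      jm <- length(intersect(mi, mj)) / length(union(mi, mj))
      if (jm < main_threshold) next
      ig <- length(intersect(gi, gj))
      if (ig == 0) next
      jg <- ig / length(union(gi, gj))
      u <- records$patient_id[i]; v <- records$patient_id[j]
      edges[[length(edges) + 1]] <- data.frame(
        u = min(u, v), v = max(u, v), weight = jg,
        stringsAsFactors = FALSE)
    }
  }
  if (length(edges) == 0) {
    return(data.frame(u = character(0), v = character(0),
                      weight = numeric(0)))
  }
  out <- do.call(rbind, edges)
  out <- out[order(out$u, out$v), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# --- modularity oracle: dense-matrix definition ---------------------------
modularity_oracle <- function(network, membership, resolution = 1) {
  nodes <- network$nodes
  n <- length(nodes)
  a <- matrix(0, n, n, dimnames = list(nodes, nodes))
  for (t in seq_len(nrow(network$edges))) {
    u <- network$edges$u[t]; v <- network$edges$v[t]
    w <- network$edges$weight[t]
    a[u, v] <- a[u, v] + w
    a[v, u] <- a[v, u] + w
  }
  k <- rowSums(a)
  m2 <- sum(a)  # 2m
  q <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (membership[nodes[i]] == membership[nodes[j]]) {
        q <- q + a[i, j] - resolution * k[i] * k[j] / m2
      }
    }
  }
  as.numeric(q / m2)
}

# all set partitions of 1..n as lists of membership vectors
# (restricted-growth-string enumeration)
all_partitions <- function(n) {
  out <- list()
  grow <- function(prefix, maxid) {
    if (length(prefix) == n) {
      out[[length(out) + 1]] <<- prefix
      return(invisible())
    }
    for (b in seq_len(maxid + 1)) {
      grow(c(prefix, b), max(maxid, b))
    }
  }
  grow(integer(0), 0L)
  out
}

# exhaustive-search modularity optimum over all partitions
best_modularity <- function(network, resolution = 1) {
  nodes <- network$nodes
  parts <- all_partitions(length(nodes))
  best <- -Inf
  for (p in parts) {
    q <- modularity_oracle(network, stats::setNames(p, nodes), resolution)
    if (q > best) best <- q
  }
  best
}

# small weighted network straight from an edge triple list
net_of <- function(...) {
  e <- do.call(rbind, lapply(list(...), function(x) {
    data.frame(u = as.character(x[[1]]), v = as.character(x[[2]]),
               weight = as.numeric(x[[3]]), stringsAsFactors = FALSE)
  }))
  psnstrat:::new_psn_network(unique(c(e$u, e$v)), e)
}

# unit-weight graph helpers
triangle <- function(a, b, c) {
  list(list(a, b, 1), list(b, c, 1), list(a, c, 1))
}
clique_edges <- function(ids) {
  out <- list()
  for (i in seq_along(ids)) {
    for (j in seq_along(ids)) {
      if (i < j) out[[length(out) + 1]] <- list(ids[i], ids[j], 1)
    }
  }
  out
}

# --- 2x2 chi-square closed-form oracle ------------------------------------
chi2_closed_form <- function(c_ij, c_i, c_j, n) {
  a <- as.numeric(c_ij); b <- as.numeric(c_i - c_ij)
  c2 <- as.numeric(c_j - c_ij); d <- as.numeric(n - c_i - c_j + c_ij)
  n <- as.numeric(n)
  n * (a * d - b * c2)^2 /
    ((a + b) * (c2 + d) * (a + c2) * (b + d))
}

# --- ARI oracle: direct pair counting -------------------------------------
ari_oracle <- function(a, b) {
  n <- length(a)
  s11 <- s00 <- s10 <- s01 <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i >= j) next
      same_a <- a[i] == a[j]; same_b <- b[i] == b[j]
      if (same_a && same_b) s11 <- s11 + 1
      else if (!same_a && !same_b) s00 <- s00 + 1
      else if (same_a) s10 <- s10 + 1
      else s01 <- s01 + 1
    }
  }
  tot <- s11 + s00 + s10 + s01
  expected <- (s11 + s10) * (s11 + s01) / tot
  maxi <- ((s11 + s10) + (s11 + s01)) / 2
  if (maxi == expected) return(1)
  (s11 - expected) / (maxi - expected)
}

# --- BigClam likelihood oracle --------------------------------------------
bigclam_ll_oracle <- function(f, edges) {
  # edges: 2-column matrix of node indices; f: n x k
  n <- nrow(f)
  adj <- matrix(FALSE, n, n)
  for (t in seq_len(nrow(edges))) {
    adj[edges[t, 1], edges[t, 2]] <- TRUE
    adj[edges[t, 2], edges[t, 1]] <- TRUE
  }
  ll <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i >= j) next
      s <- sum(f[i, ] * f[j, ])
      if (adj[i, j]) {
        ll <- ll + log(1 - exp(-max(s, 1e-10)))
      } else {
        ll <- ll - s
      }
    }
  }
  ll
}
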