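# Independent reference implementations used as oracles. These are
# deliberately naive (dictionaries, exhaustive enumeration) and share no
# code with the package internals they check.

# Exhaustive between-class-variance maximization over all split points;
# ties resolved at the smallest level.
brute_otsu <- function(counts) {
  levels <- seq_along(counts) - 1
  total <- sum(counts)
  best <- -Inf
  best_t <- NA_integer_
  for (t in levels) {
    lo <- levels <= t
    w0 <- sum(counts[lo])
    w1 <- total - w0
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum(counts[lo] * levels[lo]) / w0
    mu1 <- sum(counts[!lo] * levels[!lo]) / w1
    sb <- (w0 / total) * (w1 / total) * (mu0 - mu1)^2
    if (sb > best + 1e-9) {
      best <- sb
      best_t <- as.integer(t)
    }
  }
  list(t = best_t, sigma_b2 = best)
}

# Naive replay of the sorted-edge merge procedure with a plain region
# dictionary (list of pixel sets); returns row-major region ids.
oracle_replay <- function(img, connectivity, k_scale) {
  g <- sort_edges(build_graph(img, connectivity))
  n <- g$n_vertices
  reg_of <- seq_len(n)
  members <- as.list(seq_len(n))
  internal <- rep(0, n)
  e <- g$edges
  for (r in seq_len(nrow(e))) {
    a <- reg_of[e$i[r]]
    b <- reg_of[e$j[r]]
    if (a == b) next
    w <- e$w[r]
    dt <- min(internal[a] + k_scale / length(members[[a]]),
              internal[b] + k_scale / length(members[[b]]))
    if (w <= dt) {
      members[[a]] <- c(members[[a]], members[[b]])
      reg_of[members[[b]]] <- a
      internal[a] <- max(internal[a], internal[b], w)
      members[[b]] <- integer(0)
    }
  }
  reg_of
}

# Connected components of constant intensity by breadth-first search.
bfs_constant_components <- function(px, connectivity = 8L) {
  h <- nrow(px); w <- ncol(px)
  lab <- matrix(0L, h, w)
  nxt <- 0L
  offs <- if (connectivity == 8L) {
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    cbind(c(-1, 0, 0, 1), c(0, -1, 1, 0))
  }
  for (r0 in seq_len(h)) for (c0 in seq_len(w)) {
    if (lab[r0, c0] > 0L) next
    nxt <- nxt + 1L
    queue <- matrix(c(r0, c0), 1)
    lab[r0, c0] <- nxt
    while (nrow(queue) > 0L) {
      cur <- queue[1, ]; queue <- queue[-1, , drop = FALSE]
      for (k in seq_len(nrow(offs))) {
        rr <- cur[1] + offs[k, 1]; cc <- cur[2] + offs[k, 2]
        if (rr >= 1 && rr <= h && cc >= 1 && cc <= w &&
            lab[rr, cc] == 0L && px[rr, cc] == px[cur[1], cur[2]]) {
          lab[rr, cc] <- nxt
          queue <- rbind(queue, c(rr, cc))
        }
      }
    }
  }
  lab
}

# Canonical form of a labeling: relabel by first appearance in
# row-major order, so partitions can be compared up to renumbering.
canon_rowmajor <- function(labels) {
  v <- if (is.matrix(labels)) as.vector(t(labels)) else labels
  match(v, unique(v))
}

# AUC by exhaustive pair counting: concordant pairs + half the ties.
brute_auc <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# Maximum-cardinality minimum-cost assignment by exhaustive enumeration
# over all injective maps from the smaller side (tiny inputs only).
brute_matching <- function(pairs, n_left, n_right) {
  best_card <- 0L
  best_cost <- Inf
  cost_mat <- matrix(Inf, n_left, n_right)
  cost_mat[cbind(pairs$l, pairs$r)] <- pairs$cost
  subsets <- function(v) {
    out <- list(integer(0))
    for (x in v) out <- c(out, lapply(out, function(s) c(s, x)))
    out
  }
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      out <- c(out, lapply(perms(v[-i]), function(p) c(v[i], p)))
    out
  }
  for (ls in subsets(seq_len(n_left))) {
    if (length(ls) > n_right) next
    for (rsub in subsets(seq_len(n_right))) {
      if (length(rsub) != length(ls)) next
      for (rp in perms(rsub)) {
        cost <- sum(cost_mat[cbind(ls, rp)])
        if (!is.finite(cost)) next
        if (length(ls) > best_card ||
            (length(ls) == best_card && cost < best_cost)) {
          best_card <- length(ls)
          best_cost <- cost
        }
      }
    }
  }
  list(cardinality = best_card, cost = best_cost)
}

random_gray_image <- function(h, w, max_level = 255L, levels = NULL) {
  vals <- if (is.null(levels)) sample(0:max_level, h * w, replace = TRUE)
          else sample(levels, h * w, replace = TRUE)
  gray_image(matrix(as.integer(vals), h, w), max_level = max_level)
}
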