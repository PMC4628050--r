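# Minimum-cost maximum-cardinality bipartite matching by successive
# shortest augmenting paths: this is unit-capacity min-cost flow with a
# super-source over all free left nodes, so each augmentation uses the
# globally shortest path (SPFA label-correcting search on the residual
# graph, which handles the negative reverse arcs exactly) and the final
# matching is the cheapest one of maximum cardinality.
#
# adj_r[[l]], adj_c[[l]]: admissible right nodes and costs for left l.
# Returns list(match_l, match_r, total_cost); 0 = unmatched.
min_cost_max_matching <- function(n_left, n_right, adj_r, adj_c) {
  match_l <- integer(n_left)
  match_r <- integer(n_right)
  cost_r <- numeric(n_right) # cost of the edge currently matching r
  eps <- 1e-12
  repeat {
    sources <- which(match_l == 0L &
                       vapply(adj_r, length, integer(1)) > 0L)
    if (length(sources) == 0L) break
    dist_l <- rep(Inf, n_left)
    dist_r <- rep(Inf, n_right)
    prev_r <- integer(n_right)
    dist_l[sources] <- 0
    queue <- sources
    in_queue <- logical(n_left)
    in_queue[sources] <- TRUE
    while (length(queue) > 0L) {
      l <- queue[[1L]]
      queue <- queue[-1L]
      in_queue[l] <- FALSE
      rs <- adj_r[[l]]
      nd <- dist_l[l] + adj_c[[l]]
      upd <- nd < dist_r[rs] - eps
      if (!any(upd)) next
      rr <- rs[upd]
      dist_r[rr] <- nd[upd]
      prev_r[rr] <- l
      ml <- match_r[rr]
      has <- ml > 0L
      if (any(has)) {
        back_l <- ml[has]
        ndl <- dist_r[rr[has]] - cost_r[rr[has]]
        better <- ndl < dist_l[back_l] - eps
        if (any(better)) {
          bl <- back_l[better]
          dist_l[bl] <- ndl[better]
          push <- bl[!in_queue[bl]]
          if (length(push)) {
            queue <- c(queue, push)
            in_queue[push] <- TRUE
          }
        }
      }
    }
    free_r <- which(match_r == 0L & is.finite(dist_r))
    if (length(free_r) == 0L) break
    target <- free_r[which.min(dist_r[free_r])]
    r <- target
    repeat {
      l <- prev_r[r]
      prev_match <- match_l[l]
      match_l[l] <- r
      match_r[r] <- l
      cost_r[r] <- adj_c[[l]][match(r, adj_r[[l]])]
      if (prev_match == 0L) break # reached a free (source) left node
      r <- prev_match
    }
  }
  list(match_l = match_l, match_r = match_r, total_cost = sum(cost_r))
}

# Greedy nearest-unmatched fallback for very large edgel sets: matches
# admissible pairs in ascending distance order. Maximal, not maximum.
greedy_matching <- function(n_left, n_right, pairs) {
  ord <- order(pairs$cost, pairs$l, pairs$r)
  match_l <- integer(n_left)
  match_r <- integer(n_right)
  total <- 0
  for (k in ord) {
    l <- pairs$l[k]; r <- pairs$r[k]
    if (match_l[l] == 0L && match_r[r] == 0L) {
      match_l[l] <- r
      match_r[r] <- l
      total <- total + pairs$cost[k]
    }
  }
  list(match_l = match_l, match_r = match_r, total_cost = total)
}
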