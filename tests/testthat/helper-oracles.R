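# Independent oracles used across the test files. They re-derive quantities
# by exhaustive enumeration or direct definition, never by calling the code
# paths they check.

# --- exhaustive DTL reconciliation oracle -----------------------------------
# Enumerates every mapping of internal virus nodes onto host nodes; given a
# full placement the per-node event label choices are independent, so the
# minimum cost is the sum of per-node minima and the MPR count the product of
# per-node argmin label counts, summed over optimal placements.
brute_force_dtl <- function(virus_tree, host_tree, map,
                            costs = c(cospeciation = 0, transfer = 1,
                                      duplication = 1, loss = 1)) {
  stopifnot(ape::is.binary(virus_tree), ape::is.binary(host_tree))
  nh <- ape::Ntip(host_tree); NH <- nh + host_tree$Nnode
  np <- ape::Ntip(virus_tree); NP <- np + virus_tree$Nnode
  # ancestor-or-self and depth matrices for the host
  anc <- matrix(FALSE, NH, NH); diag(anc) <- TRUE
  for (e in ape::postorder(host_tree)) {
    p <- host_tree$edge[e, 1]; ch <- host_tree$edge[e, 2]
    anc[p, ] <- anc[p, ] | anc[ch, ]
  }
  depth <- rep(0L, NH)
  for (e in rev(ape::postorder(host_tree)))
    depth[host_tree$edge[e, 2]] <- depth[host_tree$edge[e, 1]] + 1L
  ddist <- matrix(Inf, NH, NH)            # edges from a down to b when a anc b
  for (a in seq_len(NH)) for (b in seq_len(NH))
    if (anc[a, b]) ddist[a, b] <- depth[b] - depth[a]
  kids <- matrix(NA_integer_, NH, 2)
  for (e in seq_len(nrow(host_tree$edge))) {
    p <- host_tree$edge[e, 1]; ch <- host_tree$edge[e, 2]
    kids[p, if (is.na(kids[p, 1])) 1 else 2] <- ch
  }
  pkids <- matrix(NA_integer_, NP, 2)
  for (e in seq_len(nrow(virus_tree$edge))) {
    p <- virus_tree$edge[e, 1]; ch <- virus_tree$edge[e, 2]
    pkids[p, if (is.na(pkids[p, 1])) 1 else 2] <- ch
  }
  sigma <- match(map$host_tip[match(virus_tree$tip.label, map$virus_tip)],
                 host_tree$tip.label)
  internals <- (np + 1L):NP
  grid <- as.matrix(expand.grid(rep(list(seq_len(NH)), length(internals))))
  place <- function(node, row) {
    if (node <= np) rep(sigma[node], nrow(grid)) else grid[, match(node, internals)]
  }
  total <- rep(0, nrow(grid)); count <- rep(1, nrow(grid))
  incomp <- !anc & !t(anc)
  for (p in internals) {
    h <- place(p); m1 <- place(pkids[p, 1]); m2 <- place(pkids[p, 2])
    ij <- function(a, b) cbind(a, b)
    candidate <- matrix(Inf, nrow(grid), 4)  # D, T(c2 jumps), T(c1 jumps), S
    d1 <- ddist[ij(h, m1)]; d2 <- ddist[ij(h, m2)]
    candidate[, 1] <- costs[["duplication"]] + costs[["loss"]] * (d1 + d2)
    jump2 <- incomp[ij(h, m2)]; jump1 <- incomp[ij(h, m1)]
    candidate[jump2, 2] <- costs[["transfer"]] + costs[["loss"]] * d1[jump2]
    candidate[jump1, 3] <- costs[["transfer"]] + costs[["loss"]] * d2[jump1]
    hin <- !is.na(kids[h, 1])
    if (any(hin)) {
      h1 <- kids[h, 1]; h2 <- kids[h, 2]
      s12 <- hin & anc[ij(h1, m1)] & anc[ij(h2, m2)]
      s21 <- hin & anc[ij(h1, m2)] & anc[ij(h2, m1)]
      candidate[s12, 4] <- costs[["cospeciation"]] +
        costs[["loss"]] * (ddist[ij(h1, m1)][s12] + ddist[ij(h2, m2)][s12])
      candidate[s21, 4] <- costs[["cospeciation"]] +
        costs[["loss"]] * (ddist[ij(h1, m2)][s21] + ddist[ij(h2, m1)][s21])
    }
    mn <- do.call(pmin, as.data.frame(candidate))
    nlab <- rowSums(candidate <= mn + 1e-9 & is.finite(candidate))
    total <- total + mn
    count <- count * nlab
  }
  best <- min(total)
  list(min_cost = best,
       mpr_count = if (is.finite(best))
         sum(count[abs(total - best) <= 1e-9]) else 0)
}

# random reconciliation instance: host tree, virus tree, random tip map
random_dtl_instance <- function(n_virus, n_host) {
  host <- ape::rtree(n_host)
  host$tip.label <- paste0("H", seq_len(n_host))
  host$edge.length <- NULL
  virus <- ape::rtree(n_virus)
  virus$tip.label <- paste0("v", seq_len(n_virus))
  virus$edge.length <- NULL
  map <- data.frame(virus_tip = virus$tip.label,
                    host_tip = sample(host$tip.label, n_virus, replace = TRUE),
                    stringsAsFactors = FALSE)
  list(virus = virus, host = host, map = map)
}

# --- independent bipartition enumeration ------------------------------------
# Splits via tip x tip path matrices: for each internal edge, the side of the
# split is recovered by deleting the edge and flooding the adjacency graph.
brute_force_splits <- function(tree) {
  n <- ape::Ntip(tree)
  if (n < 4) return(character(0))
  edges <- tree$edge
  adj <- lapply(seq_len(n + tree$Nnode), function(i) integer(0))
  for (e in seq_len(nrow(edges))) {
    a <- edges[e, 1]; b <- edges[e, 2]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  out <- character(0)
  for (e in seq_len(nrow(edges))) {
    a <- edges[e, 1]; b <- edges[e, 2]
    # flood from b with the edge (a,b) removed
    seen <- rep(FALSE, length(adj)); seen[b] <- TRUE
    queue <- b
    while (length(queue) > 0) {
      v <- queue[[1]]; queue <- queue[-1]
      for (w in adj[[v]]) {
        if ((v == a && w == b) || (v == b && w == a)) next
        if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
      }
    }
    side <- sort(tree$tip.label[which(seen[seq_len(n)])])
    if (length(side) < 2 || length(side) > n - 2) next
    other <- sort(setdiff(tree$tip.label, side))
    key <- if (length(side) < length(other) ||
               (length(side) == length(other) && min(side) < min(other))) {
      paste(side, collapse = "\r")
    } else paste(other, collapse = "\r")
    out <- c(out, key)
  }
  sort(unique(out))
}

random_bltree <- function(n) {
  tr <- ape::rtree(n)
  tr$tip.label <- paste0("t", seq_len(n))
  tr
}

random_dtl_instance_seeded <- function(n_virus, n_host, seed) {
  set.seed(seed)
  random_dtl_instance(n_virus, n_host)
}

# canonical split keys via the exported bipartition interface
split_keys_test <- function(tree) {
  vapply(picobirnatax::bipartitions(tree), paste, "", collapse = "\r")
}
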