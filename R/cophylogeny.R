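#' Virus-host congruence: tip-host maps
#'
#' A tip-host map links each virus tip to one tip of the host cladogram, and
#' optionally each host tip to a host/source category (e.g. "Primate",
#' "Microbial-aquatic"). Maps are plain data frames with columns
#' \code{virus_tip}, \code{host_tip} and optionally \code{host_category}.
#'
#' @param path TSV file with columns \code{virus_tip}, \code{host_tip}
#'   (optional \code{host_category}).
#' @return a validated data frame.
#' @export
read_tip_host_map <- function(path) {
  df <- read_tsv_plain(path)
  validate_tip_host_map(df)
}

#' @rdname read_tip_host_map
#' @param map a data frame with the columns described above.
#' @export
validate_tip_host_map <- function(map) {
  need <- c("virus_tip", "host_tip")
  miss <- setdiff(need, names(map))
  if (length(miss) > 0L)
    stopf("tip-host map lacks column(s): %s", paste(miss, collapse = ", "))
  dup <- unique(map$virus_tip[duplicated(map$virus_tip)])
  if (length(dup) > 0L)
    stopf("virus tip(s) mapped more than once: %s", paste(dup, collapse = ", "))
  map
}

#' Expand a host cladogram to the virus tip set
#'
#' Bridges the unequal leaf sets of a virus tree and a host cladogram before
#' topological comparison: each host tip carrying k mapped virus tips becomes a
#' polytomy of those k tips (or is relabelled when k = 1); host tips with no
#' mapped virus are pruned.
#'
#' @param host_cladogram a \code{phylo} object.
#' @param map a tip-host map (see \code{\link{read_tip_host_map}}).
#' @return a \code{phylo} object whose tip set equals \code{map$virus_tip}.
#' @export
expand_host_tree <- function(host_cladogram, map) {
  map <- validate_tip_host_map(map)
  missing <- setdiff(unique(map$host_tip), host_cladogram$tip.label)
  if (length(missing) > 0L)
    stopf("virus tip(s) mapped to host(s) absent from the cladogram: %s",
          paste(missing, collapse = ", "))
  used <- intersect(host_cladogram$tip.label, unique(map$host_tip))
  tr <- host_cladogram
  drop <- setdiff(tr$tip.label, used)
  if (length(drop) > 0L) {
    if (length(used) == 1L) {
      # everything maps to one host: star over the virus tips
      vt <- map$virus_tip
      return(parse_newick(paste0("(", paste(vt, collapse = ","), ");")))
    }
    tr <- ape::drop.tip(tr, drop)
  }
  # graft polytomies by Newick substitution on safe placeholder labels
  ph <- paste0("h__", seq_along(tr$tip.label))
  orig <- tr$tip.label
  tr$tip.label <- ph
  nwk <- ape::write.tree(tr)
  for (i in seq_along(ph)) {
    vt <- map$virus_tip[map$host_tip == orig[i]]
    rep <- if (length(vt) == 1L) vt else paste0("(", paste(vt, collapse = ","), ")")
    nwk <- sub(paste0(ph[i], "(?![0-9])"), rep, nwk, perl = TRUE)
  }
  out <- ape::read.tree(text = nwk)
  out$edge.length <- NULL
  out
}

#' Normalized PH85 (Penny-Hendy) distance between virus and host trees
#'
#' The topological distance underlying virus-host co-divergence tests: the
#' symmetric difference of the two trees' non-trivial bipartition sets, divided
#' by the total number of such bipartitions, giving a value in [0, 1]. 0 means
#' identical unrooted topologies (complete co-divergence); 1 means no shared
#' splits (complete cross-species transmission).
#'
#' Because many virus tips can map to one host tip, two comparison modes are
#' provided. \code{"expanded-host-tree"} (default) grafts each host tip into a
#' polytomy of its viruses (\code{\link{expand_host_tree}}) and compares once.
#' \code{"resample-one-per-host"} repeatedly draws one virus tip per host,
#' restricts both trees to the draw, and reports the mean distance.
#'
#' @param virus_tree a \code{phylo} object (>= 4 tips); treated as unrooted.
#' @param host_cladogram a \code{phylo} object; treated as unrooted.
#' @param map a tip-host map.
#' @param mode \code{"expanded-host-tree"} or \code{"resample-one-per-host"}.
#' @param resamples number of draws in resampling mode.
#' @param seed integer seed for resampling mode.
#' @return a list of class \code{nph85_result}: \code{distance},
#'   \code{mode}, \code{n_shared}, \code{n_virus_splits}, \code{n_host_splits}
#'   (diagnostics refer to the single comparison in expanded mode, means in
#'   resampling mode).
#' @export
nph85 <- function(virus_tree, host_cladogram, map,
                  mode = c("expanded-host-tree", "resample-one-per-host"),
                  resamples = 100L, seed = NULL) {
  mode <- match.arg(mode)
  map <- validate_tip_host_map(map)
  extra <- setdiff(virus_tree$tip.label, map$virus_tip)
  if (length(extra) > 0L)
    stopf("virus tip(s) without host mapping: %s", paste(extra, collapse = ", "))
  map <- map[map$virus_tip %in% virus_tree$tip.label, , drop = FALSE]
  if (ape::Ntip(virus_tree) < 4L) stopf("nph85 requires at least 4 virus tips")

  if (mode == "expanded-host-tree") {
    ht <- expand_host_tree(host_cladogram, map)
    res <- nph85_pair(virus_tree, ht)
    return(structure(c(res, list(mode = mode)), class = "nph85_result"))
  }

  hosts <- split(map$virus_tip, map$host_tip)
  with_seed(seed, {
    ds <- numeric(resamples); sh <- nv <- nh <- numeric(resamples)
    for (r in seq_len(resamples)) {
      pick <- vapply(hosts, function(v) v[sample.int(length(v), 1L)], "")
      if (length(pick) < 4L) stopf("fewer than 4 tips after one-per-host restriction")
      vt <- ape::keep.tip(virus_tree, pick)
      m2 <- map[map$virus_tip %in% pick, , drop = FALSE]
      ht <- expand_host_tree(host_cladogram, m2)
      p <- nph85_pair(vt, ht)
      ds[r] <- p$distance; sh[r] <- p$n_shared
      nv[r] <- p$n_virus_splits; nh[r] <- p$n_host_splits
    }
    structure(list(distance = mean(ds), n_shared = mean(sh),
                   n_virus_splits = mean(nv), n_host_splits = mean(nh),
                   mode = mode, per_draw = ds),
              class = "nph85_result")
  })
}

# normalized symmetric bipartition difference of two trees on the same tip set
nph85_pair <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label))
    stopf("trees have different tip sets")
  k1 <- split_keys(t1); k2 <- split_keys(t2)
  denom <- length(k1) + length(k2)
  shared <- length(intersect(k1, k2))
  d <- if (denom == 0L) 0 else (denom - 2L * shared) / denom
  list(distance = d, n_shared = shared,
       n_virus_splits = length(k1), n_host_splits = length(k2))
}

#' @export
print.nph85_result <- function(x, ...) {
  cat(sprintf("nPH85 distance: %.4f  (mode: %s)\n", x$distance, x$mode))
  cat(sprintf("  splits: virus %s, host %s, shared %s\n",
              format(x$n_virus_splits), format(x$n_host_splits), format(x$n_shared)))
  invisible(x)
}

#' Event costs for parsimony reconciliation
#'
#' Defaults follow the convention of charging nothing for co-divergence and a
#' unit cost for cross-species transmission (host switch), duplication and
#' extinction (loss).
#'
#' @param cospeciation,transfer,duplication,loss non-negative costs.
#' @return a named numeric vector of class \code{event_costs}.
#' @export
event_costs <- function(cospeciation = 0, transfer = 1, duplication = 1, loss = 1) {
  v <- c(cospeciation = cospeciation, transfer = transfer,
         duplication = duplication, loss = loss)
  if (any(v < 0)) stopf("event costs must be non-negative")
  structure(v, class = "event_costs")
}

# --- internal indexing helpers for the reconciliation DP --------------------

# children matrix, ancestor-or-self matrix, depth, incomparable index lists
host_index <- function(tree) {
  n <- ape::Ntip(tree); m <- tree$Nnode; N <- n + m
  if (any(tabulate(tree$edge[, 1], N) > 2L)) stopf("tree is not binary")
  kids <- matrix(NA_integer_, N, 2)
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    kids[p, if (is.na(kids[p, 1])) 1 else 2] <- ch
  }
  root <- n + 1L
  depth <- rep(NA_integer_, N); depth[root] <- 0L
  for (e in rev(ape::postorder(tree)))       # preorder over edges
    depth[tree$edge[e, 2]] <- depth[tree$edge[e, 1]] + 1L
  anc <- matrix(FALSE, N, N)                 # anc[a, d]: a is ancestor-or-self of d
  diag(anc) <- TRUE
  for (e in ape::postorder(tree)) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    anc[p, ] <- anc[p, ] | anc[ch, ]
  }
  incomp <- lapply(seq_len(N), function(v) which(!anc[v, ] & !anc[, v]))
  postn <- c(tree$edge[ape::postorder(tree), 2], root)  # children before parents
  list(n = n, N = N, root = root, kids = kids, depth = depth,
       anc = anc, incomp = incomp, postorder = postn)
}

# parasite postorder node sequence (children before parents, root last)
node_postorder <- function(tree) {
  c(tree$edge[ape::postorder(tree), 2], ape::Ntip(tree) + 1L)
}

#' Maximum-parsimony (DTL) reconciliation of a virus tree with a host tree
#'
#' Undated duplication-transfer-loss dynamic program. Each internal virus node
#' is mapped to a host node and labelled co-divergence, duplication, or
#' transfer (host switch); losses (extinctions) are charged per host edge
#' crossed while a lineage is passed down the host tree. Transfers may land on
#' any host edge not ancestrally related to the donor (the host tree is an
#' undated cladogram, so no further time consistency is imposed). The program
#' returns the minimum total event cost and the exact number of distinct
#' minimum-cost reconciliations (MPRs), counted alongside the minimum.
#'
#' Host-tree polytomies are resolved deterministically under \code{seed}
#' before the DP (the resolution used is returned for audit); virus-tree
#' polytomies are an error.
#'
#' @param virus_tree rooted, fully resolved \code{phylo}.
#' @param host_cladogram rooted \code{phylo}; polytomies allowed.
#' @param map a tip-host map covering every virus tip.
#' @param costs an \code{\link{event_costs}} vector.
#' @param seed seed for the (deterministic) polytomy resolution.
#' @return an object of class \code{dtl_reconciliation}: \code{min_cost},
#'   \code{mpr_count}, the DP tables, and the (possibly resolved) host tree.
#' @seealso \code{\link{event_likelihoods}} to sample reconciliations.
#' @export
reconcile_mpr <- function(virus_tree, host_cladogram, map,
                          costs = event_costs(), seed = 1L) {
  map <- validate_tip_host_map(map)
  if (!ape::is.binary(virus_tree))
    stopf("virus tree contains polytomies; resolve it before reconciliation")
  if (!ape::is.rooted(virus_tree)) stopf("virus tree must be rooted")
  host <- host_cladogram
  resolved <- FALSE
  if (!ape::is.binary(host)) {
    host <- with_seed(seed, ape::multi2di(host, random = TRUE))
    resolved <- TRUE
  }
  if (!ape::is.rooted(host)) stopf("host tree must be rooted")
  unmapped <- setdiff(virus_tree$tip.label, map$virus_tip)
  if (length(unmapped) > 0L)
    stopf("unmapped virus tip(s): %s", paste(unmapped, collapse = ", "))
  bad <- setdiff(map$host_tip[match(virus_tree$tip.label, map$virus_tip)],
                 host$tip.label)
  if (length(bad) > 0L)
    stopf("host(s) absent from cladogram: %s", paste(bad, collapse = ", "))

  H <- host_index(host)
  np <- ape::Ntip(virus_tree); NP <- np + virus_tree$Nnode
  pkids <- matrix(NA_integer_, NP, 2)
  for (e in seq_len(nrow(virus_tree$edge))) {
    p <- virus_tree$edge[e, 1]; ch <- virus_tree$edge[e, 2]
    pkids[p, if (is.na(pkids[p, 1])) 1 else 2] <- ch
  }
  sigma <- match(map$host_tip[match(virus_tree$tip.label, map$virus_tip)],
                 host$tip.label)

  cS <- costs[["cospeciation"]]; cT <- costs[["transfer"]]
  cD <- costs[["duplication"]]; cL <- costs[["loss"]]

  E <- matrix(Inf, NP, H$N); NE <- matrix(0, NP, H$N)
  IN <- matrix(Inf, NP, H$N); NIN <- matrix(0, NP, H$N)
  OUT <- matrix(Inf, NP, H$N); NOUT <- matrix(0, NP, H$N)

  hpost <- H$postorder
  internal_h <- which(!is.na(H$kids[, 1]))

  fill_in_out <- function(p) {
    for (h in hpost) {
      cand <- E[p, h]; cnt <- NE[p, h]
      k <- H$kids[h, ]
      if (!is.na(k[1])) {
        for (hc in k) {
          v <- IN[p, hc] + cL
          if (v < cand - 1e-9) { cand <- v; cnt <- NIN[p, hc] }
          else if (abs(v - cand) <= 1e-9 && is.finite(v)) cnt <- cnt + NIN[p, hc]
        }
      }
      IN[p, h] <<- cand; NIN[p, h] <<- cnt
    }
    for (h in seq_len(H$N)) {
      inc <- H$incomp[[h]]
      if (length(inc) == 0L) { OUT[p, h] <<- Inf; NOUT[p, h] <<- 0; next }
      v <- E[p, inc]
      mn <- min(v)
      OUT[p, h] <<- mn
      NOUT[p, h] <<- if (is.finite(mn)) sum(NE[p, inc][abs(v - mn) <= 1e-9]) else 0
    }
  }

  for (p in node_postorder(virus_tree)) {
    if (p <= np) {
      E[p, ] <- Inf; E[p, sigma[p]] <- 0
      NE[p, ] <- 0; NE[p, sigma[p]] <- 1
      fill_in_out(p)
      next
    }
    c1 <- pkids[p, 1]; c2 <- pkids[p, 2]
    best <- rep(Inf, H$N); cnt <- rep(0, H$N)
    addc <- function(v, k) {
      lt <- v < best - 1e-9
      best[lt] <<- v[lt]; cnt[lt] <<- k[lt]
      eq <- abs(v - best) <= 1e-9 & is.finite(v) & !lt
      cnt[eq] <<- cnt[eq] + k[eq]
    }
    # duplication at h
    addc(cD + IN[c1, ] + IN[c2, ], NIN[c1, ] * NIN[c2, ])
    # transfer at h (either child jumps)
    addc(cT + IN[c1, ] + OUT[c2, ], NIN[c1, ] * NOUT[c2, ])
    addc(cT + IN[c2, ] + OUT[c1, ], NIN[c2, ] * NOUT[c1, ])
    # co-divergence at internal h
    if (length(internal_h) > 0L) {
      h1 <- H$kids[internal_h, 1]; h2 <- H$kids[internal_h, 2]
      for (sw in 1:2) {
        a <- if (sw == 1) c1 else c2; b <- if (sw == 1) c2 else c1
        v <- rep(Inf, H$N); k <- rep(0, H$N)
        v[internal_h] <- cS + IN[a, h1] + IN[b, h2]
        k[internal_h] <- NIN[a, h1] * NIN[b, h2]
        addc(v, k)
      }
    }
    E[p, ] <- best; NE[p, ] <- cnt
    fill_in_out(p)
  }

  proot <- np + 1L
  mn <- min(E[proot, ])
  mpr <- sum(NE[proot, abs(E[proot, ] - mn) <= 1e-9])
  structure(list(
    min_cost = unname(mn), mpr_count = unname(mpr),
    costs = costs, virus_tree = virus_tree, host_tree = host,
    host_resolved = resolved, host_index = H,
    sigma = sigma, pkids = pkids, n_virus_tips = np,
    E = E, NE = NE, IN = IN, NIN = NIN, OUT = OUT, NOUT = NOUT),
    class = "dtl_reconciliation")
}

#' @export
print.dtl_reconciliation <- function(x, ...) {
  cat(sprintf("DTL reconciliation: %d virus tips onto %d host tips\n",
              x$n_virus_tips, x$host_index$n))
  cat(sprintf("  minimum event cost: %g\n  optimal reconciliations (MPRs): %g\n",
              x$min_cost, x$mpr_count))
  if (x$host_resolved)
    cat("  (host polytomies were resolved deterministically before the DP)\n")
  invisible(x)
}

# sample one reconciliation uniformly from the MPRs by stochastic backtracking;
# returns event counts c(cospeciation, transfer, duplication, loss)
sample_one_mpr <- function(rec) {
  H <- rec$host_index
  ev <- c(cospeciation = 0, transfer = 0, duplication = 0, loss = 0)
  pick <- function(w) {
    if (length(w) == 1L) return(1L)
    sample.int(length(w), 1L, prob = w)
  }
  resolve_in <- function(p, h) {
    # descend via losses until stopping at a node where E attains IN
    repeat {
      opts <- list(); wts <- numeric(0)
      if (abs(E_at(p, h) - rec$IN[p, h]) <= 1e-9 && is.finite(rec$IN[p, h]) &&
          abs(rec$E[p, h] - rec$IN[p, h]) <= 1e-9) {
        opts[[length(opts) + 1L]] <- c(0L, h); wts <- c(wts, rec$NE[p, h])
      }
      k <- H$kids[h, ]
      if (!is.na(k[1])) {
        for (hc in k) {
          if (abs(rec$IN[p, hc] + rec$costs[["loss"]] - rec$IN[p, h]) <= 1e-9 &&
              is.finite(rec$IN[p, hc])) {
            opts[[length(opts) + 1L]] <- c(1L, hc); wts <- c(wts, rec$NIN[p, hc])
          }
        }
      }
      ch <- opts[[pick(wts)]]
      if (ch[1] == 0L) { resolve_e(p, ch[2]); return(invisible(NULL)) }
      ev["loss"] <<- ev["loss"] + 1
      h <- ch[2]
    }
  }
  E_at <- function(p, h) rec$E[p, h]
  resolve_out <- function(p, h) {
    inc <- H$incomp[[h]]
    v <- rec$E[p, inc]
    sel <- inc[abs(v - rec$OUT[p, h]) <= 1e-9 & is.finite(v)]
    w <- rec$NE[p, sel]
    resolve_e(p, sel[pick(w)])
  }
  resolve_e <- function(p, h) {
    if (p <= rec$n_virus_tips) return(invisible(NULL))
    c1 <- rec$pkids[p, 1]; c2 <- rec$pkids[p, 2]
    tgt <- rec$E[p, h]
    cs <- rec$costs
    opts <- list(); wts <- numeric(0)
    add <- function(tag, w) {
      opts[[length(opts) + 1L]] <<- tag; wts <<- c(wts, w)
    }
    v <- cs[["duplication"]] + rec$IN[c1, h] + rec$IN[c2, h]
    if (is.finite(v) && abs(v - tgt) <= 1e-9) add(list("D"), rec$NIN[c1, h] * rec$NIN[c2, h])
    v <- cs[["transfer"]] + rec$IN[c1, h] + rec$OUT[c2, h]
    if (is.finite(v) && abs(v - tgt) <= 1e-9) add(list("T", c1, c2), rec$NIN[c1, h] * rec$NOUT[c2, h])
    v <- cs[["transfer"]] + rec$IN[c2, h] + rec$OUT[c1, h]
    if (is.finite(v) && abs(v - tgt) <= 1e-9) add(list("T", c2, c1), rec$NIN[c2, h] * rec$NOUT[c1, h])
    k <- H$kids[h, ]
    if (!is.na(k[1])) {
      for (sw in 1:2) {
        a <- if (sw == 1) c1 else c2; b <- if (sw == 1) c2 else c1
        v <- cs[["cospeciation"]] + rec$IN[a, k[1]] + rec$IN[b, k[2]]
        if (is.finite(v) && abs(v - tgt) <= 1e-9)
          add(list("S", a, b), rec$NIN[a, k[1]] * rec$NIN[b, k[2]])
      }
    }
    ch <- opts[[pick(wts)]]
    if (ch[[1]] == "D") {
      ev["duplication"] <<- ev["duplication"] + 1
      resolve_in(c1, h); resolve_in(c2, h)
    } else if (ch[[1]] == "T") {
      ev["transfer"] <<- ev["transfer"] + 1
      resolve_in(ch[[2]], h); resolve_out(ch[[3]], h)
    } else {
      ev["cospeciation"] <<- ev["cospeciation"] + 1
      resolve_in(ch[[2]], k[1]); resolve_in(ch[[3]], k[2])
    }
  }
  proot <- rec$n_virus_tips + 1L
  roots <- which(abs(rec$E[proot, ] - rec$min_cost) <= 1e-9 &
                 is.finite(rec$E[proot, ]))
  h0 <- roots[pick(rec$NE[proot, roots])]
  resolve_e(proot, h0)
  ev
}

#' Event likelihoods over sampled optimal reconciliations
#'
#' Draws reconciliations uniformly at random from the set of maximum-parsimony
#' reconciliations (stochastic backtracking weighted by optimal-solution
#' counts) and reports each event type's share of all events, averaged over
#' the samples.
#'
#' @param rec a \code{\link{reconcile_mpr}} result.
#' @param n_samples number of reconciliations to draw (default 100).
#' @param seed integer seed; sampling is reproducible bit-for-bit.
#' @return an object of class \code{reconciliation_summary}: \code{min_cost},
#'   \code{mpr_count}, \code{sampled_reconciliations},
#'   \code{event_proportions} (named: cospeciation, transfer, duplication,
#'   loss; also aliased \code{extinction} = loss) and \code{per_sample}
#'   (matrix of event counts, one row per sample).
#' @export
event_likelihoods <- function(rec, n_samples = 100L, seed = 1L) {
  stopifnot(inherits(rec, "dtl_reconciliation"), n_samples >= 1L)
  per <- with_seed(seed, {
    t(vapply(seq_len(n_samples), function(i) sample_one_mpr(rec), numeric(4)))
  })
  colnames(per) <- c("cospeciation", "transfer", "duplication", "loss")
  tot <- rowSums(per)
  props <- colMeans(per / ifelse(tot == 0, 1, tot))
  if (all(tot == 0)) props[] <- 0
  structure(list(
    min_cost = rec$min_cost, mpr_count = rec$mpr_count,
    sampled_reconciliations = n_samples,
    event_proportions = c(props, extinction = unname(props[["loss"]])),
    per_sample = per),
    class = "reconciliation_summary")
}

#' @export
print.reconciliation_summary <- function(x, ...) {
  cat(sprintf("Reconciliation summary: min cost %g over %g MPR(s); %d sample(s)\n",
              x$min_cost, x$mpr_count, x$sampled_reconciliations))
  p <- x$event_proportions[c("cospeciation", "transfer", "duplication", "loss")]
  cat(sprintf("  co-divergence %.3f | transfer (CST) %.3f | duplication %.3f | loss (extinction) %.3f\n",
              p[1], p[2], p[3], p[4]))
  invisible(x)
}
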