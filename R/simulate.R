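#' Random Yule host tree
#'
#' @param n_tips number of host tips.
#' @param seed integer seed.
#' @return a rooted binary \code{phylo} with tips \code{H1..Hn}.
#' @export
sim_host_tree <- function(n_tips, seed = NULL) {
  with_seed(seed, {
    tr <- ape::rphylo(n_tips, birth = 1, death = 0)
    tr$tip.label <- paste0("H", seq_len(n_tips))
    tr$node.label <- NULL
    tr
  })
}

#' Simulate a virus tree descending a host tree under a DTL event model
#'
#' A single virus lineage enters at the host root and is propagated down the
#' host tree. At each host bifurcation the lineage co-diverges with
#' probability 1 - (p_transfer + p_duplication + p_loss); otherwise it
#' transfers (splits, one copy jumping to a uniformly chosen host node not
#' ancestrally related to the current one), duplicates (splits in place), or
#' goes extinct. Duplicated / staying lineages re-draw an event at the same
#' bifurcation. At the host root no transfer recipient exists, so the event
#' probabilities are renormalized over the remaining kinds there. The
#' realized virus tree (extinct lineages pruned), the tip-host map, and the
#' exact realized event counts are returned; internal virus nodes always
#' equal cospeciations + transfers + duplications.
#'
#' @param host_tree rooted binary \code{phylo}.
#' @param p_transfer,p_duplication,p_loss per-bifurcation event
#'   probabilities; their sum must be < 1.
#' @param n_extant_target cap on extant virus tips; replicates exceeding it
#'   (or dying out, or ending with < 2 tips) are retried up to
#'   \code{max_tries} times.
#' @param seed integer seed.
#' @param max_tries retry bound (default 100).
#' @return object of class \code{simulated_history}: \code{virus_tree},
#'   \code{host_tree}, \code{map} (tip-host data frame), \code{event_counts}
#'   (cospeciation, transfer, duplication, loss), \code{params}.
#' @export
simulate_cophylogeny <- function(host_tree, p_transfer = 0, p_duplication = 0,
                                 p_loss = 0, n_extant_target = 4L * ape::Ntip(host_tree),
                                 seed = NULL, max_tries = 100L) {
  stopifnot(p_transfer >= 0, p_duplication >= 0, p_loss >= 0)
  if (p_transfer + p_duplication + p_loss >= 1)
    stopf("event probabilities must sum to < 1")
  if (!ape::is.binary(host_tree) || !ape::is.rooted(host_tree))
    stopf("host tree must be rooted and binary")
  H <- host_index(host_tree)
  n <- H$n
  with_seed(seed, {
    for (try in seq_len(max_tries)) {
      env <- new.env()
      env$counts <- c(cospeciation = 0, transfer = 0, duplication = 0, loss = 0)
      env$tip_i <- 0L
      env$map <- list()
      env$overflow <- FALSE
      res <- sim_lineage(H, host_tree, H$root, p_transfer, p_duplication,
                         p_loss, n_extant_target, env)
      if (env$overflow || is.null(res) || env$tip_i < 2L) next
      nwk <- paste0(res$nwk, ";")
      vt <- ape::read.tree(text = nwk)
      map <- data.frame(
        virus_tip = names(env$map),
        host_tip = host_tree$tip.label[unlist(env$map)],
        stringsAsFactors = FALSE)
      return(structure(list(
        virus_tree = vt, host_tree = host_tree, map = map,
        event_counts = env$counts,
        params = list(p_transfer = p_transfer, p_duplication = p_duplication,
                      p_loss = p_loss, seed = seed, tries = try)),
        class = "simulated_history"))
    }
    stopf("simulation failed %d times (all lineages lost or tip cap %d exceeded)",
          max_tries, n_extant_target)
  })
}

# one lineage at host node h; returns list(nwk=..) or NULL if the whole
# sub-lineage went extinct. Event/loss counts accumulate in env.
sim_lineage <- function(H, host_tree, h, pt, pd, pl, cap, env) {
  if (env$overflow) return(NULL)
  if (is.na(H$kids[h, 1])) {                       # host tip: virus survives here
    env$tip_i <- env$tip_i + 1L
    if (env$tip_i > cap) { env$overflow <- TRUE; return(NULL) }
    lab <- paste0("v", env$tip_i)
    env$map[[lab]] <- h
    return(list(nwk = paste0(lab, ":1")))
  }
  inc <- H$incomp[[h]]
  probs <- c(co = 1 - pt - pd - pl, transfer = pt, dup = pd, loss = pl)
  if (length(inc) == 0L) {                         # no transfer recipient at root
    probs["co"] <- probs["co"] + probs["transfer"]
    probs["transfer"] <- 0
  }
  ev <- sample(names(probs), 1L, prob = probs)
  if (ev == "loss") return(NULL)
  if (ev == "co") {
    a <- sim_lineage(H, host_tree, H$kids[h, 1], pt, pd, pl, cap, env)
    b <- sim_lineage(H, host_tree, H$kids[h, 2], pt, pd, pl, cap, env)
    return(join_lineages(a, b, "cospeciation", env))
  }
  if (ev == "dup") {
    a <- sim_lineage(H, host_tree, h, pt, pd, pl, cap, env)
    b <- sim_lineage(H, host_tree, h, pt, pd, pl, cap, env)
    return(join_lineages(a, b, "duplication", env))
  }
  recipient <- if (length(inc) == 1L) inc else inc[sample.int(length(inc), 1L)]
  a <- sim_lineage(H, host_tree, h, pt, pd, pl, cap, env)      # donor copy stays
  b <- sim_lineage(H, host_tree, recipient, pt, pd, pl, cap, env)
  join_lineages(a, b, "transfer", env)
}

join_lineages <- function(a, b, event, env) {
  if (is.null(a) && is.null(b)) return(NULL)
  if (is.null(a) || is.null(b)) {                  # one side extinct: node suppressed
    env$counts["loss"] <- env$counts["loss"] + 1
    return(if (is.null(a)) b else a)
  }
  env$counts[event] <- env$counts[event] + 1
  list(nwk = paste0("(", a$nwk, ",", b$nwk, "):1"))
}

#' @export
print.simulated_history <- function(x, ...) {
  cat(sprintf("Simulated cophylogeny: %d virus tips on %d hosts\n",
              ape::Ntip(x$virus_tree), ape::Ntip(x$host_tree)))
  cat(sprintf("  true events: co-div %d, transfer %d, duplication %d, loss %d\n",
              x$event_counts[1], x$event_counts[2], x$event_counts[3],
              x$event_counts[4]))
  invisible(x)
}

#' Simulate a tree ensemble with planted clusters and migrant tips
#'
#' Builds, for every ensemble tree, long-stem clusters of tips
#' (\code{c<i>_<j>}) on a pectinate backbone, with cluster-internal topology
#' redrawn per tree. Each chosen migrant tip is relocated out of its home
#' cluster onto a foreign cluster's stem in at least one tree. Supports are
#' planted so that intact-cluster MRCAs (and nodes inside clusters) draw from
#' \code{support_range} while backbone and attachment nodes stay below 80.
#'
#' @param n_clusters number of planted clusters (>= 2).
#' @param cluster_sizes integer vector (recycled to \code{n_clusters}); each
#'   >= 2.
#' @param n_trees ensemble size.
#' @param n_migrants number of migrant tips (< min cluster size).
#' @param support_range numeric length-2; planted cluster supports (>= 80
#'   recommended).
#' @param seed integer seed.
#' @return object of class \code{planted_ensemble}: \code{trees} (named
#'   list), \code{membership} (named character vector tip -> cluster label),
#'   \code{migrants}, \code{moved} (list per tree of tips relocated in it),
#'   \code{seeds} (the planted clusters as \code{\link{clade_seed}}s).
#' @export
simulate_ensemble <- function(n_clusters = 4L, cluster_sizes = 10L,
                              n_trees = 5L, n_migrants = 0L,
                              support_range = c(90, 100), seed = NULL) {
  stopifnot(n_clusters >= 2L, n_trees >= 1L)
  sizes <- rep_len(cluster_sizes, n_clusters)
  if (any(sizes < 2L)) stopf("cluster sizes must be >= 2")
  if (n_migrants >= min(sizes))
    stopf("n_migrants must be smaller than the smallest cluster")
  labels <- lapply(seq_len(n_clusters), function(i)
    paste0("c", i, "_", seq_len(sizes[i])))
  membership <- stats::setNames(
    rep(paste0("cluster", seq_len(n_clusters)), sizes), unlist(labels))
  with_seed(seed, {
    migrants <- if (n_migrants > 0L)
      sample(unlist(labels), n_migrants) else character(0)
    move_in <- lapply(seq_len(n_trees), function(t) character(0))
    for (mg in migrants) {
      sel <- which(stats::runif(n_trees) < 0.5)
      if (length(sel) == 0L) sel <- sample.int(n_trees, 1L)
      for (t in sel) move_in[[t]] <- c(move_in[[t]], mg)
    }
    trees <- vector("list", n_trees)
    for (t in seq_len(n_trees)) {
      moved <- move_in[[t]]
      blocks <- character(n_clusters)
      # which foreign cluster receives each moved tip
      target <- vapply(moved, function(mg) {
        home <- membership[[mg]]
        sample(setdiff(seq_len(n_clusters),
                       match(home, paste0("cluster", seq_len(n_clusters)))), 1L)
      }, 0L)
      for (i in seq_len(n_clusters)) {
        mem <- setdiff(labels[[i]], moved)
        if (length(mem) == 1L) {
          blk <- paste0(mem, ":1.0")
        } else {
          sub <- ape::rtree(length(mem))
          sub$tip.label <- sample(mem)
          sub$edge.length <- stats::runif(nrow(sub$edge), 0.01, 0.05)
          blk <- paste0(sub(";$", "", ape::write.tree(sub)), ":1.0")
        }
        for (mg in moved[target == i])       # graft migrant onto this stem
          blk <- paste0("(", blk, ",", mg, ":0.3):0.5")
        blocks[i] <- blk
      }
      nwk <- blocks[n_clusters]
      for (i in rev(seq_len(n_clusters - 1L)))
        nwk <- paste0("(", blocks[i], ",", nwk, "):0.1")
      tr <- ape::read.tree(text = paste0(nwk, ";"))
      # plant supports: inside clusters high, elsewhere below threshold
      n <- ape::Ntip(tr)
      sup <- round(stats::runif(tr$Nnode, 50, 79))
      sets <- clade_tip_sets(tr)
      for (i in seq_len(n_clusters)) {
        mem <- setdiff(labels[[i]], moved)
        v <- if (length(mem) == 1L) NA_integer_ else ape::getMRCA(tr, mem)
        if (is.na(v)) next
        inside <- which(vapply((n + 1L):(n + tr$Nnode), function(u)
          all(sets[[u]] %in% sets[[v]]), TRUE))
        sup[inside] <- round(stats::runif(length(inside),
                                          support_range[1], support_range[2]))
      }
      tr$node.label <- as.character(sup)
      trees[[t]] <- tr
    }
    names(trees) <- paste0("tree", seq_len(n_trees))
    seeds <- lapply(seq_len(n_clusters), function(i)
      clade_seed(paste0("cluster", i), labels[[i]], origin = "user-supplied"))
    structure(list(trees = trees, membership = membership,
                   migrants = migrants, moved = move_in, seeds = seeds),
              class = "planted_ensemble")
  })
}

BACKGROUND_FORBIDDEN <- c("AGGA", "GGAG", "GAGG")

# random DNA of length n containing no Shine-Dalgarno 4-mer (hence no 5/6-mer)
clean_background <- function(n) {
  repeat {
    s <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
    if (!any(vapply(BACKGROUND_FORBIDDEN,
                    function(m) grepl(m, s, fixed = TRUE), TRUE)))
      return(s)
  }
}

# a 24-nt (or utr-long) window classifying exactly as `cls`
planted_window <- function(cls, window = 24L) {
  repeat {
    bg <- clean_background(window)
    if (cls == "none") {
      w <- bg
    } else {
      motif <- sample(RBS_MOTIFS[[cls]], 1L)
      k <- nchar(motif)
      off <- sample.int(window - k + 1L, 1L) - 1L
      w <- paste0(substr(bg, 1, off), motif, substr(bg, off + k + 1L, window))
    }
    if (classify_window(w)$motif_class == cls) return(w)
  }
}

#' Simulate annotated segments with planted RBS motif classes
#'
#' Generates segments whose ORF upstream windows are clean background
#' sequence (rejection-sampled to contain no Shine-Dalgarno k-mer) with the
#' drawn class's motif spliced in, verified against
#' \code{\link{classify_window}} so the planted class always equals the
#' scanned class. ORFs are distributed as evenly as possible across segments.
#' Supply either \code{class_probabilities} (stochastic composition) or
#' \code{class_counts} (exact composition, in the order 6-mer, 5-mer, 4-mer,
#' none, summing to \code{n_orfs}).
#'
#' @param n_segments number of segments.
#' @param n_orfs total ORFs across the set.
#' @param class_probabilities numeric length-4 (6-mer, 5-mer, 4-mer, none)
#'   summing to 1.
#' @param class_counts integer length-4 alternative to probabilities.
#' @param utr_length length of the 5' UTR before each first ORF (>= 24).
#' @param orf_length ORF length in nt (multiple of 3, default 60).
#' @param dataset_label label for the set.
#' @param seed integer seed.
#' @return object of class \code{planted_segment_set}: \code{segments} (list
#'   of \code{\link{annotated_segment}}), \code{planted} (data frame
#'   \code{segment_id}, \code{orf_id}, \code{class}).
#' @export
simulate_segments <- function(n_segments, n_orfs,
                              class_probabilities = NULL, class_counts = NULL,
                              utr_length = 24L, orf_length = 60L,
                              dataset_label = "synthetic", seed = NULL) {
  stopifnot(utr_length >= 24L, orf_length %% 3L == 0L, n_orfs >= n_segments)
  classes <- c("6-mer", "5-mer", "4-mer", "none")
  if (is.null(class_counts) == is.null(class_probabilities))
    stopf("supply exactly one of class_probabilities or class_counts")
  with_seed(seed, {
    cls <- if (!is.null(class_counts)) {
      stopifnot(length(class_counts) == 4L, sum(class_counts) == n_orfs)
      sample(rep(classes, class_counts))
    } else {
      stopifnot(length(class_probabilities) == 4L,
                abs(sum(class_probabilities) - 1) < 1e-9)
      sample(classes, n_orfs, replace = TRUE, prob = class_probabilities)
    }
    per_seg <- rep(n_orfs %/% n_segments, n_segments)
    extra <- n_orfs %% n_segments
    if (extra > 0L) per_seg[seq_len(extra)] <- per_seg[seq_len(extra)] + 1L
    segments <- vector("list", n_segments)
    planted <- list()
    k <- 0L
    for (s in seq_len(n_segments)) {
      sid <- sprintf("%s_seg%03d", gsub("[^A-Za-z0-9]+", "_", dataset_label), s)
      seq_parts <- character(0)
      orfs <- list()
      pos <- 0L
      for (j in seq_len(per_seg[s])) {
        k <- k + 1L
        w <- planted_window(cls[k])
        lead <- if (utr_length > 24L) clean_background(utr_length - 24L) else ""
        body <- paste0("ATG",
                       paste(sample(c("GCA", "GCC", "TGC", "TTC", "CAC", "ATC"),
                                    orf_length / 3L - 2L, replace = TRUE),
                             collapse = ""),
                       "TAA")
        seq_parts <- c(seq_parts, lead, w, body)
        start <- pos + nchar(lead) + 24L
        orf_id <- sprintf("%s_orf%d", sid, j)
        orfs[[j]] <- data.frame(orf_id = orf_id, start = start,
                                end = start + orf_length, strand = "+",
                                stringsAsFactors = FALSE)
        planted[[k]] <- data.frame(segment_id = sid, orf_id = orf_id,
                                   class = cls[k], stringsAsFactors = FALSE)
        pos <- start + orf_length
      }
      segments[[s]] <- annotated_segment(
        sid, paste(seq_parts, collapse = ""), do.call(rbind, orfs),
        dataset_label)
    }
    structure(list(segments = segments, planted = do.call(rbind, planted)),
              class = "planted_segment_set")
  })
}

#' A small synthetic host cladogram over animal host categories
#'
#' A hand-built stand-in cladogram over the animal host/source categories used
#' for tip annotation (mammalian orders, bird, reptile, fish, arthropod,
#' other invertebrate), following textbook vertebrate/invertebrate
#' relationships. It is synthetic: it asserts no published phylogeny and
#' exists so examples and tests have a realistic polytomy-bearing host tree.
#'
#' @return a rooted \code{phylo} with category-named tips.
#' @export
host_category_cladogram <- function() {
  parse_newick(paste0(
    "((((((Primate,Rodent,Lagomorph),(Feline,Canine),",
    "((Bovidae,Cervidae),Suidae,(Equidae,Dromedary)),Bat),Tasmanian_devil),",
    "Avian,Reptile),Fish),(Arthropod,Other_invertebrate));"))
}
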