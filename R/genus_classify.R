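#' Candidate-genus seed clades
#'
#' A clade seed is a named set of tips proposed as a candidate genus. Seeds can
#' be detected on a reference tree (\code{\link{detect_seeds}}) or supplied by
#' the user; within a seed list the member sets must be pairwise disjoint.
#'
#' @param genus_label character label (e.g. \code{"Alphapicobirnavirus"}).
#' @param member_tips character vector of tip labels.
#' @param origin \code{"detected"} or \code{"user-supplied"}.
#' @return an object of class \code{clade_seed}.
#' @export
clade_seed <- function(genus_label, member_tips, origin = "user-supplied") {
  stopifnot(is.character(genus_label), length(genus_label) == 1L,
            length(member_tips) >= 1L)
  structure(list(genus_label = genus_label,
                 member_tips = sort(unique(member_tips)),
                 origin = origin),
            class = "clade_seed")
}

validate_seeds <- function(seeds, min_seed_size = 1L) {
  stopifnot(length(seeds) >= 1L)
  all_tips <- unlist(lapply(seeds, `[[`, "member_tips"))
  dup <- unique(all_tips[duplicated(all_tips)])
  if (length(dup) > 0L)
    stopf("seeds are not disjoint; shared tip(s): %s",
          paste(utils::head(dup, 10), collapse = ", "))
  small <- vapply(seeds, function(s) length(s$member_tips) < min_seed_size, TRUE)
  if (any(small))
    stopf("seed(s) below min_seed_size: %s",
          paste(vapply(seeds[small], `[[`, "", "genus_label"), collapse = ", "))
  labs <- vapply(seeds, `[[`, "", "genus_label")
  if (anyDuplicated(labs)) stopf("duplicate genus labels among seeds")
  invisible(seeds)
}

#' Read / write seed tables
#'
#' TSV with columns \code{genus_label}, \code{tip_id}.
#' @param path TSV file path.
#' @return a list of \code{\link{clade_seed}} objects.
#' @export
read_seeds <- function(path) {
  df <- read_tsv_plain(path)
  if (!all(c("genus_label", "tip_id") %in% names(df)))
    stopf("seed file needs columns genus_label, tip_id")
  sp <- split(df$tip_id, df$genus_label)
  seeds <- Map(function(lab, tips) clade_seed(lab, tips, origin = "user-supplied"),
               names(sp), sp)
  validate_seeds(unname(seeds))
  unname(seeds)
}

#' Detect candidate genus clades on a reference tree
#'
#' Formalizes by-eye cluster picking with an explicit rule: a clade qualifies
#' as a seed when (a) its MRCA support is at least \code{min_support}, (b) its
#' stem branch is at least \code{min_stem_factor} times the median internal
#' branch length, and (c) it holds at least \code{min_seed_size} tips. Among
#' qualifying nodes only maximal ones are kept (a seed never contains
#' another). Detected seeds are labelled \code{"clade1"}, \code{"clade2"}, ...
#' in order of decreasing size.
#'
#' @param reference_tree rooted \code{phylo} with branch lengths and supports.
#' @param min_support support threshold in percent (default 80, the SH-aLRT
#'   convention).
#' @param min_stem_factor multiple of the median internal branch length the
#'   stem must reach (default 2).
#' @param min_seed_size minimum clade size (default 5).
#' @return list of \code{\link{clade_seed}} objects (possibly empty, with a
#'   warning).
#' @export
detect_seeds <- function(reference_tree, min_support = 80,
                         min_stem_factor = 2, min_seed_size = 5L) {
  tr <- reference_tree
  if (!ape::is.rooted(tr)) stopf("reference tree must be rooted")
  if (is.null(tr$edge.length)) stopf("reference tree must have branch lengths")
  n <- ape::Ntip(tr)
  sets <- clade_tip_sets(tr)
  sup <- node_supports(tr)
  internal_edges <- tr$edge[, 2] > n
  med <- stats::median(tr$edge.length[internal_edges])
  stem <- rep(NA_real_, n + tr$Nnode)
  stem[tr$edge[, 2]] <- tr$edge.length
  qual <- integer(0)
  for (v in (n + 1L):(n + tr$Nnode)) {
    s <- sup[v - n]
    if (is.na(s) || s < min_support) next
    if (is.na(stem[v]) || stem[v] < min_stem_factor * med) next
    if (length(sets[[v]]) < min_seed_size) next
    qual <- c(qual, v)
  }
  if (length(qual) == 0L) {
    warnf("no clade meets the seed criteria")
    return(list())
  }
  # maximal: drop any qualifying node nested inside another qualifying node
  keep <- qual[vapply(qual, function(v) {
    !any(vapply(qual, function(u)
      u != v && all(sets[[v]] %in% sets[[u]]), TRUE))
  }, TRUE)]
  keep <- keep[order(-lengths(sets[keep]),
                     vapply(sets[keep], `[`, "", 1L))]
  seeds <- lapply(seq_along(keep), function(i)
    clade_seed(paste0("clade", i), sets[[keep[i]]], origin = "detected"))
  validate_seeds(seeds)
  seeds
}

#' Assess a seed's membership in one tree
#'
#' Finds the seed's representative clade in the tree: among internal nodes
#' with support at least \code{min_support} whose tips are at least
#' \code{purity} seed members, the node containing the most seed members (ties
#' broken by higher purity, then smaller clade, then lexicographically
#' smallest tip set). Seed members inside that clade are scored as clustering
#' with their draft genus; members outside (or all members, when no node
#' qualifies) are not.
#'
#' @param tree a rooted \code{phylo} with supports.
#' @param seed a \code{\link{clade_seed}}.
#' @param min_support support threshold (percent, default 80).
#' @param purity minimum fraction of clade tips that are seed members
#'   (default 0.9).
#' @param tree_id identifier copied into the output.
#' @return data frame (one row per seed member present in the tree) with
#'   columns \code{tree_id}, \code{genus_label}, \code{tip_id},
#'   \code{in_supported_clade}, \code{support_at_clade}.
#' @export
assess_membership <- function(tree, seed, min_support = 80, purity = 0.9,
                              tree_id = NA_character_) {
  members <- intersect(seed$member_tips, tree$tip.label)
  if (length(members) == 0L)
    stopf("seed '%s' has no members in this tree", seed$genus_label)
  n <- ape::Ntip(tree)
  sets <- clade_tip_sets(tree)
  sup <- node_supports(tree)
  best <- NULL
  for (v in (n + 1L):(n + tree$Nnode)) {
    s <- sup[v - n]
    if (is.na(s) || s < min_support) next
    clade <- sets[[v]]
    k <- sum(clade %in% members)
    if (k == 0L) next
    pur <- k / length(clade)
    if (pur < purity) next
    cand <- list(node = v, k = k, purity = pur, size = length(clade),
                 support = s, tips = clade)
    if (is.null(best)) { best <- cand; next }
    better <- cand$k > best$k ||
      (cand$k == best$k && cand$purity > best$purity + 1e-12) ||
      (cand$k == best$k && abs(cand$purity - best$purity) <= 1e-12 &&
         cand$size < best$size) ||
      (cand$k == best$k && abs(cand$purity - best$purity) <= 1e-12 &&
         cand$size == best$size &&
         paste(cand$tips, collapse = "\r") < paste(best$tips, collapse = "\r"))
    if (better) best <- cand
  }
  inside <- if (is.null(best)) rep(FALSE, length(members)) else members %in% best$tips
  data.frame(tree_id = tree_id, genus_label = seed$genus_label,
             tip_id = members, in_supported_clade = inside,
             support_at_clade = if (is.null(best)) NA_real_ else best$support,
             stringsAsFactors = FALSE)
}

#' Classify an ensemble of trees against seed clades
#'
#' A tip is assigned to its seed's genus only when it clusters inside the
#' seed's supported representative clade in every tree of the ensemble
#' (\code{\link{assess_membership}}); otherwise it is reported as
#' \code{"unclassified"}. By default every ensemble tree must contain every
#' seed member; set \code{require_all_tips = FALSE} to demand consistency only
#' in the trees where a tip is present (for outgroup-restricted ensembles).
#'
#' @param trees a named list of rooted \code{phylo} objects (names are tree
#'   ids; unnamed lists get \code{tree1}, \code{tree2}, ...).
#' @param seeds list of \code{\link{clade_seed}} objects (pairwise disjoint).
#' @param min_support,purity see \code{\link{assess_membership}}.
#' @param require_all_tips logical (default \code{TRUE}).
#' @return an object of class \code{genus_assignment}: \code{assignments}
#'   (data frame: \code{tip_id}, \code{genus}, \code{n_trees_consistent},
#'   \code{n_trees_present}) and \code{evidence} (the per-tree membership
#'   records).
#' @export
classify_ensemble <- function(trees, seeds, min_support = 80, purity = 0.9,
                              require_all_tips = TRUE) {
  if (length(trees) == 0L) stopf("empty tree ensemble")
  validate_seeds(seeds)
  if (is.null(names(trees)) || any(names(trees) == ""))
    names(trees) <- paste0("tree", seq_along(trees))
  ev <- list()
  for (tid in names(trees)) {
    tr <- trees[[tid]]
    for (seed in seeds) {
      if (require_all_tips) {
        absent <- setdiff(seed$member_tips, tr$tip.label)
        if (length(absent) > 0L)
          stopf("tree '%s' lacks seed member(s) of '%s': %s", tid,
                seed$genus_label, paste(utils::head(absent, 5), collapse = ", "))
      }
      if (!any(seed$member_tips %in% tr$tip.label)) next
      ev[[length(ev) + 1L]] <-
        assess_membership(tr, seed, min_support, purity, tree_id = tid)
    }
  }
  evidence <- do.call(rbind, ev)
  # deterministic regardless of ensemble order
  evidence <- evidence[order(evidence$genus_label, evidence$tip_id,
                             evidence$tree_id), , drop = FALSE]
  rownames(evidence) <- NULL
  agg <- stats::aggregate(in_supported_clade ~ genus_label + tip_id,
                          data = evidence,
                          FUN = function(x) c(sum(x), length(x)))
  n_cons <- agg$in_supported_clade[, 1]
  n_pres <- agg$in_supported_clade[, 2]
  assigned <- n_cons == n_pres
  assignments <- data.frame(
    tip_id = agg$tip_id,
    genus = ifelse(assigned, agg$genus_label, "unclassified"),
    n_trees_consistent = n_cons,
    n_trees_present = n_pres,
    stringsAsFactors = FALSE)
  assignments <- assignments[order(assignments$tip_id), , drop = FALSE]
  rownames(assignments) <- NULL
  structure(list(assignments = assignments, evidence = evidence,
                 min_support = min_support, purity = purity),
            class = "genus_assignment")
}

#' @export
print.genus_assignment <- function(x, ...) {
  tab <- table(x$assignments$genus)
  cat(sprintf("Genus assignment over %d tip(s) (min support %g, purity %g):\n",
              nrow(x$assignments), x$min_support, x$purity))
  for (g in names(sort(tab, decreasing = TRUE)))
    cat(sprintf("  %-24s %d\n", g, tab[[g]]))
  invisible(x)
}

#' Per-genus core counts
#'
#' @param assignment a \code{\link{classify_ensemble}} result.
#' @return data frame with columns \code{genus}, \code{n_core}.
#' @export
core_counts <- function(assignment) {
  tab <- table(assignment$assignments$genus)
  df <- data.frame(genus = names(tab), n_core = as.integer(tab),
                   stringsAsFactors = FALSE)
  df[order(df$genus), , drop = FALSE]
}
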