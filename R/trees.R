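#' Parse a Newick string into a phylo object with validated support values
#'
#' Trees are handled as \code{ape::phylo} objects throughout the package.
#' Internal-node support values (e.g. SH-aLRT percentages emitted by IQ-TREE)
#' are accepted either as internal node labels (\code{")85:0.1"}) or as bare
#' numeric bracket comments (\code{")[85]:0.1"}); both end up in
#' \code{node.label} and can be recovered with \code{\link{node_supports}}.
#'
#' @param text a Newick string (single tree, terminated by \code{;}).
#' @return an object of class \code{phylo}. Polytomies are preserved.
#' @examples
#' tr <- parse_newick("((A:1,B:1)90:1,C:2);")
#' node_supports(tr)
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  # locate unbalanced parentheses before handing off, so the error names an offset
  chars <- strsplit(text, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) stopf("malformed Newick: unmatched ')' at character %d", i)
    }
  }
  if (depth > 0L) stopf("malformed Newick: %d unclosed '(' (string ends at character %d)",
                        depth, length(chars))
  if (sum(chars == "'") %% 2L != 0L) stopf("malformed Newick: unbalanced quote")
  # bracket-comment support dialect: ")[85]:" -> ")85:"
  text <- gsub("\\)\\[([0-9]+\\.?[0-9]*)\\]", ")\\1", text)
  tr <- tryCatch(ape::read.tree(text = text),
                 error = function(e) stopf("malformed Newick: %s", conditionMessage(e)))
  if (is.null(tr)) stopf("malformed Newick: could not parse tree")
  dup <- unique(tr$tip.label[duplicated(tr$tip.label)])
  if (length(dup) > 0L)
    stopf("duplicate tip label(s): %s", paste(dup, collapse = ", "))
  sup <- node_supports(tr)
  bad <- which(!is.na(sup) & (sup < 0 | sup > 100))
  if (length(bad) > 0L)
    stopf("support value(s) outside [0, 100]: %s", paste(sup[bad], collapse = ", "))
  if (!is.null(tr$edge.length) && any(tr$edge.length < 0))
    stopf("negative branch length(s) present")
  tr
}

#' Write a phylo object to a Newick string
#'
#' Inverse of \code{\link{parse_newick}}: supports are written back as internal
#' node labels.
#'
#' @param tree a \code{phylo} object.
#' @param digits significant digits for branch lengths.
#' @return a Newick string.
#' @export
write_newick <- function(tree, digits = 10) {
  ape::write.tree(tree, digits = digits)
}

#' Numeric support values per internal node
#'
#' @param tree a \code{phylo} object.
#' @return numeric vector of length \code{tree$Nnode}, indexed in node-number
#'   order (node \code{Ntip+i} is element \code{i}); \code{NA} where no numeric
#'   label is present.
#' @export
node_supports <- function(tree) {
  if (is.null(tree$node.label)) return(rep(NA_real_, tree$Nnode))
  suppressWarnings(as.numeric(tree$node.label))
}

#' Is a tree rooted (binary basal split)?
#'
#' A tree whose basal node is a polytomy is treated as unrooted; \code{ape}
#' stores such trees rooted at an arbitrary node.
#'
#' @param tree a \code{phylo} object.
#' @return logical.
#' @export
is_rooted_tree <- function(tree) ape::is.rooted(tree)

# Tip sets of every clade, indexed by node number (tips map to themselves).
clade_tip_sets <- function(tree) {
  n <- ape::Ntip(tree)
  m <- tree$Nnode
  sets <- vector("list", n + m)
  for (i in seq_len(n)) sets[[i]] <- tree$tip.label[i]
  for (e in ape::postorder(tree)) {          # children complete before parents
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    sets[[p]] <- c(sets[[p]], sets[[ch]])
  }
  lapply(sets, sort)
}

canonical_split <- function(side, all_tips) {
  n <- length(all_tips)
  other <- setdiff(all_tips, side)
  if (length(side) < length(other)) return(sort(side))
  if (length(other) < length(side)) return(sort(other))
  # equal halves: keep the side holding the lexicographically smallest tip
  if (min(side) < min(other)) sort(side) else sort(other)
}

#' Non-trivial bipartitions of a tree
#'
#' Every internal edge of the unrooted topology induces a split of the tip set;
#' trivial splits (one tip versus the rest) are excluded, and the canonical
#' representation (smaller side; ties broken by the side holding the
#' lexicographically smallest tip) is independent of where the tree is rooted.
#'
#' @param tree a \code{phylo} object.
#' @return a list of sorted character vectors (tip-label sets), one per
#'   non-trivial split, ordered deterministically; empty for trees with fewer
#'   than 4 tips or a star topology.
#' @export
bipartitions <- function(tree) {
  n <- ape::Ntip(tree)
  if (n < 4L) return(list())
  tips <- sort(tree$tip.label)
  sets <- clade_tip_sets(tree)
  root <- n + 1L
  out <- list()
  for (v in (n + 1L):(n + tree$Nnode)) {
    if (v == root) next
    side <- sets[[v]]
    if (length(side) < 2L || length(side) > n - 2L) next
    out[[length(out) + 1L]] <- canonical_split(side, tips)
  }
  keys <- vapply(out, paste, "", collapse = "\r")
  out <- out[!duplicated(keys)]
  out[order(vapply(out, paste, "", collapse = "\r"))]
}

split_keys <- function(tree) {
  vapply(bipartitions(tree), paste, "", collapse = "\r")
}

#' Midpoint-root a tree
#'
#' Places the root at the midpoint of the longest tip-to-tip path. Ties among
#' equally long paths are broken by the lexicographically smallest (sorted)
#' tip-label pair, so the result is deterministic. All branch lengths must be
#' present.
#'
#' @param tree a \code{phylo} object with branch lengths.
#' @return a rooted \code{phylo} object with the same unrooted topology and
#'   total path lengths.
#' @export
midpoint_root <- function(tree) {
  if (is.null(tree$edge.length) || anyNA(tree$edge.length))
    stopf("midpoint_root requires branch lengths on every edge")
  n <- ape::Ntip(tree)
  if (n == 2L) {
    tot <- sum(tree$edge.length)
    tree$edge.length <- rep(tot / 2, length(tree$edge.length))
    return(tree)
  }
  D <- ape::dist.nodes(tree)
  tipD <- D[seq_len(n), seq_len(n), drop = FALSE]
  best <- max(tipD)
  idx <- which(tipD == best, arr.ind = TRUE)
  idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
  pairs <- cbind(tree$tip.label[idx[, 1]], tree$tip.label[idx[, 2]])
  pairs <- t(apply(pairs, 1, sort))
  ord <- order(pairs[, 1], pairs[, 2])
  a <- idx[ord[1], 1]; b <- idx[ord[1], 2]
  half <- best / 2
  path <- ape::nodepath(tree, a, b)
  cum <- 0
  for (k in seq_len(length(path) - 1L)) {
    u <- path[k]; v <- path[k + 1L]
    len <- D[u, v]
    if (cum + len >= half - 1e-12) {
      x <- half - cum                       # distance from u along edge (u,v)
      erow <- which((tree$edge[, 1] == u & tree$edge[, 2] == v) |
                    (tree$edge[, 1] == v & tree$edge[, 2] == u))
      ch <- tree$edge[erow, 2]
      d_child <- if (ch == v) len - x else x
      if (d_child <= 1e-12) {
        # midpoint falls on the child node itself
        if (ch <= n) {
          rooted <- phytools::reroot(tree, ch, position = 1e-9 * max(len, 1))
        } else {
          rooted <- ape::root(tree, node = ch, resolve.root = TRUE)
        }
      } else if (d_child >= len - 1e-12) {
        pa <- tree$edge[erow, 1]
        rooted <- if (pa == n + 1L) tree else ape::root(tree, node = pa, resolve.root = TRUE)
      } else {
        # reroot() measures position from the rootward end of ch's edge
        rooted <- phytools::reroot(tree, ch, position = len - d_child)
      }
      return(rooted)
    }
    cum <- cum + len
  }
  tree
}

#' Root a tree on the stem edge of an outgroup
#'
#' @param tree a \code{phylo} object.
#' @param outgroup_tips character vector of tip labels; must form a split of
#'   the unrooted topology (i.e. be monophyletic under some rooting).
#' @return a rooted \code{phylo} object with the ingroup topology unchanged.
#' @export
root_with_outgroup <- function(tree, outgroup_tips) {
  outgroup_tips <- unique(outgroup_tips)
  if (length(outgroup_tips) == 0L) stopf("outgroup is empty")
  missing <- setdiff(outgroup_tips, tree$tip.label)
  if (length(missing) > 0L)
    stopf("outgroup tip(s) not in tree: %s", paste(missing, collapse = ", "))
  n <- ape::Ntip(tree)
  if (length(outgroup_tips) >= n)
    stopf("outgroup cannot contain every tip")
  if (length(outgroup_tips) > 1L && length(outgroup_tips) < n - 1L) {
    og <- sort(outgroup_tips)
    sets <- clade_tip_sets(ape::unroot(tree))
    keys <- vapply(sets, paste, "", collapse = "\r")
    ogk <- paste(og, collapse = "\r")
    compk <- paste(sort(setdiff(tree$tip.label, og)), collapse = "\r")
    if (!(ogk %in% keys || compk %in% keys)) {
      # name the interlopers: tips inside the outgroup's best-covering clade
      ut <- ape::unroot(tree)
      mr <- ape::getMRCA(ut, og)
      inside <- setdiff(sets[[mr]], og)
      stopf("outgroup is not monophyletic under any rooting; conflicting tip(s): %s",
            paste(utils::head(sort(inside), 10), collapse = ", "))
    }
  }
  ape::root(tree, outgroup = outgroup_tips, resolve.root = TRUE)
}

#' Most recent common ancestor and monophyly test
#'
#' @param tree a rooted \code{phylo} object.
#' @param tips character vector of tip labels (subset of the tree's tips).
#' @return \code{mrca_node()} returns the node number of the MRCA.
#'   \code{is_monophyletic_with_support()} returns a list with elements
#'   \code{monophyletic} (logical: the MRCA clade's tip set equals \code{tips})
#'   and \code{support} (the MRCA node's support value, \code{NA} if absent).
#' @export
mrca_node <- function(tree, tips) {
  unknown <- setdiff(tips, tree$tip.label)
  if (length(unknown) > 0L)
    stopf("unknown tip label(s): %s", paste(unknown, collapse = ", "))
  if (length(tips) == 1L) return(match(tips, tree$tip.label))
  ape::getMRCA(tree, tips)
}

#' @rdname mrca_node
#' @export
is_monophyletic_with_support <- function(tree, tips) {
  v <- mrca_node(tree, tips)
  sets <- clade_tip_sets(tree)
  mono <- setequal(sets[[v]], tips)
  n <- ape::Ntip(tree)
  sup <- if (v > n) node_supports(tree)[v - n] else NA_real_
  list(monophyletic = mono, support = sup, node = v)
}
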