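# Exhaustive maximum-parsimony trees for multi-region/multi-component tumor
# samples. Characters are binary presence/absence of somatic variants; the
# implicit root is the all-absent germline state, carried as an outgroup
# leaf. Rooting the unrooted topology on the outgroup edge keeps every
# internal node binary, so plain Fitch bottom-up counting plus deterministic
# top-down refinement yields both the parsimony length and per-edge change
# counts.

# -- topology enumeration -----------------------------------------------------
# A rooted binary tree over the m region leaves corresponds one-to-one to an
# unrooted binary tree over m + 1 leaves (regions + germline outgroup).
# Trees are nested lists: a leaf is an integer, an internal node list(l, r).

attach_leaf_everywhere <- function(tree, leaf) {
  out <- list(list(tree, leaf))
  if (is.list(tree)) {
    for (side in 1:2) {
      for (sub in attach_leaf_everywhere(tree[[side]], leaf)) {
        t2 <- tree
        t2[[side]] <- sub
        out[[length(out) + 1L]] <- t2
      }
    }
  }
  out
}

enumerate_rooted_trees <- function(m) {
  trees <- list(1L)
  if (m == 1L) return(trees)
  for (leaf in 2:m) {
    trees <- unlist(lapply(trees, attach_leaf_everywhere, leaf = leaf),
                    recursive = FALSE)
  }
  trees
}

# Compile a nested tree over m region leaves into flat arrays for Fitch.
# Node ids: regions 1..m, outgroup m+1, internal nodes m+2 .. 2m, root 2m+1.
# Returns internal rows in postorder (children before parents); the root
# (children: top internal/leaf node and the outgroup) is the last row.
compile_topology <- function(tree, m) {
  parents <- integer(0)
  kids <- matrix(0L, nrow = 0L, ncol = 2L)
  counter <- m + 1L
  walk <- function(node) {
    if (!is.list(node)) return(as.integer(node))
    l <- walk(node[[1L]]); r <- walk(node[[2L]])
    counter <<- counter + 1L
    parents <<- c(parents, counter)
    kids <<- rbind(kids, c(l, r))
    counter
  }
  top <- walk(tree)
  root <- 2L * m + 1L
  parents <- c(parents, root)
  kids <- rbind(kids, c(top, m + 1L))
  list(parents = parents, kids = kids, root = root, m = m)
}

.topology_cache <- new.env(parent = emptyenv())

compiled_topologies <- function(m) {
  key <- as.character(m)
  if (!is.null(.topology_cache[[key]])) return(.topology_cache[[key]])
  compiled <- lapply(enumerate_rooted_trees(m), compile_topology, m = m)
  .topology_cache[[key]] <- compiled
  compiled
}

# -- Fitch scoring ------------------------------------------------------------
# States are bitmasks over characters: 1 = {absent}, 2 = {present}, 3 = both.

fitch_codes <- function(topo, leaf_codes) {
  n_nodes <- 2L * topo$m + 1L
  nchar_ <- ncol(leaf_codes)
  codes <- matrix(0L, n_nodes, nchar_)
  codes[seq_len(topo$m), ] <- leaf_codes
  codes[topo$m + 1L, ] <- 1L  # germline outgroup: all absent
  events <- integer(nchar_)
  for (i in seq_along(topo$parents)) {
    a <- bitwAnd(codes[topo$kids[i, 1L], ], codes[topo$kids[i, 2L], ])
    o <- bitwOr(codes[topo$kids[i, 1L], ], codes[topo$kids[i, 2L], ])
    empty <- a == 0L
    codes[topo$parents[i], ] <- ifelse(empty, o, a)
    events <- events + empty
  }
  list(codes = codes, events = events, length = sum(events))
}

fitch_length <- function(topo, leaf_codes) {
  fitch_codes(topo, leaf_codes)$length
}

# Deterministic top-down refinement. The root is assigned the germline state
# (absent) for every character, which is always compatible because the
# outgroup leaf is a root child. Returns per-node states and per-edge gains
# (0 -> 1) and losses (1 -> 0), edges indexed by their child node.
fitch_refine <- function(topo, fit) {
  codes <- fit$codes
  n_nodes <- nrow(codes)
  nchar_ <- ncol(codes)
  states <- matrix(0L, n_nodes, nchar_)
  states[topo$root, ] <- 1L
  gains <- matrix(FALSE, n_nodes, nchar_)
  losses <- matrix(FALSE, n_nodes, nchar_)
  for (i in rev(seq_along(topo$parents))) {
    p <- topo$parents[i]
    for (child in topo$kids[i, ]) {
      shared <- bitwAnd(states[p, ], codes[child, ])
      s <- ifelse(shared > 0L, states[p, ], codes[child, ])
      states[child, ] <- s
      gains[child, ] <- states[p, ] == 1L & s == 2L
      losses[child, ] <- states[p, ] == 2L & s == 1L
    }
  }
  list(states = states, gains = gains, losses = losses)
}

# Leaves (region names) below each node; used for edge labels and tie-breaks.
leaves_below <- function(topo, region_names) {
  below <- vector("list", 2L * topo$m + 1L)
  for (i in seq_len(topo$m)) below[[i]] <- region_names[i]
  below[[topo$m + 1L]] <- character(0)  # outgroup excluded from clade labels
  for (i in seq_along(topo$parents)) {
    below[[topo$parents[i]]] <- sort(c(below[[topo$kids[i, 1L]]],
                                       below[[topo$kids[i, 2L]]]))
  }
  below
}

topology_signature <- function(topo, region_names) {
  below <- leaves_below(topo, region_names)
  internal <- setdiff(topo$parents, topo$root)
  paste(sort(vapply(below[internal], paste, character(1), collapse = ",")),
        collapse = "|")
}

# -- public interface ---------------------------------------------------------

#' Maximum-parsimony tree of tumor regions/components
#'
#' Exhaustive search over all unrooted binary topologies on the regions plus
#' an all-absent germline outgroup (at most 8 regions, i.e. 9 leaves), scored
#' by Fitch small parsimony on the binary presence/absence characters. The
#' minimum-length tree is returned rooted at the germline; among equally
#' parsimonious trees the one with the lexicographically smallest
#' leaf-partition signature is chosen, so the output is deterministic. Edge
#' lengths are the number of character changes assigned to each edge by
#' deterministic Fitch refinement (the germline root state is all-absent).
#'
#' @param presence Binary matrix, regions x variants, with region row names
#'   and variant-key column names.
#' @param outgroup_label Tip label for the germline outgroup (default
#'   "germline").
#' @return Object of class \code{cs_phylo}: list with \code{newick},
#'   \code{phylo} (ape tree, branch lengths = mutation counts),
#'   \code{parsimony_length}, \code{edges} (data frame: edge label = comma-
#'   separated regions below it, length, is_trunk, is_terminal),
#'   \code{gains}/\code{losses} (per-variant lists of edge labels), and the
#'   input \code{presence}.
#' @export
build_parsimony_tree <- function(presence, outgroup_label = "germline") {
  presence <- as.matrix(presence)
  m <- nrow(presence)
  if (m < 2L) stop("need at least 2 regions")
  if (m > 8L) {
    stop("more than 8 regions: exhaustive search not supported; ",
         "reduce regions or use an external heuristic search")
  }
  if (!all(presence %in% c(0, 1))) stop("presence matrix must be binary")
  region_names <- rownames(presence)
  if (is.null(region_names)) {
    region_names <- paste0("R", seq_len(m))
    rownames(presence) <- region_names
  }
  if (is.null(colnames(presence))) {
    colnames(presence) <- paste0("v", seq_len(ncol(presence)))
  }
  if (outgroup_label %in% region_names) {
    stop("outgroup label collides with a region name")
  }
  leaf_codes <- matrix(1L + as.integer(presence), nrow = m)

  best <- NULL
  best_len <- Inf
  best_sig <- NULL
  for (topo in compiled_topologies(m)) {
    len <- fitch_length(topo, leaf_codes)
    if (len > best_len) next
    sig <- topology_signature(topo, region_names)
    if (len < best_len || sig < best_sig) {
      best <- topo; best_len <- len; best_sig <- sig
    }
  }

  fit <- fitch_codes(best, leaf_codes)
  ref <- fitch_refine(best, fit)
  below <- leaves_below(best, region_names)
  n_nodes <- 2L * m + 1L
  non_root <- setdiff(seq_len(n_nodes), best$root)
  edge_label <- vapply(below, function(l) {
    if (length(l)) paste(l, collapse = ",") else outgroup_label
  }, character(1))
  edge_len <- rowSums(ref$gains + ref$losses)

  edges <- data.frame(
    node = non_root,
    label = edge_label[non_root],
    length = edge_len[non_root],
    is_trunk = vapply(below[non_root], length, integer(1)) == m,
    is_terminal = non_root <= m + 1L,
    stringsAsFactors = FALSE
  )

  variant_ids <- colnames(presence)
  gains <- lapply(seq_along(variant_ids), function(j) {
    edge_label[which(ref$gains[, j])]
  })
  losses <- lapply(seq_along(variant_ids), function(j) {
    edge_label[which(ref$losses[, j])]
  })
  names(gains) <- names(losses) <- variant_ids

  nwk <- paste0(newick_string(best, best$root, region_names, edge_len,
                              outgroup_label), ";")
  phylo <- ape::read.tree(text = nwk)

  structure(list(
    newick = nwk, phylo = phylo, parsimony_length = best_len,
    edges = edges, gains = gains, losses = losses,
    leaves = region_names, outgroup = outgroup_label, presence = presence
  ), class = "cs_phylo")
}

newick_string <- function(topo, node, region_names, edge_len, outgroup_label) {
  if (node <= topo$m) {
    return(paste0(region_names[node], ":", edge_len[node]))
  }
  if (node == topo$m + 1L) {
    return(paste0(outgroup_label, ":", edge_len[node]))
  }
  i <- which(topo$parents == node)
  kids <- topo$kids[i, ]
  inner <- paste(
    vapply(kids, function(k) {
      newick_string(topo, k, region_names, edge_len, outgroup_label)
    }, character(1)),
    collapse = ","
  )
  if (node == topo$root) {
    paste0("(", inner, ")")
  } else {
    paste0("(", inner, "):", edge_len[node])
  }
}

#' @export
print.cs_phylo <- function(x, ...) {
  cat("Maximum-parsimony tumor tree over", length(x$leaves), "regions",
      sprintf("(+ %s outgroup)\n", x$outgroup))
  cat("  parsimony length:", x$parsimony_length, "\n")
  trunk <- x$edges[x$edges$is_trunk, , drop = FALSE]
  if (nrow(trunk)) cat("  trunk length:", trunk$length[1L], "\n")
  cat("  newick:", x$newick, "\n")
  invisible(x)
}

#' Place driver mutations on a parsimony tree
#'
#' Each driver is assigned to the edge(s) where Fitch refinement places its
#' absent-to-present change. Drivers with several gain edges exhibit
#' homoplasy and are flagged, with all gain edges listed. When per-region CCF
#' values are supplied, a driver is annotated clonal when every region
#' carrying it has CCF at or above the cutoff.
#'
#' @param tree \code{cs_phylo} object from \code{\link{build_parsimony_tree}}.
#' @param drivers Character vector of variant keys (must be columns of the
#'   tree's presence matrix).
#' @param ccf Optional numeric matrix, regions x variants, of cancer cell
#'   fractions.
#' @param clonal_cutoff CCF cutoff for clonality (default 0.8).
#' @return The tree with a \code{driver_placements} data frame added:
#'   driver, edge (semicolon-joined labels when homoplastic), on_trunk,
#'   homoplasy, clonal.
#' @export
place_drivers <- function(tree, drivers, ccf = NULL, clonal_cutoff = 0.8) {
  stopifnot(inherits(tree, "cs_phylo"))
  missing <- setdiff(drivers, colnames(tree$presence))
  if (length(missing)) {
    stop("drivers absent from presence matrix: ", paste(missing, collapse = ", "))
  }
  trunk_label <- paste(sort(tree$leaves), collapse = ",")
  rows <- lapply(drivers, function(d) {
    edges <- tree$gains[[d]]
    if (length(edges) == 0L) edges <- NA_character_
    clonal <- NA
    if (!is.null(ccf)) {
      carrying <- rownames(tree$presence)[tree$presence[, d] == 1]
      if (length(carrying)) clonal <- all(ccf[carrying, d] >= clonal_cutoff)
    }
    data.frame(
      driver = d,
      edge = paste(edges, collapse = ";"),
      on_trunk = identical(edges, trunk_label),
      homoplasy = length(edges) > 1L,
      clonal = clonal,
      stringsAsFactors = FALSE
    )
  })
  tree$driver_placements <- do.call(rbind, rows)
  tree
}
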