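# Synthetic biphasic (carcinoma/sarcoma) and multi-region tumors with known
# clonal structure, for exercising trunk/branch partitioning and the
# maximum-parsimony tree stages against recorded truth.

#' Generate a biphasic tumor (carcinoma + sarcoma variant sets)
#'
#' Draws a total mutation count from the subtype's burden distribution, makes
#' each mutation shared (trunk) with the subtype's trunk-fraction probability,
#' and splits the private remainder evenly between the carcinoma and sarcoma
#' components. Drivers are planted on the trunk with high probability in the
#' copy-number subtypes and allowed on branches in the hypermutator subtypes.
#'
#' @param subtype One of POLE/MSI/CNH/CNL.
#' @param seed Integer seed.
#' @param config Cohort configuration (supplies burden anchors and default
#'   trunk fractions).
#' @param n_total Total number of distinct mutations; default drawn from the
#'   subtype's SNV+indel distributions.
#' @param trunk_fraction Probability a mutation is shared; default the
#'   subtype's configured trunk fraction (e.g. 15/16 for CNL).
#' @param n_drivers Number of driver mutations to plant.
#' @return List: carcinoma / sarcoma (variant data frames, component_id set),
#'   drivers (data frame: key, location, clonal), truth (planted and realized
#'   trunk fraction, counts).
#' @export
generate_biphasic <- function(subtype = c("CNL", "CNH", "POLE", "MSI"),
                              seed = 1L, config = cohort_config(),
                              n_total = NULL, trunk_fraction = NULL,
                              n_drivers = NULL) {
  subtype <- match.arg(subtype)
  with_seed(seed, {
    if (is.null(trunk_fraction)) trunk_fraction <- config$trunk_fraction[[subtype]]
    stopifnot(trunk_fraction > 0, trunk_fraction <= 1)
    anchors <- config$counts[[subtype]]
    if (is.null(n_total)) {
      n_total <- max(2L, rcount_anchored(1, anchors$snv) +
                       rcount_anchored(1, anchors$indel))
    }
    if (is.null(n_drivers)) {
      n_drivers <- c(POLE = 12L, MSI = 8L, CNH = 4L, CNL = 3L)[[subtype]]
    }
    n_drivers <- min(n_drivers, n_total)
    pool <- panel_genes()
    purity <- 0.7
    n_indel <- round(0.15 * n_total)
    vars <- random_passengers("biphasic", n_total - n_indel, n_indel,
                              config$spectra[[subtype]], pool, purity,
                              config$depth, config$clonal_prob)
    n_total <- nrow(vars)  # after de-duplication

    is_trunk <- stats::runif(n_total) < trunk_fraction
    # guarantee a non-empty tumor even at tiny n
    if (!any(is_trunk)) is_trunk[1L] <- TRUE
    to_a <- stats::runif(n_total) < 0.5
    in_ca <- is_trunk | to_a
    in_sa <- is_trunk | !to_a

    keys <- variant_key(vars)
    driver_trunk_prob <- if (subtype %in% c("CNH", "CNL")) 1.0 else 0.6
    want_trunk <- stats::runif(n_drivers) < driver_trunk_prob
    trunk_idx <- which(is_trunk)
    branch_idx <- which(!is_trunk)
    di <- integer(0)
    for (w in want_trunk) {
      src <- if (w && length(setdiff(trunk_idx, di))) {
        setdiff(trunk_idx, di)
      } else {
        setdiff(seq_len(n_total), di)
      }
      di <- c(di, src[sample.int(length(src), 1L)])
    }
    clonal_prob_trunk <- if (subtype %in% c("CNH", "CNL")) 0.8 else 0.5
    drivers <- data.frame(
      key = keys[di],
      location = ifelse(is_trunk[di], "trunk", "branch"),
      clonal = ifelse(is_trunk[di],
                      stats::runif(length(di)) < clonal_prob_trunk,
                      stats::runif(length(di)) < 0.15),
      stringsAsFactors = FALSE
    )

    ca <- vars[in_ca, , drop = FALSE]; ca$component_id <- "Ca"
    sa <- vars[in_sa, , drop = FALSE]; sa$component_id <- "Sa"
    list(
      carcinoma = ca, sarcoma = sa, drivers = drivers,
      truth = list(
        subtype = subtype,
        trunk_fraction_planted = trunk_fraction,
        trunk_fraction_realized = sum(is_trunk) / n_total,
        n_total = n_total, n_trunk = sum(is_trunk)
      )
    )
  })
}

# random rooted bifurcating nested tree over leaves 1..m
random_nested_tree <- function(m) {
  tree <- 1L
  if (m == 1L) return(tree)
  for (leaf in 2:m) {
    options <- attach_leaf_everywhere(tree, leaf)
    tree <- options[[sample.int(length(options), 1L)]]
  }
  tree
}

#' Generate a multi-region tumor with a planted phylogeny
#'
#' Draws a random bifurcating topology over the regions, drops mutations on
#' its edges (Poisson counts; internal edges and the trunk carry at least one
#' mutation so the topology is identifiable), and emits the binary
#' region-by-variant presence matrix implied by the tree. With zero homoplasy
#' the matrix is a perfect phylogeny and the parsimony reconstruction must
#' recover the planted topology exactly.
#'
#' @param n_regions Number of sampled regions (2-8).
#' @param seed Integer seed.
#' @param trunk_mean Poisson mean for trunk (shared) mutations (default 30).
#' @param branch_mean Poisson mean for branch mutations (default 8).
#' @param homoplasy_rate Per-mutation probability of an extra independent
#'   gain on a second edge (default 0).
#' @return List: presence (regions x variants), phylo (planted ape tree with
#'   germline outgroup, branch lengths = mutation counts), newick,
#'   edge_counts (named by clade label), truth (edge labels per mutation).
#' @export
generate_multiregion <- function(n_regions = 4L, seed = 1L, trunk_mean = 30,
                                 branch_mean = 8, homoplasy_rate = 0) {
  stopifnot(n_regions >= 2L, n_regions <= 8L)
  with_seed(seed, {
    m <- as.integer(n_regions)
    region_names <- paste0("T", seq_len(m))
    topo <- compile_topology(random_nested_tree(m), m)
    below <- leaves_below(topo, region_names)
    top_node <- topo$kids[nrow(topo$kids), 1L]
    non_root <- setdiff(seq_len(2L * m + 1L), c(topo$root, m + 1L))

    edge_counts <- integer(2L * m + 1L)
    for (node in non_root) {
      edge_counts[node] <- if (node == top_node) {
        stats::rpois(1, trunk_mean) + 1L
      } else if (node > m + 1L) {
        stats::rpois(1, branch_mean) + 1L
      } else {
        stats::rpois(1, branch_mean)
      }
    }

    labels <- vapply(below, function(l) paste(l, collapse = ","), character(1))
    cols <- list()
    truth_edge <- character(0)
    vi <- 0L
    for (node in non_root) {
      if (edge_counts[node] == 0L) next
      carriers <- as.integer(match(below[[node]], region_names))
      for (k in seq_len(edge_counts[node])) {
        vi <- vi + 1L
        v <- integer(m)
        v[carriers] <- 1L
        edge_lab <- labels[node]
        if (homoplasy_rate > 0 && stats::runif(1) < homoplasy_rate) {
          other <- sample(setdiff(non_root, node), 1L)
          v[as.integer(match(below[[other]], region_names))] <- 1L
          edge_lab <- paste(edge_lab, labels[other], sep = ";")
        }
        cols[[vi]] <- v
        truth_edge <- c(truth_edge, edge_lab)
      }
    }
    presence <- do.call(cbind, cols)
    rownames(presence) <- region_names
    colnames(presence) <- sprintf("mut%04d", seq_len(ncol(presence)))

    nwk <- paste0(newick_string(topo, topo$root, region_names, edge_counts,
                                "germline"), ";")
    list(
      presence = presence, phylo = ape::read.tree(text = nwk), newick = nwk,
      edge_counts = stats::setNames(edge_counts[non_root], labels[non_root]),
      truth = data.frame(variant = colnames(presence), edge = truth_edge,
                         stringsAsFactors = FALSE)
    )
  })
}
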