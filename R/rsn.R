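#' @title Subtrait decomposition and RSN block statistics
#' @description A significant trait is oriented so positive entries
#'   mean greater integrity in the higher-weight group, split into an
#'   enhanced and a diminished subtrait at a z threshold, reduced to
#'   the giant connected component (discarding spurious edges touching
#'   only one or a few areas), and summarized per
#'   resting-state-network block. The maximal enhanced presence serves
#'   as the null threshold for flagging over-represented diminished
#'   blocks.
#' @name subtrait-rsn
NULL

new_subtrait <- function(edges, polarity, n_nodes, z_thresh) {
  structure(edges, polarity = polarity, n_nodes = as.integer(n_nodes),
            z_thresh = z_thresh,
            class = c("subtrait", class(tibble::tibble())))
}

#' Orientation of a trait from its group weight difference
#'
#' Positive trait entries should mean greater presence in the
#' elevated-weight group. Returns +1 when the `elevated` group has the
#' higher mean weight, -1 otherwise; multiply the trait by this before
#' splitting.
#'
#' @param weights Named numeric weight vector (names = subject ids).
#' @param groups Grouping vector aligned with `weights`.
#' @param elevated Group whose elevated presence defines "enhanced"
#'   (default `"relative"`).
#' @return +1 or -1.
#' @export
trait_orientation <- function(weights, groups, elevated = "relative") {
  g <- as.character(groups)
  if (!elevated %in% g) rlang::abort(sprintf("Group '%s' not found.", elevated))
  d <- mean(weights[g == elevated]) - mean(weights[g != elevated])
  if (d >= 0) 1 else -1
}

#' Split a trait into enhanced and diminished subtraits
#'
#' The trait vector is standardized (z-scored over edges) and oriented;
#' entries above `+z_thresh` become the enhanced subtrait, entries
#' below `-z_thresh` the diminished one (magnitudes = |z|); everything
#' in between is dropped as spurious.
#'
#' @param trait Numeric edge vector (length `n (n - 1) / 2`).
#' @param orientation +1 or -1, see [trait_orientation()].
#' @param z_thresh Positive inclusion threshold on the standardized
#'   trait (default 2).
#' @param n_nodes Node count; inferred from the vector length when
#'   omitted.
#' @return List with `enhanced` and `diminished` subtraits (tibbles
#'   with `i`, `j`, `magnitude` and attributes `polarity`, `n_nodes`,
#'   `z_thresh`). Warns when both are empty.
#' @export
split_subtraits <- function(trait, orientation = 1, z_thresh = 2,
                            n_nodes = NULL) {
  stopifnot(orientation %in% c(-1, 1))
  if (z_thresh < 0) rlang::abort("`z_thresh` must be non-negative.")
  n_nodes <- n_nodes %||% nodes_from_edges(length(trait))
  if (is.na(n_nodes)) {
    rlang::abort("Trait length is not a valid edge-vector length.")
  }
  z <- orientation * (trait - mean(trait)) / sd(trait)
  ep <- edge_pairs(n_nodes)
  enh_idx <- which(z > z_thresh)
  dim_idx <- which(z < -z_thresh)
  enhanced <- new_subtrait(
    tibble::tibble(i = ep$i[enh_idx], j = ep$j[enh_idx],
                   magnitude = z[enh_idx]),
    "enhanced", n_nodes, z_thresh)
  diminished <- new_subtrait(
    tibble::tibble(i = ep$i[dim_idx], j = ep$j[dim_idx],
                   magnitude = -z[dim_idx]),
    "diminished", n_nodes, z_thresh)
  if (nrow(enhanced) == 0 && nrow(diminished) == 0) {
    rlang::warn("All trait entries fall below the threshold; both subtraits are empty.")
  }
  list(enhanced = enhanced, diminished = diminished)
}

#' Giant connected component of a subtrait
#'
#' Keeps only the edges whose both endpoints belong to the largest
#' connected component of the graph formed by the subtrait's edges.
#' Ties on node count are broken by edge count, then by smallest node
#' index.
#'
#' @param sub A subtrait tibble from [split_subtraits()].
#' @return The filtered subtrait (same class and attributes).
#' @export
giant_component <- function(sub) {
  if (nrow(sub) == 0) return(sub)
  g <- igraph::graph_from_data_frame(
    data.frame(from = sub$i, to = sub$j), directed = FALSE)
  comp <- igraph::components(g)
  memb <- comp$membership
  vnames <- as.integer(names(memb))
  sizes <- comp$csize
  best_size <- max(sizes)
  cand <- which(sizes == best_size)
  if (length(cand) > 1) {
    ecount <- vapply(cand, function(ci) {
      nodes <- vnames[memb == ci]
      sum(sub$i %in% nodes & sub$j %in% nodes)
    }, numeric(1))
    cand <- cand[ecount == max(ecount)]
    if (length(cand) > 1) {
      minnode <- vapply(cand, function(ci) min(vnames[memb == ci]), numeric(1))
      cand <- cand[which.min(minnode)]
    }
  }
  keep_nodes <- vnames[memb == cand[1]]
  out <- sub[sub$i %in% keep_nodes & sub$j %in% keep_nodes, ]
  new_subtrait(out, attr(sub, "polarity"), attr(sub, "n_nodes"),
               attr(sub, "z_thresh"))
}

#' Per-RSN-block presence of a subtrait
#'
#' For every unordered network pair (a, b) over the G networks of the
#' partition (G(G+1)/2 blocks), presence = sum of retained edge
#' magnitudes in the block divided by a size-correcting denominator:
#' either the number of retained edges in the block (default; mean
#' magnitude per retained edge) or the number of possible edges of the
#' block given the network sizes. Blocks with no retained edges have
#' presence 0.
#'
#' @param sub Subtrait tibble.
#' @param partition Partition tibble covering all nodes.
#' @param denominator_mode `"retained_edges"` (default) or
#'   `"possible_edges"`.
#' @return An `rsn_presence` tibble: `network_a`, `network_b`,
#'   `presence`, `sum_magnitude`, `n_retained`, `denominator`; the
#'   polarity and mode ride along as attributes.
#' @export
rsn_presence <- function(sub, partition,
                         denominator_mode = c("retained_edges",
                                              "possible_edges")) {
  denominator_mode <- match.arg(denominator_mode)
  n <- attr(sub, "n_nodes")
  if (nrow(partition) < n ||
      (nrow(sub) > 0 && max(sub$i, sub$j) > nrow(partition))) {
    rlang::abort("Subtrait references nodes outside the partition.")
  }
  nets <- levels(partition$network)
  G <- length(nets)
  sizes <- table(partition$network)
  grid <- tidyr::expand_grid(a = seq_len(G), b = seq_len(G)) |>
    dplyr::filter(.data$a <= .data$b)
  possible <- ifelse(grid$a == grid$b,
                     sizes[grid$a] * (sizes[grid$a] - 1) / 2,
                     sizes[grid$a] * sizes[grid$b])
  lab <- as.integer(partition$network)
  if (nrow(sub) > 0) {
    ea <- pmin(lab[sub$i], lab[sub$j])
    eb <- pmax(lab[sub$i], lab[sub$j])
    key <- paste(ea, eb)
    agg <- tibble::tibble(key = key, magnitude = sub$magnitude) |>
      dplyr::group_by(.data$key) |>
      dplyr::summarise(sum_magnitude = sum(.data$magnitude),
                       n_retained = dplyr::n(), .groups = "drop")
  } else {
    agg <- tibble::tibble(key = character(0), sum_magnitude = numeric(0),
                          n_retained = integer(0))
  }
  out <- tibble::tibble(
    network_a = factor(nets[grid$a], levels = nets),
    network_b = factor(nets[grid$b], levels = nets),
    key = paste(grid$a, grid$b)) |>
    dplyr::left_join(agg, by = "key") |>
    dplyr::mutate(
      sum_magnitude = dplyr::coalesce(.data$sum_magnitude, 0),
      n_retained = dplyr::coalesce(.data$n_retained, 0L),
      denominator = dplyr::case_when(
        denominator_mode == "possible_edges" ~ as.numeric(possible),
        .default = as.numeric(.data$n_retained)),
      presence = dplyr::if_else(.data$denominator > 0,
                                .data$sum_magnitude / .data$denominator, 0)) |>
    dplyr::select("network_a", "network_b", "presence", "sum_magnitude",
                  "n_retained", "denominator")
  structure(out, polarity = attr(sub, "polarity"),
            denominator_mode = denominator_mode,
            class = c("rsn_presence", class(tibble::tibble())))
}

#' Flag over-represented diminished blocks
#'
#' Under the working hypothesis that the at-risk group gains no true
#' integrity, the maximal block presence of the *enhanced* subtrait is
#' treated as the noise ceiling: any diminished block exceeding it is
#' flagged as over-represented. The validation record notes whether
#' the hypothesis check holds (all enhanced values below the maximal
#' diminished presence).
#'
#' @param enhanced,diminished `rsn_presence` tibbles over the same
#'   partition.
#' @return List of class `rsn_overrep`: `threshold` (max enhanced
#'   presence; 0 with a warning when the enhanced subtrait is empty),
#'   `blocks` (diminished presence with `overrepresented` flags),
#'   `validation` (`max_enhanced`, `max_diminished`,
#'   `hypothesis_supported`).
#' @export
overrepresented_blocks <- function(enhanced, diminished) {
  if (!identical(levels(enhanced$network_a), levels(diminished$network_a))) {
    rlang::abort("Presence maps use different partitions.")
  }
  if (all(enhanced$n_retained == 0)) {
    rlang::warn("Enhanced subtrait is empty; threshold is 0 and every nonzero diminished block is flagged.")
    threshold <- 0
  } else {
    threshold <- max(enhanced$presence)
  }
  blocks <- dplyr::mutate(tibble::as_tibble(diminished),
                          overrepresented = .data$presence > threshold)
  max_dim <- if (all(diminished$n_retained == 0)) 0 else
    max(diminished$presence)
  structure(list(threshold = threshold, blocks = blocks,
                 validation = list(max_enhanced = threshold,
                                   max_diminished = max_dim,
                                   hypothesis_supported = threshold < max_dim)),
            class = "rsn_overrep")
}

#' @export
print.rsn_overrep <- function(x, ...) {
  cat(sprintf(
    "<rsn_overrep> threshold (max enhanced presence) = %.4f; max diminished = %.4f; hypothesis %s\n",
    x$threshold, x$validation$max_diminished,
    if (x$validation$hypothesis_supported) "supported" else "not supported"))
  flagged <- dplyr::filter(x$blocks, .data$overrepresented)
  if (nrow(flagged) > 0) {
    cat("Over-represented diminished blocks:\n")
    print(dplyr::select(flagged, "network_a", "network_b", "presence"))
  } else {
    cat("No over-represented blocks.\n")
  }
  invisible(x)
}

#' Full RSN block analysis of one trait
#'
#' Convenience wrapper: orients the trait by the group weight
#' difference, splits it into subtraits, retains giant components,
#' computes block presences for both polarities and flags
#' over-represented diminished blocks.
#'
#' @param trait Numeric edge vector.
#' @param weights Named weight vector for the trait.
#' @param groups Group labels aligned with `weights`.
#' @param partition Partition tibble.
#' @param z_thresh Subtrait inclusion threshold (default 2).
#' @param denominator_mode See [rsn_presence()].
#' @param elevated Group defining "enhanced" (default `"relative"`).
#' @return List of class `rsn_analysis`: `orientation`, `enhanced`,
#'   `diminished` (giant-component subtraits), `presence_enhanced`,
#'   `presence_diminished`, `overrep`.
#' @export
rsn_block_analysis <- function(trait, weights, groups, partition,
                               z_thresh = 2,
                               denominator_mode = "retained_edges",
                               elevated = "relative") {
  orientation <- trait_orientation(weights, groups, elevated)
  parts <- split_subtraits(trait, orientation, z_thresh,
                           n_nodes = nrow(partition))
  enh <- giant_component(parts$enhanced)
  dim_ <- giant_component(parts$diminished)
  pe <- rsn_presence(enh, partition, denominator_mode)
  pd <- rsn_presence(dim_, partition, denominator_mode)
  ov <- overrepresented_blocks(pe, pd)
  structure(list(orientation = orientation, enhanced = enh,
                 diminished = dim_, presence_enhanced = pe,
                 presence_diminished = pd, overrep = ov,
                 z_thresh = z_thresh, denominator_mode = denominator_mode),
            class = "rsn_analysis")
}
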