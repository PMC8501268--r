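test_that("split_subtraits partitions thresholded entries by polarity", {
  # antisymmetric toy trait: one strong positive, one strong negative edge
  n <- 6; m <- n_edges(n)
  trait <- rep(0, m)
  trait[1] <- 30   # edge (1,2)
  trait[5] <- -30  # edge (1,6)
  parts <- split_subtraits(trait, orientation = 1, z_thresh = 2)
  expect_equal(nrow(parts$enhanced), 1)
  expect_equal(nrow(parts$diminished), 1)
  expect_equal(c(parts$enhanced$i, parts$enhanced$j), c(1, 2))
  expect_equal(c(parts$diminished$i, parts$diminished$j), c(1, 6))
  expect_true(all(parts$enhanced$magnitude > 0))
  expect_true(all(parts$diminished$magnitude > 0))

  # orientation -1 swaps the polarities
  flip <- split_subtraits(trait, orientation = -1, z_thresh = 2)
  expect_equal(c(flip$enhanced$i, flip$enhanced$j), c(1, 6))

  # z_thresh = 0: every nonzero standardized entry is assigned,
  # counts add up to m (no exact zeros after standardization here)
  withr::with_seed(1, v <- rnorm(n_edges(10)))
  all_in <- split_subtraits(v, z_thresh = 0)
  expect_equal(nrow(all_in$enhanced) + nrow(all_in$diminished), n_edges(10))
  expect_equal(nrow(dplyr::inner_join(
    tibble::as_tibble(all_in$enhanced)[, c("i", "j")],
    tibble::as_tibble(all_in$diminished)[, c("i", "j")],
    by = c("i", "j"))), 0)

  # Gaussian tail mass: about 4.55% of entries survive |z| > 2
  withr::with_seed(2, {
    big <- rnorm(n_edges(200))
    sp <- split_subtraits(big, z_thresh = 2)
    frac <- (nrow(sp$enhanced) + nrow(sp$diminished)) / n_edges(200)
    expect_equal(frac, 2 * pnorm(-2), tolerance = 0.15)
  })

  # all entries below threshold: empty subtraits with a warning
  expect_warning(split_subtraits(rep(c(1, 1.001), 3), z_thresh = 5),
                 "empty")
})

test_that("giant_component matches the DFS oracle and keeps invariants", {
  mk <- function(edges_ij, n = 30) {
    conntrait:::new_subtrait(
      tibble::tibble(i = edges_ij[, 1], j = edges_ij[, 2],
                     magnitude = rep(1, nrow(edges_ij))),
      "diminished", n, 2)
  }
  # chain {1-2, 2-3} plus separate dyad {7-8}: chain is kept
  sub <- mk(rbind(c(1, 2), c(2, 3), c(7, 8)))
  out <- giant_component(sub)
  expect_equal(sort(unique(c(out$i, out$j))), 1:3)

  # triangle beats an isolated dyad
  sub2 <- mk(rbind(c(1, 2), c(2, 3), c(1, 3), c(9, 10)))
  out2 <- giant_component(sub2)
  expect_equal(sort(unique(c(out2$i, out2$j))), 1:3)

  # empty input passes through
  empty <- mk(matrix(numeric(0), 0, 2))
  expect_equal(nrow(giant_component(empty)), 0)

  # 200 random graphs: membership identical to the DFS oracle
  withr::with_seed(55, {
    for (r in 1:200) {
      n <- sample(5:30, 1)
      ne <- sample(1:40, 1)
      ep <- edge_pairs(n)
      pick <- ep[sample(nrow(ep), min(ne, nrow(ep))), ]
      sub <- conntrait:::new_subtrait(
        tibble::tibble(i = pick$i, j = pick$j,
                       magnitude = runif(nrow(pick)) + 0.1),
        "enhanced", n, 2)
      got <- giant_component(sub)
      comp <- dfs_components(pick)
      sizes <- table(comp)
      giant_nodes <- as.integer(names(comp)[comp %in%
        as.integer(names(sizes)[sizes == max(sizes)])])
      # oracle: edges whose both ends lie in some maximal component;
      # compare on the package's tie-break (node count, edge count,
      # smallest node) by checking the kept edge set is one of the
      # maximal components' edge sets
      kept_nodes <- sort(unique(c(got$i, got$j)))
      cand_ids <- as.integer(names(sizes)[sizes == max(sizes)])
      match_any <- any(vapply(cand_ids, function(ci) {
        nodes <- sort(as.integer(names(comp)[comp == ci]))
        identical(kept_nodes, nodes)
      }, logical(1)))
      expect_true(match_any)
      # subgraph of the input, and idempotent
      expect_true(all(paste(got$i, got$j) %in% paste(pick$i, pick$j)))
      expect_identical(giant_component(got), got)
    }
  })
})

test_that("giant_component tie-breaks by edge count then smallest node", {
  # two components with 3 nodes each: a triangle (3 edges) and a chain
  # (2 edges) -> triangle wins on edge count
  sub <- conntrait:::new_subtrait(
    tibble::tibble(i = c(4, 5, 4, 1, 2), j = c(5, 6, 6, 2, 3),
                   magnitude = rep(1, 5)),
    "enhanced", 10, 2)
  out <- giant_component(sub)
  expect_equal(sort(unique(c(out$i, out$j))), 4:6)

  # two identical chains -> the one containing the smallest node wins
  sub2 <- conntrait:::new_subtrait(
    tibble::tibble(i = c(5, 6, 1, 2), j = c(6, 7, 2, 3),
                   magnitude = rep(1, 4)),
    "enhanced", 10, 2)
  out2 <- giant_component(sub2)
  expect_equal(sort(unique(c(out2$i, out2$j))), 1:3)
})

test_that("rsn_presence computes block sums over the right denominators", {
  part <- generate_partition(8, c(A = 4, B = 4))
  mk <- function(df) conntrait:::new_subtrait(df, "diminished", 8, 2)

  # one A-B edge of magnitude 2: retained-edges presence is 2
  one <- mk(tibble::tibble(i = 1, j = 5, magnitude = 2))
  pres <- rsn_presence(one, part)
  ab <- dplyr::filter(pres, .data$network_a == "A", .data$network_b == "B")
  expect_equal(ab$presence, 2)
  # zero-edge blocks have presence 0 and the grid covers G(G+1)/2 blocks
  expect_equal(nrow(pres), 3)
  expect_equal(dplyr::filter(pres, .data$network_a == "A",
                             .data$network_b == "A")$presence, 0)

  # two within-A edges, magnitudes 1 and 3
  two <- mk(tibble::tibble(i = c(1, 2), j = c(2, 3), magnitude = c(1, 3)))
  p_ret <- rsn_presence(two, part)
  aa <- dplyr::filter(p_ret, .data$network_a == "A", .data$network_b == "A")
  expect_equal(aa$presence, 2)        # (1+3)/2 retained edges
  p_pos <- rsn_presence(two, part, denominator_mode = "possible_edges")
  aa2 <- dplyr::filter(p_pos, .data$network_a == "A", .data$network_b == "A")
  expect_equal(aa2$presence, 4 / 6)   # 4 over the 6 possible A-A edges

  # conservation: sum(presence * denominator) == sum of magnitudes
  withr::with_seed(7, {
    for (r in 1:20) {
      n <- 20
      part2 <- generate_partition(n, c(A = 6, B = 7, C = 7))
      ep <- edge_pairs(n)
      pick <- ep[sample(nrow(ep), 25), ]
      sub <- mk2 <- conntrait:::new_subtrait(
        tibble::tibble(i = pick$i, j = pick$j, magnitude = rexp(25)),
        "enhanced", n, 2)
      for (mode in c("retained_edges", "possible_edges")) {
        pr <- rsn_presence(sub, part2, mode)
        expect_equal(sum(pr$presence * pr$denominator), sum(sub$magnitude),
                     tolerance = 1e-12)
      }
    }
  })

  # nodes outside the partition are an error
  bad <- mk(tibble::tibble(i = 1, j = 12, magnitude = 1))
  expect_error(rsn_presence(bad, part), "outside")
})

test_that("overrepresentation thresholds on the maximal enhanced presence", {
  part <- generate_partition(8, c(A = 4, B = 4))
  mk <- function(df, pol) conntrait:::new_subtrait(df, pol, 8, 2)
  enh <- rsn_presence(
    mk(tibble::tibble(i = c(1, 2), j = c(2, 3), magnitude = c(0.5, 0.7)),
       "enhanced"), part)
  dim_lo <- rsn_presence(
    mk(tibble::tibble(i = 5, j = 6, magnitude = 0.3), "diminished"), part)
  ov <- overrepresented_blocks(enh, dim_lo)
  expect_equal(ov$threshold, 0.6)     # max enhanced presence
  expect_false(any(ov$blocks$overrepresented))
  expect_false(ov$validation$hypothesis_supported)

  dim_hi <- rsn_presence(
    mk(tibble::tibble(i = c(5, 6), j = c(6, 7), magnitude = c(2, 4)),
       "diminished"), part)
  ov2 <- overrepresented_blocks(enh, dim_hi)
  flagged <- dplyr::filter(ov2$blocks, .data$overrepresented)
  expect_equal(as.character(flagged$network_a), "B")
  expect_equal(as.character(flagged$network_b), "B")
  expect_true(ov2$validation$hypothesis_supported)

  # empty enhanced subtrait: threshold 0, warning, nonzero blocks flagged
  empty_enh <- rsn_presence(mk(tibble::tibble(i = integer(0), j = integer(0),
                                              magnitude = numeric(0)),
                               "enhanced"), part)
  expect_warning(ov3 <- overrepresented_blocks(empty_enh, dim_lo), "empty")
  expect_equal(ov3$threshold, 0)
  expect_true(any(ov3$blocks$overrepresented))
})

test_that("a planted diminished block is flagged and background is not", {
  part <- generate_partition(60)
  hits <- logical(20)
  clean <- logical(20)
  for (r in 1:20) {
    pat <- generate_trait_patterns(
      part,
      list(list(trait_block("visual", "visual", sign = -1, amplitude = 4),
                trait_block("default_mode", "default_mode", sign = 1,
                            amplitude = 2))),
      seed = 7000 + r)
    res <- rsn_block_analysis(pat[1, ],
                              weights = setNames(c(1, 1, 0, 0),
                                                 paste0("s", 1:4)),
                              groups = c("relative", "relative",
                                         "control", "control"),
                              partition = part, z_thresh = 2)
    flagged <- dplyr::filter(res$overrep$blocks, .data$overrepresented)
    key <- paste(flagged$network_a, flagged$network_b)
    hits[r] <- "visual visual" %in% key
    clean[r] <- all(key == "visual visual")
  }
  expect_gte(mean(hits & clean), 0.9)
})

test_that("trait orientation follows the elevated-weight group", {
  w <- setNames(c(2, 2, 0.5, 0.5), paste0("s", 1:4))
  g <- c("relative", "relative", "control", "control")
  expect_equal(trait_orientation(w, g), 1)
  expect_equal(trait_orientation(-w + 2.5, g), -1)
  expect_error(trait_orientation(w, rep("x", 4)), "not found")

  # rsn_block_analysis flips a sign-inverted trait back: the planted
  # diminished block is recovered either way
  part <- generate_partition(60)
  pat <- generate_trait_patterns(
    part, list(list(trait_block("visual", "visual", sign = -1,
                                amplitude = 4),
                    trait_block("default_mode", "default_mode", sign = 1,
                                amplitude = 2))), seed = 123)
  for (flip in c(1, -1)) {
    res <- rsn_block_analysis(flip * pat[1, ], w * flip - (flip == -1) * 0,
                              groups = g, partition = part)
    # with weights fixed to "relatives higher", orientation must undo flip
    flagged <- dplyr::filter(res$overrep$blocks, .data$overrepresented)
    expect_true("visual" %in% as.character(flagged$network_a))
  }
})
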