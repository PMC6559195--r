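# Ontology validation, parental aggregation, hemisphere splitting, ROI
# overlap reports and incidence maps.

toy_ont <- function() {
  # root -> {A -> {a1, a2}, B -> {b1}}
  ontology_table(data.frame(
    id = c(1L, 2L, 3L, 4L, 5L, 6L),
    acronym = c("root", "A", "B", "a1", "a2", "b1"),
    name = c("root", "region A", "region B", "sub a1", "sub a2", "sub b1"),
    parent_id = c(NA, 1L, 1L, 2L, 2L, 3L)
  ))
}

test_that("ontology validation rejects malformed tables", {
  expect_s3_class(toy_ont(), "ontology_table")
  expect_error(ontology_table(data.frame(id = c(1, 1), acronym = c("a", "b"),
                                         name = c("a", "b"),
                                         parent_id = c(NA, NA))), "duplicate")
  expect_error(ontology_table(data.frame(id = 1L, acronym = "a", name = "a",
                                         parent_id = 9L)), "missing")
  expect_error(ontology_table(data.frame(id = c(1L, 2L), acronym = c("a", "b"),
                                         name = c("a", "b"),
                                         parent_id = c(2L, 1L))), "cycle")
})

test_that("parental aggregation matches the brute-force ancestor walk", {
  ont <- toy_ont()
  lab <- label_volume(array(c(4L, 5L, 6L, 0L), c(4, 1, 1)))
  ag <- aggregate_to_parents(lab, ont, c(2L, 3L))
  expect_equal(as.vector(ag$data), c(2, 2, 3, 0))

  # identity when the parent set is the leaves themselves
  idm <- aggregate_to_parents(lab, ont, c(4L, 5L, 6L))
  expect_equal(as.vector(idm$data), as.vector(lab$data))

  # a root voxel with no ancestor in the set becomes a reported orphan
  labr <- label_volume(array(c(1L, 4L), c(2, 1, 1)))
  agr <- aggregate_to_parents(labr, ont, 2L)
  expect_equal(as.vector(agr$data), c(0, 2))
  expect_equal(attr(agr, "orphans"), 1L)

  expect_error(aggregate_to_parents(lab, ont, integer(0)), "empty")
  expect_error(aggregate_to_parents(lab, ont, 99L), "not in ontology")
})

test_that("aggregation agrees with exhaustive path enumeration on random forests", {
  set.seed(42)
  for (rep in 1:5) {
    n <- sample(20:100, 1)
    # random forest: parent of node i is a uniformly chosen earlier node
    parent <- c(NA_integer_, vapply(2:n, function(i)
      if (runif(1) < 0.1) NA_integer_ else sample.int(i - 1, 1), integer(1)))
    ont <- ontology_table(data.frame(
      id = seq_len(n), acronym = paste0("n", seq_len(n)),
      name = paste0("node ", seq_len(n)), parent_id = parent))
    parent_set <- sort(sample(seq_len(n), max(2, n %/% 5)))
    codes <- sample(seq_len(n), 24, replace = TRUE)
    lab <- label_volume(array(as.integer(codes), c(24, 1, 1)))
    ag <- aggregate_to_parents(lab, ont, parent_set)
    oracle <- vapply(codes, oracle_nearest_ancestor, integer(1),
                     ont = ont, parent_set = parent_set)
    expect_equal(as.vector(ag$data), as.numeric(oracle))

    # idempotence once the codomain is inside the parent set
    nz <- as.vector(ag$data)
    nz <- nz[nz != 0]
    if (length(nz)) {
      ag2 <- aggregate_to_parents(label_volume(array(as.integer(nz), c(length(nz), 1, 1))),
                                  ont, parent_set)
      expect_equal(as.vector(ag2$data), nz)
    }

    # conservation: non-background voxels either keep a label or are orphans
    orphans <- attr(ag, "orphans")
    expect_equal(sum(ag$data > 0) + sum(codes %in% orphans), length(codes))
  }
})

test_that("hemisphere split conserves counts and is invertible", {
  ta <- make_toy_atlas(depth = 2, branching = 3)
  sp <- split_hemispheres(ta$labels)
  off <- attr(sp, "hemisphere_offset")
  base <- ta$labels$data
  for (id in ta$leaf_ids) {
    l <- sum(sp$data == id)
    r <- sum(sp$data == id + off)
    expect_equal(l + r, sum(base == id))
    expect_equal(l, r)  # mirrored phantom is symmetric
  }
  # distinct non-background codes double for the mirrored phantom
  n0 <- length(setdiff(unique(as.vector(base)), 0))
  n1 <- length(setdiff(unique(as.vector(sp$data)), 0))
  expect_equal(n1, 2 * n0)

  merged <- merge_hemispheres(sp)
  expect_equal(merged$data, base)

  expect_error(split_hemispheres(ta$labels, hemisphere_offset = 3L), "collides")
  expect_error(split_hemispheres(ta$labels, midline_index = 100), "midline")
})

test_that("region overlap reports count voxels and fractions correctly", {
  ont <- toy_ont()
  arr <- array(0L, c(8, 4, 2))
  arr[1:4, , ] <- 4L
  arr[5:8, , ] <- 5L
  lab <- label_volume(arr)

  # ROI inside one region
  roi <- array(0, c(8, 4, 2))
  roi[2:3, 2:3, ] <- 1
  rep1 <- region_overlap_report(roi, lab, ont)
  expect_equal(nrow(rep1), 1)
  expect_equal(rep1$fraction_of_roi, 1)
  expect_equal(rep1$voxels_in_roi, 8)
  expect_equal(rep1$fraction_of_region, 8 / 32)

  # ROI straddling both regions equally
  roi2 <- array(0, c(8, 4, 2))
  roi2[3:6, 1, 1] <- 1
  rep2 <- region_overlap_report(roi2, lab, ont)
  expect_equal(sort(rep2$fraction_of_roi), c(0.5, 0.5))
  expect_equal(attr(rep2, "background_fraction"), 0)

  # ROI entirely in background
  arrbg <- array(0L, c(8, 4, 2))
  labbg <- label_volume(arrbg)
  rep3 <- region_overlap_report(roi2, labbg, ont)
  expect_equal(nrow(rep3), 0)
  expect_equal(attr(rep3, "background_fraction"), 1)

  expect_error(region_overlap_report(array(0, c(8, 4, 2)), lab, ont), "empty ROI")
})

test_that("incidence maps equal the elementwise mask sum", {
  d <- c(6, 6, 4)
  m1 <- array(0, d); m1[1:3, , ] <- 1
  m2 <- array(0, d); m2[4:6, , ] <- 1

  # N identical masks give N x mask
  out <- incidence_map(list(m1, m1, m1))
  expect_equal(out$data, 3 * m1)

  # disjoint masks never exceed 1
  expect_equal(max(incidence_map(list(m1, m2))$data), 1)

  # random masks match direct elementwise addition
  set.seed(9)
  ms <- lapply(1:3, function(i) array(rbinom(prod(d), 1, 0.4), d))
  out3 <- incidence_map(ms)
  expect_equal(out3$data, ms[[1]] + ms[[2]] + ms[[3]])
  expect_equal(sum(out3$data), sum(sapply(ms, sum)))

  expect_error(incidence_map(list(m1, array(0, c(2, 2, 2)))), "differ")
  expect_error(incidence_map(list(array(2, d))), "binary")
  expect_error(incidence_map(list()), "at least one")
})
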