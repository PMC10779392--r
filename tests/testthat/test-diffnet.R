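test_that("difference sets enumerate 10/21/35 pairs for a 5+7 cohort", {
  set.seed(11)
  edges <- matrix(stats::runif(6 * 12, -1, 1), 6, 12)
  groups <- rep(c("control", "cko"), c(5, 7))
  cc <- connectomes_from_edges(edges, groups)
  ds <- difference_matrices(cc)
  expect_equal(ncol(ds$control_control$diffs), 10L)
  expect_equal(ncol(ds$cko_cko$diffs), 21L)
  expect_equal(ncol(ds$control_cko$diffs), 35L)
  # cross pairs are oriented control - cko
  expect_equal(ds$control_cko$diffs[, 1],
               edges[, 1] - edges[, 6], ignore_attr = TRUE)
  # within pairs are element-wise subtractions, each counted once
  expect_equal(ds$control_control$diffs[, 1],
               edges[, 1] - edges[, 2], ignore_attr = TRUE)
  expect_false(any(duplicated(ds$cko_cko$pairs)))

  same <- connectomes_from_edges(edges[, c(1, 1, 1, 1)],
                                 rep(c("control", "cko"), each = 2))
  ds0 <- difference_matrices(same)
  expect_true(all(ds0$control_cko$diffs == 0))

  expect_error(difference_matrices(cc[c(1, 6, 7)]), "at least 2")
})

test_that("pattern similarity is orientation-invariant and detects planted structure", {
  set.seed(12)
  edges <- matrix(stats::rnorm(10 * 8, sd = 0.1), 10, 8)
  groups <- rep(c("control", "cko"), each = 4)
  ds <- difference_matrices(connectomes_from_edges(edges, groups))

  res <- pairwise_pattern_r2(ds$control_control, ds$cko_cko,
                             n_perm = 200, seed = 1)
  flipped <- ds$cko_cko
  flipped$diffs[, 2] <- -flipped$diffs[, 2]
  res_f <- pairwise_pattern_r2(ds$control_control, flipped,
                               n_perm = 200, seed = 1)
  expect_equal(res$mean_r2, res_f$mean_r2, tolerance = 1e-12)
  expect_equal(res$p, res_f$p)

  # a single identical pair against itself has R2 exactly 1
  single <- ds$control_control
  single$diffs <- single$diffs[, 1, drop = FALSE]
  self <- pairwise_pattern_r2(single, single, n_perm = 50, seed = 1)
  expect_equal(self$mean_r2, 1, tolerance = 1e-12)

  # planted subject pattern (b > 0, no group effect): within-class mean R2
  # beats its own permutation null
  spec <- cohort_spec(n_control = 4, n_cko = 4, n_regions = 20,
                      n_frames = 300, subject_effect_sd = 0.25,
                      group_effect = 0, seed = 13)
  ch <- simulate_bold_cohort(spec)
  dsp <- difference_matrices(lapply(ch$series, compute_connectome))
  within <- pairwise_pattern_r2(dsp$control_control, n_perm = 500,
                                seed = 2)
  expect_gt(within$mean_r2, within$null_q95)
  expect_lt(within$p, 0.05)

  zero <- ds$control_control
  zero$diffs[, 1] <- 0
  expect_error(pairwise_pattern_r2(zero, n_perm = 10), "degenerate pair")
})

test_that("class patterns are RMS aggregates whose correlation has a t-transform p", {
  set.seed(14)
  d <- structure(list(class = "control-control", pairs = NULL,
                      diffs = matrix(c(3, -4, 0, 4, 3, 0), 3, 2)),
                 class = "difference_set")
  # per-edge RMS of {3,4}, {-4,3}, {0,0}
  expect_equal(class_pattern(d), c(sqrt(12.5), sqrt(12.5), 0))

  p1 <- stats::runif(10)
  expect_equal(class_pattern_correlation(p1, p1)$r, 1)
  p2 <- stats::runif(10)
  hand <- stats::cor(p1, p2)
  res <- class_pattern_correlation(p1, p2)
  expect_equal(res$r, hand, tolerance = 1e-12)
  expect_equal(res$r_squared, hand^2, tolerance = 1e-12)
  expect_error(class_pattern_correlation(p1, rep(1, 10)), "constant")
  expect_error(class_pattern_correlation(p1, p2[1:5]), "length")

  # shuffled pattern falls below the permutation bound almost surely
  set.seed(15)
  long_a <- stats::runif(200)
  shuffled <- sample(long_a)
  expect_gt(class_pattern_correlation(long_a, long_a)$r_squared, 0.99)
  expect_lt(class_pattern_correlation(long_a, shuffled)$r_squared, 0.05)
})

test_that("discriminative network retains planted edges, honours threshold monotonicity", {
  spec <- cohort_spec(n_control = 8, n_cko = 8, n_regions = 16,
                      n_frames = 400, group_effect = 0.35, seed = 16)
  ch <- simulate_bold_cohort(spec)
  cc <- lapply(ch$series, compute_connectome)
  net2 <- group_discriminative_edges(cc, threshold = 0.2)
  net5 <- group_discriminative_edges(cc, threshold = 0.5)
  expect_true(all(net5$edges$edge %in% net2$edges$edge))
  expect_true(all(net2$edges$r_squared > 0.2))
  # planted edges raise cko synchrony -> sign +1
  planted_rows <- net2$edges[net2$edges$edge %in% ch$truth$group_edges, ]
  expect_true(all(planted_rows$sign == 1))
  expect_true(all(net2$regions %in% seq_len(16)))

  # identical connectomes -> empty network, all edges flagged zero-variance
  same <- connectomes_from_edges(
    matrix(rep(stats::runif(6), 4), 6, 4),
    rep(c("control", "cko"), each = 2))
  expect_warning(net0 <- group_discriminative_edges(same), "zero variance")
  expect_equal(nrow(net0$edges), 0L)
  expect_true(all(net0$r_squared == 0))
})

test_that("per-edge R2 equals the squared point-biserial correlation", {
  set.seed(17)
  edges <- matrix(stats::rnorm(6 * 10), 6, 10)
  groups <- rep(c("control", "cko"), each = 5)
  net <- group_discriminative_edges(connectomes_from_edges(edges, groups),
                                    threshold = 0.99)
  hand <- apply(edges, 1, function(e)
    stats::cor(e, as.numeric(groups == "cko"))^2)
  expect_equal(net$r_squared, hand, tolerance = 1e-12)
})

test_that("region summary tallies edges by macro-region, sign and hemisphere", {
  tab <- toy_region_table(2)  # regions 1,2 left; 3,4 right
  empty <- structure(list(edges = data.frame(edge = integer(),
                                             i = integer(), j = integer(),
                                             region_i = character(),
                                             region_j = character(),
                                             r_squared = numeric(),
                                             sign = numeric()),
                          r_squared = numeric(6), threshold = 0.2,
                          regions = integer(),
                          region_ids = as.character(1:4)),
                     class = "discriminative_network")
  s0 <- map_edges_to_regions(empty, tab)
  expect_true(all(s0$n_edges == 0))

  net <- empty
  net$edges <- data.frame(edge = c(1L, 2L, 6L),
                          i = c(1L, 1L, 3L), j = c(2L, 3L, 4L),
                          region_i = c("1", "1", "3"),
                          region_j = c("2", "3", "4"),
                          r_squared = c(0.5, 0.4, 0.3),
                          sign = c(1, -1, 1))
  net$regions <- c(1L, 2L, 3L, 4L)
  s <- map_edges_to_regions(net, tab)
  # macro m1 holds regions 1 (left) and 3 (right): touched by all 3 edges
  m1 <- s[s$macro_region == "m1", ]
  expect_equal(m1$n_edges, 3L)
  expect_equal(m1$n_increase, 2L)
  expect_equal(m1$n_decrease, 1L)
  expect_equal(m1$n_inter, 1L)
  # macro m2 holds regions 2 and 4: edges 1 and 6
  m2 <- s[s$macro_region == "m2", ]
  expect_equal(m2$n_edges, 2L)
  expect_equal(m2$n_intra_left, 1L)
  expect_equal(m2$n_intra_right, 1L)
})
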