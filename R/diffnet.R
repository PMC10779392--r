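#' Pairwise connectome difference matrices
#'
#' Subtracting one subject's connectome from another's, edge-wise,
#' characterises what distinguishes that pair. Differences are formed for
#' every unordered within-group pair (control-control, cko-cko) and every
#' cross pair oriented control - cko. With n = 5 control and n = 7 cko
#' subjects this yields 10, 21 and 35 pairs.
#'
#' @param connectomes list of `connectome` objects on one region ordering.
#' @param groups group label per connectome (`"control"`/`"cko"`); taken
#'   from the connectomes when omitted.
#' @return Named list of three `difference_set` objects
#'   (`control_control`, `cko_cko`, `control_cko`), each holding `diffs`
#'   (edges x pairs matrix of edge differences), `pairs` (pair metadata)
#'   and `class`.
#' @export
difference_matrices <- function(connectomes, groups = NULL) {
  if (is.null(groups))
    groups <- vapply(connectomes, function(cc) cc$group, character(1))
  subjects <- vapply(connectomes, function(cc) cc$subject, character(1))
  if (!all(groups %in% c("control", "cko")))
    stop("groups must be 'control' or 'cko'", call. = FALSE)
  edges <- vapply(connectomes, function(cc) vectorize_edges(cc)$value,
                  numeric(length(vectorize_edges(connectomes[[1L]])$value)))
  ctrl <- which(groups == "control")
  cko <- which(groups == "cko")
  if (length(ctrl) < 2L || length(cko) < 2L)
    stop("each group needs at least 2 subjects (control: ", length(ctrl),
         ", cko: ", length(cko), ")", call. = FALSE)
  within_set <- function(members, class) {
    pr <- t(utils::combn(members, 2L))
    diffs <- edges[, pr[, 1L], drop = FALSE] -
             edges[, pr[, 2L], drop = FALSE]
    structure(list(class = class,
                   pairs = data.frame(a = subjects[pr[, 1L]],
                                      b = subjects[pr[, 2L]],
                                      stringsAsFactors = FALSE),
                   diffs = diffs),
              class = "difference_set")
  }
  cross <- expand.grid(a = ctrl, b = cko)
  cross_diffs <- edges[, cross$a, drop = FALSE] -
                 edges[, cross$b, drop = FALSE]
  list(control_control = within_set(ctrl, "control-control"),
       cko_cko = within_set(cko, "cko-cko"),
       control_cko = structure(
         list(class = "control-cko",
              pairs = data.frame(a = subjects[cross$a],
                                 b = subjects[cross$b],
                                 stringsAsFactors = FALSE),
              diffs = cross_diffs),
         class = "difference_set"))
}

#' @export
print.difference_set <- function(x, ...) {
  cat("<difference_set> ", x$class, ": ", ncol(x$diffs), " pairs x ",
      nrow(x$diffs), " edges\n", sep = "")
  invisible(x)
}

# Mean squared Pearson correlation between the columns of two
# edge x pair matrices; `within` drops self/duplicate combinations.
mean_r2_between <- function(a, b, within) {
  za <- scale(a)
  zb <- scale(b)
  r <- crossprod(za, zb) / (nrow(a) - 1L)
  if (within) {
    mean(r[upper.tri(r)]^2)
  } else {
    mean(r^2)
  }
}

#' Similarity of difference matrices within or between classes
#'
#' Pearson correlation is computed for every pair of difference vectors
#' (all cross combinations for two distinct sets; all distinct unordered
#' combinations within one set) and summarised as the mean R-squared.
#' Significance comes from an edge-label permutation null: each draw
#' applies one random permutation to the edge axis of the second set and
#' recomputes the mean R-squared.
#'
#' All statistics are squared, so they are invariant to the orientation
#' of any pair's subtraction.
#'
#' @param set_a,set_b `difference_set` objects; pass the same object (or
#'   `set_b = NULL`) for the within-class statistic.
#' @param n_perm permutation draws (default 10000).
#' @param seed integer seed for the permutation null.
#' @return List with `mean_r2`, `p` (permutation, one-sided for
#'   mean R-squared above null), `n_pairs_compared`, `null_q95`.
#' @export
pairwise_pattern_r2 <- function(set_a, set_b = NULL, n_perm = 10000L,
                                seed = 1L) {
  within <- is.null(set_b) || identical(set_a, set_b)
  a <- set_a$diffs
  b <- if (within) a else set_b$diffs
  if (any(apply(a, 2L, stats::sd) == 0) ||
      any(apply(b, 2L, stats::sd) == 0))
    stop("degenerate pair: all-zero difference vector", call. = FALSE)
  # a single-pair set has no distinct within combinations; compare the
  # lone vector with itself as a cross pair (R-squared 1 by construction)
  if (within && ncol(a) < 2L) within <- FALSE
  obs <- mean_r2_between(a, b, within)
  n_compared <- if (within) ncol(a) * (ncol(a) - 1L) / 2L
                else ncol(a) * ncol(b)
  null_vals <- numeric(n_perm)
  E <- nrow(a)
  withr_seed(seed, {
    for (k in seq_len(n_perm)) {
      perm <- sample.int(E)
      null_vals[k] <- mean_r2_between(a, b[perm, , drop = FALSE], within)
    }
  })
  list(mean_r2 = obs,
       p = (1 + sum(null_vals >= obs)) / (1 + n_perm),
       n_pairs_compared = n_compared,
       null_q95 = stats::quantile(null_vals, 0.95, names = FALSE))
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
withr_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Per-edge class pattern (RMS of difference values)
#'
#' Aggregates a difference set into one non-negative value per edge: the
#' root-mean-square of that edge's difference values across all pairs in
#' the class. RMS is used because within-class pair orientation is
#' arbitrary.
#'
#' @param set a `difference_set`.
#' @return Numeric vector, one value per edge.
#' @export
class_pattern <- function(set) {
  sqrt(rowMeans(set$diffs^2))
}

#' Correlation between two class patterns
#'
#' Pearson r across edges of two RMS patterns, with R-squared and the
#' two-sided t-transform p at df = E - 2. A positive correlation between
#' the control-control and cko-cko patterns indicates a subject-specific
#' connectivity pattern shared across groups.
#'
#' @param pattern_a,pattern_b numeric per-edge patterns of equal length.
#' @return List with `r`, `r_squared`, `p`, `n_edges`.
#' @export
class_pattern_correlation <- function(pattern_a, pattern_b) {
  if (length(pattern_a) != length(pattern_b))
    stop("patterns have different lengths", call. = FALSE)
  if (stats::sd(pattern_a) == 0 || stats::sd(pattern_b) == 0)
    stop("constant pattern", call. = FALSE)
  ct <- stats::cor.test(pattern_a, pattern_b)
  list(r = unname(ct$estimate), r_squared = unname(ct$estimate)^2,
       p = ct$p.value, n_edges = length(pattern_a))
}

#' Extract the group-discriminative network
#'
#' Per edge, R-squared is the squared point-biserial correlation between
#' edge strength and group membership across subjects. Edges with
#' R-squared above the threshold are retained, signed by the direction of
#' the group difference (+1 = higher synchrony in cko). Edges with zero
#' variance across subjects are assigned R-squared 0 with a warning.
#'
#' @param connectomes list of `connectome` objects.
#' @param groups group label per connectome (taken from the connectomes
#'   when omitted).
#' @param threshold R-squared retention threshold (default 0.2).
#' @return Object of class `discriminative_network`: `edges` (data.frame
#'   of retained edges with `edge`, `i`, `j`, `r_squared`, `sign`),
#'   `r_squared` (all edges), `threshold`, `regions` (indices touching a
#'   retained edge), `region_ids`.
#' @export
group_discriminative_edges <- function(connectomes, groups = NULL,
                                       threshold = 0.2) {
  if (is.null(groups))
    groups <- vapply(connectomes, function(cc) cc$group, character(1))
  if (sum(groups == "control") < 2L || sum(groups == "cko") < 2L)
    stop("each group needs at least 2 subjects", call. = FALSE)
  region_ids <- connectomes[[1L]]$region_ids
  n_regions <- length(region_ids)
  idx <- edge_index_table(n_regions)
  edges <- vapply(connectomes, function(cc) cc$matrix[idx],
                  numeric(nrow(idx)))         # edges x subjects
  g <- as.numeric(groups == "cko")
  sds <- apply(edges, 1L, stats::sd)
  r2 <- numeric(nrow(idx))
  ok <- sds > 0
  if (any(!ok))
    warning(sum(!ok), " edge(s) with zero variance across subjects ",
            "assigned R-squared 0", call. = FALSE)
  if (any(ok)) {
    ze <- t(scale(t(edges[ok, , drop = FALSE])))
    zg <- as.numeric(scale(g))
    r <- as.numeric(ze %*% zg) / (length(g) - 1L)
    r2[ok] <- r^2
  }
  mean_diff <- rowMeans(edges[, groups == "cko", drop = FALSE]) -
               rowMeans(edges[, groups == "control", drop = FALSE])
  keep <- which(r2 > threshold)
  retained <- data.frame(edge = keep,
                         i = idx[keep, "i"], j = idx[keep, "j"],
                         region_i = region_ids[idx[keep, "i"]],
                         region_j = region_ids[idx[keep, "j"]],
                         r_squared = r2[keep],
                         sign = sign(mean_diff[keep]),
                         stringsAsFactors = FALSE)
  structure(list(edges = retained, r_squared = r2, threshold = threshold,
                 regions = sort(unique(c(idx[keep, ]))),
                 region_ids = region_ids),
            class = "discriminative_network")
}

#' @export
print.discriminative_network <- function(x, ...) {
  cat("<discriminative_network> R2 > ", x$threshold, ": ",
      nrow(x$edges), " edges over ", length(x$regions), " regions\n",
      sep = "")
  invisible(x)
}

#' Region-level summary of a discriminative network
#'
#' Counts retained edges per macro-region, split by sign and hemisphere
#' class; an edge touching two macro-regions contributes to both.
#'
#' @param net a `discriminative_network`.
#' @param region_table region lookup table.
#' @return data.frame with columns `macro_region`, `n_edges`,
#'   `n_increase`, `n_decrease`, `n_intra_left`, `n_intra_right`,
#'   `n_inter`.
#' @export
map_edges_to_regions <- function(net, region_table) {
  tab <- region_table[match(net$region_ids, region_table$label), ]
  macro <- unique(tab$macro_region)
  hemi <- tab$hemisphere
  cls <- if (nrow(net$edges))
    edge_hemisphere_class(as.matrix(net$edges[, c("i", "j")]), hemi)
  else character(0)
  rows <- lapply(macro, function(mr) {
    members <- which(tab$macro_region == mr)
    touch <- net$edges$i %in% members | net$edges$j %in% members
    data.frame(macro_region = mr,
               n_edges = sum(touch),
               n_increase = sum(touch & net$edges$sign > 0),
               n_decrease = sum(touch & net$edges$sign < 0),
               n_intra_left = sum(touch & cls == "intra-left"),
               n_intra_right = sum(touch & cls == "intra-right"),
               n_inter = sum(touch & cls == "inter-hemisphere"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
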