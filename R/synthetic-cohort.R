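#' Default structured base connectome
#'
#' A plausible resting-state base correlation structure for a mirrored
#' two-hemisphere parcellation: homotopic (left-right mirror) pairs
#' correlate most strongly, within-hemisphere pairs moderately, remaining
#' inter-hemisphere pairs weakly. Regions 1..R/2 are left, the rest right,
#' with region k mirrored by region k + R/2.
#'
#' @param n_regions even region count (default 28, i.e. 14 per
#'   hemisphere).
#' @param homotopic,intra,inter correlation levels for the three pair
#'   classes.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
default_base_connectome <- function(n_regions = 28L, homotopic = 0.5,
                                    intra = 0.2, inter = 0.05) {
  if (n_regions %% 2L != 0L)
    stop("n_regions must be even (mirrored hemispheres)", call. = FALSE)
  half <- n_regions / 2L
  hemi <- rep(c("left", "right"), each = half)
  C0 <- matrix(inter, n_regions, n_regions)
  same <- outer(hemi, hemi, "==")
  C0[same] <- intra
  mirror <- cbind(seq_len(half), seq_len(half) + half)
  C0[mirror] <- homotopic
  C0[mirror[, c(2L, 1L)]] <- homotopic
  diag(C0) <- 1
  project_to_correlation(C0)
}

#' Repair a symmetric matrix to a valid correlation matrix
#'
#' Eigenvalues are clipped at a small positive floor and the diagonal is
#' renormalised to 1. Used after planting edge effects on a base
#' connectome, which can push the matrix outside the positive-definite
#' cone.
#'
#' @param m symmetric matrix.
#' @param floor eigenvalue floor (default 1e-6).
#' @return A symmetric positive-definite matrix with unit diagonal.
#' @export
project_to_correlation <- function(m, floor = 1e-6) {
  m <- (m + t(m)) / 2
  es <- eigen(m, symmetric = TRUE)
  vals <- pmax(es$values, floor)
  out <- es$vectors %*% (vals * t(es$vectors))
  d <- diag(out)
  if (any(d <= 0))
    stop("matrix not repairable to positive-definite", call. = FALSE)
  out <- out / sqrt(d %o% d)
  out <- (out + t(out)) / 2
  diag(out) <- 1
  out
}

#' Specification of a synthetic BOLD cohort
#'
#' Defaults mirror the study conditions: 5 control and 7 cKO subjects,
#' a 28-region coarse parcellation (14 per hemisphere), 1002 frames
#' (3 runs of 334 repetitions) at TR 1.8 s. A subject-identity pattern
#' (zero-mean edge offsets of sd `subject_effect_sd` on `subject_edges`,
#' the same edge set in both groups) and a group pattern (offset
#' `group_effect` on `group_edges`, cKO only) are planted on a shared
#' base connectome; each subject's target correlation matrix is the
#' positive-definite repair of that sum.
#'
#' @param n_control,n_cko subjects per group (defaults 5, 7).
#' @param n_regions region count (default 28).
#' @param n_frames frames per subject (default 1002 = 3 x 334).
#' @param tr repetition time, s (default 1.8).
#' @param base_connectome base correlation matrix C0; default
#'   [default_base_connectome()].
#' @param subject_edges canonical edge indices carrying the
#'   subject-identity pattern; default 20 edges sampled from the seed.
#' @param subject_effect_sd sd of per-subject offsets on those edges, in
#'   correlation units (default 0.15).
#' @param group_edges edge indices carrying the group pattern; default 10
#'   edges sampled disjoint from `subject_edges`.
#' @param group_effect signed correlation offset added on `group_edges`
#'   for cKO subjects (default 0.3).
#' @param noise_sd sd of additive observation noise relative to the
#'   unit-variance latent signal (default 0.3).
#' @param seed integer seed (default 1).
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_control = 5L, n_cko = 7L, n_regions = 28L,
                        n_frames = 1002L, tr = 1.8,
                        base_connectome = NULL,
                        subject_edges = NULL, subject_effect_sd = 0.15,
                        group_edges = NULL, group_effect = 0.3,
                        noise_sd = 0.3, seed = 1L) {
  if (n_control < 1L || n_cko < 1L) stop("need subjects in both groups",
                                         call. = FALSE)
  if (n_frames <= n_regions)
    stop("n_frames must exceed n_regions", call. = FALSE)
  if (is.null(base_connectome))
    base_connectome <- default_base_connectome(n_regions)
  if (nrow(base_connectome) != n_regions)
    stop("base_connectome size does not match n_regions", call. = FALSE)
  n_edges <- n_regions * (n_regions - 1L) / 2L
  if (is.null(subject_edges) || is.null(group_edges)) {
    # default planted sets: 20 subject-pattern and 10 disjoint
    # group-pattern edges, scaled down for small parcellations
    n_subj <- min(20L, n_edges %/% 3L)
    n_grp <- min(10L, n_edges %/% 6L)
    if (n_subj < 1L || n_grp < 1L)
      stop("too few edges to place default effect sets; supply ",
           "subject_edges and group_edges explicitly", call. = FALSE)
    withr_seed(seed + 1000L, {
      pool <- sample.int(n_edges, n_subj + n_grp)
      if (is.null(subject_edges))
        subject_edges <- sort(pool[seq_len(n_subj)])
      if (is.null(group_edges))
        group_edges <- sort(setdiff(sample.int(n_edges, n_edges),
                                    subject_edges)[seq_len(n_grp)])
    })
  }
  subject_edges <- as.integer(subject_edges)
  group_edges <- as.integer(group_edges)
  if (any(subject_edges < 1L) || any(subject_edges > n_edges) ||
      any(group_edges < 1L) || any(group_edges > n_edges))
    stop("edge indices out of range 1..", n_edges, call. = FALSE)
  if (noise_sd < 0 || subject_effect_sd < 0)
    stop("effect and noise sds must be >= 0", call. = FALSE)
  structure(list(n_control = as.integer(n_control),
                 n_cko = as.integer(n_cko),
                 n_regions = as.integer(n_regions),
                 n_frames = as.integer(n_frames), tr = tr,
                 base_connectome = base_connectome,
                 subject_edges = subject_edges,
                 subject_effect_sd = subject_effect_sd,
                 group_edges = group_edges, group_effect = group_effect,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Simulate a BOLD cohort with planted connectivity structure
#'
#' For subject s with subject offsets `b_s` (zero-mean normal, sd
#' `subject_effect_sd`, on `subject_edges`) the target correlation is
#' `T_s = project_to_correlation(C0 + b_s + 1[cko] * group_effect on
#' group_edges)`. Region series are drawn as Gaussian with population
#' correlation exactly `T_s` (Cholesky factorisation), then independent
#' observation noise of sd `noise_sd` is added. Identical (spec, seed)
#' reproduce the cohort bit-identically.
#'
#' @param spec a [cohort_spec()].
#' @return List with `series` (list of [region_timeseries]), `meta`
#'   (subject metadata data.frame) and `truth` (ground-truth list:
#'   per-subject target matrices, planted edge sets and effect sizes).
#' @export
simulate_bold_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n_sub <- spec$n_control + spec$n_cko
  groups <- rep(c("control", "cko"), c(spec$n_control, spec$n_cko))
  subjects <- sprintf("sub%02d", seq_len(n_sub))
  idx <- edge_index_table(spec$n_regions)
  region_ids <- seq_len(spec$n_regions)
  targets <- vector("list", n_sub)
  series <- vector("list", n_sub)
  withr_seed(spec$seed, {
    subj_offsets <- matrix(
      stats::rnorm(n_sub * length(spec$subject_edges),
                   sd = spec$subject_effect_sd),
      nrow = length(spec$subject_edges))
    sexes <- sample(c("M", "F"), n_sub, replace = TRUE)
    weights <- round(stats::rnorm(n_sub, mean = 34, sd = 3), 1)
    for (s in seq_len(n_sub)) {
      target <- spec$base_connectome
      eij <- idx[spec$subject_edges, , drop = FALSE]
      target[eij] <- target[eij] + subj_offsets[, s]
      target[eij[, c(2L, 1L)]] <- target[eij]
      if (groups[s] == "cko" && length(spec$group_edges)) {
        gij <- idx[spec$group_edges, , drop = FALSE]
        target[gij] <- target[gij] + spec$group_effect
        target[gij[, c(2L, 1L)]] <- target[gij]
      }
      target <- tryCatch(project_to_correlation(target),
                         error = function(e)
                           stop("subject ", subjects[s], ": ",
                                conditionMessage(e), call. = FALSE))
      targets[[s]] <- target
      z <- matrix(stats::rnorm(spec$n_frames * spec$n_regions),
                  nrow = spec$n_frames)
      x <- z %*% chol(target)
      if (spec$noise_sd > 0)
        x <- x + matrix(stats::rnorm(length(x), sd = spec$noise_sd),
                        nrow = spec$n_frames)
      series[[s]] <- region_timeseries(x, region_ids,
                                       subject = subjects[s],
                                       group = groups[s], tr = spec$tr)
    }
  })
  meta <- data.frame(subject = subjects, group = groups, sex = sexes,
                     body_weight = pmax(weights, 20),
                     excluded = FALSE, stringsAsFactors = FALSE)
  truth <- list(targets = targets,
                group_edges = spec$group_edges,
                group_effect = spec$group_effect,
                subject_edges = spec$subject_edges,
                subject_effect_sd = spec$subject_effect_sd,
                spec = spec)
  list(series = series, meta = validate_subject_meta(meta), truth = truth)
}

#' Labelled brain phantom cohort with planted volume effects
#'
#' Each subject's phantom is a 3D label image holding mirrored left/right
#' cuboid regions over background. Region volumes are base volumes times
#' the group's per-region scaling times multiplicative per-subject
#' jitter; cuboid side lengths scale as the cube root so that rasterised
#' volume tracks the target up to voxel rounding. The returned truth
#' table stores the exact rasterised voxel count times voxel volume.
#'
#' @param n_regions_per_hemisphere regions per hemisphere (default 14).
#' @param n_control,n_cko subjects per group (defaults 5, 7).
#' @param voxel_dims mm per axis (default 0.2 isotropic, the anatomical
#'   acquisition resolution).
#' @param group_scalings named list mapping group to a per-region scaling
#'   vector (recycled scalar allowed); default all 1.
#' @param jitter_sd sd of multiplicative log-normal per-subject
#'   per-region volume jitter (default 0.02).
#' @param subject_scale_sd sd of a multiplicative log-normal per-subject
#'   global brain-size factor applied to every region (default 0.05,
#'   the between-animal size variation the phantom emulates).
#' @param base_side base cuboid side length in voxels (default 6).
#' @param seed integer seed.
#' @return List with `atlases` (list of per-subject lists: `labels` a
#'   [volume_image] of integer labels, `subject`, `group`),
#'   `region_table`, `meta`, and `truth_volumes` (long data.frame
#'   subject/region/volume_mm3, exact).
#' @export
make_atlas_phantom <- function(n_regions_per_hemisphere = 14L,
                               n_control = 5L, n_cko = 7L,
                               voxel_dims = c(0.2, 0.2, 0.2),
                               group_scalings = NULL,
                               jitter_sd = 0.02, subject_scale_sd = 0.05,
                               base_side = 6L, seed = 1L) {
  n_half <- as.integer(n_regions_per_hemisphere)
  n_regions <- 2L * n_half
  scale_name <- if (n_half <= 14L) "coarse" else "medium"
  region_table <- data.frame(
    label = seq_len(n_regions),
    region = paste0("region_", rep(seq_len(n_half), 2L), "_",
                    rep(c("L", "R"), each = n_half)),
    hemisphere = rep(c("left", "right"), each = n_half),
    macro_region = paste0("macro_",
                          rep(rep(seq_len(ceiling(n_half / 2)),
                                  each = 2L)[seq_len(n_half)], 2L)),
    scale = scale_name, ventricle = FALSE, stringsAsFactors = FALSE)
  if (is.null(group_scalings))
    group_scalings <- list(control = rep(1, n_regions),
                           cko = rep(1, n_regions))
  group_scalings <- lapply(group_scalings, function(s) {
    s <- rep_len(as.numeric(s), n_regions)
    if (any(s <= 0)) stop("scalings must be positive", call. = FALSE)
    s
  })
  # layout: regions on a grid of cells, one hemisphere per x-half
  n_cols <- ceiling(sqrt(n_half))
  n_rows <- ceiling(n_half / n_cols)
  cell <- 2L * base_side  # room for growth up to ~8x volume
  nx <- 2L * n_cols * cell
  ny <- n_rows * cell
  nz <- cell
  groups <- rep(c("control", "cko"), c(n_control, n_cko))
  subjects <- sprintf("sub%02d", seq_along(groups))
  atlases <- vector("list", length(groups))
  truth <- list()
  withr_seed(seed, {
    jit <- matrix(exp(stats::rnorm(length(groups) * n_regions,
                                   sd = jitter_sd)),
                  nrow = n_regions)
    if (jitter_sd == 0) jit[] <- 1
    subj_scale <- exp(stats::rnorm(length(groups), sd = subject_scale_sd))
    if (subject_scale_sd == 0) subj_scale[] <- 1
    jit <- sweep(jit, 2L, subj_scale, "*")
    weights <- round(stats::rnorm(length(groups), 34, 3), 1)
    sexes <- sample(c("M", "F"), length(groups), replace = TRUE)
  })
  base_vol <- base_side^3
  # fixed compact fill order for one cell: voxels sorted by distance from
  # the cell's inner corner, so a region of N voxels is the first N voxels
  # and rasterised volume equals the target count exactly
  cc <- expand.grid(x = seq_len(cell - 1L), y = seq_len(cell - 1L),
                    z = seq_len(cell - 1L))
  fill_order <- cc[order(cc$x^2 + cc$y^2 + cc$z^2, cc$x, cc$y, cc$z), ]
  max_vox <- nrow(fill_order)
  for (s in seq_along(groups)) {
    grid <- array(0L, c(nx, ny, nz))
    scal <- group_scalings[[groups[s]]]
    for (k in seq_len(n_half)) {
      col <- (k - 1L) %% n_cols
      row <- (k - 1L) %/% n_cols
      y0 <- row * cell
      for (side_of_brain in 1:2) {
        lab <- if (side_of_brain == 1L) k else k + n_half
        n_vox <- round(base_vol * scal[lab] * jit[lab, s])
        n_vox <- min(max(1L, n_vox), max_vox)
        fo <- fill_order[seq_len(n_vox), ]
        xs <- if (side_of_brain == 1L) col * cell + fo$x
              else nx + 1L - (col * cell + fo$x)  # mirrored in x
        grid[cbind(xs, y0 + fo$y, fo$z)] <- lab
      }
    }
    counts <- tabulate(grid[grid > 0L], nbins = n_regions)
    truth[[s]] <- data.frame(subject = subjects[s],
                             region = seq_len(n_regions),
                             volume_mm3 = counts * prod(voxel_dims),
                             stringsAsFactors = FALSE)
    atlases[[s]] <- list(labels = volume_image(grid, voxel_dims),
                         subject = subjects[s], group = groups[s])
  }
  meta <- data.frame(subject = subjects, group = groups, sex = sexes,
                     body_weight = pmax(weights, 20), excluded = FALSE,
                     stringsAsFactors = FALSE)
  list(atlases = atlases, region_table = validate_region_table(region_table),
       meta = validate_subject_meta(meta),
       truth_volumes = do.call(rbind, truth))
}

#' Simulate a time-of-flight angiogram phantom
#'
#' Axis-aligned cylindrical tubes at `vessel_level` rasterised over a
#' noisy background; the returned truth is the exact rasterised lumen
#' voxel count. A voxel belongs to a tube lumen when its centre lies
#' within the tube radius of the axis and inside the tube's length span.
#'
#' @param grid length-3 integer grid size.
#' @param voxel_dims mm per axis (default 0.075 isotropic, the angiogram
#'   acquisition resolution).
#' @param tube_specs list of tubes, each a list with `axis` (1, 2 or 3),
#'   `center` (length-2, voxel coordinates in the two off-axis
#'   dimensions), `radius` (voxels), `from`, `to` (voxel span along the
#'   axis).
#' @param background_level,vessel_level mean intensities (vessel must
#'   exceed background).
#' @param noise_sd background noise sd.
#' @param seed integer seed.
#' @return List with `volume` (a [volume_image]), `lumen_voxels` (exact
#'   truth count), `lumen_mask` (logical array).
#' @export
simulate_angiogram <- function(grid = c(40L, 40L, 40L),
                               voxel_dims = c(0.075, 0.075, 0.075),
                               tube_specs = list(),
                               background_level = 6000,
                               vessel_level = 9000,
                               noise_sd = 200, seed = 1L) {
  if (vessel_level <= background_level)
    stop("vessel_level must exceed background_level", call. = FALSE)
  lumen <- array(FALSE, grid)
  coords <- lapply(grid, seq_len)
  for (tube in tube_specs) {
    off <- setdiff(1:3, tube$axis)
    d1 <- coords[[off[1L]]] - tube$center[1L]
    d2 <- coords[[off[2L]]] - tube$center[2L]
    disk <- outer(d1^2, d2^2, "+") <= tube$radius^2
    span <- coords[[tube$axis]] >= tube$from &
            coords[[tube$axis]] <= tube$to
    tube_mask <- array(FALSE, grid[c(tube$axis, off)])
    tube_mask[span, , ] <- rep(disk, each = sum(span))
    lumen <- lumen | aperm(tube_mask, order(c(tube$axis, off)))
  }
  withr_seed(seed, {
    vol <- array(stats::rnorm(prod(grid), mean = background_level,
                              sd = noise_sd), grid)
  })
  vol[lumen] <- vessel_level
  list(volume = volume_image(vol, voxel_dims),
       lumen_voxels = sum(lumen), lumen_mask = lumen)
}

#' Simulate two-group univariate morphometry samples
#'
#' Independent normal draws for a control and a knockout group, e.g.
#' tadpole ventricular lengths.
#'
#' @param mean_control,mean_ko group means.
#' @param sd common standard deviation (>= 0).
#' @param n_per_group sample size per group (>= 2).
#' @param seed integer seed.
#' @return List with numeric vectors `control` and `ko`.
#' @export
simulate_morphometry <- function(mean_control, mean_ko, sd, n_per_group,
                                 seed = 1L) {
  if (sd < 0) stop("sd must be >= 0", call. = FALSE)
  if (n_per_group < 2L)
    stop("n_per_group must be at least 2", call. = FALSE)
  withr_seed(seed, {
    control <- stats::rnorm(n_per_group, mean_control, sd)
    ko <- stats::rnorm(n_per_group, mean_ko, sd)
  })
  list(control = control, ko = ko)
}
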