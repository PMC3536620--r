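# Synthetic cohort generation. A one-factor-per-module Gaussian model keeps
# the planted correlation structure analytically tractable: regions i and j
# of the same module have expected correlation
#   lambda_i * lambda_j / sqrt((lambda_i^2 + sigma^2) (lambda_j^2 + sigma^2))
# while regions of different modules are uncorrelated unless one of them is
# a hub carrying cross-loadings on several module factors. Negative values
# are truncated at zero (densities are counts), which biases correlations
# when a region's mean sits close to zero relative to its total SD; the
# presets therefore lift every baseline to at least five total (factor +
# noise) SDs above zero.

#' Specify a synthetic cohort
#'
#' @param n_regions Number of regions R.
#' @param groups Named integer vector: subjects per experimental group, in
#'   the order the groups should be generated.
#' @param module_membership Integer vector of length R mapping each region
#'   to a module id; 0 marks background regions outside every module.
#' @param factor_loadings Numeric vector of length R: loading of each region
#'   on its own module factor (ignored for background regions).
#' @param noise_sd Region-level noise SD (same units as activity).
#' @param baseline_mean Numeric vector (length R or 1) of baseline activity
#'   densities.
#' @param hub_set Integer indices of hub regions; hubs additionally load on
#'   every other module factor with `hub_cross_loading`.
#' @param hub_cross_loading Loading of hub regions on non-own modules.
#' @param factor_correlation Correlation between any two module factors,
#'   in `[0, 1)`, implemented through a shared global factor
#'   (`f_m = sqrt(1 - rho) e_m + sqrt(rho) g`). Zero (the default) gives
#'   independent modules; positive values emulate the brain-wide common
#'   activation component that couples anatomical modules, so that the
#'   expected cross-module correlation of regions i and j becomes
#'   `u_i u_j rho` with `u` the region-factor correlations.
#' @param negative_region Optional region index whose loadings are
#'   sign-flipped, planting a region that correlates negatively with its
#'   module (emulating an anterodorsal-thalamus-like observation).
#' @param group_effects Optional numeric matrix (groups x regions) of
#'   additive mean shifts, rows in `groups` order.
#' @param region_names Optional region abbreviations (default `R001`...).
#' @param rng_seed Integer seed; one global stream per cohort, groups drawn
#'   in `groups` order, so a fixed seed gives byte-identical cohorts.
#' @return A `synthetic_spec` object.
#' @seealso [generate_cohort()], [spec_modular()], [spec_fearlike()],
#'   [spec_assortative_core()]
#' @export
synthetic_spec <- function(n_regions,
                           groups,
                           module_membership,
                           factor_loadings,
                           noise_sd = 1,
                           baseline_mean = 20,
                           hub_set = integer(),
                           hub_cross_loading = 0,
                           factor_correlation = 0,
                           negative_region = NULL,
                           group_effects = NULL,
                           region_names = NULL,
                           rng_seed = 1L) {
  if (!is_count(n_regions, 2L)) stop_field("n_regions", "must be a count >= 2")
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    stop_field("groups", "must be a named vector (label -> n_subjects)")
  if (any(groups < 3L) || any(groups != round(groups)))
    stop_field("groups", "needs n_subjects >= 3 for every group")
  if (!is.numeric(noise_sd) || length(noise_sd) != 1L || noise_sd <= 0)
    stop_field("noise_sd", "must be a single value > 0")
  if (length(module_membership) != n_regions)
    stop_field("module_membership", "must have one entry per region")
  if (any(module_membership < 0) ||
      any(module_membership != round(module_membership)))
    stop_field("module_membership", "must be non-negative integers")
  if (length(factor_loadings) != n_regions)
    stop_field("factor_loadings", "must have one entry per region")
  baseline_mean <- rep_len(as.numeric(baseline_mean), n_regions)
  if (any(baseline_mean < 0))
    stop_field("baseline_mean", "must be >= 0")
  if (length(hub_set) > 0L &&
      (any(hub_set < 1L) || any(hub_set > n_regions)))
    stop_field("hub_set", "indices out of range")
  if (!is.numeric(factor_correlation) || length(factor_correlation) != 1L ||
      factor_correlation < 0 || factor_correlation >= 1)
    stop_field("factor_correlation", "must be in [0, 1)")
  if (!is.null(negative_region) &&
      !(is_count(negative_region, 1L) && negative_region <= n_regions))
    stop_field("negative_region", "must be a single region index")
  if (!is.null(group_effects)) {
    group_effects <- as.matrix(group_effects)
    if (nrow(group_effects) != length(groups) ||
        ncol(group_effects) != n_regions)
      stop_field("group_effects", "must be a groups x regions matrix")
  }
  if (is.null(region_names))
    region_names <- sprintf("R%03d", seq_len(n_regions))
  if (length(region_names) != n_regions || anyDuplicated(region_names))
    stop_field("region_names", "must be unique, one per region")
  structure(
    list(n_regions = as.integer(n_regions),
         groups = groups,
         module_membership = as.integer(module_membership),
         factor_loadings = as.numeric(factor_loadings),
         noise_sd = noise_sd,
         baseline_mean = baseline_mean,
         hub_set = as.integer(hub_set),
         hub_cross_loading = hub_cross_loading,
         factor_correlation = factor_correlation,
         negative_region = if (is.null(negative_region)) NULL
                           else as.integer(negative_region),
         group_effects = group_effects,
         region_names = region_names,
         rng_seed = as.integer(rng_seed)),
    class = "synthetic_spec")
}

#' Loading matrix implied by a synthetic spec
#'
#' Rows are regions, columns module factors. Non-hub regions load only on
#' their own module; hubs additionally load on every other module with the
#' spec's cross-loading. The negative region's row is sign-flipped.
#'
#' @param spec A [synthetic_spec()].
#' @return Numeric R x M matrix.
#' @export
loading_matrix <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  m <- max(spec$module_membership, 0L)
  lam <- matrix(0, spec$n_regions, m)
  for (i in seq_len(spec$n_regions)) {
    own <- spec$module_membership[i]
    if (own > 0L) lam[i, own] <- spec$factor_loadings[i]
  }
  for (h in spec$hub_set) {
    own <- spec$module_membership[h]
    cross <- setdiff(seq_len(m), own)
    lam[h, cross] <- spec$hub_cross_loading
  }
  if (!is.null(spec$negative_region))
    lam[spec$negative_region, ] <- -lam[spec$negative_region, ]
  rownames(lam) <- spec$region_names
  lam
}

#' Expected correlation matrix implied by a synthetic spec
#'
#' Closed form of the planted structure: cov = Lambda Lambda' + sigma^2 I,
#' converted to a correlation matrix. Ignores zero-truncation (negligible at
#' the baselines the presets use).
#'
#' @param spec A [synthetic_spec()].
#' @return Symmetric R x R correlation matrix.
#' @export
expected_correlations <- function(spec) {
  lam <- loading_matrix(spec)
  m <- ncol(lam)
  phi <- matrix(spec$factor_correlation, m, m)
  diag(phi) <- 1
  cv <- lam %*% phi %*% t(lam) + diag(spec$noise_sd^2, spec$n_regions)
  r <- stats::cov2cor(cv)
  dimnames(r) <- list(spec$region_names, spec$region_names)
  r
}

#' Generate a synthetic cohort
#'
#' Draws one [activity_table()] per group under the spec's factor model:
#' `x = baseline + group shift + Lambda f + eps` with module factors `f`
#' shared across the regions of a module within each subject. Values are
#' truncated at zero.
#'
#' @param spec A [synthetic_spec()].
#' @return Named list of [activity_table()], one per group, in spec order.
#' @export
#' @examples
#' spec <- spec_modular(n_modules = 2, module_size = 5, n_background = 0,
#'                      groups = c(g1 = 8), seed = 1)
#' cohort <- generate_cohort(spec)
#' cohort$g1
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  lam <- loading_matrix(spec)
  m <- ncol(lam)
  with_rng(spec$rng_seed, {
    out <- vector("list", length(spec$groups))
    names(out) <- names(spec$groups)
    rho <- spec$factor_correlation
    for (gi in seq_along(spec$groups)) {
      n <- spec$groups[[gi]]
      f <- matrix(rnorm(m * n), m, n)
      if (rho > 0 && m > 0L) {
        gshared <- rnorm(n)
        f <- sqrt(1 - rho) * f +
          sqrt(rho) * matrix(gshared, m, n, byrow = TRUE)
      }
      eps <- matrix(rnorm(spec$n_regions * n, sd = spec$noise_sd),
                    spec$n_regions, n)
      x <- spec$baseline_mean + (if (m > 0L) lam %*% f else 0) + eps
      if (!is.null(spec$group_effects))
        x <- x + spec$group_effects[gi, ]
      x[x < 0] <- 0
      dimnames(x) <- list(spec$region_names,
                          sprintf("%s_s%d", names(spec$groups)[gi],
                                  seq_len(n)))
      out[[gi]] <- activity_table(x, names(spec$groups)[gi])
    }
    out
  })
}

#' Generate a cohort with no planted structure
#'
#' All regions are independent (every loading zero) and there are no group
#' effects, so any correlation is sampling noise. Used for type-I-error and
#' calibration checks.
#'
#' @param n_regions Number of regions (>= 2).
#' @param groups Named integer vector of subjects per group.
#' @param noise_sd Noise SD.
#' @param seed Integer seed.
#' @param baseline_mean Baseline density (default keeps truncation
#'   negligible).
#' @return Named list of [activity_table()].
#' @export
generate_null_cohort <- function(n_regions, groups, noise_sd = 1, seed = 1L,
                                 baseline_mean = 20) {
  spec <- synthetic_spec(
    n_regions = n_regions, groups = groups,
    module_membership = rep(0L, n_regions),
    factor_loadings = rep(0, n_regions),
    noise_sd = noise_sd, baseline_mean = baseline_mean,
    rng_seed = seed)
  generate_cohort(spec)
}

# Baselines for the preset cohorts: a varied density pattern lifted so
# every region's mean sits at least five total (factor + noise) SDs above
# zero, keeping truncation at zero negligible even for strongly loaded hub
# regions.
.preset_baselines <- function(r, membership, loadings, noise_sd = 1,
                              fc = 0, hub_set = integer(),
                              hub_cross = 0) {
  m <- max(membership, 0L)
  lam <- matrix(0, r, m)
  for (i in seq_len(r))
    if (membership[i] > 0L) lam[i, membership[i]] <- loadings[i]
  for (h in hub_set)
    lam[h, setdiff(seq_len(m), membership[h])] <- hub_cross
  phi <- matrix(fc, m, m); diag(phi) <- 1
  sds <- sqrt(rowSums((lam %*% phi) * lam) + noise_sd^2)
  pmax(10 + 15 * (seq_len(r) %% 7) / 6, 5 * sds)
}

#' Preset: clean modular cohort
#'
#' `n_modules` equally sized modules with a common within-module loading
#' plus optional background (independent) regions. With the default
#' `lambda = 3`, `noise_sd = 1` the planted within-module correlation is
#' 0.9, strong enough that the primary-threshold network recovers modules
#' as dense blocks at n = 8 subjects.
#'
#' @param n_modules,module_size,n_background Cohort geometry.
#' @param lambda Within-module loading.
#' @param noise_sd Noise SD.
#' @param groups Named integer vector of subjects per group.
#' @param seed Integer seed.
#' @return A [synthetic_spec()].
#' @export
spec_modular <- function(n_modules = 3, module_size = 20, n_background = 24,
                         lambda = 4, noise_sd = 1,
                         groups = c(grp1 = 8), seed = 1L) {
  r <- n_modules * module_size + n_background
  membership <- c(rep(seq_len(n_modules), each = module_size),
                  rep(0L, n_background))
  synthetic_spec(
    n_regions = r, groups = groups,
    module_membership = membership,
    factor_loadings = rep(lambda, r),
    noise_sd = noise_sd,
    baseline_mean = .preset_baselines(r, membership, rep(lambda, r),
                                      noise_sd),
    rng_seed = seed)
}

#' Preset: fear-memory-like cohort
#'
#' Emulates the qualitative shape of a remote fear memory co-activation
#' network: a densely intercorrelated thalamic-hippocampal-cortical-like
#' core module containing three planted hub regions with stronger, cleaner
#' loadings; many small satellite modules; a shared global activation
#' component (`factor_correlation`) that couples the modules so satellites
#' attach to the core the way peripheral regions do in observed networks;
#' one negatively coupled region; and background regions that enter the
#' network only through sampling noise. Four groups of eight subjects
#' mirror a genotype x retention-delay design, with an additive activity
#' increase on core regions in the remote-delay wild-type-like group.
#'
#' @param seed Integer seed.
#' @param groups Named integer vector of subjects per group.
#' @param core_n,n_sat,sat_size Geometry: core size and number/size of
#'   satellite modules.
#' @param lambda_core,lambda_sat,lambda_hub Loadings of core members,
#'   satellite members and hubs.
#' @param factor_correlation Correlation between module factors.
#' @return A [synthetic_spec()].
#' @export
spec_fearlike <- function(seed = 1L,
                          groups = c(wt_1d = 8, wt_36d = 8,
                                     het_1d = 8, het_36d = 8),
                          core_n = 12L, n_sat = 18L, sat_size = 3L,
                          lambda_core = 3, lambda_sat = 2.2,
                          lambda_hub = 3, hub_cross = 3, factor_correlation = 0.55) {
  r <- 84L
  n_mod <- core_n + n_sat * sat_size
  if (n_mod + 1L > r)
    stop("fearlike geometry exceeds 84 regions")
  membership <- integer(r)
  membership[seq_len(core_n)] <- 1L
  membership[core_n + seq_len(n_sat * sat_size)] <-
    rep(1L + seq_len(n_sat), each = sat_size)
  loadings <- numeric(r)
  loadings[membership == 1L] <- lambda_core
  loadings[membership > 1L] <- lambda_sat
  hubs <- c(1L, 2L, 3L)
  loadings[hubs] <- lambda_hub
  neg <- n_mod + 1L                    # coupled to the core, sign-flipped
  membership[neg] <- 1L
  loadings[neg] <- lambda_core
  effects <- matrix(0, length(groups), r)
  if ("wt_36d" %in% names(groups))
    effects[match("wt_36d", names(groups)), membership == 1L] <- 3
  synthetic_spec(
    n_regions = r, groups = groups,
    module_membership = membership,
    factor_loadings = loadings,
    noise_sd = 1,
    baseline_mean = .preset_baselines(r, membership, loadings, 1,
                                      factor_correlation, hubs, hub_cross),
    hub_set = hubs, hub_cross_loading = hub_cross,
    factor_correlation = factor_correlation,
    negative_region = neg,
    group_effects = effects,
    rng_seed = seed)
}

#' Preset: star-core cohort for hub identification
#'
#' One planted hub region with a near-noiseless loading on a moderately
#' coupled blob module (the hub's correlations with blob members are
#' stronger and cleaner than members' correlations with one another), plus
#' weak cross-loadings onto every peripheral module, many two-region
#' satellite modules (active dumbbell pairs with degree 1 and betweenness
#' 0 that anchor the percentile ranking), and independent background
#' regions. The hub is, by construction, the region with the strongest and
#' broadest coupling, so it ranks at the top of both degree and
#' betweenness across threshold tiers in most cohorts.
#'
#' Even so, recovery is not certain: at n = 8 subjects the sampling noise
#' of a correlation coefficient (SE about 0.45 on the z scale) lets a few
#' blob members or chance bridges overtake the hub in betweenness in a
#' minority of cohorts. See the methods vignette for the design analysis.
#'
#' @param seed Integer seed.
#' @param groups Named integer vector of subjects per group.
#' @return A [synthetic_spec()] with `hub_set` of size 1.
#' @export
spec_star_core <- function(seed = 1L, groups = c(grp1 = 8)) {
  n_mem <- 24L; n_pair <- 20L
  n_blob <- 1L + n_mem; n_dumb <- 2L * n_pair
  r <- 84L
  membership <- c(rep(1L, n_blob),
                  rep(1L + seq_len(n_pair), each = 2L),
                  rep(0L, r - n_blob - n_dumb))
  loadings <- c(20, rep(1.7, n_mem), rep(3, n_dumb),
                rep(0, r - n_blob - n_dumb))
  synthetic_spec(
    n_regions = r, groups = groups,
    module_membership = membership,
    factor_loadings = loadings,
    noise_sd = 1,
    baseline_mean = .preset_baselines(r, membership, loadings, 1,
                                      0, 1L, 0.5),
    hub_set = 1L, hub_cross_loading = 0.5,
    rng_seed = seed)
}

#' Preset: assortative-core cohort
#'
#' A mutually interconnected set of high-loading core regions (a planted
#' rich club) plus many small peripheral modules. The resulting network has
#' its high-degree nodes wired to one another, the configuration whose
#' resilience to targeted attack exceeds that of degree-matched rewired
#' controls.
#'
#' @param seed Integer seed.
#' @param groups Named integer vector of subjects per group.
#' @return A [synthetic_spec()].
#' @export
spec_assortative_core <- function(seed = 1L, groups = c(grp1 = 8)) {
  core_n <- 20L; sat_size <- 4L; n_sat <- 16L
  r <- core_n + sat_size * n_sat
  membership <- c(rep(1L, core_n),
                  rep(1L + seq_len(n_sat), each = sat_size))
  loadings <- c(rep(4, core_n),          # near-clique core, r ~ 0.94
                rep(2, sat_size * n_sat)) # small satellites, r ~ 0.8
  synthetic_spec(
    n_regions = r, groups = groups,
    module_membership = membership,
    factor_loadings = loadings,
    noise_sd = 1,
    baseline_mean = .preset_baselines(r, membership, loadings),
    rng_seed = seed)
}
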