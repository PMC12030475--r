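#' Configuration for the synthetic community generator
#'
#' Defines the simulated study: a full-factorial design of climate levels x
#' herbivore treatments x blocks, climate-specific species pools with
#' tunable overlap, Dirichlet percent-cover abundances, lognormal species
#' base traits with a per-trait climate gradient (the turnover signal), and
#' additive plot-level intraspecific shifts driven by climate, treatment and
#' their interaction (the ITV signal).
#'
#' @param n_blocks Blocks (replicate sites) per climate level.
#' @param pool_size Species pool size per climate level.
#' @param pool_overlap Fraction of each pool shared with the adjacent
#'   climate's pool, in \[0, 1\]; 1 means a single common pool.
#' @param abundance_concentration Symmetric Dirichlet concentration for
#'   per-plot relative covers; larger values give more even communities.
#' @param traits A tibble with columns `trait`, `log_mean`, `log_sd` giving
#'   the lognormal base-trait distributions (defaults emulate leaf area in
#'   mm2, SLA in mm2/mg, LDMC and LNC in mg/g and seed mass in mg).
#' @param turnover_strength Named numeric, log-scale shift of a species'
#'   base trait per climate step of its home pool; this is what makes pools
#'   functionally different, i.e. the species-turnover signal.
#' @param itv_frac_climate,itv_frac_treatment,itv_frac_interaction Magnitude
#'   of the additive intraspecific shifts, expressed as a fraction of the
#'   trait's baseline scale `exp(log_mean)`; applied as
#'   `delta * (level_index - 2)` per factor (and the product of the two
#'   centred indices for the interaction).
#' @param itv_noise_frac Standard deviation of residual intraspecific noise,
#'   as a fraction of `exp(log_mean)`.
#' @param covariation_mode `"independent"`, `"reinforcing"` (ITV climate
#'   shifts aligned with the between-pool base-trait gradient) or
#'   `"opposing"` (anti-aligned).
#' @param share_abundances If `TRUE`, the same relative-cover draws are
#'   reused across climates (plots in the same block position x treatment get
#'   identical covers), removing abundance-driven turnover.
#' @param seed Integer seed; fixed seed implies bit-reproducible output.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_blocks = 3,
                       pool_size = 12,
                       pool_overlap = 0.15,
                       abundance_concentration = 1.5,
                       traits = default_sim_traits(),
                       turnover_strength = NULL,
                       itv_frac_climate = 0.12,
                       itv_frac_treatment = 0.08,
                       itv_frac_interaction = 0.04,
                       itv_noise_frac = 0.05,
                       covariation_mode = c("independent", "reinforcing",
                                            "opposing"),
                       share_abundances = FALSE,
                       seed = 1L) {
  covariation_mode <- match.arg(covariation_mode)
  if (pool_overlap < 0 || pool_overlap > 1) {
    abort("pool_overlap must be in [0, 1]",
          class = "traitpart_config_error")
  }
  if (abundance_concentration <= 0) {
    abort("abundance_concentration must be positive",
          class = "traitpart_config_error")
  }
  if (n_blocks < 1 || pool_size < 2) {
    abort("need n_blocks >= 1 and pool_size >= 2",
          class = "traitpart_config_error")
  }
  if (any(c(itv_frac_climate, itv_frac_treatment, itv_frac_interaction,
            itv_noise_frac) < 0)) {
    abort("ITV effect and noise fractions must be >= 0",
          class = "traitpart_config_error")
  }
  n_shared <- round(pool_overlap * pool_size)
  if (n_shared > pool_size) {
    abort("pool too small for the requested overlap",
          class = "traitpart_config_error")
  }
  if (is.null(turnover_strength)) {
    turnover_strength <- setNames(rep(0.25, nrow(traits)), traits$trait)
  }
  stopifnot(all(traits$trait %in% names(turnover_strength)))
  structure(list(
    n_climates = 3L, n_treatments = 3L, n_blocks = as.integer(n_blocks),
    pool_size = as.integer(pool_size), pool_overlap = pool_overlap,
    n_shared = as.integer(n_shared),
    abundance_concentration = abundance_concentration,
    traits = traits, turnover_strength = turnover_strength,
    itv_frac_climate = itv_frac_climate,
    itv_frac_treatment = itv_frac_treatment,
    itv_frac_interaction = itv_frac_interaction,
    itv_noise_frac = itv_noise_frac,
    covariation_mode = covariation_mode,
    share_abundances = share_abundances,
    seed = as.integer(seed)
  ), class = "sim_config")
}

# Mixed regimes need species spanning the climate gradient (50% pool
# overlap), a strong and therefore reliably-signed between-pool gradient,
# fairly even abundances, and ITV shifts dominated by the aligned climate
# component; otherwise the covariation sign is set by sampling noise rather
# than by the regime.
mixed_regime_config <- function(mode, seed) {
  sim_config(
    covariation_mode = mode, pool_overlap = 0.5,
    abundance_concentration = 10,
    turnover_strength = setNames(rep(0.4, length(trait_names)), trait_names),
    itv_frac_climate = 0.25, itv_frac_treatment = 0.05,
    itv_frac_interaction = 0.02, seed = seed
  )
}

#' Default base-trait distributions for the generator
#'
#' Lognormal parameters chosen to give realistic magnitudes for a
#' Mediterranean oak-savanna understory: LA around 500 mm2, SLA around
#' 15 mm2/mg, LDMC around 250 mg/g, LNC around 20 mg/g, seed mass around
#' 2 mg.
#'
#' @return A tibble with columns `trait`, `log_mean`, `log_sd`.
#' @export
default_sim_traits <- function() {
  tibble(
    trait = trait_names,
    log_mean = log(c(500, 15, 250, 20, 2)),
    log_sd = c(0.6, 0.35, 0.3, 0.3, 0.8)
  )
}

#' Preset configurations exercising named decomposition regimes
#'
#' @param name One of `"turnover_only"` (no intraspecific shifts or noise),
#'   `"itv_only"` (a single shared pool, shared abundance draws, nonzero ITV
#'   shifts), `"mixed_positive"` (turnover plus reinforcing ITV) or
#'   `"mixed_negative"` (turnover plus opposing ITV).
#' @param seed Integer seed passed to [sim_config()].
#' @return A `sim_config`.
#' @export
sim_regime <- function(name = c("turnover_only", "itv_only",
                                "mixed_positive", "mixed_negative"),
                       seed = 1L) {
  name <- match.arg(name)
  switch(name,
    turnover_only = sim_config(
      itv_frac_climate = 0, itv_frac_treatment = 0,
      itv_frac_interaction = 0, itv_noise_frac = 0, seed = seed
    ),
    itv_only = sim_config(
      pool_overlap = 1, share_abundances = TRUE,
      turnover_strength = setNames(rep(0, 5), trait_names),
      abundance_concentration = 50,
      itv_frac_climate = 0.25, itv_frac_treatment = 0.15,
      itv_frac_interaction = 0.08, seed = seed
    ),
    mixed_positive = mixed_regime_config("reinforcing", seed),
    mixed_negative = mixed_regime_config("opposing", seed)
  )
}

#' Generate a synthetic plant community with known structure
#'
#' Produces a full-factorial plot design (3 climates x 3 treatments x
#' `n_blocks` blocks), per-climate species pools with the requested overlap,
#' per-plot percent-cover abundances from a symmetric Dirichlet, species
#' base traits from climate-shifted lognormals, and plot-specific trait
#' values equal to base + ITV shift(climate, treatment, interaction) +
#' noise.  Pooled ("fixed") trait records are the means of the realised
#' plot-specific values across occupied plots, so the specific = fixed + ITV
#' identity holds by construction.
#'
#' @param config A [sim_config()].
#' @return A list of class `trait_community` with elements `design`,
#'   `abundance`, `traits` (validated tibbles), `ground_truth` (every effect
#'   used, sufficient to predict the expected sign of decomposition
#'   covariation terms) and `config`.
#' @export
#' @examples
#' com <- sim_community(sim_regime("turnover_only", seed = 42))
#' head(com$abundance)
sim_community <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  nc <- config$n_climates; nt <- config$n_treatments; nb <- config$n_blocks
  P <- config$pool_size

  # Species pools: climate 1 gets fresh species; each later climate shares
  # n_shared species with the previous pool and adds fresh ones.
  pools <- vector("list", nc)
  home <- integer(0)
  n_species <- 0L
  new_species <- function(k, ci) {
    ids <- sprintf("sp%03d", n_species + seq_len(k))
    n_species <<- n_species + k
    home <<- c(home, setNames(rep(ci, k), ids))
    ids
  }
  pools[[1]] <- new_species(P, 1L)
  for (ci in seq_len(nc)[-1]) {
    shared <- if (config$n_shared > 0) {
      pools[[ci - 1]][seq_len(config$n_shared)]
    } else character(0)
    pools[[ci]] <- c(shared, new_species(P - length(shared), ci))
  }
  species <- names(home)

  # Base traits: lognormal, log-mean shifted by the home climate's position
  # on the gradient (centred at the intermediate climate).
  tr <- config$traits
  base <- matrix(NA_real_, n_species, nrow(tr),
                 dimnames = list(species, tr$trait))
  for (j in seq_len(nrow(tr))) {
    tau <- config$turnover_strength[[tr$trait[j]]]
    base[, j] <- rlnorm(n_species,
                        tr$log_mean[j] + tau * (home - 2),
                        tr$log_sd[j])
  }

  # Plot design: blocks are site letters, one letter per climate x replicate.
  design <- tidyr::expand_grid(
    climate = factor(climate_levels, levels = climate_levels),
    rep = seq_len(nb),
    treatment = factor(treatment_levels, levels = treatment_levels)
  )
  design$block <- factor(LETTERS[(as.integer(design$climate) - 1) * nb +
                                   design$rep])
  design$plot_id <- sprintf("p%02d", seq_len(nrow(design)))
  design <- as_plot_design(design[, c("plot_id", "climate", "treatment",
                                      "block")])

  # Abundances: symmetric Dirichlet over the climate pool, scaled to % cover.
  rdirichlet1 <- function(k, alpha) {
    g <- rgamma(k, shape = alpha)
    g / sum(g)
  }
  shared_draws <- NULL
  if (config$share_abundances) {
    shared_draws <- replicate(nb * nt,
                              rdirichlet1(P, config$abundance_concentration),
                              simplify = FALSE)
  }
  meta <- tidyr::expand_grid(climate_i = seq_len(nc), rep = seq_len(nb),
                             treat_i = seq_len(nt))
  ab_list <- vector("list", nrow(meta))
  for (r in seq_len(nrow(meta))) {
    ci <- meta$climate_i[r]
    pool <- pools[[ci]]
    w <- if (config$share_abundances) {
      shared_draws[[(meta$rep[r] - 1) * nt + meta$treat_i[r]]]
    } else {
      rdirichlet1(P, config$abundance_concentration)
    }
    ab_list[[r]] <- tibble(plot_id = design$plot_id[r], species = pool,
                           cover = 100 * w)
  }
  abundance <- as_abundance(bind_rows(ab_list))

  # Plot-specific trait values: base + additive ITV shifts + noise.
  scale_t <- setNames(exp(tr$log_mean), tr$trait)
  # Climate ITV shift per (trait, climate).  Independent mode uses the plain
  # centred-index pattern delta * (c - 2).  Reinforcing/opposing modes align
  # the shift with (against) the realised between-pool base-trait
  # differences of this draw, scaled so the largest shift equals
  # itv_frac_climate * trait scale.
  climate_shift <- matrix(0, nrow(tr), nc, dimnames = list(tr$trait, NULL))
  for (j in seq_len(nrow(tr))) {
    trait <- tr$trait[j]
    if (config$covariation_mode == "independent") {
      climate_shift[j, ] <- config$itv_frac_climate * scale_t[[trait]] *
        (seq_len(nc) - 2)
    } else {
      # Realised, abundance-weighted base-trait mean of each climate's
      # community: the between-pool difference the fixed CWMs will express.
      pool_means <- vapply(seq_len(nc), function(ci) {
        rows <- abundance[abundance$plot_id %in%
                            design$plot_id[as.integer(design$climate) == ci], ]
        sum(rows$cover * base[rows$species, j]) / sum(rows$cover)
      }, numeric(1))
      dev <- pool_means - mean(pool_means)
      if (max(abs(dev)) > 0) dev <- dev / max(abs(dev))
      s <- if (config$covariation_mode == "reinforcing") 1 else -1
      climate_shift[j, ] <- s * config$itv_frac_climate *
        scale_t[[trait]] * dev
    }
  }
  delta_t <- config$itv_frac_treatment * scale_t
  delta_i <- config$itv_frac_interaction * scale_t
  noise_sd <- config$itv_noise_frac * scale_t

  trait_rows <- vector("list", nrow(meta))
  for (r in seq_len(nrow(meta))) {
    ci <- meta$climate_i[r]; ti <- meta$treat_i[r]
    pool <- pools[[ci]]
    vals <- lapply(seq_len(nrow(tr)), function(j) {
      trait <- tr$trait[j]
      shift <- climate_shift[trait, ci] + delta_t[[trait]] * (ti - 2) +
        delta_i[[trait]] * (ci - 2) * (ti - 2)
      v <- base[pool, j] + shift +
        rnorm(length(pool), 0, noise_sd[[trait]])
      pmax(v, 1e-3 * scale_t[[trait]])
    })
    trait_rows[[r]] <- tibble(
      species = rep(pool, times = nrow(tr)),
      plot_id = design$plot_id[r],
      trait = rep(tr$trait, each = length(pool)),
      value = unlist(vals)
    )
  }
  traits <- bind_rows(trait_rows)
  traits <- add_pooled_traits(traits, abundance)
  traits <- as_trait_table(traits)

  ground_truth <- list(
    seed = config$seed,
    pools = pools,
    species_home_climate = home,
    base_traits = base,
    itv_climate_shift = climate_shift,
    itv_treatment_delta = delta_t,
    itv_interaction_delta = delta_i,
    itv_noise_sd = noise_sd,
    turnover_strength = config$turnover_strength,
    covariation_mode = config$covariation_mode,
    expected_covariation_sign = switch(config$covariation_mode,
      independent = 0, reinforcing = 1, opposing = -1
    )
  )
  structure(list(design = design, abundance = abundance, traits = traits,
                 ground_truth = ground_truth, config = config),
            class = "trait_community")
}
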