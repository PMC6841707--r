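#' Default multi-scale variance fractions for the environmental generator
#'
#' Percent of total (log-scale) variance assigned to each spatial scale
#' (biome, floodplain, zone, habitat, residual) for the ten biogeochemical
#' variables, the nested structure the generator emulates: most variables
#' vary chiefly among floodplains, ammonium and the benthic stocks chiefly
#' at habitat/residual scales. Rows sum to 100.
#'
#' @return 10 x 5 numeric matrix, variables as rows.
#' @export
default_variance_fractions <- function() {
  m <- rbind(
    DOC = c(0, 63, 4, 13, 20),
    NH4 = c(0, 0, 13, 0, 87),
    NO3 = c(0, 60, 4, 2, 34),
    DON = c(0, 64, 3, 3, 30),
    TN  = c(11, 63, 9, 0, 17),
    SRP = c(0, 73, 0, 21, 6),
    TP  = c(0, 87, 1, 9, 4),
    NP  = c(0, 65, 7, 3, 25),
    chla = c(0, 8, 0, 13, 79),
    BOM = c(0, 0, 8, 19, 73)
  )
  colnames(m) <- c("biome", "floodplain", "zone", "habitat", "residual")
  # renormalise rows to exactly 100 (source percentages are rounded)
  sweep(m, 1, rowSums(m), "/") * 100
}

#' Scenario configuration for the synthetic generator
#'
#' Bundles every knob of the synthetic study: the sampling design (floodplains
#' per sub-biome, zones, habitat types, replicates), the nested variance
#' fractions per variable, the three sub-biome N:P regimes (means 1.8, 12.7
#' and 30.7 for N-limited montane, N-rich montane and grassland), the
#' community (taxon count, guild composition, niche slopes with the
#' heterocystous-cyanobacteria slope on log N:P negative, latent-factor
#' module structure, zone-affinity offsets) and the read-depth distribution.
#'
#' @param n_floodplains named integer: floodplains per sub-biome.
#' @param habitats_per_zone habitat types sampled per zone.
#' @param reps_per_habitat replicate samples per habitat unit.
#' @param variance_fractions matrix as [default_variance_fractions()].
#' @param total_log_variance total variance of each variable on log scale.
#' @param np_regimes named numeric: target mean molar N:P per sub-biome.
#' @param n_taxa total taxon count.
#' @param guild_sizes named integer: taxa per guild (remainder "other").
#' @param hetero_np_slope,cyano_np_slope niche slope on standardised log N:P
#'   for heterocystous and other cyanobacteria (negative: advantage under N
#'   limitation).
#' @param background_slope_sd sd of small random niche slopes of other taxa.
#' @param n_modules number of true co-abundance modules.
#' @param module_fraction fraction of taxa belonging to a module.
#' @param module_loading absolute latent-factor loading of module taxa.
#' @param negative_loading_fraction fraction of module taxa loading
#'   negatively (mixed-sign modules yield negative associations).
#' @param shared_loading loading of all module taxa on one community-wide
#'   factor (interconnects modules; 0 disables).
#' @param n_dominant number of dominant "suppressor" taxa whose blooms
#'   absorb read share; through compositional closure their waxing and
#'   waning makes every other taxon's read fraction co-vary positively (the
#'   mechanism behind dense all-positive networks; 0 disables).
#' @param dominant_base,dominant_loading log-baseline and bloom-factor
#'   loading of the dominant taxa.
#' @param zone_offset magnitude of the zone-affinity offset on log
#'   abundance. Because the zone contrast is a binary driver it can carry
#'   read-fraction correlations all the way to +/-1, unlike Gaussian
#'   factors whose raw-scale anti-correlations are bounded.
#' @param oppose_zones_by_sign if `TRUE`, negative-loading module taxa get
#'   the opposite zone affinity to their module's positive taxa.
#' @param factor_dist `"binary"` (default) or `"gaussian"` latent factor
#'   states. Binary (+/-1 bloom/no-bloom regimes) is the default because a
#'   two-state driver carries its correlation structure onto the read-
#'   fraction scale undamped, the way real bloom dynamics do; Gaussian
#'   factors are attenuated by the exponential link.
#' @param occupancy probability that an unstructured taxon (no module, not
#'   dominant) occurs in a given habitat unit; draws are shared by replicate
#'   samples of the unit. Values below 1 create the patchy incidence
#'   structure that drives Sorensen beta diversity and its
#'   turnover-dominated partition; module and dominant taxa are never
#'   dropped so the co-abundance structure is untouched.
#' @param base_sd sd of taxon log-baseline abundances.
#' @param noise_sd sd of residual log-abundance noise.
#' @param depth_meanlog,depth_sdlog log-normal read-depth distribution.
#' @param seed default seed carried by the scenario.
#' @return list of class `scenario_config`.
#' @export
scenario_config <- function(
    n_floodplains = c(`montane-n-limited` = 3, `montane-n-rich` = 3,
                      grassland = 4),
    habitats_per_zone = 3, reps_per_habitat = 2,
    variance_fractions = default_variance_fractions(),
    total_log_variance = 0.6,
    np_regimes = c(`montane-n-limited` = 1.8, `montane-n-rich` = 12.7,
                   grassland = 30.7),
    n_taxa = 90,
    guild_sizes = c(`heterocystous-cyanobacteria` = 10,
                    `other-cyanobacteria` = 8, diatom = 18),
    hetero_np_slope = -1.0, cyano_np_slope = -0.5,
    background_slope_sd = 0.25,
    n_modules = 3, module_fraction = 0.5, module_loading = 0.85,
    negative_loading_fraction = 0, shared_loading = 0,
    n_dominant = 0, dominant_base = 3, dominant_loading = 1.8,
    zone_offset = 0.4, oppose_zones_by_sign = FALSE,
    factor_dist = c("binary", "gaussian"),
    occupancy = 0.8, base_sd = 1.0, noise_sd = 0.35,
    depth_meanlog = log(20000), depth_sdlog = 0.2,
    seed = 1L) {
  if (any(abs(rowSums(variance_fractions) - 100) > 1e-9))
    stop("scenario_config: variance fractions must sum to 100 per variable",
         call. = FALSE)
  stopifnot(n_taxa > 0, sum(guild_sizes) <= n_taxa,
            all(n_floodplains >= 0), habitats_per_zone >= 1,
            reps_per_habitat >= 1)
  factor_dist <- match.arg(factor_dist)
  cfg <- as.list(environment())
  class(cfg) <- "scenario_config"
  cfg
}

#' Named scenario presets
#'
#' Four frozen study conditions:
#' * `"n-limited"`: 3 montane floodplains under N limitation (N:P ~ 1.8);
#'   sparser module membership, mixed-sign loadings, opposing zone
#'   affinities, no shared factor — the regime expected to yield smaller,
#'   more negative, more modular networks.
#' * `"n-rich"`: 3 montane N-rich floodplains (N:P ~ 12.7); dense
#'   all-positive modules tied together by a community-wide factor.
#' * `"grassland"`: 4 grassland floodplains (N:P ~ 30.7), similar to
#'   n-rich with slightly weaker coupling.
#' * `"null"`: no niche slopes, no modules, no zone structure — taxa
#'   exchangeable.
#'
#' @param scenario preset name.
#' @param seed seed stored in the config.
#' @return a [scenario_config()].
#' @export
scenario_preset <- function(scenario = c("n-limited", "n-rich", "grassland",
                                         "null"), seed = 1L) {
  scenario <- match.arg(scenario)
  switch(scenario,
    "n-limited" = scenario_config(
      n_floodplains = c(`montane-n-limited` = 3),
      habitats_per_zone = 3, reps_per_habitat = 3,   # 54 samples
      module_fraction = 0.45, n_modules = 3, module_loading = 1.1,
      negative_loading_fraction = 0.25, shared_loading = 0, n_dominant = 0,
      zone_offset = 0.2, noise_sd = 0.35,
      oppose_zones_by_sign = TRUE, seed = seed),
    "n-rich" = scenario_config(
      n_floodplains = c(`montane-n-rich` = 3),
      habitats_per_zone = 3, reps_per_habitat = 2,   # 36 samples
      module_fraction = 0.75, n_modules = 3, module_loading = 0.5,
      negative_loading_fraction = 0, shared_loading = 0,
      n_dominant = 4, dominant_base = 3.5, dominant_loading = 2.2,
      noise_sd = 0.25, oppose_zones_by_sign = FALSE, seed = seed),
    "grassland" = scenario_config(
      n_floodplains = c(grassland = 4),
      habitats_per_zone = 3, reps_per_habitat = 1,   # 24 samples
      module_fraction = 0.7, n_modules = 3, module_loading = 0.55,
      negative_loading_fraction = 0.02, shared_loading = 0,
      n_dominant = 4, dominant_base = 3.2, dominant_loading = 2.0,
      noise_sd = 0.25, oppose_zones_by_sign = FALSE, seed = seed),
    "null" = scenario_config(
      hetero_np_slope = 0, cyano_np_slope = 0, background_slope_sd = 0,
      module_fraction = 0, n_modules = 0, module_loading = 0,
      shared_loading = 0, n_dominant = 0, zone_offset = 0,
      occupancy = 1, seed = seed))
}

#' Generate the nested sampling hierarchy of a scenario
#'
#' Builds floodplains per sub-biome, both lateral zones, `habitats_per_zone`
#' habitat units per zone and `reps_per_habitat` replicate samples per
#' habitat unit, with projected coordinates: floodplains scattered at
#' regional scale (~100 km), habitats within floodplains at local scale
#' (~1 km). Habitat types are drawn from each zone's pool with
#' regime-dependent evenness: free-flowing floodplains sample types nearly
#' uniformly while dam-regulated ones draw from a strongly skewed
#' distribution, so predictable flow begets higher habitat diversity
#' (Shannon H of habitat types) — the gradient the flow-habitat analyses
#' exploit.
#'
#' @param cfg a `scenario_config`.
#' @param seed integer seed.
#' @return list: `hierarchy` (a [sample_hierarchy()]), `sub_biome` (named by
#'   floodplain), `flow_regime` (named by floodplain; all grassland plus one
#'   montane floodplain dammed, the rest free-flowing).
#' @export
gen_hierarchy <- function(cfg, seed = cfg$seed) {
  fp_names <- unlist(lapply(names(cfg$n_floodplains), function(sb) {
    k <- cfg$n_floodplains[[sb]]
    if (k == 0) return(character(0))
    prefix <- c(`montane-n-limited` = "ML", `montane-n-rich` = "MR",
                grassland = "GR")[[sb]]
    paste0(prefix, seq_len(k))
  }))
  sub_biome <- rep(names(cfg$n_floodplains), cfg$n_floodplains)
  names(sub_biome) <- fp_names
  biome <- ifelse(sub_biome == "grassland", "grassland", "montane")
  regime <- ifelse(sub_biome == "grassland", "dammed", "free-flowing")
  # half the study's floodplains sit below dams, all grassland ones included
  montane_fp <- fp_names[biome == "montane"]
  if (length(montane_fp)) regime[montane_fp[1]] <- "dammed"
  with_seed(seed, {
    fx <- stats::runif(length(fp_names), 0, 3e5)
    fy <- stats::runif(length(fp_names), 0, 3e5)
    rows <- list()
    for (f in seq_along(fp_names)) {
      skew <- if (regime[f] == "dammed") 3.2 else 0.3
      for (z in c("main-channel", "off-channel")) {
        pool <- habitat_types()[[z]]
        w <- exp(skew * stats::rnorm(length(pool)))
        habs <- sample(pool, cfg$habitats_per_zone, replace = TRUE,
                       prob = w / sum(w))
        for (u in seq_along(habs)) for (r in seq_len(cfg$reps_per_habitat)) {
          rows[[length(rows) + 1L]] <- data.frame(
            sample_id = sprintf("%s_%s_u%d_%s_r%d", fp_names[f],
                                substr(z, 1, 4), u, habs[u], r),
            biome = biome[f], floodplain = fp_names[f], zone = z,
            habitat = habs[u],
            x = fx[f] + stats::runif(1, 0, 1000),
            y = fy[f] + stats::runif(1, 0, 1000),
            stringsAsFactors = FALSE)
        }
      }
    }
    df <- do.call(rbind, rows)
    h <- sample_hierarchy(df$sample_id, df$biome, df$floodplain, df$zone,
                          df$habitat, df$x, df$y)
    list(hierarchy = h, sub_biome = sub_biome, flow_regime = regime)
  })
}

#' Generate a daily discharge series
#'
#' Daily log-discharge is a mean plus a seasonal harmonic plus AR(1) noise.
#' Free-flowing rivers get a strong snowmelt harmonic (amplitude much larger
#' than the noise); dammed rivers get an almost flat harmonic plus irregular
#' square release pulses, mimicking hydropeaking-style operation that
#' decouples flow magnitude from season.
#'
#' @param years number of years (>= 2; Colwell needs two cycles).
#' @param regime `"free-flowing"` or `"dammed"`.
#' @param seed integer seed.
#' @param mean_log mean log-discharge (default `log(10)` m3/s).
#' @param amplitude seasonal harmonic amplitude; default 1.2 (free) or 0.15
#'   (dammed).
#' @param ar_sd,ar_rho AR(1) innovation sd and autocorrelation.
#' @param pulses_per_year,pulse_amplitude dam-release pulse rate and
#'   log-amplitude range (dammed regime only).
#' @param river river name.
#' @return a [flow_series()] of length `365 * years`.
#' @export
gen_flow <- function(years, regime = c("free-flowing", "dammed"), seed = 1L,
                     mean_log = log(10), amplitude = NULL, ar_sd = 0.25,
                     ar_rho = 0.7, pulses_per_year = 10,
                     pulse_amplitude = c(0.3, 1.2), river = regime) {
  regime <- match.arg(regime)
  if (years < 2) stop("gen_flow: need at least 2 years", call. = FALSE)
  if (is.null(amplitude))
    amplitude <- if (regime == "free-flowing") 1.2 else 0.15
  nd <- 365L * years
  doy <- rep(seq_len(365L), years)
  with_seed(seed, {
    seasonal <- amplitude * cos(2 * pi * (doy - 150) / 365)
    eps <- numeric(nd)
    if (ar_sd > 0) {
      innov <- stats::rnorm(nd, 0, ar_sd)
      eps[1] <- innov[1] / sqrt(1 - ar_rho^2)
      for (t in 2:nd) eps[t] <- ar_rho * eps[t - 1] + innov[t]
    }
    pulse <- numeric(nd)
    if (regime == "dammed" && pulses_per_year > 0) {
      n_pulse <- stats::rpois(1, pulses_per_year * years)
      if (n_pulse > 0) {
        starts <- sample.int(nd, n_pulse, replace = TRUE)
        for (k in seq_len(n_pulse)) {
          len <- sample(3:20, 1)
          amp <- stats::runif(1, pulse_amplitude[1], pulse_amplitude[2]) *
            sample(c(-1, 1), 1)
          idx <- starts[k]:min(nd, starts[k] + len - 1)
          pulse[idx] <- pulse[idx] + amp
        }
      }
    }
    q <- exp(mean_log + seasonal + eps + pulse)
    dates <- seq.Date(as.Date("1980-01-01"), by = "day", length.out = nd)
    # drop Feb 29 alignment issues by using a synthetic 365-day calendar
    dates <- as.Date("1979-12-31") + seq_len(nd)
    flow_series(river, dates, q)
  })
}

#' Generate the nested environmental table of a scenario
#'
#' Each variable is built on the log scale as a grand mean plus independent
#' Gaussian effects drawn at the biome, floodplain, zone and habitat levels
#' (variances proportional to the configured percentage fractions of
#' `total_log_variance`) plus residual noise, then exponentiated. TN and TP
#' additionally receive sub-biome offsets so that mean molar N:P matches the
#' configured regimes; N:P is then computed from the generated TN and TP on
#' a molar basis (14.007 and 30.974 g/mol), not drawn directly.
#'
#' @param cfg a `scenario_config`.
#' @param hier output of [gen_hierarchy()] (hierarchy + sub_biome).
#' @param seed integer seed.
#' @return data.frame: `sample_id`, the ten variables (concentration or
#'   areal units), `NP` molar.
#' @export
gen_env <- function(cfg, hier, seed = cfg$seed) {
  h <- hier$hierarchy
  sub_biome <- hier$sub_biome
  fr <- cfg$variance_fractions
  if (any(abs(rowSums(fr) - 100) > 1e-9))
    stop("gen_env: variance fractions must sum to 100", call. = FALSE)
  grand <- c(DOC = log(3), NH4 = log(8), NO3 = log(30), DON = log(150),
             TN = log(0.35), SRP = log(6), TP = log(25),
             NP = NA, chla = log(2.5), BOM = log(30))
  # sub-biome offsets on log TN / log TP chosen to hit the target mean N:P
  np_target <- cfg$np_regimes
  with_seed(seed, {
    n <- nrow(h)
    vars <- rownames(fr)
    out <- data.frame(sample_id = h$sample_id, stringsAsFactors = FALSE)
    key <- list(biome = h$biome,
                floodplain = h$floodplain,
                zone = paste(h$floodplain, h$zone),
                habitat = paste(h$floodplain, h$zone, h$habitat))
    for (v in setdiff(vars, "NP")) {
      y <- rep(grand[[v]], n)
      for (lv in names(key)) {
        sd_lv <- sqrt(fr[v, lv] / 100 * cfg$total_log_variance)
        labs <- key[[lv]]
        eff <- stats::setNames(stats::rnorm(length(unique(labs)), 0, sd_lv),
                               unique(labs))
        y <- y + eff[labs]
      }
      y <- y + stats::rnorm(n, 0, sqrt(fr[v, "residual"] / 100 *
                                         cfg$total_log_variance))
      out[[v]] <- exp(unname(y))
    }
    # impose the N:P regimes: shift log TP per floodplain's sub-biome so the
    # molar ratio centres on the target (TN in mg/L, TP in ug/L)
    sb <- sub_biome[h$floodplain]
    target <- np_target[sb]
    if (anyNA(target))
      stop("gen_env: missing N:P regime for sub-biome(s) ",
           paste(unique(sb[is.na(target)]), collapse = ", "), call. = FALSE)
    tn_molar <- out$TN / 14.007 * 1000         # umol/L from mg/L
    tp_molar_now <- out$TP / 30.974            # umol/L from ug/L
    ratio_now <- mean(tn_molar) / mean(tp_molar_now)
    out$TP <- out$TP * (ratio_now / unname(target))
    out$NP <- (out$TN / 14.007 * 1000) / (out$TP / 30.974)
    out
  })
}

#' Generate a community count table with known ground truth
#'
#' Per-sample expected log-abundance of each taxon is a log-normal baseline
#' plus niche responses to standardised environmental axes (log N:P and log
#' DOC; cyanobacterial guilds carry negative N:P slopes, so their read
#' fraction rises under N limitation), plus latent-factor terms defining
#' true co-abundance modules (factor shared within a module; the loading
#' sign sets the association sign; an optional community-wide factor couples
#' modules), plus a zone-affinity offset. Reads are drawn multinomially at a
#' log-normal depth. The returned ground truth records module membership,
#' niche slopes, loadings and zone affinities for recovery tests.
#'
#' @param cfg a `scenario_config`.
#' @param env output of [gen_env()].
#' @param hier output of [gen_hierarchy()].
#' @param seed integer seed.
#' @return list: `counts` (a [count_table()]), `truth` (list with
#'   `module`, `loadings`, `niche_slopes`, `zone_affinity`, `guild`,
#'   `flow_regime`, `variance_fractions`, `depths`).
#' @export
gen_community <- function(cfg, env, hier, seed = cfg$seed) {
  h <- hier$hierarchy
  stopifnot(identical(env$sample_id, h$sample_id))
  n <- nrow(h)
  Tn <- cfg$n_taxa
  guild <- rep("other", Tn)
  gi <- 1L
  for (g in names(cfg$guild_sizes)) {
    k <- cfg$guild_sizes[[g]]
    guild[gi:(gi + k - 1L)] <- g
    gi <- gi + k
  }
  z_np <- as.numeric(scale(log(env$NP)))
  z_doc <- as.numeric(scale(log(env$DOC)))
  if (all(!is.finite(z_np))) z_np <- rep(0, n)
  if (all(!is.finite(z_doc))) z_doc <- rep(0, n)
  with_seed(seed, {
    base <- stats::rnorm(Tn, 0, cfg$base_sd)
    slopes <- cbind(
      NP = stats::rnorm(Tn, 0, cfg$background_slope_sd),
      DOC = stats::rnorm(Tn, 0, cfg$background_slope_sd))
    slopes[guild == "heterocystous-cyanobacteria", "NP"] <- cfg$hetero_np_slope
    slopes[guild == "other-cyanobacteria", "NP"] <- cfg$cyano_np_slope
    module <- integer(Tn)
    # factor columns: one per module, one shared, one per dominant taxon
    # (independent blooms keep any one dominant's pairwise anti-correlation
    # with the rest below threshold while their joint share still swings)
    n_mod_cols <- max(cfg$n_modules, 0)
    loadings <- matrix(0, Tn, n_mod_cols + 1L + max(cfg$n_dominant, 0))
    if (cfg$n_modules > 0 && cfg$module_fraction > 0) {
      n_member <- round(cfg$module_fraction * Tn)
      members <- sample.int(Tn, n_member)
      module[members] <- rep_len(seq_len(cfg$n_modules), n_member)
      # module taxa mildly abundant: enough reads to keep their signal, but
      # not so many that their blooms drive the whole denominator (which
      # would couple all remaining taxa through compositional closure)
      base[members] <- stats::rnorm(n_member, 0.3, 0.4)
      for (t in members) {
        sgn <- if (stats::runif(1) < cfg$negative_loading_fraction) -1 else 1
        loadings[t, module[t]] <- sgn * cfg$module_loading
        loadings[t, n_mod_cols + 1L] <- cfg$shared_loading
      }
    }
    dominant <- integer(0)
    if (cfg$n_dominant > 0) {
      pool <- which(module == 0 & guild == "other")
      dominant <- sample(pool, min(cfg$n_dominant, length(pool)))
      base[dominant] <- cfg$dominant_base
      for (k in seq_along(dominant))
        loadings[dominant[k], n_mod_cols + 1L + k] <- cfg$dominant_loading
    }
    zone_aff <- sample(c("main-channel", "off-channel"), Tn, replace = TRUE)
    zone_mag <- rep(cfg$zone_offset, Tn)
    if (cfg$oppose_zones_by_sign && cfg$n_modules > 0) {
      for (md in seq_len(cfg$n_modules)) {
        zz <- sample(c("main-channel", "off-channel"), 1)
        other <- setdiff(c("main-channel", "off-channel"), zz)
        zone_aff[module == md & loadings[, md] > 0] <- zz
        zone_aff[module == md & loadings[, md] < 0] <- other
      }
      # keep the strong zone contrast specific to module taxa; otherwise
      # non-members would bridge modules through shared zone structure
      zone_mag[module == 0] <- 0.3 * cfg$zone_offset
    }
    factors <- if (cfg$factor_dist == "binary")
      matrix(sample(c(-1, 1), n * ncol(loadings), replace = TRUE), n)
    else matrix(stats::rnorm(n * ncol(loadings)), n)
    off <- (h$zone == "off-channel") * 1
    zone_term <- outer(ifelse(zone_aff == "off-channel", zone_mag,
                              -zone_mag), off)  # taxa x samples
    lambda <- matrix(base, Tn, n) +
      slopes %*% rbind(z_np, z_doc) +
      loadings %*% t(factors) +
      zone_term +
      matrix(stats::rnorm(Tn * n, 0, cfg$noise_sd), Tn, n)
    if (cfg$occupancy < 1) {
      # habitat-unit-level patchiness of unstructured taxa: shared by
      # replicates within a unit, independent across units and taxa
      unit <- factor(paste(h$floodplain, h$zone, h$habitat))
      eligible <- which(module == 0 & !(seq_len(Tn) %in% dominant))
      pres <- matrix(stats::rbinom(length(eligible) * nlevels(unit), 1,
                                   cfg$occupancy),
                     length(eligible), nlevels(unit))
      lambda[eligible, ] <- lambda[eligible, ] -
        12 * (1 - pres[, as.integer(unit), drop = FALSE])
    }
    if (any(!is.finite(lambda)))
      stop("gen_community: non-finite expected abundance", call. = FALSE)
    depth <- pmax(1000L, round(stats::rlnorm(n, cfg$depth_meanlog,
                                             cfg$depth_sdlog)))
    counts <- vapply(seq_len(n), function(j) {
      pr <- exp(lambda[, j] - max(lambda[, j]))
      stats::rmultinom(1, depth[j], pr)[, 1]
    }, integer(Tn))
    ids <- sprintf("fam%03d", seq_len(Tn))
    rownames(counts) <- ids
    colnames(counts) <- h$sample_id
    phylum <- ifelse(grepl("cyano", guild), "Cyanobacteria",
                     ifelse(guild == "diatom", "Bacillariophyta", "OtherPhyla"))
    ct <- count_table(counts, ids,
                      lineage = paste(phylum, ids, sep = ";"), guild = guild)
    truth <- list(module = stats::setNames(module, ids),
                  dominant = ids[dominant],
                  loadings = loadings, niche_slopes = slopes,
                  zone_affinity = stats::setNames(zone_aff, ids),
                  guild = stats::setNames(guild, ids),
                  flow_regime = hier$flow_regime,
                  variance_fractions = cfg$variance_fractions,
                  depths = depth)
    list(counts = ct, truth = truth)
  })
}

#' Simulate a full scenario to memory or disk
#'
#' Runs [gen_hierarchy()], [gen_env()], [gen_community()] and per-river
#' [gen_flow()] under one seed; optionally writes counts, metadata,
#' environment and flow TSVs plus a ground-truth JSON to a directory.
#'
#' @param scenario preset name (see [scenario_preset()]) or a
#'   `scenario_config`.
#' @param seed integer seed.
#' @param out_dir optional output directory.
#' @param flow_years years of daily flow per river.
#' @return list: `config`, `hierarchy`, `sub_biome`, `flow_regime`, `env`,
#'   `counts`, `truth`, `flows` (named list of `flow_series`).
#' @export
simulate_scenario <- function(scenario = "n-limited", seed = 1L,
                              out_dir = NULL, flow_years = 30) {
  cfg <- if (inherits(scenario, "scenario_config")) scenario
    else scenario_preset(scenario, seed = seed)
  cfg$seed <- seed
  hier <- gen_hierarchy(cfg, seed = derive_seed(seed, "hierarchy"))
  env <- gen_env(cfg, hier, seed = derive_seed(seed, "env"))
  com <- gen_community(cfg, env, hier, seed = derive_seed(seed, "community"))
  flows <- lapply(seq_along(hier$flow_regime), function(i)
    gen_flow(flow_years, hier$flow_regime[i],
             seed = derive_seed(seed, paste0("flow", i)),
             river = names(hier$flow_regime)[i]))
  names(flows) <- names(hier$flow_regime)
  out <- list(config = cfg, hierarchy = hier$hierarchy,
              sub_biome = hier$sub_biome, flow_regime = hier$flow_regime,
              env = env, counts = com$counts, truth = com$truth,
              flows = flows)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_count_table(com$counts, file.path(out_dir, "counts.tsv"))
    write_sample_hierarchy(hier$hierarchy, file.path(out_dir, "metadata.tsv"))
    utils::write.table(env, file.path(out_dir, "env.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    for (nm in names(flows))
      write_flow_series(flows[[nm]], file.path(out_dir,
                                               paste0("flow_", nm, ".tsv")))
    truth_json <- com$truth
    truth_json$loadings <- unname(as.data.frame(truth_json$loadings))
    truth_json$niche_slopes <- as.data.frame(truth_json$niche_slopes)
    jsonlite::write_json(
      c(truth_json["module"],
        list(zone_affinity = as.list(com$truth$zone_affinity),
             flow_regime = as.list(hier$flow_regime),
             guild = as.list(com$truth$guild))),
      file.path(out_dir, "ground_truth.json"), auto_unbox = TRUE)
  }
  out
}

#' Simulate the full ten-floodplain study
#'
#' Combines the three sub-biome presets' community structure into one
#' design: 3 N-limited montane, 3 N-rich montane and 4 grassland
#' floodplains generated jointly under the default nested environmental
#' variance, with per-sub-biome network structure applied to the respective
#' samples by generating each sub-biome's community from its preset and
#' binding the tables.
#'
#' @param seed integer seed.
#' @param flow_years years of daily flow per river.
#' @return list as [simulate_scenario()] per sub-biome plus pooled
#'   `hierarchy`, `env`, `counts`, `flow_regime`.
#' @export
simulate_study <- function(seed = 1L, flow_years = 30) {
  parts <- lapply(c("n-limited", "n-rich", "grassland"), function(sc)
    simulate_scenario(sc, seed = derive_seed(seed, sc),
                      flow_years = flow_years))
  names(parts) <- c("n-limited", "n-rich", "grassland")
  hier <- do.call(rbind, lapply(parts, function(p) as.data.frame(p$hierarchy)))
  rownames(hier) <- NULL
  h <- sample_hierarchy(hier$sample_id, hier$biome, hier$floodplain,
                        hier$zone, hier$habitat, hier$x, hier$y)
  env <- do.call(rbind, lapply(parts, function(p) p$env))
  rownames(env) <- NULL
  counts <- do.call(cbind, lapply(parts, function(p) p$counts$counts))
  ct <- count_table(counts, rownames(counts),
                    lineage = parts[[1]]$counts$lineage,
                    guild = parts[[1]]$counts$guild)
  sub_biome <- do.call(c, lapply(parts, function(p) p$sub_biome))
  names(sub_biome) <- sub("^[^.]*\\.", "", names(sub_biome))
  flow_regime <- do.call(c, lapply(parts, function(p) p$flow_regime))
  names(flow_regime) <- sub("^[^.]*\\.", "", names(flow_regime))
  flows <- do.call(c, lapply(parts, function(p) p$flows))
  names(flows) <- sub("^[^.]*\\.", "", names(flows))
  list(parts = parts, hierarchy = h, env = env, counts = ct,
       sub_biome = sub_biome, flow_regime = flow_regime, flows = flows,
       seed = seed)
}
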