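#' Pearson association with t-test
#'
#' The generic bivariate summary used for the study's headline
#' relationships (habitat diversity vs flow seasonality, cyanobacterial
#' fraction vs N:P, keystone abundance vs richness).
#'
#' @param x,y numeric vectors.
#' @return list: `r`, `p`, `n`.
#' @export
pearson_assoc <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3 || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
    return(list(r = NA_real_, p = NA_real_, n = sum(ok)))
  ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}

#' Run configuration for the full pipeline
#'
#' @param filter_prevalence,filter_reads taxon filter settings.
#' @param rarefy_depth rarefaction depth (samples below it are dropped).
#' @param collapse_level lineage rank for taxon collapse (family = 2 in the
#'   generator's `phylum;family` lineage).
#' @param r_threshold,p_max,min_samples network inference settings.
#' @param n_perm permutations for ANOSIM/envfit/forward selection.
#' @param n_boot bootstrap replicates for flow seasonality.
#' @param seed global seed; every stochastic stage gets a derived sub-seed.
#' @param out_dir optional directory for stage outputs (TSV).
#' @return list of class `run_config`.
#' @export
run_config <- function(filter_prevalence = 0.25, filter_reads = 20,
                       rarefy_depth = 10000, collapse_level = 2,
                       r_threshold = 0.6, p_max = 0.01, min_samples = 10,
                       n_perm = 999, n_boot = 999, seed = 1L,
                       out_dir = NULL) {
  cfg <- as.list(environment())
  class(cfg) <- "run_config"
  cfg
}

#' Run the full floodplain-microbiome workflow
#'
#' Orchestrates every stage over one study's inputs: table preparation
#' (filter, rarefy, collapse), Colwell flow seasonality with bootstrap CIs
#' per river, alpha diversity and beta partitioning per floodplain, NMDS +
#' ANOSIM + environmental vectors, variance components per environmental
#' variable, db-MEM construction with forward selection and
#' environment-versus-space partitioning, C-score screening and one
#' co-occurrence network per group, plus the headline Pearson associations.
#' Deterministic given (inputs, config, seed).
#'
#' @param counts a [count_table()] (raw, pre-filtering).
#' @param hierarchy a [sample_hierarchy()].
#' @param env environmental table (`sample_id` + variables).
#' @param flows named list of [flow_series()], one per floodplain.
#' @param groups named character: network group (e.g. sub-biome) per
#'   floodplain; defaults to one group per biome.
#' @param cfg a [run_config()].
#' @return list of stage results; see Details in the package vignette.
#' @export
run_pipeline <- function(counts, hierarchy, env, flows = NULL,
                         groups = NULL, cfg = run_config()) {
  stopifnot(inherits(counts, "count_table"),
            inherits(hierarchy, "sample_hierarchy"))
  stage <- "prepare"
  res <- list(config = cfg)
  tryCatch({
    filtered <- filter_taxa(counts, cfg$filter_prevalence, cfg$filter_reads)
    rare <- rarefy(filtered, cfg$rarefy_depth,
                   seed = derive_seed(cfg$seed, "rarefy"))
    fam <- collapse_taxa(rare, cfg$collapse_level)
    keep <- colnames(fam$counts)
    h <- hierarchy[hierarchy$sample_id %in% keep, , drop = FALSE]
    class(h) <- c("sample_hierarchy", "data.frame")
    h <- pair_samples(fam, h)$hierarchy
    ev <- env[match(h$sample_id, env$sample_id), , drop = FALSE]
    res$prepared <- list(family_table = fam, hierarchy = h, env = ev,
                         n_dropped = ncol(counts$counts) - length(keep))

    if (!is.null(flows)) {
      stage <- "flow"
      res$flow <- do.call(rbind, lapply(names(flows), function(nm) {
        cb <- colwell_bootstrap(flows[[nm]], n_boot = cfg$n_boot,
                                seed = derive_seed(cfg$seed, paste0("boot", nm)))
        data.frame(river = nm, M = cb$M, se = cb$se,
                   ci_lo = cb$ci[1], ci_hi = cb$ci[2])
      }))
      res$habitat_diversity <- vapply(unique(h$floodplain), function(f)
        habitat_diversity(h, f), numeric(1))
    }

    stage <- "diversity"
    res$alpha <- shannon_alpha(fam)
    fps <- unique(h$floodplain)
    res$beta <- do.call(rbind, lapply(fps, function(f) {
      sel <- h$floodplain == f
      if (sum(sel) < 3) return(NULL)
      inc <- multi_site_beta(fam, sel, "incidence")
      ab <- multi_site_beta(fam, sel, "abundance")
      data.frame(floodplain = f, sorensen = inc["total"],
                 turnover = inc["turnover"], nestedness = inc["nestedness"],
                 bray = ab["total"], bray_balanced = ab["turnover"],
                 bray_gradient = ab["nestedness"], row.names = NULL)
    }))
    res$contributions <- taxon_contributions(fam)
    if (!is.null(fam$guild)) {
      res$cyano_fraction <- guild_fractions(
        fam, c("heterocystous-cyanobacteria", "other-cyanobacteria"))
      res$hetero_fraction <- guild_fractions(fam,
                                             "heterocystous-cyanobacteria")
    }

    stage <- "ordination"
    ev_num <- ev[, setdiff(names(ev), "sample_id"), drop = FALSE]
    logev <- log(as.matrix(ev_num))
    res$pca <- nipals_pca(logev, n_axes = 2)
    res$dispersion <- group_dispersion(res$pca, h$floodplain)
    bc <- bray_curtis(fam)
    res$nmds <- nmds(bc, seed = derive_seed(cfg$seed, "nmds"))
    res$anosim_floodplain <- anosim(bc, h$floodplain, n_perm = cfg$n_perm,
                                    seed = derive_seed(cfg$seed, "anosim_fp"))
    if (length(unique(h$biome)) > 1)
      res$anosim_biome <- anosim(bc, h$biome, n_perm = cfg$n_perm,
                                 seed = derive_seed(cfg$seed, "anosim_bio"))
    res$envfit <- envfit_vectors(res$nmds, logev, n_perm = cfg$n_perm,
                                 seed = derive_seed(cfg$seed, "envfit"))

    stage <- "scales"
    res$vca <- do.call(rbind, lapply(names(ev_num), function(v) {
      out <- tryCatch(vca(ev, h, v), error = function(e) NULL)
      if (is.null(out)) return(NULL)
      data.frame(variable = v, t(stats::setNames(out$percent, out$component)))
    }))
    Y <- hellinger(fam)
    mem <- build_dbmem(cbind(h$x, h$y))
    sel_spa <- forward_select_rda(Y, as.data.frame(mem$vectors),
                                  n_perm = cfg$n_perm,
                                  seed = derive_seed(cfg$seed, "fwd_spa"))
    sel_env <- forward_select_rda(Y, as.data.frame(scale(logev)),
                                  n_perm = cfg$n_perm,
                                  seed = derive_seed(cfg$seed, "fwd_env"))
    res$selected <- list(spatial = sel_spa$selected,
                         environmental = sel_env$selected)
    if (length(sel_spa$selected) && length(sel_env$selected)) {
      res$varpart <- varpart_fractions(
        Y, scale(logev)[, sel_env$selected, drop = FALSE],
        mem$vectors[, sel_spa$selected, drop = FALSE])
    }

    stage <- "networks"
    if (is.null(groups))
      groups <- stats::setNames(h$biome[match(unique(h$floodplain),
                                              h$floodplain)],
                                unique(h$floodplain))
    grp_of_sample <- groups[h$floodplain]
    res$cscore <- lapply(unique(grp_of_sample), function(g) {
      sel <- grp_of_sample == g
      cscore_test(subset_count_table(fam, samples = sel),
                  n_null = max(99, min(cfg$n_perm, 299)),
                  seed = derive_seed(cfg$seed, paste0("cscore", g)))
    })
    names(res$cscore) <- unique(grp_of_sample)
    res$networks <- lapply(unique(grp_of_sample), function(g) {
      sel <- grp_of_sample == g
      tryCatch(
        analyze_network(fam, samples = sel, h = h, group_label = g,
                        seed = derive_seed(cfg$seed, paste0("net", g)),
                        r_threshold = cfg$r_threshold, p_max = cfg$p_max,
                        min_samples = cfg$min_samples),
        error = function(e) NULL)
    })
    names(res$networks) <- unique(grp_of_sample)
    res$network_table <- do.call(rbind, lapply(res$networks, function(z)
      if (!is.null(z)) z$summary))

    stage <- "associations"
    if (!is.null(res$flow)) {
      hd <- res$habitat_diversity[res$flow$river]
      res$assoc_habitat_flow <- pearson_assoc(res$flow$M, hd)
    }
    if (!is.null(res$cyano_fraction)) {
      np <- ev$NP[match(names(res$cyano_fraction), ev$sample_id)]
      res$assoc_cyano_np <- pearson_assoc(res$cyano_fraction, log(np))
      res$assoc_hetero_np <- pearson_assoc(res$hetero_fraction, log(np))
    }
    richness <- colSums(fam$counts > 0)
    res$assoc_keystone_richness <- lapply(res$networks, function(z) {
      if (is.null(z) || !length(z$keystones)) return(NULL)
      ks_ab <- colSums(relative_abundance(fam)[z$keystones, , drop = FALSE])
      pearson_assoc(ks_ab, richness)
    })
  }, error = function(e) {
    stop("run_pipeline: stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  if (!is.null(cfg$out_dir)) write_pipeline_outputs(res, cfg$out_dir)
  res
}

# write the main per-stage tables under out_dir
write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, nm) if (!is.null(df))
    utils::write.table(df, file.path(out_dir, nm), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  wt(res$flow, "flow_seasonality.tsv")
  wt(res$beta, "beta_partition.tsv")
  wt(res$vca, "variance_components.tsv")
  wt(res$network_table, "network_summary.tsv")
  wt(data.frame(sample_id = names(res$alpha), shannon = res$alpha),
     "alpha_diversity.tsv")
  wt(res$envfit, "envfit.tsv")
  invisible(out_dir)
}
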