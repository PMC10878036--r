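#' Configuration of the synthetic lake generator
#'
#' The generator emulates the statistical structure the downstream analysis
#' assumes: 16 monthly time points from September across two depth layers;
#' thermal stratification with a two-month mixed (de-stratified) window in
#' which the layer communities converge; layer-specific, seasonally forced
#' prokaryotic and viral communities; a cohort of summer-blooming ASVs whose
#' phages track them proportionally; host-prediction evidence with decoys;
#' and temperature-driven prokaryotic production. All randomness is drawn
#' from named substreams of `seed`, so adding one output never perturbs the
#' others and the same seed reproduces every table exactly.
#'
#' Bloomer trajectories are a year-round heavy-tailed baseline (detectable
#' but mostly below the dominance threshold) plus a narrow Gaussian bloom
#' peaking in July-September of the second year. The baseline is shared with
#' the bloomer's phages (they track the host's whole trajectory), which is
#' what makes planted pairs separable from coincidental summer co-risers.
#'
#' @param seed master seed (integer).
#' @param n_months months, starting in September of `start_year`.
#' @param n_asv,n_lbv community sizes.
#' @param n_bloomers number of summer-blooming ASVs.
#' @param phages_per_bloomer planted phages per bloomer.
#' @param n_persistent_deep deep-layer taxa given low temporal noise so they
#'   persist (and mostly stay dominant) through the study.
#' @param bloom_peak_relab expected relative abundance at the bloom peak.
#' @param bloom_base_relab median of the bloomer's year-round baseline.
#' @param bloom_base_sdlog lognormal sd of the baseline (heavy-tailed).
#' @param bloom_base_cap ceiling on baseline months, as a fraction of the
#'   peak (keeps the series maximum inside the bloom window).
#' @param bloom_width range of Gaussian bloom widths (months).
#' @param bloom_center_jitter uniform jitter around the July/August/September
#'   peak months.
#' @param bloom_peak_noise_sd lognormal noise on the bloom envelope.
#' @param virus_tracking_noise_sd lognormal noise of phage-host tracking.
#' @param phage_host_ratio phage virome fraction per unit host fraction.
#' @param tracking_lag months by which phages lag their host (default 0).
#' @param mixing_months calendar months in which the water column mixes.
#' @param temp_surface_range surface temperature range over the year (deg C).
#' @param temp_deep_base,temp_deep_amp deep temperature sinusoid (deg C).
#' @param asv_weight_sdlog,asv_month_noise_sd,asv_seasonal_amp,deep_seasonal_amp
#'   community-structure knobs for the prokaryotes.
#' @param offlayer_factor abundance factor of a layer specialist in the
#'   other layer.
#' @param lbv_weight_sdlog,lbv_month_noise_sd,lbv_seasonal_amp,lbv_affinity_shape
#'   community-structure knobs for the non-planted viruses; affinity is
#'   Beta(shape, shape), bimodal for shape < 1 (layer specialists).
#' @param host_assigned_fraction fraction of non-planted viruses that carry
#'   valid host evidence (the candidate pool of the pairing stage).
#' @param decoy_evidence_rate rate of additional sub-threshold evidence lines.
#' @param library_size_mean,library_size_mean_lbv mean sequencing depths.
#' @param coverage_halfsat read count at which expected covered fraction is
#'   0.5; coverage saturates as counts grow.
#' @param coverage_noise_sd lognormal jitter on coverage fractions.
#' @param lbv_length_range contig length range (bp).
#' @param production_months month indices with production measurements
#'   (default May-November of the second year).
#' @param production_base surface/deep production at deep-water temperature
#'   (cells per litre per day).
#' @param production_temp_coef exponential temperature coefficient (per deg C).
#' @param production_rep_sd lognormal replicate noise.
#' @param production_replicates replicates per measurement.
#' @param production_fold_band expected surface:deep fold range implied by
#'   the above (recorded in the ground truth).
#' @param conversion_factor cells produced per pmol incorporated.
#' @param start_year calendar year of month 0 (a September).
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_months = 16L, n_asv = 300L, n_lbv = 1500L,
                       n_bloomers = 13L, phages_per_bloomer = 2L,
                       n_persistent_deep = 20L,
                       bloom_peak_relab = 0.03,
                       bloom_base_relab = 0.016,
                       bloom_base_sdlog = 1.5,
                       bloom_base_cap = 0.95,
                       bloom_width = c(0.35, 0.9),
                       bloom_center_jitter = 0.2,
                       bloom_peak_noise_sd = 0.15,
                       virus_tracking_noise_sd = 0.2,
                       phage_host_ratio = 0.4,
                       tracking_lag = 0L,
                       mixing_months = c(2L, 3L),
                       temp_surface_range = c(8.5, 28.9),
                       temp_deep_base = 8.3, temp_deep_amp = 0.4,
                       asv_weight_sdlog = 1.2, asv_month_noise_sd = 0.3,
                       asv_seasonal_amp = 0.8, deep_seasonal_amp = 0.3,
                       offlayer_factor = 0.05,
                       lbv_weight_sdlog = 0.8, lbv_month_noise_sd = 0.45,
                       lbv_seasonal_amp = 0.15, lbv_affinity_shape = 0.3,
                       host_assigned_fraction = 0.2,
                       decoy_evidence_rate = 0.05,
                       library_size_mean = 5e4,
                       library_size_mean_lbv = 3e5,
                       coverage_halfsat = 4, coverage_noise_sd = 0.05,
                       lbv_length_range = c(10000L, 80000L),
                       production_months = 8:14,
                       production_base = c(surface = 4e7, deep = 5e6),
                       production_temp_coef = 0.12,
                       production_rep_sd = 0.1,
                       production_replicates = 3L,
                       production_fold_band = c(8, 120),
                       conversion_factor = 1.83e6,
                       start_year = 2018L) {
  cfg <- as.list(environment())
  if (cfg$n_bloomers > cfg$n_asv) stop_("n_bloomers must be <= n_asv")
  if (cfg$n_bloomers * cfg$phages_per_bloomer > cfg$n_lbv)
    stop_("too many planted phages for n_lbv")
  for (f in c("bloom_peak_relab", "bloom_base_relab", "virus_tracking_noise_sd",
              "host_assigned_fraction", "decoy_evidence_rate",
              "bloom_base_cap"))
    assert_scalar_num(cfg[[f]], f, lower = 0, upper = 1)
  if (cfg$bloom_base_relab >= cfg$bloom_peak_relab)
    stop_("bloomer baseline must sit below the bloom peak")
  if (cfg$n_months < 13L)
    stop_("the design needs the second year's July-September window (n_months >= 13)")
  class(cfg) <- "sim_config"
  cfg
}

# Deterministic temperature forcing. Surface follows a sinusoid over the
# configured range peaking in August; the deep layer is nearly constant.
# In mixing months the column is homogenised: deep tracks surface to 0.2 C.
sim_temperatures <- function(cfg) {
  idx <- seq_len(cfg$n_months) - 1L
  cal <- month_calendar(idx)
  mid <- mean(cfg$temp_surface_range)
  amp <- diff(cfg$temp_surface_range) / 2
  t_s <- mid + amp * cos(2 * pi * (cal - 8) / 12)
  t_d <- cfg$temp_deep_base + cfg$temp_deep_amp * cos(2 * pi * (cal - 2) / 12)
  mix <- cal %in% cfg$mixing_months
  t_d[mix] <- t_s[mix] - 0.2
  # vertical exchange strength decays with stratification (temperature
  # difference); ~0.94 in mixed months, ~0 at the height of stratification
  mix_frac <- exp(-pmax(t_s - t_d, 0) / 3)
  data.frame(month_index = idx, calendar_month = cal,
             year = month_year(idx, cfg$start_year),
             temp_surface = t_s, temp_deep = t_d, mixing = mix,
             mix_frac = mix_frac)
}

sim_metadata <- function(cfg) {
  tt <- sim_temperatures(cfg)
  do_s <- 11.5 - 0.12 * tt$temp_surface
  do_d <- ifelse(tt$mixing, 10.2, 5.5)
  meta <- rbind(
    data.frame(sample_id = sprintf("m%02d_surface", tt$month_index),
               month_index = tt$month_index, calendar_month = tt$calendar_month,
               year = tt$year, layer = "surface", depth_m = 0.5,
               temperature_C = tt$temp_surface, do_mgL = round(do_s, 2)),
    data.frame(sample_id = sprintf("m%02d_deep", tt$month_index),
               month_index = tt$month_index, calendar_month = tt$calendar_month,
               year = tt$year, layer = "deep", depth_m = 60,
               temperature_C = tt$temp_deep, do_mgL = do_d))
  validate_metadata(as_metadata(meta, cfg$start_year))
}

phylum_pool <- c("Actinobacteria", "Bacteroidetes", "Cyanobacteria",
                 "Alphaproteobacteria", "Betaproteobacteria",
                 "Verrucomicrobia", "Chloroflexi", "Gammaproteobacteria",
                 "Planctomycetes")

# Seasonal multiplier with a taxon-specific preferred calendar month.
seasonal_factor <- function(cal, phase, amp) exp(amp * cos(2 * pi * (cal - phase) / 12))

# Expected community compositions (features x samples) for the prokaryotes,
# plus the bloomer bookkeeping. Mixing months get the layer-averaged
# composition (vertical convergence).
sim_asv_expected <- function(cfg, meta) {
  tt <- sim_temperatures(cfg)
  ids <- sprintf("ASV_%04d", seq_len(cfg$n_asv))
  par <- with_seed(derive_seed(cfg$seed, "asv_params"), {
    w <- exp(stats::rnorm(cfg$n_asv, 0, cfg$asv_weight_sdlog))
    grp <- sample(c("shared", "surface", "deep"), cfg$n_asv, TRUE,
                  prob = c(0.4, 0.3, 0.3))
    phase <- stats::runif(cfg$n_asv, 0.5, 12.5)
    bloomers <- sample(ids, cfg$n_bloomers)
    deep_ids <- ids[grp == "deep"]
    persistent <- deep_ids[order(-w[match(deep_ids, ids)])]
    persistent <- persistent[seq_len(min(cfg$n_persistent_deep, length(persistent)))]
    phyla <- sample(phylum_pool, cfg$n_asv, TRUE)
    phyla[match(bloomers, ids)] <- rep(phylum_pool[1:6],
                                       length.out = cfg$n_bloomers)
    list(w = w, grp = grp, phase = phase, bloomers = bloomers,
         persistent = persistent, phyla = phyla)
  })
  bloom <- with_seed(derive_seed(cfg$seed, "bloom"), {
    centers <- rep(c(10, 11, 12), length.out = cfg$n_bloomers) +
      stats::runif(cfg$n_bloomers, -cfg$bloom_center_jitter, cfg$bloom_center_jitter)
    widths <- stats::runif(cfg$n_bloomers, cfg$bloom_width[1], cfg$bloom_width[2])
    # heavy-tailed year-round baseline, capped below the bloom peak so the
    # series maximum stays inside the bloom window
    base <- matrix(pmin(exp(stats::rnorm(cfg$n_bloomers * cfg$n_months,
                                         log(cfg$bloom_base_relab),
                                         cfg$bloom_base_sdlog)),
                        cfg$bloom_base_cap * cfg$bloom_peak_relab),
                   cfg$n_bloomers, cfg$n_months)
    peak_noise <- matrix(exp(stats::rnorm(cfg$n_bloomers * cfg$n_months, 0,
                                          cfg$bloom_peak_noise_sd)),
                         cfg$n_bloomers, cfg$n_months)
    list(centers = centers, widths = widths, base = base, peak_noise = peak_noise)
  })
  noise <- with_seed(derive_seed(cfg$seed, "asv_noise"), {
    sd_i <- rep(cfg$asv_month_noise_sd, cfg$n_asv)
    sd_i[match(par$persistent, ids)] <- 0.2
    list(surface = matrix(exp(stats::rnorm(cfg$n_asv * cfg$n_months, 0,
                                           sd_i)), cfg$n_asv, cfg$n_months),
         deep = matrix(exp(stats::rnorm(cfg$n_asv * cfg$n_months, 0,
                                        sd_i)), cfg$n_asv, cfg$n_months))
  })
  is_bloom <- ids %in% par$bloomers
  bloom_row <- match(ids, par$bloomers)

  comp <- list()
  for (layer in c("surface", "deep")) {
    amp <- if (layer == "surface") cfg$asv_seasonal_amp else cfg$deep_seasonal_amp
    laymat <- matrix(0, cfg$n_asv, cfg$n_months,
                     dimnames = list(ids, NULL))
    for (m in seq_len(cfg$n_months)) {
      cal <- tt$calendar_month[m]
      fac <- ifelse(par$grp == "shared", 1,
                    ifelse(par$grp == layer, 1, cfg$offlayer_factor))
      mass <- par$w * fac * seasonal_factor(cal, par$phase, amp) *
        (if (layer == "surface") noise$surface[, m] else noise$deep[, m])
      mass[is_bloom] <- 0
      other <- mass / sum(mass)
      # planted bloomers: explicit relative-abundance trajectories
      tgt <- numeric(cfg$n_asv)
      for (b in which(is_bloom)) {
        i <- bloom_row[b]
        env <- cfg$bloom_peak_relab *
          exp(-0.5 * ((m - 1 - bloom$centers[i]) / bloom$widths[i])^2)
        env <- if (env < 5e-4) 0 else env
        tgt[b] <- if (layer == "surface")
          bloom$base[i, m] + env * bloom$peak_noise[i, m]
        else 0
      }
      laymat[, m] <- other * (1 - sum(tgt))
      laymat[is_bloom, m] <- tgt[is_bloom]
    }
    comp[[layer]] <- laymat
  }
  comp <- apply_vertical_mixing(comp, tt$mix_frac)
  list(comp = comp, params = par, bloom = bloom, ids = ids)
}

# Convergence of the two layers' compositions toward their average,
# proportional to the month's vertical-exchange strength.
apply_vertical_mixing <- function(comp, mix_frac) {
  for (m in seq_along(mix_frac)) {
    avg <- (comp$surface[, m] + comp$deep[, m]) / 2
    comp$surface[, m] <- (1 - mix_frac[m]) * comp$surface[, m] + mix_frac[m] * avg
    comp$deep[, m] <- (1 - mix_frac[m]) * comp$deep[, m] + mix_frac[m] * avg
  }
  comp
}

# Expected viral compositions. Planted phages follow their host's expected
# relative abundance in the same layer (optionally lagged), times lognormal
# tracking noise; the rest of the virome has its own layer affinity and
# seasonal phase. Under `couple = FALSE` the planted contigs are rebuilt
# with the independent construction (null data).
sim_lbv_expected <- function(cfg, asv, couple = TRUE) {
  tt <- sim_temperatures(cfg)
  ids <- sprintf("LBV_%05d", seq_len(cfg$n_lbv))
  n_pair <- cfg$n_bloomers * cfg$phages_per_bloomer
  par <- with_seed(derive_seed(cfg$seed, "lbv_params"), {
    lengths <- as.integer(round(stats::runif(cfg$n_lbv, cfg$lbv_length_range[1],
                                             cfg$lbv_length_range[2])))
    w <- exp(stats::rnorm(cfg$n_lbv, 0, cfg$lbv_weight_sdlog))
    aff <- stats::rbeta(cfg$n_lbv, cfg$lbv_affinity_shape, cfg$lbv_affinity_shape)
    phase <- stats::runif(cfg$n_lbv, 0.5, 12.5)
    paired <- sample(ids, n_pair)
    owner <- rep(asv$params$bloomers, each = cfg$phages_per_bloomer)
    track <- array(exp(stats::rnorm(n_pair * cfg$n_months * 2, 0,
                                    cfg$virus_tracking_noise_sd)),
                   dim = c(n_pair, cfg$n_months, 2))
    list(lengths = stats::setNames(lengths, ids), w = w, aff = aff,
         phase = phase, paired = paired, owner = owner, track = track)
  })
  noise <- with_seed(derive_seed(cfg$seed, "lbv_noise"), {
    list(surface = matrix(exp(stats::rnorm(cfg$n_lbv * cfg$n_months, 0,
                                           cfg$lbv_month_noise_sd)),
                          cfg$n_lbv, cfg$n_months),
         deep = matrix(exp(stats::rnorm(cfg$n_lbv * cfg$n_months, 0,
                                        cfg$lbv_month_noise_sd)),
                       cfg$n_lbv, cfg$n_months))
  })
  is_pair <- couple & ids %in% par$paired
  pair_row <- match(ids, par$paired)
  comp <- list()
  for (layer in c("surface", "deep")) {
    li <- if (layer == "surface") 1L else 2L
    amp_l <- if (layer == "surface") cfg$lbv_seasonal_amp else 0.3 * cfg$lbv_seasonal_amp
    affl <- if (layer == "surface") par$aff else 1 - par$aff
    laymat <- matrix(0, cfg$n_lbv, cfg$n_months, dimnames = list(ids, NULL))
    for (m in seq_len(cfg$n_months)) {
      cal <- tt$calendar_month[m]
      mass <- par$w * (0.02 + affl) * seasonal_factor(cal, par$phase, amp_l) *
        (if (layer == "surface") noise$surface[, m] else noise$deep[, m])
      mass[is_pair] <- 0
      other <- mass / sum(mass)
      tgt <- numeric(cfg$n_lbv)
      if (any(is_pair)) {
        m_host <- max(1L, m - cfg$tracking_lag)
        for (v in which(is_pair)) {
          i <- pair_row[v]
          host_frac <- asv$comp[[layer]][par$owner[i], m_host]
          tgt[v] <- cfg$phage_host_ratio * host_frac * par$track[i, m, li]
        }
      }
      laymat[, m] <- other * (1 - sum(tgt))
      laymat[is_pair, m] <- tgt[is_pair]
    }
    comp[[layer]] <- laymat
  }
  comp <- apply_vertical_mixing(comp, tt$mix_frac)
  list(comp = comp, params = par, ids = ids)
}

# Multinomial read sampling of an expected composition, one column per
# sample, library sizes Poisson around the configured mean.
sample_counts <- function(comp_list, meta, lib_mean, stream_seed,
                          read_weight = NULL) {
  ids <- rownames(comp_list$surface)
  counts <- matrix(0L, length(ids), nrow(meta),
                   dimnames = list(ids, meta$sample_id))
  with_seed(stream_seed, {
    for (r in seq_len(nrow(meta))) {
      m <- meta$month_index[r] + 1L
      p <- comp_list[[meta$layer[r]]][, m]
      if (!is.null(read_weight)) p <- p * read_weight
      if (sum(p) == 0) next
      lib <- max(1000L, stats::rpois(1L, lib_mean))
      counts[, r] <- stats::rmultinom(1L, lib, p / sum(p))[, 1L]
    }
  })
  counts
}

sim_evidence <- function(cfg, lbv, taxonomy) {
  paired <- lbv$params$paired
  owner_phy <- taxonomy$phylum[match(lbv$params$owner, taxonomy$feature_id)]
  with_seed(derive_seed(cfg$seed, "evidence"), {
    rows <- list()
    add <- function(lbv_id, method, taxon, sg = NA, idp = NA, aln = NA,
                    ev = NA, gf = NA, marker = NA) {
      rows[[length(rows) + 1L]] <<- data.frame(
        lbv_id = lbv_id, method = method, taxon = taxon,
        sg_score = sg, identity_pct = idp, aln_len_bp = as.integer(aln),
        evalue = ev, gene_fraction = gf, marker = marker)
    }
    cycle <- c("i", "ii", "iii", "iv", "vi")
    for (k in seq_along(paired)) {
      method <- cycle[(k - 1L) %% length(cycle) + 1L]
      tax <- owner_phy[k]
      if (method == "ii" && !tax %in% marker_taxa) method <- "iii"
      switch(method,
        i = add(paired[k], "i", tax, sg = stats::runif(1, 0.2, 0.9)),
        ii = add(paired[k], "ii", tax,
                 marker = names(marker_taxa)[match(tax, marker_taxa)]),
        iii = add(paired[k], "iii", tax, idp = 100,
                  aln = stats::runif(1, 30, 45), ev = 1e-10),
        iv = add(paired[k], "iv", tax, idp = stats::runif(1, 97.5, 100),
                 aln = stats::runif(1, 30, 60), ev = 1e-8),
        vi = add(paired[k], "vi", tax, gf = stats::runif(1, 0.85, 0.99)))
    }
    nonpaired <- setdiff(lbv$ids, paired)
    n_host <- round(cfg$host_assigned_fraction * length(nonpaired))
    decoy_hosts <- sample(nonpaired, n_host)
    for (d in decoy_hosts) {
      method <- sample(c("i", "iii", "iv", "vi"), 1L)
      tax <- sample(phylum_pool, 1L)
      switch(method,
        i = add(d, "i", tax, sg = stats::runif(1, 0.2, 0.9)),
        iii = add(d, "iii", tax, idp = 100, aln = stats::runif(1, 30, 45),
                  ev = 1e-10),
        iv = add(d, "iv", tax, idp = stats::runif(1, 97.5, 100),
                 aln = stats::runif(1, 30, 60), ev = 1e-8),
        vi = add(d, "vi", tax, gf = stats::runif(1, 0.85, 0.99)))
    }
    # sub-threshold noise lines that validation must reject
    n_bad <- stats::rpois(1L, cfg$decoy_evidence_rate * cfg$n_lbv)
    if (n_bad > 0) for (d in sample(lbv$ids, n_bad, replace = TRUE)) {
      method <- sample(c("i", "iv", "vi"), 1L)
      tax <- sample(phylum_pool, 1L)
      switch(method,
        i = add(d, "i", tax, sg = stats::runif(1, 0.01, 0.15)),
        iv = add(d, "iv", tax, idp = stats::runif(1, 80, 96),
                 aln = stats::runif(1, 30, 60), ev = 1e-8),
        vi = add(d, "vi", tax, gf = stats::runif(1, 0.3, 0.8)))
    }
    ev <- do.call(rbind, rows)
    rownames(ev) <- NULL
    ev
  })
}

sim_production <- function(cfg) {
  tt <- sim_temperatures(cfg)
  sub <- tt[tt$month_index %in% cfg$production_months, ]
  with_seed(derive_seed(cfg$seed, "production"), {
    rows <- list()
    for (r in seq_len(nrow(sub))) for (layer in c("surface", "deep")) {
      temp <- if (layer == "surface") sub$temp_surface[r] else sub$temp_deep[r]
      expected <- cfg$production_base[[layer]] *
        exp(cfg$production_temp_coef * (temp - cfg$temp_deep_base))
      reps <- expected * exp(stats::rnorm(cfg$production_replicates, 0,
                                          cfg$production_rep_sd))
      rows[[length(rows) + 1L]] <- data.frame(
        month_index = sub$month_index[r], layer = layer,
        replicate = seq_along(reps),
        production_cells_L_d = reps,
        incorporation_pmol_L_d = reps / cfg$conversion_factor,
        expected_cells_L_d = expected)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Generate a synthetic lake data set
#'
#' See [sim_config()] for the structure being emulated. Returns every table
#' the pipeline consumes plus the planted ground truth.
#'
#' @param cfg a [sim_config()].
#' @param couple plant virus-host coupling (`FALSE` gives the null data set).
#' @return list of class `lake_sim`: `meta`, `asv_counts`, `taxonomy`,
#'   `lbv_counts` (lengths attached), `coverage`, `evidence`, `production`,
#'   `truth`, `config`.
#' @export
simulate_lake <- function(cfg = sim_config(), couple = TRUE) {
  stopifnot(inherits(cfg, "sim_config"))
  meta <- sim_metadata(cfg)
  asv <- sim_asv_expected(cfg, meta)
  lbv <- sim_lbv_expected(cfg, asv, couple = couple)

  asv_counts <- feature_table(
    sample_counts(asv$comp, meta, cfg$library_size_mean,
                  derive_seed(cfg$seed, "asv_counts")),
    "counts")
  lbv_counts <- feature_table(
    sample_counts(lbv$comp, meta, cfg$library_size_mean_lbv,
                  derive_seed(cfg$seed, "lbv_counts"),
                  read_weight = lbv$params$lengths[lbv$ids]),
    "counts", lengths_bp = lbv$params$lengths)

  coverage <- with_seed(derive_seed(cfg$seed, "coverage"), {
    cc <- lbv_counts$values
    cv <- cc / (cc + cfg$coverage_halfsat) *
      exp(matrix(stats::rnorm(length(cc), 0, cfg$coverage_noise_sd),
                 nrow(cc), ncol(cc)))
    pmin(pmax(cv, 0), 1)
  })
  dimnames(coverage) <- dimnames(lbv_counts$values)

  taxonomy <- data.frame(feature_id = asv$ids, phylum = asv$params$phyla,
                         class = NA_character_)
  evidence <- sim_evidence(cfg, lbv, taxonomy)
  production <- sim_production(cfg)

  truth <- list(
    true_pairs = if (couple)
      data.frame(asv_id = lbv$params$owner, lbv_id = lbv$params$paired)
    else data.frame(asv_id = character(), lbv_id = character()),
    true_hosts = stats::setNames(
      taxonomy$phylum[match(lbv$params$owner, taxonomy$feature_id)],
      lbv$params$paired),
    bloomer_ids = asv$params$bloomers,
    season_labels = classify_seasons(meta),
    planted_production = unique(production[, c("month_index", "layer",
                                               "expected_cells_L_d")]),
    production_fold_band = cfg$production_fold_band,
    asv_expected = asv$comp,
    lbv_expected = lbv$comp)

  structure(list(meta = meta, asv_counts = asv_counts, taxonomy = taxonomy,
                 lbv_counts = lbv_counts, coverage = coverage,
                 evidence = evidence, production = production,
                 truth = truth, config = cfg),
            class = "lake_sim")
}

#' Null data set: identical marginal structure, no virus-host coupling
#' @param cfg a [sim_config()].
#' @return a `lake_sim` whose `truth$true_pairs` is empty.
#' @export
null_lake <- function(cfg = sim_config()) simulate_lake(cfg, couple = FALSE)

#' @export
print.lake_sim <- function(x, ...) {
  cat(sprintf(paste0(
    "synthetic lake: %d months x 2 layers, %d ASVs (%d bloomers), ",
    "%d viral contigs (%d planted pairs)\n"),
    x$config$n_months, x$config$n_asv, x$config$n_bloomers,
    x$config$n_lbv, nrow(x$truth$true_pairs)))
  invisible(x)
}

#' Write every simulated table to a directory (TSV + ground-truth JSON)
#' @param sim a `lake_sim`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_lake_sim <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_metadata(sim$meta, file.path(dir, "metadata.tsv"))
  write_feature_table(sim$asv_counts, file.path(dir, "asv_counts.tsv"))
  write_feature_table(sim$lbv_counts, file.path(dir, "lbv_counts.tsv"))
  utils::write.table(
    data.frame(feature_id = names(sim$lbv_counts$lengths_bp),
               length_bp = sim$lbv_counts$lengths_bp),
    file.path(dir, "lbv_lengths.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  cov <- feature_table(sim$coverage, "counts")
  write_feature_table(cov, file.path(dir, "lbv_coverage.tsv"))
  write_evidence(sim$evidence, file.path(dir, "host_evidence.tsv"))
  utils::write.table(sim$taxonomy, file.path(dir, "asv_taxonomy.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$production, file.path(dir, "production.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(true_pairs = sim$truth$true_pairs,
         true_hosts = as.list(sim$truth$true_hosts),
         bloomer_ids = sim$truth$bloomer_ids),
    file.path(dir, "ground_truth.json"))
  invisible(dir)
}
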