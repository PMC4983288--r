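#' Configuration for the synthetic study generator
#'
#' Bundles every knob of the synthetic data generator. The defaults
#' emulate the study conditions the pipeline is designed for: a panel
#' of 131 accessions genotyped as 10-plant bulks on a ~3000-marker
#' SNP array laid out on 21 linkage groups, with a two-level
#' population structure (2 groups split into 8 subgroups) whose
#' drift levels match the AMOVA signature of a structured European
#' cereal collection, affine signal distortion plus Gaussian noise on
#' the intensity ratios, and a Gamma total-intensity distribution
#' calibrated so about 1% of cells violate the [0.25, 2.5] bounds.
#'
#' @param n_accessions number of accessions (bulks).
#' @param plants_per_bulk plants pooled per accession; allele
#'   frequencies live on the 1/(2*plants_per_bulk) grid.
#' @param n_markers number of SNP markers.
#' @param linkage_groups character vector of linkage group names.
#' @param lg_lengths_cM numeric map length per linkage group.
#' @param unmapped_frac fraction of markers without a map position.
#' @param n_groups,subgroups_per_group two-level structure tree.
#' @param fst_group,fst_subgroup,fst_accession Balding-Nichols drift at
#'   the group, subgroup and accession level, each in [0, 1). The
#'   defaults are calibrated so a two-level AMOVA on the generated
#'   panel partitions the molecular variance roughly 22% between
#'   groups, 18% among subgroups and 60% within subgroups -- the
#'   signature of a structured European cereal collection in which
#'   accessions (landraces, old varieties) carry substantial
#'   individual drift.
#' @param freq_range range of ancestral allele frequencies (uniform).
#' @param signal_bias_a,signal_gain_b,signal_sd affine distortion and
#'   Gaussian noise of the observed ratio:
#'   `clip(a + b * freq + N(0, sd), 0, 1)`.
#' @param r_shape,r_mean Gamma shape and mean of the total intensity
#'   R; the defaults put ~1% of draws outside [0.25, 2.5].
#' @param ld_scale_cM if non-NULL, exponential LD scale: allele
#'   frequencies of markers on a linkage group are coupled through a
#'   latent Gaussian AR(1) with correlation `exp(-d / ld_scale_cM)`
#'   at map distance d. NULL = independent markers.
#' @param qtl data.frame with columns `marker` (id, or NA to sample
#'   one at random among mapped markers) and `var_explained`
#'   (fraction of liability variance); NULL = no QTL.
#' @param h2_polygenic polygenic fraction of liability variance.
#' @param liability_scale slope from the standardized liability to the
#'   logit of the tolerance probability; 2 spreads probabilities
#'   toward the extremes, giving the bimodal Fv/Fm pattern seen in
#'   freezing assays.
#' @param logit_intercept intercept of the tolerance logit.
#' @param n_experiments,plants_per_experiment freezing-assay design;
#'   the defaults (5 experiments x 6 plants) measure 30 plants per
#'   accession in total.
#' @param n_optimal_experiments experiments run under optimal
#'   hardening (the rest are sub-optimal).
#' @param experiment_sd SD of the experiment effects (logit scale).
#' @param fvfm_beta_tol,fvfm_beta_sus Beta parameters of the Fv/Fm
#'   mixture components (scaled by `fvfm_max`) for tolerant and
#'   susceptible plants.
#' @param fvfm_max physiological maximum of Fv/Fm (0.77).
#' @param n_environments,env_sd,trait_sd field-trial design for the
#'   quantitative traits (environments, environment-effect SD,
#'   residual SD).
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_accessions = 131,
                       plants_per_bulk = 10,
                       n_markers = 3000,
                       linkage_groups = sprintf("Mrg%02d", 1:21),
                       lg_lengths_cM = rep(135, 21),
                       unmapped_frac = 0.2,
                       n_groups = 2,
                       subgroups_per_group = 4,
                       fst_group = 0.11,
                       fst_subgroup = 0.103,
                       fst_accession = 0.341,
                       freq_range = c(0.05, 0.95),
                       signal_bias_a = 0.02,
                       signal_gain_b = 0.96,
                       signal_sd = 0.03,
                       r_shape = 9,
                       r_mean = 1.3,
                       ld_scale_cM = NULL,
                       qtl = NULL,
                       h2_polygenic = 0.5,
                       liability_scale = 2,
                       logit_intercept = 0,
                       n_experiments = 5,
                       plants_per_experiment = 6,
                       n_optimal_experiments = 3,
                       experiment_sd = 0.5,
                       fvfm_beta_tol = c(8, 1.5),
                       fvfm_beta_sus = c(1.2, 6),
                       fvfm_max = 0.77,
                       n_environments = 2,
                       env_sd = 1,
                       trait_sd = 1) {
  stopifnot(plants_per_bulk >= 1,
            fst_group >= 0, fst_group < 1,
            fst_subgroup >= 0, fst_subgroup < 1,
            fst_accession >= 0, fst_accession < 1,
            length(linkage_groups) == length(lg_lengths_cM),
            unmapped_frac >= 0, unmapped_frac < 1)
  if (!is.null(qtl)) {
    qtl <- as.data.frame(qtl, stringsAsFactors = FALSE)
    stopifnot(all(c("marker", "var_explained") %in% names(qtl)))
    if (sum(qtl$var_explained) + h2_polygenic >= 1)
      stop("QTL variance fractions plus h2_polygenic must sum below 1")
  } else if (h2_polygenic >= 1) stop("h2_polygenic must be below 1")
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

## Balding-Nichols drift: child frequency ~ Beta around parent p with F
.bn_drift <- function(p, fst) {
  if (fst == 0) return(p)
  a <- p * (1 - fst) / fst
  b <- (1 - p) * (1 - fst) / fst
  stats::rbeta(length(p), a, b)
}

#' Simulate structured pooled-sample array signals with known truth
#'
#' Generates a two-channel signal matrix, a genetic map and the full
#' ground truth. Ancestral allele frequencies are uniform on
#' `freq_range`; group and then subgroup frequencies drift by a
#' hierarchical Balding-Nichols (Beta) model with the configured
#' per-level F_ST. Each accession is a bulk of `plants_per_bulk`
#' diploid plants, so its true allele frequency is a binomial draw on
#' the `1/(2*plants_per_bulk)` grid. The observed ratio applies an
#' affine distortion plus Gaussian noise, clipped to [0, 1]; the total
#' intensity R is Gamma, and X = R * ratio, Y = R * (1 - ratio).
#' Optionally, allele frequencies along a linkage group are coupled
#' through a latent Gaussian AR(1) so LD decays exponentially with
#' map distance.
#'
#' @param config a [sim_config()].
#' @param seed RNG seed; the generator never touches global RNG state.
#' @return list with `signals` ([signal_matrix()]), `map` (data.frame
#'   `marker`, `linkage_group`, `position_cM`), and `truth` (class
#'   `sim_truth`: group/subgroup labels, true bulk frequencies,
#'   accession-level frequencies, the config).
#' @export
simulate_genotypes <- function(config = sim_config(), seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(seed, {
    cf <- config
    n <- cf$n_accessions; m <- cf$n_markers
    acc <- sprintf("ACC%04d", seq_len(n))
    mrk <- sprintf("SNP%05d", seq_len(m))
    ## structure tree: balanced assignment of accessions
    n_sub <- cf$n_groups * cf$subgroups_per_group
    sub_id <- rep(seq_len(n_sub), length.out = n)
    sub_id <- sort(sub_id)
    grp_of_sub <- rep(seq_len(cf$n_groups), each = cf$subgroups_per_group)
    groups <- stats::setNames(paste0("G", grp_of_sub[sub_id]), acc)
    subgroups <- stats::setNames(paste0("S", sub_id), acc)
    ## map: markers on linkage groups proportional to length
    lg_idx <- sample(seq_along(cf$linkage_groups), m, replace = TRUE,
                     prob = cf$lg_lengths_cM)
    pos <- stats::runif(m, 0, cf$lg_lengths_cM[lg_idx])
    lg <- cf$linkage_groups[lg_idx]
    if (cf$unmapped_frac > 0) {
      un <- sample(m, round(cf$unmapped_frac * m))
      lg[un] <- NA_character_; pos[un] <- NA_real_
    }
    map <- data.frame(marker = mrk, linkage_group = lg,
                      position_cM = pos, stringsAsFactors = FALSE)
    ## hierarchical frequencies
    p0 <- stats::runif(m, cf$freq_range[1], cf$freq_range[2])
    p_grp <- vapply(seq_len(cf$n_groups), function(g) .bn_drift(p0, cf$fst_group),
                    numeric(m))
    p_sub <- vapply(seq_len(n_sub), function(s)
      .bn_drift(p_grp[, grp_of_sub[s]], cf$fst_subgroup), numeric(m))
    ## accession-level drift, then bulk sampling of 2*plants copies
    copies <- 2 * cf$plants_per_bulk
    P <- t(p_sub[, sub_id, drop = FALSE])     # n x m subpop frequency
    if (cf$fst_accession > 0) {
      f3 <- cf$fst_accession
      P <- matrix(stats::rbeta(n * m, P * (1 - f3) / f3,
                               (1 - P) * (1 - f3) / f3), n, m)
    }
    if (is.null(cf$ld_scale_cM)) {
      cnt <- matrix(stats::rbinom(n * m, copies, P), n, m)
    } else {
      ## latent Gaussian AR(1) along each linkage group; marginals stay
      ## binomial so frequencies remain on the 1/copies grid
      U <- matrix(stats::rnorm(n * m), n, m)
      ord <- order(map$linkage_group, map$position_cM, na.last = TRUE)
      for (ii in seq_along(ord)[-1]) {
        j <- ord[ii]; jp <- ord[ii - 1]
        if (is.na(map$linkage_group[j]) || is.na(map$linkage_group[jp]) ||
            map$linkage_group[j] != map$linkage_group[jp]) next
        rho <- exp(-(map$position_cM[j] - map$position_cM[jp]) /
                     cf$ld_scale_cM)
        U[, j] <- rho * U[, jp] + sqrt(1 - rho^2) * U[, j]
      }
      cnt <- matrix(stats::qbinom(stats::pnorm(U), copies, P), n, m)
    }
    freq <- cnt / copies
    ## signal model
    ratio <- cf$signal_bias_a + cf$signal_gain_b * freq
    if (cf$signal_sd > 0)
      ratio <- ratio + matrix(stats::rnorm(n * m, 0, cf$signal_sd), n, m)
    ratio <- pmin(pmax(ratio, 0), 1)
    R <- matrix(stats::rgamma(n * m, shape = cf$r_shape,
                              scale = cf$r_mean / cf$r_shape), n, m)
    X <- R * ratio; Y <- R * (1 - ratio)
    dimnames(X) <- dimnames(Y) <- list(acc, mrk)
    truth <- structure(list(groups = groups, subgroups = subgroups,
                            bulk_freq = `dimnames<-`(freq, list(acc, mrk)),
                            accession_freq = `dimnames<-`(
                              P, list(acc, mrk)),
                            map = map, config = cf),
                       class = "sim_truth")
    list(signals = signal_matrix(X, Y), map = map, truth = truth)
  })
}

#' Simulate phenotypes from a genotype ground truth
#'
#' Builds an accession liability as the sum of the configured QTL
#' effects on the true bulk allele frequencies, a polygenic term
#' (multivariate normal with covariance proportional to the true
#' frequency-based kinship), and residual noise, with the variance
#' fractions given in the config. The tolerance probability of an
#' accession in an experiment is the inverse logit of
#' `logit_intercept + liability_scale * liability + experiment
#' effect`; plant survival is Bernoulli, and each plant's Fv/Fm is
#' drawn from a two-component scaled-Beta mixture (tolerant high,
#' susceptible low) bounded by `fvfm_max`. Quantitative field traits
#' (hull percentage analogue `trait_q`) come from an additive
#' accession + environment model sharing the same liability.
#'
#' @param truth `sim_truth` from [simulate_genotypes()].
#' @param seed RNG seed.
#' @return list with `pheno` (long data.frame: `accession`, `trait`,
#'   `value`, `environment`, `plant`, `condition`) and `truth`
#'   augmented with `liability`, `tolerance_prob` (per accession, at
#'   the average experiment effect), `experiment_effects`, `qtl`
#'   (resolved marker ids and effects).
#' @export
simulate_phenotypes <- function(truth, seed = NULL) {
  stopifnot(inherits(truth, "sim_truth"))
  cf <- truth$config
  with_seed(seed, {
    F <- truth$bulk_freq
    n <- nrow(F)
    acc <- rownames(F)
    ## QTL part
    qtl_tab <- NULL
    g_qtl <- rep(0, n)
    v_qtl <- 0
    if (!is.null(cf$qtl) && nrow(cf$qtl)) {
      qtl_tab <- cf$qtl
      mapped <- truth$map$marker[!is.na(truth$map$position_cM)]
      for (i in seq_len(nrow(qtl_tab))) {
        if (is.na(qtl_tab$marker[i]))
          qtl_tab$marker[i] <- sample(mapped, 1)
      }
      qtl_tab$beta <- 0
      for (i in seq_len(nrow(qtl_tab))) {
        x <- F[, qtl_tab$marker[i]]
        s <- stats::sd(x)
        if (s == 0) stop("QTL marker is monomorphic in the bulk truth")
        qtl_tab$beta[i] <- sqrt(qtl_tab$var_explained[i]) / s
        g_qtl <- g_qtl + qtl_tab$beta[i] * (x - mean(x))
      }
      v_qtl <- sum(qtl_tab$var_explained)
    }
    ## polygenic part via the true frequency-based kinship
    g_poly <- rep(0, n)
    if (cf$h2_polygenic > 0) {
      Ktrue <- kinship_from_ratios(truth$bulk_freq)
      ev <- eigen(unclass(Ktrue), symmetric = TRUE)
      L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)))
      g_poly <- sqrt(cf$h2_polygenic) * drop(L %*% stats::rnorm(n))
    }
    e <- stats::rnorm(n, 0, sqrt(max(1 - v_qtl - cf$h2_polygenic, 0)))
    liability <- g_qtl + g_poly + e
    ## freezing assay
    exp_eff <- stats::rnorm(cf$n_experiments, 0, cf$experiment_sd)
    cond <- c(rep("optimal", cf$n_optimal_experiments),
              rep("sub-optimal", cf$n_experiments - cf$n_optimal_experiments))
    eta0 <- cf$logit_intercept + cf$liability_scale * liability
    tol_prob <- stats::plogis(eta0 + mean(exp_eff))
    rows <- vector("list", cf$n_experiments)
    for (k in seq_len(cf$n_experiments)) {
      pk <- stats::plogis(eta0 + exp_eff[k])
      np <- cf$plants_per_experiment
      state <- matrix(stats::rbinom(n * np, 1, rep(pk, np)), n, np)
      fv <- matrix(0, n, np)
      n_tol <- sum(state == 1)
      fv[state == 1] <- cf$fvfm_max *
        stats::rbeta(n_tol, cf$fvfm_beta_tol[1], cf$fvfm_beta_tol[2])
      fv[state == 0] <- cf$fvfm_max *
        stats::rbeta(n * np - n_tol, cf$fvfm_beta_sus[1], cf$fvfm_beta_sus[2])
      rows[[k]] <- data.frame(
        accession = rep(acc, np), trait = "fvfm",
        value = as.vector(fv),
        environment = sprintf("EXP%d", k),
        plant = rep(seq_len(np), each = n),
        condition = cond[k], stringsAsFactors = FALSE)
    }
    ## quantitative field trait from the same additive liability
    env_eff <- stats::rnorm(cf$n_environments, 0, cf$env_sd)
    qrows <- vector("list", cf$n_environments)
    for (k in seq_len(cf$n_environments)) {
      qrows[[k]] <- data.frame(
        accession = acc, trait = "trait_q",
        value = 10 * liability + env_eff[k] +
          stats::rnorm(n, 0, cf$trait_sd),
        environment = sprintf("ENV%d", k),
        plant = NA_integer_, condition = NA_character_,
        stringsAsFactors = FALSE)
    }
    pheno <- rbind(do.call(rbind, rows), do.call(rbind, qrows))
    truth$liability <- stats::setNames(liability, acc)
    truth$tolerance_prob <- stats::setNames(tol_prob, acc)
    truth$experiment_effects <- exp_eff
    truth$qtl <- qtl_tab
    list(pheno = pheno, truth = truth)
  })
}
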