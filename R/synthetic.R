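## Synthetic dossier generator. Emulates the statistical structure of public
## registration data -- structural modules of toxicants, guideline dose-grid
## pile-ups from limit-dose censoring, correlated 28d/90d NOAEL pairs with
## occasional large discrepancies, GHS hazard flags with data-lacking and
## inconclusive records -- so that every downstream stage of the pipeline is
## testable without any download. Fingerprints are abstract bit sets, not
## chemically realistic structures.

#' Configuration for the synthetic dossier generator
#'
#' All stochastic behaviour of the generator is controlled here; the same
#' `(seed, config)` pair always yields bit-identical datasets, and each
#' artifact (fingerprints, acute studies, repeated-dose studies, hazards)
#' draws from its own stream split off the master seed, so adding a stage
#' never perturbs earlier outputs.
#'
#' @param seed Master integer seed.
#' @param module_sizes Integer sizes of the structural modules; their sum is
#'   the dataset size. The default is nine modules totalling 1,059
#'   substances, the size of the canonical modelling dataset.
#' @param fingerprint_length Bits per fingerprint (>= 64).
#' @param core_density Probability that a module-core bit is on.
#' @param within_module_similarity Target expected Tanimoto similarity
#'   between members of one module, in (1/3, 1]; per-bit mutation of the
#'   module core is tuned to reach it. 1 means identical copies.
#' @param clustering_strength Probability that a substance's toxicity follows
#'   its module's latent state rather than an independent coin flip with the
#'   target prevalence.
#' @param target_prevalence Desired toxicant fraction (aggregated LD50 below
#'   2,000 mg/kg b.w.); default 268/1059.
#' @param p_snap Probability that an acute study value is censored/snapped to
#'   its guideline's dose grid, producing the characteristic pile-ups at
#'   2,000 and 5,000 mg/kg.
#' @param dose_grids Named list of per-guideline ordered dose grids (mg/kg).
#' @param studies_per_substance_probs Probabilities of 1, 2 or 3 acute
#'   studies per substance.
#' @param noael_correlation Correlation of 28-day and 90-day log10 NOAELs.
#' @param noael_shift_log10 Downward shift (log10) of the 90-day marginal
#'   relative to the 28-day one (the longer study tends to find lower
#'   no-effect levels).
#' @param noael_sd_log10 Marginal SD of log10 NOAELs.
#' @param discordant_fraction Fraction of pairs replaced by anomalous ones
#'   with 90-day NOAEL far above the 28-day NOAEL.
#' @param discordant_factor Multiplier applied in those anomalous pairs.
#' @param bulgheroni_npv Target negative predictive value of the
#'   "28-day NOAEL > 200" rule; the coupling between acute class and NOAEL
#'   is calibrated to it.
#' @param noael_gt200_nontox Probability that a non-toxicant's 28-day NOAEL
#'   exceeds 200 mg/kg (the free parameter of that calibration).
#' @param noael_limit_fraction Probability that a substance with an
#'   unremarkable 28-day result (NOAEL > 200) comes from clean limit-dose
#'   studies reporting a NOAEL of `>= 1,000` mg/kg in both durations -- the
#'   mechanism behind the pile-up of NOAELs at the limit dose and the bulk
#'   of the high-28d/high-90d concordance.
#' @param p_28d Probability a substance has a 28-day study.
#' @param p_90d_given_28d Probability a 28-day substance also has a 90-day
#'   study.
#' @param data_lacking_rate,inconclusive_rate Per-hazard probabilities that a
#'   flag is reported as `data_lacking` / `inconclusive` instead of its
#'   derived status.
#' @return A `generator_config` list.
#' @export
generator_config <- function(seed = 1L,
                             module_sizes = c(260L, 190L, 150L, 120L, 100L,
                                              80L, 70L, 50L, 39L),
                             fingerprint_length = 256L,
                             core_density = 0.3,
                             within_module_similarity = 0.9,
                             clustering_strength = 0.9,
                             target_prevalence = 268 / 1059,
                             p_snap = 0.5,
                             dose_grids = list(
                               TG401 = c(5, 50, 300, 2000, 5000),
                               TG420 = c(5, 50, 300, 2000),
                               TG423 = c(5, 50, 300, 2000, 5000),
                               TG425 = c(5, 50, 300, 2000, 5000)),
                             studies_per_substance_probs = c(0.6, 0.3, 0.1),
                             noael_correlation = 0.7,
                             noael_shift_log10 = 0.25,
                             noael_sd_log10 = 0.5,
                             discordant_fraction = 0.02,
                             discordant_factor = 5,
                             bulgheroni_npv = 0.945,
                             noael_gt200_nontox = 0.75,
                             noael_limit_fraction = 0.24,
                             p_28d = 0.8,
                             p_90d_given_28d = 0.7,
                             data_lacking_rate = 0.05,
                             inconclusive_rate = 0.005) {
  module_sizes <- as.integer(module_sizes)
  stopifnot(length(module_sizes) >= 1L, all(module_sizes >= 1L),
            fingerprint_length >= 64L,
            core_density > 0, core_density < 1,
            within_module_similarity > 0, within_module_similarity <= 1,
            clustering_strength >= 0, clustering_strength <= 1,
            target_prevalence > 0, target_prevalence < 1,
            p_snap >= 0, p_snap <= 1,
            noael_correlation >= 0, noael_correlation <= 1,
            discordant_fraction >= 0, discordant_fraction < 1,
            bulgheroni_npv > 0, bulgheroni_npv < 1,
            noael_limit_fraction >= 0, noael_limit_fraction < 1)
  structure(list(seed = as.integer(seed), module_sizes = module_sizes,
                 n_modules = length(module_sizes),
                 fingerprint_length = as.integer(fingerprint_length),
                 core_density = core_density,
                 within_module_similarity = within_module_similarity,
                 clustering_strength = clustering_strength,
                 target_prevalence = target_prevalence,
                 p_snap = p_snap, dose_grids = dose_grids,
                 studies_per_substance_probs = studies_per_substance_probs,
                 noael_correlation = noael_correlation,
                 noael_shift_log10 = noael_shift_log10,
                 noael_sd_log10 = noael_sd_log10,
                 discordant_fraction = discordant_fraction,
                 discordant_factor = discordant_factor,
                 bulgheroni_npv = bulgheroni_npv,
                 noael_gt200_nontox = noael_gt200_nontox,
                 noael_limit_fraction = noael_limit_fraction,
                 p_28d = p_28d, p_90d_given_28d = p_90d_given_28d,
                 data_lacking_rate = data_lacking_rate,
                 inconclusive_rate = inconclusive_rate),
            class = "generator_config")
}

## Expected within-module Tanimoto when members copy a core of density d and
## flip each bit independently with probability q.
expected_within_tanimoto <- function(q, d) {
  num <- d * (1 - q)^2 + (1 - d) * q^2
  den <- d * (1 - q^2) + (1 - d) * (2 * q - q^2)
  num / den
}

## Solve the per-bit mutation probability for a target expected similarity.
mutation_rate_for <- function(target, density) {
  if (target >= 1) return(0)
  floor_sim <- expected_within_tanimoto(0.5, density)   # fully random members
  if (target <= floor_sim)
    stop(sprintf(paste0("within_module_similarity %.3f is not achievable: ",
                        "the floor at full mutation is %.3f"),
                 target, floor_sim), call. = FALSE)
  stats::uniroot(function(q) expected_within_tanimoto(q, density) - target,
                 c(1e-9, 0.5 - 1e-9), tol = 1e-10)$root
}

## Inverse-CDF sampler for a truncated normal.
rtnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(runif(n, plo, phi), mean, sd)
}

#' Generate module-structured binary fingerprints
#'
#' Each module gets a random core bit pattern; members copy it with a
#' per-bit mutation rate tuned so the expected within-module Tanimoto
#' similarity equals `within_module_similarity`, while independent cores
#' keep the expected between-module similarity far below the 0.7 graph
#' threshold. Each module carries a latent toxicity state; the set of toxic
#' modules is chosen so that their total size best matches the target
#' prevalence, and each substance follows its module's state with
#' probability `clustering_strength` (otherwise an independent coin flip at
#' the target prevalence).
#'
#' @param cfg A [generator_config()].
#' @return List with `substances` (data frame: `substance_id`, `module`
#'   (0-based ground truth), `toxic` (latent logical)), and `fingerprints`
#'   (logical matrix, ids as rownames).
#' @export
generate_fingerprints <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  n <- sum(cfg$module_sizes)
  q <- mutation_rate_for(cfg$within_module_similarity, cfg$core_density)
  with_seed(derive_seed(cfg$seed, "fingerprints"), {
    ids <- sprintf("S%04d", seq_len(n))
    module <- rep(seq_along(cfg$module_sizes) - 1L, cfg$module_sizes)
    cores <- matrix(runif(cfg$n_modules * cfg$fingerprint_length) <
                      cfg$core_density,
                    nrow = cfg$n_modules)
    ## guarantee a non-empty core so Tanimoto stays defined
    for (m in seq_len(cfg$n_modules))
      if (!any(cores[m, ])) cores[m, 1L] <- TRUE
    fp <- cores[module + 1L, , drop = FALSE]
    if (q > 0) {
      flip <- matrix(runif(length(fp)) < q, nrow = nrow(fp))
      fp <- xor(fp, flip)
      empty <- rowSums(fp) == 0L
      fp[empty, 1L] <- TRUE
    }
    rownames(fp) <- ids

    ## toxic module set: greedy size match to the target prevalence
    target_n <- cfg$target_prevalence * n
    ord <- order(-cfg$module_sizes)
    chosen <- logical(cfg$n_modules); running <- 0
    for (m in ord) {
      if (abs(running + cfg$module_sizes[m] - target_n) <
          abs(running - target_n)) {
        chosen[m] <- TRUE
        running <- running + cfg$module_sizes[m]
      }
    }
    module_toxic <- chosen[module + 1L]
    follows <- runif(n) < cfg$clustering_strength
    coin <- runif(n) < cfg$target_prevalence
    toxic <- ifelse(follows, module_toxic, coin)
    list(substances = data.frame(substance_id = ids, module = module,
                                 toxic = toxic, stringsAsFactors = FALSE),
         fingerprints = fp)
  })
}

#' Generate acute oral toxicity studies
#'
#' Every substance gets 1--3 acute studies under a guideline drawn from the
#' empirical usage mix (TG 401 dominant). A latent log10-LD50 is drawn from
#' the substance's toxicity class (truncated on its side of 2,000 mg/kg so
#' the aggregated label matches the latent class); study-level values add
#' lognormal noise and, with probability `p_snap`, are censored to the
#' guideline's dose grid -- non-toxicants to the largest grid dose at or
#' below their value with a `greater_equal` qualifier (the limit-dose
#' convention that piles values up at 2,000 and 5,000), toxicants to the
#' nearest sub-2,000 grid dose. Each substance receives at least one
#' Klimisch-1 key study.
#'
#' @param substances Data frame from [generate_fingerprints()].
#' @param cfg A [generator_config()].
#' @return A validated `study_table` of acute studies.
#' @export
generate_acute_studies <- function(substances, cfg) {
  stopifnot(inherits(cfg, "generator_config"),
            all(c("substance_id", "toxic") %in% names(substances)))
  n <- nrow(substances)
  lt <- log10(2000)
  gl_mix <- c(TG401 = 0.75, TG420 = 0.11, TG423 = 0.11, TG425 = 0.015,
              other = 0.015)
  with_seed(derive_seed(cfg$seed, "acute"), {
    ## toxicants sit mostly near the threshold (borderline substances are
    ## the common case), non-toxicants well above it
    latent <- ifelse(substances$toxic,
                     rtnorm(n, log10(800), 0.45, upper = lt - 1e-6),
                     rtnorm(n, log10(4500), 0.35, lower = lt))
    n_st <- sample.int(3L, n, replace = TRUE,
                       prob = cfg$studies_per_substance_probs)
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      k <- n_st[i]
      gl <- sample(names(gl_mix), k, replace = TRUE, prob = gl_mix)
      val <- 10^(latent[i] + rnorm(k, 0, 0.1))
      ## keep every study on the latent class's side of the threshold so the
      ## aggregated label is the latent label
      val <- if (substances$toxic[i]) pmin(val, 1999) else pmax(val, 2000)
      qual <- rep("exact", k)
      snap <- runif(k) < cfg$p_snap
      for (j in which(snap)) {
        grid <- cfg$dose_grids[[gl[j]]]
        if (is.null(grid)) next
        if (!substances$toxic[i]) {
          cand <- grid[grid >= 2000 & grid <= val[j]]
          if (!length(cand)) cand <- min(grid[grid >= 2000])
          val[j] <- max(cand); qual[j] <- "greater_equal"
        } else {
          cand <- grid[grid < 2000]
          val[j] <- cand[which.min(abs(log(cand) - log(val[j])))]
        }
      }
      klim <- c(1L, sample.int(4L, k - 1L, replace = TRUE,
                               prob = c(0.4, 0.3, 0.2, 0.1)))
      rows[[i]] <- data.frame(
        substance_id = substances$substance_id[i],
        endpoint = "acute_oral", guideline = gl,
        klimisch = klim,
        key_study = c(TRUE, rep(FALSE, k - 1L)),
        read_across = c(FALSE, runif(k - 1L) < 0.15),
        value = val, qualifier = qual, stringsAsFactors = FALSE)
    }
    as_study_table(do.call(rbind, rows))
  })
}

#' Generate paired 28-day / 90-day repeated-dose studies
#'
#' A subset of substances receives a 28-day (TG 407) study and, of those, a
#' further subset a matched 90-day (TG 408) study. The 28-day NOAEL is
#' coupled to the substance's acute class: the probability that it exceeds
#' 200 mg/kg is `noael_gt200_nontox` for non-toxicants, and for toxicants is
#' solved so that the "NOAEL > 200 implies LD50 >= 2,000" rule attains the
#' configured negative predictive value at the configured prevalence. The
#' 90-day log10-NOAEL follows the 28-day one with correlation
#' `noael_correlation` and a downward marginal shift; a configurable
#' fraction of pairs is replaced by anomalous ones (90-day far above
#' 28-day), emulating the discrepancies that motivate study flagging.
#'
#' @inheritParams generate_acute_studies
#' @return A validated `study_table` of repeated-dose studies.
#' @export
generate_repeated_dose_studies <- function(substances, cfg) {
  stopifnot(inherits(cfg, "generator_config"),
            all(c("substance_id", "toxic") %in% names(substances)))
  n <- nrow(substances)
  p <- cfg$target_prevalence
  a <- cfg$noael_gt200_nontox
  nu <- cfg$bulgheroni_npv
  ## P(NOAEL > 200 | toxicant) from NPV = (1-p)a / ((1-p)a + p b)
  b <- (1 - p) * a * (1 - nu) / (nu * p)
  if (b >= 1)
    stop("bulgheroni_npv target is infeasible at this prevalence",
         call. = FALSE)
  l200 <- log10(200)
  mu28 <- log10(300); s <- cfg$noael_sd_log10
  rho <- cfg$noael_correlation
  with_seed(derive_seed(cfg$seed, "repeated"), {
    has28 <- runif(n) < cfg$p_28d
    has90 <- has28 & runif(n) < cfg$p_90d_given_28d
    gt200 <- ifelse(substances$toxic, runif(n) < b, runif(n) < a)
    ## clean limit-dose pairs: both studies run to 1,000 mg/kg with no
    ## effect, reported as ">= 1,000" in both durations
    limit <- gt200 & runif(n) < cfg$noael_limit_fraction
    log28 <- ifelse(gt200,
                    rtnorm(n, mu28, s, lower = l200 + 1e-9),
                    rtnorm(n, mu28, s, upper = l200))
    log90 <- (mu28 - cfg$noael_shift_log10) + rho * (log28 - mu28) +
      sqrt(max(0, 1 - rho^2)) * s * rnorm(n)
    disc <- !limit & runif(n) < cfg$discordant_fraction
    log90[disc] <- log28[disc] + log10(cfg$discordant_factor)
    log28[limit] <- log10(1000)
    log90[limit] <- log10(1000)
    qual <- ifelse(limit, "greater_equal", "exact")
    klim <- function(m) sample.int(3L, m, replace = TRUE,
                                   prob = c(0.6, 0.25, 0.15))
    mk <- function(idx, ep, gl, logv) {
      m <- length(idx)
      data.frame(substance_id = substances$substance_id[idx],
                 endpoint = ep, guideline = gl, klimisch = klim(m),
                 key_study = TRUE, read_across = FALSE,
                 value = 10^logv, qualifier = qual[idx],
                 stringsAsFactors = FALSE)
    }
    out <- rbind(mk(which(has28), "repeated_28d", "TG407", log28[has28]),
                 mk(which(has90), "repeated_90d", "TG408", log90[has90]))
    as_study_table(out)
  })
}

#' Derive GHS hazard flags from aggregated acute toxicity
#'
#' Oral hazard flags follow the GHS acute-category bands of the aggregated
#' LD50 (H300 at or below 50, H301 in (50, 300], H302 in (300, 2,000], H303
#' in (2,000, 5,000] mg/kg). H303 (Category 5) is an optional
#' classification that regulators rarely apply, so it is only assigned to a
#' small random fraction of the substances in its band; the aspiration
#' hazards H304/H305 are sparse positives unrelated to the oral bands. Each
#' flag is independently replaced by `data_lacking` / `inconclusive` at the
#' configured rates.
#'
#' @param substances Data frame with `substance_id`.
#' @param agg_ld50 Named numeric vector of aggregated LD50 values (mg/kg),
#'   names = substance ids.
#' @param cfg A [generator_config()].
#' @return A validated hazard table (see [as_hazard_table()]).
#' @export
generate_hazard_flags <- function(substances, agg_ld50, cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  ids <- substances$substance_id
  v <- unname(agg_ld50[ids])
  with_seed(derive_seed(cfg$seed, "hazards"), {
    status <- function(pos) ifelse(pos, "positive", "negative")
    df <- data.frame(
      substance_id = ids,
      ## band boundaries are half-open downward: censored dose-grid values
      ## (e.g. a study snapped to the 300 mg/kg cut-off) are lower bounds,
      ## so a value at a grid point belongs to the band above it
      H300 = status(!is.na(v) & v < 50),
      H301 = status(!is.na(v) & v >= 50 & v < 300),
      H302 = status(!is.na(v) & v >= 300 & v < 2000),
      H303 = status(!is.na(v) & v >= 2000 & v <= 5000 &
                      runif(length(ids)) < 0.02),
      H304 = status(runif(length(ids)) < 0.07),
      H305 = status(runif(length(ids)) < 0.001),
      stringsAsFactors = FALSE)
    for (h in hazard_codes()) {
      u <- runif(length(ids))
      df[[h]][u < cfg$data_lacking_rate] <- "data_lacking"
      df[[h]][u >= cfg$data_lacking_rate &
                u < cfg$data_lacking_rate + cfg$inconclusive_rate] <-
        "inconclusive"
    }
    as_hazard_table(df)
  })
}

#' Generate synthetic molecular descriptors
#'
#' Produces the 27-column descriptor table consumed by the supervised
#' learners. Each descriptor is a linear blend of a toxicity signal (scaled
#' negative latent log-LD50), a module-specific structural effect and noise,
#' with per-descriptor informativeness and scale: polarizability- and
#' aromaticity-type descriptors carry most of the signal, count-type
#' descriptors are rounded non-negative, and scales span orders of magnitude
#' (so feature standardisation genuinely matters downstream).
#'
#' @param substances Data frame with `substance_id`, `module`, `toxic`.
#' @param agg_ld50 Named numeric vector of aggregated LD50 values.
#' @param cfg A [generator_config()].
#' @return Descriptor data frame: `substance_id` + 27 named columns.
#' @export
generate_descriptors <- function(substances, agg_ld50, cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  ids <- substances$substance_id
  n <- length(ids)
  signal <- -scale(log10(unname(agg_ld50[ids])))[, 1L]
  specs <- descriptor_specs()
  with_seed(derive_seed(cfg$seed, "descriptors"), {
    mod_eff <- matrix(rnorm(cfg$n_modules * nrow(specs), 0, 0.6),
                      nrow = cfg$n_modules)
    out <- data.frame(substance_id = ids, stringsAsFactors = FALSE)
    for (j in seq_len(nrow(specs))) {
      z <- specs$alpha[j] * signal +
        mod_eff[substances$module + 1L, j] +
        rnorm(n, 0, 1 - specs$alpha[j] / 2)
      v <- specs$mu[j] + specs$scale[j] * z
      if (specs$count[j]) v <- pmax(0, round(v))
      out[[specs$name[j]]] <- v
    }
    out
  })
}

#' Canonical descriptor names
#'
#' The 27 molecular descriptor names used by the modelling dataset (the
#' similarity feature `KNN` is separate and excluded here).
#'
#' @return Character vector of 27 names.
#' @export
descriptor_names <- function() descriptor_specs()$name

descriptor_specs <- function() {
  ## name, toxicity-signal weight, base level, scale, integer-count flag
  df <- rbind(
    c("TPSA",                 0.55,  60,   30, 0),
    c("AcidicGroupCount",     0.05,   1,    1, 1),
    c("Apol",                 0.45,  30,   12, 0),
    c("HBondAcceptorCount",   0.35,   4,    2, 1),
    c("RuleOfFive",           0.30,   1,    1, 1),
    c("EccentricConnectivity",0.30, 120,   60, 1),
    c("MannholdLogP",         0.30,   2,    1.5, 0),
    c("AromaticAtomsCount",   0.15,   6,    4, 1),
    c("Bpol",                 0.60,  14,    6, 0),
    c("ZagrebIndex",          0.30,  90,   40, 1),
    c("FractionalPSA",        0.10,   0.3,  0.12, 0),
    c("LargestPiSystem",      0.35,   7,    4, 1),
    c("XLogP",                0.30,   2.5,  1.8, 0),
    c("LargestChain",         0.30,   6,    3, 1),
    c("HybridizationRatio",   0.28,   0.6,  0.25, 0),
    c("AromaticBondsCount",   0.50,   6,    4, 1),
    c("RotatableBondsCount",  0.40,   5,    3, 1),
    c("AtomCount",            0.35,  40,   15, 1),
    c("FragmentComplexity",   0.35, 500,  300, 0),
    c("Weight",               0.35, 250,  100, 0),
    c("BondCount",            0.32,  42,   15, 1),
    c("VadjMaDescriptor",     0.32,   6,    1.5, 0),
    c("LongestAliphaticChain",0.30,   5,    3, 1),
    c("PetitjeanNumber",      0.26,   0.45, 0.12, 0),
    c("FMF",                  0.18,   0.5,  0.2, 0),
    c("HBondDonorCount",      0.14,   2,    1.3, 1),
    c("BasicGroupCount",      0.05,   1,    1, 1))
  data.frame(name = df[, 1L], alpha = as.numeric(df[, 2L]),
             mu = as.numeric(df[, 3L]), scale = as.numeric(df[, 4L]),
             count = as.numeric(df[, 5L]) == 1, stringsAsFactors = FALSE)
}

#' Generate a complete synthetic dossier dataset
#'
#' Runs all generator stages in order and returns everything the pipeline
#' ingests: substances with latent ground truth, fingerprints, acute and
#' repeated-dose study tables, aggregated LD50s, hazard flags and
#' descriptors.
#'
#' @param cfg A [generator_config()].
#' @return A `synthetic_dossier` list.
#' @export
generate_dossier <- function(cfg = generator_config()) {
  fps <- generate_fingerprints(cfg)
  acute <- generate_acute_studies(fps$substances, cfg)
  agg <- aggregate_endpoints(acute, endpoint = "acute_oral")
  agg_ld50 <- setNames(agg$mean_value, agg$substance_id)
  repeated <- generate_repeated_dose_studies(fps$substances, cfg)
  hazards <- generate_hazard_flags(fps$substances, agg_ld50, cfg)
  descriptors <- generate_descriptors(fps$substances, agg_ld50, cfg)
  structure(list(config = cfg, substances = fps$substances,
                 fingerprints = fps$fingerprints,
                 acute_studies = acute, repeated_studies = repeated,
                 agg_ld50 = agg_ld50, hazards = hazards,
                 descriptors = descriptors),
            class = "synthetic_dossier")
}

#' Write a synthetic dossier to the interchange files
#'
#' Emits `studies.csv` (acute + repeated rows), `fingerprints.fp`,
#' `descriptors.csv` and `hazards.csv` under `dir`.
#'
#' @param dossier A `synthetic_dossier` from [generate_dossier()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_dossier <- function(dossier, dir) {
  stopifnot(inherits(dossier, "synthetic_dossier"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- c(studies = file.path(dir, "studies.csv"),
         fingerprints = file.path(dir, "fingerprints.fp"),
         descriptors = file.path(dir, "descriptors.csv"),
         hazards = file.path(dir, "hazards.csv"))
  write_study_table(rbind(as.data.frame(dossier$acute_studies),
                          as.data.frame(dossier$repeated_studies)),
                    p[["studies"]])
  write_fingerprints(dossier$fingerprints, p[["fingerprints"]])
  write_descriptors(dossier$descriptors, p[["descriptors"]])
  write.table(dossier$hazards, p[["hazards"]], sep = ",", row.names = FALSE,
              quote = FALSE)
  invisible(p)
}
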