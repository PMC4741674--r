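#' Generative model for serum anti-glycan antibody signals
#'
#' Encodes the reverse-typing structure of serum antibody profiles: a
#' subject's serum carries antibodies against the ABO determinants absent
#' from their own cells (type O: anti-A and anti-B; A: anti-B; B: anti-A;
#' AB: neither), so signals to a foreign determinant sit an
#' `incompat_delta` above baseline, modulated by isotype and glycan
#' density. IgG separates blood types more strongly than IgM, and IgG
#' separation is larger on high-density glycans while IgM tends to do
#' relatively better on low-density presentations; the default multipliers
#' encode exactly that ordering.
#'
#' All quantities are on the log2 RFU scale.
#'
#' @param baseline_mu mean signal toward a self/compatible determinant
#'   (default 8).
#' @param incompat_delta log2 units added when the determinant is foreign
#'   to the subject's blood type (default 4).
#' @param sigma Gaussian noise SD (default 1).
#' @param isotype_scale named multipliers on `incompat_delta` per isotype.
#' @param density_effect named multipliers per `<isotype>.<density class>`
#'   combination; components with unknown density use 1.
#' @param crossreact_epsilon small positive bleed-through added toward a
#'   self determinant (default 0.3).
#' @param mislabel_rate probability that a recorded blood type differs from
#'   the true one (default 0).
#' @return a list of class `signal_model`.
#' @export
signal_model <- function(baseline_mu = 8, incompat_delta = 4, sigma = 1,
                         isotype_scale = c(IgG = 1, IgM = 0.7),
                         density_effect = c(IgG.high = 1, IgG.low = 0.7,
                                            IgM.high = 0.85, IgM.low = 1),
                         crossreact_epsilon = 0.3, mislabel_rate = 0) {
  stopifnot(sigma > 0, incompat_delta >= 0,
            mislabel_rate >= 0, mislabel_rate < 0.5,
            all(isotype_scale > 0), all(density_effect > 0),
            all(c("IgG", "IgM") %in% names(isotype_scale)),
            all(c("IgG.high", "IgG.low", "IgM.high", "IgM.low") %in%
                  names(density_effect)))
  structure(list(baseline_mu = baseline_mu, incompat_delta = incompat_delta,
                 sigma = sigma, isotype_scale = isotype_scale,
                 density_effect = density_effect,
                 crossreact_epsilon = crossreact_epsilon,
                 mislabel_rate = mislabel_rate),
            class = "signal_model")
}

#' Default ABO blood-type frequencies
#'
#' Approximate U.S. population distribution, configurable everywhere it is
#' used.
#'
#' @return named probability vector over O, A, B, AB.
#' @export
default_type_freqs <- function() c(O = 0.45, A = 0.40, B = 0.11, AB = 0.04)

# Determinants foreign to a blood type under the Landsteiner rule.
foreign_determinants <- function(type) {
  switch(type,
         O = c("A", "B"), A = "B", B = "A", AB = character(0),
         stop("unknown blood type: ", type))
}

#' Simulate serum antibody profiles with blood-type structure
#'
#' For each sample with true type `t` and each component with determinant
#' `d` in \{A, B\}, the signal mean is
#' `baseline_mu + incompat_delta * isotype_scale * density_effect` when `d`
#' is foreign to `t`, and `baseline_mu + crossreact_epsilon` when `d` is
#' self; components with other determinants sit at `baseline_mu`. Gaussian
#' noise with SD `sigma` is added. Recorded blood types equal the truth
#' except with probability `mislabel_rate`, when they are flipped to a
#' uniformly chosen other type. Identical seeds give identical output.
#'
#' @param n number of samples.
#' @param components component table from [parse_component_names()] (or a
#'   character vector of names); must contain at least one A- and one
#'   B-determinant component.
#' @param model a [signal_model()].
#' @param type_freqs named probabilities over O/A/B/AB summing to 1.
#' @param seed integer RNG seed.
#' @param true_types optional character vector overriding the sampled true
#'   blood types (length `n`).
#' @param id_prefix prefix for generated sample identifiers.
#' @return list with elements `profiles` (a `glycan_profiles` object) and
#'   `truth` (named character vector sample -> true blood type).
#' @export
simulate_profiles <- function(n, components = default_component_panel(),
                              model = signal_model(),
                              type_freqs = default_type_freqs(),
                              seed = 1L, true_types = NULL,
                              id_prefix = "S") {
  if (is.character(components)) components <- parse_component_names(components)
  stopifnot(n >= 1, nrow(components) >= 1, inherits(model, "signal_model"))
  if (abs(sum(type_freqs) - 1) > 1e-9) stop("type_freqs must sum to 1")
  if (!all(c("A", "B") %in% components$determinant)) {
    stop("components must include at least one A- and one B-determinant")
  }

  set.seed(seed)
  samples <- sprintf("%s%03d", id_prefix, seq_len(n))
  types <- if (is.null(true_types)) {
    sample(names(type_freqs), n, replace = TRUE, prob = type_freqs)
  } else {
    stopifnot(length(true_types) == n)
    true_types
  }

  recorded <- types
  flip <- stats::runif(n) < model$mislabel_rate
  if (any(flip)) {
    all_types <- c("O", "A", "B", "AB")
    recorded[flip] <- vapply(types[flip], function(t) {
      sample(setdiff(all_types, t), 1L)
    }, "")
  }

  k <- nrow(components)
  # foreign indicator per (sample, component)
  foreign <- matrix(FALSE, n, k)
  selfdet <- matrix(FALSE, n, k)
  is_ab_det <- components$determinant %in% c("A", "B")
  for (i in seq_len(n)) {
    f <- foreign_determinants(types[i])
    foreign[i, ] <- components$determinant %in% f
    selfdet[i, ] <- is_ab_det & !foreign[i, ]
  }

  dens_mult <- function(iso) {
    dc <- components$density_class
    m <- rep(1, k)
    known <- !is.na(dc)
    m[known] <- model$density_effect[paste0(iso, ".", dc[known])]
    m
  }
  mean_mat <- function(iso) {
    delta <- model$incompat_delta * model$isotype_scale[[iso]] * dens_mult(iso)
    model$baseline_mu +
      foreign * rep(delta, each = n) +
      selfdet * model$crossreact_epsilon
  }
  igg <- mean_mat("IgG") + matrix(stats::rnorm(n * k, 0, model$sigma), n, k)
  igm <- mean_mat("IgM") + matrix(stats::rnorm(n * k, 0, model$sigma), n, k)
  dimnames(igg) <- dimnames(igm) <- list(samples, components$name)

  metadata <- data.frame(sample_id = samples, recorded_blood_type = recorded,
                         source = "synthetic", stringsAsFactors = FALSE)
  list(profiles = glycan_profiles(igg, igm, metadata = metadata),
       truth = stats::setNames(types, samples))
}

#' Generative model for cohort survival data
#'
#' Overall survival (OS) is drawn from a lognormal (default) or exponential
#' law whose median is `baseline_median` months, multiplied by
#' `vaccine_bo_multiplier` only for vaccine-arm patients of blood type B or
#' O, and further by `forssman_multiplier` only when such a patient is also
#' a Forssman responder. The control-arm survival law is identical across
#' blood types by construction, and the Forssman response rate does not
#' depend on blood type. Model-predicted survival (`hps_months`) is the
#' baseline median times lognormal noise, independent of blood type, so
#' OS minus prediction isolates the treatment-by-type effect.
#'
#' @param os_distribution `"lognormal"` or `"exponential"`.
#' @param baseline_median median OS in months absent any effect
#'   (default 16.3).
#' @param os_sdlog lognormal shape (SD of log OS; default 0.8).
#' @param vaccine_bo_multiplier multiplicative effect on median OS for B/O
#'   vaccine-arm patients (default 30/16.3).
#' @param forssman_multiplier additional multiplicative effect for B/O
#'   vaccine-arm Forssman responders (default 1.5).
#' @param hps_noise_sd SD, in months, of the predicted-survival noise
#'   (default 6).
#' @param forssman_response_rate probability of a Forssman response,
#'   identical for all blood types (default 0.5).
#' @param censor_rate probability a patient is administratively censored
#'   (default 0; censoring time drawn uniformly below the event time).
#' @return a list of class `survival_model`.
#' @export
survival_model <- function(os_distribution = c("lognormal", "exponential"),
                           baseline_median = 16.3, os_sdlog = 0.8,
                           vaccine_bo_multiplier = 30 / 16.3,
                           forssman_multiplier = 1.5,
                           hps_noise_sd = 6,
                           forssman_response_rate = 0.5,
                           censor_rate = 0) {
  os_distribution <- match.arg(os_distribution)
  stopifnot(baseline_median > 0, os_sdlog > 0,
            vaccine_bo_multiplier > 0, forssman_multiplier > 0,
            hps_noise_sd >= 0,
            forssman_response_rate >= 0, forssman_response_rate <= 1,
            censor_rate >= 0, censor_rate < 1)
  structure(list(os_distribution = os_distribution,
                 baseline_median = baseline_median, os_sdlog = os_sdlog,
                 vaccine_bo_multiplier = vaccine_bo_multiplier,
                 forssman_multiplier = forssman_multiplier,
                 hps_noise_sd = hps_noise_sd,
                 forssman_response_rate = forssman_response_rate,
                 censor_rate = censor_rate),
            class = "survival_model")
}

#' Simulate a two-arm patient cohort with blood-type-dependent benefit
#'
#' @param n_vaccine,n_control arm sizes (positive integers).
#' @param smodel a [survival_model()].
#' @param sigmodel a [signal_model()]; governs mislabeling of recorded
#'   blood types and, when `profiles = TRUE`, the linked antibody profiles.
#' @param type_freqs named blood-type probabilities.
#' @param seed integer RNG seed.
#' @param profiles if TRUE, also simulate a linked `glycan_profiles` object
#'   for the cohort (same seed stream).
#' @param components component panel for the linked profiles.
#' @return list with `cohort` (data.frame: `patient_id`, `arm`,
#'   `true_blood_type`, `recorded_blood_type`, `os_months`, `event`,
#'   `hps_months`, `forssman_pre`, `forssman_post`, `forssman_responder`)
#'   and, when requested, `profiles`.
#' @export
simulate_cohort <- function(n_vaccine, n_control,
                            smodel = survival_model(),
                            sigmodel = signal_model(),
                            type_freqs = default_type_freqs(),
                            seed = 1L, profiles = FALSE,
                            components = default_component_panel()) {
  stopifnot(n_vaccine >= 1, n_control >= 1,
            inherits(smodel, "survival_model"),
            inherits(sigmodel, "signal_model"))
  set.seed(seed)
  n <- n_vaccine + n_control
  ids <- sprintf("P%03d", seq_len(n))
  arm <- c(rep("vaccine", n_vaccine), rep("control", n_control))
  types <- sample(names(type_freqs), n, replace = TRUE, prob = type_freqs)

  recorded <- types
  flip <- stats::runif(n) < sigmodel$mislabel_rate
  if (any(flip)) {
    all_types <- c("O", "A", "B", "AB")
    recorded[flip] <- vapply(types[flip], function(t) {
      sample(setdiff(all_types, t), 1L)
    }, "")
  }

  responder <- stats::runif(n) < smodel$forssman_response_rate
  bo <- types %in% c("B", "O")
  med <- rep(smodel$baseline_median, n)
  eff <- arm == "vaccine" & bo
  med[eff] <- med[eff] * smodel$vaccine_bo_multiplier
  med[eff & responder] <- med[eff & responder] * smodel$forssman_multiplier

  os <- if (smodel$os_distribution == "lognormal") {
    stats::rlnorm(n, meanlog = log(med), sdlog = smodel$os_sdlog)
  } else {
    stats::rexp(n, rate = log(2) / med)
  }

  event <- rep(TRUE, n)
  cens <- stats::runif(n) < smodel$censor_rate
  if (any(cens)) {
    os[cens] <- os[cens] * stats::runif(sum(cens))
    event[cens] <- FALSE
  }

  hps_sdlog <- smodel$hps_noise_sd / smodel$baseline_median
  hps <- smodel$baseline_median * exp(stats::rnorm(n, 0, hps_sdlog))

  # Forssman total-Ig signals, log2 scale: responders rise >= 2 (>= 4-fold)
  pre <- stats::rnorm(n, 8, 0.5)
  delta <- ifelse(responder,
                  2 + stats::rexp(n, rate = 2),
                  pmin(stats::rnorm(n, 0.3, 0.5), 1.9))
  post <- pre + delta

  cohort <- data.frame(
    patient_id = ids, arm = arm,
    true_blood_type = types, recorded_blood_type = recorded,
    os_months = os, event = event, hps_months = hps,
    forssman_pre = pre, forssman_post = post,
    forssman_responder = responder,
    stringsAsFactors = FALSE
  )
  out <- list(cohort = cohort)
  if (profiles) {
    sim <- simulate_profiles(n, components = components, model = sigmodel,
                             type_freqs = type_freqs, seed = seed + 1L,
                             true_types = types, id_prefix = "P")
    sim$profiles$metadata$recorded_blood_type <- recorded
    out$profiles <- sim$profiles
  }
  out
}
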