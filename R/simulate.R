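#' Configuration for the synthetic cohort generator
#'
#' @param n sample count (>= 4).
#' @param p gene count (>= k).
#' @param k number of informative latent factors (>= 0).
#' @param effect_size scale of the true log-hazard score.
#' @param noise_sd gene-level Gaussian noise standard deviation.
#' @param baseline_scale rate of the exponential baseline hazard (per year).
#' @param censor_rate target censored fraction in [0, 1).
#' @param seed integer seed; the draw is fully reproducible from it.
#' @return A `"sim_config"` list.
#' @export
sim_config <- function(n = 300, p = 500, k = 5, effect_size = 1.5,
                       noise_sd = 1, baseline_scale = 0.2,
                       censor_rate = 0.3, seed = 1) {
  stopifnot(n >= 4, p >= k, k >= 0, censor_rate >= 0, censor_rate < 1,
            noise_sd >= 0, baseline_scale > 0)
  structure(list(n = as.integer(n), p = as.integer(p), k = as.integer(k),
                 effect_size = effect_size, noise_sd = noise_sd,
                 baseline_scale = baseline_scale, censor_rate = censor_rate,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# P(censoring time < event time) for two independent exponentials with rates
# rc (censoring) and re (event) is rc/(rc+re); averaged over samples this is
# monotone in rc, so the target censored fraction is solvable by bisection.
calibrate_censor_rate <- function(event_rates, target) {
  if (target == 0) return(0)
  f <- function(rc) mean(rc / (rc + event_rates)) - target
  lo <- 1e-12; hi <- 1
  it <- 0
  while (f(hi) < 0 && it < 200) { hi <- hi * 2; it <- it + 1 }
  if (f(hi) < 0) sc_stop("censoring-rate calibration failed for target %.3f", target)
  stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
}

#' Simulate a cohort with a planted low-dimensional risk signal
#'
#' Draws `k` standard-normal latent factors per sample, a fixed unit
#' coefficient vector `beta` on them, and embeds the factors into `p` genes
#' through a sparse loading matrix plus Gaussian noise.  Event times follow a
#' proportional-hazards model with exponential baseline,
#' `T ~ Exp(baseline_scale * exp(s_i))` with true score
#' `s_i = effect_size * beta' L_i`; independent exponential censoring is
#' calibrated by root-finding so the expected censored fraction matches
#' `censor_rate`.
#'
#' @param config a [sim_config()].
#' @return A list with elements `cohort` (a [cohort()]) and `truth`
#'   (`beta_latent`, per-sample `risk_score`, the loading matrix `W`, and the
#'   calibrated censoring rate).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n; p <- config$p; k <- config$k
  L <- matrix(stats::rnorm(n * k), n, k)
  beta <- if (k > 0) {
    b <- stats::rnorm(k); b / sqrt(sum(b^2))
  } else numeric(0)
  s <- if (k > 0) config$effect_size * drop(L %*% beta) else numeric(n) * 0
  # sparse loadings: each factor hits ~10% of genes
  W <- matrix(0, k, p)
  if (k > 0) {
    n_hit <- max(1L, ceiling(0.1 * p))
    for (j in seq_len(k)) {
      idx <- sample.int(p, n_hit)
      W[j, idx] <- stats::rnorm(n_hit)
    }
  }
  E <- matrix(stats::rnorm(n * p, sd = config$noise_sd), n, p)
  raw <- (if (k > 0) L %*% W else matrix(0, n, p)) + E
  X <- log1p(exp(raw))                     # softplus: nonnegative, monotone
  event_rate <- config$baseline_scale * exp(s)
  t_event <- stats::rexp(n, rate = event_rate)
  rc <- calibrate_censor_rate(event_rate, config$censor_rate)
  if (rc > 0) {
    t_cens <- stats::rexp(n, rate = rc)
    time <- pmin(t_event, t_cens)
    event <- as.integer(t_event <= t_cens)
  } else {
    time <- t_event
    event <- rep(1L, n)
  }
  ids <- sprintf("s%04d", seq_len(n))
  genes <- sprintf("g%04d", seq_len(p))
  ch <- cohort(X, time, event, sample_ids = ids, genes = genes,
               cancer_type = "SIM")
  ch$provenance$simulated <- list(seed = config$seed)
  list(cohort = ch,
       truth = list(beta_latent = beta, risk_score = s, W = W,
                    censor_param = rc))
}

#' Simulate several cohorts, optionally sharing signal geometry
#'
#' With `shared_latent = TRUE` all cohorts reuse the loading matrix and latent
#' coefficient vector of the first config (same signal geometry, independent
#' samples), emulating transcriptionally similar cancer types whose pooled
#' data share a prognostic axis; otherwise each cohort is an independent draw.
#'
#' @param configs named list of [sim_config()]s; names become cancer types.
#' @param shared_latent logical.
#' @return Named list with `cohorts` (list of [cohort()]) and `truths`.
#' @export
simulate_multi_cancer <- function(configs, shared_latent = TRUE) {
  if (length(configs) < 2L) sc_stop("need at least two configs")
  if (is.null(names(configs)) || any(names(configs) == ""))
    sc_stop("configs must be named by cancer type")
  out <- vector("list", length(configs)); truths <- vector("list", length(configs))
  ref <- NULL
  for (i in seq_along(configs)) {
    cfg <- configs[[i]]
    sim <- simulate_cohort(cfg)
    if (shared_latent) {
      if (is.null(ref)) ref <- sim$truth
      else {
        # redraw this cohort's expression/outcomes under the reference geometry
        sim <- resimulate_under(cfg, ref)
      }
    }
    sim$cohort$cancer_type <- names(configs)[i]
    sim$cohort$sample_ids <- paste0(names(configs)[i], "_", sim$cohort$sample_ids)
    rownames(sim$cohort$X) <- sim$cohort$sample_ids
    out[[i]] <- sim$cohort; truths[[i]] <- sim$truth
  }
  names(out) <- names(truths) <- names(configs)
  list(cohorts = out, truths = truths)
}

resimulate_under <- function(config, ref) {
  set.seed(child_seed(config$seed, 7L))
  n <- config$n; p <- config$p; k <- config$k
  stopifnot(k == length(ref$beta_latent), p == ncol(ref$W))
  L <- matrix(stats::rnorm(n * k), n, k)
  s <- config$effect_size * drop(L %*% ref$beta_latent)
  E <- matrix(stats::rnorm(n * p, sd = config$noise_sd), n, p)
  X <- log1p(exp(L %*% ref$W + E))
  event_rate <- config$baseline_scale * exp(s)
  t_event <- stats::rexp(n, rate = event_rate)
  rc <- calibrate_censor_rate(event_rate, config$censor_rate)
  if (rc > 0) {
    t_cens <- stats::rexp(n, rate = rc)
    time <- pmin(t_event, t_cens); event <- as.integer(t_event <= t_cens)
  } else { time <- t_event; event <- rep(1L, n) }
  ch <- cohort(X, time, event, sample_ids = sprintf("s%04d", seq_len(n)),
               genes = sprintf("g%04d", seq_len(p)), cancer_type = "SIM")
  list(cohort = ch,
       truth = list(beta_latent = ref$beta_latent, risk_score = s, W = ref$W,
                    censor_param = rc))
}
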