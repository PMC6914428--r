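# Synthetic cohort generator: mirror-paired regions grouped into networks,
# block-structured target correlation matrices whose homotopic and
# cross-network blocks drift linearly with age, Gaussian time series drawn
# from them, and a ground-truth record for recovery tests.

#' Simulation configuration
#'
#' Defaults describe a resting-state cohort: ages uniform over 19-80,
#' `t_len = 230` timepoints (a ~8-min run at TR = 2 s after 10 discarded
#' volumes), six canonical networks of 4 homotopic pairs each, moderate
#' within-network coupling (r = 0.5), weak between-network coupling
#' (r = 0.1) and strong homotopic coupling (r = 0.6).  Aging effects are
#' planted per network: `homotopic_age_slope` (r units per year, typically
#' negative) moves the homotopic block, `cross_network_age_slope` (typically
#' positive) moves every within-hemisphere block between the designated
#' network and the others.
#'
#' @param n_subjects cohort size.
#' @param age_range numeric length 2 (years).
#' @param networks named integer vector: homotopic pairs per network.
#' @param t_len timepoints per subject.
#' @param within_network_r baseline within-network, within-hemisphere r.
#' @param between_network_r baseline between-network r (also used for all
#'   cross-hemisphere non-homotopic entries).
#' @param homotopic_r0 homotopic pair r at the youngest age.
#' @param homotopic_age_slope scalar or per-network named vector (r/year).
#' @param cross_network_age_slope scalar or per-network named vector
#'   (r/year).
#' @param noise_sd s.d. of additional white measurement noise (0 = none;
#'   note it attenuates all correlations by `1/(1+noise_sd^2)`).
#' @param ar1 lag-1 autocorrelation of the innovations (0 = white).
#' @param fd_meanlog,fd_sdlog lognormal parameters of mean FD (mm).
#' @param fd_log_age_slope additive drift of `fd_meanlog` per year.
#' @param seed default master seed for [simulate_cohort()].
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 100,
                       age_range = c(19, 80),
                       networks = c(SMN = 4, AN = 4, VN = 4,
                                    FPN = 4, VAN = 4, DMN = 4),
                       t_len = 230,
                       within_network_r = 0.5,
                       between_network_r = 0.1,
                       homotopic_r0 = 0.6,
                       homotopic_age_slope = 0,
                       cross_network_age_slope = 0,
                       noise_sd = 0,
                       ar1 = 0,
                       fd_meanlog = log(0.08),
                       fd_sdlog = 0.4,
                       fd_log_age_slope = 0.005,
                       seed = NULL) {
  networks <- unlist(networks)  # tolerate JSON-config named lists
  expand <- function(x) {
    x <- unlist(x)
    if (length(x) == 1 && is.null(names(x)))
      return(stats::setNames(rep(x, length(networks)), names(networks)))
    out <- stats::setNames(rep(0, length(networks)), names(networks))
    out[names(x)] <- x
    out
  }
  cfg <- list(n_subjects = n_subjects, age_range = as.numeric(age_range),
              networks = networks, t_len = t_len,
              within_network_r = within_network_r,
              between_network_r = between_network_r,
              homotopic_r0 = homotopic_r0,
              homotopic_age_slope = expand(homotopic_age_slope),
              cross_network_age_slope = expand(cross_network_age_slope),
              noise_sd = noise_sd, ar1 = ar1,
              fd_meanlog = fd_meanlog, fd_sdlog = fd_sdlog,
              fd_log_age_slope = fd_log_age_slope, seed = seed)
  class(cfg) <- "sim_config"
  # correlations must stay inside (-1, 1) across the whole age range
  for (age in cfg$age_range) {
    s <- sim_target_entries(cfg, age)
    if (any(abs(unlist(s)) >= 1))
      stop("configuration error: slopes push correlations outside (-1, 1)")
  }
  cfg
}

# target entry values at one age
sim_target_entries <- function(cfg, age) {
  da <- age - cfg$age_range[1]
  list(within = cfg$within_network_r,
       between = cfg$between_network_r,
       cross = cfg$between_network_r +
         outer(cfg$cross_network_age_slope, cfg$cross_network_age_slope,
               "+") * da,
       homotopic = cfg$homotopic_r0 + cfg$homotopic_age_slope * da)
}

#' Region table implied by a simulation configuration
#'
#' Left block first, then right, each ordered by pair index; names carry the
#' network membership.
#'
#' @param cfg a [sim_config()].
#' @return a [region_table()].
#' @export
sim_region_table <- function(cfg) {
  n_pairs <- sum(cfg$networks)
  net <- rep(names(cfg$networks), cfg$networks)
  region_table(
    region_id = 0:(2 * n_pairs - 1),
    hemisphere = rep(c("L", "R"), each = n_pairs),
    pair_index = c(0:(n_pairs - 1), 0:(n_pairs - 1)),
    name = paste0(rep(net, 2), "_", rep(c("L", "R"), each = n_pairs), "_",
                  c(0:(n_pairs - 1), 0:(n_pairs - 1)))
  )
}

# network index (1..K) per region, in region-table order
sim_true_labels <- function(cfg) {
  rep(rep(seq_along(cfg$networks), cfg$networks), 2)
}

#' Target correlation matrix at a given age
#'
#' Block structure over `2R` regions (L block then R block, pair order):
#' `within_network_r` inside each network per hemisphere; between-network
#' within-hemisphere blocks at `between_network_r` plus the summed
#' `cross_network_age_slope` increments of the two networks; homotopic pair
#' entries at `homotopic_r0 + homotopic_age_slope * (age - age_min)`; all
#' other cross-hemisphere entries at `between_network_r`.  Repaired to the
#' nearest positive-definite correlation matrix by eigenvalue clipping;
#' repairs moving any entry by more than 0.05 are rejected.
#'
#' @param cfg a [sim_config()].
#' @param age age in years.
#' @return `2R x 2R` correlation matrix (attribute `shrinkage` = largest
#'   entry change from PD repair).
#' @export
build_covariance <- function(cfg, age) {
  ent <- sim_target_entries(cfg, age)
  labs_h <- rep(seq_along(cfg$networks), cfg$networks)  # per pair
  n_pairs <- length(labs_h)
  same_net <- outer(labs_h, labs_h, "==")
  # within-hemisphere block
  wh <- matrix(0, n_pairs, n_pairs)
  wh[same_net] <- ent$within
  wh[!same_net] <- ent$cross[cbind(labs_h[row(wh)[!same_net]],
                                   labs_h[col(wh)[!same_net]])]
  diag(wh) <- 1
  # cross-hemisphere block: homotopic pairs on the diagonal
  ch <- matrix(ent$between, n_pairs, n_pairs)
  diag(ch) <- ent$homotopic[labs_h]
  s <- rbind(cbind(wh, ch), cbind(t(ch), wh))
  shrink <- 0
  ev <- eigen(s, symmetric = TRUE)
  if (min(ev$values) < 1e-8) {
    vals <- pmax(ev$values, 1e-8)
    s2 <- ev$vectors %*% (vals * t(ev$vectors))
    d <- 1 / sqrt(diag(s2))
    s2 <- s2 * outer(d, d)
    shrink <- max(abs(s2 - s))
    if (shrink > 0.05)
      stop("configuration error: covariance not positive definite ",
           "(required shrinkage ", signif(shrink, 3), " > 0.05)")
    s <- (s2 + t(s2)) / 2
  }
  attr(s, "shrinkage") <- shrink
  s
}

#' Simulate one subject
#'
#' `t_len` draws from a multivariate normal with the age-specific target
#' covariance (optionally AR(1)-correlated over time), plus optional white
#' measurement noise; sex ~ Bernoulli(0.5); mean FD lognormal with an
#' age-drifting location.
#'
#' @param cfg a [sim_config()].
#' @param age age in years.
#' @param seed integer seed (`NULL` = use current RNG state).
#' @param subject_id id string.
#' @return a [subject_record()].
#' @export
simulate_subject <- function(cfg, age, seed = NULL, subject_id = "sim") {
  s <- build_covariance(cfg, age)
  cl <- chol(s)
  with_seed(seed, {
    n <- nrow(s)
    innov <- matrix(stats::rnorm(cfg$t_len * n), cfg$t_len, n)
    if (cfg$ar1 != 0) {
      phi <- cfg$ar1
      for (t in 2:cfg$t_len)
        innov[t, ] <- phi * innov[t - 1, ] + sqrt(1 - phi^2) * innov[t, ]
    }
    ts <- innov %*% cl
    if (cfg$noise_sd > 0)
      ts <- ts + matrix(stats::rnorm(cfg$t_len * n, sd = cfg$noise_sd),
                        cfg$t_len, n)
    subject_record(
      subject_id = subject_id, timeseries = ts, age = age,
      sex = stats::rbinom(1, 1, 0.5),
      mean_fd = stats::rlnorm(1, cfg$fd_meanlog +
                                cfg$fd_log_age_slope * (age - cfg$age_range[1]),
                              cfg$fd_sdlog))
  })
}

#' Simulate a full cohort with ground truth
#'
#' Ages are drawn uniformly over `cfg$age_range`.  The returned `truth`
#' record carries the planted partition and slopes for recovery tests.
#'
#' @param cfg a [sim_config()].
#' @param seed master seed (defaults to `cfg$seed`).
#' @return list with `subjects` (list of [subject_record()]), `regions`,
#'   `truth` (labels, network names, slopes) and `config`.
#' @export
simulate_cohort <- function(cfg, seed = cfg$seed) {
  regions <- sim_region_table(cfg)
  ages <- with_seed(seed, stats::runif(cfg$n_subjects, cfg$age_range[1],
                                       cfg$age_range[2]))
  subjects <- vector("list", cfg$n_subjects)
  for (i in seq_len(cfg$n_subjects)) {
    subjects[[i]] <- simulate_subject(
      cfg, ages[i],
      seed = if (is.null(seed)) NULL else derive_seed(seed, i),
      subject_id = sprintf("sub-%04d", i))
  }
  truth <- list(labels = sim_true_labels(cfg),
                network_names = stats::setNames(names(cfg$networks),
                                                seq_along(cfg$networks)),
                homotopic_age_slope = cfg$homotopic_age_slope,
                cross_network_age_slope = cfg$cross_network_age_slope)
  list(subjects = subjects, regions = regions, truth = truth, config = cfg)
}

#' Covariate table of a cohort
#'
#' @param subjects list of [subject_record()]s.
#' @return data.frame with subject_id, age, sex, mean_fd.
#' @export
cohort_covariates <- function(subjects) {
  data.frame(
    subject_id = vapply(subjects, function(s) s$subject_id, character(1)),
    age = vapply(subjects, function(s) s$age, numeric(1)),
    sex = vapply(subjects, function(s) s$sex, integer(1)),
    mean_fd = vapply(subjects, function(s) s$mean_fd, numeric(1)),
    stringsAsFactors = FALSE)
}
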