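#' Load a piecewise-constant population-size trajectory
#'
#' @param path TSV with columns `N` (diploid size) and `generations`
#'   (epoch duration), one row per epoch ordered past -> present.
#' @param drop_terminal drop the first and last rows (terminal PSMC-style
#'   intervals are prone to runaway behaviour).
#' @return data.frame of class `pop_trajectory` with columns `N`, `t`;
#'   attribute `terminal_dropped` records the flag.
#' @export
load_trajectory <- function(path, drop_terminal = FALSE) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t")
  names(tab)[1:2] <- c("N", "t")
  pop_trajectory(tab$N, tab$t, drop_terminal = drop_terminal)
}

#' Construct a population trajectory in code
#' @param N diploid sizes per epoch (past -> present).
#' @param t epoch durations in generations.
#' @param drop_terminal drop first and last epochs.
#' @return data.frame of class `pop_trajectory`.
#' @export
pop_trajectory <- function(N, t, drop_terminal = FALSE) {
  if (!length(N) || length(N) != length(t)) stop("need matching N and t vectors")
  bad <- which(N < 2 | t < 1)
  if (length(bad)) stop("invalid trajectory row(s): ", paste(bad, collapse = ", "),
                        " (need N >= 2, t >= 1)")
  if (drop_terminal) {
    if (length(N) <= 2) stop("dropping terminal epochs leaves no trajectory")
    N <- N[-c(1, length(N))]
    t <- t[-c(1, length(t))]
  }
  out <- data.frame(N = as.numeric(N), t = as.numeric(t))
  class(out) <- c("pop_trajectory", "data.frame")
  attr(out, "terminal_dropped") <- drop_terminal
  out
}

#' Write a trajectory TSV
#' @param traj a `pop_trajectory`.
#' @param path output file.
#' @export
write_trajectory <- function(traj, path) {
  utils::write.table(data.frame(N = traj$N, generations = traj$t), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Draw selection coefficients from a gamma DFE
#'
#' Selection coefficients are `s = -Gamma(shape, scale = |mean|/shape)`,
#' so all draws are non-positive with expectation `dfe_mean`.
#'
#' @param n number of draws.
#' @param dfe_mean mean selection coefficient (negative; default -0.043).
#' @param dfe_shape gamma shape (default 0.23).
#' @return numeric vector of `n` non-positive selection coefficients.
#' @export
sample_dfe <- function(n, dfe_mean = -0.043, dfe_shape = 0.23) {
  stopifnot(n >= 1)
  if (dfe_shape <= 0) stop("dfe_shape must be > 0")
  if (dfe_mean >= 0) stop("dfe_mean must be negative")
  -stats::rgamma(n, shape = dfe_shape, scale = abs(dfe_mean) / dfe_shape)
}

#' Simulation parameters for the forward Wright-Fisher model
#'
#' Defaults suit ancient-elephantid-scale analyses: per-site mutation
#' rate 3.8e-8 per generation, gamma DFE with mean -0.043 and shape 0.23
#' (human-estimated), dominance 0.5, 100 sites per class, 460 replicates,
#' burn-in 100,000 generations (expressed in unrescaled units).
#'
#' @param mu per-site per-generation mutation rate.
#' @param dfe_mean,dfe_shape gamma DFE parameters (mean < 0, shape > 0).
#' @param h dominance coefficient in `[0, 1]`.
#' @param sites_per_class sites per replicate per class.
#' @param replicates number of replicates.
#' @param burn_in burn-in generations at the first epoch's size
#'   (unrescaled; a floor of 10N rescaled generations is enforced).
#' @param rescale_Q population rescaling factor `Q >= 1`: simulations run at
#'   `N/Q`, `t/Q`, `mu*Q`, `s*Q`.
#' @param sample_window generations before the end over which heterozygosity
#'   is time-averaged (rescaled units; 0 samples only the final generation).
#' @param sample_every thinning interval within the sample window.
#' @return list of class `sim_params`.
#' @export
sim_params <- function(mu = 3.8e-8, dfe_mean = -0.043, dfe_shape = 0.23,
                       h = 0.5, sites_per_class = 100, replicates = 460,
                       burn_in = 1e5, rescale_Q = 1,
                       sample_window = 0, sample_every = 100) {
  stopifnot(mu > 0, dfe_mean < 0, dfe_shape > 0, h >= 0, h <= 1,
            sites_per_class >= 1, replicates >= 1, rescale_Q >= 1)
  if (mu * rescale_Q >= 0.1) stop("mu * Q must be < 0.1 (rescaling invalid)")
  structure(list(mu = mu, dfe_mean = dfe_mean, dfe_shape = dfe_shape, h = h,
                 sites_per_class = sites_per_class, replicates = replicates,
                 burn_in = burn_in, rescale_Q = rescale_Q,
                 sample_window = sample_window, sample_every = sample_every),
            class = "sim_params")
}

# One Wright-Fisher generation for vectors of derived-allele frequencies.
# Deterministic viability selection (fitnesses 1, 1+hs, 1+s), symmetric
# recurrent mutation at rate mu, then binomial drift over 2N gametes.
wf_generation <- function(q, s, h, mu, N) {
  wAA <- 1 + s
  wAa <- 1 + h * s
  num <- q * q * wAA + q * (1 - q) * wAa
  den <- q * q * wAA + 2 * q * (1 - q) * wAa + (1 - q) * (1 - q)
  qs <- num / den
  qm <- qs * (1 - mu) + (1 - qs) * mu
  stats::rbinom(length(q), 2 * N, qm) / (2 * N)
}

#' Forward Wright-Fisher simulation of neutral and selected site classes
#'
#' Sites evolve independently (free recombination) as biallelic
#' Wright-Fisher processes with deterministic selection (genotype fitnesses
#' 1, 1+hs, 1+s for the derived allele), symmetric recurrent mutation, and
#' binomial drift, through a burn-in at the first epoch's size followed by
#' the supplied trajectory. Rescaling by `Q` maps `N -> N/Q`, `t -> t/Q`,
#' `mu -> mu Q`, `s -> s Q`. Heterozygosity per site is `2q(1-q)`.
#'
#' @param trajectory a `pop_trajectory` (past -> present).
#' @param params a `sim_params`.
#' @param s_fixed optional fixed selection coefficient for the selected
#'   class (unrescaled); default draws per-site coefficients from the gamma
#'   DFE. Rescaled DFE draws below -1 are treated as lethal (clamped to -1);
#'   a *fixed* s with `|sQ| >= 1` is rejected.
#' @param record_epochs record per-replicate class means at each epoch end.
#' @param init initial allele frequencies: `"zero"` starts all sites fixed
#'   for the ancestral allele; `"stationary"` warm-starts the *neutral*
#'   class from the symmetric-mutation stationary law Beta(4Nmu, 4Nmu) at
#'   the first epoch's (rescaled) size, useful when equilibration from zero
#'   would dominate the run time. The selected class always starts at zero.
#' @return list of class `sim_result`: `H_neutral`, `H_selected`
#'   (replicate-length vectors of time-averaged final heterozygosity),
#'   `epoch_H` (matrix replicate x epoch per class, if recorded), `params`,
#'   `trajectory`.
#' @export
simulate_forward <- function(trajectory, params, s_fixed = NULL,
                             record_epochs = FALSE,
                             init = c("zero", "stationary")) {
  init <- match.arg(init)
  stopifnot(inherits(trajectory, "pop_trajectory"), inherits(params, "sim_params"))
  Q <- params$rescale_Q
  mu <- params$mu * Q
  N_epochs <- pmax(2, round(trajectory$N / Q))
  t_epochs <- pmax(1, round(trajectory$t / Q))
  n_per_class <- params$replicates * params$sites_per_class

  if (!is.null(s_fixed)) {
    s_sel <- rep(s_fixed * Q, n_per_class)
    if (any(abs(s_sel) >= 1)) stop("|s * Q| >= 1 after rescaling: invalid")
  } else {
    s_sel <- pmax(sample_dfe(n_per_class, params$dfe_mean, params$dfe_shape) * Q, -1)
  }
  s <- c(rep(0, n_per_class), s_sel)
  q <- rep(0, 2 * n_per_class)
  if (init == "stationary") {
    a <- 4 * N_epochs[1] * mu
    q[seq_len(n_per_class)] <- stats::rbeta(n_per_class, a, a)
  }
  h <- params$h

  burn <- max(ceiling(params$burn_in / Q), 10 * N_epochs[1])
  for (g in seq_len(burn)) q <- wf_generation(q, s, h, mu, N_epochs[1])

  epoch_H <- NULL
  if (record_epochs) {
    epoch_H <- list(neutral = matrix(NA_real_, params$replicates, nrow(trajectory)),
                    selected = matrix(NA_real_, params$replicates, nrow(trajectory)))
  }
  # accumulate time-averaged H over the sampling window of the final epoch
  acc <- rep(0, 2 * n_per_class)
  n_acc <- 0L
  total_gens <- sum(t_epochs)
  gen_done <- 0L
  for (e in seq_along(N_epochs)) {
    N <- N_epochs[e]
    for (g in seq_len(t_epochs[e])) {
      q <- wf_generation(q, s, h, mu, N)
      gen_done <- gen_done + 1L
      rem <- total_gens - gen_done
      if (rem < params$sample_window &&
          (rem %% params$sample_every == 0L || rem == 0L)) {
        acc <- acc + 2 * q * (1 - q)
        n_acc <- n_acc + 1L
      }
    }
    if (record_epochs) {
      Hsite <- 2 * q * (1 - q)
      epoch_H$neutral[, e] <- rep_means_block(Hsite[seq_len(n_per_class)],
                                              params$replicates,
                                              params$sites_per_class)
      epoch_H$selected[, e] <- rep_means_block(Hsite[n_per_class + seq_len(n_per_class)],
                                               params$replicates,
                                               params$sites_per_class)
    }
  }
  if (n_acc == 0L) {
    acc <- 2 * q * (1 - q)
    n_acc <- 1L
  }
  Hsite <- acc / n_acc
  out <- list(
    H_neutral = rep_means_block(Hsite[seq_len(n_per_class)],
                                params$replicates, params$sites_per_class),
    H_selected = rep_means_block(Hsite[n_per_class + seq_len(n_per_class)],
                                 params$replicates, params$sites_per_class),
    epoch_H = epoch_H, params = params, trajectory = trajectory)
  class(out) <- "sim_result"
  out
}

# mean over sites within each replicate; sites are laid out replicate-major
# (site index varies fastest within a replicate block)
rep_means_block <- function(x, replicates, sites) {
  colMeans(matrix(x, nrow = sites, ncol = replicates))
}

#' Closed-form neutral heterozygosity decay under a trajectory
#'
#' Neutral heterozygosity decays by a factor `(1 - 1/(2N))^t` per epoch.
#'
#' @param H0 starting heterozygosity in `[0, 1]`.
#' @param trajectory a `pop_trajectory`.
#' @return numeric vector of expected H at the end of each epoch.
#' @export
expected_neutral_decay <- function(H0, trajectory) {
  stopifnot(H0 >= 0, H0 <= 1)
  H0 * cumprod((1 - 1 / (2 * trajectory$N))^trajectory$t)
}

#' Summarize simulation replicates
#'
#' @param result a `sim_result`.
#' @param n_boot bootstrap resamples for the percentile CI of the ratio.
#' @param conf confidence level (default 0.95).
#' @return list: `mean_Hs` (neutral-class mean), `mean_Hn` (selected-class
#'   mean), `ratio` (ratio of means, Hn/Hs), `ci` (percentile bootstrap over
#'   replicates), `n_replicates`.
#' @export
summarize_replicates <- function(result, n_boot = 1000, conf = 0.95) {
  hn <- result$H_selected
  hs <- result$H_neutral
  stopifnot(length(hs) >= 2, length(hs) == length(hn))
  mean_hs <- mean(hs)
  mean_hn <- mean(hn)
  ratio <- if (mean_hs > 0) mean_hn / mean_hs else NA_real_
  ci <- c(NA_real_, NA_real_)
  if (!is.na(ratio)) {
    R <- length(hs)
    boots <- vapply(seq_len(n_boot), function(b) {
      i <- sample.int(R, R, replace = TRUE)
      if (mean(hs[i]) > 0) mean(hn[i]) / mean(hs[i]) else NA_real_
    }, numeric(1))
    ci <- unname(stats::quantile(boots, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                                 na.rm = TRUE))
  }
  list(mean_Hs = mean_hs, mean_Hn = mean_hn, ratio = ratio, ci = ci,
       n_replicates = length(hs))
}
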