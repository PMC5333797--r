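#!/usr/bin/env Rscript
# Forward Wright-Fisher expectations for the census: equilibrium Hn/Hs at
# the pre-decline population size under the gamma DFE, the closed-form
# neutral decay under a decline to N = 300, and the post-decline rise of
# Hn/Hs. Population sizes are rescaled by Q = 10 throughout; replicate and
# site counts here are a fast desk-scale version of the full run in
# scripts/acceptance.R.

suppressPackageStartupMessages(library(meltdownr))

out_dir <- "results/demography"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
set.seed(2022)

# three-epoch toy trajectory: ancestral 10^4, decline, 300 at the end
traj <- pop_trajectory(c(1e4, 3e3, 300), c(2000, 1000, 300))
write_trajectory(traj, file.path(out_dir, "trajectory.tsv"))

# closed-form neutral decay along the trajectory from the equilibrium level
H0 <- 0.00161
decay <- expected_neutral_decay(H0, traj)
message(sprintf("closed-form neutral H after each epoch: %s",
                paste(signif(decay, 4), collapse = ", ")))

p <- sim_params(mu = 3.8e-8, dfe_mean = -0.043, dfe_shape = 0.23, h = 0.5,
                sites_per_class = 60, replicates = 150, burn_in = 1e5,
                rescale_Q = 10)
r <- simulate_forward(traj, p, record_epochs = TRUE)
ratios <- vapply(seq_len(nrow(traj)), function(e) {
  mean(r$epoch_H$selected[, e]) / mean(r$epoch_H$neutral[, e])
}, numeric(1))
summ <- summarize_replicates(r)
message(sprintf("epoch-end Hn/Hs along the decline: %s",
                paste(round(ratios, 3), collapse = " -> ")))
message(sprintf("final mean Hs = %.5g, Hn = %.5g, ratio %.3f (95%% CI %.3f-%.3f)",
                summ$mean_Hs, summ$mean_Hn, summ$ratio, summ$ci[1], summ$ci[2]))
utils::write.table(
  data.frame(epoch = seq_len(nrow(traj)), N = traj$N, t = traj$t,
             H_neutral = colMeans(r$epoch_H$neutral),
             H_selected = colMeans(r$epoch_H$selected),
             ratio = ratios, closed_form_neutral = decay),
  file.path(out_dir, "epoch_summaries.tsv"), sep = "\t", quote = FALSE,
  row.names = FALSE)
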