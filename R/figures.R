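#' Reproduce the simulation summary figures
#'
#' Re-runs the simulation studies behind the package's validation figures
#' and writes, per figure, a tab-delimited summary (mean and 5th/95th
#' percentile per condition and estimator) and a rendered PDF plot.
#'
#' * `fig2` - analytical ceiling vs true ceiling (correlation and R-squared)
#'   across noise-variance levels, i.i.d. noise, identity estimator.
#' * `fig3` - analytic vs Monte Carlo ceiling agreement, i.i.d. noise.
#' * `fig4` - all five estimators vs the true ceiling, i.i.d. noise.
#' * `fig5` - estimators under AR(1) noise across lag-1 levels.
#' * `fig6` - estimators across non-stationarity factors.
#' * `fig7` - estimators under AR(0.25) noise plus run-to-run response
#'   variability across noise levels.
#' * `fig8` - model accuracy vs the ceiling across training sizes and
#'   ridge penalties.
#'
#' @param which Character vector of figure ids (`"fig2"` ... `"fig8"`).
#' @param scale Fraction in `(0, 1]` scaling replications and (for pooled
#'   scenarios) voxels; 1 reproduces the full-size experiments.
#' @param outdir Output directory (created if missing).
#' @param seed Master seed.
#' @return Invisibly, a named list of summary tables.
#' @export
reproduce_figures <- function(which = paste0("fig", 2:8), scale = 0.25,
                              outdir = "figures", seed = 1) {
  stopifnot(scale > 0, scale <= 1)
  which <- match.arg(which, paste0("fig", 2:8), several.ok = TRUE)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  reps <- max(2L, as.integer(round(100 * scale)))
  vox <- max(50L, as.integer(round(1000 * scale)))
  out <- list()

  scen <- function(...) scenario_spec(..., n_replications = reps,
                                      n_voxels = vox, seed = seed)
  grid_run <- function(specs, cond_name, cond_vals, ...) {
    tabs <- mapply(function(sp, cv) {
      r <- run_scenario(sp, ...)
      s <- r$summary
      s[[cond_name]] <- cv
      s
    }, specs, cond_vals, SIMPLIFY = FALSE)
    do.call(rbind, tabs)
  }

  noise_vars <- c(1, 5, 10, 20, 40)
  if ("fig2" %in% which) {
    specs <- lapply(noise_vars, function(nv) scen("iid", snr = 1 / nv))
    tab <- grid_run(specs, "noise_variance", noise_vars, estimators = "ols")
    out$fig2 <- tab
    write_result_table(tab, file.path(outdir, "fig2_summary.tsv"))
    plot_band_figure(tab, "noise_variance", file.path(outdir, "fig2.pdf"),
                     xlab = "noise variance", r2_panel = TRUE)
  }
  if ("fig3" %in% which) {
    specs <- lapply(noise_vars, function(nv) scen("iid", snr = 1 / nv))
    tab <- grid_run(specs, "noise_variance", noise_vars, estimators = "ols",
                    methods = c("analytic", "mc"))
    out$fig3 <- tab
    write_result_table(tab, file.path(outdir, "fig3_summary.tsv"))
    grDevices::pdf(file.path(outdir, "fig3.pdf"), width = 7, height = 4)
    a <- tab[tab$method == "analytic", ]; m <- tab[tab$method == "monte_carlo", ]
    graphics::plot(a$mean, m$mean, xlab = "analytic NC", ylab = "Monte Carlo NC",
                   pch = 19, col = "steelblue"); graphics::abline(0, 1, col = "grey")
    grDevices::dev.off()
  }
  if ("fig4" %in% which) {
    specs <- lapply(noise_vars, function(nv) scen("iid", snr = 1 / nv))
    tab <- grid_run(specs, "noise_variance", noise_vars)
    out$fig4 <- tab
    write_result_table(tab, file.path(outdir, "fig4_summary.tsv"))
    plot_band_figure(tab, "noise_variance", file.path(outdir, "fig4.pdf"),
                     xlab = "noise variance")
  }
  if ("fig5" %in% which) {
    lags <- c(0.2, 0.4, 0.6, 0.8)
    specs <- lapply(lags, function(a) scen("ar1", snr = 1, ar_coefficient = a))
    tab <- grid_run(specs, "lag1", lags)
    out$fig5 <- tab
    write_result_table(tab, file.path(outdir, "fig5_summary.tsv"))
    plot_band_figure(tab, "lag1", file.path(outdir, "fig5.pdf"),
                     xlab = "lag-1 autocorrelation")
  }
  if ("fig6" %in% which) {
    factors <- c(1, 1.5, 2, 2.5, 3)
    specs <- lapply(factors, function(f)
      scen("nonstationary", snr = 1, nst_factor = f))
    tab <- grid_run(specs, "nst_factor", factors)
    out$fig6 <- tab
    write_result_table(tab, file.path(outdir, "fig6_summary.tsv"))
    plot_band_figure(tab, "nst_factor", file.path(outdir, "fig6.pdf"),
                     xlab = "non-stationarity factor")
  }
  if ("fig7" %in% which) {
    specs <- lapply(noise_vars, function(nv)
      scen("ar1_run_effects", snr = 1 / nv, ar_coefficient = 0.25))
    tab <- grid_run(specs, "noise_variance", noise_vars)
    out$fig7 <- tab
    write_result_table(tab, file.path(outdir, "fig7_summary.tsv"))
    plot_band_figure(tab, "noise_variance", file.path(outdir, "fig7.pdf"),
                     xlab = "noise variance")
  }
  if ("fig8" %in% which) {
    tab_n <- regularization_experiment(n_replications = reps, seed = seed)
    grid <- 10^seq(-2, 4, by = 0.5)
    tab_l <- regularization_experiment(n_train = 126L, lambdas = grid,
                                       n_replications = reps, seed = seed + 1)
    agg <- function(t, by) {
      do.call(rbind, lapply(split(t, t[by]), function(s) {
        data.frame(s[1, by, drop = FALSE],
                   rho_model = mean(s$rho_model),
                   rho_model_p5 = stats::quantile(s$rho_model, 0.05),
                   rho_model_p95 = stats::quantile(s$rho_model, 0.95),
                   rho_nc = mean(s$rho_nc), row.names = NULL)
      }))
    }
    s_n <- agg(tab_n, c("n_train", "lambda")); s_l <- agg(tab_l, "lambda")
    s_n <- s_n[order(s_n$lambda, s_n$n_train), ]
    s_l <- s_l[order(s_l$lambda), ]
    out$fig8 <- list(by_n_train = s_n, by_lambda = s_l)
    write_result_table(s_n, file.path(outdir, "fig8_summary.tsv"))
    write_result_table(s_l, file.path(outdir, "fig8_lambda_summary.tsv"))
    grDevices::pdf(file.path(outdir, "fig8.pdf"), width = 9, height = 4)
    graphics::par(mfrow = c(1, 2))
    lam <- sort(unique(s_n$lambda))
    graphics::matplot(sort(unique(s_n$n_train)),
                      cbind(sapply(lam, function(l) s_n$rho_model[s_n$lambda == l]),
                            s_n$rho_nc[s_n$lambda == lam[1]]),
                      type = "b", pch = 19, lty = 1, xlab = "training stimuli",
                      ylab = "correlation", col = c("forestgreen", "firebrick", "blue"))
    graphics::legend("bottomright", bty = "n", lty = 1, pch = 19,
                     col = c("forestgreen", "firebrick", "blue"),
                     legend = c(sprintf("lambda=%g", lam), "noise ceiling"))
    graphics::plot(log10(s_l$lambda), s_l$rho_model, type = "b", pch = 19,
                   col = "firebrick", xlab = "log10(lambda)", ylab = "correlation",
                   ylim = range(c(s_l$rho_model, s_l$rho_nc)))
    graphics::abline(h = mean(s_l$rho_nc), col = "blue")
    grDevices::dev.off()
  }
  invisible(out)
}

# mean + [5,95] band plot, one panel per estimator, true ceiling in red
plot_band_figure <- function(tab, cond, path, xlab = cond, r2_panel = FALSE) {
  ests <- unique(tab$estimator)
  grDevices::pdf(path, width = 2.5 * length(ests) + 2, height = if (r2_panel) 7 else 4)
  on.exit(grDevices::dev.off())
  graphics::par(mfrow = c(if (r2_panel) 2 else 1, max(length(ests), 1)))
  for (e in ests) {
    s <- tab[tab$estimator == e, ]
    s <- s[order(s[[cond]]), ]
    graphics::plot(s[[cond]], s$mean, type = "l", col = "blue", ylim = c(0, 1),
                   xlab = xlab, ylab = "noise ceiling (rho)", main = e)
    graphics::polygon(c(s[[cond]], rev(s[[cond]])), c(s$true_p5, rev(s$true_p95)),
                      col = grDevices::adjustcolor("grey", 0.5), border = NA)
    graphics::lines(s[[cond]], s$true_mean, col = "red")
    graphics::lines(s[[cond]], s$mean, col = "blue")
    graphics::lines(s[[cond]], s$p5, col = "blue", lty = 2)
    graphics::lines(s[[cond]], s$p95, col = "blue", lty = 2)
  }
  if (r2_panel) {
    for (e in ests) {
      s <- tab[tab$estimator == e, ]
      s <- s[order(s[[cond]]), ]
      graphics::plot(s[[cond]], s$mean^2, type = "l", col = "blue", ylim = c(0, 1),
                     xlab = xlab, ylab = "noise ceiling (R2)", main = e)
      graphics::lines(s[[cond]], s$true_mean^2, col = "red")
    }
  }
  invisible(path)
}
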